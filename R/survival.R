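#' Kaplan-Meier product-limit estimator
#'
#' Implements the product-limit estimate from first principles:
#' `S(t_k) = prod_{j <= k} (1 - d_j / n_j)` over the distinct times `t_j`
#' carrying at least one event, with `d_j` events among the `n_j` subjects
#' at risk just before `t_j`. A subject censored at time `t` stays in the
#' risk set of an event at the same `t` (events before censorings at
#' ties).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (0 = censored).
#' @return a [KMCurve-class]. With no events the curve has no time points
#'   and the estimate is identically 1.
#' @examples
#' kmEstimator(c(1, 2, 3), c(1, 1, 1))   # S = 2/3, 1/3, 0
#' @export
kmEstimator <- function(time, event) {
    if (is.data.frame(time)) { event <- time$event; time <- time$time }
    if (!length(time)) stop("no survival records")
    stopifnot(length(time) == length(event), all(time > 0),
              all(event %in% c(0, 1)))
    ut <- sort(unique(time[event == 1]))
    if (!length(ut))
        return(new("KMCurve", time = numeric(0), surv = numeric(0),
                   nRisk = numeric(0), nEvent = numeric(0)))
    nRisk <- vapply(ut, function(t) sum(time >= t), numeric(1))
    nEvent <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
    surv <- cumprod(1 - nEvent / nRisk)
    new("KMCurve", time = ut, surv = surv, nRisk = nRisk, nEvent = nEvent)
}

setMethod("show", "KMCurve", function(object) {
    cat("KMCurve: ", length(object@time), " event time(s)\n", sep = "")
    if (length(object@time))
        print(data.frame(time = object@time, n.risk = object@nRisk,
                         n.event = object@nEvent,
                         surv = signif(object@surv, 4)), row.names = FALSE)
})

#' Two-group log-rank test
#'
#' At every distinct pooled event time, the observed events in the "high"
#' group are compared with their hypergeometric expectation given the
#' margins; the statistic is `(O - E)^2 / V` summed over times, referred
#' to the chi-square distribution on 1 degree of freedom.
#'
#' @param timeHigh,eventHigh,timeLow,eventLow follow-up times and 0/1
#'   event indicators for the two groups. The first argument may instead
#'   be a `data.frame` with `time` and `event` columns (then the third
#'   must be too).
#' @return a [LogRankResult-class].
#' @examples
#' hi <- data.frame(time = c(1, 2, 3), event = 1)
#' lo <- data.frame(time = c(4, 5, 6), event = 1)
#' logrankTest(hi, lo)
#' @export
logrankTest <- function(timeHigh, eventHigh = NULL, timeLow = NULL,
                        eventLow = NULL) {
    if (is.data.frame(timeHigh)) {
        lo <- timeLow
        if (!is.data.frame(lo)) stop("both groups must be data frames")
        eventHigh <- timeHigh$event; timeHigh <- timeHigh$time
        eventLow <- lo$event; timeLow <- lo$time
    }
    if (!length(timeHigh) || !length(timeLow))
        stop("both groups must be non-empty")
    if (sum(eventHigh) + sum(eventLow) == 0)
        stop("no events")
    ut <- sort(unique(c(timeHigh[eventHigh == 1], timeLow[eventLow == 1])))
    o <- e <- v <- 0
    for (t in ut) {
        n1 <- sum(timeHigh >= t); n0 <- sum(timeLow >= t)
        d1 <- sum(timeHigh == t & eventHigh == 1)
        d0 <- sum(timeLow == t & eventLow == 1)
        n <- n1 + n0; d <- d1 + d0
        if (n < 2) next
        o <- o + d1
        e <- e + d * n1 / n
        v <- v + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
    }
    chi <- if (v > 0) (o - e)^2 / v else 0
    new("LogRankResult", chiSquare = chi,
        pValue = max(stats::pchisq(chi, 1, lower.tail = FALSE),
                     .Machine$double.xmin),
        nHigh = length(timeHigh), nLow = length(timeLow))
}

setMethod("show", "LogRankResult", function(object) {
    cat(sprintf("Log-rank: chi-square = %.4g (1 df), p = %.4g (n = %d vs %d)\n",
                object@chiSquare, object@pValue, object@nHigh, object@nLow))
})

#' Split survival records by a gene's expression
#'
#' `high` holds the records with expression strictly above the cutoff,
#' `low` those at or below it. With `method = "median"` the cutoff is the
#' sample median; with `method = "quantile"` the `q` quantile.
#'
#' @param records survival `data.frame` (columns `time`, `event`, one
#'   column per gene).
#' @param gene gene column to split on.
#' @param method `"median"` or `"quantile"`.
#' @param q quantile in (0, 1) for `method = "quantile"`.
#' @return list with `high`, `low` (record subsets) and `cutoff`.
#' @export
dichotomizeByExpression <- function(records, gene,
                                    method = c("median", "quantile"),
                                    q = 0.5) {
    method <- match.arg(method)
    if (!gene %in% names(records))
        stop("gene '", gene, "' absent from the survival records")
    x <- records[[gene]]
    if (length(unique(x)) < 2L)
        stop("degenerate split: all expression values identical for '",
             gene, "'")
    cutoff <- if (method == "median") stats::median(x)
              else stats::quantile(x, q, names = FALSE)
    hi <- x > cutoff
    if (!any(hi) || all(hi))
        stop("degenerate split: cutoff leaves an empty group for '",
             gene, "'")
    list(high = records[hi, , drop = FALSE],
         low = records[!hi, , drop = FALSE], cutoff = cutoff)
}

#' Survival screen of a gene list
#'
#' For each gene, dichotomize the cohort by expression and log-rank-test
#' high versus low. The default median split is reproducible; the
#' `"scan"` option scans the 0.25-0.75 quantiles and keeps the minimum p,
#' which is optimistic (a warning says so) but mirrors the "best cutoff"
#' behavior of popular survival portals.
#'
#' @param genes gene symbols, each a column of `records`.
#' @param records survival `data.frame`.
#' @param endpoint label, `"OS"` or `"RFS"` (annotation only; the records
#'   carry whichever endpoint was loaded).
#' @param alpha significance level on the log-rank p (default 0.05, raw;
#'   `pAdjust = "BH"` applies Benjamini-Hochberg across the gene list).
#' @param cutoff `"median"` (default) or `"scan"`.
#' @param pAdjust `"none"` or `"BH"`.
#' @return `data.frame`: gene, endpoint, cutoff_method, cutoff_value,
#'   chi_square, p_value, n_high, n_low, significant.
#' @export
screenSurvival <- function(genes, records, endpoint = c("OS", "RFS"),
                           alpha = 0.05, cutoff = c("median", "scan"),
                           pAdjust = c("none", "BH")) {
    endpoint <- match.arg(endpoint)
    cutoff <- match.arg(cutoff)
    pAdjust <- match.arg(pAdjust)
    missing <- setdiff(genes, names(records))
    if (length(missing))
        stop("gene(s) absent from survival records: ",
             paste(missing, collapse = ", "))
    if (cutoff == "scan")
        warning("quantile-scan cutoffs take the minimum p over a grid; ",
                "the resulting p-values are optimistic")
    one <- function(g) {
        qs <- if (cutoff == "median") 0.5 else seq(0.25, 0.75, by = 0.05)
        best <- NULL
        for (q in qs) {
            sp <- dichotomizeByExpression(records, g, "quantile", q)
            lr <- logrankTest(sp$high, timeLow = sp$low)
            if (is.null(best) || lr@pValue < best$p)
                best <- list(p = lr@pValue, chi = lr@chiSquare,
                             cut = sp$cutoff, nh = lr@nHigh, nl = lr@nLow)
        }
        best
    }
    res <- lapply(genes, one)
    out <- data.frame(
        gene = genes, endpoint = endpoint, cutoff_method = cutoff,
        cutoff_value = vapply(res, `[[`, numeric(1), "cut"),
        chi_square = vapply(res, `[[`, numeric(1), "chi"),
        p_value = vapply(res, `[[`, numeric(1), "p"),
        n_high = vapply(res, `[[`, numeric(1), "nh"),
        n_low = vapply(res, `[[`, numeric(1), "nl"),
        stringsAsFactors = FALSE)
    p <- if (pAdjust == "BH") stats::p.adjust(out$p_value, "BH")
         else out$p_value
    out$significant <- p < alpha
    out
}
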