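#' Two-sided Welch t-test p-value
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom, two-sided tail probability. Degenerate inputs follow fixed
#' rules rather than erroring: if both groups have zero variance and equal
#' means the difference carries no evidence and p = 1; if both have zero
#' variance but unequal means the statistic diverges and the smallest
#' positive representable probability is returned with a warning.
#'
#' @param a,b numeric vectors, length >= 2 each, finite.
#' @return two-sided p-value in (0, 1].
#' @examples
#' welchTPValue(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welchTPValue <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("values must be finite")
    p <- .welchVec(matrix(a, 1L), matrix(b, 1L))
    p[[1L]]
}

## vectorized Welch across rows of two matrices (genes x samples)
.welchVec <- function(A, B) {
    na <- ncol(A); nb <- ncol(B)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (na - 1L)
    vb <- rowSums((B - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    p <- numeric(nrow(A))
    zero <- se2 == 0
    if (any(zero)) {
        eq <- zero & (ma == mb)
        p[eq] <- 1
        if (any(zero & !eq)) {
            warning("zero variance in both groups with unequal means; ",
                    "p underflows and is reported as the smallest ",
                    "representable probability")
            p[zero & !eq] <- .Machine$double.xmin
        }
    }
    if (any(!zero)) {
        i <- !zero
        tstat <- (ma[i] - mb[i]) / sqrt(se2[i])
        df <- se2[i]^2 /
            ((va[i] / na)^2 / (na - 1L) + (vb[i] / nb)^2 / (nb - 1L))
        p[i] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    }
    pmax(p, .Machine$double.xmin)   # keep p strictly positive
}

#' Classify a gene's direction under fold-change and p-value gates
#'
#' `"up"` iff `log2fc > fcThreshold` and `p < pThreshold`; `"down"` iff
#' `log2fc < -fcThreshold` and `p < pThreshold`; otherwise
#' `"not_significant"`. Inequalities are strict, so a gene sitting exactly
#' on a threshold is not significant.
#'
#' @param log2fc numeric vector of log2 fold changes (tumor minus normal).
#' @param p numeric vector of p-values.
#' @param fcThreshold,pThreshold positive gates (defaults 2 and 0.05).
#' @return character vector of direction calls.
#' @examples
#' classifyDirection(c(2.5, -2.2, 2.0), c(0.01, 0.04, 0.01))
#' @export
classifyDirection <- function(log2fc, p, fcThreshold = 2, pThreshold = 0.05) {
    stopifnot(fcThreshold > 0, pThreshold > 0)
    out <- rep("not_significant", length(log2fc))
    sig <- p < pThreshold
    out[sig & log2fc > fcThreshold] <- "up"
    out[sig & log2fc < -fcThreshold] <- "down"
    out
}

#' Differential-expression screen of one cohort
#'
#' For every gene: log2 fold change = mean over tumor samples minus mean
#' over normal samples (values already log2), two-sided Welch t p-value,
#' and the direction call of [classifyDirection()] under the stated gates.
#' P-values feed the gate raw by default; `pAdjust = "BH"` applies
#' Benjamini-Hochberg across genes first.
#'
#' @param cohort an [ExpressionCohort-class] with both groups present
#'   (>= 2 samples each).
#' @param fcThreshold,pThreshold screening gates (defaults 2 and 0.05).
#' @param pAdjust `"none"` (default) or `"BH"`.
#' @return a [DegScreen-class]; its table is sorted by `|log2fc|`
#'   descending.
#' @examples
#' sim <- simulateCohorts(simParams(genesTotal = 50, seed = 7))
#' scr <- computeDeg(sim$cohorts[[1]])
#' nSignificant(scr)
#' @export
computeDeg <- function(cohort, fcThreshold = 2, pThreshold = 0.05,
                       pAdjust = c("none", "BH")) {
    stopifnot(is(cohort, "ExpressionCohort"))
    pAdjust <- match.arg(pAdjust)
    grp <- sampleGroups(cohort)
    m <- exprValues(cohort)
    if (sum(grp == "tumor") < 2L || sum(grp == "normal") < 2L)
        stop("each group needs at least 2 samples for the screen")
    A <- m[, grp == "tumor", drop = FALSE]
    B <- m[, grp == "normal", drop = FALSE]
    log2fc <- rowMeans(A) - rowMeans(B)
    p <- .welchVec(A, B)
    if (pAdjust == "BH") p <- stats::p.adjust(p, "BH")
    tb <- data.frame(gene = rownames(m), log2fc = unname(log2fc),
                     p_value = unname(p),
                     direction = classifyDirection(log2fc, p, fcThreshold,
                                                   pThreshold),
                     stringsAsFactors = FALSE)
    tb <- tb[order(-abs(tb$log2fc)), , drop = FALSE]
    rownames(tb) <- NULL
    new("DegScreen", datasetId = datasetId(cohort),
        fcThreshold = fcThreshold, pThreshold = pThreshold,
        pAdjust = pAdjust, table = tb)
}

#' @rdname DegScreen-class
#' @aliases degTable nSignificant degDirections
#' @export
setMethod("degTable", "DegScreen", function(x) x@table)

#' @rdname DegScreen-class
#' @export
setMethod("nSignificant", "DegScreen",
    function(x) sum(x@table$direction != "not_significant"))

#' @rdname DegScreen-class
#' @export
setMethod("degDirections", "DegScreen", function(x) {
    d <- x@table$direction
    names(d) <- x@table$gene
    d
})

setMethod("show", "DegScreen", function(object) {
    d <- object@table$direction
    cat("DegScreen '", object@datasetId, "': ", nrow(object@table),
        " genes, gates |log2FC| > ", object@fcThreshold, ", p < ",
        object@pThreshold,
        if (object@pAdjust != "none") paste0(" (", object@pAdjust, ")"),
        "\n  significant: ", sum(d != "not_significant"),
        " (", sum(d == "up"), " up, ", sum(d == "down"), " down)\n",
        sep = "")
})
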