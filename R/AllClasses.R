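#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' One cohort of log2 expression with tumor/normal labels
#'
#' `ExpressionCohort` extends [SummarizedExperiment::SummarizedExperiment]
#' with a single assay `"log2expr"` (genes x samples, log2 scale, finite) and
#' a mandatory per-sample `group` column in `colData` taking values
#' `"tumor"` or `"normal"`. The cohort label is stored in
#' `metadata(x)$datasetId`.
#'
#' @slot .. inherited from `SummarizedExperiment`; no additional slots.
#'
#' @seealso [ExpressionCohort()] for construction,
#'   [readExpressionTable()] for import, [computeDeg()] for the
#'   differential-expression screen.
#' @exportClass ExpressionCohort
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "log2expr")
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, "all expression values must be finite numbers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    grp <- SummarizedExperiment::colData(object)$group
    if (is.null(grp) || any(is.na(grp)) ||
        !all(grp %in% c("tumor", "normal")))
        msg <- c(msg, "colData$group must label every sample 'tumor' or 'normal'")
    id <- S4Vectors::metadata(object)$datasetId
    if (is.null(id) || !is.character(id) || length(id) != 1L)
        msg <- c(msg, "metadata(x)$datasetId must be a single character label")
    if (length(msg)) msg else TRUE
})

#' Per-cohort differential-expression screen result
#'
#' Holds one record per gene (log2 fold change tumor minus normal, two-sided
#' p-value, direction call) together with the gates that produced the calls.
#' Direction is `"up"` iff `log2fc > fcThreshold` and `p < pThreshold`,
#' `"down"` iff `log2fc < -fcThreshold` and `p < pThreshold`, otherwise
#' `"not_significant"` (strict inequalities).
#'
#' @slot datasetId cohort label.
#' @slot fcThreshold,pThreshold the gates used (defaults 2 and 0.05).
#' @slot pAdjust `"none"` or `"BH"`; which p-values fed the gate.
#' @slot table `data.frame` with columns `gene`, `log2fc`, `p_value`,
#'   `direction`, sorted by `|log2fc|` descending.
#'
#' @seealso [computeDeg()]; accessors `degTable()`, `nSignificant()`,
#'   `degDirections()`
#' @exportClass DegScreen
setClass("DegScreen",
    representation(datasetId = "character", fcThreshold = "numeric",
                   pThreshold = "numeric", pAdjust = "character",
                   table = "data.frame"))

setValidity("DegScreen", function(object) {
    msg <- character()
    tb <- object@table
    need <- c("gene", "log2fc", "p_value", "direction")
    if (!all(need %in% names(tb)))
        return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
    if (!all(tb$direction %in% c("up", "down", "not_significant")))
        msg <- c(msg, "direction must be up/down/not_significant")
    if (anyDuplicated(tb$gene))
        msg <- c(msg, "duplicate gene in table")
    want <- classifyDirection(tb$log2fc, tb$p_value,
                              object@fcThreshold, object@pThreshold)
    if (!identical(want, tb$direction))
        msg <- c(msg, "direction calls inconsistent with the stated gates")
    if (length(msg)) msg else TRUE
})

#' Direction-consistent multi-cohort DEG intersection
#'
#' Genes significant with the same direction in every cohort form
#' `upCommon` / `downCommon`; genes significant everywhere but with mixed
#' directions are `conflicted` (reported, never silently merged). The
#' per-cohort direction of every gene in the shared universe is kept in
#' `membership` (genes x cohorts character matrix).
#'
#' @slot upCommon,downCommon,conflicted character vectors of gene ids.
#' @slot membership character matrix of per-cohort directions over the
#'   common gene universe.
#' @seealso [intersectDegs()]
#' @exportClass DegIntersection
setClass("DegIntersection",
    representation(upCommon = "character", downCommon = "character",
                   conflicted = "character", membership = "matrix"))

setValidity("DegIntersection", function(object) {
    msg <- character()
    if (length(intersect(object@upCommon, object@downCommon)))
        msg <- c(msg, "upCommon and downCommon must be disjoint")
    m <- object@membership
    if (length(object@upCommon) &&
        !all(m[object@upCommon, , drop = FALSE] == "up"))
        msg <- c(msg, "every upCommon gene must be 'up' in every cohort")
    if (length(object@downCommon) &&
        !all(m[object@downCommon, , drop = FALSE] == "down"))
        msg <- c(msg, "every downCommon gene must be 'down' in every cohort")
    if (length(msg)) msg else TRUE
})

#' Kaplan-Meier product-limit curve
#'
#' Survival estimate at the distinct event times of a censored sample:
#' `S(t_k) = prod_{j<=k} (1 - d_j/n_j)` with `d_j` events among `n_j` at
#' risk just before `t_j`. Ties between events and censorings at the same
#' time count the events first (standard product-limit convention).
#'
#' @slot time strictly increasing distinct times with at least one event.
#' @slot surv product-limit estimate at each time.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent number of events at each time.
#' @seealso [kmEstimator()]
#' @exportClass KMCurve
setClass("KMCurve",
    representation(time = "numeric", surv = "numeric",
                   nRisk = "numeric", nEvent = "numeric"))

setValidity("KMCurve", function(object) {
    msg <- character()
    n <- length(object@time)
    if (length(object@surv) != n || length(object@nRisk) != n ||
        length(object@nEvent) != n)
        return("time, surv, nRisk, nEvent must have equal length")
    if (n) {
        if (is.unsorted(object@time, strictly = TRUE))
            msg <- c(msg, "event times must be strictly increasing")
        if (any(diff(object@surv) > 1e-12) || any(object@surv < -1e-12) ||
            any(object@surv > 1 + 1e-12))
            msg <- c(msg, "surv must be non-increasing within [0, 1]")
        if (any(diff(object@nRisk) > 0))
            msg <- c(msg, "nRisk must be non-increasing")
        if (any(object@nEvent < 1))
            msg <- c(msg, "each reported time must carry at least one event")
    }
    if (length(msg)) msg else TRUE
})

#' Two-group log-rank test result
#'
#' Observed-versus-expected events across the pooled distinct event times,
#' chi-square statistic `(O - E)^2 / V` on 1 degree of freedom.
#'
#' @slot chiSquare statistic, non-negative.
#' @slot pValue two-sided tail probability in (0, 1].
#' @slot nHigh,nLow group sizes.
#' @seealso [logrankTest()]
#' @exportClass LogRankResult
setClass("LogRankResult",
    representation(chiSquare = "numeric", pValue = "numeric",
                   nHigh = "integer", nLow = "integer"))

setValidity("LogRankResult", function(object) {
    msg <- character()
    if (object@chiSquare < 0) msg <- c(msg, "chiSquare must be >= 0")
    if (object@pValue <= 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Pairwise correlation-bin scores and cumulative gene ranking
#'
#' For a gene set, `pairScores` holds the integer points (0-3) assigned to
#' each off-diagonal Pearson coefficient by [binCorrelation()];
#' `cumulative[i]` is the sum of gene i's `n - 1` pair scores, and `rank`
#' is the dense rank by cumulative score descending (ties share a rank).
#'
#' @slot genes ordered gene ids.
#' @slot r the Pearson matrix the scores were derived from.
#' @slot pairScores symmetric integer matrix, diagonal `NA` (excluded).
#' @slot cumulative named numeric vector of per-gene cumulative scores.
#' @slot rank named integer vector of dense ranks (1 = highest score).
#' @seealso [cumulativeScores()], [rankCoreGenes()]
#' @exportClass ScoreTable
setClass("ScoreTable",
    representation(genes = "character", r = "matrix", pairScores = "matrix",
                   cumulative = "numeric", rank = "integer"))

setValidity("ScoreTable", function(object) {
    msg <- character()
    n <- length(object@genes)
    ps <- object@pairScores
    if (!all(dim(ps) == n))
        return("pairScores must be n x n")
    off <- ps[row(ps) != col(ps)]
    if (!all(off %in% 0:3))
        msg <- c(msg, "off-diagonal pair scores must be integers in 0..3")
    if (!isTRUE(all.equal(ps, t(ps))))
        msg <- c(msg, "pairScores must be symmetric")
    if (any(object@cumulative < 0) || any(object@cumulative > 3 * (n - 1)))
        msg <- c(msg, "cumulative scores must lie in [0, 3(n-1)]")
    if (length(msg)) msg else TRUE
})
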