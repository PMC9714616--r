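#' Construct an ExpressionCohort
#'
#' Bundles a genes-by-samples matrix of log2-scale expression with per-sample
#' tumor/normal labels and a cohort label. Expression is assumed to be on
#' log2 scale already, as in processed microarray series matrices; use
#' `log2Transform = TRUE` to apply `log2(x + 1)` to linear-scale values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). All values finite.
#' @param group character vector, one of `"tumor"`/`"normal"` per sample;
#'   either unnamed in column order or named by sample id.
#' @param datasetId single character cohort label.
#' @param log2Transform apply `log2(x + 1)` to `values` first.
#'
#' @return an [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' co <- ExpressionCohort(m, c("tumor", "tumor", "normal", "normal"), "toy")
#' datasetId(co)
#' table(sampleGroups(co))
#' @export
ExpressionCohort <- function(values, group, datasetId = "cohort",
                             log2Transform = FALSE) {
    values <- as.matrix(values)
    if (isTRUE(log2Transform)) {
        if (any(values < 0))
            stop("log2Transform requires non-negative linear-scale values")
        values <- log2(values + 1)
    }
    if (!is.null(names(group))) {
        missing <- setdiff(colnames(values), names(group))
        if (length(missing))
            stop("no group label for sample(s): ",
                 paste(missing, collapse = ", "))
        group <- unname(group[colnames(values)])
    }
    if (length(group) != ncol(values))
        stop("need one group label per sample")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = values),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       row.names = colnames(values)),
        metadata = list(datasetId = as.character(datasetId)))
    obj <- new("ExpressionCohort", se)
    validObject(obj)
    obj
}

#' @rdname ExpressionCohort
#' @aliases datasetId sampleGroups exprValues
#' @export
setMethod("datasetId", "ExpressionCohort",
    function(x) S4Vectors::metadata(x)$datasetId)

#' @rdname ExpressionCohort
#' @export
setMethod("sampleGroups", "ExpressionCohort", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' @rdname ExpressionCohort
#' @export
setMethod("exprValues", "ExpressionCohort",
    function(x) SummarizedExperiment::assay(x, "log2expr"))

setMethod("show", "ExpressionCohort", function(object) {
    g <- sampleGroups(object)
    cat("ExpressionCohort '", datasetId(object), "': ",
        nrow(object), " genes x ", ncol(object), " samples (",
        sum(g == "tumor"), " tumor / ", sum(g == "normal"), " normal)\n",
        sep = "")
})
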