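#' Direction-consistent intersection of per-cohort DEG lists
#'
#' The multi-cohort (Venn) stage: a gene enters `upCommon` only if it is
#' called `"up"` in every cohort, `downCommon` only if `"down"` everywhere.
#' Genes significant in every cohort but with mixed directions are
#' reported as `conflicted` and excluded from both common sets. The
#' intersection is computed over the genes shared by all cohorts; genes
#' missing from some cohort's universe (platform differences) are dropped
#' from consideration with a message.
#'
#' @param results list of [DegScreen-class] objects, length >= 2.
#' @return a [DegIntersection-class].
#' @examples
#' sim <- simulateCohorts(simParams(genesTotal = 100, seed = 3))
#' ix <- intersectDegs(lapply(sim$cohorts, computeDeg))
#' length(ix@upCommon); length(ix@downCommon)
#' @export
intersectDegs <- function(results) {
    if (!length(results))
        stop("need at least one DegScreen; >= 2 for a meaningful intersection")
    stopifnot(all(vapply(results, is, logical(1), "DegScreen")))
    if (length(results) < 2L)
        warning("single cohort: intersection degenerates to its DEG list")
    universes <- lapply(results, function(r) degTable(r)$gene)
    common <- Reduce(intersect, universes)
    dropped <- length(unique(unlist(universes))) - length(common)
    if (dropped > 0L)
        message(sprintf(
            "%d gene(s) absent from >=1 cohort excluded from the intersection universe",
            dropped))
    membership <- vapply(results, function(r) degDirections(r)[common],
                         character(length(common)))
    if (is.null(dim(membership)))            # single common gene edge case
        membership <- matrix(membership, nrow = 1L,
                             dimnames = list(common, NULL))
    rownames(membership) <- common
    colnames(membership) <- vapply(results, function(r) r@datasetId,
                                   character(1))
    allSig <- rowSums(membership != "not_significant") == ncol(membership)
    up <- allSig & rowSums(membership == "up") == ncol(membership)
    down <- allSig & rowSums(membership == "down") == ncol(membership)
    new("DegIntersection",
        upCommon = sort(common[up]), downCommon = sort(common[down]),
        conflicted = sort(common[allSig & !up & !down]),
        membership = membership)
}

setMethod("show", "DegIntersection", function(object) {
    cat("DegIntersection over ", ncol(object@membership), " cohorts: ",
        length(object@upCommon), " up, ", length(object@downCommon),
        " down, ", length(object@conflicted), " conflicted\n", sep = "")
})
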