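#' Pairwise Pearson correlation matrix of a gene set
#'
#' Sample Pearson coefficients between genes over the selected samples of
#' a cohort (tumor samples by default — the disease context the scoring
#' stage is defined in). Zero-variance genes cannot be correlated; they
#' are dropped with a warning so the scoring stage only sees well-defined
#' coefficients.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param genes gene symbols to correlate (>= 2).
#' @param group `"tumor"` (default), `"normal"` or `"all"`.
#' @return symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
pearsonMatrix <- function(cohort, genes, group = c("tumor", "normal", "all")) {
    group <- match.arg(group)
    stopifnot(is(cohort, "ExpressionCohort"), length(genes) >= 2L)
    missing <- setdiff(genes, rownames(cohort))
    if (length(missing))
        stop("gene(s) absent from cohort: ", paste(missing, collapse = ", "))
    keep <- if (group == "all") rep(TRUE, ncol(cohort))
            else sampleGroups(cohort) == group
    if (sum(keep) < 3L)
        stop("need at least 3 samples in the selected group")
    m <- t(exprValues(cohort)[genes, keep, drop = FALSE])
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
        warning("zero-variance gene(s) excluded from correlation: ",
                paste(genes[sds == 0], collapse = ", "))
        m <- m[, sds > 0, drop = FALSE]
        if (ncol(m) < 2L) stop("fewer than 2 genes with variance")
    }
    r <- stats::cor(m)
    (r + t(r)) / 2   # enforce exact symmetry
}

#' Bin a Pearson coefficient to correlation points
#'
#' The scoring rule of the screen: very weak |r| < 0.4 scores 0 points,
#' weak 0.4 <= |r| < 0.6 scores 1, strong 0.6 <= |r| < 0.8 scores 2, very
#' strong 0.8 <= |r| <= 1 scores 3. Bins are left-closed (the last also
#' right-closed), so the boundary values 0.4/0.6/0.8 fall in the higher
#' bin. The sign of r is ignored.
#'
#' @param r numeric vector of Pearson coefficients, |r| <= 1.
#' @return integer vector of scores in 0..3.
#' @examples
#' binCorrelation(c(0.35, -0.5, 0.7, -0.9))   # 0 1 2 3
#' @export
binCorrelation <- function(r) {
    if (any(!is.finite(r)) || any(abs(r) > 1))
        stop("|r| must be finite and <= 1")
    a <- abs(r)
    as.integer((a >= 0.4) + (a >= 0.6) + (a >= 0.8))
}

#' Cumulative correlation scores of a gene set
#'
#' Applies [binCorrelation()] to every off-diagonal entry of a Pearson
#' matrix and sums each gene's `n - 1` pair scores into its cumulative
#' score; genes are dense-ranked by cumulative score descending with ties
#' sharing a rank.
#'
#' @param r symmetric Pearson correlation matrix with gene dimnames
#'   (as from [pearsonMatrix()]), `n >= 2`.
#' @return a [ScoreTable-class].
#' @examples
#' r <- matrix(c(1, .9, .5, .9, 1, .3, .5, .3, 1), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' cumulativeScore(cumulativeScores(r))   # A 4, B 3, C 1
#' @export
cumulativeScores <- function(r) {
    stopifnot(is.matrix(r), nrow(r) >= 2L, nrow(r) == ncol(r))
    if (is.null(rownames(r))) stop("correlation matrix needs gene dimnames")
    if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix not symmetric")
    genes <- rownames(r)
    ps <- matrix(binCorrelation(r), nrow(r), ncol(r),
                 dimnames = dimnames(r))
    diag(ps) <- NA_integer_
    cum <- rowSums(ps, na.rm = TRUE)
    ## dense rank: distinct scores in decreasing order, ties share a rank
    rk <- match(-cum, sort(unique(-cum)))
    names(rk) <- genes
    new("ScoreTable", genes = genes, r = r, pairScores = ps,
        cumulative = cum, rank = stats::setNames(as.integer(rk), genes))
}

#' @rdname ScoreTable-class
#' @aliases cumulativeScore geneRanks pairScores
#' @export
setMethod("cumulativeScore", "ScoreTable", function(x) x@cumulative)

#' @rdname ScoreTable-class
#' @export
setMethod("geneRanks", "ScoreTable", function(x) x@rank)

#' @rdname ScoreTable-class
#' @export
setMethod("pairScores", "ScoreTable", function(x) x@pairScores)

setMethod("show", "ScoreTable", function(object) {
    ord <- order(-object@cumulative, object@genes, method = "radix")
    cat("ScoreTable:", length(object@genes), "genes\n")
    print(data.frame(gene = object@genes[ord],
                     cumulative = unname(object@cumulative[ord]),
                     rank = unname(object@rank[ord])), row.names = FALSE)
})

#' Top-ranked core risk genes
#'
#' Returns the genes occupying the top `k` dense ranks of a
#' [ScoreTable-class], ordered by cumulative score descending with ties
#' broken alphabetically for display. A tie at the k-th rank expands the
#' list beyond `k`; the attribute `tieExpanded` flags when that happened.
#'
#' @param table a [ScoreTable-class].
#' @param k number of top ranks to take, `1 <= k <= n`.
#' @return character vector of gene symbols with a logical attribute
#'   `tieExpanded`.
#' @export
rankCoreGenes <- function(table, k) {
    stopifnot(is(table, "ScoreTable"), k >= 1L, k <= length(table@genes))
    rk <- table@rank
    ord <- order(rk, table@genes, method = "radix")
    ## rank cutoff by position k: take all ranks occupied by the first k
    ## positions, expanding through ties
    cutRank <- rk[ord][min(k, length(ord))]
    sel <- ord[rk[ord] <= cutRank]
    out <- table@genes[sel]
    attr(out, "tieExpanded") <- length(out) > k
    out
}
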