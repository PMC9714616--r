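#' Relative expression by the 2^-ddCt method
#'
#' For each patient with complete data: `dCt_tumor = Ct(target, tumor) -
#' Ct(reference, tumor)`, `dCt_adjacent` analogously, `ddCt = dCt_tumor -
#' dCt_adjacent`, and `fold change = 2^-ddCt`. Patients lacking any of
#' the four Ct values are excluded with a message. Higher Ct means fewer
#' cycles' worth of transcript, so a positive ddCt is lower expression in
#' tumor (fold change < 1).
#'
#' @param records Ct `data.frame` as from [readCtTable()] or
#'   [simulateCt()].
#' @param target target gene symbol.
#' @param reference reference (housekeeping) gene symbol, default
#'   `"ACTB"`.
#' @return list of class `RelativeExpression`: `gene`, `reference`,
#'   per-patient `delta_ct_tumor`, `delta_ct_adjacent`, `delta_delta_ct`,
#'   `fold_change`, the group `mean_fold_change`, `mean_ddct`, `se_ddct`,
#'   and `n`; `p_value`/`significant` are filled by
#'   [testRelativeExpression()].
#' @examples
#' ct <- data.frame(patient_id = "p1",
#'                  tissue = c("tumor", "tumor", "adjacent", "adjacent"),
#'                  gene = c("T", "ACTB", "T", "ACTB"),
#'                  ct = c(25, 20, 24, 20))
#' deltaDeltaCt(ct, "T")$fold_change   # 2^-1 = 0.5
#' @export
deltaDeltaCt <- function(records, target, reference = "ACTB") {
    if (identical(target, reference))
        stop("target and reference gene must differ")
    if (!any(records$gene == reference))
        stop("reference gene '", reference, "' absent from the Ct records")
    if (!any(records$gene == target))
        stop("target gene '", target, "' absent from the Ct records")
    getCt <- function(pat, tis, g) {
        v <- records$ct[records$patient_id == pat & records$tissue == tis &
                        records$gene == g]
        if (length(v)) mean(v) else NA_real_
    }
    pats <- unique(records$patient_id)
    dct_t <- dct_a <- numeric(0)
    kept <- character(0)
    for (pat in pats) {
        tt <- getCt(pat, "tumor", target); rt <- getCt(pat, "tumor", reference)
        ta <- getCt(pat, "adjacent", target)
        ra <- getCt(pat, "adjacent", reference)
        if (anyNA(c(tt, rt, ta, ra))) next
        kept <- c(kept, pat)
        dct_t <- c(dct_t, tt - rt)
        dct_a <- c(dct_a, ta - ra)
    }
    if (length(kept) < length(pats))
        message(sprintf("excluded %d patient(s) with incomplete Ct blocks",
                        length(pats) - length(kept)))
    if (!length(kept))
        stop("no patient has complete Ct data for '", target, "'")
    ddct <- dct_t - dct_a
    out <- list(gene = target, reference = reference, patients = kept,
                delta_ct_tumor = dct_t, delta_ct_adjacent = dct_a,
                delta_delta_ct = ddct, fold_change = 2^(-ddct),
                mean_fold_change = mean(2^(-ddct)),
                mean_ddct = mean(ddct),
                se_ddct = if (length(ddct) > 1L)
                    stats::sd(ddct) / sqrt(length(ddct)) else NA_real_,
                n = length(kept), p_value = NA_real_, significant = NA)
    class(out) <- "RelativeExpression"
    out
}

#' @export
print.RelativeExpression <- function(x, ...) {
    cat(sprintf(
        "2^-ddCt for %s (vs %s, n = %d): mean fold change %.3g, ddCt %.3g +/- %.3g",
        x$gene, x$reference, x$n, x$mean_fold_change, x$mean_ddct,
        x$se_ddct), "\n")
    if (!is.na(x$p_value))
        cat(sprintf("  paired t on dCt: p = %.4g (%s)\n", x$p_value,
                    if (isTRUE(x$significant)) "significant"
                    else "not significant"))
    invisible(x)
}

#' Test tumor-versus-adjacent relative expression
#'
#' Two-sided Student's t-test on the per-patient dCt values, paired by
#' default (equivalently a one-sample t on ddCt), which is the natural
#' scale for approximately normal qPCR noise. The degenerate case of all
#' per-patient differences exactly zero yields p = 1.
#'
#' @param expr a `RelativeExpression` from [deltaDeltaCt()].
#' @param alpha significance level (default 0.05).
#' @param paired paired (default) or unpaired t-test on the dCt values.
#' @return `expr` with `p_value` and `significant` filled in.
#' @export
testRelativeExpression <- function(expr, alpha = 0.05, paired = TRUE) {
    stopifnot(inherits(expr, "RelativeExpression"))
    if (expr$n < 2L) stop("need >= 2 patients with complete data")
    if (paired) {
        d <- expr$delta_delta_ct
        p <- if (stats::sd(d) == 0) {
            if (all(d == 0)) 1
            else .Machine$double.xmin   # constant nonzero shift
        } else stats::t.test(d)$p.value
    } else {
        p <- welchTPValue(expr$delta_ct_tumor, expr$delta_ct_adjacent)
    }
    expr$p_value <- p
    expr$significant <- p < alpha
    expr
}
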