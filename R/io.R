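#' Read a tab-separated expression table into an ExpressionCohort
#'
#' Expects the common processed-microarray layout: first column gene symbol,
#' header row of sample ids, one numeric column per sample. Lines starting
#' with `"!"` (series-matrix style annotation headers) are skipped, so a
#' GEO series-matrix-like file can be read directly. A companion group map
#' assigns the tumor/normal label of every sample; a sample without a label
#' is a hard error.
#'
#' Duplicate gene symbols (multiple probes per gene) are collapsed by
#' `collapse`: `"max-mean"` keeps the row with the highest mean expression
#' (the usual microarray convention), `"mean"` averages the rows. Genes with
#' any missing value are dropped with a message, so the returned cohort is
#' complete and finite.
#'
#' @param source path to a tab-separated text file.
#' @param group character vector of `"tumor"`/`"normal"` named by sample id
#'   (or unnamed, in file column order).
#' @param datasetId cohort label; defaults to the file name.
#' @param collapse duplicate-gene rule, `"max-mean"` (default) or `"mean"`.
#' @param log2Transform apply `log2(x + 1)` to linear-scale values.
#'
#' @return an [ExpressionCohort-class].
#' @seealso [writeExpressionTable()] for the inverse.
#' @export
readExpressionTable <- function(source, group, datasetId = basename(source),
                                collapse = c("max-mean", "mean"),
                                log2Transform = FALSE) {
    collapse <- match.arg(collapse)
    tb <- utils::read.delim(source, header = TRUE, sep = "\t",
                            comment.char = "!", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(tb) < 2L)
        stop("expression table needs a gene column plus >=1 sample column")
    genes <- as.character(tb[[1L]])
    vals <- tb[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (is.character(v)) {
            bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
            if (length(bad))
                stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                             genes[bad[1L]], names(vals)[j]))
            vals[[j]] <- as.numeric(v)
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
    if (anyDuplicated(genes)) {
        ndup <- sum(duplicated(genes))
        if (collapse == "max-mean") {
            keep <- order(-rowMeans(m, na.rm = TRUE))
            m <- m[keep, , drop = FALSE]
            m <- m[!duplicated(rownames(m)), , drop = FALSE]
            m <- m[unique(genes), , drop = FALSE]   # restore input order
        } else {
            m <- do.call(rbind, lapply(unique(genes), function(g)
                colMeans(m[genes == g, , drop = FALSE], na.rm = TRUE)))
            rownames(m) <- unique(genes)
        }
        message(sprintf("collapsed %d duplicate gene row(s) by %s",
                        ndup, collapse))
    }
    nok <- rowSums(is.na(m)) > 0
    if (any(nok)) {
        message(sprintf("dropped %d gene(s) with missing values", sum(nok)))
        m <- m[!nok, , drop = FALSE]
    }
    ExpressionCohort(m, group, datasetId, log2Transform = log2Transform)
}

#' Write an ExpressionCohort as a tab-separated table
#'
#' Inverse of [readExpressionTable()]: first column `gene`, one column per
#' sample. Values are written at full precision so a clean read/write
#' round-trip reproduces them bit-identically.
#'
#' @param x an [ExpressionCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
    m <- exprValues(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a survival table
#'
#' Tab-separated with columns `patient_id`, `time` (months, positive),
#' `event` (0 censored / 1 event), then one numeric column per gene.
#' Rows with missing time or event are dropped with a message; a negative
#' or zero time is a hard error.
#'
#' @param source path to a tab-separated text file.
#' @return `data.frame` with the validated records, one row per patient.
#' @export
readSurvivalTable <- function(source) {
    tb <- utils::read.delim(source, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("patient_id", "time", "event")
    if (!all(need %in% names(tb)))
        stop("survival table needs columns patient_id, time, event")
    drop <- is.na(tb$time) | is.na(tb$event)
    if (any(drop)) {
        message(sprintf("dropped %d row(s) with missing time/event", sum(drop)))
        tb <- tb[!drop, , drop = FALSE]
    }
    if (any(tb$time <= 0))
        stop("non-positive follow-up time")
    if (!all(tb$event %in% c(0, 1)))
        stop("event must be 0 (censored) or 1 (event)")
    rownames(tb) <- NULL
    tb
}

#' Write a survival table
#' @param records survival `data.frame` as returned by [readSurvivalTable()]
#'   or [simulateSurvival()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSurvivalTable <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' Tab-separated long format with columns `patient_id`, `tissue`
#' (`"tumor"` or `"adjacent"`), `gene`, `ct` (cycle threshold, mean of
#' technical replicates). Non-numeric Ct or an unknown tissue label is a
#' hard error. Whether every patient/tissue block carries the reference
#' gene is checked later, at delta-delta-Ct time.
#'
#' @param source path to a tab-separated text file.
#' @return `data.frame` of validated Ct records.
#' @export
readCtTable <- function(source) {
    tb <- utils::read.delim(source, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("patient_id", "tissue", "gene", "ct")
    if (!all(need %in% names(tb)))
        stop("Ct table needs columns patient_id, tissue, gene, ct")
    if (is.character(tb$ct)) {
        bad <- is.na(suppressWarnings(as.numeric(tb$ct)))
        if (any(bad))
            stop(sprintf("non-numeric ct for patient '%s', gene '%s'",
                         tb$patient_id[which(bad)[1L]],
                         tb$gene[which(bad)[1L]]))
        tb$ct <- as.numeric(tb$ct)
    }
    if (any(!is.finite(tb$ct)))
        stop("ct values must be finite")
    if (!all(tb$tissue %in% c("tumor", "adjacent")))
        stop("tissue labels must be 'tumor' or 'adjacent'")
    tb[order(tb$patient_id, tb$tissue, method = "radix"), , drop = FALSE]
}

#' Write a Ct table
#' @param records Ct `data.frame` as returned by [readCtTable()] or
#'   [simulateCt()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
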