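#' Verify discovery DEG directions in an independent cohort
#'
#' The large-sample verification step: every gene in the discovery
#' intersection is looked up in an independent cohort's DEG screen and
#' confirmed only if it is significant there with the same direction.
#' Genes absent from the validation cohort's universe are marked
#' unverifiable, never dropped.
#'
#' @param discovery a [DegIntersection-class].
#' @param validation a [DegScreen-class] on the validation cohort.
#' @return `data.frame`: gene, discovery_direction, validation_direction,
#'   confirmed, unverifiable.
#' @export
verifyDirections <- function(discovery, validation) {
    stopifnot(is(discovery, "DegIntersection"), is(validation, "DegScreen"))
    genes <- c(discovery@upCommon, discovery@downCommon)
    disc <- c(rep("up", length(discovery@upCommon)),
              rep("down", length(discovery@downCommon)))
    vdir <- degDirections(validation)
    val <- unname(vdir[genes])
    unver <- !(genes %in% names(vdir))
    val[unver] <- NA_character_
    out <- data.frame(gene = genes, discovery_direction = disc,
                      validation_direction = val,
                      confirmed = !unver & !is.na(val) & val == disc,
                      unverifiable = unver, stringsAsFactors = FALSE)
    out[order(out$gene, method = "radix"), , drop = FALSE]
}

.asCohortInput <- function(entry) {
    if (is(entry, "ExpressionCohort")) return(entry)
    grp <- entry$groups
    if (is.character(grp) && length(grp) == 1L && file.exists(grp)) {
        g <- utils::read.delim(grp, stringsAsFactors = FALSE)
        grp <- stats::setNames(g[[2L]], g[[1L]])
    } else grp <- unlist(grp)
    readExpressionTable(entry$path, grp,
                        datasetId = entry$id %||% basename(entry$path),
                        collapse = entry$collapse %||% "max-mean",
                        log2Transform = isTRUE(entry$log2_transform))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## cbind cohorts over their shared gene universe
.poolCohorts <- function(cohorts) {
    common <- Reduce(intersect, lapply(cohorts, rownames))
    vals <- do.call(cbind, lapply(cohorts, function(co)
        exprValues(co)[common, , drop = FALSE]))
    grp <- unlist(lapply(cohorts, function(co) unname(sampleGroups(co))))
    colnames(vals) <- make.unique(colnames(vals))
    ExpressionCohort(vals, grp, datasetId = "pooled")
}

#' Run the full risk-gene screening pipeline
#'
#' Orchestrates the funnel: per-cohort DEG screen, direction-consistent
#' intersection, optional independent-cohort direction verification,
#' overall-survival screen of the verified genes (survivors form the
#' "risk set"), correlation-bin cumulative scoring and core-gene ranking
#' of the risk set, qPCR 2^-ddCt validation, and an optional second
#' (relapse-free survival) pass over the qPCR-validated genes.
#'
#' `config` is a named list or a path to a YAML file. Either
#' `config$simulate` (arguments to [simParams()]) generates all inputs
#' synthetically, or `config$cohorts` names expression tables (each entry:
#' `path`, `groups` as named list or two-column TSV path, optional `id`,
#' `collapse`, `log2_transform`), with optional `validation` (same form),
#' `survival`, `rfs_survival` and `ct` table paths. Thresholds live under
#' `config$params`: `fc_threshold` (2), `p_threshold` (0.05), `p_adjust`
#' ("none"), `alpha` (0.05), `cutoff` ("median"), `reference_gene`
#' ("ACTB"), `core_k` (4).
#'
#' Stages that lack their input stop the funnel: the report is returned
#' with `status = "partial"` and `completed_stages` saying how far it got.
#'
#' @param config named list or YAML file path.
#' @return a `PipelineReport`: a named list with per-stage parameters and
#'   outputs, serializable with [writePipelineReport()].
#' @examples
#' rep <- runPipeline(list(simulate = list(genesTotal = 200, seed = 11)))
#' rep$core_genes
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    prm <- config$params %||% list()
    fc <- prm$fc_threshold %||% 2
    pth <- prm$p_threshold %||% 0.05
    padj <- prm$p_adjust %||% "none"
    alpha <- prm$alpha %||% 0.05
    cutoff <- prm$cutoff %||% "median"
    refGene <- prm$reference_gene %||% "ACTB"
    coreK <- prm$core_k %||% 4L

    report <- list(parameters = list(fc_threshold = fc, p_threshold = pth,
                                     p_adjust = padj, alpha = alpha,
                                     cutoff = cutoff, reference_gene = refGene,
                                     core_k = coreK),
                   status = "partial", completed_stages = character(0))
    truth <- NULL

    ## ---- inputs -------------------------------------------------------
    if (!is.null(config$simulate)) {
        sp <- do.call(simParams, config$simulate)
        sim <- simulateCohorts(sp)
        cohorts <- sim$cohorts
        truth <- sim$truth
        validation <- simulateValidationCohort(truth, sp)
        survTab <- simulateSurvival(truth, sp, endpoint = "OS")
        rfsTab <- simulateSurvival(truth, sp, endpoint = "RFS")
        ctTab <- simulateCt(truth, sp)
        refGene <- sp$referenceGene
        report$parameters$reference_gene <- refGene
        report$seed <- sp$seed
        report$truth <- truth[c("planted_up", "planted_down", "core_module")]
    } else {
        if (is.null(config$cohorts) || length(config$cohorts) < 2L)
            stop("config must name >= 2 discovery cohorts (or a simulate block)")
        cohorts <- lapply(config$cohorts, .asCohortInput)
        validation <- if (!is.null(config$validation))
            .asCohortInput(config$validation) else NULL
        survTab <- if (!is.null(config$survival))
            readSurvivalTable(config$survival) else NULL
        rfsTab <- if (!is.null(config$rfs_survival))
            readSurvivalTable(config$rfs_survival) else NULL
        ctTab <- if (!is.null(config$ct)) readCtTable(config$ct) else NULL
    }

    ## ---- DEG screen per cohort ---------------------------------------
    screens <- lapply(cohorts, computeDeg, fcThreshold = fc,
                      pThreshold = pth, pAdjust = padj)
    report$deg_counts <- stats::setNames(
        vapply(screens, nSignificant, numeric(1)),
        vapply(screens, function(s) s@datasetId, character(1)))
    report$completed_stages <- c(report$completed_stages, "deg")

    ## ---- intersection -------------------------------------------------
    ix <- intersectDegs(screens)
    report$intersection <- list(up_common = ix@upCommon,
                                down_common = ix@downCommon,
                                conflicted = ix@conflicted)
    report$completed_stages <- c(report$completed_stages, "intersect")
    candidates <- c(ix@upCommon, ix@downCommon)

    ## ---- independent-cohort direction verification --------------------
    if (!is.null(validation)) {
        vscreen <- computeDeg(validation, fcThreshold = fc, pThreshold = pth,
                              pAdjust = padj)
        vt <- verifyDirections(ix, vscreen)
        report$verification <- vt
        candidates <- vt$gene[vt$confirmed]
        report$completed_stages <- c(report$completed_stages, "verify")
    }
    if (!length(candidates)) {
        report$risk_set <- character(0)
        return(structure(report, class = "PipelineReport"))
    }

    ## ---- overall-survival screen --------------------------------------
    if (is.null(survTab)) return(structure(report, class = "PipelineReport"))
    genes <- intersect(candidates, names(survTab))
    surv <- screenSurvival(genes, survTab, endpoint = "OS", alpha = alpha,
                           cutoff = cutoff)
    report$os_screen <- surv
    riskSet <- surv$gene[surv$significant]
    report$risk_set <- riskSet
    report$completed_stages <- c(report$completed_stages, "survival")

    ## ---- core-gene scoring --------------------------------------------
    if (length(riskSet) >= 2L) {
        ## score on the validation cohort when present (the large-sample
        ## context), else on the pooled discovery cohorts
        scoreCohort <- if (!is.null(validation)) validation
                       else .poolCohorts(cohorts)
        r <- pearsonMatrix(scoreCohort, riskSet, group = "tumor")
        st <- cumulativeScores(r)
        core <- rankCoreGenes(st, min(coreK, length(riskSet)))
        report$score_table <- data.frame(
            gene = st@genes, cumulative = unname(cumulativeScore(st)),
            rank = unname(geneRanks(st)), stringsAsFactors = FALSE)
        report$core_genes <- as.character(core)
        report$core_tie_expanded <- isTRUE(attr(core, "tieExpanded"))
        report$completed_stages <- c(report$completed_stages, "score")
    }

    ## ---- qPCR validation ----------------------------------------------
    if (!is.null(ctTab)) {
        qgenes <- intersect(riskSet, unique(ctTab$gene))
        qres <- lapply(qgenes, function(g)
            testRelativeExpression(deltaDeltaCt(ctTab, g, refGene),
                                   alpha = alpha))
        qtab <- data.frame(
            gene = qgenes,
            mean_fold_change = vapply(qres, `[[`, numeric(1),
                                      "mean_fold_change"),
            mean_ddct = vapply(qres, `[[`, numeric(1), "mean_ddct"),
            p_value = vapply(qres, `[[`, numeric(1), "p_value"),
            significant = vapply(qres, `[[`, logical(1), "significant"),
            stringsAsFactors = FALSE)
        disc <- c(rep("up", length(ix@upCommon)),
                  rep("down", length(ix@downCommon)))
        names(disc) <- c(ix@upCommon, ix@downCommon)
        qtab$discovery_direction <- unname(disc[qtab$gene])
        qtab$direction_concordant <- ifelse(
            qtab$discovery_direction == "up",
            qtab$mean_fold_change > 1, qtab$mean_fold_change < 1)
        report$qpcr <- qtab
        report$qpcr_validated <- qtab$gene[qtab$significant &
                                           qtab$direction_concordant]
        report$completed_stages <- c(report$completed_stages, "qpcr")
    }

    ## ---- optional RFS pass over the clinically validated set ----------
    if (!is.null(rfsTab) && !is.null(report$qpcr_validated) &&
        length(report$qpcr_validated)) {
        rgenes <- intersect(report$qpcr_validated, names(rfsTab))
        if (length(rgenes)) {
            report$rfs_screen <- screenSurvival(rgenes, rfsTab,
                                                endpoint = "RFS",
                                                alpha = alpha,
                                                cutoff = cutoff)
            report$completed_stages <- c(report$completed_stages, "rfs")
        }
    }

    report$status <- "complete"
    structure(report, class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
    cat("PipelineReport [", x$status, "]: stages ",
        paste(x$completed_stages, collapse = " -> "), "\n", sep = "")
    if (!is.null(x$deg_counts)) {
        cat("  DEGs per cohort: ",
            paste(sprintf("%s=%d", names(x$deg_counts), x$deg_counts),
                  collapse = ", "), "\n", sep = "")
    }
    if (!is.null(x$intersection))
        cat("  intersection: ", length(x$intersection$up_common), " up, ",
            length(x$intersection$down_common), " down, ",
            length(x$intersection$conflicted), " conflicted\n", sep = "")
    if (!is.null(x$risk_set))
        cat("  risk set (OS-significant): ", length(x$risk_set),
            " gene(s)\n", sep = "")
    if (!is.null(x$core_genes))
        cat("  core genes: ", paste(x$core_genes, collapse = ", "), "\n",
            sep = "")
    if (!is.null(x$qpcr_validated))
        cat("  qPCR-validated: ", length(x$qpcr_validated), " gene(s)\n",
            sep = "")
    invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (the whole report, losslessly re-loadable with
#' [readPipelineReport()]) plus flat TSVs for the tabular stages into
#' `dir`.
#'
#' @param report a `PipelineReport` from [runPipeline()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writePipelineReport <- function(report, dir) {
    stopifnot(inherits(report, "PipelineReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(dir, "report.json"),
                         digits = I(17), auto_unbox = TRUE, null = "null",
                         dataframe = "columns")
    for (nm in c("os_screen", "rfs_screen", "qpcr", "score_table",
                 "verification"))
        if (!is.null(report[[nm]]))
            utils::write.table(report[[nm]],
                               file.path(dir, paste0(nm, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Re-load a serialized pipeline report
#' @param dir directory written by [writePipelineReport()].
#' @return the `PipelineReport` list.
#' @export
readPipelineReport <- function(dir) {
    rep <- jsonlite::read_json(file.path(dir, "report.json"),
                               simplifyVector = TRUE)
    structure(rep, class = "PipelineReport")
}
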