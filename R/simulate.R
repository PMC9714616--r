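#' Simulation parameters for synthetic PTC screening cohorts
#'
#' Collects every knob of the synthetic-data generator in one validated
#' list. The defaults describe the conditions the screen is designed for:
#' three microarray-style cohorts sharing a gene universe, 8 planted
#' upregulated and 15 planted downregulated genes at effect size
#' `effectSize = 4` log2 units (comfortably past the |log2FC| > 2 gate),
#' a 4-gene core module whose members share a latent factor in tumor
#' samples, hazard-linked survival for every planted gene, and paired
#' tumor/adjacent Ct tables for 8 patients.
#'
#' @param nCohorts number of discovery cohorts (>= 1).
#' @param genesTotal size of the shared gene universe.
#' @param nUp,nDown numbers of planted up-/down-regulated genes.
#' @param coreSize size of the correlated core module (subset of the
#'   planted genes, drawn from the downregulated set first, mirroring the
#'   thyroid-differentiation genes the screen targets).
#' @param effectSize planted |log2FC| Delta, in log2 units (> 0; 0 allowed
#'   for null calibration).
#' @param effectJitterSd sd of the per-cohort jitter around `effectSize`,
#'   emulating inter-platform variability.
#' @param loading within-module latent-factor loading in (0, 1); equals the
#'   target pairwise Pearson correlation between core-module genes in
#'   tumor samples.
#' @param noiseSd per-gene Gaussian noise sd on the log2 scale.
#' @param samplesPerGroup tumor (= normal) samples per cohort.
#' @param baselineHazard exponential event rate per month at average
#'   expression (default 0.02, median ~35 months).
#' @param hazardCoef log-hazard increment per sd of expression attached to
#'   every planted gene (sign follows the planted direction; 0 detaches
#'   survival from expression).
#' @param censoringRate target fraction of censored patients in (0, 1);
#'   0 disables censoring.
#' @param survivalN number of patients in the survival table.
#' @param qpcrN number of paired tumor/adjacent patients in the Ct table.
#' @param ctEffect planted tumor-vs-adjacent delta-delta-Ct magnitude for
#'   planted genes (Ct cycles; higher Ct = lower expression, so planted-down
#'   genes get +ctEffect and planted-up genes -ctEffect).
#' @param ctNoiseSd Ct measurement noise sd (cycles).
#' @param referenceGene housekeeping gene label added to Ct tables with a
#'   zero planted effect (default `"ACTB"`).
#' @param seed integer fixing all randomness of the generator.
#'
#' @return a validated list of class `SimParams`.
#' @examples
#' p <- simParams(seed = 1)
#' sim <- simulateCohorts(p)
#' sim$truth$core_module
#' @export
simParams <- function(nCohorts = 3L, genesTotal = 1000L, nUp = 8L,
                      nDown = 15L, coreSize = 4L, effectSize = 4,
                      effectJitterSd = 0.4, loading = 0.8, noiseSd = 0.5,
                      samplesPerGroup = 20L, baselineHazard = 0.02,
                      hazardCoef = 1, censoringRate = 0.3,
                      survivalN = 200L, qpcrN = 8L, ctEffect = 2,
                      ctNoiseSd = 0.25, referenceGene = "ACTB",
                      seed = 1L) {
    p <- list(nCohorts = as.integer(nCohorts),
              genesTotal = as.integer(genesTotal),
              nUp = as.integer(nUp), nDown = as.integer(nDown),
              coreSize = as.integer(coreSize), effectSize = effectSize,
              effectJitterSd = effectJitterSd, loading = loading,
              noiseSd = noiseSd, samplesPerGroup = as.integer(samplesPerGroup),
              baselineHazard = baselineHazard, hazardCoef = hazardCoef,
              censoringRate = censoringRate, survivalN = as.integer(survivalN),
              qpcrN = as.integer(qpcrN), ctEffect = ctEffect,
              ctNoiseSd = ctNoiseSd, referenceGene = referenceGene,
              seed = as.integer(seed))
    stopifnot(p$nCohorts >= 1L, p$genesTotal >= 1L, p$nUp >= 0L,
              p$nDown >= 0L, p$coreSize >= 0L, p$effectSize >= 0,
              p$loading > 0, p$loading < 1, p$noiseSd > 0,
              p$samplesPerGroup >= 2L, p$baselineHazard > 0,
              p$censoringRate >= 0, p$censoringRate < 1,
              p$survivalN >= 2L, p$qpcrN >= 2L, p$ctNoiseSd > 0)
    if (p$nUp + p$nDown > p$genesTotal)
        stop("more planted genes than genes in the universe")
    if (p$coreSize > p$nUp + p$nDown)
        stop("core module larger than the planted gene set")
    class(p) <- "SimParams"
    p
}

## latent-factor coefficient giving pairwise within-module correlation
## r = loading when each gene is  b*f + noise  with f ~ N(0,1):
## r = b^2 / (b^2 + noiseSd^2)  =>  b = noiseSd * sqrt(r / (1 - r))
.factorCoef <- function(p) p$noiseSd * sqrt(p$loading / (1 - p$loading))

.plantTruth <- function(p) {
    genes <- sprintf("gene%04d", seq_len(p$genesTotal))
    planted <- sample(genes, p$nUp + p$nDown)
    up <- sort(planted[seq_len(p$nUp)])
    down <- sort(setdiff(planted, up))
    ## core module drawn from the downregulated set first (the study's core
    ## genes are under-expressed differentiation genes), then up if needed
    core <- c(down, up)[seq_len(p$coreSize)]
    coef <- c(rep(p$hazardCoef, length(up)), rep(-p$hazardCoef, length(down)))
    names(coef) <- c(up, down)
    list(planted_up = up, planted_down = down, core_module = sort(core),
         null_genes = sort(setdiff(genes, planted)), hazard_links = coef,
         genes = genes)
}

#' Simulate multi-cohort expression data with planted truth
#'
#' Each cohort is a genes-by-samples log2 matrix: null genes are baseline
#' plus Gaussian noise in both groups; planted genes are shifted in tumor
#' samples by a cohort-specific effect jittered around `effectSize`
#' (upregulated +, downregulated -); core-module genes additionally share
#' a latent factor in tumor samples, inducing pairwise Pearson correlation
#' approximately equal to `loading`. All cohorts share the same gene
#' universe and the same planted truth. Fully deterministic under
#' `params$seed`.
#'
#' @param params a [simParams()] object.
#' @return list with elements `cohorts` (list of
#'   [ExpressionCohort-class]) and `truth` (planted gene sets, core
#'   module, hazard links).
#' @export
simulateCohorts <- function(params) {
    stopifnot(inherits(params, "SimParams"))
    p <- params
    set.seed(p$seed)
    truth <- .plantTruth(p)
    nS <- 2L * p$samplesPerGroup
    group <- rep(c("tumor", "normal"), each = p$samplesPerGroup)
    b <- .factorCoef(p)
    baseline <- stats::runif(p$genesTotal, 4, 12)   # shared across cohorts
    names(baseline) <- truth$genes
    cohorts <- vector("list", p$nCohorts)
    for (k in seq_len(p$nCohorts)) {
        delta <- p$effectSize +
            if (p$effectSize > 0) stats::rnorm(1, 0, p$effectJitterSd) else 0
        m <- matrix(stats::rnorm(p$genesTotal * nS, 0, p$noiseSd),
                    p$genesTotal, nS,
                    dimnames = list(truth$genes,
                                    sprintf("c%d_s%02d", k, seq_len(nS))))
        m <- m + baseline
        tum <- group == "tumor"
        m[truth$planted_up, tum] <- m[truth$planted_up, tum] + delta
        m[truth$planted_down, tum] <- m[truth$planted_down, tum] - delta
        if (length(truth$core_module) && sum(tum)) {
            f <- stats::rnorm(sum(tum))
            m[truth$core_module, tum] <- m[truth$core_module, tum] +
                b * rep(f, each = length(truth$core_module))
        }
        cohorts[[k]] <- ExpressionCohort(m, group,
                                         datasetId = sprintf("synth%d", k))
    }
    truth$genes <- NULL
    list(cohorts = cohorts, truth = truth)
}

#' Simulate hazard-linked survival records
#'
#' Patients get standardized log2 expression for every gene in the truth's
#' universe-of-interest (planted genes plus a configurable number of null
#' genes); core-module genes share the latent factor. Event times are
#' exponential with log-hazard
#' `log(baselineHazard) + sum(coef * z)` over the hazard-linked genes, and
#' censoring times are uniform on `(0, b)` with `b` solved so the expected
#' censored fraction equals `censoringRate`.
#'
#' @param truth planted truth from [simulateCohorts()].
#' @param params a [simParams()] object.
#' @param nNull number of unlinked null genes to carry along (for
#'   false-positive-rate checks).
#' @param endpoint `"OS"` or `"RFS"`; the two endpoints use independent
#'   random draws from the same truth.
#' @return `data.frame` with columns `patient_id`, `time`, `event`, then
#'   one column of standardized expression per gene.
#' @export
simulateSurvival <- function(truth, params, nNull = 10L,
                             endpoint = c("OS", "RFS")) {
    stopifnot(inherits(params, "SimParams"))
    endpoint <- match.arg(endpoint)
    p <- params
    set.seed(p$seed + if (endpoint == "OS") 1000L else 1500L)
    n <- p$survivalN
    genes <- c(truth$planted_up, truth$planted_down,
               utils::head(truth$null_genes, nNull))
    z <- matrix(stats::rnorm(n * length(genes)), n, length(genes),
                dimnames = list(NULL, genes))
    if (length(truth$core_module)) {
        ## same latent-factor structure as the expression cohorts, on the
        ## standardized scale: z = sqrt(r)*f + sqrt(1-r)*e
        f <- stats::rnorm(n)
        r <- p$loading
        z[, truth$core_module] <- sqrt(r) * f +
            sqrt(1 - r) * z[, truth$core_module]
    }
    coef <- truth$hazard_links
    lp <- if (length(coef)) drop(z[, names(coef), drop = FALSE] %*% coef)
          else rep(0, n)
    rate <- p$baselineHazard * exp(lp)
    t_event <- stats::rexp(n, rate)
    if (p$censoringRate > 0) {
        ## b solved so mean over subjects of P(U(0,b) < Exp(rate_i)) hits
        ## the target censored fraction
        censFrac <- function(b) mean((1 - exp(-rate * b)) / (rate * b))
        lo <- 1e-6; hi <- 1
        while (censFrac(hi) > p$censoringRate && hi < 1e9) hi <- hi * 2
        b <- stats::uniroot(function(x) censFrac(x) - p$censoringRate,
                            c(lo, hi))$root
        t_cens <- stats::runif(n, 0, b)
        event <- as.integer(t_event <= t_cens)
        time <- pmin(t_event, t_cens)
    } else {
        event <- rep(1L, n)
        time <- t_event
    }
    data.frame(patient_id = sprintf("p%03d", seq_len(n)),
               time = time, event = event, z,
               check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulate a large validation cohort from an existing planted truth
#'
#' Emulates the large-sample verification step: one extra cohort drawn
#' from the same planted truth (same gene universe, directions and core
#' module) but with its own samples, typically many more of them, and no
#' inter-platform effect jitter.
#'
#' @param truth planted truth from [simulateCohorts()].
#' @param params a [simParams()] object.
#' @param samplesPerGroup tumor (= normal) sample count (default 250).
#' @param datasetId cohort label.
#' @return an [ExpressionCohort-class].
#' @export
simulateValidationCohort <- function(truth, params, samplesPerGroup = 250L,
                                     datasetId = "validation") {
    stopifnot(inherits(params, "SimParams"))
    p <- params
    set.seed(p$seed + 3000L)
    genes <- sort(c(truth$planted_up, truth$planted_down, truth$null_genes))
    nS <- 2L * as.integer(samplesPerGroup)
    group <- rep(c("tumor", "normal"), each = samplesPerGroup)
    m <- matrix(stats::rnorm(length(genes) * nS, 0, p$noiseSd),
                length(genes), nS,
                dimnames = list(genes, sprintf("v_s%03d", seq_len(nS))))
    m <- m + stats::runif(length(genes), 4, 12)
    tum <- group == "tumor"
    m[truth$planted_up, tum] <- m[truth$planted_up, tum] + p$effectSize
    m[truth$planted_down, tum] <- m[truth$planted_down, tum] - p$effectSize
    if (length(truth$core_module)) {
        f <- stats::rnorm(sum(tum))
        m[truth$core_module, tum] <- m[truth$core_module, tum] +
            .factorCoef(p) * rep(f, each = length(truth$core_module))
    }
    ExpressionCohort(m, group, datasetId = datasetId)
}

#' Simulate paired tumor/adjacent qPCR Ct records
#'
#' Long-format Ct table for `qpcrN` patients: each planted-down gene has a
#' tumor-minus-adjacent delta-delta-Ct of `+ctEffect` (more cycles = less
#' transcript), each planted-up gene `-ctEffect`, and the reference gene a
#' planted effect of exactly zero. Gaussian measurement noise `ctNoiseSd`
#' on every Ct value.
#'
#' @inheritParams simulateSurvival
#' @return `data.frame` of Ct records (`patient_id`, `tissue`, `gene`,
#'   `ct`).
#' @export
simulateCt <- function(truth, params) {
    stopifnot(inherits(params, "SimParams"))
    p <- params
    set.seed(p$seed + 2000L)
    genes <- c(truth$planted_up, truth$planted_down, p$referenceGene)
    effect <- c(rep(-p$ctEffect, length(truth$planted_up)),
                rep(p$ctEffect, length(truth$planted_down)), 0)
    names(effect) <- genes
    base <- stats::runif(length(genes), 18, 28)   # per-gene adjacent-tissue Ct
    names(base) <- genes
    grid <- expand.grid(gene = genes,
                        tissue = c("adjacent", "tumor"),
                        patient_id = sprintf("q%02d", seq_len(p$qpcrN)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ## patient-level Ct offset (RNA input/quality) cancels within ddCt
    pat_off <- stats::rnorm(p$qpcrN, 0, 1)
    names(pat_off) <- sprintf("q%02d", seq_len(p$qpcrN))
    ct <- base[grid$gene] + pat_off[grid$patient_id] +
        ifelse(grid$tissue == "tumor", effect[grid$gene], 0) +
        stats::rnorm(nrow(grid), 0, p$ctNoiseSd)
    out <- data.frame(patient_id = grid$patient_id, tissue = grid$tissue,
                      gene = grid$gene, ct = as.numeric(ct),
                      stringsAsFactors = FALSE)
    out[order(out$patient_id, out$tissue, method = "radix"), , drop = FALSE]
}
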