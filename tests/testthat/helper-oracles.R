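# Independent oracles kept deliberately naive: they re-state the
# definitions as double loops / hand arithmetic, not as calls into the
# code paths they check.

# brute-force cumulative correlation scores (naive double loop)
bruteCumulative <- function(r) {
    n <- nrow(r)
    cum <- stats::setNames(numeric(n), rownames(r))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        a <- abs(r[i, j])
        s <- if (a < 0.4) 0 else if (a < 0.6) 1 else if (a < 0.8) 2 else 3
        cum[i] <- cum[i] + s
    }
    cum
}

# a valid random correlation matrix via cor() of a random data matrix
randomCorrMatrix <- function(nGenes, nSamples = nGenes + 5L) {
    x <- matrix(stats::rnorm(nSamples * nGenes), nSamples, nGenes)
    r <- stats::cor(x)
    dimnames(r) <- list(paste0("g", seq_len(nGenes)),
                        paste0("g", seq_len(nGenes)))
    (r + t(r)) / 2
}

# small deterministic cohort: first `nTumorUp` genes shifted up in tumor
toyCohort <- function(nGenes = 6L, nPerGroup = 5L, shift = 3, sd = 0.3,
                      seed = 1L, id = "toy") {
    set.seed(seed)
    m <- matrix(stats::rnorm(nGenes * 2L * nPerGroup, 8, sd),
                nGenes, 2L * nPerGroup,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(2L * nPerGroup))))
    grp <- rep(c("tumor", "normal"), each = nPerGroup)
    m[1L, grp == "tumor"] <- m[1L, grp == "tumor"] + shift
    ExpressionCohort(m, grp, id)
}

# random censored survival sample with ties (integer times)
randomSurvivalData <- function(n, seed) {
    set.seed(seed)
    time <- ceiling(stats::rexp(n, 0.2))
    event <- stats::rbinom(n, 1L, 0.7)
    data.frame(time = time, event = event)
}
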