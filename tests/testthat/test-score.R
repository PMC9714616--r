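test_that("Pearson matrix captures exact linear relations", {
    set.seed(5)
    n <- 12L
    g1 <- rnorm(n, 8)
    m <- rbind(g1 = g1, g2 = 2 * g1 + 1, g3 = -g1)
    colnames(m) <- paste0("s", seq_len(n))
    co <- ExpressionCohort(m, rep(c("tumor", "normal"), each = n / 2), "lin")
    r <- pearsonMatrix(co, c("g1", "g2", "g3"), group = "all")
    expect_equal(r["g1", "g2"], 1, tolerance = 1e-12)
    expect_equal(r["g1", "g3"], -1, tolerance = 1e-12)
    expect_equal(diag(r), c(g1 = 1, g2 = 1, g3 = 1))
    expect_equal(r, t(r))
})

test_that("independent genes decorrelate at large n", {
    set.seed(6)
    m <- matrix(rnorm(2 * 1000, 8), 2, 1000,
                dimnames = list(c("a", "b"), paste0("s", 1:1000)))
    co <- ExpressionCohort(m, rep("tumor", 1000), "null")
    r <- pearsonMatrix(co, c("a", "b"))
    expect_lt(abs(r["a", "b"]), 0.1)
})

test_that("zero-variance genes are flagged and excluded", {
    m <- rbind(a = rnorm(10, 8), b = rnorm(10, 8), flat = rep(2, 10))
    colnames(m) <- paste0("s", 1:10)
    co <- ExpressionCohort(m, rep("tumor", 10), "zv")
    expect_warning(r <- pearsonMatrix(co, c("a", "b", "flat")),
                   "zero-variance.*flat")
    expect_identical(rownames(r), c("a", "b"))
})

test_that("correlation binning follows the 0.4/0.6/0.8 point scale", {
    expect_identical(binCorrelation(c(0.35, -0.5, 0.7, -0.9)),
                     c(0L, 1L, 2L, 3L))
    expect_identical(binCorrelation(c(0, 1, -1)), c(0L, 3L, 3L))
    # left-closed boundaries fall upward
    expect_identical(binCorrelation(c(0.4, 0.6, 0.8)), c(1L, 2L, 3L))
    expect_error(binCorrelation(1.2), "<= 1")
})

test_that("cumulative scores match hand-binned toy matrices", {
    r <- matrix(c(1, 0.9, 0.5,
                  0.9, 1, 0.3,
                  0.5, 0.3, 1), 3, 3,
                dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
    st <- cumulativeScores(r)
    expect_equal(cumulativeScore(st), c(g1 = 4, g2 = 3, g3 = 1))
    expect_identical(geneRanks(st), c(g1 = 1L, g2 = 2L, g3 = 3L))
    # 18 genes all pairwise |r| >= 0.8: every cumulative = 3 * 17 = 51
    n <- 18L
    r2 <- matrix(0.85, n, n); diag(r2) <- 1
    dimnames(r2) <- list(paste0("g", 1:n), paste0("g", 1:n))
    expect_true(all(cumulativeScore(cumulativeScores(r2)) == 51))
    # all very weak: all zero
    r3 <- matrix(0.1, 4, 4); diag(r3) <- 1
    dimnames(r3) <- list(letters[1:4], letters[1:4])
    expect_true(all(cumulativeScore(cumulativeScores(r3)) == 0))
})

test_that("cumulative scores equal the brute-force double loop on random matrices", {
    set.seed(42)
    for (i in 1:100) {
        r <- randomCorrMatrix(sample(2:20, 1))
        st <- cumulativeScores(r)
        expect_identical(unname(cumulativeScore(st)),
                         unname(bruteCumulative(r)))
        # handshake identity
        ps <- pairScores(st)
        expect_equal(sum(cumulativeScore(st)), sum(ps, na.rm = TRUE))
        expect_lte(max(cumulativeScore(st)), 3 * (nrow(r) - 1))
    }
})

test_that("scores are invariant under gene-order permutation", {
    set.seed(7)
    r <- randomCorrMatrix(10)
    st <- cumulativeScore(cumulativeScores(r))
    perm <- sample(10)
    st2 <- cumulativeScore(cumulativeScores(r[perm, perm]))
    expect_equal(st2[names(st)], st)
})

test_that("top-k ranking is dense, alphabetical on ties, and expands ties", {
    cum <- c(A = 12, B = 12, C = 10, D = 9, E = 8)   # max 3(n-1) = 12
    # build a ScoreTable shell around the chosen cumulative scores
    rk <- match(-cum, sort(unique(-cum)))
    st <- new("ScoreTable", genes = names(cum),
              r = diag(5), pairScores = {
                  m <- matrix(0L, 5, 5); diag(m) <- NA_integer_
                  dimnames(m) <- list(names(cum), names(cum)); m
              },
              cumulative = cum, rank = as.integer(rk))
    top <- rankCoreGenes(st, 4)
    expect_identical(as.character(top), c("A", "B", "C", "D"))
    expect_false(attr(top, "tieExpanded"))
    # all-equal scores: k = 1 returns everything, flagged
    cumEq <- c(A = 3, B = 3, C = 3)
    stEq <- new("ScoreTable", genes = names(cumEq), r = diag(3),
                pairScores = {
                    m <- matrix(1L, 3, 3); diag(m) <- NA_integer_
                    dimnames(m) <- list(names(cumEq), names(cumEq)); m
                },
                cumulative = cumEq, rank = rep(1L, 3))
    topEq <- rankCoreGenes(stEq, 1)
    expect_identical(as.character(topEq), c("A", "B", "C"))
    expect_true(attr(topEq, "tieExpanded"))
    expect_length(rankCoreGenes(st, 5), 5L)
})

test_that("planted core module tops the ranking on synthetic cohorts", {
    p <- simParams(seed = 301)
    sim <- simulateCohorts(p)
    risk <- c(sim$truth$planted_up, sim$truth$planted_down)
    val <- simulateValidationCohort(sim$truth, p)
    st <- cumulativeScores(pearsonMatrix(val, risk, group = "tumor"))
    top <- rankCoreGenes(st, length(sim$truth$core_module))
    expect_setequal(as.character(top), sim$truth$core_module)
})
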