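mkCt <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(patient_id = r[[1]], tissue = r[[2]], gene = r[[3]],
                   ct = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

test_that("delta-delta-Ct analytics are exact", {
    ct <- mkCt(list("p1", "tumor", "T", 25), list("p1", "tumor", "ACTB", 20),
               list("p1", "adjacent", "T", 24),
               list("p1", "adjacent", "ACTB", 20))
    re <- deltaDeltaCt(ct, "T")
    expect_equal(re$delta_delta_ct, 1)
    expect_equal(re$fold_change, 0.5)
    # all four Ct equal: no change
    ct0 <- mkCt(list("p1", "tumor", "T", 22), list("p1", "tumor", "ACTB", 22),
                list("p1", "adjacent", "T", 22),
                list("p1", "adjacent", "ACTB", 22))
    re0 <- deltaDeltaCt(ct0, "T")
    expect_equal(re0$delta_delta_ct, 0)
    expect_equal(re0$fold_change, 1)
    # ddCt = -2 doubles twice
    ct2 <- mkCt(list("p1", "tumor", "T", 20), list("p1", "tumor", "ACTB", 20),
                list("p1", "adjacent", "T", 22),
                list("p1", "adjacent", "ACTB", 20))
    expect_equal(deltaDeltaCt(ct2, "T")$fold_change, 4)
})

test_that("fold-change inversion identity holds for random ddCt", {
    set.seed(8)
    d <- rnorm(50, 0, 3)
    expect_equal(2^(-d) * 2^(-(-d)), rep(1, 50), tolerance = 1e-12)
    # and through the API: relabeling tissues inverts the fold change
    p <- simParams(seed = 41)
    sim <- simulateCohorts(p)
    ct <- simulateCt(sim$truth, p)
    g <- sim$truth$planted_down[1]
    re <- deltaDeltaCt(ct, g)
    swapped <- ct
    swapped$tissue <- ifelse(ct$tissue == "tumor", "adjacent", "tumor")
    reSwap <- deltaDeltaCt(swapped, g)
    expect_equal(re$fold_change * reSwap$fold_change, rep(1, re$n),
                 tolerance = 1e-12)
    expect_equal(testRelativeExpression(re)$p_value,
                 testRelativeExpression(reSwap)$p_value, tolerance = 1e-12)
})

test_that("incomplete patient blocks are excluded; missing reference errors", {
    ct <- mkCt(list("p1", "tumor", "T", 25), list("p1", "tumor", "ACTB", 20),
               list("p1", "adjacent", "T", 24),
               list("p1", "adjacent", "ACTB", 20),
               list("p2", "tumor", "T", 25))   # p2 lacks everything else
    expect_message(re <- deltaDeltaCt(ct, "T"), "excluded 1 patient")
    expect_equal(re$n, 1L)
    expect_error(deltaDeltaCt(ct, "T", reference = "GAPDH"),
                 "reference gene")
    expect_error(deltaDeltaCt(ct, "ACTB", reference = "ACTB"),
                 "must differ")
})

test_that("planted Ct effects are recovered with correct sign at n = 8", {
    p <- simParams(seed = 43)
    sim <- simulateCohorts(p)
    ct <- simulateCt(sim$truth, p)
    for (g in sim$truth$planted_down) {
        re <- testRelativeExpression(deltaDeltaCt(ct, g))
        expect_lt(re$mean_fold_change, 1)
        expect_true(re$significant)
    }
    for (g in sim$truth$planted_up) {
        re <- testRelativeExpression(deltaDeltaCt(ct, g))
        expect_gt(re$mean_fold_change, 1)
        expect_true(re$significant)
    }
})

test_that("null planted effect rejects near the nominal rate", {
    hits <- 0L
    reps <- 200L
    for (s in seq_len(reps)) {
        p <- simParams(seed = 5000L + s, ctEffect = 0, nUp = 1L, nDown = 1L,
                       coreSize = 0L, genesTotal = 10L)
        truth <- simulateCohorts(p)$truth
        ct <- simulateCt(truth, p)
        re <- testRelativeExpression(deltaDeltaCt(ct, truth$planted_up[1]))
        hits <- hits + re$significant
    }
    expect_gt(hits / reps, 0.01)
    expect_lt(hits / reps, 0.12)
})

test_that("degenerate all-zero differences give p = 1; tiny n errors", {
    ct <- mkCt(list("p1", "tumor", "T", 22), list("p1", "tumor", "ACTB", 20),
               list("p1", "adjacent", "T", 22),
               list("p1", "adjacent", "ACTB", 20),
               list("p2", "tumor", "T", 23), list("p2", "tumor", "ACTB", 21),
               list("p2", "adjacent", "T", 23),
               list("p2", "adjacent", "ACTB", 21))
    re <- deltaDeltaCt(ct, "T")
    expect_equal(re$delta_delta_ct, c(0, 0))
    expect_equal(testRelativeExpression(re)$p_value, 1)
    one <- deltaDeltaCt(ct[ct$patient_id == "p1", ], "T")
    expect_error(testRelativeExpression(one), ">= 2 patients")
})
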