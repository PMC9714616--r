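test_that("KM estimator reproduces hand-computed product-limit values", {
    # three events, no censoring: S = 2/3, 1/3, 0
    km <- kmEstimator(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km@time, c(1, 2, 3))
    expect_equal(km@surv, c(2/3, 1/3, 0), tolerance = 1e-12)
    # censored at 1, events at 2 and 3: risk sets {2,3} -> S = 1/2, 0
    km2 <- kmEstimator(c(1, 2, 3), c(0, 1, 1))
    expect_equal(km2@time, c(2, 3))
    expect_equal(km2@surv, c(1/2, 0), tolerance = 1e-12)
    # all censored: flat curve, no event times
    km3 <- kmEstimator(c(1, 2, 3), c(0, 0, 0))
    expect_length(km3@time, 0L)
    expect_error(kmEstimator(numeric(0), numeric(0)), "no survival records")
})

test_that("KM estimator agrees with the survival package on random data", {
    skip_if_not_installed("survival")
    for (s in 1:100) {
        d <- randomSurvivalData(n = sample(5:50, 1), seed = s)
        km <- kmEstimator(d$time, d$event)
        sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
        ev <- sf$n.event > 0
        expect_equal(km@time, sf$time[ev], tolerance = 1e-12)
        expect_equal(km@surv, sf$surv[ev], tolerance = 1e-10)
        expect_equal(km@nRisk, sf$n.risk[ev])
        expect_equal(km@nEvent, sf$n.event[ev])
    }
})

test_that("log-rank gives chi2 = 0, p = 1 on identical groups", {
    d <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
    lr <- logrankTest(d, timeLow = d)
    expect_equal(lr@chiSquare, 0)
    expect_equal(lr@pValue, 1)
})

test_that("log-rank matches the survival package on toy and random data", {
    skip_if_not_installed("survival")
    hi <- data.frame(time = c(1, 2, 3), event = 1)
    lo <- data.frame(time = c(4, 5, 6), event = 1)
    lr <- logrankTest(hi, timeLow = lo)
    sd6 <- survival::survdiff(
        survival::Surv(time, event) ~ g,
        data = rbind(cbind(hi, g = 1), cbind(lo, g = 0)))
    expect_equal(lr@chiSquare, sd6$chisq, tolerance = 1e-8)
    expect_equal(lr@pValue,
                 stats::pchisq(sd6$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
    for (s in 1:30) {
        a <- randomSurvivalData(sample(5:40, 1), seed = 1000 + s)
        b <- randomSurvivalData(sample(5:40, 1), seed = 2000 + s)
        if (sum(a$event) + sum(b$event) == 0) next
        lr <- logrankTest(a, timeLow = b)
        sd <- survival::survdiff(
            survival::Surv(time, event) ~ g,
            data = rbind(cbind(a, g = 1), cbind(b, g = 0)))
        expect_equal(lr@chiSquare, sd$chisq, tolerance = 1e-8)
    }
})

test_that("log-rank is symmetric under group swap and needs events", {
    a <- randomSurvivalData(20, seed = 3)
    b <- randomSurvivalData(25, seed = 4)
    lr1 <- logrankTest(a, timeLow = b)
    lr2 <- logrankTest(b, timeLow = a)
    expect_equal(lr1@chiSquare, lr2@chiSquare, tolerance = 1e-12)
    expect_equal(lr1@pValue, lr2@pValue, tolerance = 1e-12)
    z <- data.frame(time = c(1, 2), event = 0)
    expect_error(logrankTest(z, timeLow = z), "no events")
})

test_that("expression dichotomization splits at the median cutoff", {
    rec <- data.frame(patient_id = paste0("p", 1:4), time = 1:4, event = 1,
                      TPO = c(1, 2, 3, 4), FLAT = 1)
    sp <- dichotomizeByExpression(rec, "TPO")
    expect_equal(sp$cutoff, 2.5)
    expect_identical(sp$high$patient_id, c("p3", "p4"))
    expect_identical(sp$low$patient_id, c("p1", "p2"))
    rec2 <- rec; rec2$TPO <- c(1, 1, 2, 2)
    sp2 <- dichotomizeByExpression(rec2, "TPO")
    expect_equal(nrow(sp2$high), 2L)
    expect_equal(nrow(sp2$low), 2L)
    expect_error(dichotomizeByExpression(rec, "FLAT"), "degenerate split")
    expect_error(dichotomizeByExpression(rec, "ABSENT"), "absent")
})

test_that("survival screen recovers a hazard-linked gene and respects alpha", {
    p <- simParams(seed = 31)
    sim <- simulateCohorts(p)
    # hazard link on one gene only
    g <- sim$truth$planted_up[1]
    truth <- sim$truth
    truth$hazard_links <- stats::setNames(1, g)
    surv <- simulateSurvival(truth, p, nNull = 30L)
    scr <- screenSurvival(c(g, utils::head(sim$truth$null_genes, 30L)),
                          surv)
    expect_true(scr$significant[scr$gene == g])
    # null genes reject at roughly the nominal rate
    nullRate <- mean(scr$significant[scr$gene != g])
    expect_lt(nullRate, 0.25)
    # vacuous gate
    scrAll <- screenSurvival(c(g, sim$truth$null_genes[1]), surv, alpha = 1)
    expect_true(all(scrAll$significant))
    # scanned cutoffs warn about optimism
    expect_warning(screenSurvival(g, surv, cutoff = "scan"), "optimistic")
})

test_that("hazard-linked high-expression group has worse survival", {
    p <- simParams(seed = 37)
    sim <- simulateCohorts(p)
    surv <- simulateSurvival(sim$truth, p)
    g <- sim$truth$planted_up[1]      # coefficient +1
    sp <- dichotomizeByExpression(surv, g)
    medSurv <- function(km) km@time[which(km@surv <= 0.5)[1]]
    expect_lt(medSurv(kmEstimator(sp$high)), medSurv(kmEstimator(sp$low)))
})
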