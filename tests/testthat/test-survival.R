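test_that("the product-limit estimate matches a hand computation", {
    time <- c(2, 3, 5, 7)
    event <- c(0, 1, 1, 0)
    km <- kmEstimate(time, event)
    s <- summary(km$fit, times = c(3, 5))$surv
    expect_equal(s, c(2 / 3, 1 / 3))
    expect_equal(km$median, 5)
    ref <- oracleKm(time, event)
    expect_equal(ref$surv, c(2 / 3, 1 / 3))
})

test_that("with no censoring the curve is the empirical survival function", {
    set.seed(21)
    time <- rexp(40, 0.1)
    km <- kmEstimate(time, rep(TRUE, 40))
    st <- sort(time)
    expect_equal(summary(km$fit, times = st)$surv,
                 (40 - seq_len(40)) / 40)
    # all censored: flat curve, undefined median
    km2 <- kmEstimate(time, rep(FALSE, 40))
    expect_true(all(km2$fit$surv == 1))
    expect_true(is.na(km2$median))
})

test_that("the log-rank statistic matches the O-E oracle", {
    set.seed(5)
    time <- c(rexp(25, 0.2), rexp(25, 0.5))
    event <- rbinom(50, 1, 0.8)
    group <- rep(c("a", "b"), each = 25)
    got <- logrankTest(time, event, group)
    expect_equal(got$chisq, oracleLogrank(time, event, group),
                 tolerance = 1e-8)
    # identical groups: statistic 0, p = 1
    t2 <- rep(c(1, 2, 3, 4), 2)
    e2 <- rep(c(1, 1, 0, 1), 2)
    g2 <- rep(c("a", "b"), each = 4)
    same <- logrankTest(t2, e2, g2)
    expect_equal(same$chisq, 0, tolerance = 1e-12)
    expect_equal(same$p, 1, tolerance = 1e-9)
    expect_error(logrankTest(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("the log-rank test detects a hazard ratio of 3", {
    rej <- mean(vapply(1:50, function(r) {
        set.seed(600 + r)
        time <- c(rexp(100, 0.1), rexp(100, 0.3))
        group <- rep(c("a", "b"), each = 100)
        logrankTest(time, rep(TRUE, 200), group)$p < 0.05
    }, TRUE))
    expect_gte(rej, 0.9)
})

test_that("Bonferroni adjustment is exact arithmetic with a cap", {
    expect_equal(bonferroniAdjust(0.01, 8), 0.08)
    expect_equal(bonferroniAdjust(0.005, 8), 0.04)
    expect_equal(bonferroniAdjust(0.5, 4), 1.0)
    expect_equal(bonferroniAdjust(c(0.002, 0.2), 5), c(0.01, 1.0))
    expect_error(bonferroniAdjust(c(0.1, 0.2), 1), "at least")
})

test_that("stratification assigns groups by the cutoff sign only", {
    cl <- data.frame(patient_id = paste0("P", 1:6),
                     time = c(10, 20, 30, 15, 25, 35),
                     event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                     mgmt = factor(rep("unknown", 6),
                                   levels = c("methylated", "unmethylated",
                                              "unknown")))
    v <- c(-0.6, -0.3, -0.5, 0.2, -0.49, -1.0)
    s <- stratifyCohort(cl, v, cutoff = -0.49, feature = "skew",
                        nTests = 8)
    expect_equal(as.character(s@groups),
                 ifelse(v >= -0.49, "group1", "group2"))
    expect_equal(s@adjustedP, min(1, 8 * s@logrankP))
    expect_error(stratifyCohort(cl, v, cutoff = 99), "degenerate-split")
})

test_that("the MGMT combination groups methylated low-feature patients", {
    cl <- data.frame(patient_id = paste0("P", 1:8),
                     time = c(40, 35, 12, 10, 30, 8, 20, 22),
                     event = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                               FALSE),
                     mgmt = factor(c("methylated", "methylated",
                                     "unmethylated", "unmethylated",
                                     "methylated", "unmethylated",
                                     "unknown", "methylated"),
                                   levels = c("methylated", "unmethylated",
                                              "unknown")))
    v <- c(-0.6, -0.55, -0.6, -0.1, -0.2, -0.7, -0.6, -0.52)
    s <- combineMgmt(cl, v, cutoff = -0.49, feature = "skew",
                     horizon = 30)
    # unknown MGMT excluded; methylated & value < cutoff -> group1
    expect_length(s@groups, 7L)
    known <- cl$mgmt != "unknown"
    expect_equal(as.character(s@groups),
                 ifelse(cl$mgmt[known] == "methylated" &
                        v[known] < -0.49, "methylated+low", "rest"))
    expect_false(is.null(s@survivalAt))
    expect_equal(unique(s@survivalAt$time), 30)
    expect_error(combineMgmt(cl, rep(0, 8), cutoff = -10), "degenerate")
})

test_that("external validation freezes cutoffs and ignores outcomes", {
    set.seed(8)
    n <- 30
    cl <- data.frame(patient_id = paste0("P", 1:n),
                     time = rexp(n, 0.05), event = rbinom(n, 1, 0.7) == 1,
                     mgmt = factor(sample(c("methylated", "unmethylated"),
                                          n, TRUE),
                                   levels = c("methylated", "unmethylated",
                                              "unknown")))
    x <- cbind(fA = rnorm(n), fB = rnorm(n))
    cuts <- data.frame(feature = c("fA", "fB"),
                       optimal = c(0.1, -0.2), median = c(0.0, 0.05))
    res <- validateExternal(cl, x, cuts, mode = "training_optimal")
    expect_named(res, c("fA", "fB"))
    expect_equal(as.character(res$fA@groups),
                 ifelse(x[, "fA"] >= 0.1, "group1", "group2"))
    expect_equal(res$fA@adjustedP, min(1, 2 * res$fA@logrankP))
    # shuffling outcomes must not change group assignment (leakage guard)
    cl2 <- cl
    perm <- sample(n)
    cl2$time <- cl$time[perm]
    cl2$event <- cl$event[perm]
    res2 <- validateExternal(cl2, x, cuts, mode = "training_optimal")
    expect_identical(res2$fA@groups, res$fA@groups)
    # the mode switch changes only the cutoff constants
    resM <- validateExternal(cl, x, cuts, mode = "training_median")
    expect_equal(as.character(resM$fA@groups),
                 ifelse(x[, "fA"] >= 0.0, "group1", "group2"))
    expect_error(validateExternal(cl, x[, "fA", drop = FALSE], cuts),
                 "configuration error")
})
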