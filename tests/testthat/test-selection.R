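test_that("standardization uses population SD and freezes its parameters", {
    x <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(2, 4, 9))
    expect_warning(std <- standardizeFeatures(x), "constant")
    expect_equal(std$x[, "f1"], c(-1, 0, 1) * sqrt(3 / 2),
                 ignore_attr = TRUE)
    expect_equal(std$dropped, "f2")
    expect_equal(colMeans(std$x), c(f1 = 0, f3 = 0))
    # idempotence up to tolerance
    std2 <- standardizeFeatures(std$x)
    expect_equal(std2$x, std$x, tolerance = 1e-12)
    # frozen transform applies unchanged to new data
    xv <- cbind(f1 = c(10, -2), f3 = c(0, 1))
    expect_equal(applyStandardization(xv, std$center, std$scale)[, "f1"],
                 (c(10, -2) - 2) / sqrt(2 / 3), ignore_attr = TRUE)
    # missing values exclude the feature, not the patient
    xm <- cbind(f1 = c(1, 2, NA), f2 = c(1, 3, 5))
    expect_warning(stdm <- standardizeFeatures(xm), "incomplete")
    expect_equal(colnames(stdm$x), "f2")
})

test_that("LASSO recovers a planted predictor among pure noise", {
    hits <- 0L
    for (rep in 1:20) {
        set.seed(400 + rep)
        n <- 200
        x <- matrix(rnorm(n * 50), n,
                    dimnames = list(NULL, paste0("noise", 1:50)))
        planted <- rnorm(n)
        prob <- plogis(2.0 * planted)   # planted log-odds 2.0
        y <- rbinom(n, 1, prob)
        xx <- cbind(planted = planted, x)
        sel <- lassoSelect(scale(xx), y, seed = rep)
        if ("planted" %in% selectedFeatures(sel)$feature) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("duplicated informative features are not selected together", {
    set.seed(77)
    n <- 300
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * z))
    x <- cbind(a = z, b = z, n1 = rnorm(n), n2 = rnorm(n))
    sel <- selectedFeatures(lassoSelect(scale(x), y, seed = 1))
    expect_lte(sum(c("a", "b") %in% sel$feature), 1L)
    # coefficients are reported in decreasing absolute value
    expect_false(is.unsorted(rev(abs(sel$coefficient))))
})

test_that("selection demands both outcome classes", {
    x <- matrix(rnorm(40), 20)
    colnames(x) <- c("a", "b")
    expect_error(lassoSelect(x, rep(1, 20)), "both")
})

test_that("Youden cutpoint equals exhaustive search", {
    res <- youdenCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
    expect_equal(res$cutoff, 2.5)
    expect_equal(res$J, 1)
    expect_equal(res$orientation, "ge")
    # status independent of the feature: J = 0
    ind <- youdenCutoff(c(1, 2, 1, 2), c(0, 0, 1, 1))
    expect_equal(ind$J, 0)
    for (seed in 1:50) {
        set.seed(seed)
        n <- sample(6:40, 1)
        v <- round(rnorm(n), 2)
        s <- rbinom(n, 1, 0.5)
        if (length(unique(s)) < 2 || length(unique(v)) < 2) next
        got <- youdenCutoff(v, s)
        ref <- oracleYouden(v, s)
        expect_equal(got$J, ref$J)
        expect_equal(got$cutoff, ref$cutoff)
    }
    expect_error(youdenCutoff(rep(1, 6), c(0, 0, 0, 1, 1, 1)), "constant")
})

test_that("Youden cutpoint agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(123)
    v <- rnorm(60)
    s <- rbinom(60, 1, plogis(1.5 * v))
    got <- youdenCutoff(v, s)
    roc <- pROC::roc(s, v, quiet = TRUE, direction = "<")
    best <- pROC::coords(roc, "best", best.method = "youden",
                         ret = c("threshold", "youden"))
    expect_equal(got$J, max(best$youden) - 1, tolerance = 1e-9)
})
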