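test_that("phantoms are deterministic given the seed", {
    a <- makePhantom(smallPhantom(seed = 42))
    b <- makePhantom(smallPhantom(seed = 42))
    d <- makePhantom(smallPhantom(seed = 43))
    expect_identical(getSequence(a, "T1WI_CE"), getSequence(b, "T1WI_CE"))
    expect_identical(tumorMask(a), tumorMask(b))
    expect_false(identical(getSequence(a, "T1WI"), getSequence(d, "T1WI")))
    expect_identical(extractFeatures(a, families = "histogram"),
                     extractFeatures(b, families = "histogram"))
})

test_that("an equal-axis phantom is nearly spherical", {
    st <- makePhantom(smallPhantom(seed = 1, axes = c(8, 8, 8)))
    f <- shapeFeatures(tumorMask(st), voxelSpacing(st))
    expect_gte(f[["sphericity"]], 0.95)
})

test_that("a spec whose ellipsoid exceeds the grid is rejected", {
    expect_error(PhantomSpec(gridSize = c(24L, 24L, 24L), axes = c(12, 8, 8)),
                 "exceeds the grid")
    expect_error(PhantomSpec(axes = c(-1, 5, 5)), "positive")
})

test_that("rim edge width drives Gabor edge skewness monotonically", {
    lv <- c(0.3, 0.7, 1.1, 1.5, 2.0)
    mn <- vapply(lv, function(sg) {
        mean(vapply(1:4, function(sd) {
            st <- makePhantom(smallPhantom(seed = 300 + sd, rimWidth = sg))
            m <- gaborBank(st, sequences = "T1WI_CE", thetas = 0,
                           frequencies = "2", restrict = "mask")[[1]]
            gaborStats(m, tumorMask(st))[["skewness"]]
        }, 1))
    }, 1)
    expect_equal(abs(cor(lv, mn, method = "spearman")), 1)
})

test_that("short texture correlation lengths raise GLCM contrast", {
    con <- vapply(c(0.6, 2.5), function(tl) {
        mean(vapply(1:3, function(sd) {
            st <- makePhantom(smallPhantom(seed = 500 + sd,
                                           textureLength = tl))
            q <- quantizeVolume(getSequence(st, "T1WI"), tumorMask(st),
                                128L)
            glcmFeatures(glcmMatrix(q))[["contrast"]]
        }, 1))
    }, 1)
    expect_gt(con[1], con[2])
})

test_that("FLAIR carries an edema halo beyond the tumor mask", {
    st <- makePhantom(smallPhantom(seed = 9))
    m <- tumorMask(st)
    fl <- getSequence(st, "FLAIR")
    spec <- smallPhantom(seed = 9)
    # voxels just outside the mask are brighter on FLAIR than background
    d <- dim(m)
    ctr <- round((d + 1) / 2)
    edge <- fl[ctr[1] + round(spec@axes[1]) + 1, ctr[2], ctr[3]]
    bg <- fl[2, 2, 2]
    expect_gt(edge, bg + spec@haloContrast / 2)
})

test_that("simulated outcomes follow the proportional-hazards model", {
    cs <- smallCohort(n = 1000L, seed = 77L)
    tr <- simulateOutcomes(cs)
    expect_equal(nrow(tr), 1000L)
    expect_true(all(tr$time > 0))
    # empirical event count within 3 SE of the analytic expectation
    lam <- exp(tr$loghazard)
    Tm <- cs@censorTmax
    pEvent <- 1 - (1 - exp(-lam * Tm)) / (lam * Tm)
    mu <- sum(pEvent)
    se <- sqrt(sum(pEvent * (1 - pEvent)))
    expect_lt(abs(sum(tr$event) - mu), 3 * se)
    # removing censoring yields all events
    noCens <- simulateOutcomes(smallCohort(n = 200L, seed = 3L,
                                           censorTmax = 1e6))
    expect_true(all(noCens$event))
})

test_that("a protective MGMT effect yields longer methylated survival", {
    better <- vapply(1:50, function(r) {
        cs <- smallCohort(n = 200L, seed = 700L + r, betaImg = 0,
                          betaMgmt = -0.7)
        tr <- simulateOutcomes(cs)
        med <- function(sel) {
            f <- survival::survfit(
                survival::Surv(tr$time[sel], tr$event[sel]) ~ 1)
            unname(summary(f)$table["median"])
        }
        m1 <- med(tr$mgmt == "methylated")
        m0 <- med(tr$mgmt == "unmethylated")
        is.na(m1) || (!is.na(m0) && m1 > m0)
    }, TRUE)
    expect_gte(mean(better), 0.9)
})

test_that("outcome redraws keep patients fixed and honor new coefficients", {
    cs <- smallCohort(n = 50L, seed = 12L)
    tr <- simulateOutcomes(cs)
    tr2 <- redrawOutcomes(tr, cs, seed = 99L)
    expect_identical(tr2$param, tr$param)
    expect_identical(tr2$mgmt, tr$mgmt)
    expect_false(identical(tr2$time, tr$time))
    csNull <- smallCohort(n = 50L, seed = 12L, betaImg = 0, betaMgmt = 0)
    tr3 <- redrawOutcomes(tr, csNull, seed = 99L)
    expect_true(all(tr3$loghazard == csNull@beta0))
})

test_that("cohorts pass through the real I/O path losslessly", {
    dir <- withr::local_tempdir()
    cs <- smallCohort(n = 2L, seed = 5L)
    ch <- makeCohort(cs, dir = dir, keepStudies = TRUE)
    p1 <- ch$truth$patient_id[1]
    st <- loadStudy(file.path(dir, paste0(p1, "_t1.nii.gz")),
                    file.path(dir, paste0(p1, "_t1ce.nii.gz")),
                    file.path(dir, paste0(p1, "_flair.nii.gz")),
                    file.path(dir, paste0(p1, "_mask.nii.gz")), id = p1)
    expect_equal(getSequence(st, "T1WI_CE"),
                 getSequence(ch$studies[[1]], "T1WI_CE"))
    cl <- loadClinical(file.path(dir, "clinical.csv"))
    expect_equal(cl$time, ch$clinical$time, tolerance = 1e-6)
    expect_equal(as.character(cl$mgmt), as.character(ch$clinical$mgmt))
})
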