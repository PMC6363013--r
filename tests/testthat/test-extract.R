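test_that("the catalog has exactly 286 stable, ordered names", {
    cat <- featureCatalog()
    expect_equal(nrow(cat), 286L)
    expect_equal(anyDuplicated(cat$name), 0L)
    expect_equal(sum(cat$family == "histogram"), 60L)
    expect_equal(sum(cat$family == "glcm"), 78L)
    expect_equal(sum(cat$family == "glszm"), 48L)
    expect_equal(sum(cat$family == "gabor"), 96L)
    expect_equal(sum(cat$family == "morphology"), 4L)
    expect_equal(sum(cat$sequence == "T1WI_CE" &
                     cat$family == "histogram"), 20L)
    expect_true("T1WI_CE.gabor.theta0_f2_skewness" %in% cat$name)
    expect_true("T1WI_CE.histogram.p10" %in% cat$name)
    expect_true("FLAIR.histogram.iqr" %in% cat$name)
    expect_true("T1WI.glcm.cluster_prominence" %in% cat$name)
    expect_true("T1WI.glcm.difference_variance" %in% cat$name)
    expect_true(all(c("shape.morphology.sphericity",
                      "shape.morphology.surface_to_volume_ratio") %in%
                    cat$name))
})

test_that("extraction yields the full deterministic catalog", {
    st <- makePhantom(smallPhantom(seed = 8))
    f1 <- extractFeatures(st)
    expect_length(f1, 286L)
    expect_identical(names(f1), featureCatalog()$name)
    expect_identical(f1, extractFeatures(st))
    # family subsets line up with the catalog subsets
    fg <- extractFeatures(st, families = "gabor")
    expect_identical(names(fg), featureCatalog("gabor")$name)
    expect_identical(unname(fg), unname(f1[names(fg)]))
})

test_that("texture blocks are invariant to affine intensity rescaling", {
    st <- makePhantom(smallPhantom(seed = 11))
    st2 <- MRIStudy(patientId(st), 2.5 * getSequence(st, "T1WI") + 40,
                    getSequence(st, "T1WI_CE"), getSequence(st, "FLAIR"),
                    tumorMask(st), voxelSpacing(st))
    f1 <- extractFeatures(st, families = c("glcm", "glszm"))
    f2 <- extractFeatures(st2, families = c("glcm", "glszm"))
    expect_equal(f1, f2)
    h1 <- extractFeatures(st, families = "histogram")
    h2 <- extractFeatures(st2, families = "histogram")
    expect_false(isTRUE(all.equal(h1[["T1WI.histogram.mean"]],
                                  h2[["T1WI.histogram.mean"]])))
})

test_that("permuting voxels preserves histograms but not texture", {
    set.seed(14)
    d <- c(6, 6, 2)
    v <- array(sort(rnorm(prod(d))), d)   # spatially ordered values
    m <- array(1L, d)
    perm <- sample(prod(d))
    vp <- array(as.vector(v)[perm], d)
    expect_equal(histogramFeatures(v, m), histogramFeatures(vp, m))
    c1 <- glcmFeatures(glcmMatrix(quantizeVolume(v, m, 8L)))[["contrast"]]
    c2 <- glcmFeatures(glcmMatrix(quantizeVolume(vp, m, 8L)))[["contrast"]]
    expect_false(isTRUE(all.equal(c1, c2)))
})

test_that("a cohort experiment carries features, catalog and clinical data", {
    cs <- smallCohort(n = 6L, seed = 21L)
    re <- extractCohortFeatures(cs, families = c("histogram", "shape"))
    expect_s4_class(re, "RadiomicsExperiment")
    expect_equal(dim(re), c(64L, 6L))
    cd <- SummarizedExperiment::colData(re)
    expect_true(all(c("time", "event", "mgmt") %in% colnames(cd)))
    expect_equal(SummarizedExperiment::rowData(re)$family[1], "histogram")
    x <- featureMatrix(re)
    expect_equal(dim(x), c(6L, 64L))
    cl <- clinicalTable(re)
    expect_equal(cl$time, S4Vectors::metadata(re)$truth$time)
    # shape features depend only on the mask, not the sequence intensities
    st <- makePhantom(RadSurv:::phantomSpecFor(
        cs, S4Vectors::metadata(re)$truth[1, ]))
    expect_equal(unname(x[1, "shape.morphology.volume"]),
                 sum(tumorMask(st)) * prod(voxelSpacing(st)))
})
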