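test_that("NIfTI round-trip preserves voxel values and geometry", {
    st <- makePhantom(smallPhantom(seed = 4))
    dir <- withr::local_tempdir()
    paths <- writeStudy(st, dir)
    st2 <- loadStudy(paths["t1"], paths["t1ce"], paths["flair"],
                     paths["mask"], id = patientId(st))
    expect_equal(getSequence(st2, "T1WI"), getSequence(st, "T1WI"))
    expect_equal(getSequence(st2, "T1WI_CE"), getSequence(st, "T1WI_CE"))
    expect_equal(getSequence(st2, "FLAIR"), getSequence(st, "FLAIR"))
    expect_identical(tumorMask(st2), tumorMask(st))
    expect_equal(voxelSpacing(st2), voxelSpacing(st))
    # binarization is idempotent: reloading the already-binary mask again
    st3 <- loadStudy(paths["t1"], paths["t1ce"], paths["flair"],
                     paths["mask"], id = "again")
    expect_identical(tumorMask(st3), tumorMask(st2))
})

test_that("geometry and mask contract violations are reported", {
    st <- makePhantom(smallPhantom(seed = 5))
    dir <- withr::local_tempdir()
    paths <- writeStudy(st, dir)
    # empty mask
    empty <- file.path(dir, "empty_mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0L, dim(tumorMask(st))),
                                       pixdim = voxelSpacing(st)), empty)
    expect_error(loadStudy(paths["t1"], paths["t1ce"], paths["flair"],
                           empty, id = "x"), "empty-mask")
    # mismatched dimensions on one volume
    odd <- file.path(dir, "odd_flair.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, c(33, 32, 32)),
                                       pixdim = c(1, 1, 1)), odd)
    expect_error(loadStudy(paths["t1"], paths["t1ce"], odd,
                           paths["mask"], id = "x"),
                 "geometry error.*flair")
    expect_error(loadStudy(paths["t1"], paths["t1ce"], paths["flair"],
                           file.path(dir, "nope.nii"), id = "x"),
                 "not found")
})

test_that("clinical CSV parsing maps fields and validates times", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("patient_id,time,event,mgmt",
                 "P1,36.0,1,methylated",
                 "P2,43.0,0,",
                 "P3,12.5,1,Unmethylated"), f)
    cl <- loadClinical(f)
    expect_equal(cl$time, c(36, 43, 12.5))
    expect_equal(cl$event, c(TRUE, FALSE, TRUE))
    expect_equal(as.character(cl$mgmt),
                 c("methylated", "unknown", "unmethylated"))
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("patient_id,time,event,mgmt", "P1,0,1,methylated"), f2)
    expect_error(loadClinical(f2), "row\\(s\\) 1")
    # day-scale conversion
    f3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("patient_id,time,event,mgmt", "P1,587,1,methylated"), f3)
    expect_equal(loadClinical(f3, daysToMonths = TRUE)$time, 587 / 30.44)
    # round trip through writeClinical
    out <- withr::local_tempfile(fileext = ".csv")
    writeClinical(cl, out)
    expect_equal(loadClinical(out), cl)
})

test_that("MRIStudy validity enforces the geometric contract", {
    a <- array(1, c(4, 4, 4))
    m <- array(1L, c(4, 4, 4))
    expect_error(MRIStudy("x", a, a, array(1, c(5, 4, 4)), m),
                 "grid")
    expect_error(MRIStudy("x", a, a, a, array(0L, c(4, 4, 4))), "empty")
    expect_error(MRIStudy("x", a, a, a, m, spacing = c(1, -1, 1)),
                 "positive")
})
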