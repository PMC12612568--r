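test_that("subject sampling is seed-deterministic and validates inputs", {
  cal <- defaultCalibration("metastasis")
  t1 <- sampleSubjectParams("metastasis", cal, seed = 7)
  t2 <- sampleSubjectParams("metastasis", cal, seed = 7)
  expect_identical(t1@anchors, t2@anchors)
  expect_identical(t1@volumes, t2@volumes)
  expect_error(sampleSubjectParams("carcinoma", cal, seed = 1),
               "unknown group")
  bad <- cal
  bad@params$median[1] <- 2  # f median outside (0,1)
  expect_error(sampleSubjectParams("metastasis", bad, seed = 1))
})

test_that("sampled anchors recover the calibrated medians and IQRs", {
  for (grp in c("HGG", "metastasis")) {
    cal <- defaultCalibration(grp)
    subs <- lapply(1:500, function(i)
      sampleSubjectParams(grp, cal, seed = 10000 + i))
    for (tis in c("enhancing", "non_enhancing", "edema")) {
      for (par in c("f", "D", "Dstar", "K")) {
        vals <- vapply(subs, function(s) s@anchors[tis, par], 0)
        if (par %in% c("D", "Dstar")) vals <- vals * 1e6
        row <- cal@params[cal@params$tissue == tis &
                          cal@params$param == par, ]
        med <- median(vals)
        expect_gte(med, row$q25)
        expect_lte(med, row$q75)
      }
    }
    # absence frequency tracks the calibrated probability
    absent <- mean(!vapply(subs, function(s)
      s@presence[["non_enhancing"]], TRUE))
    expect_lt(abs(absent - cal@absenceProb[["non_enhancing"]]), 0.07)
  }
})

test_that("lesion geometry hits target volumes with disjoint nested masks", {
  truth <- makeTruth(volumes = c(12, 8, 40))
  m <- buildLesionGeometry(truth, c(32, 32, 32), c(4, 4, 4), seed = 3)
  vv <- prod(c(4, 4, 4)) / 1000
  target <- truth@volumes
  got <- tissueVolumes(m)
  for (tis in names(target))
    expect_lt(abs(got[[tis]] - target[[tis]]), vv + 1e-9)
  expect_false(any(m@enhancing & m@nonEnhancing))
  expect_false(any(m@enhancing & m@edema))
  expect_false(any(m@nonEnhancing & m@edema))
  # an 8 mL compartment at 2 mm isotropic voxels is 1000 voxels
  m2 <- buildLesionGeometry(makeTruth(volumes = c(2, 2, 8)),
                            c(48, 48, 48), c(2, 2, 2), seed = 4)
  expect_equal(sum(m2@edema), 1000)
})

test_that("absent compartments give empty masks; oversize lesions reject", {
  truth <- makeTruth(presence = c(TRUE, FALSE, TRUE),
                     volumes = c(10, 0, 30))
  m <- buildLesionGeometry(truth, c(24, 24, 24), c(5, 5, 5), seed = 5)
  expect_equal(sum(m@nonEnhancing), 0)
  expect_gt(sum(m@enhancing), 0)
  expect_gt(sum(m@edema), 0)
  big <- makeTruth(volumes = c(100, 100, 400))
  expect_error(buildLesionGeometry(big, c(10, 10, 10), c(2, 2, 2), seed = 1),
               "exceeds grid capacity")
})

test_that("the noiseless joint signal reduces to each sub-model", {
  sch <- paperBScheme(); b <- bValues(sch)
  # K = 0 everywhere: joint model is exactly the IVIM biexponential
  truth <- makeTruth(f = c(0.3, 0.3, 0.3), K = c(0, 0, 0),
                     volumes = c(4, 2, 10), jitterSd = 0)
  m <- buildLesionGeometry(truth, c(16, 16, 16), c(5, 5, 5), seed = 6)
  dwi <- synthesizeDwi(truth, m, sch, snr = Inf, seed = 6)
  vox <- which(m@enhancing)[1]
  sig <- vapply(seq_along(b), function(j)
    dwi@signal[, , , j][vox], 0)
  expect_equal(sig, ivimSignal(b, 1000, 0.3, truth@anchors["enhancing", "Dstar"],
                               truth@anchors["enhancing", "D"]),
               tolerance = 1e-9)
  # f = 0: joint model is exactly the kurtosis model
  truth0 <- makeTruth(f = c(0, 0, 0), jitterSd = 0, volumes = c(4, 2, 10))
  dwi0 <- synthesizeDwi(truth0, m, sch, snr = Inf, seed = 6,
                        backgroundParams = c(f = 0, D = 800e-6,
                                             Dstar = 5000e-6, K = 0.7))
  sig0 <- vapply(seq_along(b), function(j) dwi0@signal[, , , j][vox], 0)
  expect_equal(sig0, kurtosisSignal(b, 1000, truth0@anchors["enhancing", "D"],
                                    truth0@anchors["enhancing", "K"]),
               tolerance = 1e-9)
  # b = 0 volume equals S0 inside the brain
  expect_equal(dwi@signal[, , , 1][vox], 1000, tolerance = 1e-9)
})

test_that("the Rician noise level matches the requested SNR", {
  truth <- makeTruth(jitterSd = 0, volumes = c(4, 2, 10))
  m <- buildLesionGeometry(truth, c(20, 20, 20), c(5, 5, 5), seed = 8)
  for (snr in c(20, 40, 80)) {
    dwi <- synthesizeDwi(truth, m, paperBScheme(), snr = snr, seed = 9)
    # b = 0 has a single average: mean/SD estimates the per-average SNR
    vals <- dwi@signal[, , , 1][m@edema]
    expect_lt(abs(mean(vals) / sd(vals) - snr) / snr, 0.1)
  }
})

test_that("cohort generation is reproducible and validates sizes", {
  c1 <- generateCohort(1, 1, masterSeed = 99, gridShape = c(16, 16, 16),
                       voxelDims = c(6, 6, 6))
  c2 <- generateCohort(1, 1, masterSeed = 99, gridShape = c(16, 16, 16),
                       voxelDims = c(6, 6, 6))
  expect_identical(c1$subjects[[1]]$dwi@signal, c2$subjects[[1]]$dwi@signal)
  expect_identical(c1$subjects[[2]]$truth@anchors,
                   c2$subjects[[2]]$truth@anchors)
  expect_identical(c1$manifest$label, c("HGG", "metastasis"))
  expect_error(generateCohort(0, 1), "at least one")
  expect_true(all(c("label", "tissue", "param", "median_anchor") %in%
                  names(c1$summary)))
})

test_that("every generated subject has pairwise disjoint tissue masks", {
  co <- generateCohort(3, 3, masterSeed = 17, gridShape = c(16, 16, 16),
                       voxelDims = c(6, 6, 6))
  for (s in co$subjects) {
    m <- s$masks
    expect_false(any(m@enhancing & m@nonEnhancing))
    expect_false(any(m@enhancing & m@edema))
    expect_false(any(m@nonEnhancing & m@edema))
  }
})
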