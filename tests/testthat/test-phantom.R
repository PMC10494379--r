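test_that("noise-free lesion voxels reproduce the forward model exactly", {
  spec <- PhantomSpec(snr = Inf)
  truth <- progBiexp()
  ph <- generatePhantom(spec, truth, defaultScheme)
  idx <- which(ph$mask != 0, arr.ind = TRUE)[1, ]
  curve <- ph$volume[idx[1], idx[2], idx[3], ]
  expect_equal(curve / curve[1],
               predictSignal(truth, bValues(defaultScheme)),
               tolerance = 1e-12)
  # blended truth: equal mixture of the two decays
  bl <- list(biexp = truth, stretched = progStretched(), weight = 0.5)
  ph2 <- generatePhantom(spec, bl, defaultScheme)
  curve2 <- ph2$volume[idx[1], idx[2], idx[3], ]
  expect_equal(curve2 / curve2[1],
               0.5 * predictSignal(truth, bValues(defaultScheme)) +
                 0.5 * predictSignal(progStretched(),
                                     bValues(defaultScheme)),
               tolerance = 1e-12)
})

test_that("phantom noise draws are reproducible per seed", {
  spec <- PhantomSpec(snr = 50, seed = 123)
  a <- generatePhantom(spec, progBiexp(), defaultScheme)
  b <- generatePhantom(spec, progBiexp(), defaultScheme)
  expect_identical(a$volume, b$volume)
  spec2 <- PhantomSpec(snr = 50, seed = 124)
  c <- generatePhantom(spec2, progBiexp(), defaultScheme)
  expect_false(identical(a$volume, c$volume))
})

test_that("Rician noise is unbiased to 3 SE in the high-SNR limit", {
  set.seed(7)
  clean <- rep(1000, 1000)
  noisy <- addRicianNoise(clean, 20)
  se <- sd(noisy) / sqrt(length(noisy))
  expect_lt(abs(mean(noisy) - 1000), 3 * se + 20^2 / (2 * 1000))
})

test_that("the paper-like preset encodes the two-group geometry", {
  ps <- paperLikePreset()
  expect_identical(ps$nProg, 22L)
  expect_identical(ps$nPseudo, 18L)
  expect_identical(ps$prog@label, "progression")
  # central-slice lesion cross-section inside the 45-65 mm^2 ROI band
  mask <- generatePhantom(ps$spec, progBiexp(), ps$scheme)$mask
  central <- sum(mask[, , ps$spec@center[3]]) * prod(ps$spec@pixdim[1:2])
  expect_gte(central, 45)
  expect_lte(central, 65)
})

test_that("cohort truths follow the generating distributions", {
  ps <- paperLikePreset(snr = Inf)
  cohort <- generateCohort(ps$prog, ps$pseudo, spec = ps$spec,
                           seed = 11, preset = "paper-like")
  tt <- truthTable(cohort)
  expect_identical(nrow(tt), 40L)
  for (g in c("progression", "pseudoprogression")) {
    dist <- if (g == "progression") ps$prog else ps$pseudo
    sub <- tt[tt$group == g, ]
    for (p in c("adc", "d", "dstar", "f", "ddc", "alpha")) {
      # 3 SE: twelve simultaneous checks need more than a 95% band each
      bound <- 3 * dist@sds[[p]] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[p]]) - dist@means[[p]]), bound)
    }
  }
  # all draws satisfy the parameter-validity invariants
  expect_true(all(tt$f >= 0 & tt$f <= 1))
  expect_true(all(tt$alpha > 0 & tt$alpha <= 1))
  expect_true(all(tt$dstar >= tt$d))
})

test_that("cohort generation is a pure function of (preset, seed)", {
  ps <- paperLikePreset()
  a <- generateCohort(ps$prog, ps$pseudo, nProg = 2L, nPseudo = 2L,
                      spec = ps$spec, seed = 5)
  b <- generateCohort(ps$prog, ps$pseudo, nProg = 2L, nPseudo = 2L,
                      spec = ps$spec, seed = 5)
  expect_identical(truthTable(a), truthTable(b))
  expect_identical(subjects(a)[[1]]$volume, subjects(b)[[1]]$volume)
  c <- generateCohort(ps$prog, ps$pseudo, nProg = 2L, nPseudo = 2L,
                      spec = ps$spec, seed = 6)
  expect_false(identical(truthTable(a)$d, truthTable(c)$d))
})

test_that("near-zero spread pins subject truths at the group means", {
  ps <- paperLikePreset(snr = Inf)
  tight <- GroupParameterDistribution(
    "progression", means = ps$prog@means,
    sds = setNames(rep(1e-9, 6), names(ps$prog@sds)))
  cohort <- generateCohort(tight, ps$pseudo, nProg = 1L, nPseudo = 1L,
                           spec = ps$spec, seed = 3)
  tr <- truthTable(cohort)[1, ]
  expect_equal(tr$d, ps$prog@means[["d"]], tolerance = 1e-5)
  expect_equal(tr$alpha, ps$prog@means[["alpha"]], tolerance = 1e-5)
})

test_that("infeasible truncation is rejected as an input error", {
  ps <- paperLikePreset()
  bad <- GroupParameterDistribution(
    "progression",
    means = replace(ps$prog@means, "adc", 9e-2),
    sds = replace(ps$prog@sds, "adc", 1e-4))
  expect_error(generateCohort(bad, ps$pseudo, nProg = 1L, nPseudo = 1L,
                              spec = ps$spec, seed = 1),
               "infeasible truncation")
})

test_that("second-reader masks perturb but overlap the original", {
  mask <- array(0, c(12, 12, 8))
  mask[4:9, 4:9, 3:6] <- 1 # ~144-voxel ROI
  expect_identical(simulateSecondReader(mask, jitter = 0), mask)
  m1 <- simulateSecondReader(mask, jitter = 1, seed = 21)
  m2 <- simulateSecondReader(mask, jitter = 1, seed = 21)
  expect_identical(m1, m2)
  expect_false(identical(m1, mask))
  set.seed(77)
  overlaps <- vapply(seq_len(200), function(i) {
    m <- simulateSecondReader(mask, jitter = 1)
    sum(m != 0 & mask != 0) / sum(mask != 0)
  }, numeric(1))
  expect_gt(mean(overlaps), 0.5)
  expect_error(simulateSecondReader(array(0, c(4, 4, 4)), jitter = 1),
               "empty")
})
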