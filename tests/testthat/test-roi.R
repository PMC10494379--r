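maskFromCounts <- function(counts, nx = 6, ny = 6) {
  m <- array(0, c(nx, ny, length(counts)))
  for (z in seq_along(counts))
    if (counts[z] > 0) m[seq_len(counts[z]), 1, z] <- 1
  m
}

constantMaps <- function(shape, values, pixdim = c(2.5, 2.5, 4)) {
  maps <- lapply(values, function(v) array(v, shape))
  names(maps) <- c("adc", "d", "dstar", "f", "ddc", "alpha")
  new("ParameterMaps", maps = maps, quality = array(3, shape),
      pixdim = pixdim, xform = diag(4))
}

test_that("maximal-slice selection maximises in-mask voxels", {
  m <- maskFromCounts(c(0, 5, 9, 9, 5, 0), nx = 10)
  sel <- selectMaximalSlices(m)
  expect_identical(as.integer(sel), 2:4) # 1-based slices with sum 23
  expect_false(attr(sel, "partial"))
  # uniform counts tie-break toward the inferior-most triple
  selU <- selectMaximalSlices(maskFromCounts(rep(4, 6)))
  expect_identical(as.integer(selU), 1:3)
  # single-slice mask flagged partial
  selS <- selectMaximalSlices(maskFromCounts(c(0, 3, 0)))
  expect_identical(as.integer(selS), 2L)
  expect_true(attr(selS, "partial"))
  expect_error(selectMaximalSlices(array(0, c(2, 2, 2))), "empty")
})

test_that("lesion measurement averages in-mask voxels on chosen slices", {
  shape <- c(6, 6, 5)
  maps <- constantMaps(shape, as.list(1:6))
  mask <- array(0, shape); mask[2:4, 2:4, 2:4] <- 1
  meas <- measureLesion(maps, mask, subject = "S1", warnArea = FALSE)
  expect_identical(nrow(meas), 6L)
  expect_equal(meas$value, as.numeric(1:6))
  expect_equal(meas$area_mm2[1], 9 * 6.25)
  # two-valued map with equal counts averages to the midpoint
  maps2 <- constantMaps(shape, as.list(rep(0, 6)))
  g <- array(2, shape); g[1:2, , ] <- 8
  maps2@maps$adc <- g
  mask2 <- array(0, shape); mask2[2:3, 2:3, 2:4] <- 1 # half 8, half 2
  m2 <- measureLesion(maps2, mask2, warnArea = FALSE)
  expect_equal(m2$value[m2$parameter == "adc"], 5)
  # repeats with identical deterministic masks change nothing
  m3 <- measureLesion(maps, mask, repeats = 5L, warnArea = FALSE)
  expect_equal(m3$value, meas$value)
})

test_that("empty-parameter ROIs warn and area checks fire", {
  shape <- c(6, 6, 5)
  maps <- constantMaps(shape, as.list(1:6))
  maps@maps$dstar[] <- NA_real_
  mask <- array(0, shape); mask[2:4, 2:4, 2:4] <- 1
  w <- capture_warnings(measureLesion(maps, mask, warnArea = FALSE))
  expect_true(any(grepl("no finite voxels", w)))
  big <- array(1, shape) # 36 voxels/slice x 6.25 mm^2 >> 65 mm^2
  w2 <- capture_warnings(measureLesion(maps, big, warnArea = TRUE))
  expect_true(any(grepl("45-65", w2)))
})

test_that("the lesion table pivots to one row per subject and reader", {
  shape <- c(6, 6, 5)
  maps <- constantMaps(shape, as.list(1:6))
  mask <- array(0, shape); mask[2:4, 2:4, 2:4] <- 1
  rows <- do.call(rbind, lapply(sprintf("S%02d", 1:40), function(id) {
    rbind(measureLesion(maps, mask, subject = id, reader = "R1",
                        warnArea = FALSE),
          measureLesion(maps, mask, subject = id, reader = "R2",
                        warnArea = FALSE))
  }))
  groups <- setNames(rep(c("progression", "pseudoprogression"), 20),
                     sprintf("S%02d", 1:40))
  tab <- buildLesionTable(rows, groups)
  expect_identical(dim(tab), c(80L, 9L))
  expect_identical(names(tab), c("subject", "group", "reader", "adc", "d",
                                 "d_star", "f", "ddc", "alpha"))
  expect_false(is.unsorted(tab$subject))
  # empty input is an empty table, not an error
  expect_identical(nrow(buildLesionTable(rows[0, ], groups)), 0L)
  # single subject, single reader
  one <- buildLesionTable(rows[1:6, ], groups)
  expect_identical(nrow(one), 1L)
  # conflicting duplicates are an input error
  dup <- rbind(rows[1:6, ], transform(rows[1:6, ], value = value + 1))
  expect_error(buildLesionTable(dup, groups), "conflicting")
})

test_that("homogeneous phantom ROI means equal the voxel truth", {
  ps <- paperLikePreset(snr = Inf)
  cohort <- generateCohort(ps$prog, ps$pseudo, nProg = 1L, nPseudo = 1L,
                           spec = ps$spec, seed = 8)
  tab <- measureCohort(cohort, readers = 1L, jitter = 0)
  truth <- derivedTruths(cohort)
  for (i in 1:2) {
    expect_equal(tab$d[i], truth$d[i], tolerance = 1e-6)
    expect_equal(tab$ddc[i], truth$ddc[i], tolerance = 1e-6)
    expect_equal(tab$alpha[i], truth$alpha[i], tolerance = 1e-6)
    expect_equal(tab$adc[i], truth$adc[i], tolerance = 1e-6)
  }
})
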