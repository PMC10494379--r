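#' Select the three consecutive maximal axial slices
#'
#' The ROI protocol measures lesions on the three consecutive axial slices
#' carrying the most in-mask voxels. Ties are broken toward the
#' inferior-most (lowest-index) triple. The axial axis is the third voxel
#' dimension; indices are 1-based. If the mask spans fewer than three
#' slices, all occupied slices are returned with attribute
#' \code{partial = TRUE}.
#'
#' @param mask 3D binary array.
#' @return integer vector of slice indices (ascending), with attribute
#'   \code{partial}.
#' @export
selectMaximalSlices <- function(mask) {
  if (length(dim(mask)) != 3L) stop("mask must be 3D")
  counts <- apply(mask != 0, 3L, sum)
  if (sum(counts) == 0L) stop("mask is empty")
  occupied <- which(counts > 0L)
  if (length(occupied) < 3L) {
    out <- occupied
    attr(out, "partial") <- TRUE
    return(out)
  }
  nz <- length(counts)
  sums <- vapply(seq_len(nz - 2L),
                 function(i) sum(counts[i:(i + 2L)]), numeric(1L))
  start <- which.max(sums) # which.max takes the first (inferior-most) tie
  out <- start:(start + 2L)
  attr(out, "partial") <- FALSE
  out
}

#' Measure one lesion on the parameter maps
#'
#' Applies the ROI protocol to one lesion: select the three consecutive
#' maximal slices of the mask, average each parameter map over the in-mask,
#' non-missing voxels on those slices, and repeat the measurement
#' \code{repeats} times (identical for a deterministic mask; pass a list of
#' per-repeat masks, e.g. from \code{\link{simulateSecondReader}}, to model
#' intra-reader variability). The repeat means are averaged. The ROI area
#' is the mean per-slice in-mask voxel count times the in-plane voxel
#' area; a warning is raised when it falls outside the 45-65 mm^2 band of
#' the emulated protocol.
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param mask 3D binary array, or a list of such arrays (one per repeat).
#' @param subject subject identifier.
#' @param reader reader identifier.
#' @param repeats number of repeat measurements (default 3).
#' @param warnArea warn when the ROI area leaves the 45-65 mm^2 band.
#' @return data.frame with one row per parameter: subject, reader,
#'   parameter, value, area_mm2, slice_lo, slice_hi, n_voxels.
#' @export
measureLesion <- function(maps, mask, subject = "S01", reader = "R1",
                          repeats = 3L, warnArea = TRUE) {
  masks <- if (is.list(mask)) mask else rep(list(mask), repeats)
  if (length(masks) != repeats)
    stop("need one mask per repeat (or a single mask)")
  shape <- dim(maps@maps[[1L]])
  inPlaneArea <- prod(maps@pixdim[1:2])
  perRepeat <- lapply(masks, function(m) {
    if (!identical(dim(m), shape))
      stop("mask shape does not match the parameter maps")
    slices <- selectMaximalSlices(m)
    sel <- array(FALSE, shape)
    sel[, , slices] <- m[, , slices] != 0
    vals <- vapply(maps@maps, function(g) {
      v <- g[sel]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1L))
    list(vals = vals, area = sum(sel) / length(slices) * inPlaneArea,
         slices = range(slices), n = sum(sel))
  })
  vals <- rowMeans(vapply(perRepeat, `[[`, numeric(6L), "vals"))
  area <- mean(vapply(perRepeat, `[[`, numeric(1L), "area"))
  if (warnArea && (area < 45 || area > 65))
    warning(sprintf("ROI area %.1f mm^2 outside the 45-65 mm^2 band",
                    area), call. = FALSE)
  if (anyNA(vals))
    warning("some parameters had no finite voxels in the ROI; ",
            "rows recorded as NA", call. = FALSE)
  data.frame(subject = subject, reader = reader,
             parameter = names(maps@maps), value = unname(vals),
             area_mm2 = area,
             slice_lo = perRepeat[[1L]]$slices[1L],
             slice_hi = perRepeat[[1L]]$slices[2L],
             n_voxels = perRepeat[[1L]]$n,
             row.names = NULL)
}

#' Assemble the per-lesion, per-reader parameter table
#'
#' Pivots long-format ROI measurements into the wide lesion table that the
#' statistics layer consumes: one row per (subject, reader), one column
#' per parameter, ordered by subject then reader.
#'
#' @param measurements data.frame as returned by (rbinding)
#'   \code{\link{measureLesion}} calls.
#' @param groups named character vector mapping subject id to group label.
#' @return data.frame with columns subject, group, reader, adc, d, d_star,
#'   f, ddc, alpha.
#' @export
buildLesionTable <- function(measurements, groups) {
  cols <- c("adc", "d", "dstar", "f", "ddc", "alpha")
  out <- data.frame(subject = character(0L), group = character(0L),
                    reader = character(0L))
  for (p in cols) out[[p]] <- numeric(0L)
  names(out) <- c("subject", "group", "reader",
                  c("adc", "d", "d_star", "f", "ddc", "alpha"))
  if (nrow(measurements) == 0L) return(out)
  key <- paste(measurements$subject, measurements$reader,
               measurements$parameter)
  dup <- duplicated(key)
  if (any(dup)) {
    agree <- vapply(which(dup), function(i) {
      first <- which(key == key[i])[1L]
      isTRUE(all.equal(measurements$value[i], measurements$value[first]))
    }, logical(1L))
    if (!all(agree))
      stop("conflicting duplicate (subject, reader, parameter) values")
    measurements <- measurements[!dup, ]
  }
  wide <- stats::reshape(
    measurements[, c("subject", "reader", "parameter", "value")],
    idvar = c("subject", "reader"), timevar = "parameter",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  missing <- setdiff(cols, names(wide))
  for (p in missing) wide[[p]] <- NA_real_
  wide$group <- unname(groups[wide$subject])
  wide <- wide[order(wide$subject, wide$reader),
               c("subject", "group", "reader", cols)]
  names(wide) <- c("subject", "group", "reader",
                   "adc", "d", "d_star", "f", "ddc", "alpha")
  rownames(wide) <- NULL
  wide
}

#' Measure every lesion of a cohort
#'
#' Runs fit + ROI measurement over a whole \linkS4class{PhantomCohort}:
#' fits the three models at every lesion voxel, then applies the ROI
#' protocol once per reader. Reader 1 uses the true lesion mask; further
#' readers use \code{\link{simulateSecondReader}} perturbations of it,
#' seeded deterministically from the cohort seed.
#'
#' @param cohort a \linkS4class{PhantomCohort}.
#' @param config a \linkS4class{FittingConfig}.
#' @param readers number of readers (>= 1).
#' @param jitter reader-disagreement scale passed to
#'   \code{\link{simulateSecondReader}}, voxels.
#' @param warnArea passed to \code{\link{measureLesion}}.
#' @return lesion table as from \code{\link{buildLesionTable}}.
#' @export
measureCohort <- function(cohort, config = FittingConfig(), readers = 2L,
                          jitter = 0.5, warnArea = FALSE) {
  rows <- list()
  groups <- character(0L)
  for (s in cohort@subjects) {
    maps <- fitVolume(s$volume, cohort@scheme, s$mask, config,
                      pixdim = cohort@spec@pixdim)
    groups[s$id] <- s$group
    for (r in seq_len(readers)) {
      m <- if (r == 1L) s$mask
      else simulateSecondReader(s$mask, jitter = jitter,
                                seed = (s$seed + r) %% .Machine$integer.max)
      rows[[length(rows) + 1L]] <-
        measureLesion(maps, m, subject = s$id,
                      reader = sprintf("R%d", r), warnArea = warnArea)
    }
  }
  buildLesionTable(do.call(rbind, rows), groups)
}
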