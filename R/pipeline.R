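#' Run the whole analysis in memory
#'
#' Convenience chain simulate -> fit -> measure -> report: generates the
#' two-group phantom cohort, fits the three models at every lesion voxel,
#' applies the ROI protocol for each reader and runs the diagnostic
#' statistics. Reproducible given (preset, seed).
#'
#' @param seed integer seed driving every random draw.
#' @param snr phantom SNR at b = 0; Inf disables noise.
#' @param preset cohort preset; currently "paper-like".
#' @param nProg,nPseudo optional group-size overrides (defaults from the
#'   preset: 22 and 18).
#' @param readers number of readers for the ROI protocol.
#' @param jitter inter-reader mask perturbation scale, voxels.
#' @param config a \linkS4class{FittingConfig}.
#' @return list: cohort (\linkS4class{PhantomCohort}), table (lesion
#'   table) and report (\linkS4class{DiagnosticReport}).
#' @export
runPipeline <- function(seed = 1L, snr = 50, preset = "paper-like",
                        nProg = NULL, nPseudo = NULL, readers = 2L,
                        jitter = 0.5, config = FittingConfig()) {
  if (!identical(preset, "paper-like"))
    stop("unknown preset: ", preset)
  ps <- paperLikePreset(snr = snr)
  cohort <- generateCohort(ps$prog, ps$pseudo,
                           nProg = if (is.null(nProg)) ps$nProg else nProg,
                           nPseudo = if (is.null(nPseudo)) ps$nPseudo
                                     else nPseudo,
                           spec = ps$spec, scheme = ps$scheme,
                           seed = seed, preset = preset)
  table <- measureCohort(cohort, config = config, readers = readers,
                         jitter = jitter)
  list(cohort = cohort, table = table,
       report = buildReport(table, positive = "progression"))
}

#' Pipeline commands
#'
#' Disk-backed stages of the pipeline, wrapped by the command-line script
#' in \code{system.file("scripts", "mbdwi", package = "mbDWI")}.
#' \code{cmdSimulate} writes a cohort (NIfTI volumes and masks, truth CSV,
#' manifest JSON); \code{cmdFit} writes six parameter maps plus a quality
#' map per subject, skipping already-fitted subjects unless forced;
#' \code{cmdRoi} builds the lesion table CSV; \code{cmdReport} runs the
#' statistics and writes the report files.
#'
#' @param out,dir directories.
#' @param seed integer seed.
#' @param preset cohort preset name.
#' @param snr phantom SNR at b = 0.
#' @param nProg,nPseudo optional group-size overrides.
#' @return \code{cmdSimulate}: the cohort directory, invisibly.
#' @name pipeline-commands
#' @export
cmdSimulate <- function(out, seed = 1L, preset = "paper-like", snr = 50,
                        nProg = NULL, nPseudo = NULL) {
  if (!identical(preset, "paper-like"))
    stop("unknown preset: ", preset)
  ps <- paperLikePreset(snr = snr)
  cohort <- generateCohort(ps$prog, ps$pseudo,
                           nProg = if (is.null(nProg)) ps$nProg else nProg,
                           nPseudo = if (is.null(nPseudo)) ps$nPseudo
                                     else nPseudo,
                           spec = ps$spec, scheme = ps$scheme,
                           seed = seed, preset = preset)
  writeCohort(cohort, out)
  invisible(out)
}

.subjectDirs <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  list(info = info, dirs = file.path(dir, info$subjects))
}

#' @rdname pipeline-commands
#' @param config a \linkS4class{FittingConfig}.
#' @param force refit subjects whose maps already exist.
#' @return \code{cmdFit}: invisibly, a list with fitted, skipped and
#'   failed subject ids.
#' @export
cmdFit <- function(dir, config = FittingConfig(), force = FALSE) {
  sd <- .subjectDirs(dir)
  bvalPath <- file.path(dir, "bvals.txt")
  if (!file.exists(bvalPath)) stop("missing b-value table: ", bvalPath)
  scheme <- readBValues(bvalPath)
  fitted <- skipped <- failed <- character(0L)
  for (s in sd$dirs) {
    id <- basename(s)
    if (!force && file.exists(file.path(s, "maps_adc.nii.gz"))) {
      skipped <- c(skipped, id)
      next
    }
    ok <- tryCatch({
      vol <- RNifti::readNifti(file.path(s, "dwi.nii.gz"))
      mask <- RNifti::readNifti(file.path(s, "mask.nii.gz"))
      maps <- fitVolume(array(as.numeric(vol), dim(vol)), scheme,
                        array(as.numeric(mask), dim(mask)), config,
                        pixdim = RNifti::pixdim(mask)[1:3])
      writeParameterMaps(maps, file.path(s, "maps"))
      TRUE
    }, error = function(e) {
      warning("subject ", id, " failed: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) fitted <- c(fitted, id) else failed <- c(failed, id)
  }
  invisible(list(fitted = fitted, skipped = skipped, failed = failed))
}

#' @rdname pipeline-commands
#' @param readers number of readers.
#' @param jitter inter-reader perturbation scale, voxels.
#' @return \code{cmdRoi}: the lesion table (also written to
#'   \code{lesion_table.csv}).
#' @export
cmdRoi <- function(dir, readers = 2L, jitter = 0.5, seed = NULL) {
  sd <- .subjectDirs(dir)
  if (is.null(seed)) seed <- sd$info$seed
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  groups <- stats::setNames(truth$group, truth$subject)
  rows <- list()
  for (s in sd$dirs) {
    id <- basename(s)
    maps <- readParameterMaps(file.path(s, "maps"))
    mask <- RNifti::readNifti(file.path(s, "mask.nii.gz"))
    mask <- array(as.numeric(mask), dim(mask))
    for (r in seq_len(readers)) {
      m <- if (r == 1L) mask
      else simulateSecondReader(mask, jitter = jitter,
                                seed = (seed + 131L * match(id, basename(sd$dirs)) + r) %%
                                  .Machine$integer.max)
      rows[[length(rows) + 1L]] <-
        measureLesion(maps, m, subject = id, reader = sprintf("R%d", r),
                      warnArea = FALSE)
    }
  }
  table <- buildLesionTable(do.call(rbind, rows), groups)
  utils::write.csv(table, file.path(dir, "lesion_table.csv"),
                   row.names = FALSE)
  table
}

#' @rdname pipeline-commands
#' @param table lesion table data.frame, or path to its CSV.
#' @param positive positive group label.
#' @return \code{cmdReport}: the \linkS4class{DiagnosticReport} (files
#'   written to \code{out}).
#' @export
cmdReport <- function(table, out, positive = "progression") {
  if (is.character(table)) table <- utils::read.csv(table)
  report <- buildReport(table, positive = positive)
  writeReport(report, out)
  report
}
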