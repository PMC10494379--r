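#' Read and write b-value tables
#'
#' b-values are stored as plain text, either FSL-style (one
#' whitespace-separated line) or one value per line.
#'
#' @param path file path.
#' @return \code{readBValues}: a \linkS4class{BValueScheme}.
#' @export
readBValues <- function(path) {
  if (!file.exists(path)) stop("b-value table not found: ", path)
  BValueScheme(scan(path, what = numeric(), quiet = TRUE))
}

#' @rdname readBValues
#' @param scheme a \linkS4class{BValueScheme}.
#' @export
writeBValues <- function(scheme, path) {
  writeLines(paste(scheme@values, collapse = " "), path)
  invisible(path)
}

.asNiftiImage <- function(arr, pixdim) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim
  img
}

#' Write parameter maps as NIfTI-1 files
#'
#' One file per parameter, suffixed \code{_adc}, \code{_d}, \code{_dstar},
#' \code{_f}, \code{_ddc}, \code{_alpha}, plus \code{_quality}.
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
writeParameterMaps <- function(maps, prefix) {
  suffix <- c(adc = "adc", d = "d", dstar = "dstar", f = "f",
              ddc = "ddc", alpha = "alpha")
  paths <- character(0L)
  for (p in names(suffix)) {
    path <- paste0(prefix, "_", suffix[[p]], ".nii.gz")
    RNifti::writeNifti(.asNiftiImage(maps@maps[[p]], maps@pixdim), path)
    paths <- c(paths, path)
  }
  qpath <- paste0(prefix, "_quality.nii.gz")
  RNifti::writeNifti(.asNiftiImage(maps@quality, maps@pixdim), qpath)
  invisible(c(paths, qpath))
}

#' @rdname writeParameterMaps
#' @export
readParameterMaps <- function(prefix) {
  getArr <- function(suffix) {
    img <- RNifti::readNifti(paste0(prefix, "_", suffix, ".nii.gz"))
    array(as.numeric(img), dim(img))
  }
  arrs <- lapply(c(adc = "adc", d = "d", dstar = "dstar", f = "f",
                   ddc = "ddc", alpha = "alpha"), getArr)
  img <- RNifti::readNifti(paste0(prefix, "_adc.nii.gz"))
  new("ParameterMaps", maps = arrs, quality = getArr("quality"),
      pixdim = RNifti::pixdim(img)[1:3],
      xform = structure(RNifti::xform(img), code = NULL))
}

#' Write a phantom cohort to disk
#'
#' One directory per subject (4D DWI volume and lesion mask as NIfTI-1),
#' plus the shared b-value table, the ground-truth CSV and a JSON manifest
#' recording preset, seed and group sizes.
#'
#' @param cohort a \linkS4class{PhantomCohort}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBValues(cohort@scheme, file.path(dir, "bvals.txt"))
  pix <- cohort@spec@pixdim
  for (s in cohort@subjects) {
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    RNifti::writeNifti(.asNiftiImage(s$volume, c(pix, 1)),
                       file.path(sdir, "dwi.nii.gz"))
    RNifti::writeNifti(.asNiftiImage(s$mask, pix),
                       file.path(sdir, "mask.nii.gz"))
  }
  truth <- truthTable(cohort)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  groups <- vapply(cohort@subjects, `[[`, character(1L), "group")
  manifest <- list(preset = cohort@preset, seed = cohort@seed,
                   n_progression = sum(groups == "progression"),
                   n_pseudoprogression = sum(groups == "pseudoprogression"),
                   snr = cohort@spec@snr, b_values = cohort@scheme@values,
                   subjects = vapply(cohort@subjects, `[[`, character(1L),
                                     "id"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
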