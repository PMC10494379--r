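#' @rdname FittingConfig-class
#' @param bSplitThreshold b-value split for the segmented IVIM fit, s/mm^2.
#' @param lower,upper named parameter bounds; defaults are wide enough to
#'   contain brain-tissue values with margin: d in (1e-6, 5e-3),
#'   dStar in (1e-4, 5e-1), f in [0, 1], ddc in (1e-6, 1e-1),
#'   alpha in (0.01, 1].
#' @param refine run the full bounded nonlinear refinement after the
#'   segmented initialisation.
#' @param adcMethod "two-point" or "loglinear".
#' @param biexpForm "sum" (as-printed exp(-b(D*+D))) or "conventional".
#' @param tol solver tolerance.
#' @param maxIter maximum solver iterations.
#' @export
FittingConfig <- function(bSplitThreshold = 200,
                          lower = c(d = 1e-6, dStar = 1e-4, f = 0,
                                    ddc = 1e-6, alpha = 0.01),
                          upper = c(d = 5e-3, dStar = 5e-1, f = 1,
                                    ddc = 1e-1, alpha = 1),
                          refine = TRUE,
                          adcMethod = c("two-point", "loglinear"),
                          biexpForm = c("sum", "conventional"),
                          tol = 1e-12, maxIter = 200L) {
  new("FittingConfig", bSplitThreshold = bSplitThreshold,
      lower = lower, upper = upper, refine = refine,
      adcMethod = match.arg(adcMethod), biexpForm = match.arg(biexpForm),
      tol = tol, maxIter = as.integer(maxIter))
}

#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

#' @rdname accessors
#' @param object,... see \code{stats::coef}.
#' @export
setMethod("coef", "FitResult", function(object, ...) coef(object@params))

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", if (object@converged) "converged" else "NOT converged",
      ", n = ", object@nPoints, ", SSE = ", format(object@residualSSE),
      ")\n", sep = "")
  show(object@params)
})

.failedFit <- function(params, n) {
  new("FitResult", params = params, residualSSE = NA_real_,
      converged = FALSE, nPoints = as.integer(n))
}

.normalise <- function(curve) curve@signal / curve@signal[1L]

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Monoexponential (ADC) fit
#'
#' Closed-form ADC from the b = 0 and b = 1000 points, mirroring the
#' conventional two-b DWI protocol: ADC = ln(S(0)/S(1000)) / 1000. With
#' \code{adcMethod = "loglinear"} a log-linear least-squares slope over all
#' b-values is used instead.
#'
#' A non-positive signal at either point, or a non-decaying curve, yields a
#' non-converged result with NA parameters rather than an error, so that
#' volume fitting degrades per voxel.
#'
#' @param curve a \linkS4class{DecayCurve} containing b = 0 and, for the
#'   two-point method, b = 1000.
#' @param config a \linkS4class{FittingConfig}.
#' @return a \linkS4class{FitResult} holding \linkS4class{MonoexpParams}.
#' @export
fitADC <- function(curve, config = FittingConfig()) {
  b <- bValues(curve)
  s <- .normalise(curve)
  if (config@adcMethod == "two-point") {
    i <- match(1000, b)
    if (is.na(i)) stop("two-point ADC needs b = 1000 in the scheme")
    if (s[i] <= 0 || s[i] >= 1)
      return(.failedFit(MonoexpParams(NA_real_), 2L))
    adc <- log(1 / s[i]) / 1000
    res <- sum((s[c(1L, i)] - .monoDecay(b[c(1L, i)], adc))^2)
    n <- 2L
  } else {
    ok <- s > 0
    if (sum(ok) < 2L) return(.failedFit(MonoexpParams(NA_real_), sum(ok)))
    fit <- stats::lm.fit(cbind(1, b[ok]), log(s[ok]))
    adc <- -fit$coefficients[[2L]]
    if (!is.finite(adc) || adc <= 0)
      return(.failedFit(MonoexpParams(NA_real_), as.integer(sum(ok))))
    res <- sum((s - .monoDecay(b, adc))^2)
    n <- as.integer(sum(ok))
  }
  new("FitResult", params = MonoexpParams(adc), residualSSE = res,
      converged = TRUE, nPoints = n)
}

#' Biexponential (IVIM) fit
#'
#' Segmented estimation stabilises the ill-conditioned biexponential
#' inversion: (1) log-linear fit of the high-b points
#' (b >= \code{bSplitThreshold}) gives D and an intercept; (2) the
#' perfusion fraction is f = 1 - exp(intercept) on the S(0)-normalised
#' curve, clipped to [0, 1]; (3) a bounded 1-D least squares over the full
#' curve, with D and f held fixed, gives D*; (4, default) a bounded
#' Levenberg-Marquardt refinement over (D, D*, f) initialised from steps
#' 1-3. The fitted D* is constrained to D* >= D.
#'
#' @param curve a \linkS4class{DecayCurve} with at least six b-values on
#'   both sides of the split threshold.
#' @param config a \linkS4class{FittingConfig}.
#' @return a \linkS4class{FitResult} holding \linkS4class{BiexpParams}.
#' @export
fitBiexp <- function(curve, config = FittingConfig()) {
  b <- bValues(curve)
  n <- length(b)
  if (n < 6L) stop("biexponential fit needs at least six b-values")
  if (!config@bSplitThreshold %in% b[-c(1L, n)] &&
      !(any(b >= config@bSplitThreshold) && any(b < config@bSplitThreshold)))
    stop("b-values must span both sides of bSplitThreshold")
  s <- .normalise(curve)
  lo <- config@lower; hi <- config@upper
  form <- config@biexpForm
  boundary <- BiexpParams(lo["d"], max(lo["dStar"], lo["d"]), lo["f"])

  if (any(s <= 0) || stats::sd(s) == 0)
    return(.failedFit(boundary, n))

  ## step 1: high-b log-linear fit
  hiIdx <- which(b >= config@bSplitThreshold)
  if (length(hiIdx) < 2L) stop("need >= 2 b-values at or above the split")
  fit1 <- stats::lm.fit(cbind(1, b[hiIdx]), log(s[hiIdx]))
  d <- .clamp(-fit1$coefficients[[2L]], lo["d"], hi["d"])
  if (-fit1$coefficients[[2L]] <= 0) # non-decaying tail: degenerate curve
    return(.failedFit(boundary, n))
  ## step 2: perfusion fraction from the extrapolated intercept
  f <- .clamp(1 - exp(fit1$coefficients[[1L]]), lo["f"], hi["f"])
  ## step 3: 1-D bounded least squares for D* with d, f fixed
  dsLo <- max(lo["dStar"], d)
  sse1d <- function(ds) sum((s - .biexpDecay(b, d, ds, f, form))^2)
  dStar <- if (f > 0)
    stats::optimize(sse1d, c(dsLo, hi["dStar"]), tol = 1e-12)$minimum
  else dsLo
  est <- c(d = unname(d), dStar = unname(dStar), f = unname(f))
  conv <- TRUE

  ## step 4: full bounded nonlinear refinement
  if (config@refine) {
    resid <- function(p) s - .biexpDecay(b, p[1L], p[2L], p[3L], form)
    nlfit <- minpack.lm::nls.lm(
      par = est, fn = resid,
      lower = unname(lo[c("d", "dStar", "f")]),
      upper = unname(hi[c("d", "dStar", "f")]),
      control = minpack.lm::nls.lm.control(
        ftol = config@tol, ptol = config@tol, maxiter = config@maxIter))
    est <- nlfit$par
    conv <- nlfit$info %in% 1:4
  }
  if (est[["dStar"]] < est[["d"]]) est[["dStar"]] <- est[["d"]]
  params <- BiexpParams(est[["d"]], est[["dStar"]], est[["f"]])
  res <- sum((s - .biexpDecay(b, est[["d"]], est[["dStar"]], est[["f"]],
                              form))^2)
  new("FitResult", params = params, residualSSE = res, converged = conv,
      nPoints = as.integer(n))
}

#' Stretched-exponential fit
#'
#' Bounded Levenberg-Marquardt least squares of
#' S(b)/S(0) = exp(-(b DDC)^alpha) on the normalised signal. DDC is
#' initialised from the two-point ADC (clamped into bounds) and alpha at
#' 0.8; bounds are ddc in (1e-6, 1e-1) mm^2/s and alpha in (0.01, 1].
#'
#' @param curve a \linkS4class{DecayCurve} with at least four positive
#'   b-values.
#' @param config a \linkS4class{FittingConfig}.
#' @return a \linkS4class{FitResult} holding \linkS4class{StretchedParams}.
#' @export
fitStretched <- function(curve, config = FittingConfig()) {
  b <- bValues(curve)
  n <- length(b)
  if (sum(b > 0) < 4L) stop("stretched fit needs >= 4 positive b-values")
  s <- .normalise(curve)
  lo <- config@lower; hi <- config@upper
  boundary <- StretchedParams(lo["ddc"], hi["alpha"])
  if (any(s <= 0) || stats::sd(s) == 0)
    return(.failedFit(boundary, n))

  adc0 <- if (1000 %in% b && s[match(1000, b)] > 0 && s[match(1000, b)] < 1)
    log(1 / s[match(1000, b)]) / 1000 else 1e-3
  start <- c(ddc = unname(.clamp(adc0, lo["ddc"] * 1.01, hi["ddc"] * 0.99)),
             alpha = 0.8)
  resid <- function(p) s - .stretchedDecay(b, p[1L], p[2L])
  nlfit <- minpack.lm::nls.lm(
    par = start, fn = resid,
    lower = unname(lo[c("ddc", "alpha")]),
    upper = unname(hi[c("ddc", "alpha")]),
    control = minpack.lm::nls.lm.control(
      ftol = config@tol, ptol = config@tol, maxiter = config@maxIter))
  est <- nlfit$par
  params <- StretchedParams(est[["ddc"]], est[["alpha"]])
  new("FitResult", params = params,
      residualSSE = sum(resid(est)^2), converged = nlfit$info %in% 1:4,
      nPoints = as.integer(n))
}

#' Fit all three decay models to one curve
#'
#' @inheritParams fitBiexp
#' @return named list of three \linkS4class{FitResult} objects
#'   (mono, biexp, stretched).
#' @export
fitCurve <- function(curve, config = FittingConfig()) {
  list(mono = fitADC(curve, config),
       biexp = fitBiexp(curve, config),
       stretched = fitStretched(curve, config))
}

#' Voxel-wise parameter maps for a 4D volume
#'
#' Fits the monoexponential, biexponential and stretched-exponential models
#' at every masked voxel of a 4D multi-b volume. Voxel failures are
#' recorded in the quality grid and never abort the volume; unmasked voxels
#' carry NA. Voxels are mutually independent, so the result does not depend
#' on traversal order.
#'
#' @param volume 4D numeric array; 4th dimension matches the scheme length.
#' @param scheme a \linkS4class{BValueScheme}.
#' @param mask 3D array; nonzero marks voxels to fit.
#' @param config a \linkS4class{FittingConfig}.
#' @param pixdim voxel size, mm.
#' @param xform 4x4 NIfTI orientation matrix (identity scaled by pixdim by
#'   default).
#' @return a \linkS4class{ParameterMaps} object.
#' @export
fitVolume <- function(volume, scheme, mask, config = FittingConfig(),
                      pixdim = c(1, 1, 1), xform = NULL) {
  dims <- dim(volume)
  if (length(dims) != 4L) stop("volume must be 4D")
  if (dims[4L] != length(scheme@values))
    stop("4th dimension must match the number of b-values")
  if (!identical(dim(mask), dims[1:3]))
    stop("mask shape must match the spatial shape of the volume")
  if (is.null(xform)) xform <- diag(c(pixdim, 1))

  shape <- dims[1:3]
  blank <- array(NA_real_, shape)
  maps <- list(adc = blank, d = blank, dstar = blank, f = blank,
               ddc = blank, alpha = blank)
  quality <- array(NA_real_, shape)

  idx <- which(mask != 0)
  if (length(idx)) {
    flat <- matrix(volume, prod(shape), dims[4L])
    for (v in idx) {
      sig <- flat[v, ]
      if (sig[1L] <= 0) { quality[v] <- 0; next }
      curve <- DecayCurve(sig, scheme)
      fits <- fitCurve(curve, config)
      maps$adc[v] <- fits$mono@params@adc
      maps$d[v] <- fits$biexp@params@d
      maps$dstar[v] <- fits$biexp@params@dStar
      maps$f[v] <- fits$biexp@params@f
      maps$ddc[v] <- fits$stretched@params@ddc
      maps$alpha[v] <- fits$stretched@params@alpha
      quality[v] <- sum(vapply(fits, converged, logical(1L)))
    }
  }
  new("ParameterMaps", maps = maps, quality = quality,
      pixdim = as.numeric(pixdim), xform = xform)
}

#' @rdname accessors
#' @export
setMethod("paramMaps", "ParameterMaps", function(x) x@maps)

#' @rdname accessors
#' @export
setMethod("fitQuality", "ParameterMaps", function(x) x@quality)

setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@maps[[1L]])
  cat("ParameterMaps", paste(d, collapse = " x "), "voxels;",
      sum(!is.na(object@quality)), "fitted\n")
  cat("  parameters:", paste(names(object@maps), collapse = ", "), "\n")
  cat("  voxel size:", paste(object@pixdim, collapse = " x "), "mm\n")
})
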