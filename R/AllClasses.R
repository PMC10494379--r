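#' @import methods
NULL

.isPositive <- function(x) all(is.na(x) | x > 0)

#' Diffusion b-value scheme
#'
#' Ordered set of diffusion weightings (b-values, s/mm^2) at which a DWI
#' acquisition samples the signal decay. The default scheme is the 12-point
#' multi-b protocol (0, 10, 20, 40, 60, 70, 80, 100, 200, 400, 800, 1000).
#'
#' @slot values numeric vector of b-values, s/mm^2; strictly increasing,
#'   starting at 0.
#' @export
setClass("BValueScheme", representation(values = "numeric"),
         validity = function(object) {
           v <- object@values
           if (length(v) < 2L) return("need at least two b-values")
           if (anyNA(v)) return("b-values must be finite")
           if (v[1L] != 0) return("first b-value must be 0")
           if (any(diff(v) <= 0)) return("b-values must be strictly increasing")
           if (any(v < 0)) return("b-values must be non-negative")
           TRUE
         })

#' Signal decay curve
#'
#' One voxel's (or one ROI-mean) diffusion signal S(b) sampled over a
#' \linkS4class{BValueScheme}. Intensities are in arbitrary scanner units;
#' all model fitting normalises by the measured S(0).
#'
#' @slot scheme a \linkS4class{BValueScheme}.
#' @slot signal numeric vector of non-negative intensities, same length as
#'   the scheme; \code{signal[1]} is S(0) and must be positive.
#' @export
setClass("DecayCurve",
         representation(scheme = "BValueScheme", signal = "numeric"),
         validity = function(object) {
           s <- object@signal
           if (length(s) != length(object@scheme@values))
             return("signal and scheme lengths differ")
           if (anyNA(s) || any(s < 0)) return("signal must be non-negative")
           if (s[1L] <= 0) return("S(0) must be positive")
           TRUE
         })

#' Decay-model parameter classes
#'
#' Parameter containers for the three decay models. Diffusion coefficients
#' are stored in physical units of mm^2/s (so a typical tissue ADC is about
#' 1e-3); the reporting layer multiplies by 10^3 for display in the
#' conventional "x10^-3" convention. NA values mark a failed fit.
#'
#' @slot adc apparent diffusion coefficient, mm^2/s.
#' @aliases BiexpParams-class StretchedParams-class DiffusionParams-class
#' @name MonoexpParams-class
#' @export
setClass("DiffusionParams", representation("VIRTUAL"))

#' @export
setClass("MonoexpParams", contains = "DiffusionParams",
         representation(adc = "numeric"),
         validity = function(object) {
           if (length(object@adc) != 1L) return("adc must be scalar")
           if (!.isPositive(object@adc)) return("adc must be positive")
           TRUE
         })

#' @export
setClass("BiexpParams", contains = "DiffusionParams",
         representation(d = "numeric", dStar = "numeric", f = "numeric"),
         validity = function(object) {
           if (any(lengths(list(object@d, object@dStar, object@f)) != 1L))
             return("d, dStar, f must be scalars")
           if (!.isPositive(object@d)) return("d must be positive")
           if (!.isPositive(object@dStar)) return("dStar must be positive")
           f <- object@f
           if (!is.na(f) && (f < 0 || f > 1)) return("f must lie in [0, 1]")
           if (!is.na(object@d) && !is.na(object@dStar) &&
               object@dStar < object@d)
             return("dStar must be >= d (compartment identifiability)")
           TRUE
         })

#' @export
setClass("StretchedParams", contains = "DiffusionParams",
         representation(ddc = "numeric", alpha = "numeric"),
         validity = function(object) {
           if (any(lengths(list(object@ddc, object@alpha)) != 1L))
             return("ddc and alpha must be scalars")
           if (!.isPositive(object@ddc)) return("ddc must be positive")
           a <- object@alpha
           if (!is.na(a) && (a <= 0 || a > 1))
             return("alpha must lie in (0, 1]")
           TRUE
         })

#' Fit configuration
#'
#' Controls for the per-voxel model fits.
#'
#' @slot bSplitThreshold b-value (s/mm^2) separating the perfusion-sensitive
#'   low-b regime from the diffusion-dominated high-b regime used by the
#'   segmented biexponential fit; default 200.
#' @slot lower,upper named numeric bounds for d, dStar, f, ddc, alpha
#'   (mm^2/s or dimensionless).
#' @slot refine logical; run the full bounded nonlinear refinement after the
#'   segmented biexponential initialisation (default TRUE).
#' @slot adcMethod "two-point" (b = 0 and 1000 only, the conventional-DWI
#'   ADC) or "loglinear" (log-linear least squares over all b-values).
#' @slot biexpForm "sum": fast compartment decays as exp(-b (D* + D));
#'   "conventional": exp(-b D*).
#' @slot tol convergence tolerance passed to the Levenberg-Marquardt solver.
#' @slot maxIter maximum solver iterations.
#' @export
setClass("FittingConfig",
         representation(bSplitThreshold = "numeric",
                        lower = "numeric", upper = "numeric",
                        refine = "logical", adcMethod = "character",
                        biexpForm = "character",
                        tol = "numeric", maxIter = "integer"),
         validity = function(object) {
           need <- c("d", "dStar", "f", "ddc", "alpha")
           if (!all(need %in% names(object@lower)) ||
               !all(need %in% names(object@upper)))
             return("lower/upper must name d, dStar, f, ddc, alpha")
           if (any(object@lower[need] >= object@upper[need]))
             return("each lower bound must be below its upper bound")
           if (!object@adcMethod %in% c("two-point", "loglinear"))
             return("adcMethod must be 'two-point' or 'loglinear'")
           if (!object@biexpForm %in% c("sum", "conventional"))
             return("biexpForm must be 'sum' or 'conventional'")
           TRUE
         })

#' Single-curve fit result
#'
#' @slot params the fitted \linkS4class{DiffusionParams}; NA-valued on
#'   failure.
#' @slot residualSSE sum of squared residuals on the normalised signal.
#' @slot converged logical.
#' @slot nPoints number of b-values used.
#' @export
setClass("FitResult",
         representation(params = "DiffusionParams", residualSSE = "numeric",
                        converged = "logical", nPoints = "integer"),
         validity = function(object) {
           if (!is.na(object@residualSSE) && object@residualSSE < 0)
             return("residualSSE must be non-negative")
           TRUE
         })

#' Voxel-wise parameter maps
#'
#' 3D parameter grids produced by \code{\link{fitVolume}}: one grid per
#' parameter (adc, d, dstar, f, ddc, alpha, all mm^2/s or dimensionless)
#' plus an integer fit-quality grid counting, per voxel, how many of the
#' three model fits converged (0-3). Voxels outside the mask are NA.
#'
#' @slot maps named list of 3D numeric arrays sharing one shape.
#' @slot quality 3D array, number of converged models per voxel.
#' @slot pixdim voxel size along each spatial axis, mm.
#' @slot xform 4x4 NIfTI orientation matrix.
#' @export
setClass("ParameterMaps",
         representation(maps = "list", quality = "array",
                        pixdim = "numeric", xform = "matrix"),
         validity = function(object) {
           need <- c("adc", "d", "dstar", "f", "ddc", "alpha")
           if (!all(need %in% names(object@maps)))
             return("maps must include adc, d, dstar, f, ddc, alpha")
           dims <- lapply(object@maps, dim)
           if (length(unique(dims)) != 1L)
             return("all maps must share one shape")
           if (!identical(dim(object@quality), dims[[1L]]))
             return("quality grid shape differs from the maps")
           if (length(object@pixdim) != 3L || any(object@pixdim <= 0))
             return("pixdim must be three positive voxel sizes")
           TRUE
         })

#' Phantom geometry and noise specification
#'
#' Describes one synthetic lesion volume: an ellipsoidal lesion embedded in
#' a homogeneous background, sampled over a b-value scheme and corrupted
#' with Rician noise at a stated SNR (defined at b = 0 in the lesion).
#'
#' @slot dim spatial grid shape, voxels.
#' @slot pixdim voxel size, mm.
#' @slot center ellipsoid centre, voxel coordinates (1-based).
#' @slot radii ellipsoid semi-axes, voxels.
#' @slot background \linkS4class{BiexpParams} for non-lesion voxels.
#' @slot s0Lesion,s0Background unattenuated signal levels, arbitrary units.
#' @slot snr signal-to-noise ratio at b = 0 in the lesion; Inf disables
#'   noise.
#' @slot noiseModel currently "rician".
#' @slot seed RNG seed for the noise draw; NA uses the current RNG stream.
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", pixdim = "numeric",
                        center = "numeric", radii = "numeric",
                        background = "BiexpParams",
                        s0Lesion = "numeric", s0Background = "numeric",
                        snr = "numeric", noiseModel = "character",
                        seed = "numeric"),
         validity = function(object) {
           if (length(object@dim) != 3L || any(object@dim < 1L))
             return("dim must be three positive extents")
           if (length(object@pixdim) != 3L || any(object@pixdim <= 0))
             return("pixdim must be three positive voxel sizes")
           if (length(object@center) != 3L || length(object@radii) != 3L)
             return("center and radii must each have three components")
           if (any(object@radii <= 0)) return("radii must be positive")
           if (any(object@center - object@radii < 1) ||
               any(object@center + object@radii > object@dim))
             return("lesion ellipsoid must lie strictly inside the volume")
           if (object@snr <= 0) return("snr must be positive")
           if (object@noiseModel != "rician")
             return("only the 'rician' noise model is available")
           TRUE
         })

#' Per-group generating distribution for phantom lesions
#'
#' Mean and SD, per parameter, of the truncated normal from which subject
#' ground-truth parameters are drawn. Units are mm^2/s for adc, d, dstar and
#' ddc; f and alpha are dimensionless.
#'
#' @slot label group name ("progression" or "pseudoprogression").
#' @slot means,sds named numeric vectors over
#'   \code{c("adc","d","dstar","f","ddc","alpha")}.
#' @export
setClass("GroupParameterDistribution",
         representation(label = "character", means = "numeric",
                        sds = "numeric"),
         validity = function(object) {
           need <- c("adc", "d", "dstar", "f", "ddc", "alpha")
           if (!all(need %in% names(object@means)) ||
               !all(need %in% names(object@sds)))
             return("means and sds must name adc, d, dstar, f, ddc, alpha")
           if (any(object@sds[need] <= 0)) return("sds must be positive")
           if (any(object@means[need] <= 0)) return("means must be positive")
           if (object@means["f"] > 1) return("mean f must lie in [0, 1]")
           if (object@means["alpha"] > 1)
             return("mean alpha must lie in (0, 1]")
           TRUE
         })

#' Labelled synthetic lesion cohort
#'
#' A list of phantom subjects, each holding a 4D volume, an ROI mask, the
#' drawn ground-truth parameters and a group label. Generation is a pure
#' function of (preset, seed).
#'
#' @slot subjects list; each element has fields id, group, truth (named
#'   numeric of the six drawn parameters), volume (4D array), mask (3D
#'   array), seed.
#' @slot scheme the \linkS4class{BValueScheme} sampled.
#' @slot spec the \linkS4class{PhantomSpec} template used.
#' @slot seed the cohort-level seed.
#' @slot preset preset name, or "custom".
#' @export
setClass("PhantomCohort",
         representation(subjects = "list", scheme = "BValueScheme",
                        spec = "PhantomSpec", seed = "numeric",
                        preset = "character"))

#' Diagnostic statistics report
#'
#' Aggregate of the full statistics chain over one lesion table: group
#' comparison (pooled t), interobserver agreement (ICC(2,1) and
#' Bland-Altman), and diagnostic performance (ROC with Youden-optimal
#' cutoff, DeLong confidence intervals and pairwise DeLong AUC
#' comparisons), per diffusion parameter.
#'
#' @slot groupStats data.frame: parameter, per-group mean/sd/n, t, df, p.
#' @slot agreement data.frame: parameter, icc, icc_ci_low, icc_ci_high,
#'   band, bias, loa_low, loa_high, n_pairs (empty when only one reader).
#' @slot performance data.frame: parameter, auc, auc_ci_low, auc_ci_high,
#'   cutoff, youden, sensitivity, specificity, direction.
#' @slot aucComparisons data.frame of pairwise DeLong tests.
#' @slot normality data.frame of per-group Lilliefors results.
#' @slot metadata list: positive class, readers, group sizes, note that no
#'   multiple-testing correction is applied.
#' @export
setClass("DiagnosticReport",
         representation(groupStats = "data.frame", agreement = "data.frame",
                        performance = "data.frame",
                        aucComparisons = "data.frame",
                        normality = "data.frame", metadata = "list"))
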