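#' Default multi-b acquisition scheme
#'
#' The 12-point b-value protocol used throughout: 0, 10, 20, 40, 60, 70,
#' 80, 100, 200, 400, 800, 1000 s/mm^2. The dense low-b sampling (eight
#' points at or below 100) is what makes the perfusion compartment of the
#' biexponential model estimable.
#'
#' @return numeric vector of 12 b-values.
#' @export
defaultBValues <- function()
  c(0, 10, 20, 40, 60, 70, 80, 100, 200, 400, 800, 1000)

#' @rdname BValueScheme-class
#' @param values numeric vector of b-values, s/mm^2.
#' @export
BValueScheme <- function(values = defaultBValues())
  new("BValueScheme", values = as.numeric(values))

#' @rdname DecayCurve-class
#' @param scheme a \linkS4class{BValueScheme}.
#' @param signal numeric vector of intensities, same length as the scheme.
#' @export
DecayCurve <- function(signal, scheme = BValueScheme())
  new("DecayCurve", scheme = scheme, signal = as.numeric(signal))

#' @rdname MonoexpParams-class
#' @param adc apparent diffusion coefficient, mm^2/s.
#' @export
MonoexpParams <- function(adc) new("MonoexpParams", adc = as.numeric(adc))

#' @rdname MonoexpParams-class
#' @param d true (tissue) diffusion coefficient, mm^2/s.
#' @param dStar pseudodiffusion coefficient, mm^2/s; must be >= d.
#' @param f perfusion fraction in [0, 1].
#' @export
BiexpParams <- function(d, dStar, f)
  new("BiexpParams", d = as.numeric(d), dStar = as.numeric(dStar),
      f = as.numeric(f))

#' @rdname MonoexpParams-class
#' @param ddc distributed diffusion coefficient, mm^2/s.
#' @param alpha heterogeneity index in (0, 1]; 1 recovers monoexponential
#'   decay.
#' @export
StretchedParams <- function(ddc, alpha)
  new("StretchedParams", ddc = as.numeric(ddc), alpha = as.numeric(alpha))

.checkB <- function(b) {
  if (anyNA(b) || any(b < 0)) stop("b-values must be non-negative")
  as.numeric(b)
}

## Raw numerical kernels, shared by the S4 methods and the fitters.
.monoDecay <- function(b, adc) exp(-b * adc)

.biexpDecay <- function(b, d, dStar, f, form = "sum") {
  rate <- if (form == "sum") dStar + d else dStar
  (1 - f) * exp(-b * d) + f * exp(-b * rate)
}

.stretchedDecay <- function(b, ddc, alpha) exp(-(b * ddc)^alpha)

#' @rdname predictSignal
#' @export
setMethod("predictSignal", "MonoexpParams", function(params, b, ...) {
  b <- .checkB(b)
  if (is.na(params@adc)) stop("adc is NA")
  .monoDecay(b, params@adc)
})

#' @rdname predictSignal
#' @param form exponent convention for the fast compartment; see above.
#' @export
setMethod("predictSignal", "BiexpParams",
          function(params, b, form = c("sum", "conventional"), ...) {
  b <- .checkB(b)
  form <- match.arg(form)
  if (anyNA(c(params@d, params@dStar, params@f)))
    stop("biexponential parameters contain NA")
  .biexpDecay(b, params@d, params@dStar, params@f, form)
})

#' @rdname predictSignal
#' @export
setMethod("predictSignal", "StretchedParams", function(params, b, ...) {
  b <- .checkB(b)
  if (anyNA(c(params@ddc, params@alpha)))
    stop("stretched parameters contain NA")
  .stretchedDecay(b, params@ddc, params@alpha)
})

#' @describeIn accessors b-values of a scheme or curve.
#' @export
setMethod("bValues", "BValueScheme", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("bValues", "DecayCurve", function(x) x@scheme@values)

#' @describeIn accessors signal intensities of a curve.
#' @export
setMethod("signals", "DecayCurve", function(x) x@signal)

#' @export
setMethod("coef", "MonoexpParams", function(object, ...)
  c(adc = object@adc))

#' @export
setMethod("coef", "BiexpParams", function(object, ...)
  c(d = object@d, dstar = object@dStar, f = object@f))

#' @export
setMethod("coef", "StretchedParams", function(object, ...)
  c(ddc = object@ddc, alpha = object@alpha))

setMethod("show", "BValueScheme", function(object) {
  cat("BValueScheme with", length(object@values), "b-values (s/mm^2):\n")
  cat(" ", paste(object@values, collapse = ", "), "\n")
})

setMethod("show", "DecayCurve", function(object) {
  cat("DecayCurve over", length(object@signal), "b-values; S(0) =",
      format(object@signal[1L]), "\n")
})

setMethod("show", "MonoexpParams", function(object) {
  cat("Monoexponential: ADC =", format(object@adc * 1e3),
      "x10^-3 mm^2/s\n")
})

setMethod("show", "BiexpParams", function(object) {
  cat("Biexponential (IVIM): D =", format(object@d * 1e3),
      "x10^-3 mm^2/s, D* =", format(object@dStar * 1e3),
      "x10^-3 mm^2/s, f =", format(object@f), "\n")
})

setMethod("show", "StretchedParams", function(object) {
  cat("Stretched-exponential: DDC =", format(object@ddc * 1e3),
      "x10^-3 mm^2/s, alpha =", format(object@alpha), "\n")
})

#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an mbDWI object.
#' @name accessors
NULL
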