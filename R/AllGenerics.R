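#' Predict the normalised decay signal S(b)/S(0)
#'
#' Forward evaluation of a decay model at one or more b-values. All three
#' models return exactly 1 at b = 0 and decay monotonically for valid
#' parameters.
#'
#' @param params a \linkS4class{MonoexpParams}, \linkS4class{BiexpParams}
#'   or \linkS4class{StretchedParams} object.
#' @param b numeric vector of b-values, s/mm^2 (non-negative).
#' @param ... passed to methods; the \code{BiexpParams} method accepts
#'   \code{form = c("sum", "conventional")} selecting whether the fast
#'   compartment decays as exp(-b (D* + D)) or exp(-b D*).
#' @return numeric vector of signal ratios in (0, 1].
#' @export
setGeneric("predictSignal", function(params, b, ...)
  standardGeneric("predictSignal"))

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("paramMaps", function(x) standardGeneric("paramMaps"))

#' @rdname accessors
#' @export
setGeneric("fitQuality", function(x) standardGeneric("fitQuality"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
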