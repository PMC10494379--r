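#' Rician noise for magnitude MR images
#'
#' Magnitude-MRI noise: the observed intensity is the modulus of the clean
#' signal plus complex Gaussian noise,
#' sqrt((clean + g1)^2 + g2^2) with g1, g2 ~ N(0, sigma). At high local SNR
#' this is approximately Gaussian around the clean value; at low SNR it is
#' biased upward (the Rician floor).
#'
#' @param clean numeric array or vector of noise-free intensities.
#' @param sigma Gaussian component SD, same units as \code{clean}.
#' @return noisy values, same shape as \code{clean}.
#' @export
addRicianNoise <- function(clean, sigma) {
  n <- length(clean)
  out <- sqrt((clean + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(clean))) dim(out) <- dim(clean)
  out
}

## truncated-normal draw by rejection; errors out when the truncation
## window carries essentially no mass (mean far outside the valid range)
.rtrunc <- function(n, mean, sd, lower, upper) {
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-6)
    stop("infeasible truncation: mean ", mean, " with sd ", sd,
         " has no mass in [", lower, ", ", upper, "]")
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(2L * ceiling((n - length(out)) / mass), mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

.paramRanges <- list(adc = c(1e-6, 1e-2), d = c(1e-6, 5e-3),
                     dstar = c(1e-4, 5e-1), f = c(0, 1),
                     ddc = c(1e-6, 1e-1), alpha = c(0.01, 1))

#' @rdname GroupParameterDistribution-class
#' @param label group name.
#' @param means,sds named numeric vectors over
#'   \code{c("adc","d","dstar","f","ddc","alpha")}; diffusion coefficients
#'   in mm^2/s.
#' @export
GroupParameterDistribution <- function(label, means, sds)
  new("GroupParameterDistribution", label = label, means = means, sds = sds)

#' @rdname PhantomSpec-class
#' @param dim,pixdim,center,radii,background,s0Lesion,s0Background,snr,noiseModel,seed
#'   see the class slots.
#' @export
PhantomSpec <- function(dim = c(16L, 16L, 9L), pixdim = c(2.5, 2.5, 4),
                        center = c(8, 8, 5), radii = c(1.9, 1.9, 2.2),
                        background = BiexpParams(0.8e-3, 10e-3, 0.05),
                        s0Lesion = 1000, s0Background = 800,
                        snr = 50, noiseModel = "rician", seed = NA_real_)
  new("PhantomSpec", dim = as.integer(dim), pixdim = pixdim,
      center = center, radii = radii, background = background,
      s0Lesion = s0Lesion, s0Background = s0Background, snr = snr,
      noiseModel = noiseModel, seed = as.numeric(seed))

#' The two-group study preset
#'
#' Generating distributions and sample sizes emulating a 40-lesion
#' glioblastoma follow-up cohort: 22 progression and 18 pseudoprogression
#' lesions whose per-lesion parameter means and SDs follow the published
#' group summaries (diffusion coefficients stored in mm^2/s; the reporting
#' layer displays them x10^3). The phantom geometry gives a lesion
#' cross-section of about 56 mm^2 at the central slice, inside the 45-65
#' mm^2 ROI band of the emulated protocol, and SNR 50 at b = 0.
#'
#' @param snr signal-to-noise ratio at b = 0; Inf disables noise.
#' @return list with elements \code{prog}, \code{pseudo}
#'   (\linkS4class{GroupParameterDistribution}), \code{nProg},
#'   \code{nPseudo}, \code{spec} (\linkS4class{PhantomSpec}) and
#'   \code{scheme}.
#' @export
paperLikePreset <- function(snr = 50) {
  prog <- GroupParameterDistribution(
    "progression",
    means = c(adc = 1.315e-3, d = 1.084e-3, dstar = 53.841e-3,
              f = 0.333, ddc = 1.177e-3, alpha = 0.673),
    sds = c(adc = 0.175e-3, d = 0.126e-3, dstar = 26.578e-3,
            f = 0.108, ddc = 0.397e-3, alpha = 0.092))
  pseudo <- GroupParameterDistribution(
    "pseudoprogression",
    means = c(adc = 1.956e-3, d = 1.741e-3, dstar = 25.613e-3,
              f = 0.239, ddc = 1.692e-3, alpha = 0.879),
    sds = c(adc = 0.306e-3, d = 0.213e-3, dstar = 8.951e-3,
            f = 0.086, ddc = 0.350e-3, alpha = 0.091))
  list(prog = prog, pseudo = pseudo, nProg = 22L, nPseudo = 18L,
       spec = PhantomSpec(snr = snr), scheme = BValueScheme())
}

.ellipsoidMask <- function(dim, center, radii) {
  x <- (seq_len(dim[1L]) - center[1L]) / radii[1L]
  y <- (seq_len(dim[2L]) - center[2L]) / radii[2L]
  z <- (seq_len(dim[3L]) - center[3L]) / radii[3L]
  g <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.numeric(g <= 1), dim)
}

.lesionDecay <- function(truth, b) {
  if (is(truth, "BiexpParams")) return(predictSignal(truth, b))
  if (is.list(truth) && all(c("biexp", "stretched") %in% names(truth))) {
    w <- if (is.null(truth$weight)) 0.5 else truth$weight
    return(w * predictSignal(truth$biexp, b) +
             (1 - w) * predictSignal(truth$stretched, b))
  }
  stop("truth must be a BiexpParams or a list(biexp, stretched, weight)")
}

#' Generate one phantom lesion volume
#'
#' Builds a 4D multi-b volume containing an ellipsoidal lesion embedded in
#' a homogeneous background with distinct (white-matter-like) parameters,
#' then applies per-voxel, per-b Rician noise with
#' sigma = S0(lesion) / SNR.
#'
#' The lesion ground truth is either a plain \linkS4class{BiexpParams}
#' (pure biexponential decay) or a blend
#' \code{list(biexp = , stretched = , weight = 0.5)}, in which each lesion
#' voxel decays as the weighted mixture of the biexponential and
#' stretched-exponential predictions — a sub-voxel water pool of which one
#' part shows perfusion-driven biexponential behaviour and the other
#' anomalous (heterogeneous) diffusion. The cohort generator uses the
#' blend so that all six drawn parameters leave a signature in the signal.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param truth lesion ground truth; see Details.
#' @param scheme a \linkS4class{BValueScheme}.
#' @return list with \code{volume} (4D array) and \code{mask} (3D lesion
#'   mask).
#' @export
generatePhantom <- function(spec, truth, scheme = BValueScheme()) {
  b <- scheme@values
  mask <- .ellipsoidMask(spec@dim, spec@center, spec@radii)
  lesionDecay <- spec@s0Lesion * .lesionDecay(truth, b)
  bgDecay <- spec@s0Background * predictSignal(spec@background, b)
  nb <- length(b)
  vol <- array(0, c(spec@dim, nb))
  for (k in seq_len(nb)) {
    sl <- array(bgDecay[k], spec@dim)
    sl[mask != 0] <- lesionDecay[k]
    vol[, , , k] <- sl
  }
  if (is.finite(spec@snr)) {
    if (!is.na(spec@seed)) set.seed(spec@seed)
    vol <- addRicianNoise(vol, spec@s0Lesion / spec@snr)
  }
  list(volume = vol, mask = mask)
}

#' Generate a labelled two-group phantom cohort
#'
#' Draws one lesion per subject, with per-subject ground-truth parameters
#' sampled independently from the group's truncated normal distribution
#' (truncated to each parameter's valid range, and D* redrawn until
#' D* >= D), then generates the subject's noisy 4D volume with
#' \code{\link{generatePhantom}}. The whole cohort is a pure function of
#' the inputs and \code{seed}.
#'
#' Lesion signal is the blended biexponential + stretched decay of the
#' drawn parameters (see \code{\link{generatePhantom}}); the drawn values
#' define the intended marginal distributions and are recorded in the
#' truth table, while the model-consistent per-model truths (the
#' noise-free best fits to the generated curve) are available from
#' \code{\link{derivedTruths}}.
#'
#' @param distProg,distPseudo \linkS4class{GroupParameterDistribution}s.
#' @param nProg,nPseudo subjects per group.
#' @param spec template \linkS4class{PhantomSpec}.
#' @param scheme a \linkS4class{BValueScheme}.
#' @param seed integer cohort seed.
#' @param preset preset tag recorded in the object.
#' @param blendWeight weight of the biexponential component in the lesion
#'   signal (default 0.5).
#' @return a \linkS4class{PhantomCohort}.
#' @export
generateCohort <- function(distProg, distPseudo, nProg = 22L,
                           nPseudo = 18L, spec = PhantomSpec(),
                           scheme = BValueScheme(), seed = 1L,
                           preset = "custom", blendWeight = 0.5) {
  if (nProg < 1L || nPseudo < 1L) stop("need at least one subject per group")
  set.seed(seed)
  groups <- c(rep("progression", nProg), rep("pseudoprogression", nPseudo))
  dists <- list(progression = distProg, pseudoprogression = distPseudo)
  n <- nProg + nPseudo
  subjectSeeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    dist <- dists[[groups[i]]]
    tr <- vapply(names(.paramRanges), function(p)
      .rtrunc(1L, dist@means[[p]], dist@sds[[p]],
              .paramRanges[[p]][1L], .paramRanges[[p]][2L]),
      numeric(1L))
    while (tr[["dstar"]] < tr[["d"]])
      tr[["dstar"]] <- .rtrunc(1L, dist@means[["dstar"]],
                               dist@sds[["dstar"]],
                               .paramRanges$dstar[1L], .paramRanges$dstar[2L])
    subjSpec <- spec
    subjSpec@seed <- as.numeric(subjectSeeds[i])
    truth <- list(biexp = BiexpParams(tr[["d"]], tr[["dstar"]], tr[["f"]]),
                  stretched = StretchedParams(tr[["ddc"]], tr[["alpha"]]),
                  weight = blendWeight)
    ph <- generatePhantom(subjSpec, truth, scheme)
    subjects[[i]] <- list(id = sprintf("S%02d", i), group = groups[i],
                          truth = tr, volume = ph$volume, mask = ph$mask,
                          seed = subjectSeeds[i],
                          blendWeight = blendWeight)
  }
  new("PhantomCohort", subjects = subjects, scheme = scheme, spec = spec,
      seed = as.numeric(seed), preset = preset)
}

#' @rdname accessors
#' @export
setMethod("subjects", "PhantomCohort", function(x) x@subjects)

#' @describeIn accessors drawn ground-truth parameters of a cohort, one
#'   row per subject.
#' @export
setMethod("truthTable", "PhantomCohort", function(x) {
  rows <- lapply(x@subjects, function(s)
    data.frame(subject = s$id, group = s$group, t(s$truth),
               seed = s$seed))
  do.call(rbind, rows)
})

setMethod("show", "PhantomCohort", function(object) {
  tab <- table(vapply(object@subjects, `[[`, character(1L), "group"))
  cat("PhantomCohort (preset '", object@preset, "', seed ",
      object@seed, "):\n", sep = "")
  for (g in names(tab)) cat("  ", g, ": ", tab[[g]], " lesions\n", sep = "")
})

#' Model-consistent ground truths
#'
#' The phantom signal blends biexponential and stretched decay, so no
#' single model's parameters describe it exactly; the model-consistent
#' "truth" of a subject is defined as the noise-free best fit of each
#' model to the subject's generating curve (model mismatch is inherent).
#' Used as the reference in recovery tests.
#'
#' @param cohort a \linkS4class{PhantomCohort}.
#' @param config a \linkS4class{FittingConfig}.
#' @return data.frame: subject, group and the noise-free best-fit adc, d,
#'   dstar, f, ddc, alpha.
#' @export
derivedTruths <- function(cohort, config = FittingConfig()) {
  rows <- lapply(cohort@subjects, function(s) {
    tr <- s$truth
    truth <- list(biexp = BiexpParams(tr[["d"]], tr[["dstar"]], tr[["f"]]),
                  stretched = StretchedParams(tr[["ddc"]], tr[["alpha"]]),
                  weight = if (is.null(s$blendWeight)) 0.5 else s$blendWeight)
    clean <- .lesionDecay(truth, cohort@scheme@values)
    curve <- DecayCurve(clean, cohort@scheme)
    bi <- fitBiexp(curve, config)
    st <- fitStretched(curve, config)
    data.frame(subject = s$id, group = s$group,
               adc = fitADC(curve, config)@params@adc,
               d = bi@params@d, dstar = bi@params@dStar, f = bi@params@f,
               ddc = st@params@ddc, alpha = st@params@alpha)
  })
  do.call(rbind, rows)
}

.shift3d <- function(arr, by) {
  d <- dim(arr)
  out <- array(0, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - by[a]
    i[i < 1L | i > d[a]] <- NA_integer_
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1L]], ok[[2L]], ok[[3L]]] <-
    arr[src[[1L]][ok[[1L]]], src[[2L]][ok[[2L]]], src[[3L]][ok[[3L]]]]
  out
}

.neighbourCount <- function(mask) {
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- array(0, dim(mask))
  for (r in seq_len(nrow(shifts))) out <- out + .shift3d(mask, shifts[r, ])
  out
}

#' Simulate a second reader's ROI tracing
#'
#' Perturbs an ROI mask the way an independent reader's manual tracing
#' would differ from the first: a small random translation plus random
#' toggling of boundary voxels (erosion/dilation). The perturbed mask must
#' overlap the original by at least 50% of the original volume; the draw
#' is retried a bounded number of times before failing.
#'
#' @param mask 3D binary array (nonzero = in ROI).
#' @param jitter displacement scale, voxels; 0 returns the mask unchanged.
#' @param seed optional RNG seed.
#' @param maxTries retry bound for the overlap constraint.
#' @return perturbed 3D binary mask.
#' @export
simulateSecondReader <- function(mask, jitter = 1, seed = NULL,
                                 maxTries = 25L) {
  if (sum(mask != 0) == 0L) stop("mask is empty")
  if (!is.null(seed)) set.seed(seed)
  if (jitter == 0) return(mask)
  nOrig <- sum(mask != 0)
  pToggle <- min(0.5, 0.25 * jitter)
  for (try in seq_len(maxTries)) {
    shift <- round(stats::rnorm(3L, 0, jitter))
    m <- .shift3d(mask, shift)
    nb <- .neighbourCount(m)
    innerBoundary <- which(m != 0 & nb < 6)
    outerBoundary <- which(m == 0 & nb > 0)
    m[innerBoundary] <- ifelse(
      stats::runif(length(innerBoundary)) < pToggle, 0, m[innerBoundary])
    m[outerBoundary] <- ifelse(
      stats::runif(length(outerBoundary)) < pToggle, 1, m[outerBoundary])
    overlap <- sum(m != 0 & mask != 0) / nOrig
    if (overlap >= 0.5 && sum(m != 0) > 0L) return(m)
  }
  stop("could not satisfy the 50% overlap constraint; jitter too large")
}
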