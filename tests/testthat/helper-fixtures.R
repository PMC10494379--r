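# Shared fixtures: forward-generated curves, brute-force oracles and a
# cached end-to-end pipeline run reused across test files.

defaultScheme <- BValueScheme()

cleanCurve <- function(params, scale = 1, scheme = defaultScheme)
  DecayCurve(scale * predictSignal(params, bValues(scheme)), scheme)

# Table-2-like group means used as representative tissue values
progBiexp <- function() BiexpParams(1.084e-3, 53.841e-3, 0.333)
pseudoBiexp <- function() BiexpParams(1.741e-3, 25.613e-3, 0.239)
progStretched <- function() StretchedParams(1.177e-3, 0.673)

relErr <- function(est, truth) max(abs(est - truth) / abs(truth))

# Exhaustive Mann-Whitney pair counting: the AUC oracle
bruteForceAUC <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# ICC(2,1) oracle built from an independent ANOVA decomposition (aov)
aovICC21 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# One full paper-like pipeline run (22 + 18 lesions, SNR 50, two readers),
# computed once and shared by the report and acceptance tests.
.pipelineCache <- new.env(parent = emptyenv())
cachedPipeline <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.pipelineCache[[key]]))
    .pipelineCache[[key]] <- runPipeline(seed = seed)
  .pipelineCache[[key]]
}
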