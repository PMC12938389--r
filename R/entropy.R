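#' Configuration of the entropy estimators
#'
#' Collects the estimator parameters used throughout the pipeline.
#' Defaults follow the feature-extraction protocol: embedding dimension
#' 2 and tolerance 0.15 (as a fraction of the segment SD) for
#' approximate/sample/fuzzy entropy, permutation order 6 with delay 1,
#' and a singular-spectrum trajectory window of 500 samples.
#'
#' @param m_embed embedding dimension for approximate/sample/fuzzy
#'   entropy.
#' @param r_tol tolerance; a fraction of the segment SD when
#'   `r_mode = "sd_scaled"`, an absolute amplitude otherwise.
#' @param r_mode `"sd_scaled"` (default) or `"absolute"`.
#' @param m_perm permutation-entropy order.
#' @param tau permutation-entropy time delay (samples).
#' @param sse_window singular-spectrum trajectory window length L
#'   (samples). Capped at two thirds of the analyzed segment length so
#'   the trajectory matrix never degenerates (500/750 at the default
#'   epoch geometry).
#' @param sse_weight `"sigma"`: singular values normalized directly
#'   (default); `"sigma_sq"`: squared singular values.
#' @param fuzzy_power exponent of the fuzzy membership function.
#' @param perm_normalize divide permutation entropy by log(m_perm!)?
#' @param segment `"full_epoch"` (default) or `"post_stimulus"`; which
#'   part of each epoch the estimators see.
#' @return an object of class `entropy_config`.
#' @export
entropy_config <- function(m_embed = 2L, r_tol = 0.15,
                           r_mode = c("sd_scaled", "absolute"),
                           m_perm = 6L, tau = 1L,
                           sse_window = 500L,
                           sse_weight = c("sigma", "sigma_sq"),
                           fuzzy_power = 2,
                           perm_normalize = FALSE,
                           segment = c("full_epoch", "post_stimulus")) {
  r_mode <- match.arg(r_mode)
  sse_weight <- match.arg(sse_weight)
  segment <- match.arg(segment)
  if (m_embed < 1) stop("m_embed must be >= 1")
  if (r_tol <= 0 || (r_mode == "sd_scaled" && r_tol >= 1))
    stop("r_tol must be in (0, 1) when SD-scaled")
  if (m_perm < 2) stop("m_perm must be >= 2")
  if (tau < 1) stop("tau must be >= 1")
  if (sse_window < 2) stop("sse_window must be >= 2")
  structure(list(m_embed = as.integer(m_embed), r_tol = r_tol,
                 r_mode = r_mode, m_perm = as.integer(m_perm),
                 tau = as.integer(tau), sse_window = as.integer(sse_window),
                 sse_weight = sse_weight, fuzzy_power = fuzzy_power,
                 perm_normalize = perm_normalize, segment = segment),
            class = "entropy_config")
}

tolerance_r <- function(x, cfg) {
  if (cfg$r_mode == "sd_scaled") cfg$r_tol * sd(x) else cfg$r_tol
}

#' Approximate entropy
#'
#' ApEn(m, r) with Chebyshev distance and self-matches included:
#' Phi^m - Phi^(m+1), where Phi^m is the mean over templates of the log
#' relative frequency of templates within tolerance r. A zero-variance
#' signal returns 0 with attribute `degenerate = TRUE`.
#'
#' @param x numeric vector (single-channel epoch segment).
#' @param cfg an [entropy_config()].
#' @return scalar, nats.
#' @export
approximate_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n <= cfg$m_embed + 1) stop("signal too short for m_embed")
  if (sd(x) == 0)
    return(structure(0, degenerate = TRUE))
  .template_entropies_cpp(as.numeric(x), cfg$m_embed,
                          tolerance_r(x, cfg), cfg$fuzzy_power)[1]
}

#' Sample entropy
#'
#' SampEn(m, r) = -log(A/B): B counts template pairs (i != j) matching
#' at length m within Chebyshev tolerance r, A the same at length m+1,
#' self-matches excluded. When no pairs match at either length the value
#' is undefined and `NA` is returned with attribute
#' `undefined = TRUE` (such epochs are excluded from regional averages).
#'
#' @inheritParams approximate_entropy
#' @return scalar, nats, or `NA` when undefined.
#' @export
sample_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n <= cfg$m_embed + 1) stop("signal too short for m_embed")
  if (sd(x) == 0)
    return(structure(0, degenerate = TRUE))
  te <- .template_entropies_cpp(as.numeric(x), cfg$m_embed,
                                tolerance_r(x, cfg), cfg$fuzzy_power)
  if (te[2] == 0 || te[3] == 0)
    return(structure(NA_real_, undefined = TRUE))
  -log(te[2] / te[3])
}

#' Fuzzy entropy
#'
#' Templates are mean-centered; similarity is the fuzzy membership
#' exp(-(d/r)^p) of the Chebyshev distance d. FuzzyEn =
#' log(phi^m) - log(phi^(m+1)).
#'
#' @inheritParams approximate_entropy
#' @return scalar, nats.
#' @export
fuzzy_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n <= cfg$m_embed + 1) stop("signal too short for m_embed")
  if (sd(x) == 0)
    return(structure(0, degenerate = TRUE))
  .template_entropies_cpp(as.numeric(x), cfg$m_embed,
                          tolerance_r(x, cfg), cfg$fuzzy_power)[4]
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of consecutive
#' `m_perm`-tuples at delay `tau`; ties are broken by index order
#' (stable ranking). Optionally normalized by log(m_perm!).
#'
#' @inheritParams approximate_entropy
#' @return scalar, nats (dimensionless if normalized).
#' @export
permutation_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  if (n < cfg$m_perm) stop("signal shorter than permutation order")
  h <- .permen_cpp(as.numeric(x), cfg$m_perm, cfg$tau)
  if (cfg$perm_normalize) h <- h / log(factorial(cfg$m_perm))
  h
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal: positive frequencies are
#' doubled, negative frequencies zeroed, DC (and Nyquist for even
#' length) kept.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Envelope entropy
#'
#' Shannon entropy of the normalized instantaneous-amplitude envelope:
#' the envelope a_j is the modulus of the analytic signal, p_j =
#' a_j / sum(a), and H = -sum p_j log p_j. H is maximal (log N) for a
#' constant envelope and small when envelope energy is concentrated in
#' bursts, so it quantifies amplitude-modulation complexity.
#'
#' @inheritParams approximate_entropy
#' @return scalar, nats, in `[0, log(length(x))]`.
#' @export
envelope_entropy <- function(x, cfg = entropy_config()) {
  if (length(x) < 8) stop("signal too short for envelope estimation")
  a <- Mod(analytic_signal(x))
  s <- sum(a)
  if (s == 0) stop("all-zero signal has no envelope")
  p <- a / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Singular spectrum entropy
#'
#' Shannon entropy of the normalized singular values of the signal's
#' lagged (Hankel) trajectory matrix with window length L =
#' `cfg$sse_window` (capped at 2N/3): p_i = sigma_i / sum(sigma),
#' H = -sum p_i log p_i. With `sse_weight = "sigma_sq"` the squared
#' singular values (component variances) are normalized instead.
#'
#' @inheritParams approximate_entropy
#' @return scalar, nats.
#' @export
singular_spectrum_entropy <- function(x, cfg = entropy_config()) {
  n <- length(x)
  L <- min(cfg$sse_window, floor(2 * n / 3))
  if (L < 2) stop("segment too short for singular spectrum analysis")
  K <- n - L + 1
  X <- matrix(x[outer(seq_len(L), seq_len(K) - 1L, `+`)], L, K)
  # singular values via the smaller Gram matrix's eigenvalues
  G <- if (K <= L) crossprod(X) else tcrossprod(X)
  s <- sqrt(pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0))
  if (cfg$sse_weight == "sigma_sq") s <- s^2
  tot <- sum(s)
  if (tot == 0) return(structure(0, degenerate = TRUE))
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Log-energy entropy
#'
#' E = sum_j log(x_j^2 + eps), with eps the smallest positive normal
#' double guarding zero samples. Natural log by default. Note this
#' quantity is not scale-invariant: scaling x by k adds
#' N * log(k^2).
#'
#' @inheritParams approximate_entropy
#' @param base logarithm base (default natural).
#' @return scalar (log-energy units).
#' @export
log_energy_entropy <- function(x, cfg = entropy_config(), base = exp(1)) {
  eps <- .Machine$double.xmin
  sum(log(x^2 + eps, base = base))
}

#' The seven entropy metrics of the pipeline, in canonical order
#' @return character vector of metric names.
#' @export
entropy_metrics <- function() {
  c("singular_spectrum", "approximate", "sample", "fuzzy",
    "permutation", "envelope", "log_energy")
}

# Requested estimators on one segment, sharing one kernel call for the
# three template entropies; returns named numeric.
channel_metrics <- function(x, cfg, metrics = entropy_metrics()) {
  out <- setNames(rep(NA_real_, length(metrics)), metrics)
  tmpl <- intersect(metrics, c("approximate", "sample", "fuzzy"))
  if (length(tmpl)) {
    if (sd(x) == 0) {
      out[tmpl] <- 0
    } else {
      te <- .template_entropies_cpp(as.numeric(x), cfg$m_embed,
                                    tolerance_r(x, cfg), cfg$fuzzy_power)
      if ("approximate" %in% tmpl) out["approximate"] <- te[1]
      if ("sample" %in% tmpl)
        out["sample"] <- if (te[2] == 0 || te[3] == 0) NA_real_ else
          -log(te[2] / te[3])
      if ("fuzzy" %in% tmpl) out["fuzzy"] <- te[4]
    }
  }
  for (m in setdiff(metrics, tmpl))
    out[m] <- as.numeric(switch(m,
      singular_spectrum = singular_spectrum_entropy(x, cfg),
      permutation = permutation_entropy(x, cfg),
      envelope = envelope_entropy(x, cfg),
      log_energy = log_energy_entropy(x, cfg),
      stop("unknown metric: ", m)))
  out
}

channel_entropies <- function(x, cfg) channel_metrics(x, cfg)
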