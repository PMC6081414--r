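# Shared fixtures: small configurations and independent oracles.

# A small, fast cohort configuration used by unit tests (the defaults are
# the full study conditions; tests shrink n, not the signal structure).
small_config <- function(n = 20L, seed = 1L, ...) {
  make_sim_config(n_patients = n, n_controls = n, seed = seed, ...)
}

# Two well-separated Gaussian blobs in 2D: a linearly separable toy set.
toy_separable <- function(n_per_class = 20L, gap = 6, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, mean = gap / 2), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = -gap / 2), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

# Brute-force oracle for the wrapped phase-difference variance: explicit
# loop, atan2-based wrapping, textbook two-pass variance. Kept independent
# of the package's vectorised path.
brute_force_phase_variance <- function(dphi, trim = 0.05) {
  wrapped <- numeric(length(dphi))
  for (t in seq_along(dphi)) wrapped[t] <- atan2(sin(dphi[t]), cos(dphi[t]))
  k <- ceiling(trim * length(wrapped))
  if (k > 0) wrapped <- wrapped[(k + 1):(length(wrapped) - k)]
  m <- 0
  for (t in seq_along(wrapped)) m <- m + wrapped[t]
  m <- m / length(wrapped)
  ss <- 0
  for (t in seq_along(wrapped)) ss <- ss + (wrapped[t] - m)^2
  ss / (length(wrapped) - 1)
}

# Normalised Mann-Whitney U: independent AUC oracle (ties count 1/2).
mann_whitney_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
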