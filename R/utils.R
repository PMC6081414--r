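# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Canonical row-major upper-triangle pair index over 1..n (i < j).
pair_index <- function(n) {
  if (n < 2L) stop("need at least 2 components to form pairs", call. = FALSE)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

pair_labels <- function(labels) {
  idx <- pair_index(length(labels))
  paste(labels[idx[, "i"]], labels[idx[, "j"]], sep = "-")
}

# Default component labels: the ten canonical resting-state networks when
# n = 10, generic ICN<i> otherwise.
default_icn_labels <- function(n) {
  canon <- c("MVN", "OVN", "LVN", "DMN", "CBN", "SMN", "AN", "ECN",
             "RFPN", "LFPN")
  if (n == 10L) canon else paste0("ICN", seq_len(n))
}
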