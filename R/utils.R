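# Internal helpers shared across modules.

#' Derive a deterministic substream seed from a master seed and a counter
#'
#' All stochastic stages of the pipeline consume one user-facing integer seed
#' and derive per-unit (per-spot, per-stage) substream seeds from it, so that
#' subsets of the work are reproducible independently of execution order.
#' The mixing is a fixed linear-congruential step kept below 2^31 so the
#' result is always a valid `set.seed()` argument.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer identifying the substream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  # doubles are exact below 2^53; the products stay well under that
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  s <- (abs(seed) %% m)
  s <- (s * 48271) %% m
  s <- (s + (counter %% m) * 69621) %% m
  as.integer(s)
}

# One positive scalar check with a readable error.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic 31-bit polynomial rolling hash of a character vector; used to
# stamp outputs with a configuration fingerprint without a digest dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

# Gauss-Legendre nodes/weights on (0, 1) via the Golub-Welsch eigenproblem.
gauss_legendre_01 <- function(k) {
  j <- seq_len(k - 1)
  b <- j / sqrt(4 * j^2 - 1)
  E <- diag(0, k)
  E[cbind(j, j + 1L)] <- b
  E[cbind(j + 1L, j)] <- b
  ev <- eigen(E, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = (ev$values[ord] + 1) / 2, w = ev$vectors[1, ord]^2)
}
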