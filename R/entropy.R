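#' Shannon entropy of a discrete distribution
#'
#' Computes \eqn{H(p) = -\sum_{p_i > 0} p_i \log p_i} in nats (natural
#' logarithm). Entries of exactly zero contribute nothing, following the
#' standard convention \eqn{0 \log 0 := 0}.
#'
#' @param p Numeric vector of probabilities. Must be non-negative and sum to
#'   one within `tol`.
#' @param zero_tol Entries at or below this threshold are treated as exact
#'   zeros. Guards against log-underflow on solver-noise-scale values.
#' @param tol Tolerance for the sum-to-one check.
#' @return Entropy in nats (a single non-negative number).
#' @examples
#' shannon_entropy(rep(0.25, 4))      # log(4)
#' shannon_entropy(c(0.5, 0.25, 0.25))
#' @export
shannon_entropy <- function(p, zero_tol = 1e-12, tol = 1e-6) {
  check_prob_vector(p, tol = tol, what = "p")
  p <- p[p > zero_tol]
  -sum(p * log(p))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' Computes \eqn{D_{KL}(p \| q) = \sum_{p_i > 0} p_i \log(p_i / q_i)} in
#' nats. `p` must be absolutely continuous with respect to `q`: wherever
#' `p[i] > 0`, `q[i]` must be positive too. A violation raises a structured
#' condition of class `entred_support_violation` rather than returning
#' `Inf`, so callers can record the pair as missing instead of propagating
#' an infinity.
#'
#' @param p,q Numeric probability vectors of equal length, each summing to
#'   one within `tol`.
#' @inheritParams shannon_entropy
#' @return Divergence in nats (non-negative).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
kl_divergence <- function(p, q, zero_tol = 1e-12, tol = 1e-6) {
  check_prob_vector(p, tol = tol, what = "p")
  check_prob_vector(q, tol = tol, what = "q")
  if (length(p) != length(q)) {
    stop("'p' and 'q' must have equal length (", length(p), " vs ",
         length(q), ")", call. = FALSE)
  }
  pos <- p > zero_tol
  if (any(q[pos] <= zero_tol)) {
    stop(support_violation_condition(which(pos & q <= zero_tol)))
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

# Structured condition so pipelines can distinguish a support violation
# (a data problem worth recording) from programming errors.
support_violation_condition <- function(idx) {
  structure(
    class = c("entred_support_violation", "error", "condition"),
    list(
      message = paste0(
        "support violation: p > 0 where q = 0 at position(s) ",
        paste(idx, collapse = ", ")),
      call = NULL, index = idx)
  )
}

check_prob_vector <- function(p, tol = 1e-6, what = "p") {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("'", what, "' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p)) {
    stop("'", what, "' contains NA", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("'", what, "' contains negative entries", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop("'", what, "' must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  invisible(TRUE)
}
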