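#' Draw a synthetic community from symmetric Dirichlet distributions
#'
#' Draws a vector of functional shares and a vector of relative abundances
#' for `n` species, each from a symmetric Dirichlet with concentration
#' `alpha` (via normalised gamma variates). `alpha = 1` produces uneven,
#' `alpha = 5` more even simplex points. Shares and abundances are drawn
#' independently — the weakest dependence structure consistent with a
#' generic synthetic community; see the methods vignette.
#'
#' @param n Number of species (>= 2).
#' @param alpha Dirichlet concentration parameter (> 0), common to all
#'   species.
#' @return A list with numeric vectors `shares` and `abundance`, each of
#'   length `n` and summing to 1.
#' @export
draw_community <- function(n, alpha) {
  stopifnot(n >= 2, alpha > 0)
  list(shares = rdirichlet_sym(n, alpha),
       abundance = rdirichlet_sym(n, alpha))
}

rdirichlet_sym <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  g / sum(g)
}

#' Reclassify species as unknown and renormalise
#'
#' Removes the species at positions `unknown_idx` from both the shares and
#' the abundance vector — modelling unclassified species whose functional
#' contribution is unknown — and renormalises the remaining entries to sum
#' to one. If the removal empties the support of the shares vector the
#' result is flagged missing.
#'
#' @param shares,abundance Simplex vectors of equal length.
#' @param unknown_idx Integer positions of the species reclassified as
#'   unknown (possibly empty).
#' @return A list with `shares`, `abundance` (renormalised, shortened) and
#'   `missing` (`TRUE` when no share mass remains).
#' @export
reclassify_unknown <- function(shares, abundance, unknown_idx) {
  stopifnot(length(shares) == length(abundance))
  if (length(unknown_idx) == 0L) {
    return(list(shares = shares, abundance = abundance, missing = FALSE))
  }
  stopifnot(all(unknown_idx >= 1L), all(unknown_idx <= length(shares)),
            length(unknown_idx) < length(shares))
  f <- shares[-unknown_idx]
  a <- abundance[-unknown_idx]
  if (sum(f) <= 0 || sum(a) <= 0) {
    return(list(shares = f, abundance = a, missing = TRUE))
  }
  list(shares = f / sum(f), abundance = a / sum(a), missing = FALSE)
}

#' Unclassified-species simulation
#'
#' Monte-Carlo experiment quantifying how unclassified species distort the
#' three redundancy measures. Per iteration: a concentration parameter is
#' drawn from `alpha_options` (coin flip under the default probabilities),
#' a community of `n_species` shares and abundances is drawn via
#' [draw_community()], and species are removed cumulatively in steps of
#' `unknown_step` up to `max_unknown`, in a uniformly random order. After
#' each step the sample and abundance measures are recomputed on the
#' renormalised, shortened vectors, and the reference measure is recomputed
#' with `m` held fixed at `n_species` (the unknown species still belong to
#' the reference — this is what drives its systematic underestimation).
#' Bias is observed minus true (full-information) value.
#'
#' @param n_species Community size (default 100).
#' @param n_iterations Number of Monte-Carlo iterations (default 1000).
#' @param alpha_options Candidate Dirichlet concentrations (default
#'   `c(1, 5)`).
#' @param alpha_probability Sampling probabilities for `alpha_options`
#'   (default equal).
#' @param unknown_step Species reclassified per step (default 10).
#' @param max_unknown Total species reclassified at the final step
#'   (default 80); must be a multiple of `unknown_step` and below
#'   `n_species`.
#' @param seed Optional integer seed for exact replay.
#' @return A long `data.frame` of class `fr_simulation`: columns
#'   `iteration`, `alpha`, `n_unknown`, `measure` (one of `fr_sample`,
#'   `fr_reference`, `fr_abundance`), `true`, `observed`, `bias`. The seed
#'   (if any) is attached as attribute `seed`.
#' @examples
#' res <- simulate_unknown(n_species = 20, n_iterations = 5, seed = 1)
#' summarise_simulation(res)
#' @export
simulate_unknown <- function(n_species = 100L, n_iterations = 1000L,
                             alpha_options = c(1, 5),
                             alpha_probability = NULL,
                             unknown_step = 10L, max_unknown = 80L,
                             seed = NULL) {
  stopifnot(max_unknown < n_species, max_unknown %% unknown_step == 0)
  if (is.null(alpha_probability)) {
    alpha_probability <- rep(1 / length(alpha_options), length(alpha_options))
  }
  if (!is.null(seed)) set.seed(seed)
  steps <- seq(0L, max_unknown, by = unknown_step)
  measures <- c("fr_sample", "fr_reference", "fr_abundance")

  out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    alpha <- sample(alpha_options, 1L, prob = alpha_probability)
    cm <- draw_community(n_species, alpha)
    truth <- measures_on_vectors(cm$shares, cm$abundance, m = n_species)
    removal_order <- sample.int(n_species)  # cumulative across steps

    rows <- lapply(steps, function(k) {
      red <- reclassify_unknown(cm$shares, cm$abundance,
                                removal_order[seq_len(k)])
      obs <- if (red$missing) {
        c(fr_sample = NA_real_, fr_reference = NA_real_,
          fr_abundance = NA_real_)
      } else {
        measures_on_vectors(red$shares, red$abundance, m = n_species)
      }
      data.frame(iteration = it, alpha = alpha, n_unknown = k,
                 measure = measures, true = unname(truth[measures]),
                 observed = unname(obs[measures]),
                 stringsAsFactors = FALSE)
    })
    out[[it]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$bias <- res$observed - res$true
  attr(res, "seed") <- seed
  class(res) <- c("fr_simulation", class(res))
  res
}

# Direct evaluation on bare simplex vectors (no species bookkeeping):
# the simulation's inner loop. m is the fixed reference size.
measures_on_vectors <- function(shares, abundance, m, zero_tol = 1e-12) {
  n <- length(shares)
  pos <- shares > zero_tol
  H <- -sum(shares[pos] * log(shares[pos]))
  c(fr_sample = H - log(n),
    fr_reference = H - log(m),
    fr_abundance = -sum(shares[pos] * log(shares[pos] / abundance[pos])))
}

#' Summarise an unclassified-species simulation
#'
#' Deterministic aggregation of [simulate_unknown()] output: per measure,
#' concentration parameter and unknown-count, the mean bias, its standard
#' deviation and Monte-Carlo standard error, quantiles, and the
#' inter-quartile spread.
#'
#' @param result An `fr_simulation` data.frame.
#' @param probs Quantile probabilities (default quartiles and 5/95 %).
#' @return A `data.frame` with one row per (measure, alpha, n_unknown).
#' @export
summarise_simulation <- function(result,
                                 probs = c(0.05, 0.25, 0.75, 0.95)) {
  stopifnot(nrow(result) > 0)
  groups <- split(result,
                  list(result$measure, result$alpha, result$n_unknown),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    b <- g$bias[!is.na(g$bias)]
    qs <- stats::quantile(b, probs = probs, names = FALSE)
    cbind(data.frame(measure = g$measure[1L], alpha = g$alpha[1L],
                     n_unknown = g$n_unknown[1L], n = length(b),
                     mean_bias = mean(b), sd_bias = stats::sd(b),
                     se_bias = stats::sd(b) / sqrt(length(b)),
                     iqr = unname(diff(stats::quantile(b, c(0.25, 0.75)))),
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(qs)),
                          paste0("q", probs * 100)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$measure, out$alpha, out$n_unknown), , drop = FALSE]
  rownames(out) <- NULL
  out
}
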