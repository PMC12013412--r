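#' Single-trait functional redundancy and interdependency measures
#'
#' @description
#' Four relative-entropy measures of how a function is spread over the
#' species of a microbial community, all in nats (natural logarithm):
#'
#' * `fr_sample()` — *sample taxon-based* functional redundancy,
#'   \eqn{H(\tilde f) - \log n = -D_{KL}(\tilde f \| U_n)}: the negative KL
#'   divergence between the functional shares \eqn{\tilde f_i = f_i /
#'   f_{total}} and the uniform distribution over the `n` species of the
#'   sample. Ranges over \eqn{[-\log n, 0]}; 0 iff every species
#'   contributes equally, \eqn{-\log n} iff a single species carries the
#'   whole function.
#' * `fr_reference()` — *reference taxon-based* redundancy: the same
#'   construction against the uniform distribution over the `m` species of
#'   a fixed external reference, making values comparable across samples
#'   of different richness. Ranges over \eqn{[-\log m, 0]}.
#' * `fr_abundance()` — *abundance-based* redundancy,
#'   \eqn{-D_{KL}(\tilde f \| a)}: zero iff shares mirror relative
#'   abundances exactly.
#' * `fr_interdependency()` — functional interdependency index
#'   \eqn{I = D_{KL}(\tilde f_J \| \tilde a_J)}, where `J` is the set of
#'   producers (positive shares) and \eqn{\tilde a_j = a_j / \sum_{J} a_j}
#'   the producer-renormalised abundances. Non-negative; zero iff each
#'   producer's output is proportional to its abundance (a single producer
#'   gives exactly 0). Larger values indicate that the function depends on
#'   more than the abundances of the producing species, i.e. cross-species
#'   interdependency.
#'
#' A profile whose total output is zero has no producers; each measure then
#' returns `NA_real_` (use [fr_measures()] to obtain the recorded reason).
#'
#' @param profile An [functional_profile()] aligned to the community (same
#'   species set; order may differ, matching is by identifier).
#' @param community An [community()] object.
#' @param reference An [function_reference()] for the profile's function.
#' @param zero_tol Shares/fluxes at or below this threshold count as zero
#'   (solver-noise guard; the index sets in the formulas run over strictly
#'   positive shares only).
#' @return A single numeric value in nats, or `NA_real_` if there are no
#'   producers.
#' @examples
#' com <- community(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
#' prof <- functional_profile(c(a = 2, b = 1, c = 1, d = 0), function_id = "F")
#' fr_sample(prof, com)        # H(0.5, 0.25, 0.25) - log 4
#' fr_abundance(prof, com)
#' fr_interdependency(prof, com)
#' @name fr_measures_single
NULL

#' @rdname fr_measures_single
#' @export
fr_sample <- function(profile, community, zero_tol = 1e-12) {
  f <- align_profile(profile, community)
  sh <- shares(f, zero_tol)
  if (is.null(sh)) return(NA_real_)
  -sum(sh * log(sh)) - log(length(f))
}

#' @rdname fr_measures_single
#' @export
fr_reference <- function(profile, reference, zero_tol = 1e-12) {
  stopifnot(inherits(profile, "fr_profile"), inherits(reference, "fr_reference"))
  producers <- profile$species[profile$contribution > zero_tol]
  outside <- setdiff(producers, reference$species)
  if (length(outside)) {
    stop("producer(s) not in the function reference for '",
         reference$function_id, "': ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  sh <- shares(profile$contribution, zero_tol)
  if (is.null(sh)) return(NA_real_)
  # species in the reference but absent from the sample hold zero shares
  # and drop out of the entropy sum; only log(m) changes vs fr_sample
  -sum(sh * log(sh)) - log(reference$m)
}

#' @rdname fr_measures_single
#' @export
fr_abundance <- function(profile, community, zero_tol = 1e-12) {
  f <- align_profile(profile, community)
  sh <- shares(f, zero_tol, keep_zero = TRUE)
  if (is.null(sh)) return(NA_real_)
  pos <- sh > zero_tol
  a <- community$abundance
  -sum(sh[pos] * log(sh[pos] / a[pos]))
}

#' @rdname fr_measures_single
#' @export
fr_interdependency <- function(profile, community, zero_tol = 1e-12) {
  f <- align_profile(profile, community)
  sh <- shares(f, zero_tol, keep_zero = TRUE)
  if (is.null(sh)) return(NA_real_)
  J <- sh > zero_tol
  a_J <- community$abundance[J]
  a_J <- a_J / sum(a_J)
  f_J <- sh[J] / sum(sh[J])  # re-close after clipping sub-threshold shares
  sum(f_J * log(f_J / a_J))
}

# shares: f / sum(f), with sub-threshold entries clipped to zero.
# Returns NULL when there are no producers.
shares <- function(f, zero_tol, keep_zero = FALSE) {
  f[f <= zero_tol] <- 0
  total <- sum(f)
  if (total <= zero_tol) return(NULL)
  sh <- f / total
  if (keep_zero) sh else sh[sh > 0]
}

#' Global functional interdependency index
#'
#' The median of the per-function interdependency indices of one sample,
#' summarising functional interdependency at community level. The median is
#' chosen for robustness against outliers and skew; even-length inputs use
#' the mean of the two central values (standard convention).
#'
#' @param indices Numeric vector of interdependency indices; `NA` entries
#'   (missing sample-function pairs) are dropped.
#' @param min_count Minimum number of non-missing indices required; fewer
#'   yields `NA_real_`.
#' @return The median index, or `NA_real_`.
#' @export
fr_global_interdependency <- function(indices, min_count = 1L) {
  indices <- indices[!is.na(indices)]
  if (length(indices) < min_count) return(NA_real_)
  stats::median(indices)
}

#' Compute all redundancy measures for one sample-function pair
#'
#' Evaluates the three functional redundancy measures and the
#' interdependency index together with their provenance: community size
#' `n`, reference size `m`, producer count `k`, the summed abundance of the
#' producers and a missingness reason. Biologically expected degeneracies
#' (no producers, a recorded uptake) yield `NA` measures with a reason,
#' never an error; structural inconsistencies (misaligned species, a
#' producer outside the reference) do error.
#'
#' @inheritParams fr_measures_single
#' @param status Pair status from [pair_missingness()]; `"uptake_detected"`
#'   forces all measures missing per the missingness rules.
#' @return A one-row `data.frame` with columns `function_id`, `sample_id`,
#'   `n`, `m`, `k`, `producer_abundance_sum`, `fr_sample`, `fr_reference`,
#'   `fr_abundance`, `interdependency`, `missing_reason`.
#' @examples
#' com <- community(rep(1 / 4, 4), paste0("s", 1:4))
#' prof <- functional_profile(c(1, 1, 1, 1), paste0("s", 1:4), "F")
#' ref <- function_reference("F", paste0("s", 1:7))
#' fr_measures(prof, com, ref)
#' @export
fr_measures <- function(profile, community, reference = NULL,
                        zero_tol = 1e-12, status = c("ok", "uptake_detected")) {
  status <- match.arg(status)
  f <- align_profile(profile, community)
  n <- length(community$species)
  m <- if (is.null(reference)) NA_integer_ else reference$m
  sh <- shares(f, zero_tol, keep_zero = TRUE)

  if (status == "uptake_detected" || is.null(sh)) {
    reason <- if (status == "uptake_detected") "uptake_detected" else "no_producers"
    return(result_row(profile$function_id, community$sample_id, n, m,
                      k = 0L, prod_ab = 0,
                      fs = NA_real_, fref = NA_real_, fa = NA_real_,
                      inter = NA_real_, reason = reason))
  }

  k <- sum(sh > zero_tol)
  prod_ab <- sum(community$abundance[sh > zero_tol])
  fref <- if (is.null(reference)) NA_real_ else
    tryCatch(fr_reference(profile, reference, zero_tol),
             entred_support_violation = function(e) NA_real_)
  result_row(profile$function_id, community$sample_id, n, m, k, prod_ab,
             fs = fr_sample(profile, community, zero_tol),
             fref = fref,
             fa = fr_abundance(profile, community, zero_tol),
             inter = fr_interdependency(profile, community, zero_tol),
             reason = "none")
}

result_row <- function(function_id, sample_id, n, m, k, prod_ab,
                       fs, fref, fa, inter, reason) {
  data.frame(function_id = function_id, sample_id = sample_id,
             n = as.integer(n), m = as.integer(m), k = as.integer(k),
             producer_abundance_sum = prod_ab,
             fr_sample = fs, fr_reference = fref, fr_abundance = fa,
             interdependency = inter, missing_reason = reason,
             stringsAsFactors = FALSE)
}
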