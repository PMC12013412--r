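#' Classical alpha-diversity indices
#'
#' @description
#' The diversity indices used alongside the redundancy measures:
#'
#' * `richness()` — number of species with positive abundance.
#' * `shannon_diversity()` — Shannon entropy `H(a)` of the abundance
#'   vector, in nats.
#' * `simpson_diversity()` — Simpson's diversity
#'   \eqn{D = 1 - \sum a_i^2}, in `[0, 1)`.
#' * `evenness()` — Pielou's evenness `H(a) / log(richness)`; undefined
#'   (`NA`) for a single-species community.
#'
#' Indices are computed from the community's abundances as given; any
#' restriction to a reference universe and renormalisation happens upstream
#' in [build_communities()].
#'
#' @param community An [community()] object.
#' @return A single number (see each index); `evenness()` returns
#'   `NA_real_` at richness 1.
#' @examples
#' com <- community(c(a = 0.5, b = 0.25, c = 0.25))
#' richness(com)
#' shannon_diversity(com)
#' simpson_diversity(com)
#' evenness(com)
#' @name diversity_indices
NULL

#' @rdname diversity_indices
#' @export
richness <- function(community) {
  stopifnot(inherits(community, "fr_community"))
  sum(community$abundance > 0)
}

#' @rdname diversity_indices
#' @export
shannon_diversity <- function(community) {
  stopifnot(inherits(community, "fr_community"))
  shannon_entropy(community$abundance)
}

#' @rdname diversity_indices
#' @export
simpson_diversity <- function(community) {
  stopifnot(inherits(community, "fr_community"))
  1 - sum(community$abundance^2)
}

#' @rdname diversity_indices
#' @export
evenness <- function(community) {
  r <- richness(community)
  if (r < 2L) return(NA_real_)
  shannon_diversity(community) / log(r)
}
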