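#' Gower trait dissimilarity between species
#'
#' Builds the species-by-species dissimilarity matrix
#' \eqn{d = \sqrt{1 - s}}, where `s` is Gower's general similarity
#' coefficient with equal trait weights. Quantitative traits are
#' range-normalised (`1 - |x_i - x_j| / range`); binary traits are treated
#' symmetrically (similarity 1 when both species agree, whether both carry
#' the trait or both lack it). A quantitative trait with zero range carries
#' no information and is dropped with a warning.
#'
#' @param traits Species-by-trait matrix or data.frame with species
#'   identifiers as row names. Values must be numeric; binary traits are
#'   coded 0/1.
#' @param kinds Character vector, one of `"binary"` or `"quantitative"` per
#'   trait column. If `NULL`, columns whose values all lie in `{0, 1}` are
#'   taken as binary, others as quantitative.
#' @return A symmetric numeric matrix with entries in `[0, 1]`, zero
#'   diagonal, and species identifiers as dimnames.
#' @examples
#' tr <- matrix(c(1, 0, 0, 0), ncol = 1,
#'              dimnames = list(paste0("s", 1:4), "producer"))
#' gower_dissimilarity(tr)
#' @export
gower_dissimilarity <- function(traits, kinds = NULL) {
  x <- as.matrix(traits)
  if (!is.numeric(x)) stop("trait values must be numeric", call. = FALSE)
  if (is.null(rownames(x))) {
    stop("trait matrix needs species identifiers as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated species in trait matrix", call. = FALSE)
  }
  if (ncol(x) < 1L) stop("at least one trait required", call. = FALSE)
  if (is.null(kinds)) {
    kinds <- ifelse(apply(x, 2, function(v) all(v %in% c(0, 1))),
                    "binary", "quantitative")
  }
  kinds <- match.arg(kinds, c("binary", "quantitative"), several.ok = TRUE)
  if (length(kinds) != ncol(x)) {
    stop("'kinds' must name one kind per trait column", call. = FALSE)
  }

  keep <- rep(TRUE, ncol(x))
  for (j in seq_len(ncol(x))) {
    if (kinds[j] == "quantitative") {
      rng <- diff(range(x[, j]))
      if (rng == 0) {
        warning("dropping constant quantitative trait '",
                colnames(x)[j] %||% j, "' (zero range)", call. = FALSE)
        keep[j] <- FALSE
      } else {
        x[, j] <- x[, j] / rng  # range-normalise; |xi - xj| is then in [0,1]
      }
    }
  }
  x <- x[, keep, drop = FALSE]
  kinds <- kinds[keep]
  if (ncol(x) == 0L) {
    stop("no informative traits left after dropping constant ones",
         call. = FALSE)
  }

  n <- nrow(x)
  s <- matrix(0, n, n)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    s_j <- if (kinds[j] == "binary") {
      outer(v, v, function(a, b) as.numeric(a == b))
    } else {
      1 - abs(outer(v, v, "-"))
    }
    s <- s + s_j
  }
  s <- s / ncol(x)
  d <- sqrt(pmax(1 - s, 0))  # pmax keeps the first argument's dim
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Rao's quadratic entropy
#'
#' \eqn{Q = \sum_i \sum_j d_{ij} a_i a_j}: the abundance-weighted expected
#' trait dissimilarity between two randomly drawn individuals. When all
#' between-species dissimilarities equal one, `Q` is maximal and equals
#' Simpson's diversity `D`.
#'
#' @param community An [community()] object.
#' @param d Symmetric dissimilarity matrix with zero diagonal and entries
#'   in `[0, 1]`, with dimnames covering the community's species (e.g. from
#'   [gower_dissimilarity()]).
#' @return Rao's Q, a number in `[0, 1)`.
#' @export
rao_q <- function(community, d) {
  stopifnot(inherits(community, "fr_community"))
  d <- check_dissimilarity(d, community$species)
  a <- community$abundance
  as.numeric(t(a) %*% d %*% a)
}

#' Community-level functional redundancy (Simpson minus Rao)
#'
#' The multi-trait, community-level functional redundancy
#' \eqn{FR = D - Q = 1 - \sum_i a_i^2 - \sum_i \sum_j d_{ij} a_i a_j},
#' i.e. the part of taxonomic alpha diversity not explained by functional
#' alpha diversity. Always in `[0, 1]`: 0 for a single species (or
#' maximally dissimilar traits, where `Q = D`), approaching 1 for large
#' even communities of functionally identical species. Provided as a
#' contrast: it is neither mathematically nor conceptually a special case
#' of the single-trait relative-entropy measures (see
#' [keystone_series()]).
#'
#' @inheritParams rao_q
#' @return FR in `[0, 1]`.
#' @export
community_fr <- function(community, d) {
  simpson_diversity(community) - rao_q(community, d)
}

check_dissimilarity <- function(d, species) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("'d' must be square", call. = FALSE)
  if (!is.null(rownames(d))) {
    if (!all(species %in% rownames(d))) {
      stop("dissimilarity matrix does not cover all community species",
           call. = FALSE)
    }
    d <- d[species, species, drop = FALSE]
  } else if (nrow(d) != length(species)) {
    stop("unnamed dissimilarity matrix has wrong dimension", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    stop("'d' must be symmetric with zero diagonal", call. = FALSE)
  }
  if (any(d < 0) || any(d > 1)) {
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  }
  d
}

#' Keystone scenario: one producer among increasingly rich communities
#'
#' Builds, for each richness `n = 1..n_max`, a community with uniform
#' abundances in which a single species carries the whole function
#' (shares `(1, 0, ..., 0)`), and evaluates the three single-trait
#' redundancy measures plus the community-level `FR` of [community_fr()]
#' with a single binary producer/non-producer trait (dissimilarity 1
#' between producer and non-producers, 0 otherwise).
#'
#' This is the discriminating scenario between the two frameworks: losing
#' the one producer loses the function entirely, so single-trait
#' redundancy is minimal — the reference measure is constant at `-log(m)`
#' and the sample/abundance measures fall to `-log(n)` — while the
#' community-level `FR` rises monotonically towards 1 with richness.
#'
#' @param n_max Largest community richness (default 100).
#' @param m Reference size, `>= n_max` (default 100).
#' @return A `data.frame` with columns `n`, `fr_sample`, `fr_reference`,
#'   `fr_abundance`, `community_fr`.
#' @examples
#' ks <- keystone_series(10, m = 100)
#' ks$fr_reference          # constant -log(100)
#' @export
keystone_series <- function(n_max = 100L, m = 100L) {
  stopifnot(n_max >= 1L, m >= n_max)
  ref <- function_reference("keystone", paste0("sp", seq_len(m)))
  rows <- lapply(seq_len(n_max), function(n) {
    ids <- paste0("sp", seq_len(n))
    com <- community(rep(1 / n, n), ids, sample_id = paste0("n", n))
    prof <- functional_profile(c(1, rep(0, n - 1)), ids, "keystone")
    traits <- matrix(c(1, rep(0, n - 1)), ncol = 1,
                     dimnames = list(ids, "producer"))
    d <- if (n == 1L) {
      matrix(0, 1, 1, dimnames = list(ids, ids))
    } else {
      gower_dissimilarity(traits, kinds = "binary")
    }
    data.frame(n = n,
               fr_sample = fr_sample(prof, com),
               fr_reference = fr_reference(prof, ref),
               fr_abundance = fr_abundance(prof, com),
               community_fr = community_fr(com, d))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
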