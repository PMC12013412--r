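#' Construct a community object
#'
#' A community holds the species present in one sample together with their
#' relative abundances. Every listed species must have strictly positive
#' abundance (a species present in the community model is present with
#' positive fraction); abundances are renormalised to sum to one unless
#' already normalised.
#'
#' @param abundances Numeric vector of positive relative abundances, named
#'   by species identifier, or unnamed with `species` supplied.
#' @param species Character vector of unique species identifiers; defaults
#'   to `names(abundances)`.
#' @param sample_id Optional sample identifier carried through to results.
#' @param normalise If `TRUE` (default) abundances are divided by their sum.
#'   If `FALSE`, a sum away from one is an error.
#' @return An object of class `fr_community`: a list with `species`,
#'   `abundance` (named, summing to 1) and `sample_id`.
#' @examples
#' community(c(s1 = 0.5, s2 = 0.3, s3 = 0.2))
#' @export
community <- function(abundances, species = names(abundances),
                      sample_id = NA_character_, normalise = TRUE) {
  if (is.null(species)) {
    stop("species identifiers required (name 'abundances' or pass 'species')",
         call. = FALSE)
  }
  species <- as.character(species)
  if (length(species) != length(abundances)) {
    stop("'species' and 'abundances' lengths differ", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("duplicated species identifiers: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(abundances) || anyNA(abundances)) {
    stop("abundances must be numeric and non-missing", call. = FALSE)
  }
  if (any(abundances <= 0)) {
    stop("all abundances must be strictly positive; drop absent species ",
         "before constructing the community", call. = FALSE)
  }
  a <- as.numeric(abundances)
  if (normalise) {
    a <- a / sum(a)
  } else if (abs(sum(a) - 1) > 1e-6) {
    stop("abundances do not sum to 1 and normalise = FALSE", call. = FALSE)
  }
  names(a) <- species
  structure(list(species = species, abundance = a,
                 sample_id = as.character(sample_id)),
            class = "fr_community")
}

#' @export
print.fr_community <- function(x, ...) {
  cat("<fr_community>", length(x$species), "species",
      if (!is.na(x$sample_id)) paste0("(sample ", x$sample_id, ")"), "\n")
  invisible(x)
}

#' Construct a functional profile
#'
#' The per-species quantitative output of one function in one sample, e.g.
#' maximal secretion fluxes in mmol/gDW/h with the "positive = secretion"
#' orientation. Contributions must be aligned to a community's species
#' order; all values must be non-negative (uptake is handled upstream by
#' [pair_missingness()]). The total output may be zero, in which case all
#' downstream measures are missing with reason `"no_producers"`.
#'
#' @param contributions Non-negative numeric vector, named by species or
#'   with `species` supplied.
#' @param species Character vector of species identifiers.
#' @param function_id Identifier of the function (e.g. a metabolite).
#' @param gamma Optional theoretical maximum of the function. Stored for
#'   completeness; not used by any measure.
#' @return An object of class `fr_profile`.
#' @export
functional_profile <- function(contributions, species = names(contributions),
                               function_id = NA_character_, gamma = NULL) {
  if (is.null(species)) {
    stop("species identifiers required", call. = FALSE)
  }
  species <- as.character(species)
  if (length(species) != length(contributions)) {
    stop("'species' and 'contributions' lengths differ", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("duplicated species identifiers in profile", call. = FALSE)
  }
  if (!is.numeric(contributions) || anyNA(contributions)) {
    stop("contributions must be numeric and non-missing", call. = FALSE)
  }
  if (any(contributions < 0)) {
    stop("negative contribution found; apply the secretion sign convention ",
         "and uptake screening (pair_missingness) before building profiles",
         call. = FALSE)
  }
  f <- as.numeric(contributions)
  names(f) <- species
  structure(list(species = species, contribution = f,
                 function_id = as.character(function_id), gamma = gamma),
            class = "fr_profile")
}

#' @export
print.fr_profile <- function(x, ...) {
  k <- sum(x$contribution > 0)
  cat("<fr_profile>", x$function_id, "-", length(x$species), "species,",
      k, "producer(s), total", format(sum(x$contribution)), "\n")
  invisible(x)
}

#' Construct a function reference
#'
#' The reference set for one function: all `m` species that can perform the
#' function in theory (e.g. all producers of a metabolite across a
#' reconstruction resource). `m` is fixed per function across all samples,
#' which makes the reference taxon-based redundancy comparable across
#' communities of different richness.
#'
#' @param function_id Function identifier.
#' @param species Character vector (set) of capable species, size >= 1.
#' @return An object of class `fr_reference` with elements `function_id`,
#'   `species` and `m`.
#' @export
function_reference <- function(function_id, species) {
  species <- unique(as.character(species))
  if (length(species) < 1L) {
    stop("a function reference needs at least one capable species",
         call. = FALSE)
  }
  structure(list(function_id = as.character(function_id), species = species,
                 m = length(species)),
            class = "fr_reference")
}

#' @export
print.fr_reference <- function(x, ...) {
  cat("<fr_reference>", x$function_id, "- m =", x$m, "capable species\n")
  invisible(x)
}

# Align a profile to a community: same species set, community order.
# Errors on any mismatch rather than silently reordering away a typo.
align_profile <- function(profile, community) {
  stopifnot(inherits(profile, "fr_profile"),
            inherits(community, "fr_community"))
  if (!setequal(profile$species, community$species)) {
    missing_in_p <- setdiff(community$species, profile$species)
    extra_in_p <- setdiff(profile$species, community$species)
    stop("profile and community species sets differ",
         if (length(missing_in_p))
           paste0("; absent from profile: ",
                  paste(utils::head(missing_in_p, 5), collapse = ", ")),
         if (length(extra_in_p))
           paste0("; not in community: ",
                  paste(utils::head(extra_in_p, 5), collapse = ", ")),
         call. = FALSE)
  }
  profile$contribution[community$species]
}
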