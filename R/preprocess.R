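#' Build communities from a raw abundance table
#'
#' Converts a long-form abundance table into one [community()] per sample,
#' optionally restricting to a reference universe of species first (e.g.
#' the species with a metabolic reconstruction): species outside the
#' universe and species with zero abundance are dropped, and the remaining
#' abundances are renormalised to sum to one. A sample whose abundance
#' vanishes entirely after restriction is excluded with a recorded reason.
#' The operation is idempotent: re-running it on its own output changes
#' nothing.
#'
#' @param abundances A `data.frame` with columns `sample_id`, `species_id`,
#'   `abundance` (see [read_abundance_table()] for file formats).
#' @param universe Optional character vector of admissible species
#'   identifiers; `NULL` keeps all.
#' @return A list with `communities` (named list of `fr_community`) and
#'   `excluded` (`data.frame` of excluded samples with reasons).
#' @export
build_communities <- function(abundances, universe = NULL) {
  need <- c("sample_id", "species_id", "abundance")
  if (!all(need %in% names(abundances))) {
    stop("abundance table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(abundances$abundance < 0)) {
    stop("negative abundance found", call. = FALSE)
  }
  key <- paste(abundances$sample_id, abundances$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- abundances[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (sample, species) key: (", dup$sample_id, ", ",
         dup$species_id, ")", call. = FALSE)
  }

  communities <- list()
  excluded <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (s in unique(abundances$sample_id)) {
    sub <- abundances[abundances$sample_id == s, , drop = FALSE]
    if (!is.null(universe)) {
      sub <- sub[sub$species_id %in% universe, , drop = FALSE]
    }
    sub <- sub[sub$abundance > 0, , drop = FALSE]
    if (nrow(sub) == 0L) {
      excluded <- rbind(excluded, data.frame(
        sample_id = s, reason = "no_species_in_universe",
        stringsAsFactors = FALSE))
      next
    }
    communities[[s]] <- community(sub$abundance, sub$species_id,
                                  sample_id = s)
  }
  list(communities = communities, excluded = excluded)
}

#' Sample inclusion filter by species richness
#'
#' Flags samples whose community model contains fewer than `min_species`
#' species ("fewer than" is strict: richness 25 is retained under the
#' default).
#'
#' @param communities Named list of [community()] objects.
#' @param min_species Minimum richness to retain a sample (default 25).
#' @return A list with `retained` (named list of communities) and `report`
#'   (`data.frame` of sample_id, richness, retained flag).
#' @export
apply_sample_filter <- function(communities, min_species = 25L) {
  if (length(communities) == 0L) {
    return(list(retained = communities,
                report = data.frame(sample_id = character(),
                                    richness = integer(),
                                    retained = logical(),
                                    stringsAsFactors = FALSE)))
  }
  rich <- vapply(communities, richness, integer(1))
  keep <- rich >= min_species
  list(retained = communities[keep],
       report = data.frame(sample_id = names(communities),
                           richness = unname(rich),
                           retained = unname(keep),
                           stringsAsFactors = FALSE))
}

#' Per-pair missingness status from raw fluxes
#'
#' Applies the missingness rules to a flux table (sign convention
#' "positive = secretion" already applied): a sample-function pair is
#' missing with reason `uptake_detected` when at least one microbe takes up
#' the metabolite (flux below `-tolerance`), and with reason `no_producers`
#' when no microbe secretes it (all fluxes at or below `tolerance`).
#' Otherwise the pair is `ok`; negative values within the tolerance are
#' solver noise and are clipped to zero downstream.
#'
#' @param flux A `data.frame` with columns `sample_id`, `species_id`,
#'   `function_id`, `flux`. Absent records count as zero contribution.
#' @param tolerance Magnitude below which a negative flux is treated as
#'   numerical noise rather than genuine uptake (default `1e-9`).
#' @return A `data.frame` with one row per (sample_id, function_id) pair
#'   and a `status` column in `{"ok", "uptake_detected", "no_producers"}`.
#' @export
pair_missingness <- function(flux, tolerance = 1e-9) {
  need <- c("sample_id", "species_id", "function_id", "flux")
  if (!all(need %in% names(flux))) {
    stop("flux table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(flux$sample_id, flux$species_id, flux$function_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- flux[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (sample, species, function) key: (", dup$sample_id,
         ", ", dup$species_id, ", ", dup$function_id, ")", call. = FALSE)
  }
  pair <- interaction(flux$sample_id, flux$function_id, drop = TRUE)
  status <- vapply(split(flux$flux, pair), function(v) {
    if (any(v < -tolerance)) "uptake_detected"
    else if (all(v <= tolerance)) "no_producers"
    else "ok"
  }, character(1))
  idx <- !duplicated(pair)
  out <- data.frame(sample_id = flux$sample_id[idx],
                    function_id = flux$function_id[idx],
                    status = status[as.character(pair[idx])],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Function inclusion filter by non-missing fraction
#'
#' Retains only functions with strictly more than `min_nonmissing`
#' non-missing sample-function pairs across the retained samples ("over
#' 80 %" read strictly: exactly 80 % is excluded under the default).
#'
#' @param statuses A `data.frame` as returned by [pair_missingness()],
#'   computed on retained samples only. Samples without a record for a
#'   function count as missing for that function when `all_samples` is
#'   given.
#' @param min_nonmissing Required non-missing fraction, strict (default
#'   0.8).
#' @param all_samples Optional character vector of all retained sample
#'   identifiers; defaults to the samples present in `statuses`.
#' @return A `data.frame` with columns `function_id`,
#'   `nonmissing_fraction`, `retained`.
#' @export
apply_function_filter <- function(statuses, min_nonmissing = 0.8,
                                  all_samples = NULL) {
  if (is.null(all_samples)) all_samples <- unique(statuses$sample_id)
  n_samples <- length(all_samples)
  if (nrow(statuses) == 0L || n_samples == 0L) {
    return(data.frame(function_id = character(),
                      nonmissing_fraction = numeric(),
                      retained = logical(), stringsAsFactors = FALSE))
  }
  statuses <- statuses[statuses$sample_id %in% all_samples, , drop = FALSE]
  frac <- vapply(split(statuses, statuses$function_id), function(sub) {
    sum(sub$status == "ok") / n_samples
  }, numeric(1))
  data.frame(function_id = names(frac),
             nonmissing_fraction = unname(frac),
             retained = unname(frac > min_nonmissing),
             stringsAsFactors = FALSE)
}
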