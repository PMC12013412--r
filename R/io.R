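#' Read an abundance table
#'
#' Accepts either long form — columns `sample_id`, `species_id`,
#' `abundance` — or wide form, where the first column holds species
#' identifiers and every further column is one sample. Both return the
#' same long-form `data.frame`; zero entries of a wide table are dropped
#' (absent means absent). Tab- or comma-delimited with a header row;
#' the delimiter is sniffed from the header unless given.
#'
#' @param path Path to a UTF-8 TSV/CSV file.
#' @param delim Field delimiter; `NULL` (default) sniffs `\t` vs `,` from
#'   the first line.
#' @return A `data.frame` with columns `sample_id`, `species_id`,
#'   `abundance`.
#' @export
read_abundance_table <- function(path, delim = NULL) {
  df <- read_delim_checked(path, delim)
  long_cols <- c("sample_id", "species_id", "abundance")
  if (all(long_cols %in% names(df))) {
    df <- df[, long_cols]
    df$abundance <- as.numeric(df$abundance)
    return(df)
  }
  # wide: first column = species, remaining columns = samples
  if (ncol(df) < 2L) {
    stop("abundance table '", path, "' has no sample columns", call. = FALSE)
  }
  species <- as.character(df[[1L]])
  out <- do.call(rbind, lapply(names(df)[-1L], function(s) {
    v <- as.numeric(df[[s]])
    keep <- !is.na(v) & v != 0
    data.frame(sample_id = s, species_id = species[keep],
               abundance = v[keep], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a long-form flux table
#'
#' Columns `sample_id`, `species_id`, `function_id`, `flux`. Fluxes are
#' expected in the "positive = secretion" orientation; set
#' `invert_sign = TRUE` for raw flux-variability output where secretion is
#' negative.
#'
#' @inheritParams read_abundance_table
#' @param invert_sign Multiply fluxes by -1 on read.
#' @return A validated `data.frame` (duplicate keys are an error).
#' @export
read_flux_table <- function(path, delim = NULL, invert_sign = FALSE) {
  df <- read_delim_checked(path, delim)
  need <- c("sample_id", "species_id", "function_id", "flux")
  if (!all(need %in% names(df))) {
    stop("flux table '", path, "' needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  df$flux <- as.numeric(df$flux)
  if (invert_sign) df$flux <- -df$flux
  key <- paste(df$sample_id, df$species_id, df$function_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), ][1L, ]
    stop("duplicate flux record for (", dup$sample_id, ", ",
         dup$species_id, ", ", dup$function_id, ") in '", path, "'",
         call. = FALSE)
  }
  df
}

#' Read a function reference listing
#'
#' Two columns, `function_id` and `species_id`: one row per (function,
#' capable species).
#'
#' @inheritParams read_abundance_table
#' @return A named list of [function_reference()] objects.
#' @export
read_function_reference <- function(path, delim = NULL) {
  df <- read_delim_checked(path, delim)
  need <- c("function_id", "species_id")
  if (!all(need %in% names(df))) {
    stop("reference table '", path, "' needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  refs <- lapply(split(df$species_id, df$function_id),
                 function(sp) NULL)
  for (fn in names(refs)) {
    refs[[fn]] <- function_reference(fn, df$species_id[df$function_id == fn])
  }
  refs
}

#' Read a species-by-trait matrix
#'
#' Species in rows (first column = species identifier), traits in columns.
#' An optional row with first field `#kind` declares each trait as
#' `binary` or `quantitative`; without it, kinds are inferred (all values
#' in `{0, 1}` means binary).
#'
#' @inheritParams read_abundance_table
#' @return A list with `traits` (numeric matrix, species as rownames) and
#'   `kinds` (character vector or `NULL` if to be inferred).
#' @export
read_trait_matrix <- function(path, delim = NULL) {
  df <- read_delim_checked(path, delim)
  kinds <- NULL
  kind_row <- df[[1L]] == "#kind"
  if (any(kind_row)) {
    kinds <- as.character(unlist(df[which(kind_row)[1L], -1L]))
    df <- df[!kind_row, , drop = FALSE]
  }
  traits <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(traits) <- "double"
  rownames(traits) <- as.character(df[[1L]])
  list(traits = traits, kinds = kinds)
}

read_delim_checked <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  # read identifiers as-is: "T"/"F"-style ids must not become logicals
  utils::read.delim(path, sep = delim, header = TRUE,
                    colClasses = "character",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Run the full redundancy pipeline
#'
#' Ties preprocessing and the measures together: builds communities
#' (restricted to `universe` if given), applies the richness filter,
#' derives per-pair missingness from the fluxes, applies the function
#' filter, computes all measures for every retained sample-function pair,
#' and aggregates per-sample global interdependency. Every exclusion is
#' traceable in the returned filter report.
#'
#' @param abundances Long-form abundance `data.frame` (see
#'   [read_abundance_table()]).
#' @param fluxes Long-form flux `data.frame` ("positive = secretion").
#' @param reference Named list of [function_reference()] objects, or
#'   `NULL` to derive each function's reference as the union of species
#'   ever observed producing it across the corpus (labelled `derived`;
#'   this underestimates `m`).
#' @param universe Optional admissible species set.
#' @param min_species Sample richness filter threshold (default 25).
#' @param min_nonmissing Function non-missing fraction, strict (default
#'   0.8).
#' @param tolerance Uptake/noise tolerance on fluxes (default `1e-9`).
#' @param zero_tol Share positivity threshold (default `1e-12`).
#' @return A list of class `fr_run`: `results` (one row per retained
#'   sample-function pair), `global` (per-sample global interdependency),
#'   `filter_report` (samples, functions, pair statuses, exclusion of the
#'   abundance-restriction step), and `reference_mode` (`"supplied"` or
#'   `"derived"`).
#' @export
compute_redundancy <- function(abundances, fluxes, reference = NULL,
                               universe = NULL, min_species = 25L,
                               min_nonmissing = 0.8, tolerance = 1e-9,
                               zero_tol = 1e-12) {
  built <- build_communities(abundances, universe)
  filt <- apply_sample_filter(built$communities, min_species)
  communities <- filt$retained
  if (length(communities) == 0L) {
    stop("no samples left after the richness filter", call. = FALSE)
  }

  fluxes <- fluxes[fluxes$sample_id %in% names(communities), , drop = FALSE]
  statuses <- pair_missingness(fluxes, tolerance)
  fun_filter <- apply_function_filter(statuses, min_nonmissing,
                                      all_samples = names(communities))
  kept_functions <- fun_filter$function_id[fun_filter$retained]
  if (length(kept_functions) == 0L) {
    stop("no functions left after the non-missing filter", call. = FALSE)
  }

  reference_mode <- if (is.null(reference)) "derived" else "supplied"
  if (is.null(reference)) {
    reference <- derive_reference(fluxes, tolerance)
  }

  rows <- list()
  for (i in seq_len(nrow(statuses))) {
    st <- statuses[i, ]
    if (!(st$function_id %in% kept_functions)) next
    com <- communities[[st$sample_id]]
    sub <- fluxes[fluxes$sample_id == st$sample_id &
                    fluxes$function_id == st$function_id, , drop = FALSE]
    f <- stats::setNames(rep(0, length(com$species)), com$species)
    known <- intersect(sub$species_id, com$species)
    if (length(known) < nrow(sub)) {
      stop("flux record for species absent from sample '", st$sample_id,
           "': ", paste(setdiff(sub$species_id, com$species), collapse = ", "),
           call. = FALSE)
    }
    f[sub$species_id] <- pmax(sub$flux, 0)  # clip within-tolerance noise
    prof <- functional_profile(f, function_id = st$function_id)
    ref <- reference[[st$function_id]]
    status <- if (st$status == "uptake_detected") "uptake_detected" else "ok"
    rows[[length(rows) + 1L]] <-
      fr_measures(prof, com, ref, zero_tol = zero_tol, status = status)
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$sample_id, results$function_id), ,
                     drop = FALSE]
  rownames(results) <- NULL

  global <- do.call(rbind, lapply(split(results, results$sample_id),
    function(g) data.frame(sample_id = g$sample_id[1L],
                           n_functions = sum(!is.na(g$interdependency)),
                           global_interdependency =
                             fr_global_interdependency(g$interdependency),
                           stringsAsFactors = FALSE)))
  rownames(global) <- NULL

  structure(list(results = results, global = global,
                 filter_report = list(samples = filt$report,
                                      functions = fun_filter,
                                      pair_status = statuses,
                                      restriction_excluded = built$excluded),
                 reference_mode = reference_mode),
            class = "fr_run")
}

#' @export
print.fr_run <- function(x, ...) {
  cat("<fr_run>", nrow(x$results), "sample-function pairs,",
      sum(x$filter_report$samples$retained), "samples,",
      sum(x$filter_report$functions$retained), "functions",
      paste0("(reference: ", x$reference_mode, ")"), "\n")
  invisible(x)
}

derive_reference <- function(fluxes, tolerance) {
  prod <- fluxes[fluxes$flux > tolerance, , drop = FALSE]
  refs <- list()
  for (fn in unique(fluxes$function_id)) {
    sp <- unique(prod$species_id[prod$function_id == fn])
    if (length(sp)) refs[[fn]] <- function_reference(fn, sp)
  }
  refs
}

#' Write pipeline outputs as TSV
#'
#' Writes `results.tsv`, `global_interdependency.tsv`,
#' `filter_samples.tsv`, `filter_functions.tsv` and `pair_status.tsv` into
#' `dir`. Missing values are encoded as the string `na_string` so that the
#' schema is stable regardless of missingness. Output is deterministic for
#' a given run object.
#'
#' @param run An `fr_run` object from [compute_redundancy()].
#' @param dir Output directory, created if needed.
#' @param na_string Encoding for missing values (default `"NA"`).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, na_string = "NA") {
  stopifnot(inherits(run, "fr_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "results.tsv"),
             global = file.path(dir, "global_interdependency.tsv"),
             samples = file.path(dir, "filter_samples.tsv"),
             functions = file.path(dir, "filter_functions.tsv"),
             pairs = file.path(dir, "pair_status.tsv"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = na_string)
  }
  write_tsv(run$results, paths["results"])
  write_tsv(run$global, paths["global"])
  write_tsv(run$filter_report$samples, paths["samples"])
  write_tsv(run$filter_report$functions, paths["functions"])
  write_tsv(run$filter_report$pair_status, paths["pairs"])
  invisible(paths)
}
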