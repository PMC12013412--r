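#' Built-in scenario fixtures
#'
#' Generates the worked scenarios used throughout the documentation and
#' tests, either in memory or as TSV files on disk:
#'
#' * `"toy"` — a five-species sample in which four species produce the
#'   function and the reference holds three further capable species
#'   (m = 7). The numeric abundances and fluxes are artifact choices made
#'   here (documented, not canonical).
#' * `"keystone"` — the single-producer series: for each richness
#'   `n = 1..n_max`, uniform abundances and shares `(1, 0, ..., 0)`, with
#'   a reference of size `m`.
#' * `"proportional"` — every producer's flux is proportional to its
#'   abundance, so the interdependency index is exactly zero and the
#'   abundance-based redundancy reduces to `log` of the producers' summed
#'   abundance.
#' * `"dirichlet"` — synthetic communities from [draw_community()].
#'
#' @param kind One of `"toy"`, `"keystone"`, `"proportional"`,
#'   `"dirichlet"`.
#' @param dir Output directory; `NULL` (default) returns the tables in
#'   memory instead of writing `abundances.tsv`, `fluxes.tsv`,
#'   `reference.tsv`.
#' @param n,m Community and reference sizes where applicable.
#' @param n_samples Number of samples (`"dirichlet"`, `"proportional"`).
#' @param alpha Dirichlet concentration (`"dirichlet"`).
#' @param seed Optional seed for the random kinds.
#' @return A list with `abundances`, `fluxes`, `reference` data.frames
#'   (and, when `dir` is given, attribute `paths`).
#' @examples
#' fx <- make_fixtures("toy")
#' str(fx$abundances)
#' @export
make_fixtures <- function(kind = c("toy", "keystone", "proportional",
                                   "dirichlet"),
                          dir = NULL, n = 100L, m = 100L, n_samples = 5L,
                          alpha = 1, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  fx <- switch(kind,
    toy = fixture_toy(),
    keystone = fixture_keystone(n, m),
    proportional = fixture_proportional(n, n_samples),
    dirichlet = fixture_dirichlet(n, n_samples, alpha))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(abundances = file.path(dir, "abundances.tsv"),
               fluxes = file.path(dir, "fluxes.tsv"),
               reference = file.path(dir, "reference.tsv"))
    utils::write.table(fx$abundances, paths["abundances"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fx$fluxes, paths["fluxes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fx$reference, paths["reference"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    attr(fx, "paths") <- paths
  }
  fx
}

# Five species in the sample, four of them producers, three extra capable
# species in the reference. Values are round numbers chosen for legibility.
fixture_toy <- function() {
  species <- paste0("s", 1:5)
  list(
    abundances = data.frame(sample_id = "toy", species_id = species,
                            abundance = c(0.3, 0.25, 0.2, 0.15, 0.1),
                            stringsAsFactors = FALSE),
    fluxes = data.frame(sample_id = "toy", species_id = species,
                        function_id = "F", flux = c(2, 1.5, 1, 0.5, 0),
                        stringsAsFactors = FALSE),
    reference = data.frame(function_id = "F",
                           species_id = c(species[1:4],
                                          paste0("r", 6:8)),
                           stringsAsFactors = FALSE))
}

fixture_keystone <- function(n_max, m) {
  stopifnot(m >= n_max)
  ab <- do.call(rbind, lapply(seq_len(n_max), function(n)
    data.frame(sample_id = paste0("n", n),
               species_id = paste0("sp", seq_len(n)),
               abundance = rep(1 / n, n), stringsAsFactors = FALSE)))
  fl <- data.frame(sample_id = paste0("n", seq_len(n_max)),
                   species_id = "sp1", function_id = "F", flux = 1,
                   stringsAsFactors = FALSE)
  ref <- data.frame(function_id = "F", species_id = paste0("sp", seq_len(m)),
                    stringsAsFactors = FALSE)
  list(abundances = ab, fluxes = fl, reference = ref)
}

fixture_proportional <- function(n, n_samples) {
  species <- paste0("sp", seq_len(n))
  rows_a <- list(); rows_f <- list()
  for (s in seq_len(n_samples)) {
    a <- rdirichlet_sym(n, 2)
    producers <- sort(sample.int(n, max(2L, n %/% 2L)))
    rows_a[[s]] <- data.frame(sample_id = paste0("s", s),
                              species_id = species, abundance = a,
                              stringsAsFactors = FALSE)
    rows_f[[s]] <- data.frame(sample_id = paste0("s", s),
                              species_id = species[producers],
                              function_id = "F",
                              flux = 3 * a[producers],
                              stringsAsFactors = FALSE)
  }
  list(abundances = do.call(rbind, rows_a),
       fluxes = do.call(rbind, rows_f),
       reference = data.frame(function_id = "F", species_id = species,
                              stringsAsFactors = FALSE))
}

fixture_dirichlet <- function(n, n_samples, alpha) {
  species <- paste0("sp", seq_len(n))
  rows_a <- list(); rows_f <- list()
  for (s in seq_len(n_samples)) {
    cm <- draw_community(n, alpha)
    rows_a[[s]] <- data.frame(sample_id = paste0("s", s),
                              species_id = species,
                              abundance = cm$abundance,
                              stringsAsFactors = FALSE)
    rows_f[[s]] <- data.frame(sample_id = paste0("s", s),
                              species_id = species, function_id = "F",
                              flux = cm$shares, stringsAsFactors = FALSE)
  }
  list(abundances = do.call(rbind, rows_a),
       fluxes = do.call(rbind, rows_f),
       reference = data.frame(function_id = "F", species_id = species,
                              stringsAsFactors = FALSE))
}
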