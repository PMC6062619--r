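#' Packaged summary tables for 49 ancient Eurasian samples
#'
#' The package ships, as plain-text fixtures, published sample-level
#' summary tables for 279 ancient Eurasian individuals grouped into 49
#' samples spanning European hunter-gatherers, Early Neolithic farmers,
#' steppe and Bronze Age populations, and ancient Western Asia:
#'
#' * `ancient_sample_profiles()` — sparsified mean ancestry proportions per
#'   sample over 21 ancestries (wide; `group`, `sample`, `size`, then one
#'   column per ancestry). Rows sum to 1 up to rounding of the published
#'   values (3 decimals).
#' * `ancient_haplogroups()` — Y-chromosome and mitochondrial haplogroup
#'   counts per sample, long format (a [read_haplogroup_table()] table).
#'   Samples with no assignable haplogroup at a locus are absent.
#' * `ancient_sample_groups()` — sample metadata: period `group`, sample
#'   `size`, and the finer `subgroup` used in period-level summaries
#'   (e.g. `copper_age` splits the Middle Neolithic to Copper Age group).
#' * `ancient_group_means()` — published period-level mean ancestry
#'   percentages (long: `subgroup`, `ancestry`, `percent`).
#'
#' @return A tibble (see the individual descriptions).
#' @name fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "ancestryproj")
  if (p == "") abort(paste0("packaged fixture not found: ", name))
  p
}

#' @rdname fixtures
#' @export
ancient_sample_profiles <- function() {
  readr::read_tsv(fixture_path("table1_profiles.tsv"),
                  col_types = readr::cols(
                    group = readr::col_character(),
                    sample = readr::col_character(),
                    size = readr::col_integer(),
                    .default = readr::col_double()))
}

#' @rdname fixtures
#' @export
ancient_haplogroups <- function() {
  read_haplogroup_table(fixture_path("table2_haplogroups.csv"))
}

#' @rdname fixtures
#' @export
ancient_sample_groups <- function() {
  readr::read_csv(fixture_path("sample_groups.csv"),
                  col_types = readr::cols(
                    group = readr::col_character(),
                    sample = readr::col_character(),
                    size = readr::col_integer(),
                    subgroup = readr::col_character()))
}

#' @rdname fixtures
#' @export
ancient_group_means <- function() {
  readr::read_tsv(fixture_path("group_means.tsv"),
                  col_types = readr::cols(
                    subgroup = readr::col_character(),
                    ancestry = readr::col_character(),
                    percent = readr::col_double()))
}

#' Sample profiles fixture in long (tidy) form
#'
#' Pivots [ancient_sample_profiles()] to one row per (sample, ancestry)
#' with columns `group`, `sample`, `size`, `ancestry`, `proportion`, ready
#' for [summarize_group()] and [ancestry_ratio()].
#'
#' @param subgroups Optional character vector of `subgroup` labels (see
#'   [ancient_sample_groups()]) restricting the samples.
#' @return A long tibble.
#' @export
ancient_profiles_long <- function(subgroups = NULL) {
  wide <- ancient_sample_profiles()
  long <- wide |>
    tidyr::pivot_longer(-c("group", "sample", "size"),
                        names_to = "ancestry", values_to = "proportion") |>
    rename(sample_id = "sample")
  if (!is.null(subgroups)) {
    sel <- ancient_sample_groups() |>
      filter(.data$subgroup %in% subgroups) |>
      select("group", sample_id = "sample")
    long <- long |> semi_join(sel, by = c("group", "sample_id"))
  }
  long
}
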