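#' Read a haplogroup count table
#'
#' Expects a CSV with columns `group`, `sample`, `locus` (`Y` or `MT`),
#' `haplogroup`, `count`. Samples with no assignable haplogroup at a locus
#' are simply absent (never encoded as a haplogroup named "NA").
#'
#' @param path Path to the CSV.
#' @return A validated tibble of class `haplogroup_table`.
#' @export
read_haplogroup_table <- function(path) {
  if (!file.exists(path)) abort(paste0("haplogroup table not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    group = readr::col_character(), sample = readr::col_character(),
    locus = readr::col_character(), haplogroup = readr::col_character(),
    count = readr::col_integer()))
  validate_haplogroup_table(x, path = path)
}

validate_haplogroup_table <- function(x, path = NULL) {
  where <- if (is.null(path)) "haplogroup table" else path
  need <- c("group", "sample", "locus", "haplogroup", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort(paste0(where, ": missing columns: ", paste(miss, collapse = ", ")))
  x <- as_tibble(x)
  if (nrow(x) > 0) {
    if (!all(x$locus %in% c("Y", "MT")))
      abort(paste0(where, ": locus must be 'Y' or 'MT'"))
    if (anyNA(x$haplogroup) || any(x$haplogroup %in% c("", "NA")))
      abort(paste0(where, ": empty or 'NA' haplogroup label; drop such records instead"))
    if (anyNA(x$count) || any(x$count < 1))
      abort(paste0(where, ": counts must be positive integers"))
    key <- x[c("group", "sample", "locus", "haplogroup")]
    if (anyDuplicated(key))
      abort(paste0(where, ": duplicate (group, sample, locus, haplogroup) record"))
  }
  class(x) <- unique(c("haplogroup_table", "tbl_df", "tbl", "data.frame"))
  x
}

#' Haplogroup composition by string-prefix matching
#'
#' Tallies how many uniparental lineages in a selection carry a haplogroup
#' whose name starts with any of the given prefixes. Matching is plain,
#' case-sensitive string prefixing, not phylogenetic containment: "HV"
#' counts under prefix "H", "V9" under "V", "R1" under "R", and "K(xLT)"
#' under "K". A record is counted once even if several prefixes match.
#'
#' @param table A `haplogroup_table` tibble.
#' @param locus `"Y"` or `"MT"`.
#' @param prefixes Character vector of haplogroup prefixes (the empty
#'   string matches everything).
#' @param groups Optional character vector restricting to period groups.
#' @param samples Optional character vector restricting to sample names
#'   (applied after `groups`, if both are given).
#' @return One-row tibble: `matched`, `total`, `percent` (rounded to one
#'   decimal, as conventionally displayed).
#' @export
haplogroup_composition <- function(table, locus, prefixes,
                                   groups = NULL, samples = NULL) {
  stopifnot(length(locus) == 1, locus %in% c("Y", "MT"))
  d <- table
  if (!is.null(groups)) d <- d |> filter(.data$group %in% groups)
  if (!is.null(samples)) d <- d |> filter(.data$sample %in% samples)
  if (nrow(d) == 0) abort("selection matches no haplogroup records")
  d <- d |> filter(.data$locus == !!locus)
  total <- sum(d$count)
  if (total == 0) abort("selection has no records at the requested locus")
  hit <- Reduce(`|`, lapply(unique(prefixes),
                            function(p) startsWith(d$haplogroup, p)))
  matched <- sum(d$count[hit])
  tibble(matched = matched, total = total,
         percent = round(100 * matched / total, 1))
}
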