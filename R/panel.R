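#' Read an ancestry-specific allele-frequency panel
#'
#' A frequency panel is a tab-separated table with one row per biallelic SNP
#' and columns `id`, `chrom`, `pos`, `counted_allele`, `other_allele`,
#' followed by one column of counted-allele frequencies per ancestry. Such
#' panels are typically produced by unsupervised clustering of large
#' present-day reference cohorts; the projection machinery in this package
#' holds them fixed.
#'
#' @param path Path to a tab-separated panel file with a header line.
#' @return A tibble of class `freq_panel` with the five marker-metadata
#'   columns followed by one numeric frequency column per ancestry, in the
#'   file's column order.
#' @export
#' @examples
#' panel <- simulate_panel(K = 3, M = 20, fst = 0.1, seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' write_frequency_panel(panel, tf)
#' read_frequency_panel(tf)
read_frequency_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), counted_allele = readr::col_character(),
    other_allele = readr::col_character(), .default = readr::col_double()))
  validate_frequency_panel(x, path = path)
}

#' Write a frequency panel to TSV
#'
#' @param panel A `freq_panel` tibble (see [read_frequency_panel()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_panel <- function(panel, path) {
  panel <- validate_frequency_panel(panel)
  readr::write_tsv(panel, path)
  invisible(path)
}

marker_cols <- c("id", "chrom", "pos", "counted_allele", "other_allele")

#' Validate a frequency panel
#'
#' Checks the marker metadata (unique ids, positive positions, distinct
#' single-base alleles) and that every frequency lies in \[0, 1\]. Errors
#' name the offending data line (1-based, excluding the header).
#'
#' @param x A data frame shaped like the output of [read_frequency_panel()].
#' @param path Optional source path, used in error messages.
#' @return `x` as a validated `freq_panel` tibble.
#' @export
validate_frequency_panel <- function(x, path = NULL) {
  where <- if (is.null(path)) "panel" else path
  miss <- setdiff(marker_cols, names(x))
  if (length(miss) > 0)
    abort(paste0(where, ": missing required columns: ", paste(miss, collapse = ", ")))
  x <- as_tibble(x)
  anc <- setdiff(names(x), marker_cols)
  if (length(anc) < 1) abort(paste0(where, ": no ancestry frequency columns"))
  if (anyDuplicated(anc)) abort(paste0(where, ": duplicate ancestry labels"))
  bad_line <- function(i, what)
    abort(paste0(where, ": line ", i[1], ": ", what))
  dup <- which(duplicated(x$id))
  if (length(dup) > 0) bad_line(dup, paste0("duplicate marker id '", x$id[dup[1]], "'"))
  if (anyNA(x$pos) || any(x$pos < 1)) bad_line(which(is.na(x$pos) | x$pos < 1), "pos must be >= 1")
  bases <- c("A", "C", "G", "T")
  ok <- x$counted_allele %in% bases & x$other_allele %in% bases &
    x$counted_allele != x$other_allele
  if (!all(ok)) bad_line(which(!ok), "alleles must be distinct single bases in A/C/G/T")
  fr <- as.matrix(x[anc])
  if (!is.numeric(fr) || anyNA(fr)) {
    bad <- which(apply(is.na(x[anc]), 1, any))
    bad_line(bad, "non-numeric or missing frequency")
  }
  out <- which(apply(fr < 0 | fr > 1, 1, any))
  if (length(out) > 0)
    bad_line(out, paste0("frequency outside [0, 1] (",
                         format(fr[out[1], which(fr[out[1], ] < 0 | fr[out[1], ] > 1)[1]]), ")"))
  class(x) <- unique(c("freq_panel", "tbl_df", "tbl", "data.frame"))
  x
}

#' Ancestry labels of a panel
#' @param panel A `freq_panel` tibble.
#' @return Character vector of ancestry labels, in panel column order.
#' @export
panel_ancestries <- function(panel) setdiff(names(panel), marker_cols)

#' Panel frequencies as a K x M matrix
#'
#' @param panel A `freq_panel` tibble.
#' @return Numeric matrix with one row per ancestry (rownames = labels) and
#'   one column per marker (colnames = marker ids).
#' @export
panel_freq_matrix <- function(panel) {
  anc <- panel_ancestries(panel)
  m <- t(as.matrix(panel[anc]))
  dimnames(m) <- list(anc, panel$id)
  m
}
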