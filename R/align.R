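#' Harmonize genotypes to a frequency panel
#'
#' Intersects markers by (chrom, pos) and reconciles alleles so that every
#' kept dosage counts the panel's counted allele:
#' * VCF REF = panel other allele and ALT = counted allele: dosage kept as is;
#' * alleles swapped (REF = counted, ALT = other): dosage replaced by
#'   `2 - dosage` (missing stays missing);
#' * strand-ambiguous pairs (A/T or C/G in the panel) are dropped — flipping
#'   them cannot be distinguished from strand error;
#' * any other allele combination is dropped as a mismatch.
#'
#' @param gm A [genotype_matrix()] whose marker table has `ref`/`alt` columns.
#' @param panel A `freq_panel` tibble.
#' @return An object of class `aligned_dataset`: a list with `panel`
#'   (restricted, in kept-marker order), `freqs` (K x M matrix), `genotypes`
#'   (restricted and harmonized [genotype_matrix()]) and `report` (a tibble
#'   of category counts: `kept`, `kept_swapped`, `dropped_ambiguous`,
#'   `dropped_mismatch`, which partition the (chrom, pos) intersection).
#' @export
align_genotypes_to_panel <- function(gm, panel) {
  panel <- validate_frequency_panel(panel)
  pm <- panel[marker_cols]
  vm <- gm$markers
  key_p <- paste(pm$chrom, pm$pos)
  key_v <- paste(vm$chrom, vm$pos)
  common <- intersect(key_p, key_v)
  if (length(common) == 0)
    abort("no markers shared between genotypes and panel; check marker sets (chrom/pos conventions, genome build)")

  ip <- match(common, key_p)
  iv <- match(common, key_v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- pm$counted_allele[ip] == comp[pm$other_allele[ip]]
  same <- vm$ref[iv] == pm$other_allele[ip] & vm$alt[iv] == pm$counted_allele[ip]
  swapped <- vm$ref[iv] == pm$counted_allele[ip] & vm$alt[iv] == pm$other_allele[ip]
  status <- dplyr::case_when(
    ambiguous ~ "dropped_ambiguous",
    same ~ "kept",
    swapped ~ "kept_swapped",
    TRUE ~ "dropped_mismatch")

  keep <- status %in% c("kept", "kept_swapped")
  ipk <- ip[keep]; ivk <- iv[keep]
  # keep panel order among kept markers
  ord <- order(ipk)
  ipk <- ipk[ord]; ivk <- ivk[ord]
  flip <- (status[keep])[ord] == "kept_swapped"

  dos <- gm$dosages[, ivk, drop = FALSE]
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  sub_panel <- panel[ipk, ]
  markers <- tibble(id = sub_panel$id, chrom = sub_panel$chrom, pos = sub_panel$pos,
                    ref = sub_panel$other_allele, alt = sub_panel$counted_allele)
  out_gm <- genotype_matrix(dos, markers, gm$ploidy)
  report <- tibble(category = c("kept", "kept_swapped", "dropped_ambiguous", "dropped_mismatch"),
                   n = c(sum(status == "kept"), sum(status == "kept_swapped"),
                         sum(status == "dropped_ambiguous"), sum(status == "dropped_mismatch")))
  structure(list(panel = sub_panel, freqs = panel_freq_matrix(sub_panel),
                 genotypes = out_gm, report = report),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("<aligned_dataset> ", nrow(x$genotypes$dosages), " individuals, ",
      nrow(x$panel), " markers, ", nrow(x$freqs), " ancestries\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write an alignment report as key/count TSV
#' @param aligned An `aligned_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(aligned, path) {
  readr::write_tsv(aligned$report, path)
  invisible(path)
}
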