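#' Construct a genotype matrix
#'
#' The genotype container used throughout the package: an N x M matrix of
#' counted-allele dosages (0/1/2, `NA` for missing) with marker metadata and
#' a per-individual ploidy flag. Pseudo-haploid individuals — the usual
#' representation for low-coverage ancient genomes, where one sequenced
#' allele is sampled per site and coded as homozygous — carry dosages in
#' \{0, 2, NA\} only.
#'
#' @param dosages Integer/numeric N x M matrix; rownames are individual ids,
#'   colnames are marker ids.
#' @param markers Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (alleles as stored in the source; `ref`/`alt` here mean the allele the
#'   dosage does *not* / does count).
#' @param ploidy Character vector, one of `"diploid"` or `"pseudo_haploid"`
#'   per individual, named by individual id (recycled if length 1).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, markers, ploidy = "diploid") {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) abort("dosages must have individual ids as rownames")
  if (nrow(markers) != ncol(dosages))
    abort("markers rows must match dosage columns")
  if (length(ploidy) == 1) ploidy <- rep(ploidy, nrow(dosages))
  if (length(ploidy) != nrow(dosages))
    abort("ploidy must have one entry per individual")
  if (!all(ploidy %in% c("diploid", "pseudo_haploid")))
    abort("ploidy entries must be 'diploid' or 'pseudo_haploid'")
  names(ploidy) <- rownames(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  ph <- ploidy == "pseudo_haploid"
  if (any(ph)) {
    v <- dosages[ph, , drop = FALSE]
    if (any(v == 1, na.rm = TRUE))
      abort("pseudo-haploid individuals cannot carry heterozygous dosages")
  }
  colnames(dosages) <- markers$id
  structure(list(dosages = dosages, markers = as_tibble(markers), ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " markers; ",
      sum(x$ploidy == "pseudo_haploid"), " pseudo-haploid; ",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$dosages))), sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from a VCF file
#'
#' Extracts per-individual counted-allele dosages from the GT field of a
#' (plain or bgzipped) VCF. The dosage counts the ALT allele: `0/0` is 0,
#' `0/1` is 1, `1/1` is 2 and `./.` is missing. Haploid calls (`0`, `1`)
#' are coded to \{0, 2\}; an individual whose non-missing calls are all
#' haploid is flagged `pseudo_haploid`, unless overridden via `ploidy`.
#' Multi-allelic records are skipped with a warning.
#'
#' @param path Path to a VCF file.
#' @param ploidy Optional character vector (`"diploid"`/`"pseudo_haploid"`)
#'   named by individual id, overriding automatic pseudo-haploid detection.
#' @return A [genotype_matrix()] whose marker table carries the VCF `ref`
#'   and `alt` alleles (dosage counts `alt`).
#' @export
read_genotypes_vcf <- function(path, ploidy = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort(paste0(path, ": VCF contains no records"))
  fmt <- v@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt)))
    abort(paste0(path, ": records without a GT format field"))
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi))
    warn(paste0(path, ": skipping ", sum(multi), " multi-allelic or ALT-less record(s)"))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  strip <- gsub("\\|", "/", gt)
  strip[strip %in% c(".", "./.", ".|.", "")] <- NA
  haploid <- !is.na(strip) & !grepl("/", strip)
  dos <- matrix(NA_real_, nrow(strip), ncol(strip), dimnames = dimnames(strip))
  dip <- !is.na(strip) & grepl("/", strip)
  a <- suppressWarnings(as.numeric(sub("/.*", "", strip)))
  b <- suppressWarnings(as.numeric(sub(".*/", "", strip)))
  dos[dip] <- a[dip] + b[dip]
  dos[haploid] <- 2 * suppressWarnings(as.numeric(strip[haploid]))
  # half-missing diploid calls ("./1") become missing
  dos[dip & (is.na(a) | is.na(b))] <- NA

  markers <- tibble(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)

  dosages <- t(dos)
  inds <- rownames(dosages)
  if (is.null(ploidy)) {
    auto <- vapply(inds, function(i) {
      nm <- !is.na(strip[, i])
      if (any(nm) && all(haploid[nm, i])) "pseudo_haploid" else "diploid"
    }, character(1))
    ploidy <- auto
  } else {
    if (is.null(names(ploidy)) || !all(inds %in% names(ploidy)))
      abort("ploidy override must be named by individual id and cover all individuals")
    ploidy <- ploidy[inds]
  }
  genotype_matrix(dosages, markers, ploidy)
}
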