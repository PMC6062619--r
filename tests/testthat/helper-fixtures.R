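# shared test helpers: tiny panels, VCF text, grid-search oracle

tiny_panel <- function(freqs, counted = "G", other = "A") {
  # freqs: K x M matrix (rows = ancestries)
  K <- nrow(freqs); M <- ncol(freqs)
  panel <- tibble::tibble(
    id = sprintf("m%02d", seq_len(M)), chrom = "1",
    pos = seq_len(M) * 100L,
    counted_allele = rep(counted, M), other_allele = rep(other, M))
  anc <- rownames(freqs)
  if (is.null(anc)) anc <- paste0("anc", seq_len(K))
  for (k in seq_len(K)) panel[[anc[k]]] <- freqs[k, ]
  validate_frequency_panel(panel)
}

write_vcf_text <- function(path, markers, gt, samples) {
  # markers: data.frame chrom,pos,id,ref,alt ; gt: M x n character matrix
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(cbind(markers$chrom, markers$pos, markers$id, markers$ref,
                      markers$alt, ".", ".", ".", "GT", gt), 1,
                paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  path
}

# brute-force maximizer of the two-ancestry projection likelihood over a
# q1 grid; independent of the EM path
grid_search_q1 <- function(dosages, freqs, ploidy = "diploid", step = 0.001) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(q1)
    admixture_log_likelihood(c(q1, 1 - q1), dosages, freqs, ploidy),
    numeric(1))
  grid[which.max(ll)]
}
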