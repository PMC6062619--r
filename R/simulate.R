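#' Simulate an ancestry-specific allele-frequency panel
#'
#' Draws an ancestral frequency per marker uniformly on \[0.05, 0.95\]
#' (bounded away from 0/1 so no marker is monomorphic and uninformative),
#' then, independently per ancestry, a derived frequency from the
#' Balding-Nichols distribution
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`, the standard one-parameter
#' model of F_ST-controlled divergence from a common ancestral pool.
#'
#' @param K Number of ancestries.
#' @param M Number of markers.
#' @param fst Divergence parameter F_ST in (0, 1).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param ancestries Optional ancestry labels (default `anc01`, `anc02`, ...).
#' @return A `freq_panel` tibble (see [read_frequency_panel()]) with
#'   synthetic marker ids and strictly increasing positions.
#' @export
simulate_panel <- function(K, M, fst, seed, ancestries = NULL) {
  stopifnot(K >= 1, M >= 1, fst > 0, fst < 1)
  if (is.null(ancestries)) ancestries <- sprintf("anc%02d", seq_len(K))
  stopifnot(length(ancestries) == K, !anyDuplicated(ancestries))
  set.seed(seed)
  p0 <- runif(M, 0.05, 0.95)
  fr <- vapply(seq_len(K), function(k)
    rbeta(M, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst), numeric(M))
  fr <- pmin(pmax(fr, 1e-9), 1 - 1e-9)  # rbeta can return exact 0/1
  alleles <- matrix(c("A", "C", "A", "G"), 2)[, sample(c(1, 2), M, replace = TRUE)]
  panel <- tibble(
    id = sprintf("snp%06d", seq_len(M)), chrom = "1",
    pos = cumsum(sample.int(1000L, M, replace = TRUE)),
    counted_allele = alleles[2, ], other_allele = alleles[1, ])
  panel[ancestries] <- as.data.frame(fr)
  validate_frequency_panel(panel)
}

#' Simulate admixed individuals from a frequency panel
#'
#' Admixture proportions are drawn from a Dirichlet distribution — either
#' dense (`dirichlet_alpha` of length K) or sparse (Dirichlet with
#' concentration `concentration` on a fixed `support` of ancestries, zero
#' elsewhere). Diploid dosages are Binomial(2, f) with
#' `f = sum_k q_k p_km`; pseudo-haploid individuals emit a single
#' Bernoulli(f) allele coded \{0, 2\}. Missingness is i.i.d. per entry.
#'
#' @param panel A `freq_panel` tibble.
#' @param n_individuals Number of individuals.
#' @param dirichlet_alpha Length-K positive vector (dense truth), or `NULL`
#'   when `support` is given.
#' @param support Optional integer/character vector of ancestries with
#'   nonzero truth (sparse specification).
#' @param concentration Dirichlet concentration on the support (scalar or
#'   vector, default 1).
#' @param missing_rate Probability an entry is missing, in \[0, 1).
#' @param pseudo_haploid_fraction Fraction of individuals coded
#'   pseudo-haploid (the first `round(N * fraction)` individuals).
#' @param seed Integer seed.
#' @param q_true Optional N x K matrix of fixed truths, bypassing the
#'   Dirichlet draw.
#' @return An object of class `truth_set`: list with `panel`, `freqs`
#'   (K x M), `q_true` (N x K, rows on the simplex) and `genotypes`
#'   (a [genotype_matrix()]).
#' @export
simulate_individuals <- function(panel, n_individuals,
                                 dirichlet_alpha = NULL, support = NULL,
                                 concentration = 1, missing_rate = 0,
                                 pseudo_haploid_fraction = 0, seed = 1,
                                 q_true = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            pseudo_haploid_fraction >= 0, pseudo_haploid_fraction <= 1)
  panel <- validate_frequency_panel(panel)
  P <- panel_freq_matrix(panel)
  K <- nrow(P); M <- ncol(P); N <- n_individuals
  anc <- rownames(P)
  set.seed(seed)
  if (is.null(q_true)) {
    if (is.null(dirichlet_alpha) && is.null(support))
      dirichlet_alpha <- rep(1, K)
    if (!is.null(support)) {
      idx <- if (is.character(support)) match(support, anc) else as.integer(support)
      if (anyNA(idx) || length(idx) == 0) abort("invalid sparse support")
      a <- rep(0, K); a[idx] <- concentration
    } else {
      stopifnot(length(dirichlet_alpha) == K, all(dirichlet_alpha > 0))
      a <- dirichlet_alpha
    }
    q_true <- t(vapply(seq_len(N), function(i) {
      g <- ifelse(a > 0, rgamma(K, shape = a), 0)
      g / sum(g)
    }, numeric(K)))
  }
  stopifnot(nrow(q_true) == N, ncol(q_true) == K)
  colnames(q_true) <- anc
  ids <- sprintf("ind%03d", seq_len(N))
  rownames(q_true) <- ids
  n_ph <- round(N * pseudo_haploid_fraction)
  ploidy <- rep("diploid", N)
  if (n_ph > 0) ploidy[seq_len(n_ph)] <- "pseudo_haploid"

  F_ind <- q_true %*% P                      # N x M expected frequencies
  dos <- matrix(NA_real_, N, M, dimnames = list(ids, panel$id))
  for (i in seq_len(N)) {
    if (ploidy[i] == "diploid") dos[i, ] <- rbinom(M, 2, F_ind[i, ])
    else dos[i, ] <- 2 * rbinom(M, 1, F_ind[i, ])
  }
  if (missing_rate > 0)
    dos[matrix(runif(N * M) < missing_rate, N, M)] <- NA
  markers <- tibble(id = panel$id, chrom = panel$chrom, pos = panel$pos,
                    ref = panel$other_allele, alt = panel$counted_allele)
  gm <- genotype_matrix(dos, markers, ploidy)
  structure(list(panel = panel, freqs = P, q_true = q_true, genotypes = gm),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", nrow(x$q_true), " individuals, ",
      ncol(x$freqs), " markers, ", nrow(x$freqs), " ancestries\n", sep = "")
  invisible(x)
}

#' Simulate a complete mock study on disk
#'
#' Generates a panel and an admixed cohort organized into samples, and
#' writes the complete runnable input set: panel TSV, genotype VCF, sample
#' map TSV (individual -> sample -> group), and a truth table of the
#' simulated admixture proportions. Deterministic given `seed`.
#'
#' @inheritParams simulate_individuals
#' @param K,M,fst Panel dimensions and divergence (see [simulate_panel()]).
#' @param n_samples Number of samples (groups of individuals).
#' @param individuals_per_sample Individuals per sample (scalar or vector).
#' @param dir Output directory (created if needed).
#' @return List with `truth` (a `truth_set`), `sample_map` (tibble:
#'   `individual_id`, `sample_id`, `group`) and `paths` (named list:
#'   `panel`, `vcf`, `sample_map`, `truth`).
#' @export
simulate_study <- function(K, M, fst, n_samples, individuals_per_sample,
                           dir, dirichlet_alpha = NULL, support = NULL,
                           concentration = 1, missing_rate = 0,
                           pseudo_haploid_fraction = 0, seed = 1) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      abort(paste0("cannot create output directory: ", dir))
  sizes <- rep(individuals_per_sample, length.out = n_samples)
  N <- sum(sizes)
  panel <- simulate_panel(K, M, fst, seed = seed)
  truth <- simulate_individuals(
    panel, N, dirichlet_alpha = dirichlet_alpha, support = support,
    concentration = concentration, missing_rate = missing_rate,
    pseudo_haploid_fraction = pseudo_haploid_fraction, seed = seed + 1L)
  sample_map <- tibble(
    individual_id = rownames(truth$genotypes$dosages),
    sample_id = rep(sprintf("sample%02d", seq_len(n_samples)), sizes),
    group = "simulated")
  paths <- list(panel = file.path(dir, "panel.tsv"),
                vcf = file.path(dir, "genotypes.vcf"),
                sample_map = file.path(dir, "sample_map.tsv"),
                truth = file.path(dir, "q_true.tsv"))
  write_frequency_panel(panel, paths$panel)
  write_genotypes_vcf(truth$genotypes, paths$vcf)
  readr::write_tsv(sample_map, paths$sample_map)
  as_tibble(truth$q_true) |>
    mutate(individual_id = rownames(truth$q_true), .before = 1) |>
    readr::write_tsv(paths$truth)
  list(truth = truth, sample_map = sample_map, paths = paths)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype columns; the marker table's
#' `ref`/`alt` become REF/ALT, so the ALT allele count equals the stored
#' dosage. Pseudo-haploid individuals are written as haploid calls.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  m <- gm$markers
  inds <- rownames(gm$dosages)
  gt_code <- function(d, ph) {
    if (ph) c(`0` = "0", `2` = "1")[as.character(d)]
    else c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(d)]
  }
  cols <- vapply(inds, function(i) {
    ph <- gm$ploidy[[i]] == "pseudo_haploid"
    v <- gt_code(gm$dosages[i, ], ph)
    v[is.na(v)] <- if (ph) "." else "./."
    v
  }, character(nrow(m)))
  body <- cbind(m$chrom, m$pos, m$id, m$ref, m$alt, ".", ".", ".", "GT", cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", inds), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
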