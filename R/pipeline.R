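#' Run the full projection pipeline
#'
#' Orchestrates the stages end to end: read the frequency panel and VCF,
#' harmonize markers, project every individual, attach bootstrap standard
#' errors, aggregate individuals into sparsified sample profiles, and
#' (optionally) tabulate haplogroup composition. Writes:
#'
#' * `individual_estimates.tsv` — per (individual, ancestry) `q` and `se`;
#' * `sample_profiles.tsv` — wide per-sample table (`sample_id`, `size`,
#'   one column per ancestry, 3 decimals);
#' * `alignment_report.tsv` — marker harmonization tallies;
#' * `haplogroup_composition.tsv` — only when a haplogroup table and
#'   prefix queries are supplied;
#' * `run_log.txt` — seed, options, alignment and convergence summary.
#'
#' Re-running with the same inputs and seed reproduces the outputs
#' bit-identically.
#'
#' @param panel Path to the panel TSV (see [read_frequency_panel()]).
#' @param vcf Path to the genotype VCF.
#' @param sample_map Path to a TSV mapping `individual_id` to `sample_id`
#'   (extra columns carried through).
#' @param out_dir Output directory (created if needed).
#' @param haplo_table Optional path to a haplogroup CSV.
#' @param haplo_queries Optional tibble of queries with columns `label`,
#'   `locus`, `prefixes` (comma-separated string), and optionally `groups`
#'   (comma-separated).
#' @param B Bootstrap replicates (default 200).
#' @param seed Root seed for the bootstrap (default 1).
#' @param alpha Sparsification CI level (default 0.05).
#' @param opts A [projection_options()] list.
#' @return Invisibly, a list with `estimates`, `profiles`, `aligned`,
#'   `haplo` (NULL if not requested) and `paths`.
#' @export
run_pipeline <- function(panel, vcf, sample_map, out_dir,
                         haplo_table = NULL, haplo_queries = NULL,
                         B = 200, seed = 1, alpha = 0.05,
                         opts = projection_options()) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      abort(paste0("cannot create output directory: ", out_dir))
  log_lines <- c(paste0("seed: ", seed), paste0("B: ", B),
                 paste0("alpha: ", alpha),
                 paste0("tol: ", opts$tol), paste0("max_iter: ", opts$max_iter),
                 paste0("min_markers: ", opts$min_markers))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e))))
  }
  pan <- stage("read_panel", read_frequency_panel(panel))
  gm <- stage("read_vcf", read_genotypes_vcf(vcf))
  smap <- stage("read_sample_map",
                readr::read_tsv(sample_map, col_types = readr::cols(
                  .default = readr::col_character())))
  aligned <- stage("align", align_genotypes_to_panel(gm, pan))
  log_lines <- c(log_lines, "alignment:",
                 paste0("  ", aligned$report$category, ": ", aligned$report$n))
  est <- stage("project", project_cohort(aligned, opts))
  est <- stage("bootstrap", add_bootstrap_se(est, aligned, opts, B = B, seed = seed))
  gl <- est |> dplyr::distinct(.data$individual_id, .data$converged, .data$failed)
  log_lines <- c(log_lines,
                 paste0("individuals: ", nrow(gl),
                        " (failed: ", sum(gl$failed),
                        ", non-converged: ", sum(!gl$converged, na.rm = TRUE), ")"))
  prof <- stage("aggregate", aggregate_samples(est, smap, alpha = alpha))
  paths <- list(
    estimates = file.path(out_dir, "individual_estimates.tsv"),
    profiles = file.path(out_dir, "sample_profiles.tsv"),
    alignment = file.path(out_dir, "alignment_report.tsv"),
    log = file.path(out_dir, "run_log.txt"))
  write_individual_estimates(est, paths$estimates, B = B, seed = seed)
  write_sample_profiles(prof, paths$profiles)
  write_alignment_report(aligned, paths$alignment)
  haplo <- NULL
  if (!is.null(haplo_table) && !is.null(haplo_queries)) {
    ht <- stage("read_haplogroups", read_haplogroup_table(haplo_table))
    haplo <- stage("haplogroup_composition", purrr::pmap(haplo_queries, function(...) {
      qr <- list(...)
      grp <- if (!is.null(qr$groups) && !is.na(qr$groups))
        strsplit(qr$groups, ",")[[1]] else NULL
      haplogroup_composition(ht, locus = qr$locus,
                             prefixes = strsplit(qr$prefixes, ",")[[1]],
                             groups = grp) |>
        mutate(label = qr$label, .before = 1)
    }) |> bind_rows())
    paths$haplo <- file.path(out_dir, "haplogroup_composition.tsv")
    readr::write_tsv(haplo, paths$haplo)
  }
  writeLines(log_lines, paths$log)
  invisible(list(estimates = est, profiles = prof, aligned = aligned,
                 haplo = haplo, paths = paths))
}
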