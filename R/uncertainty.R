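#' Bootstrap standard errors for one individual's ancestry proportions
#'
#' Resamples the M aligned markers with replacement (columns of `dosages`
#' and `freqs` jointly), re-runs the projection for each replicate, and
#' reports the per-ancestry sample standard deviation over replicates
#' (denominator B - 1). Replicates whose resample has no usable marker are
#' redrawn, with a cap of `10 * B` total draws. Replicate fits start from
#' the point estimate: the likelihood is concave, so the start does not
#' change the optimum, only the iteration count.
#'
#' Reproducibility: replicate r draws from a deterministic stream derived
#' from `(seed, individual_id, r)`, so results do not depend on the order
#' in which individuals are processed.
#'
#' @inheritParams project_individual
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer root seed.
#' @param point Optional precomputed `ancestry_fit` for this individual.
#' @return An object of class `ancestry_boot`: list with `individual_id`,
#'   `replicates` (B x K matrix), `se` (length-K, named), `B`, `seed`.
#' @export
bootstrap_standard_errors <- function(dosages, freqs, ploidy = "diploid",
                                      opts = projection_options(), B = 200,
                                      seed = 1, individual_id = "individual",
                                      point = NULL) {
  if (B < 2) abort("B must be at least 2")
  freqs <- as.matrix(freqs)
  M <- ncol(freqs)
  if (is.null(point))
    point <- project_individual(dosages, freqs, ploidy, opts,
                                individual_id = individual_id)
  ok <- !is.na(dosages)
  # draw the B resamples (redrawing degenerate ones) from per-replicate
  # deterministic streams, then refit them all in compiled code
  idx <- matrix(0L, M, B)
  draws <- 0L
  for (r in seq_len(B)) {
    repeat {
      draws <- draws + 1L
      if (draws > 10L * B)
        abort(paste0("individual '", individual_id,
                     "': exceeded ", 10L * B, " bootstrap draws"))
      set.seed(replicate_seed(seed, individual_id, draws))
      cand <- sample.int(M, M, replace = TRUE)
      if (sum(ok[cand]) >= opts$min_markers) break
    }
    idx[, r] <- cand
  }
  sc_c <- if (ploidy == "pseudo_haploid") 1 else 2
  a_all <- ifelse(ok, dosages / (3 - sc_c), 0)
  p_all <- clamp_freqs(freqs, opts$freq_clamp)
  reps <- .em_bootstrap_cpp(a_all, p_all, sc_c, as.integer(ok), idx - 1L,
                            unname(point$q), opts$tol, opts$max_iter)
  colnames(reps) <- rownames(freqs)
  se <- apply(reps, 2, sd)
  structure(list(individual_id = individual_id, replicates = reps,
                 se = se, B = B, seed = seed),
            class = "ancestry_boot")
}

# deterministic 32-bit stream id from (seed, id, draw index)
replicate_seed <- function(seed, individual_id, r) {
  h <- 0
  for (k in utf8ToInt(individual_id)) h <- (h * 131 + k) %% 1014741823
  as.integer((h + seed * 7919 + r * 104729) %% 2147483647)
}

#' @export
print.ancestry_boot <- function(x, ...) {
  cat("<ancestry_boot> ", x$individual_id, ": B = ", x$B,
      ", seed = ", x$seed, "\n", sep = "")
  print(round(x$se, 4))
  invisible(x)
}

#' @describeIn bootstrap_standard_errors Tidy to one row per ancestry
#'   (`individual_id`, `ancestry`, `se`, `B`, `seed`).
#' @param x An `ancestry_boot`.
#' @param ... Unused.
#' @export
tidy.ancestry_boot <- function(x, ...) {
  tibble(individual_id = x$individual_id,
         ancestry = colnames(x$replicates) %||% paste0("K", seq_along(x$se)),
         se = unname(x$se), B = x$B, seed = x$seed)
}

#' Attach bootstrap standard errors to cohort estimates
#'
#' Runs [bootstrap_standard_errors()] for every non-failed individual in an
#' [project_cohort()] result and fills the `se` column.
#'
#' @param estimates An `ancestry_estimates` tibble from [project_cohort()].
#' @param aligned The `aligned_dataset` (or `truth_set`) the estimates were
#'   fitted from.
#' @inheritParams bootstrap_standard_errors
#' @return `estimates` with `se` filled for non-failed individuals.
#' @export
add_bootstrap_se <- function(estimates, aligned, opts = projection_options(),
                             B = 200, seed = 1) {
  gm <- if (inherits(aligned, "genotype_matrix")) aligned else aligned$genotypes
  freqs <- aligned_freqs(aligned)
  ok_ids <- unique(estimates$individual_id[!estimates$failed])
  ses <- purrr::map(ok_ids, function(id) {
    q <- estimates$proportion[estimates$individual_id == id]
    names(q) <- estimates$ancestry[estimates$individual_id == id]
    pt <- structure(list(individual_id = id, q = q), class = "ancestry_fit")
    bs <- bootstrap_standard_errors(gm$dosages[id, ], freqs,
                                    ploidy = gm$ploidy[[id]], opts = opts,
                                    B = B, seed = seed, individual_id = id,
                                    point = pt)
    tidy(bs)[c("individual_id", "ancestry", "se")]
  }) |> bind_rows()
  out <- estimates |>
    select(-"se") |>
    left_join(ses, by = c("individual_id", "ancestry")) |>
    dplyr::relocate("se", .after = "proportion")
  class(out) <- unique(c("ancestry_estimates", class(out)))
  out
}

#' Write per-individual estimates and standard errors to TSV
#'
#' One row per (individual, ancestry) with columns `individual_id`,
#' `ancestry`, `q`, `se`, `B`, `seed`.
#'
#' @param estimates An `ancestry_estimates` tibble (with `se` filled).
#' @param path Output path.
#' @param B,seed Bootstrap settings to record.
#' @return `path`, invisibly.
#' @export
write_individual_estimates <- function(estimates, path, B = NA, seed = NA) {
  estimates |>
    select(individual_id = "individual_id", ancestry = "ancestry",
           q = "proportion", se = "se") |>
    mutate(B = B, seed = seed) |>
    readr::write_tsv(path)
  invisible(path)
}
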