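#' Projection options
#'
#' Tuning parameters for the EM maximization of the supervised admixture
#' likelihood.
#'
#' @param tol Relative log-likelihood convergence threshold (per accepted
#'   EM step). Default `1e-6`.
#' @param max_iter Maximum EM iterations. Default 2000.
#' @param freq_clamp Panel frequencies are clamped into
#'   `[freq_clamp, 1 - freq_clamp]` before fitting; frequencies of exactly
#'   0 or 1 would otherwise make the log-likelihood unbounded. Default `1e-6`.
#' @param min_markers Minimum number of non-missing aligned markers required
#'   to attempt a fit. Default 100.
#' @return A list of class `projection_options`.
#' @export
projection_options <- function(tol = 1e-6, max_iter = 2000,
                               freq_clamp = 1e-6, min_markers = 100) {
  stopifnot(tol > 0, tol < 1, max_iter >= 1,
            freq_clamp > 0, freq_clamp < 0.5, min_markers >= 1)
  structure(list(tol = tol, max_iter = max_iter,
                 freq_clamp = freq_clamp, min_markers = min_markers),
            class = "projection_options")
}

clamp_freqs <- function(freqs, eps) pmin(pmax(freqs, eps), 1 - eps)

check_simplex <- function(q, K, tol = 1e-6) {
  if (length(q) != K || any(q < -tol) || abs(sum(q) - 1) > tol)
    abort("q must be a length-K vector on the probability simplex")
  q <- pmax(q, 0)
  q / sum(q)
}

# dosage -> (allele count a, alleles per marker c) on the likelihood scale
allele_scale <- function(dosages, ploidy) {
  if (ploidy == "pseudo_haploid") {
    if (any(dosages == 1, na.rm = TRUE))
      abort("pseudo-haploid dosages must be 0/2/NA")
    list(a = dosages / 2, c = 1)
  } else {
    list(a = dosages, c = 2)
  }
}

#' Log-likelihood of admixture proportions given fixed panel frequencies
#'
#' The binomial projection likelihood: with expected counted-allele
#' frequency `f_m = sum_k q_k p_km` at marker m, a non-missing diploid
#' dosage `g` contributes `g * log(f) + (2 - g) * log(1 - f)`; a
#' pseudo-haploid call contributes `(g/2) * log(f) + (1 - g/2) * log(1 - f)`.
#' Missing markers contribute 0.
#'
#' @param q Admixture proportions (length K, on the simplex).
#' @param dosages Length-M dosage vector (0/1/2, NA missing), aligned to the
#'   columns of `freqs`.
#' @param freqs K x M matrix of panel frequencies.
#' @param ploidy `"diploid"` or `"pseudo_haploid"`.
#' @param freq_clamp Clamp applied to `freqs` (see [projection_options()]).
#' @return The log-likelihood (0 when all markers are missing).
#' @export
admixture_log_likelihood <- function(q, dosages, freqs, ploidy = "diploid",
                                     freq_clamp = 1e-6) {
  freqs <- as.matrix(freqs)
  q <- check_simplex(q, nrow(freqs))
  ok <- !is.na(dosages)
  if (!any(ok)) return(0)
  sc <- allele_scale(dosages[ok], ploidy)
  p <- clamp_freqs(freqs[, ok, drop = FALSE], freq_clamp)
  f <- as.vector(crossprod(p, q))
  sum(sc$a * log(f) + (sc$c - sc$a) * log(1 - f))
}

#' One EM update of the admixture proportions
#'
#' The standard multinomial EM step for the projection likelihood:
#' `q_k' = (1/C) * sum_m [ a_m q_k p_km / f_m + (c - a_m) q_k (1 - p_km) / (1 - f_m) ]`
#' with `c = 2` and `a = g` for diploid data, `c = 1` and `a = g/2` for
#' pseudo-haploid data, and `C = c *` (number of non-missing markers).
#' Zero entries of `q` stay zero: the simplex boundary is absorbing.
#'
#' @inheritParams admixture_log_likelihood
#' @return Updated length-K vector on the simplex.
#' @export
admixture_em_update <- function(q, dosages, freqs, ploidy = "diploid",
                                freq_clamp = 1e-6) {
  freqs <- as.matrix(freqs)
  q <- check_simplex(q, nrow(freqs))
  ok <- !is.na(dosages)
  if (!any(ok)) return(q)
  sc <- allele_scale(dosages[ok], ploidy)
  p <- clamp_freqs(freqs[, ok, drop = FALSE], freq_clamp)
  f <- as.vector(crossprod(p, q))
  num <- q * (p %*% (sc$a / f) + (1 - p) %*% ((sc$c - sc$a) / (1 - f)))
  out <- as.vector(num) / (sc$c * sum(ok))
  out / sum(out)
}

#' Project one individual onto a fixed ancestry panel
#'
#' Maximizes the supervised admixture likelihood over the probability
#' simplex by EM, starting from the uniform vector `1/K` (the likelihood is
#' concave in `q` for fixed frequencies, so the start does not affect the
#' optimum).
#'
#' @inheritParams admixture_log_likelihood
#' @param opts A [projection_options()] list.
#' @param init Optional starting point on the simplex.
#' @param individual_id Id used in messages and the returned object.
#' @return An object of class `ancestry_fit`: a list with `individual_id`,
#'   `q` (named by ancestry when `freqs` has rownames), `log_likelihood`,
#'   `n_markers_used`, `n_iterations`, `converged`, and `se` (`NULL` until
#'   filled by [bootstrap_standard_errors()]).
#' @seealso [project_cohort()], [tidy.ancestry_fit()]
#' @export
project_individual <- function(dosages, freqs, ploidy = "diploid",
                               opts = projection_options(), init = NULL,
                               individual_id = "individual") {
  freqs <- as.matrix(freqs)
  K <- nrow(freqs)
  ok <- !is.na(dosages)
  n_used <- sum(ok)
  if (n_used < opts$min_markers)
    abort(paste0("individual '", individual_id, "': only ", n_used,
                 " non-missing markers (min_markers = ", opts$min_markers, ")"))
  q0 <- if (is.null(init)) rep(1 / K, K) else check_simplex(init, K)
  sc <- allele_scale(dosages[ok], ploidy)
  p <- clamp_freqs(freqs[, ok, drop = FALSE], opts$freq_clamp)
  fit <- .em_fit_cpp(sc$a, p, sc$c, q0, opts$tol, opts$max_iter)
  q <- as.vector(fit$q)
  names(q) <- rownames(freqs)
  structure(list(individual_id = individual_id, q = q,
                 log_likelihood = fit$log_likelihood,
                 n_markers_used = n_used,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged, se = NULL),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("<ancestry_fit> ", x$individual_id, ": ", length(x$q), " ancestries, ",
      x$n_markers_used, " markers, logLik ", format(x$log_likelihood),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  print(round(x$q[x$q > 1e-4], 3))
  invisible(x)
}

#' @describeIn project_individual Tidy a fit into one row per ancestry
#'   (`individual_id`, `ancestry`, `proportion`, `se`).
#' @param x An `ancestry_fit`.
#' @param ... Unused.
#' @export
tidy.ancestry_fit <- function(x, ...) {
  tibble(individual_id = x$individual_id,
         ancestry = names(x$q) %||% paste0("K", seq_along(x$q)),
         proportion = unname(x$q),
         se = if (is.null(x$se)) NA_real_ else unname(x$se))
}

#' @describeIn project_individual One-row fit summary.
#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble(individual_id = x$individual_id, log_likelihood = x$log_likelihood,
         n_markers_used = x$n_markers_used, n_iterations = x$n_iterations,
         converged = x$converged)
}

#' Project every individual of an aligned dataset
#'
#' Runs [project_individual()] per individual with that individual's own
#' missingness pattern and ploidy flag. Individuals that cannot be fitted
#' (e.g. fewer non-missing markers than `min_markers`) are returned as
#' flagged failed rows rather than aborting the cohort.
#'
#' @param aligned An `aligned_dataset` from [align_genotypes_to_panel()],
#'   or a `truth_set` from [simulate_individuals()].
#' @param opts A [projection_options()] list.
#' @return A tibble of class `ancestry_estimates`, one row per
#'   (individual, ancestry): `individual_id`, `ancestry`, `proportion`,
#'   `se` (NA until bootstrapped), plus per-individual columns
#'   `log_likelihood`, `n_markers_used`, `n_iterations`, `converged`,
#'   `failed`. Failed individuals carry NA proportions.
#' @export
project_cohort <- function(aligned, opts = projection_options()) {
  gm <- if (inherits(aligned, "genotype_matrix")) aligned else aligned$genotypes
  freqs <- aligned_freqs(aligned)
  anc <- rownames(freqs)
  inds <- rownames(gm$dosages)
  rows <- purrr::map(inds, function(id) {
    fit <- tryCatch(
      project_individual(gm$dosages[id, ], freqs, ploidy = gm$ploidy[[id]],
                         opts = opts, individual_id = id),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(individual_id = id, ancestry = anc, proportion = NA_real_,
             se = NA_real_, log_likelihood = NA_real_,
             n_markers_used = sum(!is.na(gm$dosages[id, ])),
             n_iterations = NA_integer_, converged = NA, failed = TRUE,
             message = conditionMessage(fit))
    } else {
      dplyr::cross_join(tidy(fit), glance(fit)[-1]) |>
        mutate(failed = FALSE, message = NA_character_)
    }
  })
  out <- bind_rows(rows)
  class(out) <- unique(c("ancestry_estimates", class(out)))
  out
}

aligned_freqs <- function(x) {
  if (!is.null(x$freqs)) return(x$freqs)
  panel_freq_matrix(x$panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
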