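#' DerSimonian-Laird between-individual variance
#'
#' Moment estimator of the between-unit variance tau^2 used by
#' random-effects inverse-variance weighting. With fixed-effect weights
#' `w_i = 1/se_i^2` and `Q = sum w_i (x_i - x_FE)^2`,
#' `tau2 = max(0, (Q - (n - 1)) / (sum w - sum w^2 / sum w))`.
#' A single estimate returns 0 by convention. Standard errors of exactly 0
#' (possible for boundary ancestries whose bootstrap replicates are all
#' zero) are floored at 1e-6 with a warning when n > 1.
#'
#' @param estimates Numeric vector of per-individual means.
#' @param ses Matching vector of standard errors.
#' @return Non-negative scalar tau^2.
#' @export
dl_between_variance <- function(estimates, ses) {
  n <- length(estimates)
  stopifnot(length(ses) == n, n >= 1)
  if (n == 1) return(0)
  # identical estimates truncate at 0 whatever the weights; covers the
  # all-boundary (se = 0 everywhere) ancestries without flooring noise
  if (length(unique(estimates)) == 1) return(0)
  if (any(ses <= 0)) {
    warn("standard errors of 0 floored at 1e-6 for weighting")
    ses <- pmax(ses, 1e-6)
  }
  w <- 1 / ses^2
  x_fe <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - x_fe)^2)
  max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Inverse-variance-weighted combination with a random-effects component
#'
#' Combines per-individual estimates of one ancestry proportion with
#' weights `w_i = 1 / (se_i^2 + tau2)`, where tau^2 is the
#' DerSimonian-Laird between-individual variance. A single estimate passes
#' through unchanged.
#'
#' @inheritParams dl_between_variance
#' @param tau2 Between-individual variance; default `NULL` estimates it by
#'   [dl_between_variance()]. Pass 0 for a fixed-effect combination.
#' @return One-row tibble with `mean`, `se`, `tau2`, `n`.
#' @export
ivw_combine <- function(estimates, ses, tau2 = NULL) {
  n <- length(estimates)
  if (n == 0) abort("ivw_combine: empty input")
  stopifnot(length(ses) == n)
  if (n == 1)
    return(tibble(mean = estimates, se = ses, tau2 = 0, n = 1L))
  if (all(ses == 0) && length(unique(estimates)) == 1)
    return(tibble(mean = estimates[1], se = 0, tau2 = 0, n = as.integer(n)))
  if (is.null(tau2)) tau2 <- dl_between_variance(estimates, ses)
  ses <- pmax(ses, 1e-6)
  w <- 1 / (ses^2 + tau2)
  tibble(mean = sum(w * estimates) / sum(w),
         se = sqrt(1 / sum(w)), tau2 = tau2, n = as.integer(n))
}

#' Sparsify a combined profile by 95% confidence interval and renormalize
#'
#' An ancestry is retained iff its two-sided normal CI excludes 0, i.e.
#' `mean_k - z * se_k > 0` with `z = qnorm(1 - alpha/2)`. Non-significant
#' entries are set to 0 and the rest renormalized to sum to 1. If nothing
#' is significant, the single largest mean is retained at 1 with a warning.
#'
#' @param means Length-K vector of combined means (>= 0).
#' @param ses Length-K vector of combined standard errors (>= 0).
#' @param alpha Two-sided test level; default 0.05 (z = 1.96).
#' @return Tibble with columns `significant` (logical) and `proportion`
#'   (zero where not significant; nonzero entries sum to 1).
#' @export
sparsify_and_renormalize <- function(means, ses, alpha = 0.05) {
  stopifnot(length(means) == length(ses), alpha > 0, alpha < 1)
  if (all(means == 0)) abort("all combined means are 0; nothing to sparsify")
  z <- qnorm(1 - alpha / 2)
  sig <- (means - z * ses) > 0
  if (!any(sig)) {
    warn("no ancestry significant at the given level; retaining the largest mean")
    sig <- seq_along(means) == which.max(means)
  }
  prop <- ifelse(sig, means, 0)
  prop <- prop / sum(prop)
  tibble(significant = sig, proportion = prop)
}

#' Combine per-individual estimates into sample-level profiles
#'
#' Per ancestry, individuals within a sample are combined by
#' inverse-variance weighting with a DerSimonian-Laird between-individual
#' variance component; the combined profile is then sparsified by
#' confidence interval and renormalized.
#'
#' @param estimates An `ancestry_estimates` tibble with `se` filled
#'   (see [add_bootstrap_se()]). Failed individuals are dropped.
#' @param sample_map Tibble mapping `individual_id` to `sample_id` (extra
#'   columns such as `group` are carried through).
#' @param alpha Level for the sparsification CI; default 0.05.
#' @return A tibble of class `sample_profiles`, one row per
#'   (sample, ancestry): `sample_id`, `n_individuals`, `ancestry`,
#'   `combined_mean`, `combined_se`, `tau2`, `significant`, `proportion`
#'   (plus any carried grouping columns).
#' @export
aggregate_samples <- function(estimates, sample_map, alpha = 0.05) {
  stopifnot(all(c("individual_id", "sample_id") %in% names(sample_map)))
  keep <- estimates |> filter(!.data$failed)
  if (nrow(keep) == 0) abort("no successfully fitted individuals to aggregate")
  anc_order <- unique(keep$ancestry)
  dat <- keep |> dplyr::inner_join(sample_map, by = "individual_id")
  extra <- setdiff(names(sample_map), c("individual_id", "sample_id"))
  combined <- dat |>
    group_by(dplyr::across(all_of(c("sample_id", extra, "ancestry")))) |>
    summarise(res = list(ivw_combine(.data$proportion, .data$se)),
              .groups = "drop") |>
    tidyr::unnest("res") |>
    rename(combined_mean = "mean", combined_se = "se", n_individuals = "n")
  out <- combined |>
    group_by(.data$sample_id) |>
    mutate(sparsify_and_renormalize(.data$combined_mean, .data$combined_se,
                                    alpha = alpha)) |>
    ungroup() |>
    mutate(ancestry = factor(.data$ancestry, levels = anc_order)) |>
    arrange(.data$sample_id, .data$ancestry) |>
    mutate(ancestry = as.character(.data$ancestry)) |>
    select(all_of(c("sample_id", extra, "n_individuals", "ancestry",
                    "combined_mean", "combined_se", "tau2",
                    "significant", "proportion")))
  class(out) <- unique(c("sample_profiles", class(out)))
  out
}

#' Size-weighted group summary of sample profiles
#'
#' Averages sparsified sample profiles over samples with weights equal to
#' the number of individuals per sample, then renormalizes to sum to 1.
#' This is the package's declared convention for period-level means; other
#' weightings (e.g. by combined variance) are possible and give different
#' numbers.
#'
#' @param profiles A tibble with columns `sample_id`, `ancestry`,
#'   `proportion` and either `n_individuals` or `size`.
#' @return Tibble with `ancestry` and `proportion` (sums to 1).
#' @export
summarize_group <- function(profiles) {
  size_col <- intersect(c("n_individuals", "size"), names(profiles))[1]
  if (is.na(size_col)) abort("profiles must carry n_individuals or size")
  chk <- profiles |> dplyr::count(.data$sample_id, .data$ancestry)
  if (any(chk$n > 1)) abort("duplicate (sample, ancestry) rows")
  per_sample <- profiles |> dplyr::count(.data$sample_id)
  n_anc <- length(unique(profiles$ancestry))
  if (any(per_sample$n != n_anc)) abort("ancestry labels differ across samples")
  out <- profiles |>
    group_by(.data$ancestry) |>
    summarise(proportion = sum(.data[[size_col]] * .data$proportion) /
                sum(.data[[size_col]]), .groups = "drop")
  out$proportion <- out$proportion / sum(out$proportion)
  out
}

#' Ratio of two ancestry proportions
#'
#' @param profile Tibble with `ancestry` and a proportion column
#'   (`proportion` or `percent`), or a named numeric vector.
#' @param numerator,denominator Ancestry labels.
#' @return The ratio (numerator / denominator). Summaries conventionally
#'   round it to one decimal.
#' @export
ancestry_ratio <- function(profile, numerator, denominator) {
  if (is.numeric(profile)) {
    v <- profile
  } else {
    col <- intersect(c("proportion", "percent"), names(profile))[1]
    if (is.na(col)) abort("profile must carry 'proportion' or 'percent'")
    v <- setNames(profile[[col]], profile$ancestry)
  }
  for (lbl in c(numerator, denominator))
    if (!lbl %in% names(v)) abort(paste0("ancestry '", lbl, "' not in profile"))
  den <- unname(v[denominator])
  if (den == 0) abort("denominator ancestry proportion is 0")
  unname(v[numerator]) / den
}

#' Write sample profiles in a wide per-sample table
#'
#' One row per sample: `sample_id`, `size`, then one column per ancestry
#' with the final sparsified proportions rounded to 3 decimals.
#'
#' @param profiles A `sample_profiles` tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sample_profiles <- function(profiles, path) {
  wide <- profiles |>
    mutate(proportion = round(.data$proportion, 3)) |>
    select(all_of(c("sample_id", "n_individuals", "ancestry", "proportion"))) |>
    rename(size = "n_individuals") |>
    tidyr::pivot_wider(names_from = "ancestry", values_from = "proportion")
  readr::write_tsv(wide, path)
  invisible(path)
}
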