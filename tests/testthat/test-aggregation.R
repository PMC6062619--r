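test_that("DerSimonian-Laird variance matches hand and metafor evaluations", {
  # w = 400 each; Q = 72; df = 2; denom = 1200 - 400 = 800 -> tau2 = 70/800
  est <- c(0.2, 0.5, 0.8); se <- rep(0.05, 3)
  expect_equal(dl_between_variance(est, se), 0.0875)
  rma <- metafor::rma(yi = est, sei = se, method = "DL")
  expect_equal(dl_between_variance(est, se), unname(rma$tau2), tolerance = 1e-10)
  # identical estimates truncate at 0; single estimate is 0 by convention
  expect_equal(dl_between_variance(rep(0.4, 5), runif(5, 0.01, 0.1)), 0)
  expect_equal(dl_between_variance(0.3, 0.1), 0)
  expect_warning(dl_between_variance(c(0.1, 0.2), c(0, 0.1)), "floored")
})

test_that("inverse-variance combination matches hand values and metafor", {
  # fixed-effect: (0.4/0.01 + 0.8/0.04) / (1/0.01 + 1/0.04) = 0.48
  fe <- ivw_combine(c(0.4, 0.8), c(0.1, 0.2), tau2 = 0)
  expect_equal(fe$mean, 0.48)
  expect_equal(fe$se, sqrt(1 / 125))
  # equal ses and tau2 = 0 reduce to the arithmetic mean
  x <- c(0.12, 0.5, 0.31, 0.07)
  eq <- ivw_combine(x, rep(0.08, 4), tau2 = 0)
  expect_equal(eq$mean, mean(x), tolerance = 1e-12)
  # random-effects route agrees with metafor's DL fit
  est <- c(0.2, 0.45, 0.7, 0.3); se <- c(0.04, 0.06, 0.05, 0.08)
  re <- ivw_combine(est, se)
  rma <- metafor::rma(yi = est, sei = se, method = "DL")
  expect_equal(re$mean, unname(as.numeric(rma$beta)), tolerance = 1e-10)
  expect_equal(re$se, unname(rma$se), tolerance = 1e-10)
  # single individual passes through
  one <- ivw_combine(0.61, 0.07)
  expect_equal(one$mean, 0.61)
  expect_equal(one$se, 0.07)
  expect_error(ivw_combine(numeric(0), numeric(0)), "empty")
})

test_that("an inflated se never increases that individual's influence", {
  others <- c(0.30, 0.35); ses_o <- c(0.05, 0.05)
  outlier <- 0.9
  pulls <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(s) {
    m <- ivw_combine(c(others, outlier), c(ses_o, s))$mean
    abs(m - ivw_combine(others, ses_o)$mean)
  }, numeric(1))
  expect_true(all(diff(pulls) <= 1e-12))
})

test_that("sparsification zeros wide-CI ancestries and renormalizes", {
  r1 <- sparsify_and_renormalize(c(0.5, 0.5), c(0.01, 0.30))
  expect_equal(r1$significant, c(TRUE, FALSE))
  expect_equal(r1$proportion, c(1, 0))
  # all CIs exclude 0 and means already sum to 1 -> unchanged
  r2 <- sparsify_and_renormalize(c(0.3, 0.7), c(0.01, 0.01))
  expect_equal(r2$proportion, c(0.3, 0.7))
  # derived case: drop the middle, renormalize 0.3 and 0.5
  r3 <- sparsify_and_renormalize(c(0.3, 0.2, 0.5), c(0.05, 0.15, 0.05))
  expect_equal(r3$proportion, c(0.375, 0, 0.625))
  # zero pattern always equals the significance mask
  expect_equal(r3$proportion == 0, !r3$significant)
  expect_equal(sum(r3$proportion), 1, tolerance = 1e-8)
  # nothing significant: keep the largest with a warning
  expect_warning(r4 <- sparsify_and_renormalize(c(0.4, 0.6), c(0.5, 0.9)),
                 "largest")
  expect_equal(r4$proportion, c(0, 1))
  expect_error(sparsify_and_renormalize(c(0, 0), c(0.1, 0.1)), "all combined")
})

test_that("aggregate_samples produces sparsified simplex profiles per sample", {
  panel <- simulate_panel(K = 4, M = 1500, fst = 0.15, seed = 61)
  ts <- simulate_individuals(panel, 6, support = c(1, 3), concentration = 3,
                             seed = 62)
  est <- add_bootstrap_se(project_cohort(ts), ts, B = 25, seed = 5)
  smap <- tibble::tibble(individual_id = rownames(ts$q_true),
                         sample_id = rep(c("sA", "sB"), each = 3))
  prof <- suppressWarnings(aggregate_samples(est, smap))
  sums <- tapply(prof$proportion, prof$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all((prof$proportion == 0) == !prof$significant))
  expect_true(all(prof$tau2 >= 0))
  expect_true(all(prof$combined_se >= 0))
  expect_equal(unique(prof$n_individuals), 3L)
})

test_that("group summaries are size-weighted and reproduce the farmer mean", {
  long <- ancient_profiles_long(subgroups = "early_farmers")
  expect_equal(sum(unique(long[c("sample_id", "size")])$size), 58)
  gs <- summarize_group(long)
  se <- gs$proportion[gs$ancestry == "Southern European"]
  expect_equal(se, 0.470, tolerance = 0.002)
  # single profile: identity up to renormalization
  one <- long |> dplyr::filter(sample_id == "LBK_EN")
  gs1 <- summarize_group(one)
  expect_equal(gs1$proportion[gs1$ancestry == "Southern European"],
               0.492 / sum(one$proportion), tolerance = 1e-8)
  # equal sizes: arithmetic mean of rows
  two <- tibble::tibble(sample_id = rep(c("a", "b"), each = 2),
                        ancestry = rep(c("x", "y"), 2),
                        proportion = c(0.2, 0.8, 0.6, 0.4),
                        size = 5L)
  gs2 <- summarize_group(two)
  expect_equal(gs2$proportion, c(0.4, 0.6))
})

test_that("ancestry ratios divide named components", {
  prof <- tibble::tibble(ancestry = c("a", "b"), proportion = c(0.6, 0.3))
  expect_equal(ancestry_ratio(prof, "a", "b"), 2)
  expect_equal(ancestry_ratio(prof, "a", "a"), 1)
  expect_error(ancestry_ratio(prof, "a", "zz"), "not in profile")
  expect_error(ancestry_ratio(c(a = 0.2, b = 0), "a", "b"), "denominator")
})
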