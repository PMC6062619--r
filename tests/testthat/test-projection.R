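test_that("log-likelihood matches hand-computed values and edge cases", {
  freqs <- rbind(c(0.9), c(0.1))
  # f = 0.5, g = 1 diploid: ln 0.5 + ln 0.5
  expect_equal(admixture_log_likelihood(c(0.5, 0.5), 1, freqs), 2 * log(0.5))
  # all markers missing contribute 0
  expect_equal(admixture_log_likelihood(c(0.5, 0.5), c(NA, NA),
                                        cbind(freqs, freqs)), 0)
  # K = 1 collapses to the binomial log-likelihood at p
  p <- c(0.3, 0.8, 0.6)
  g <- c(1, 2, 0)
  expect_equal(admixture_log_likelihood(1, g, matrix(p, nrow = 1)),
               sum(g * log(p) + (2 - g) * log(1 - p)))
  # pseudo-haploid: one allele per marker
  expect_equal(admixture_log_likelihood(1, c(2, 0), matrix(c(0.3, 0.8), 1),
                                        ploidy = "pseudo_haploid"),
               log(0.3) + log(1 - 0.8))
  expect_error(admixture_log_likelihood(c(0.9, 0.3), 1, freqs), "simplex")
})

test_that("EM update reproduces the hand-evaluated step and respects the boundary", {
  freqs <- rbind(c(0.9), c(0.1))
  expect_equal(admixture_em_update(c(0.5, 0.5), 2, freqs), c(0.9, 0.1))
  expect_equal(admixture_em_update(1, c(0, 1, 2), matrix(c(0.2, 0.5, 0.9), 1)), 1)
  # zero entries are absorbing
  upd <- admixture_em_update(c(1, 0), c(2, 1, 0), rbind(c(0.9, 0.5, 0.2),
                                                        c(0.2, 0.4, 0.9)))
  expect_equal(upd, c(1, 0))
  # updates stay on the simplex
  q <- c(0.2, 0.3, 0.5)
  fr <- matrix(runif(30, 0.1, 0.9), nrow = 3)
  upd <- admixture_em_update(q, rbinom(10, 2, 0.5), fr)
  expect_equal(sum(upd), 1, tolerance = 1e-12)
  expect_true(all(upd >= 0))
})

test_that("a single-source individual projects onto its ancestry", {
  panel <- simulate_panel(K = 4, M = 5000, fst = 0.1, seed = 31)
  q_true <- matrix(c(0, 0, 1, 0), nrow = 1)
  ts <- simulate_individuals(panel, 1, q_true = q_true, seed = 32)
  fit <- project_individual(ts$genotypes$dosages[1, ], ts$freqs)
  expect_true(fit$converged)
  expect_gte(fit$q[["anc03"]], 0.95)
})

test_that("compiled fit agrees with iterating the reference R update", {
  panel <- simulate_panel(K = 3, M = 300, fst = 0.2, seed = 33)
  ts <- simulate_individuals(panel, 1, dirichlet_alpha = c(1, 1, 1), seed = 34)
  g <- ts$genotypes$dosages[1, ]
  # the accelerated fit and the iterated reference R update reach the same
  # stationary point of the (concave) likelihood
  opts <- projection_options(tol = 1e-10, max_iter = 5000)
  fit <- project_individual(g, ts$freqs, opts = opts)
  q <- rep(1 / 3, 3)
  for (i in 1:20000) q <- admixture_em_update(q, g, ts$freqs)
  expect_equal(unname(fit$q), q, tolerance = 1e-3)
  expect_gte(fit$log_likelihood,
             admixture_log_likelihood(q, g, ts$freqs) - 1e-6)
})

test_that("log-likelihood is non-decreasing along the EM path", {
  panel <- simulate_panel(K = 3, M = 400, fst = 0.15, seed = 35)
  ts <- simulate_individuals(panel, 1, dirichlet_alpha = c(2, 1, 1), seed = 36)
  g <- ts$genotypes$dosages[1, ]
  q <- c(0.6, 0.3, 0.1)  # start at a deliberately wrong point
  ll <- admixture_log_likelihood(q, g, ts$freqs)
  for (i in 1:200) {
    q <- admixture_em_update(q, g, ts$freqs)
    ll_new <- admixture_log_likelihood(q, g, ts$freqs)
    expect_gte(ll_new, ll - 1e-9)
    ll <- ll_new
  }
  # initializing at the truth also never decreases the likelihood
  fit <- project_individual(g, ts$freqs, init = ts$q_true[1, ])
  expect_true(fit$converged)
  expect_gte(fit$log_likelihood,
             admixture_log_likelihood(ts$q_true[1, ], g, ts$freqs) - 1e-9)
})

test_that("EM solution matches the 0.001-resolution grid-search maximizer", {
  for (seed in c(101, 102, 103)) {
    panel <- simulate_panel(K = 2, M = 50, fst = 0.3, seed = seed)
    ts <- simulate_individuals(panel, 1, dirichlet_alpha = c(1, 1),
                               seed = seed + 50)
    g <- ts$genotypes$dosages[1, ]
    fit <- project_individual(g, ts$freqs,
                              opts = projection_options(tol = 1e-12,
                                                        max_iter = 20000,
                                                        min_markers = 10))
    q1_grid <- grid_search_q1(g, ts$freqs)
    expect_lt(abs(fit$q[[1]] - q1_grid), 1e-3)
  }
})

test_that("too few markers errors naming the individual; cohort isolates it", {
  panel <- simulate_panel(K = 2, M = 200, fst = 0.1, seed = 37)
  ts <- simulate_individuals(panel, 3, dirichlet_alpha = c(1, 1), seed = 38)
  g <- ts$genotypes$dosages[1, ]
  g[51:200] <- NA
  expect_error(project_individual(g, ts$freqs, individual_id = "bad_sample"),
               "bad_sample.*min_markers")
  # cohort: one all-missing individual is flagged, others unaffected
  ts$genotypes$dosages[2, ] <- NA
  est <- project_cohort(ts)
  expect_true(all(est$failed[est$individual_id == "ind002"]))
  expect_false(any(est$failed[est$individual_id != "ind002"]))
  solo <- project_individual(ts$genotypes$dosages[1, ], ts$freqs,
                             individual_id = "ind001")
  expect_equal(est$proportion[est$individual_id == "ind001"], unname(solo$q))
})

test_that("estimates are equivariant under ancestry permutation", {
  panel <- simulate_panel(K = 4, M = 800, fst = 0.1, seed = 39)
  ts <- simulate_individuals(panel, 1, dirichlet_alpha = rep(1, 4), seed = 40)
  g <- ts$genotypes$dosages[1, ]
  fit <- project_individual(g, ts$freqs)
  perm <- c(3, 1, 4, 2)
  fit_p <- project_individual(g, ts$freqs[perm, ])
  expect_equal(unname(fit_p$q), unname(fit$q[perm]), tolerance = 1e-8)
})

test_that("tidy and glance give the broom-shaped views of a fit", {
  panel <- simulate_panel(K = 3, M = 300, fst = 0.1, seed = 41)
  ts <- simulate_individuals(panel, 1, dirichlet_alpha = rep(1, 3), seed = 42)
  fit <- project_individual(ts$genotypes$dosages[1, ], ts$freqs,
                            individual_id = "x1")
  td <- tidy(fit)
  expect_named(td, c("individual_id", "ancestry", "proportion", "se"))
  expect_equal(sum(td$proportion), 1, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$individual_id, "x1")
  expect_true(gl$converged)
})
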