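# Luria-Delbruck machinery: pmf recursion, MLE, profile CIs, rate scaling,
# CI-overlap comparisons and culture selection.

test_that("the pmf recursion reproduces hand-evaluated values at m = 1", {
  p <- ld_pmf(1, 2)
  expect_equal(p[1], exp(-1), tolerance = 1e-12)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-12)
  expect_equal(p[3], 0.5 * (exp(-1) / 3 + exp(-1) / 4), tolerance = 1e-12)
  expect_error(ld_pmf(-1, 5), "non-negative")
})

test_that("the compiled recursion agrees with a pure-R evaluation", {
  for (m in c(0.3, 1, 4.7)) {
    expect_equal(ld_pmf(m, 200), mss_pmf_R(m, 200), tolerance = 1e-13)
  }
})

test_that("pmf partial sums stay below 1 and the tail thins at the 1/k rate", {
  # the Lea-Coulson tail is heavy: P(K > k) ~ m/k, so completeness is only
  # ever approached at the 1/k_max rate
  for (m in c(0.5, 2, 10)) {
    p2k <- ld_pmf(m, 2000)
    expect_true(all(p2k >= 0))
    expect_true(all(cumsum(p2k) <= 1 + 1e-12))
    expect_lt(1 - sum(p2k), 2 * m / 2000)
    expect_lt(1 - sum(ld_pmf(m, 4000)), 1 - sum(p2k))
  }
})

test_that("the MLE matches a fine grid search", {
  expect_equal(mle_m(rep(0, 10))$m_hat, 0)

  counts <- c(0, 0, 1, 3, 0, 2, 14, 0, 1, 0)
  fit <- mle_m(counts)
  expect_equal(fit$m_hat, grid_mle(counts), tolerance = 1e-3)

  # likelihood is unimodal on this fixture: no grid point beats the MLE
  grid <- seq(0.01, 5, by = 0.01)
  ll <- vapply(grid, function(m) {
    sum(log(pmax(ld_pmf(m, max(counts))[counts + 1], 1e-300)))
  }, numeric(1))
  expect_lte(max(ll), fit$loglik + 1e-6)
})

test_that("jackpot counts are capped with a warning", {
  expect_warning(fit <- mle_m(c(0, 1, 2, 50000)), "jackpot")
  expect_true(fit$jackpot)
})

test_that("profile intervals bracket the MLE and close in analytic cases", {
  counts <- c(0, 0, 1, 3, 0, 2, 14, 0, 1, 0)
  fit <- mle_m(counts)
  ci <- profile_ci(counts)
  expect_lte(ci[1], fit$m_hat)
  expect_gte(ci[2], fit$m_hat)

  # all-zero counts: loglik = -C m, so the upper bound is chisq/(2C)
  C <- 12
  ci0 <- profile_ci(rep(0, C))
  expect_equal(ci0[1], 0)
  expect_equal(ci0[2], qchisq(0.95, 1) / (2 * C), tolerance = 1e-6)

  # the chi-square drop at both bounds equals the 95% critical value
  ll <- function(m) sum(log(pmax(ld_pmf(m, max(counts))[counts + 1], 1e-300)))
  for (b in ci) {
    expect_equal(2 * (fit$loglik - ll(b)), qchisq(0.95, 1), tolerance = 1e-4)
  }
})

test_that("CI width shrinks as cultures accumulate", {
  widths <- vapply(c(15, 30, 60), function(nc) {
    w <- vapply(1:30, function(s) {
      sim <- simulate_fluctuation(fluctuation_sim_config(
        m_true = 2, n_final = 1e8, n_cultures = nc, seed = 1000 + s
      ))
      ci <- suppressWarnings(profile_ci(pmin(sim$count, 10000)))
      ci[2] - ci[1]
    }, numeric(1))
    median(w)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("rates scale as m over the final population size", {
  r <- loh_rate(2, c(1, 3), 1e8)
  expect_equal(r$rate, 2e-8)
  expect_equal(r$ci_low, 1e-8)
  expect_equal(r$ci_high, 3e-8)

  r2 <- loh_rate(2, c(1, 3), 1e9)
  expect_equal(r$rate / r2$rate, 10)
  expect_error(loh_rate(2, c(1, 3), 0), "positive")
})

test_that("fit_fluctuation bundles the pieces with tidy/glance methods", {
  sim <- simulate_fluctuation(fluctuation_sim_config(
    m_true = 2, n_final = 1e8, n_cultures = 15, seed = 83L
  ))
  fit <- fit_fluctuation(sim$count, sim$n_final)
  expect_s3_class(fit, "ld_fit")
  expect_equal(fit$rate, fit$m_hat / 1e8)
  expect_equal(fit$rate_ci, fit$m_ci / 1e8)

  td <- tidy(fit)
  expect_equal(td$rate, fit$rate)
  expect_true(td$ci_low <= td$rate & td$rate <= td$ci_high)
  gl <- glance(fit)
  expect_equal(gl$n_cultures, 15)
  expect_output(print(fit), "m_hat")
})

test_that("strain comparisons follow the CI-overlap rule", {
  mk <- function(rate, lo, hi) {
    structure(list(rate = rate, rate_ci = c(lo, hi)), class = "ld_fit")
  }
  cmp <- compare_to_reference(mk(3e-6, 2e-6, 4e-6), mk(1e-7, 5e-8, 2e-7))
  expect_equal(cmp$fold_change, 30)
  expect_true(cmp$significant)

  same <- compare_to_reference(mk(1e-7, 5e-8, 2e-7), mk(1e-7, 5e-8, 2e-7))
  expect_equal(same$fold_change, 1)
  expect_false(same$significant)

  expect_warning(und <- compare_to_reference(mk(1e-7, 5e-8, 2e-7), mk(0, 0, 1e-9)),
                 "fold change undefined")
  expect_true(is.na(und$fold_change))
})

test_that("analyze_fluctuation fits per strain and compares to the reference", {
  wt <- simulate_fluctuation(fluctuation_sim_config(
    m_true = 0.5, n_final = 1e8, n_cultures = 15, seed = 89L
  ))
  mut <- simulate_fluctuation(fluctuation_sim_config(
    m_true = 10, n_final = 1e8, n_cultures = 15, seed = 97L
  ))
  tab <- dplyr::bind_rows(
    dplyr::mutate(wt, strain_id = "BY4743"),
    dplyr::mutate(mut, strain_id = "mutant")
  )
  res <- analyze_fluctuation(tab, reference = "BY4743")
  expect_equal(nrow(res), 2)
  expect_equal(res$fold_vs_reference[res$strain_id == "BY4743"], 1)
  expect_false(res$significant[res$strain_id == "BY4743"])
  expect_gt(res$fold_vs_reference[res$strain_id == "mutant"], 1)
  expect_true(res$significant[res$strain_id == "mutant"])
  expect_error(analyze_fluctuation(tab, reference = "nope"), "reference strain")
})

test_that("culture selection keeps the readings nearest the eligible median", {
  withr::with_seed(103, {
    od <- c(runif(15, 0.6, 2.5), runif(9, 0.1, 0.5))
    expect_equal(select_cultures(od), sort(which(od > 0.5)))
  })

  expect_equal(select_cultures(rep(1, 24)), 1:15) # ties by input order

  od <- seq(0.6, 2.9, by = 0.1)
  sel <- select_cultures(od)
  dev <- abs(od - median(od))
  subsets <- utils::combn(24, 15)
  best <- min(colSums(matrix(dev[subsets], nrow = 15)))
  expect_equal(sum(dev[sel]), best)

  expect_error(select_cultures(c(0.6, 0.7, 0.2), n_keep = 3), "above 0.5")
})
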