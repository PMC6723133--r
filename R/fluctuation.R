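# Luria-Delbruck fluctuation analysis: Lea-Coulson pmf via the
# Ma-Sandri-Sarkar recursion, maximum-likelihood mutation number,
# profile-likelihood confidence intervals, LOH rates and CI-overlap
# significance calls.

#' Lea-Coulson (Luria-Delbruck) probability mass function
#'
#' Probabilities of observing 0..`k_max` mutant colonies in a culture with
#' expected mutation number `m`, by the Ma-Sandri-Sarkar recursion:
#' `p_0 = exp(-m)`, `p_n = (m/n) * sum_{j<n} p_j / (n - j + 1)`.
#'
#' @param m Expected mutations per culture (non-negative).
#' @param k_max Largest count to evaluate.
#' @return Numeric vector of length `k_max + 1` (probabilities for counts
#'   `0:k_max`).
#' @examples
#' ld_pmf(1, 2)  # 0.36788, 0.18394, 0.10730
#' @export
ld_pmf <- function(m, k_max) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0) {
    abort("`m` must be a single non-negative number")
  }
  k_max <- check_count(k_max, "k_max")
  ld_pmf_cpp(m, k_max)
}

# Cap jackpot cultures so the quadratic recursion stays tractable; capped
# counts are still a strong signal of large m (they sit in the extreme tail).
cap_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0 || anyNA(counts) ||
      any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be non-negative integers")
  }
  jackpot <- counts > LD_JACKPOT_CAP
  if (any(jackpot)) {
    warn(paste0(sum(jackpot), " jackpot culture(s) with count > ", LD_JACKPOT_CAP,
                " capped before likelihood evaluation"))
    counts[jackpot] <- LD_JACKPOT_CAP
  }
  list(counts = counts, jackpot = any(jackpot))
}

ld_loglik <- function(counts, m) {
  if (m == 0) {
    return(if (all(counts == 0)) 0 else -Inf)
  }
  p <- ld_pmf(m, max(counts))
  sum(log(pmax(p[counts + 1], 1e-300)))
}

#' Maximum-likelihood mutation number
#'
#' Maximises the Lea-Coulson log-likelihood of per-culture mutant counts over
#' `m`, with the pmf truncated at the largest observed count. The optimiser is
#' a bracketed golden-section/parabolic search (absolute tolerance 1e-6 on
#' `m`), started near the p0-method estimate `-log(zero fraction)` when zeros
#' are present; the bracket is widened until the maximum is interior.
#'
#' @param counts Non-negative integer mutant counts, one per culture. Counts
#'   above 10^4 are capped with a jackpot warning.
#' @return List with `m_hat` and `loglik` (log-likelihood at the maximum).
#' @export
mle_m <- function(counts) {
  capped <- cap_counts(counts)
  counts <- capped$counts
  if (all(counts == 0)) {
    return(list(m_hat = 0, loglik = 0, jackpot = capped$jackpot))
  }
  zero_frac <- mean(counts == 0)
  m0 <- if (zero_frac > 0) -log(zero_frac) else max(0.1, log1p(mean(counts)))
  upper <- max(1, 4 * m0)
  f <- function(m) ld_loglik(counts, m)
  while (f(upper) > f(0.5 * upper) && upper < 1e4) upper <- upper * 2
  opt <- optimize(f, interval = c(1e-9, upper), maximum = TRUE, tol = 1e-6)
  list(m_hat = opt$maximum, loglik = opt$objective, jackpot = capped$jackpot)
}

#' Profile-likelihood confidence interval for the mutation number
#'
#' Bounds are the values of `m` at which twice the log-likelihood drop from the
#' maximum equals the chi-square(1) quantile (3.841 at `alpha = 0.05`), found
#' by bisection on each side of the MLE; the lower bound is clipped at 0. With
#' all-zero counts the likelihood is `exp(-C m)` and the interval is
#' `[0, qchisq(1 - alpha, 1) / (2 C)]`.
#'
#' @inheritParams mle_m
#' @param alpha Two-sided miscoverage (0.05 for a 95% interval).
#' @return Numeric vector `c(m_low, m_high)`.
#' @export
profile_ci <- function(counts, alpha = 0.05) {
  capped <- cap_counts(counts)
  counts <- capped$counts
  fit <- suppressWarnings(mle_m(counts))
  crit <- qchisq(1 - alpha, df = 1) / 2
  target <- fit$loglik - crit
  f <- function(m) ld_loglik(counts, m)

  bisect <- function(lo, hi, increasing) {
    # find m with f(m) = target; f monotone on the chosen side of the MLE
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
      if (hi - lo < 1e-9 * max(1, hi)) break
    }
    (lo + hi) / 2
  }

  if (fit$m_hat == 0 || all(counts == 0)) {
    m_low <- 0
    m_high <- if (all(counts == 0)) {
      crit / length(counts) # closed form: loglik(m) = -C m
    } else {
      hi <- 1
      while (f(hi) > target) hi <- hi * 2
      bisect(0, hi, increasing = FALSE)
    }
    return(c(m_low, m_high))
  }

  m_low <- if (f(1e-12) > target) 0 else bisect(1e-12, fit$m_hat, increasing = TRUE)
  hi <- fit$m_hat * 2
  while (f(hi) > target && hi < 1e6) hi <- hi * 2
  m_high <- bisect(fit$m_hat, hi, increasing = FALSE)
  c(m_low, m_high)
}

#' Convert a mutation number and CI to an LOH rate
#'
#' Rates follow the final-population convention: `rate = m / n_final`, events
#' per cell per generation.
#'
#' @param m_hat MLE mutation number.
#' @param ci Numeric `c(m_low, m_high)` on the m scale.
#' @param n_final Final cells per culture (mean taken when a vector).
#' @return One-row tibble: `m_hat`, `rate`, `ci_low`, `ci_high`, `n_final`.
#' @export
loh_rate <- function(m_hat, ci, n_final) {
  if (any(n_final <= 0)) abort("`n_final` must be positive")
  nf <- mean(n_final)
  tibble(m_hat = m_hat, rate = m_hat / nf,
         ci_low = ci[1] / nf, ci_high = ci[2] / nf, n_final = nf)
}

#' Fit a fluctuation experiment
#'
#' Bundles [mle_m()], [profile_ci()] and [loh_rate()]: maximum-likelihood
#' mutation number, profile-likelihood CI, and the rate scale.
#'
#' @inheritParams mle_m
#' @param n_final Final population size per culture (scalar or per-culture
#'   vector; the mean is used for the rate conversion).
#' @param alpha Miscoverage for the CI (default 0.05).
#' @return An object of class `ld_fit` with elements `counts`, `n_cultures`,
#'   `n_final`, `m_hat`, `loglik`, `m_ci`, `rate`, `rate_ci`, `alpha`,
#'   `jackpot`. Has [tidy()], [glance()], `print()` and [ggplot2::autoplot()]
#'   methods.
#' @export
fit_fluctuation <- function(counts, n_final, alpha = 0.05) {
  capped <- cap_counts(counts)
  counts <- capped$counts
  fit <- suppressWarnings(mle_m(counts))
  fit$jackpot <- fit$jackpot || capped$jackpot
  ci <- suppressWarnings(profile_ci(counts, alpha = alpha))
  nf <- mean(n_final)
  if (nf <= 0) abort("`n_final` must be positive")
  if (nf <= max(counts)) {
    warn("`n_final` does not exceed the largest mutant count")
  }
  structure(
    list(
      counts = counts,
      n_cultures = length(counts),
      n_final = nf,
      m_hat = fit$m_hat,
      loglik = fit$loglik,
      m_ci = ci,
      rate = fit$m_hat / nf,
      rate_ci = ci / nf,
      alpha = alpha,
      jackpot = fit$jackpot
    ),
    class = "ld_fit"
  )
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("Luria-Delbruck fluctuation fit\n")
  cat(sprintf("  cultures: %d, N_final: %.4g\n", x$n_cultures, x$n_final))
  cat(sprintf("  m_hat: %.4g  [%.4g, %.4g] (%.0f%% profile CI)\n",
              x$m_hat, x$m_ci[1], x$m_ci[2], 100 * (1 - x$alpha)))
  cat(sprintf("  rate:  %.4g  [%.4g, %.4g] per cell per generation\n",
              x$rate, x$rate_ci[1], x$rate_ci[2]))
  if (x$jackpot) cat("  (jackpot counts capped)\n")
  invisible(x)
}

#' Tidy a fluctuation fit
#'
#' @param x An `ld_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `m_hat`, `m_ci_low`, `m_ci_high`, `rate`, `ci_low`,
#'   `ci_high`.
#' @export
tidy.ld_fit <- function(x, ...) {
  tibble(
    m_hat = x$m_hat, m_ci_low = x$m_ci[1], m_ci_high = x$m_ci[2],
    rate = x$rate, ci_low = x$rate_ci[1], ci_high = x$rate_ci[2]
  )
}

#' Glance at a fluctuation fit
#'
#' @param x An `ld_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n_cultures`, `n_final`, `logLik`, `alpha`,
#'   `jackpot`.
#' @export
glance.ld_fit <- function(x, ...) {
  tibble(n_cultures = x$n_cultures, n_final = x$n_final, logLik = x$loglik,
         alpha = x$alpha, jackpot = x$jackpot)
}

#' Compare a strain's LOH rate to a reference strain
#'
#' Fold change is the ratio of point rates; the significance call follows the
#' CI-overlap rule: rates are significantly different when the two
#' confidence intervals are disjoint.
#'
#' @param test,ref `ld_fit` objects (see [fit_fluctuation()]).
#' @return One-row tibble: `fold_change`, `significant`.
#' @export
compare_to_reference <- function(test, ref) {
  stopifnot(inherits(test, "ld_fit"), inherits(ref, "ld_fit"))
  fold <- if (ref$rate == 0) {
    warn("reference rate is 0; fold change undefined")
    NA_real_
  } else {
    test$rate / ref$rate
  }
  disjoint <- test$rate_ci[1] > ref$rate_ci[2] || test$rate_ci[2] < ref$rate_ci[1]
  tibble(fold_change = fold, significant = disjoint)
}

#' Fit fluctuation experiments for a table of strains
#'
#' Data-frame-first wrapper over [fit_fluctuation()]: one fit per strain, with
#' optional fold change and CI-overlap significance against a reference strain.
#'
#' @param data Tibble with columns `strain_id`, `count`, `n_final` (one row per
#'   culture).
#' @param reference Optional `strain_id` used as the comparison baseline.
#' @param alpha Miscoverage for the CIs.
#' @return Tibble with one row per strain: `m_hat`, `rate`, `ci_low`,
#'   `ci_high`, and — when `reference` is given — `fold_vs_reference` and
#'   `significant`.
#' @export
analyze_fluctuation <- function(data, reference = NULL, alpha = 0.05) {
  data <- as_tibble(data)
  stopifnot(all(c("strain_id", "count", "n_final") %in% names(data)))
  fits <- purrr::map(split(data, data$strain_id), function(d) {
    fit_fluctuation(d$count, d$n_final, alpha = alpha)
  })
  out <- purrr::imap_dfr(fits, function(fit, id) {
    dplyr::bind_cols(tibble(strain_id = id, n_cultures = fit$n_cultures),
                     tidy(fit)[c("m_hat", "rate", "ci_low", "ci_high")])
  })
  if (!is.null(reference)) {
    if (!reference %in% names(fits)) {
      abort(paste0("reference strain not in data: ", reference))
    }
    cmp <- purrr::map_dfr(fits, compare_to_reference, ref = fits[[reference]])
    out$fold_vs_reference <- cmp$fold_change
    out$significant <- cmp$significant
  }
  out
}

#' Select similarly sized cultures by optical density
#'
#' Keeps the `n_keep` cultures whose OD readings are closest to the median of
#' all readings above `od_min` (the study kept the 15 most similar of 24
#' colonies with absorbance above 0.5). Ties are broken by input order.
#'
#' @param od Numeric vector of OD readings, in culture order.
#' @param n_keep Number of cultures to keep.
#' @param od_min Minimum eligible reading (exclusive).
#' @return Sorted integer indices into `od` of the selected cultures.
#' @export
select_cultures <- function(od, n_keep = 15L, od_min = 0.5) {
  n_keep <- check_count(n_keep, "n_keep", min = 1L)
  eligible <- which(od > od_min)
  if (length(eligible) < n_keep) {
    abort(paste0("only ", length(eligible), " readings above ", od_min,
                 "; need ", n_keep))
  }
  dev <- abs(od[eligible] - median(od[eligible]))
  keep <- eligible[order(dev, seq_along(eligible))[seq_len(n_keep)]]
  sort(keep)
}
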