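# Two-screen overlap statistics: expected overlap, representation factor and
# directional hypergeometric tail probabilities.

check_overlap_args <- function(n1, n2, N, k = NULL) {
  vals <- list(n1 = n1, n2 = n2, N = N)
  if (!is.null(k)) vals$k <- k
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort(paste0("`", nm, "` must be a single non-negative integer"))
    }
  }
  if (N < 1) abort("`N` must be positive")
  if (n1 < 1 || n2 < 1 || n1 > N || n2 > N) abort("need 0 < n1, n2 <= N")
  if (!is.null(k)) {
    if (k > min(n1, n2)) abort("`k` cannot exceed min(n1, n2)")
    if (k < max(0, n1 + n2 - N)) abort("`k` below the hypergeometric support")
  }
  invisible(NULL)
}

#' Expected overlap between two hit lists
#'
#' Under independent draws from a common background of `N` genes, two lists of
#' sizes `n1` and `n2` share `n1 * n2 / N` genes in expectation.
#'
#' @param n1,n2 Hit-list sizes.
#' @param N Background (total genes screened by both studies).
#' @return Expected number of shared genes.
#' @examples
#' expected_overlap(217, 332, 6477)
#' @export
expected_overlap <- function(n1, n2, N) {
  check_overlap_args(n1, n2, N)
  n1 * n2 / N
}

#' Representation factor of an observed overlap
#'
#' Observed shared genes divided by the expected overlap `n1 * n2 / N`. Values
#' above 1 indicate more overlap between the two screens than chance predicts.
#' Rounding to one decimal happens only at report time.
#'
#' @param k Observed overlap.
#' @inheritParams expected_overlap
#' @return Representation factor (dimensionless).
#' @examples
#' round(representation_factor(26, 217, 332, 6477), 1) # 2.3
#' @export
representation_factor <- function(k, n1, n2, N) {
  check_overlap_args(n1, n2, N, k)
  k / expected_overlap(n1, n2, N)
}

# Directional tail by summation of hypergeometric pmf terms.
hyper_tail <- function(k, n1, n2, N, upper) {
  support <- max(0, n1 + n2 - N):min(n1, n2)
  xs <- if (upper) support[support >= k] else support[support <= k]
  sum(dhyper(xs, n1, N - n1, n2))
}

normal_tail <- function(k, n1, n2, N, upper, continuity) {
  mu <- n1 * n2 / N
  sigma <- sqrt(n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1)))
  cc <- if (continuity) 0.5 else 0
  if (upper) pnorm((k - cc - mu) / sigma, lower.tail = FALSE)
  else pnorm((k + cc - mu) / sigma)
}

#' Directional overlap tail probability
#'
#' Tail probability for the observed overlap `k` under
#' `X ~ Hypergeometric(N, n1, n2)`. The tail direction follows the sign of the
#' departure from expectation: `P(X >= k)` when `k >= n1*n2/N` (enrichment),
#' `P(X <= k)` otherwise (depletion). The default method sums exact pmf terms;
#' normal approximations (with and without continuity correction) are provided
#' for comparison only.
#'
#' @inheritParams representation_factor
#' @param method `"exact"` (default), `"normal"` or `"normal-cc"`.
#' @return List with `p` and `tail` (`"upper"` or `"lower"`).
#' @examples
#' overlap_pvalue(26, 217, 332, 6477) # p = 3.995e-5, upper tail
#' @export
overlap_pvalue <- function(k, n1, n2, N,
                           method = c("exact", "normal", "normal-cc")) {
  check_overlap_args(n1, n2, N, k)
  method <- match.arg(method)
  upper <- k >= expected_overlap(n1, n2, N)
  p <- switch(method,
    "exact" = hyper_tail(k, n1, n2, N, upper),
    "normal" = normal_tail(k, n1, n2, N, upper, continuity = FALSE),
    "normal-cc" = normal_tail(k, n1, n2, N, upper, continuity = TRUE)
  )
  list(p = min(p, 1), tail = if (upper) "upper" else "lower")
}

#' Compare two screens' hit lists on a common background
#'
#' Restricts both hit lists to the supplied background, counts the overlap and
#' returns the full overlap statistics row (the layout of the multi-screen
#' comparison table: list sizes, background, expected overlap, representation
#' factor, directional tail p).
#'
#' @param hits1,hits2 Character vectors of hit gene ids.
#' @param background Character vector of all genes screened by both studies.
#' @param method Passed to [overlap_pvalue()].
#' @return One-row tibble: `k`, `n1`, `n2`, `N`, `expected`, `rf`, `p`, `tail`.
#' @export
compare_screens <- function(hits1, hits2, background,
                            method = c("exact", "normal", "normal-cc")) {
  offenders <- setdiff(union(hits1, hits2), background)
  if (length(offenders) > 0) {
    abort(paste0("hit genes absent from the background: ",
                 paste(utils::head(offenders, 10), collapse = ", "),
                 if (length(offenders) > 10) ", ..." else ""))
  }
  h1 <- intersect(unique(hits1), background)
  h2 <- intersect(unique(hits2), background)
  k <- length(intersect(h1, h2))
  n1 <- length(h1)
  n2 <- length(h2)
  N <- length(unique(background))
  pv <- overlap_pvalue(k, n1, n2, N, method = match.arg(method))
  tibble(
    k = k, n1 = n1, n2 = n2, N = N,
    expected = expected_overlap(n1, n2, N),
    rf = representation_factor(k, n1, n2, N),
    p = pv$p, tail = pv$tail
  )
}
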