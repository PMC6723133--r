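# Independent oracles used across the suite. Each deliberately takes a
# different route than the package implementation.

# Hypergeometric tail by direct combinatorial counting with choose():
# P(X >= k) = sum_x C(n1, x) C(N - n1, n2 - x) / C(N, n2).
hyper_tail_count <- function(k, n1, n2, N, upper = TRUE) {
  support <- max(0, n1 + n2 - N):min(n1, n2)
  xs <- if (upper) support[support >= k] else support[support <= k]
  sum(choose(n1, xs) * choose(N - n1, n2 - xs)) / choose(N, n2)
}

# Hypergeometric tail by exhaustive enumeration of every C(N, n2) draw.
hyper_tail_enum <- function(k, n1, n2, N, upper = TRUE) {
  draws <- utils::combn(N, n2)
  overlaps <- colSums(draws <= n1) # genes 1..n1 are the first list
  if (upper) mean(overlaps >= k) else mean(overlaps <= k)
}

# Literal Benjamini-Hochberg step-up: walk ranks from largest down, reject
# everything at or below the first passing rank.
bh_stepup_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  k_star <- 0L
  for (i in m:1) {
    if (sorted[i] <= i / m * q) {
      k_star <- i
      break
    }
  }
  rejected <- logical(m)
  if (k_star > 0) rejected[ord[seq_len(k_star)]] <- TRUE
  rejected
}

# Brute-force positional scan: enumerate every O(G^2) interval per chromosome,
# keep the hit-delimited ones, score with phyper, apply the same adjustment,
# filters and containment collapse as pge_scan, using none of its code.
pge_scan_brute <- function(hits, loci, alpha_adj = 0.01, min_hits = 3L,
                           adjust = "bonferroni", collapse = TRUE) {
  loci <- dplyr::arrange(loci, chrom, start)
  loci <- dplyr::mutate(dplyr::group_by(loci, chrom),
                        ordinal = dplyr::row_number())
  loci <- dplyr::ungroup(loci)
  N <- nrow(loci)
  K <- sum(loci$gene_id %in% hits)
  rows <- list()
  for (ch in unique(loci$chrom)) {
    lc <- loci[loci$chrom == ch, ]
    G <- nrow(lc)
    for (i in seq_len(G)) {
      for (j in i:G) {
        if (!(lc$gene_id[i] %in% hits) || !(lc$gene_id[j] %in% hits)) next
        genes <- lc[i:j, ]
        a <- sum(genes$gene_id %in% hits)
        n <- nrow(genes)
        p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, i = i, j = j, bp_start = min(genes$start),
          bp_end = max(genes$end), orf_total = n, hit_count = a, p_raw = p
        )
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  cand <- do.call(rbind, rows)
  m <- nrow(cand)
  cand$p_adj <- if (adjust == "bonferroni") pmin(1, cand$p_raw * m) else
    stats::p.adjust(cand$p_raw, method = "BH")
  keep <- cand[cand$p_adj < alpha_adj & cand$hit_count >= min_hits, ]
  if (collapse && nrow(keep) > 1) {
    drop <- rep(FALSE, nrow(keep))
    for (a_i in seq_len(nrow(keep))) {
      for (b_i in seq_len(nrow(keep))) {
        if (a_i == b_i) next
        if (keep$chrom[b_i] != keep$chrom[a_i]) next
        nested <- (keep$i[b_i] >= keep$i[a_i] && keep$j[b_i] <= keep$j[a_i]) ||
          (keep$i[b_i] <= keep$i[a_i] && keep$j[b_i] >= keep$j[a_i])
        wa <- keep$j[a_i] - keep$i[a_i]
        wb <- keep$j[b_i] - keep$i[b_i]
        if (nested && wa != wb &&
            (keep$p_adj[b_i] < keep$p_adj[a_i] ||
             (keep$p_adj[b_i] == keep$p_adj[a_i] && wb < wa))) {
          drop[a_i] <- TRUE
        }
      }
    }
    keep <- keep[!drop, ]
  }
  keep[order(keep$p_adj, keep$chrom, keep$bp_start), ]
}

# Pure-R Ma-Sandri-Sarkar recursion, mirroring the definition not the kernel.
mss_pmf_R <- function(m, k_max) {
  p <- numeric(k_max + 1)
  p[1] <- exp(-m)
  for (n in seq_len(k_max)) {
    j <- 0:(n - 1)
    p[n + 1] <- (m / n) * sum(p[j + 1] / (n - j + 1))
  }
  p
}

# Two-stage grid search for the Lea-Coulson MLE: coarse sweep of [lo, hi],
# then a 1e-4-step grid around the best coarse point.
grid_mle <- function(counts, lo = 0, hi = 5) {
  ll <- function(m) {
    if (m == 0) return(if (all(counts == 0)) 0 else -Inf)
    p <- lohscreen::ld_pmf(m, max(counts))
    sum(log(pmax(p[counts + 1], 1e-300)))
  }
  coarse <- seq(max(lo, 1e-4), hi, by = 0.005)
  best <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(lo, best - 0.01), best + 0.01, by = 1e-4)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# A small fully separable screen fixture: hits always score ++++,
# background never grows.
separable_screen <- function(n_strains = 40, n_hits = 6, seed = 11) {
  lohscreen::simulate_screen(lohscreen::screen_sim_config(
    n_strains = n_strains, n_hit_strains = n_hits,
    hit_score_distribution = c(0, 0, 0, 0, 1),
    background_score_distribution = c(1, 0, 0, 0, 0),
    false_positive_rate = 0, lawn_strain_fraction = 0, seed = seed
  ))
}
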