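# Positional gene enrichment: candidate enumeration, region scoring and the
# full scan against a brute-force all-intervals oracle.

toy_loci <- function(n = 50, chrom = "chr1") {
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", chrom, 1:n),
    chrom = chrom,
    start = (0:(n - 1)) * 2000 + 1,
    end = (0:(n - 1)) * 2000 + 1500
  )
}

test_that("candidate regions are exactly the hit-delimited intervals", {
  loci <- toy_loci(50)
  expect_equal(nrow(enumerate_candidate_regions(character(0), loci)), 0)

  hits <- loci$gene_id[c(5, 20, 33)]
  cand <- enumerate_candidate_regions(hits, loci)
  expect_equal(nrow(cand), 3 * 4 / 2)
  expect_true(all(cand$first_gene %in% hits & cand$last_gene %in% hits))

  # brute force: all O(G^2) intervals filtered to hit-delimited endpoints
  all_int <- expand.grid(i = 1:50, j = 1:50)
  all_int <- all_int[all_int$i <= all_int$j, ]
  keep <- all_int[all_int$i %in% c(5, 20, 33) & all_int$j %in% c(5, 20, 33), ]
  expect_setequal(paste(cand$start_ordinal, cand$end_ordinal),
                  paste(keep$i, keep$j))

  expect_error(enumerate_candidate_regions("not_a_gene", loci),
               "without coordinates")
})

test_that("region scores are upper hypergeometric tails", {
  loci <- toy_loci(100)
  hits <- loci$gene_id[c(1:3, 40, 55, 60, 71, 80, 90, 99)] # 10 hits

  whole <- tibble::tibble(chrom = "chr1", start_ordinal = 1, end_ordinal = 100)
  expect_equal(score_region(whole, hits, loci)$p_raw, 1)

  empty <- tibble::tibble(chrom = "chr1", start_ordinal = 10, end_ordinal = 19)
  expect_equal(score_region(empty, hits, loci)$p_raw, 1)

  region <- tibble::tibble(chrom = "chr1", start_ordinal = 1, end_ordinal = 10)
  scored <- score_region(region, hits, loci)
  expect_equal(scored$hit_count, 3)
  expect_equal(scored$p_raw, hyper_tail_count(3, 10, 10, 100, upper = TRUE))
})

test_that("widening a region without adding hits never lowers p_raw", {
  loci <- toy_loci(60)
  hits <- loci$gene_id[c(10, 12, 14)]
  widths <- 0:8
  ps <- vapply(widths, function(w) {
    region <- tibble::tibble(chrom = "chr1", start_ordinal = 10,
                             end_ordinal = 14 + w)
    score_region(region, hits, loci)$p_raw
  }, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("a planted cluster is recovered as a single significant region", {
  cfg <- genome_sim_config(
    n_chromosomes = 2, genes_per_chromosome = 100,
    planted_clusters = list(list(chrom = 1, start_index = 30, size = 5, hits = 5)),
    background_hits = 3, seed = 61L
  )
  sim <- simulate_genome(cfg)
  regions <- pge_scan(sim$hits, sim$loci)
  expect_equal(nrow(regions), 1)
  expect_lt(regions$p_adj, 0.01)
  planted <- sprintf("g01_%04d", 30:34)
  expect_true(all(planted %in% regions$hit_genes[[1]]))
})

test_that("the scan matches the brute-force all-intervals oracle", {
  withr::with_seed(71, {
    for (i in 1:20) {
      loci <- dplyr::bind_rows(toy_loci(50, "chr1"), toy_loci(50, "chr2"))
      n_hits <- sample(4:10, 1)
      hits <- sample(loci$gene_id, n_hits)
      # sprinkle a dense pocket in half the genomes so both outcomes occur
      if (i %% 2 == 0) {
        pocket <- loci$gene_id[loci$chrom == "chr1"][10:14]
        hits <- unique(c(hits, sample(pocket, 3)))
      }
      mine <- pge_scan(hits, loci, alpha_adj = 0.05, min_hits = 2)
      brute <- pge_scan_brute(hits, loci, alpha_adj = 0.05, min_hits = 2)
      expect_equal(nrow(mine), nrow(brute))
      if (nrow(mine) > 0) {
        expect_equal(mine$bp_start, brute$bp_start)
        expect_equal(mine$bp_end, brute$bp_end)
        expect_equal(mine$p_raw, brute$p_raw, tolerance = 1e-12)
        expect_equal(mine$p_adj, brute$p_adj, tolerance = 1e-12)
      }
    }
  })
})

test_that("reported p_raw equals direct rescoring and empty input yields none", {
  expect_equal(nrow(pge_scan(character(0), toy_loci(30))), 0)

  cfg <- genome_sim_config(
    n_chromosomes = 1, genes_per_chromosome = 80,
    planted_clusters = list(list(chrom = 1, start_index = 10, size = 6, hits = 4)),
    background_hits = 2, seed = 67L
  )
  sim <- simulate_genome(cfg)
  regions <- pge_scan(sim$hits, sim$loci, alpha_adj = 0.05, min_hits = 2)
  loci2 <- lohscreen:::validate_loci(sim$loci)
  for (r in seq_len(nrow(regions))) {
    ords <- loci2$ordinal[loci2$chrom == regions$chrom[r] &
                            loci2$start >= regions$bp_start[r] &
                            loci2$end <= regions$bp_end[r]]
    rescored <- score_region(
      tibble::tibble(chrom = regions$chrom[r], start_ordinal = min(ords),
                     end_ordinal = max(ords)),
      sim$hits, sim$loci
    )
    expect_equal(regions$p_raw[r], rescored$p_raw)
  }
})

test_that("output is invariant to gene relabeling and chromosome order", {
  cfg <- genome_sim_config(
    n_chromosomes = 2, genes_per_chromosome = 60,
    planted_clusters = list(list(chrom = 2, start_index = 20, size = 5, hits = 4)),
    background_hits = 4, seed = 73L
  )
  sim <- simulate_genome(cfg)
  base <- pge_scan(sim$hits, sim$loci, alpha_adj = 0.05, min_hits = 2)

  relabel <- stats::setNames(sprintf("X%03d", seq_len(nrow(sim$loci))),
                             sim$loci$gene_id)
  loci2 <- sim$loci
  loci2$gene_id <- unname(relabel[loci2$gene_id])
  loci2 <- loci2[sample(nrow(loci2)), ] # scramble row order too
  hits2 <- unname(relabel[sim$hits])
  out2 <- pge_scan(hits2, loci2, alpha_adj = 0.05, min_hits = 2)

  expect_equal(base[c("chrom", "bp_start", "bp_end", "orf_total",
                      "hit_count", "p_raw", "p_adj")],
               out2[c("chrom", "bp_start", "bp_end", "orf_total",
                      "hit_count", "p_raw", "p_adj")])
})
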