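# Synthetic-data generators: determinism, degenerate configs, and agreement
# with the analytic distributions they claim to draw from.

test_that("screen simulator is seed-deterministic and honours degenerate configs", {
  cfg <- screen_sim_config(n_strains = 60, n_hit_strains = 5, seed = 3L)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1, s2)

  quiet <- screen_sim_config(
    n_strains = 50, n_hit_strains = 5, false_positive_rate = 0,
    background_score_distribution = c(1, 0, 0, 0, 0),
    lawn_strain_fraction = 0, seed = 5L
  )
  sim <- simulate_screen(quiet)
  nonhit <- sim$observations$strain_id %in%
    sim$truth$strain_id[!sim$truth$is_hit]
  expect_true(all(sim$observations$colony_count[nonhit] == "0"))
})

test_that("screen simulator config validation rejects non-probabilities", {
  expect_error(screen_sim_config(false_positive_rate = 1.2), "probability")
  expect_error(screen_sim_config(hit_score_distribution = c(0.5, 0.5, 0.5, 0, 0)),
               "sum to 1")
  expect_error(screen_sim_config(n_hit_strains = 10, n_strains = 5), "exceeds")
})

test_that("non-hit wells grow at the configured false-positive rate", {
  # 125 non-hit strains x 2 testers x 4 replicates = 1000 wells
  cfg <- screen_sim_config(n_strains = 125, n_hit_strains = 0,
                           false_positive_rate = 0.02,
                           lawn_strain_fraction = 0, seed = 17L)
  sim <- simulate_screen(cfg)
  grew <- sum(sim$observations$colony_count != "0")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.02)
  expect_gte(grew, bounds[1])
  expect_lte(grew, bounds[2])
})

test_that("lawn strains produce lawns with both testers in every replicate", {
  cfg <- screen_sim_config(n_strains = 100, n_hit_strains = 0,
                           lawn_strain_fraction = 0.2, seed = 9L)
  sim <- simulate_screen(cfg)
  lawn_strains <- sim$truth$strain_id[sim$truth$is_lawn]
  expect_gt(length(lawn_strains), 0)
  lawn_obs <- sim$observations[sim$observations$strain_id %in% lawn_strains, ]
  expect_true(all(lawn_obs$colony_count == "LAWN"))
  expect_setequal(unique(lawn_obs$tester), c("MATa", "MATalpha"))
})

test_that("simulated hits are recovered by the calling rule at high sensitivity", {
  cfg <- screen_sim_config(
    n_strains = 500, n_hit_strains = 50,
    hit_score_distribution = c(0, 0, 0.01, 0.39, 0.60), # 0.99 mass >= +++
    seed = 23L
  )
  sim <- simulate_screen(cfg)
  calls <- call_top_hits(sim$observations)
  joined <- merge(calls, sim$truth, by = "strain_id")
  sensitivity <- mean(joined$top_hit[joined$is_hit])
  expect_gte(sensitivity, 0.95)
})

test_that("sector counts follow the configured Poisson means", {
  expect_true(all(simulate_sectors(0, n_strains = 10, seed = 1)$sector_count == 0))
  expect_error(simulate_sectors(-1, n_strains = 2), "non-negative")

  tab <- simulate_sectors(11, n_strains = 94, n_biological = 1,
                          n_technical = 3, seed = 2)
  expect_equal(nrow(tab), 94 * 3)
  se <- sqrt(11 / (94 * 3))
  expect_lt(abs(mean(tab$sector_count) - 11), 3 * se)

  expect_identical(simulate_sectors(11, n_strains = 5, seed = 7),
                   simulate_sectors(11, n_strains = 5, seed = 7))
})

test_that("genome simulator plants clusters and conserves hit counts", {
  cfg <- genome_sim_config(
    n_chromosomes = 2, genes_per_chromosome = 50,
    planted_clusters = list(list(chrom = 1, start_index = 10, size = 5, hits = 3)),
    background_hits = 0, seed = 4L
  )
  sim <- simulate_genome(cfg)
  expect_length(sim$hits, 3)
  cluster_span <- sim$loci[sim$loci$chrom == "chr01" &
                             sim$loci$ordinal %in% 10:14, ]
  hit_loci <- sim$loci[sim$loci$gene_id %in% sim$hits, ]
  expect_true(all(hit_loci$start >= min(cluster_span$start)))
  expect_true(all(hit_loci$end <= max(cluster_span$end)))

  cfg2 <- genome_sim_config(
    n_chromosomes = 3, genes_per_chromosome = 40,
    planted_clusters = list(list(chrom = 1, start_index = 5, size = 6, hits = 4),
                            list(chrom = 3, start_index = 20, size = 4, hits = 2)),
    background_hits = 7, seed = 8L
  )
  sim2 <- simulate_genome(cfg2)
  expect_length(sim2$hits, 4 + 2 + 7)
  expect_false(anyDuplicated(sim2$hits) > 0)

  expect_error(genome_sim_config(
    genes_per_chromosome = 10,
    planted_clusters = list(list(chrom = 1, start_index = 8, size = 5, hits = 2))
  ), "exceeds chromosome bounds")
})

test_that("gene maps survive a BED round trip exactly", {
  sim <- simulate_genome(genome_sim_config(n_chromosomes = 2,
                                           genes_per_chromosome = 20,
                                           background_hits = 0, seed = 6L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sim$loci, path)
  back <- read_bed(path)
  expect_equal(back[c("gene_id", "chrom", "start", "end", "ordinal")],
               sim$loci[c("gene_id", "chrom", "start", "end", "ordinal")])
})

test_that("fluctuation simulator matches its analytic zero class and pmf", {
  zero <- simulate_fluctuation(fluctuation_sim_config(m_true = 0, n_cultures = 20))
  expect_true(all(zero$count == 0))

  sim <- simulate_fluctuation(fluctuation_sim_config(
    m_true = 2, n_final = 1e8, n_cultures = 10000, seed = 31L
  ))
  n_zero <- sum(sim$count == 0)
  bounds <- qbinom(c(0.005, 0.995), 10000, exp(-2))
  expect_gte(n_zero, bounds[1])
  expect_lte(n_zero, bounds[2])

  # empirical distribution at m = 1 against the MSS pmf, counts 0..10 + tail
  sim1 <- simulate_fluctuation(fluctuation_sim_config(
    m_true = 1, n_final = 1e8, n_cultures = 20000, seed = 37L
  ))
  pmf <- ld_pmf(1, 10)
  probs <- c(pmf, 1 - sum(pmf))
  obs <- table(factor(pmin(sim1$count, 11), levels = 0:11))
  chi <- suppressWarnings(chisq.test(as.integer(obs), p = probs))
  expect_gt(chi$p.value, 0.01)

  expect_identical(
    simulate_fluctuation(fluctuation_sim_config(m_true = 1, seed = 2)),
    simulate_fluctuation(fluctuation_sim_config(m_true = 1, seed = 2))
  )
})
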