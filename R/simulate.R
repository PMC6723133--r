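# Synthetic-data generators. Every generator takes an explicit integer seed and
# leaves the global RNG state untouched (withr::with_seed), so pipelines driven
# from a single configuration seed are bit-reproducible.

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}

check_score_dist <- function(x, name) {
  if (!is.numeric(x) || length(x) != 5 || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be 5 probabilities (score levels 0..4)"))
  }
  if (abs(sum(x) - 1) > 1e-8) {
    abort(paste0("`", name, "` must sum to 1"))
  }
  invisible(x)
}

#' Configuration for the mating-plate screen simulator
#'
#' Describes a synthetic 96-well-style heterozygous-deletion screen: a set of
#' strains, a subset of true LOH hits whose wells grow strongly with a mating
#' tester, background wells that only rarely show any growth (the control
#' experiments put this false-positive rate near 2%), and a small fraction of
#' strains that grow as a lawn with both testers (pre-existing resistance, not
#' LOH).
#'
#' Score distributions are probabilities over the five ordinal growth levels
#' 0, "+", "++", "+++", "++++" (see [score_colony_count()]).
#' `background_score_distribution` is the level distribution *given* that a
#' non-hit well shows growth at all; `false_positive_rate` gates whether it
#' does.
#'
#' @param n_strains Number of deletion strains.
#' @param n_hit_strains Number of true hit strains among them.
#' @param hit_score_distribution Per-replicate level probabilities for hits.
#' @param background_score_distribution Per-replicate level probabilities for a
#'   growing non-hit well (mass at level 0 is allowed but makes the realised
#'   growth rate fall below `false_positive_rate`).
#' @param false_positive_rate Probability that a non-hit well shows any growth.
#' @param lawn_strain_fraction Probability that a strain is a constitutive lawn
#'   grower (lawn with both testers, every replicate).
#' @param replicates_per_tester Replicates pinned per strain and tester.
#' @param seed Integer seed.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_strains = 500L,
                              n_hit_strains = 25L,
                              hit_score_distribution = c(0, 0, 0.01, 0.39, 0.60),
                              background_score_distribution = c(0, 0.7, 0.3, 0, 0),
                              false_positive_rate = 0.02,
                              lawn_strain_fraction = 14 / 6477,
                              replicates_per_tester = 4L,
                              seed = 1L) {
  n_strains <- check_count(n_strains, "n_strains", min = 1L)
  n_hit_strains <- check_count(n_hit_strains, "n_hit_strains")
  if (n_hit_strains > n_strains) abort("`n_hit_strains` exceeds `n_strains`")
  check_score_dist(hit_score_distribution, "hit_score_distribution")
  check_score_dist(background_score_distribution, "background_score_distribution")
  check_prob(false_positive_rate, "false_positive_rate")
  check_prob(lawn_strain_fraction, "lawn_strain_fraction")
  replicates_per_tester <- check_count(replicates_per_tester, "replicates_per_tester", min = 1L)
  seed <- check_count(seed, "seed")
  structure(
    list(
      n_strains = n_strains,
      n_hit_strains = n_hit_strains,
      hit_score_distribution = hit_score_distribution,
      background_score_distribution = background_score_distribution,
      false_positive_rate = false_positive_rate,
      lawn_strain_fraction = lawn_strain_fraction,
      replicates_per_tester = replicates_per_tester,
      seed = seed
    ),
    class = "screen_sim_config"
  )
}

# Representative colony count for an ordinal growth level.
count_for_level <- function(level) {
  lo <- c(0L, 1L, 10L, 20L, 30L)[level + 1L]
  hi <- c(0L, 9L, 19L, 29L, 80L)[level + 1L]
  lo + floor(runif(length(level)) * (hi - lo + 1L))
}

#' Simulate a MAT-locus LOH mating screen
#'
#' Generates one well observation per strain x tester x replicate. True hit
#' strains draw every replicate from the hit score distribution; non-hit wells
#' show growth with probability `false_positive_rate` and are otherwise 0; lawn
#' strains produce the `"LAWN"` token with both testers in every replicate.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `observations` (tibble: `strain_id`, `tester`,
#'   `replicate_id`, `colony_count` as character counts or `"LAWN"`) and
#'   `truth` (tibble: `strain_id`, `is_hit`, `is_lawn`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  withr::with_seed(config$seed, {
    strain_id <- sprintf("strain%04d", seq_len(config$n_strains))
    is_hit <- seq_len(config$n_strains) <= config$n_hit_strains
    is_lawn <- !is_hit & runif(config$n_strains) < config$lawn_strain_fraction

    grid <- tidyr::expand_grid(
      strain_id = strain_id,
      tester = c("MATa", "MATalpha"),
      replicate = seq_len(config$replicates_per_tester)
    )
    grid$replicate_id <- paste0("rep", grid$replicate)
    grid <- dplyr::left_join(
      grid,
      tibble(strain_id = strain_id, is_hit = is_hit, is_lawn = is_lawn),
      by = "strain_id"
    )

    n_wells <- nrow(grid)
    level <- integer(n_wells)
    hit_rows <- grid$is_hit
    level[hit_rows] <- sample(0:4, sum(hit_rows), replace = TRUE,
                              prob = config$hit_score_distribution)
    bg_rows <- !grid$is_hit & !grid$is_lawn
    grows <- bg_rows & runif(n_wells) < config$false_positive_rate
    level[grows] <- sample(0:4, sum(grows), replace = TRUE,
                           prob = config$background_score_distribution)

    counts <- as.character(count_for_level(level))
    counts[grid$is_lawn] <- LAWN_TOKEN

    list(
      observations = tibble(
        strain_id = grid$strain_id,
        tester = grid$tester,
        replicate_id = grid$replicate_id,
        colony_count = counts
      ),
      truth = tibble(strain_id = strain_id, is_hit = is_hit, is_lawn = is_lawn)
    )
  })
}

#' Simulate sector counts for a lead-plate assay
#'
#' Draws Poisson sector counts per strain and replicate, emulating the
#' secondary LOH readout in which colonies that lose the functional MET15 copy
#' appear as dark sectors (the control baseline in the study averaged 11
#' sectors per patch).
#'
#' @param lambda Mean sector count; a scalar (recycled) or one value per strain.
#' @param n_strains Number of strains (defaults to `length(lambda)`).
#' @param n_biological,n_technical Replicate structure; total replicates per
#'   strain is their product.
#' @param seed Integer seed.
#' @return Tibble with `strain_id`, `replicate_id`, `sector_count` (integer).
#' @export
simulate_sectors <- function(lambda, n_strains = length(lambda),
                             n_biological = 2L, n_technical = 3L, seed = 1L) {
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda < 0)) {
    abort("`lambda` must be non-negative")
  }
  n_strains <- check_count(n_strains, "n_strains", min = 1L)
  n_biological <- check_count(n_biological, "n_biological", min = 1L)
  n_technical <- check_count(n_technical, "n_technical", min = 1L)
  seed <- check_count(seed, "seed")
  lambda <- rep_len(lambda, n_strains)
  n_rep <- n_biological * n_technical
  withr::with_seed(seed, {
    tibble(
      strain_id = rep(sprintf("strain%04d", seq_len(n_strains)), each = n_rep),
      replicate_id = rep(paste0("bio", rep(seq_len(n_biological), each = n_technical),
                                "_tech", rep(seq_len(n_technical), n_biological)),
                         n_strains),
      sector_count = rpois(n_strains * n_rep, rep(lambda, each = n_rep))
    )
  })
}

#' Configuration for the toy-genome generator
#'
#' Lays out equally sized, non-overlapping genes along chromosomes and plants
#' clusters of hit genes at known positions, so that positional-enrichment
#' scans can be validated against a known ground truth.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome.
#' @param gene_length_bp,intergenic_bp Gene and gap lengths in bp.
#' @param planted_clusters List of clusters, each a list/vector with elements
#'   `chrom` (chromosome index), `start_index` (first gene ordinal of the
#'   cluster), `size` (genes spanned) and `hits` (hit genes inside, `<= size`).
#' @param background_hits Hits scattered uniformly outside all clusters.
#' @param seed Integer seed.
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_chromosomes = 3L, genes_per_chromosome = 100L,
                              gene_length_bp = 1500L, intergenic_bp = 500L,
                              planted_clusters = list(), background_hits = 10L,
                              seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1L)
  genes_per_chromosome <- check_count(genes_per_chromosome, "genes_per_chromosome", min = 1L)
  gene_length_bp <- check_count(gene_length_bp, "gene_length_bp", min = 1L)
  intergenic_bp <- check_count(intergenic_bp, "intergenic_bp", min = 0L)
  background_hits <- check_count(background_hits, "background_hits")
  seed <- check_count(seed, "seed")
  planted_clusters <- lapply(planted_clusters, function(cl) {
    cl <- as.list(cl)
    stopifnot(all(c("chrom", "start_index", "size", "hits") %in% names(cl)))
    cl$chrom <- check_count(cl$chrom, "chrom", min = 1L)
    cl$start_index <- check_count(cl$start_index, "start_index", min = 1L)
    cl$size <- check_count(cl$size, "size", min = 1L)
    cl$hits <- check_count(cl$hits, "hits", min = 0L)
    if (cl$chrom > n_chromosomes) abort("cluster chromosome out of range")
    if (cl$hits > cl$size) abort("cluster hits exceed cluster size")
    if (cl$start_index + cl$size - 1L > genes_per_chromosome) {
      abort("planted cluster exceeds chromosome bounds")
    }
    cl
  })
  structure(
    list(
      n_chromosomes = n_chromosomes,
      genes_per_chromosome = genes_per_chromosome,
      gene_length_bp = gene_length_bp,
      intergenic_bp = intergenic_bp,
      planted_clusters = planted_clusters,
      background_hits = background_hits,
      seed = seed
    ),
    class = "genome_sim_config"
  )
}

#' Simulate a gene map with planted hit clusters
#'
#' @param config A [genome_sim_config()].
#' @return A list with `loci` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `ordinal`; 1-based inclusive coordinates) and `hits` (character vector of
#'   hit gene ids).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  withr::with_seed(config$seed, {
    g <- config$genes_per_chromosome
    pitch <- config$gene_length_bp + config$intergenic_bp
    loci <- tidyr::expand_grid(chrom_i = seq_len(config$n_chromosomes),
                               ordinal = seq_len(g))
    loci <- tibble(
      gene_id = sprintf("g%02d_%04d", loci$chrom_i, loci$ordinal),
      chrom = sprintf("chr%02d", loci$chrom_i),
      start = (loci$ordinal - 1L) * pitch + 1L,
      end = (loci$ordinal - 1L) * pitch + config$gene_length_bp,
      ordinal = loci$ordinal
    )

    cluster_gene <- character(0)
    hits <- character(0)
    for (cl in config$planted_clusters) {
      idx <- cl$start_index + seq_len(cl$size) - 1L
      genes <- sprintf("g%02d_%04d", cl$chrom, idx)
      cluster_gene <- c(cluster_gene, genes)
      # hits anchored at both cluster ends so the planted span is recoverable
      chosen <- if (cl$hits >= 2L) {
        c(genes[1L], genes[length(genes)],
          sample(genes[-c(1L, length(genes))], cl$hits - 2L))
      } else if (cl$hits == 1L) {
        sample(genes, 1L)
      } else {
        character(0)
      }
      hits <- c(hits, chosen)
    }
    if (anyDuplicated(hits)) abort("planted clusters produced duplicate hit genes")

    pool <- setdiff(loci$gene_id, cluster_gene)
    if (config$background_hits > length(pool)) {
      abort("background_hits exceeds genes outside planted clusters")
    }
    hits <- c(hits, sample(pool, config$background_hits))
    list(loci = loci, hits = hits)
  })
}

#' Configuration for the fluctuation-experiment simulator
#'
#' @param m_true Expected mutation events per culture (dimensionless).
#' @param n_final Final population size per culture (cells).
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed.
#' @return A list of class `fluctuation_sim_config`.
#' @export
fluctuation_sim_config <- function(m_true, n_final = 1e8, n_cultures = 15L,
                                   seed = 1L) {
  if (!is.numeric(m_true) || length(m_true) != 1 || is.na(m_true) || m_true < 0) {
    abort("`m_true` must be a single non-negative number")
  }
  if (!is.numeric(n_final) || length(n_final) != 1 || is.na(n_final) || n_final < 1) {
    abort("`n_final` must be >= 1")
  }
  n_cultures <- check_count(n_cultures, "n_cultures", min = 1L)
  seed <- check_count(seed, "seed")
  structure(
    list(m_true = m_true, n_final = n_final, n_cultures = n_cultures, seed = seed),
    class = "fluctuation_sim_config"
  )
}

#' Simulate Luria-Delbruck mutant counts
#'
#' Per culture, the number of mutation events is Poisson(`m_true`); each event
#' founds a clone whose final size is `floor(1/U)` with `U ~ Uniform(0,1)`,
#' truncated at `n_final` — the standard Lea-Coulson-consistent clone-size
#' sampler, whose compound-Poisson sum follows the Ma-Sandri-Sarkar pmf
#' computed by [ld_pmf()].
#'
#' @param config A [fluctuation_sim_config()].
#' @return Tibble with `culture_id`, `count`, `n_final`.
#' @export
simulate_fluctuation <- function(config) {
  stopifnot(inherits(config, "fluctuation_sim_config"))
  withr::with_seed(config$seed, {
    counts <- vapply(seq_len(config$n_cultures), function(i) {
      n_mut <- rpois(1L, config$m_true)
      if (n_mut == 0L) return(0)
      sum(pmin(floor(1 / runif(n_mut)), config$n_final))
    }, numeric(1))
    tibble(
      culture_id = sprintf("culture%03d", seq_len(config$n_cultures)),
      count = counts,
      n_final = config$n_final
    )
  })
}
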