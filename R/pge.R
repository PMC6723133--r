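# Positional gene enrichment: scan chromosomes for gene intervals
# over-represented among hits under a hypergeometric model.

validate_loci <- function(loci) {
  loci <- as_tibble(loci)
  needed <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols) > 0) {
    abort(paste0("loci lack columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(loci$gene_id)) abort("duplicate gene_ids in loci")
  if (any(loci$start > loci$end)) abort("loci with start > end")
  loci <- dplyr::arrange(loci, .data$chrom, .data$start)
  loci %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(ordinal = dplyr::row_number()) %>%
    dplyr::ungroup()
}

#' Enumerate hit-delimited candidate regions
#'
#' Per chromosome, all gene-ordinal intervals whose first and last genes are
#' both hits. Any interval maximising enrichment must be delimited by hits
#' (trimming a non-hit end gene only raises the hit density), so this set
#' contains every optimal region while testing only `h * (h + 1) / 2`
#' candidates per chromosome with `h` hits.
#'
#' @param hits Character vector of hit gene ids (must all appear in `loci`).
#' @param loci Gene map tibble with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_bed()] or [simulate_genome()].
#' @return Tibble of candidates: `chrom`, `start_ordinal`, `end_ordinal`,
#'   `first_gene`, `last_gene`.
#' @export
enumerate_candidate_regions <- function(hits, loci) {
  loci <- validate_loci(loci)
  missing_hits <- setdiff(hits, loci$gene_id)
  if (length(missing_hits) > 0) {
    abort(paste0("hits without coordinates: ",
                 paste(utils::head(missing_hits, 10), collapse = ", ")))
  }
  empty <- tibble(chrom = character(0), start_ordinal = integer(0),
                  end_ordinal = integer(0), first_gene = character(0),
                  last_gene = character(0))
  hit_loci <- loci[loci$gene_id %in% hits, ]
  if (nrow(hit_loci) == 0) return(empty)
  purrr::map_dfr(split(hit_loci, hit_loci$chrom), function(hl) {
    ords <- sort(hl$ordinal)
    if (length(ords) == 0) return(NULL)
    pairs <- tidyr::expand_grid(i = ords, j = ords)
    pairs <- pairs[pairs$i <= pairs$j, ]
    tibble(
      chrom = hl$chrom[1],
      start_ordinal = pairs$i,
      end_ordinal = pairs$j
    )
  }) %>%
    dplyr::left_join(
      dplyr::select(loci, "chrom", start_ordinal = "ordinal", first_gene = "gene_id"),
      by = c("chrom", "start_ordinal")
    ) %>%
    dplyr::left_join(
      dplyr::select(loci, "chrom", end_ordinal = "ordinal", last_gene = "gene_id"),
      by = c("chrom", "end_ordinal")
    )
}

#' Score candidate regions for hit enrichment
#'
#' For each region, the raw p-value is the upper hypergeometric tail
#' `P(X >= hit_count)` with `X ~ Hypergeometric(N = total genes, K = total
#' hits, n = genes in region)` — the same machinery as [overlap_pvalue()].
#'
#' @param regions Candidate tibble from [enumerate_candidate_regions()] (or any
#'   tibble with `chrom`, `start_ordinal`, `end_ordinal`).
#' @inheritParams enumerate_candidate_regions
#' @return `regions` with `orf_total`, `hit_count`, `hit_genes` (list column),
#'   `bp_start`, `bp_end`, `p_raw` appended.
#' @export
score_region <- function(regions, hits, loci) {
  loci <- validate_loci(loci)
  hits <- unique(hits)
  N <- nrow(loci)
  K <- sum(loci$gene_id %in% hits)
  regions <- as_tibble(regions)
  scored <- purrr::pmap_dfr(
    regions[c("chrom", "start_ordinal", "end_ordinal")],
    function(chrom, start_ordinal, end_ordinal) {
      genes <- loci[loci$chrom == chrom &
                      loci$ordinal >= start_ordinal &
                      loci$ordinal <= end_ordinal, ]
      if (nrow(genes) == 0) abort("empty region")
      in_region_hits <- genes$gene_id[genes$gene_id %in% hits]
      n <- nrow(genes)
      a <- length(in_region_hits)
      p <- if (a == 0) 1 else sum(dhyper(a:min(K, n), K, N - K, n))
      tibble(
        orf_total = n, hit_count = a, hit_genes = list(in_region_hits),
        bp_start = min(genes$start), bp_end = max(genes$end),
        p_raw = min(p, 1)
      )
    }
  )
  dplyr::bind_cols(regions, scored)
}

#' Scan a genome for positionally enriched hit regions
#'
#' Enumerates hit-delimited candidate intervals, scores each by the upper
#' hypergeometric tail, adjusts over the number of candidates tested
#' (Bonferroni by default, BH optional), and retains regions with adjusted
#' p below `alpha_adj` and at least `min_hits` hit genes. Unless
#' `collapse = FALSE`, a redundancy filter resolves every nested pair of
#' retained regions in favour of the sharper one (smaller adjusted p; ties to
#' the narrower interval), so a significant cluster is reported once rather
#' than along with all its sub- and super-intervals.
#'
#' @inheritParams enumerate_candidate_regions
#' @param alpha_adj Significance level on the adjusted p-value.
#' @param min_hits Minimum hit genes per reported region.
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @param collapse Apply the redundancy filter (default `TRUE`).
#' @return Tibble of enriched regions: `chrom`, `bp_start`, `bp_end`,
#'   `orf_total`, `hit_count`, `hit_genes` (list column), `p_raw`, `p_adj`,
#'   sorted by `p_adj`.
#' @export
pge_scan <- function(hits, loci, alpha_adj = 0.01, min_hits = 3L,
                     adjust = c("bonferroni", "bh"), collapse = TRUE) {
  adjust <- match.arg(adjust)
  empty <- tibble(
    chrom = character(0), bp_start = numeric(0), bp_end = numeric(0),
    orf_total = integer(0), hit_count = integer(0), hit_genes = list(),
    p_raw = numeric(0), p_adj = numeric(0)
  )
  if (length(hits) == 0) return(empty)
  cand <- enumerate_candidate_regions(hits, loci)
  if (nrow(cand) == 0) return(empty)
  scored <- score_region(cand, hits, loci)
  m <- nrow(scored)
  scored$p_adj <- switch(adjust,
    bonferroni = pmin(1, scored$p_raw * m),
    bh = stats::p.adjust(scored$p_raw, method = "BH")
  )
  keep <- scored[scored$p_adj < alpha_adj & scored$hit_count >= min_hits, ]
  if (collapse && nrow(keep) > 1) {
    # within any nested pair keep the sharper region: smaller p_adj wins,
    # ties go to the narrower interval
    redundant <- vapply(seq_len(nrow(keep)), function(i) {
      nested <- keep$chrom == keep$chrom[i] &
        ((keep$start_ordinal >= keep$start_ordinal[i] &
            keep$end_ordinal <= keep$end_ordinal[i]) |
           (keep$start_ordinal <= keep$start_ordinal[i] &
              keep$end_ordinal >= keep$end_ordinal[i])) &
        (keep$end_ordinal - keep$start_ordinal !=
           keep$end_ordinal[i] - keep$start_ordinal[i])
      any(nested & (keep$p_adj < keep$p_adj[i] |
                      (keep$p_adj == keep$p_adj[i] &
                         keep$end_ordinal - keep$start_ordinal <
                         keep$end_ordinal[i] - keep$start_ordinal[i])))
    }, logical(1))
    keep <- keep[!redundant, ]
  }
  keep %>%
    dplyr::select("chrom", "bp_start", "bp_end", "orf_total", "hit_count",
                  "hit_genes", "p_raw", "p_adj") %>%
    dplyr::arrange(.data$p_adj, .data$chrom, .data$bp_start)
}
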