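# Umbrella pipeline: run the configured stages in the study's order
# (primary screen -> secondary sectoring -> overlaps -> enrichment -> PGE ->
# fluctuation), writing one TSV per stage plus a JSON summary.

#' Read a pipeline configuration from YAML
#'
#' The configuration holds one block per stage, each naming its input files and
#' thresholds; absent blocks are skipped by [run_pipeline()]. See the package
#' vignette for the schema.
#'
#' @param path Path to a YAML file.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

check_paths <- function(stage, paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(paste0("[", stage, "] input files not found: ",
                 paste(unlist(missing), collapse = ", ")))
  }
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the end-to-end screening pipeline
#'
#' Executes every stage present in `config` and writes per-stage TSVs (with a
#' provenance header naming the package version and the thresholds applied)
#' plus a `summary.json` into `out_dir`. Stage blocks:
#'
#' * `mat_screen`: `plates` (TSV: strain_id, tester, replicate_id,
#'   colony_count), optional `annotations` (gene list), optional `n_screened`.
#' * `met15`: `counts` and `control` (TSV: strain_id, replicate_id,
#'   sector_count), optional `margin` (default 2).
#' * `overlap`: `hits1`, `hits2`, `background` (gene lists).
#' * `go_enrichment`: `hits`, `background` (gene lists), `annotations`
#'   (TSV/GAF), optional `q` (default 0.05).
#' * `pge`: `hits` (gene list; defaults to the MAT-stage top hits), `loci`
#'   (BED), optional `alpha_adj`, `min_hits`, `adjust`.
#' * `fluctuation`: `counts` (TSV: strain_id, culture_id, count, n_final),
#'   optional `reference`, `alpha`.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or plain
#'   named list with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("lohscreen")),
    stages = list()
  )

  if (!is.null(config$mat_screen)) {
    cfg <- config$mat_screen
    check_paths("mat_screen", cfg["plates"])
    summary$stages$mat_screen <- run_stage("mat_screen", {
      plates <- readr::read_tsv(cfg$plates, comment = "#",
                                col_types = readr::cols(.default = "c"))
      ann <- if (!is.null(cfg$annotations)) read_gene_list(cfg$annotations) else character(0)
      calls <- call_top_hits(plates, mating_annotations = ann)
      write_stage_tsv(calls, file.path(out_dir, "mat_screen_calls.tsv"),
                      thresholds = list(rule = "all four replicates >= +++"))
      n_screened <- if (!is.null(cfg$n_screened)) cfg$n_screened else nrow(calls)
      smry <- summarize_screen(calls, n_screened)
      write_gene_list(calls$strain_id[calls$top_hit],
                      file.path(out_dir, "mat_screen_top_hits.txt"))
      as.list(smry)
    })
  }

  if (!is.null(config$met15)) {
    cfg <- config$met15
    check_paths("met15", cfg[c("counts", "control")])
    summary$stages$met15 <- run_stage("met15", {
      margin <- if (!is.null(cfg$margin)) cfg$margin else 2L
      control <- readr::read_tsv(cfg$control, comment = "#",
                                 col_types = readr::cols(.default = "c"))
      counts <- readr::read_tsv(cfg$counts, comment = "#",
                                col_types = readr::cols(.default = "c"))
      threshold <- compute_sector_threshold(control, margin = margin)
      calls <- call_sector_positive(counts, threshold)
      write_stage_tsv(calls, file.path(out_dir, "met15_calls.tsv"),
                      thresholds = list(threshold = threshold, margin = margin))
      list(threshold = threshold,
           n_positive = sum(calls$positive, na.rm = TRUE),
           n_not_assessable = sum(!calls$assessable))
    })
  }

  if (!is.null(config$overlap)) {
    cfg <- config$overlap
    check_paths("overlap", cfg[c("hits1", "hits2", "background")])
    summary$stages$overlap <- run_stage("overlap", {
      res <- compare_screens(read_gene_list(cfg$hits1),
                             read_gene_list(cfg$hits2),
                             read_gene_list(cfg$background))
      write_stage_tsv(res, file.path(out_dir, "overlap.tsv"))
      as.list(res)
    })
  }

  if (!is.null(config$go_enrichment)) {
    cfg <- config$go_enrichment
    check_paths("go_enrichment", cfg[c("hits", "background", "annotations")])
    summary$stages$go_enrichment <- run_stage("go_enrichment", {
      q <- if (!is.null(cfg$q)) cfg$q else 0.05
      res <- enrich_terms(read_gene_list(cfg$hits),
                          read_gene_list(cfg$background),
                          read_annotations(cfg$annotations), q = q)
      write_stage_tsv(res, file.path(out_dir, "go_enrichment.tsv"),
                      thresholds = list(q = q))
      list(n_terms = nrow(res), n_significant = sum(res$significant))
    })
  }

  if (!is.null(config$pge)) {
    cfg <- config$pge
    check_paths("pge", cfg[c("hits", "loci")])
    summary$stages$pge <- run_stage("pge", {
      alpha_adj <- if (!is.null(cfg$alpha_adj)) cfg$alpha_adj else 0.01
      min_hits <- if (!is.null(cfg$min_hits)) cfg$min_hits else 3L
      adjust <- if (!is.null(cfg$adjust)) cfg$adjust else "bonferroni"
      regions <- pge_scan(read_gene_list(cfg$hits), read_bed(cfg$loci),
                          alpha_adj = alpha_adj, min_hits = min_hits,
                          adjust = adjust)
      write_stage_tsv(regions, file.path(out_dir, "pge_regions.tsv"),
                      thresholds = list(alpha_adj = alpha_adj,
                                        min_hits = min_hits, adjust = adjust))
      list(n_regions = nrow(regions),
           regions = purrr::pmap(
             regions[c("chrom", "bp_start", "bp_end", "hit_count", "p_adj")], list))
    })
  }

  if (!is.null(config$fluctuation)) {
    cfg <- config$fluctuation
    check_paths("fluctuation", cfg["counts"])
    summary$stages$fluctuation <- run_stage("fluctuation", {
      alpha <- if (!is.null(cfg$alpha)) cfg$alpha else 0.05
      tab <- readr::read_tsv(cfg$counts, comment = "#", show_col_types = FALSE)
      res <- analyze_fluctuation(tab, reference = cfg$reference, alpha = alpha)
      write_stage_tsv(res, file.path(out_dir, "fluctuation_rates.tsv"),
                      thresholds = list(alpha = alpha))
      purrr::pmap(res, list)
    })
  }

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}
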