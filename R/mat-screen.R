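# Primary-screen scoring: ordinal growth levels and the top-hit calling rule.

#' Score colony counts on the ordinal growth scale
#'
#' Converts pinned-spot colony counts into the five-level growth score used to
#' read the mating plates: 0 colonies -> level 0 ("0"), 1-9 -> 1 ("+"),
#' 10-19 -> 2 ("++"), 20-29 -> 3 ("+++") and 30 or more -> 4 ("++++"). The
#' token `"LAWN"` marks confluent growth that cannot be counted; it carries no
#' level.
#'
#' @param x Vector of non-negative integer counts, or a character vector of
#'   counts possibly containing `"LAWN"`.
#' @return Tibble with one row per input: `level` (integer 0-4, `NA` for
#'   lawns), `lawn` (logical) and `label` (`"0"`, `"+"`, ..., `"++++"`,
#'   `"LAWN"`).
#' @examples
#' score_colony_count(c(0, 19, 45, "LAWN"))
#' @export
score_colony_count <- function(x) {
  x_chr <- trimws(as.character(x))
  lawn <- toupper(x_chr) == LAWN_TOKEN
  count <- suppressWarnings(as.numeric(x_chr))
  bad <- !lawn & (is.na(count) | count < 0 | count != floor(count))
  if (any(bad)) {
    abort(paste0("invalid colony counts (need non-negative integers or \"LAWN\"): ",
                 paste(utils::head(x_chr[bad], 5), collapse = ", ")))
  }
  level <- rep(NA_integer_, length(x_chr))
  level[!lawn] <- as.integer(cut(count[!lawn], c(-1, 0, 9, 19, 29, Inf),
                                 labels = FALSE)) - 1L
  label <- ifelse(lawn, LAWN_TOKEN,
                  c("0", "+", "++", "+++", "++++")[level + 1L])
  tibble(level = level, lawn = lawn, label = label)
}

#' Call top-hit strains from mating-plate observations
#'
#' Applies the screen's calling rule per strain and tester: a strain x tester
#' pairing qualifies when every one of its replicates scores at least "+++"
#' (level 3), which forces the summed score to be 12 or more. A strain is a
#' top-hit when at least one pairing qualifies and the strain is not excluded.
#' Exclusions: lawn growth with *both* testers (pre-existing resistance rather
#' than LOH), or a vendor annotation of a mating-related phenotype. A lawn with
#' only one tester voids that pairing alone; the strain may still qualify via
#' the other tester.
#'
#' @param observations Tibble/data frame with columns `strain_id`, `tester`
#'   (`"MATa"` / `"MATalpha"`), `replicate_id`, `colony_count` (counts or
#'   `"LAWN"`).
#' @param mating_annotations Character vector of strain ids with an annotated
#'   mating phenotype, excluded from calling.
#' @param n_replicates Replicates required per strain and tester.
#' @return Tibble with one row per strain: per-tester summed scores
#'   (`sum_MATa`, `sum_MATalpha`, `NA` when the pairing contains a lawn),
#'   per-tester qualification flags, `lawn_both_testers`, `mixed_lawn`,
#'   `mating_annotated`, `qualifying_testers` and `top_hit`.
#' @export
call_top_hits <- function(observations, mating_annotations = character(),
                          n_replicates = 4L) {
  obs <- as_tibble(observations)
  needed <- c("strain_id", "tester", "replicate_id", "colony_count")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("observations lack columns: ", paste(missing_cols, collapse = ", ")))
  }

  scored <- dplyr::bind_cols(obs[needed], score_colony_count(obs$colony_count))

  counts <- dplyr::count(scored, .data$strain_id, .data$tester)
  full <- tidyr::expand_grid(strain_id = unique(scored$strain_id),
                             tester = c("MATa", "MATalpha"))
  counts <- dplyr::left_join(full, counts, by = c("strain_id", "tester"))
  counts$n[is.na(counts$n)] <- 0L
  bad <- counts[counts$n != n_replicates, ]
  if (nrow(bad) > 0) {
    abort(paste0(
      "expected exactly ", n_replicates, " replicates per strain x tester; offenders: ",
      paste(utils::head(paste0(bad$strain_id, "/", bad$tester, " (", bad$n, ")"), 5),
            collapse = ", ")
    ))
  }

  per_pair <- scored %>%
    dplyr::group_by(.data$strain_id, .data$tester) %>%
    dplyr::summarise(
      any_lawn = any(.data$lawn),
      all_lawn = all(.data$lawn),
      sum_score = if (any(.data$lawn)) NA_integer_ else sum(.data$level),
      qualifies = !any(.data$lawn) && all(.data$level >= 3L),
      .groups = "drop"
    )
  per_pair$mixed <- per_pair$any_lawn & !per_pair$all_lawn
  if (any(per_pair$mixed)) {
    warn(paste0("strain x tester pairings mix lawn and countable replicates: ",
                paste(utils::head(
                  paste0(per_pair$strain_id[per_pair$mixed], "/",
                         per_pair$tester[per_pair$mixed]), 5), collapse = ", ")))
  }

  wide <- tidyr::pivot_wider(
    per_pair,
    id_cols = "strain_id",
    names_from = "tester",
    values_from = c("sum_score", "qualifies", "any_lawn", "mixed"),
    names_glue = "{.value}_{tester}"
  )

  calls <- tibble(
    strain_id = wide$strain_id,
    sum_MATa = wide$sum_score_MATa,
    sum_MATalpha = wide$sum_score_MATalpha,
    qualifies_MATa = wide$qualifies_MATa,
    qualifies_MATalpha = wide$qualifies_MATalpha,
    lawn_both_testers = wide$any_lawn_MATa & wide$any_lawn_MATalpha,
    mixed_lawn = wide$mixed_MATa | wide$mixed_MATalpha,
    mating_annotated = wide$strain_id %in% mating_annotations
  )
  calls$qualifying_testers <- purrr::map2_chr(
    calls$qualifies_MATa, calls$qualifies_MATalpha,
    function(a, b) paste(c("MATa", "MATalpha")[c(a, b)], collapse = ",")
  )
  calls$top_hit <- (calls$qualifies_MATa | calls$qualifies_MATalpha) &
    !calls$lawn_both_testers & !calls$mating_annotated
  calls
}

#' Summarise a screen's hit yield
#'
#' @param calls Output of [call_top_hits()], or any tibble with a logical
#'   `top_hit` column.
#' @param n_screened Total strains screened (must be at least the hit count).
#' @return One-row tibble: `n_top_hits`, `n_screened`, `genome_fraction_pct`
#'   (percentage, one decimal).
#' @examples
#' summarize_screen(tibble::tibble(top_hit = rep(TRUE, 217)), 6477)
#' @export
summarize_screen <- function(calls, n_screened) {
  n_screened <- check_count(n_screened, "n_screened", min = 1L)
  hits <- sum(calls$top_hit, na.rm = TRUE)
  if (n_screened < hits) abort("`n_screened` is smaller than the hit count")
  tibble(
    n_top_hits = hits,
    n_screened = n_screened,
    genome_fraction_pct = round(100 * hits / n_screened, 1)
  )
}
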