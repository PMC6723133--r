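# Secondary sectoring assay: data-driven threshold and positive calls.

parse_sector_counts <- function(x) {
  x_chr <- trimws(as.character(x))
  brown <- toupper(x_chr) %in% c(BROWN_TOKEN, "UNCOUNTABLE_BROWN")
  count <- suppressWarnings(as.numeric(x_chr))
  bad <- !brown & (is.na(count) | count < 0 | count != floor(count))
  if (any(bad)) {
    abort(paste0("invalid sector counts (need non-negative integers or \"BROWN\"): ",
                 paste(utils::head(x_chr[bad], 5), collapse = ", ")))
  }
  list(count = ifelse(brown, NA_real_, count), brown = brown)
}

#' Derive the sectoring-assay positivity threshold from control counts
#'
#' The threshold is the rounded mean sector count of a control plate plus a
#' fixed margin; with the study's control baseline of 11 sectors and the
#' default margin of 2 this yields the "13 or more sectors" rule. Uncountable
#' all-brown observations are dropped from the mean.
#'
#' @param control_counts Tibble with columns `strain_id` and `sector_count`
#'   (integer counts or `"BROWN"`).
#' @param margin Integer margin added over the control average.
#' @param per_strain If `TRUE`, average per strain first and then across
#'   strains; default pools all countable observations.
#' @return Integer threshold.
#' @export
compute_sector_threshold <- function(control_counts, margin = 2L,
                                     per_strain = FALSE) {
  margin <- check_count(margin, "margin")
  parsed <- parse_sector_counts(control_counts$sector_count)
  if (all(parsed$brown)) abort("no countable control observations")
  if (per_strain) {
    by_strain <- tapply(parsed$count, control_counts$strain_id, mean, na.rm = TRUE)
    baseline <- mean(by_strain, na.rm = TRUE)
  } else {
    baseline <- mean(parsed$count, na.rm = TRUE)
  }
  as.integer(round(baseline) + margin)
}

#' Call strains positive for LOH at the secondary locus
#'
#' A strain is positive when its mean sector count over countable replicates
#' meets or exceeds the threshold. Strains whose replicates are all uncountable
#' (entirely brown patches) cannot be assessed and carry `positive = NA`.
#'
#' @param counts Tibble with `strain_id`, `replicate_id`, `sector_count`
#'   (integer counts or `"BROWN"`).
#' @param threshold Non-negative integer threshold (see
#'   [compute_sector_threshold()]).
#' @param strict If `TRUE`, require every countable replicate to meet the
#'   threshold instead of the replicate mean.
#' @return Tibble per strain: `n_replicates`, `n_countable`, `mean_sectors`,
#'   `assessable`, `positive` (logical, `NA` when not assessable).
#' @export
call_sector_positive <- function(counts, threshold, strict = FALSE) {
  threshold <- check_count(threshold, "threshold")
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) abort("no sector observations supplied")
  parsed <- parse_sector_counts(counts$sector_count)
  counts$.count <- parsed$count

  counts %>%
    dplyr::group_by(.data$strain_id) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_countable = sum(!is.na(.data$.count)),
      mean_sectors = if (any(!is.na(.data$.count))) mean(.data$.count, na.rm = TRUE) else NA_real_,
      assessable = any(!is.na(.data$.count)),
      positive = if (!any(!is.na(.data$.count))) {
        NA
      } else if (strict) {
        all(.data$.count[!is.na(.data$.count)] >= threshold)
      } else {
        mean(.data$.count, na.rm = TRUE) >= threshold
      },
      .groups = "drop"
    )
}
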