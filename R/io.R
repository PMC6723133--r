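# Readers and writers for the pipeline's tabular formats: TSV tables, BED gene
# maps, newline gene lists, two-column annotation TSV or GAF 2.x.

#' Read a gene coordinate map from BED
#'
#' BED's 0-based half-open intervals are converted to the package's internal
#' 1-based inclusive convention (the conversion GenomicRanges applies on
#' import). Loci are sorted by position within each chromosome and given an
#' ordinal index; duplicate gene names are rejected.
#'
#' @param path Path to a 3-6 column BED file (column 4, when present, is the
#'   gene id).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   `ordinal`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 3 &&
      !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      as.numeric(f[2]) < as.numeric(f[3])
    if (!ok) abort(paste0("malformed BED line ", i, " in ", path, ": ", lines[i]))
  }
  gr <- rtracklayer::import(path, format = "BED")
  name <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  if (anyDuplicated(name)) {
    abort(paste0("duplicate gene names in ", path, ": ",
                 paste(utils::head(unique(name[duplicated(name)]), 5), collapse = ", ")))
  }
  loci <- tibble(
    gene_id = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  validate_loci(loci)
}

#' Write a gene coordinate map as 6-column BED
#'
#' Internal 1-based inclusive coordinates are converted back to BED's 0-based
#' half-open convention on export.
#'
#' @param loci Tibble with `gene_id`, `chrom`, `start`, `end` (and optionally
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  loci <- as_tibble(loci)
  strand <- if ("strand" %in% names(loci)) loci$strand else "+"
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = strand
  )
  gr$name <- loci$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a newline-delimited gene list
#'
#' @param path Path to a text file, one gene id per line; blank lines and
#'   `#` comments are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Write a newline-delimited gene list
#'
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read gene-term annotations (two-column TSV or GAF 2.x)
#'
#' A plain two-column TSV must have columns `gene` and `term` (a header row is
#' expected). GAF 2.x files (detected by the `!gaf-version` pragma or the
#' `.gaf` extension) use column 2 (DB object symbol), column 5 (term id) and
#' column 9 (aspect).
#'
#' @param path Path to the annotation file.
#' @return Tibble with `gene`, `term` and, for GAF input, `aspect`.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1)
  is_gaf <- grepl("^!gaf-version", first) || grepl("\\.gaf$", path)
  if (is_gaf) {
    raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                           col_types = readr::cols(.default = "c"))
    if (ncol(raw) < 9) abort("GAF file must have at least 9 columns")
    tibble(gene = raw[[2]], term = raw[[5]], aspect = raw[[9]])
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    stopifnot(all(c("gene", "term") %in% names(tab)))
    as_tibble(tab)
  }
}

#' Read a child-parent term hierarchy
#'
#' @param path Two-column TSV with header columns `child`, `parent`.
#' @return Tibble with `child`, `parent`.
#' @export
read_hierarchy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("child", "parent") %in% names(tab)))
  as_tibble(tab)
}

# TSV with a commented provenance header naming the tool version and the
# thresholds applied at that stage.
write_stage_tsv <- function(x, path, thresholds = list()) {
  version <- as.character(utils::packageVersion("lohscreen"))
  thr <- if (length(thresholds) > 0) {
    paste(names(thresholds), unlist(thresholds), sep = "=", collapse = " ")
  } else {
    "none"
  }
  header <- paste0("# lohscreen v", version, " | thresholds: ", thr)
  writeLines(header, path)
  x <- as_tibble(x)
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                      ~ purrr::map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

# Reads a stage TSV back, skipping the provenance comment.
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
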