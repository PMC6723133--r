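# Term-enrichment decisions: one-sided Fisher (hypergeometric) test per term,
# Benjamini-Hochberg critical values, and slim-term rollup over a parent DAG.

#' One-sided enrichment test for a single term
#'
#' Fisher's exact test for over-representation of a gene set (term) among the
#' hits, i.e. the upper hypergeometric tail `P(X >= a)` with
#' `X ~ Hypergeometric(N = |background|, K = |term n background|, n = |hits|)`.
#' Terms are restricted to the background before counting; a term disjoint from
#' the background yields `p = 1` with a warning.
#'
#' @param hits Character vector of hit genes (must lie in `background`).
#' @param background Character vector of all genes screened.
#' @param term_genes Character vector of genes annotated to the term.
#' @return One-row tibble with the 2x2 counts `a` (hits in term), `b` (hits not
#'   in term), `c` (non-hit background genes in term), `d` (non-hit background
#'   genes not in term) and the one-sided `p`.
#' @export
fisher_term_test <- function(hits, background, term_genes) {
  background <- unique(background)
  hits <- unique(hits)
  offenders <- setdiff(hits, background)
  if (length(offenders) > 0) {
    abort(paste0("hit genes absent from the background: ",
                 paste(utils::head(offenders, 10), collapse = ", ")))
  }
  term <- intersect(unique(term_genes), background)
  N <- length(background)
  n <- length(hits)
  K <- length(term)
  a <- length(intersect(hits, term))
  b <- n - a
  cc <- K - a
  d <- N - n - cc
  if (K == 0) {
    warn("term has no genes in the background; p = 1")
    p <- 1
  } else {
    p <- sum(dhyper(a:min(K, n), K, N - K, n))
  }
  tibble(a = a, b = b, c = cc, d = d, p = min(p, 1))
}

#' Benjamini-Hochberg step-up decisions
#'
#' Computes the per-rank critical values `rank / m * q` and the step-up
#' decision: all p-values with rank up to the largest rank whose ordered
#' p-value sits at or below its critical value are significant. The literal
#' per-rank comparison (`p_(i) <= i/m * q` at its own rank only) is returned
#' alongside for transparency; the step-up closure is the decision used.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q False-discovery-rate level.
#' @return Tibble in input order: `p`, `rank`, `bh_critical`, `significant`
#'   (step-up) and `significant_literal` (per-rank comparison).
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.03, 0.2), q = 0.05)
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble(p = numeric(0), rank = integer(0), bh_critical = numeric(0),
                  significant = logical(0), significant_literal = logical(0)))
  }
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  critical <- rank / m * q
  passing <- which(sort(p) <= seq_len(m) / m * q)
  k_star <- if (length(passing) > 0) max(passing) else 0L
  tibble(
    p = p,
    rank = rank,
    bh_critical = critical,
    significant = rank <= k_star,
    significant_literal = p <= critical
  )
}

#' Test every annotated term for enrichment among the hits
#'
#' Runs [fisher_term_test()] (or a binomial-tail variant) for each term in a
#' gene-term annotation table, then applies [bh_adjust()] across terms.
#'
#' @inheritParams fisher_term_test
#' @param annotations Tibble/data frame with columns `gene` and `term` (e.g.
#'   from [read_annotations()]).
#' @param q False-discovery-rate level for the BH procedure.
#' @param method `"hypergeometric"` (Fisher one-sided, default) or
#'   `"binomial"` (`P(Bin(|hits|, K/N) >= a)`), an approximation in the style
#'   of binomial-based term finders.
#' @return Tibble with one row per term: 2x2 counts, `p`, `rank`,
#'   `bh_critical`, `significant`, `significant_literal`.
#' @export
enrich_terms <- function(hits, background, annotations, q = 0.05,
                         method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  annotations <- as_tibble(annotations)
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  background <- unique(background)
  hits <- unique(hits)
  term_sets <- split(annotations$gene, annotations$term)
  res <- purrr::map_dfr(names(term_sets), function(tm) {
    out <- fisher_term_test(hits, background, term_sets[[tm]])
    if (method == "binomial") {
      K <- out$a + out$c
      out$p <- if (K == 0) 1 else {
        min(1, pbinom(out$a - 1, length(hits), K / length(background),
                      lower.tail = FALSE))
      }
    }
    dplyr::bind_cols(tibble(term_id = tm), out)
  })
  dplyr::bind_cols(
    res[setdiff(names(res), "p")],
    bh_adjust(res$p, q = q)
  ) %>%
    dplyr::relocate("term_id", "a", "b", "c", "d", "p")
}

# Ancestors (inclusive) of each node in a child->parent table, by breadth-first
# closure; errors on cycles, naming one offending cycle.
ancestor_closure <- function(hierarchy) {
  hierarchy <- as_tibble(hierarchy)
  stopifnot(all(c("child", "parent") %in% names(hierarchy)))
  parents <- split(hierarchy$parent, hierarchy$child)
  nodes <- unique(c(hierarchy$child, hierarchy$parent))
  closure <- list()
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 active, 2 done
  visit <- function(node, path) {
    if (state[[node]] == 1L) {
      cycle <- c(path[which(path == node):length(path)], node)
      abort(paste0("cycle in term hierarchy: ", paste(cycle, collapse = " -> ")))
    }
    if (state[[node]] == 2L) return(closure[[node]])
    state[[node]] <<- 1L
    anc <- node
    for (par in unique(parents[[node]])) {
      anc <- union(anc, visit(par, c(path, node)))
    }
    state[[node]] <<- 2L
    closure[[node]] <<- anc
    anc
  }
  for (node in nodes) visit(node, character(0))
  closure
}

#' Roll granular annotations up to a slim term set
#'
#' Maps each gene to every slim term that is an ancestor of (or equal to) any
#' of its annotated terms, using the transitive closure of a child -> parent
#' table. Genes supplied via `genes` that carry no annotation at all map to
#' `unknown_term` (the aspect's "unknown" catch-all) when one is given;
#' annotated genes with no slim ancestor are simply unmapped.
#'
#' @param gene_terms Tibble with columns `gene`, `term` (granular annotations).
#' @param slim_terms Character vector of slim term ids.
#' @param hierarchy Tibble with columns `child`, `parent`; must be acyclic.
#' @param genes Optional character vector of all genes under consideration.
#' @param unknown_term Optional term id assigned to genes with no annotations.
#' @return Tibble with columns `gene`, `slim_term`.
#' @export
slim_rollup <- function(gene_terms, slim_terms, hierarchy,
                        genes = NULL, unknown_term = NULL) {
  gene_terms <- as_tibble(gene_terms)
  stopifnot(all(c("gene", "term") %in% names(gene_terms)))
  closure <- ancestor_closure(hierarchy)
  anc_of <- function(term) {
    if (term %in% names(closure)) closure[[term]] else term
  }
  mapped <- gene_terms %>%
    dplyr::mutate(slim_term = purrr::map(.data$term, function(tm) {
      intersect(anc_of(tm), slim_terms)
    })) %>%
    tidyr::unnest("slim_term") %>%
    dplyr::distinct(.data$gene, .data$slim_term)
  if (!is.null(genes) && !is.null(unknown_term)) {
    unannotated <- setdiff(genes, gene_terms$gene)
    if (length(unannotated) > 0) {
      mapped <- dplyr::bind_rows(
        mapped, tibble(gene = unannotated, slim_term = unknown_term)
      )
    }
  }
  dplyr::arrange(mapped, .data$gene, .data$slim_term)
}
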