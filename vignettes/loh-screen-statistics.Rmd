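---
title: "Statistical methods for yeast LOH deletion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for yeast LOH deletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscreen)
```

## The problem

Loss of heterozygosity (LOH) — the conversion of a heterozygous locus to a
homozygous or hemizygous state — is a hallmark of genome instability. In
diploid *Saccharomyces cerevisiae*, the mating-type locus provides a clean
readout: a *MATa/MATα* diploid does not mate, so any cell that mates with a
haploid tester must have lost one *MAT* allele. Screening a heterozygous
deletion collection (≈6,500 strains, one gene disrupted per strain) with both
tester types identifies genes whose single-copy loss raises the LOH rate —
candidate haploinsufficient genome-stability genes.

`lohscreen` implements the full statistical chain such a screen needs:

1. ordinal scoring of mating-plate colony counts and the top-hit calling rule;
2. a secondary sectoring assay at a second heterozygous locus (*MET15*:
   cells that lose the functional copy precipitate PbS on lead plates and
   show dark sectors), with a control-derived threshold;
3. overlap statistics between independent screens' hit lists;
4. GO term enrichment with Benjamini–Hochberg control;
5. a positional scan for hit-dense chromosomal intervals;
6. Luria–Delbrück fluctuation analysis for quantitative LOH rates.

A synthetic-data generator reproduces the statistical structure of every
input, so the whole chain is testable without wet-lab data.

## Plate scoring and top-hit calling

Each strain is pinned against each tester in four replicates; colony counts
map onto an ordinal scale: 0 colonies → "0", 1–9 → "+", 10–19 → "++",
20–29 → "+++", 30 and above → "++++". The published ranges leave the count
30 itself unassigned ("20–29" vs "above 30"); we assign ≥30 to "++++" for
contiguity.

A strain × tester pairing qualifies when **all four replicates score at least
"+++"**. This is the effective caller: it implies the summed score ≥12 and,
because control plates show background growth of at most "++" in ~2% of
wells, it cannot be satisfied by background noise — specificity on such
backgrounds is 1 by construction. The summed 0–16 score is retained in the
output for transparency. A strain is a top-hit when either tester pairing
qualifies. Exclusions: lawn growth with *both* testers (pre-existing
resistance, not LOH — these strains lawn in every replicate), or an annotated
mating phenotype. A lawn with one tester only voids that pairing; the other
tester's replicates can still qualify the strain. That choice follows the
exclusion rule's own wording, which requires lawns with both testers.

```{r calling}
obs <- tibble::tibble(
  strain_id = "example",
  tester = rep(c("MATa", "MATalpha"), each = 4),
  replicate_id = rep(paste0("rep", 1:4), 2),
  colony_count = as.character(c(25, 31, 22, 20, 3, 0, 1, 0))
)
call_top_hits(obs)
```

## Sectoring threshold

The secondary assay counts dark sectors per patch over 2 biological × 3
technical replicates. The positivity threshold is data-driven: the rounded
mean sector count of a control plate (no known LOH genes) plus a margin of 2,
matching the "baseline 11 → threshold 13" derivation. The control mean is
pooled over all countable counts; a per-strain-first average is available
(`per_strain = TRUE`) and coincides on balanced designs. The published
decision phrase ("average of more than 13 sectors … in each replicate") is
ambiguous between a mean rule and an every-replicate rule; the mean over the
six replicates compared with ≥ threshold is the default, and
`strict = TRUE` gives the every-replicate reading. Entirely brown patches are
uncountable; such replicates are dropped from the mean rather than imputed,
and a strain with no countable replicate is reported `NOT ASSESSABLE`
(`positive = NA`) rather than scored.

## Overlap between screens

For two hit lists of sizes $n_1$, $n_2$ drawn from a common background of
$N$ genes, the expected overlap is $n_1 n_2 / N$ and the **representation
factor** is the observed overlap divided by that expectation. Significance
uses the hypergeometric tail for $X \sim \mathrm{Hyper}(N, n_1, n_2)$, with
the direction set by the departure from expectation: $P(X \ge k)$ when
$k \ge n_1 n_2 / N$, else $P(X \le k)$. This directional rule is the only one
consistent with all five published comparison p-values we reproduce (the
depleted comparison yields 0.351 only as a lower tail), so it is the default
and is reported alongside the p-value. Although the original analyses cite a
normal approximation, the exact tail reproduces every printed value at
printed precision, while the normal approximation understates deep-tail
p-values by an order of magnitude; the exact tail is therefore the default
and `method = "normal"` / `"normal-cc"` exist for comparison only. The
background $N$ is always explicit — 6,477 when comparing heterozygous-
collection screens, 5,134 (with the 180 non-essential hits) against
homozygous-collection screens — and is never inferred from the lists.

```{r overlap}
round(representation_factor(26, 217, 332, 6477), 1)
overlap_pvalue(26, 217, 332, 6477)
```

## GO term enrichment

Each term is tested one-sided for over-representation (the screens report
only enrichment): $p = P(X \ge a)$ with
$X \sim \mathrm{Hyper}(|bg|, |term \cap bg|, |hits|)$, identical to Fisher's
exact test with `alternative = "greater"`. Decisions use the
Benjamini–Hochberg step-up at $Q = 0.05$: with $m$ terms, the critical value
at rank $i$ is $iQ/m$, and all terms up to the largest rank whose ordered p
sits at or below its critical value are significant. The literal per-rank
comparison is also emitted (`significant_literal`) because published
summaries sometimes phrase the rule that way; the step-up closure is the
decision. A binomial-tail variant (`method = "binomial"`) approximates
binomial-based term finders but is not a replication of any web tool's
annotation snapshot. Slim rollup maps each gene to every slim term that is an
ancestor of any of its annotations via the transitive closure of a
child → parent table; cycles are rejected with the offending path named, and
genes with no annotations can be assigned an aspect's "unknown" term.

## Positional gene enrichment

To find chromosomal neighbourhoods dense in hits, the scan enumerates, per
chromosome, every gene-ordinal interval whose first and last genes are hits
($h(h+1)/2$ candidates for $h$ hits — any interval maximising enrichment is
hit-delimited, since trimming a non-hit end gene only sharpens it). Each
candidate is scored by the upper hypergeometric tail
$P(X \ge \text{hits in region})$ with region size as the draw, then adjusted
over the number of candidates tested — Bonferroni by default (conservative
and exactly reproducible by a brute-force oracle), BH optionally. Reported
regions need adjusted $p < 0.01$ and ≥3 hit genes, thresholds chosen to match
the published refinement criteria; the enumeration and correction themselves
are this package's own construction (the original web tool's internals are
unpublished), so published region p-values are not reproduction targets.

Nested significant intervals are redundant descriptions of one cluster, so a
collapse step resolves every nested pair in favour of the sharper region
(smaller adjusted p, ties to the narrower interval). We chose this over
dropping only enclosing regions because a significant cluster otherwise
reports itself once per sub-interval passing the filters; the unfiltered list
remains available with `collapse = FALSE`, mirroring reports of both large
regions and further-enriched subsections. Coordinates are BED on disk
(0-based half-open) and 1-based inclusive internally and in reports; strand
is ignored (position only).

## Fluctuation analysis

Quantitative LOH rates come from the classic fluctuation experiment:
parallel cultures grow from small inocula, mutants are counted on selective
plates, and the mutation number $m$ (expected mutation events per culture) is
estimated from the full count distribution. Under the Lea–Coulson model (no
differential mutant fitness, complete plating) the count pmf follows the
Ma–Sandri–Sarkar recursion

$$p_0 = e^{-m}, \qquad p_n = \frac{m}{n} \sum_{j=0}^{n-1} \frac{p_j}{n-j+1},$$

implemented in C++ because it is $O(k_{\max}^2)$ and sits inside the
likelihood optimiser. The MLE maximises $\sum_i \log p_{k_i}(m)$ with the pmf
truncated at the largest observed count, using Brent-style bracketed search
(absolute tolerance $10^{-6}$ on $m$) started near the $p_0$-method estimate
$-\log(\text{zero fraction})$. Counts above $10^4$ are jackpots — single
early mutations whose exact size carries little extra information but makes
the recursion quadratic-in-$10^6$ — and are capped at $10^4$ with a flag.

95% confidence intervals are profile-likelihood bounds: the $m$ values where
$2[\ell(\hat m) - \ell(m)] = \chi^2_{1,0.95} = 3.841$, found by bisection on
each side (lower bound clipped at 0; with all-zero counts the interval is
$[0, 3.841/2C]$ for $C$ cultures, from the closed-form likelihood
$e^{-Cm}$). Rates use the final-population convention
$\text{rate} = m / N_t$ with $N_t$ the (mean) measured final population.
Strains are compared to a reference by fold change of point rates, with
significance by **disjoint 95% CIs** — the decision rule used for the
published rate panel, which behaves like a conservative two-sample test on
fluctuation data. Two biological replicates are pooled into one fit by
default; fitting them separately is a matter of subsetting the input table.
Culture selection mirrors the published protocol: among OD readings above
0.5, keep the 15 closest to their median, ties to input order.

```{r fluctuation}
sim <- simulate_fluctuation(fluctuation_sim_config(
  m_true = 2, n_final = 1e8, n_cultures = 15, seed = 42
))
fit <- fit_fluctuation(sim$count, n_final = 1e8)
tidy(fit)
```

## What the synthetic generator does and does not emulate

The generators reproduce the *statistical* structure the downstream analysis
assumes, with the study's stated conditions as defaults:

* **Screen plates**: per-well ordinal scores; non-hit wells grow with
  probability 0.02 (the control false-positive rate) and then score at most
  "++" by default; hit wells draw from a distribution concentrated at
  "+++"/"++++"; a small fraction of strains (14/6477 by default) lawn with
  both testers in every replicate.
* **Sector counts**: Poisson around a configurable mean (11 for the control
  baseline), 2 biological × 3 technical replicates by default.
* **Gene maps**: equal-length genes on uniform spacing, with planted clusters
  whose hit genes anchor both cluster ends so the planted span is
  recoverable, plus uniform background hits.
* **Fluctuation counts**: mutation events Poisson($m$); each clone's final
  size is $\lfloor 1/U \rfloor$, $U \sim \mathrm{Unif}(0,1)$, truncated at
  $N_t$ — the standard Lea–Coulson-consistent sampler, $O(1)$ per mutation,
  whose compound-Poisson sum has exactly the Ma–Sandri–Sarkar pmf (verified
  by a chi-square test in the suite).

Every generator takes an explicit integer seed and restores the global RNG
state, so identical configurations are byte-reproducible.

Not emulated: mating biology and growth kinetics, plate edge effects,
colony-size visibility bias in sector counting, mutant-fitness differences or
partial plating in the fluctuation model, and real yeast gene geometry
(variable gene lengths, strand structure, centromeres). Passing tests
therefore demonstrate the statistical machinery is correct under the model's
assumptions, not that those assumptions hold on any particular wet-lab
dataset.

## Numerical choices and problem sizes

* Hypergeometric tails are sums of `dhyper` pmf terms over the tail; they
  agree with exhaustive enumeration of all draws for every instance with
  $N \le 25$ and with direct combinatorial counting elsewhere.
* The Lea–Coulson tail is heavy ($P(K > k) \approx m/k$), so the pmf vector
  never "completes"; truncation at the observed maximum is the standard
  likelihood treatment, and the capped-jackpot policy bounds the cost.
* Likelihood unimodality in $m$ is asserted on fixtures; the MLE matches a
  $10^{-4}$-step grid search within $10^{-3}$.
* The test suite sizes simulations to what the statistics need rather than
  what a cluster could run: 200 replicates for median-bias checks at
  $m \in \{0.5, 2, 8\}$ (15 cultures each), 500 replicates for CI coverage,
  100 runs for the 20×-mutant significance check, 200 seeded genomes for the
  positional scan's false-positive control, and 200 seeded control plates for
  the threshold derivation.
* Coverage of the 95% profile CI at 15 cultures is checked against a
  95% ± 3% band.

## Limitations

* The calling rules are faithful to one screen design (4 replicates, two
  testers); other designs need their own qualification rule.
* GO results depend entirely on the annotation snapshot supplied; the package
  deliberately does not bundle one.
* The positional scan's Bonferroni correction is conservative for heavily
  overlapping candidate intervals; BH is available but changes the
  family-wise guarantee.
* Fluctuation fits assume complete plating and neutral mutants; rates from
  experiments violating either are biased in known directions (see the
  fluctuation-analysis literature for corrections).
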