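---
title: "PTM enrichment analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PTM enrichment analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmenrich)
```

`ptmenrich` predicts which classes of posttranslational modification (PTM)
are statistically enriched in the outcome of a proteomics experiment, and
converts those classes into exact chemical modifications for a refined
database search. This vignette is the package's own account of the
statistics it implements, the parameters that matter, and the design
decisions taken where the problem was genuinely open.

## The annotation model

A protein's PTM profile is taken from curated annotation, not from spectra.
Two fields of a Swiss-Prot style record carry that information:

* **KW lines** — protein-level keywords. Those that belong to the PTM
  keyword universe (the parent keywords of the controlled vocabulary, plus
  an optional supplementary list of umbrella keywords such as
  "Phosphoprotein" or "Glycoprotein") become terms directly.
* **FT features** — residue-level annotations. Only `MOD_RES`, `CROSSLNK`,
  and `LIPID` features are considered. A feature's note, truncated at the
  first `;` (which separates the modification name from enzyme/evidence
  qualifiers like "by AURKB"), must match a controlled-vocabulary
  modification name exactly (case-sensitively); the matched entry
  contributes its parent keyword as the protein's term.

Proteins with no PTM terms stay in the database: they are real members of
the statistical population and inflate neither enrichment direction.
Secondary accessions resolve to the primary record, and isoform suffixes
(`P12345-2`) are stripped before lookup, because annotation is per
canonical entry. The enrichment population defaults to one organism's
slice of the database — selected by case-insensitive substring match on
the organism name — since cross-species background frequencies are not
comparable; the full database or a user-supplied detected-proteome
background can be chosen instead.

## SEA: the hypergeometric test

For a list with $n$ mapped proteins against a population of $N$ proteins of
which $K$ carry a term, the probability of an overlap at least as large as
the observed $m$ is the upper hypergeometric tail
$$p = \sum_{x=m}^{\min(K,n)} \binom{K}{x}\binom{N-K}{n-x}\Big/\binom{N}{n}.$$
The test is one-sided (over-representation), matching its use for
selecting modifications worth searching for; under-representation is not
reported. The implementation delegates to the hypergeometric survival
function (`phyper(..., lower.tail = FALSE)`), which works in log space and
is stable for large populations; the test suite verifies it against exact
integer-binomial enumeration over every valid $(N, K, n, m)$ with
$N \le 25$ to a relative error of $10^{-12}$.

Terms with population count $K$ below `min_population_count` (default 5)
are not tested: single-protein terms are always nominally "enriched" when
that protein is listed, and carry no transferable signal. Adjustment across
the reported terms is Benjamini–Hochberg by default, with Bonferroni, Holm,
or none selectable.

## PSEA: the weighted running-sum statistic

Proteins are ranked by a score (descending; ties broken by accession so the
ranking is total and deterministic). For a term's member set $S$ with
$N_H = |S \cap \text{list}|$ hits, the running sum starts at zero and, at
list position $i$,

* gains $|r_i|^p / N_R$ if protein $i \in S$, where
  $N_R = \sum_{j \in S} |r_j|^p$,
* loses $1/(N - N_H)$ otherwise.

The enrichment score (ES) is the value at the first position of maximal
absolute deviation; the profile always returns to zero. With weight
$p = 0$ this is exactly the classical signed two-sample Kolmogorov–Smirnov
statistic comparing hit and miss positions. The default $p = 1$ weights
hits by their score magnitude, concentrating the statistic on strongly
changed proteins, which is the conventional choice for this family of
methods and what the package mirrors.

**Null distribution.** Significance comes from uniformly permuting the
score vector over the fixed accession order — equivalently, drawing the
member positions uniformly — and recomputing ES (`n_perm`, default 1000).
Protein-score permutation is the only mode: with triplicate designs there
are too few samples for label permutation to have resolution.

**NES, p, FDR.** ES values are not comparable across set sizes, so each
observed ES is normalized by the mean |ES| of the same-sign permutation
nulls of its own term, giving the NES. The nominal p-value uses the
pseudo-count form $(1 + \#\{|e| \ge |ES|\})/(1 + |S_{\text{same sign}}|)$,
so a finite permutation run never reports exactly zero. The FDR q for a
term is the fraction of pooled same-sign null NES at least as extreme,
divided by the corresponding fraction of observed NES, clipped to
$[0, 1]$; a monotone cleanup (running minimum from the weakest |NES|
upward, within each sign) guarantees a stronger NES never receives a
larger q. Adjusted nominal p-values (BH) are reported alongside q because
the two summarize different nulls and neither dominates the other.

**Leading edge.** For ES > 0, the leading edge is the member proteins at
or before the running-sum peak. The negative branch is not symmetric by
any published convention; here it is the members at or after the peak —
the core of the depletion signal at the bottom of the list — and both
branches are documented so downstream users are not misled by the
positive-case phrasing.

## Ranking scores and occupancy ratios

The default PSEA input score per protein is
$\operatorname{sign}(\log_2 FC) \cdot (-\log_{10} p)$ from an
equal-variance two-sample t-test on replicate intensities, which preserves
both direction and strength of evidence; the raw log2 fold change is
selectable when p-values are unavailable or unstable at very low replicate
counts. SEA input lists default to adjusted p < 0.05, optionally with a
|log2FC| > 0.6 gate; both are configurable. Missing intensities are treated
as absent (not zero), and proteins with fewer than two observed replicates
in a group are skipped and reported.

Modified-peptide occupancy is normalized in three steps: per-channel total
normalization (removes labeling/loading differences), division by the
summed normalized intensity of the same protein's unmodified peptides
(cancels protein-level abundance changes, isolating occupancy), and
per-condition averaging against the control channels. The first two steps
make the ratio invariant to global channel scaling and to per-protein
abundance scaling — both properties are asserted on randomized tables in
the test suite. A modified peptide whose protein has no unmodified peptide
is excluded and reported: its occupancy is not identifiable.

## Numerical choices

* **Peak tie-break.** The running-sum peak is the first index attaining
  the maximal |value|, found with a relative tolerance of $10^{-12}$ on
  the maximum so that exact ties between a positive and a later negative
  deviation — which floating-point `cumsum` perturbs at the last bit —
  resolve to the earlier position, as exact arithmetic would.
* **Per-term sub-seeds.** Each term's permutation stream is seeded by
  `seed + hash(term)` (a 31-bit polynomial string hash), so adding or
  removing one term never changes another term's null, and the RNG is
  consumed only after canonical ranking, making input row order
  irrelevant.
* **Degenerate cases** are warned, not silently patched: ES exactly 0
  (p = 1, NES 0), no same-sign null (NES flagged `NA`, p = 1), zero pooled
  variance with equal means (t = 0, p = 1); zero pooled variance with
  different means and an all-zero weighted hit set are errors.
* **Database serialization** is versioned gzip-compressed JSON; loads of
  corrupted payloads or newer version tags fail loudly rather than
  guessing.

## The synthetic-data generator

The generator emulates the study shape the statistics are designed for: a
few hundred proteins (default 200) annotated with a handful of terms
(default 8) at moderate prevalence (default 0.2), scores distributed as
treatment-vs-control evidence — Normal(δ, σ²) for members of one planted
term, Normal(0, σ²) otherwise, with δ = 3 and σ = 1 as the planted-effect
defaults and δ = 0 as the exchangeable null used for calibration; a
heavy-tailed option (t with 3 df) is available for robustness checks.
Intensity tables use triplicate control/treatment channels with
multiplicative log2-scale noise (SD 0.1 by default, a typical
replicate-level variation for multiplexed quantification; 0 for exact
recovery checks), a planted log2 fold change of 1, and a planted occupancy
ratio of 0.5 at 20% baseline modified fraction.

Everything is a pure function of the configuration and seed, and the
rendered flat-file and vocabulary fixtures re-parse to identical databases,
so the parsers are exercised by the same harness. What the generator does
*not* emulate — and what passing tests therefore do not demonstrate —
includes correlated annotation structure (real PTM terms overlap heavily
and hierarchically), missingness patterns and intensity-dependent variance
of real quantification, shared-peptide protein inference, and any spectrum-
level effect. Calibration statements hold under the stated Gaussian score
model.

The test suite and the bundled acceptance script run at deliberately
moderate problem sizes (databases of 100–200 proteins, 200–1000
permutations, 100–500 simulation replicates), which are sufficient for the
binomial tolerance bands they assert.

## Known limitations

* Enrichment can only surface what is annotated: low-abundance or rarely
  curated PTMs are invisible, and heavily curated classes (e.g., disulfide
  bonds) are correspondingly favored — interpret against the term
  frequency table (`term_frequencies()`).
* Umbrella keywords ("Phosphoprotein") have no exact mass and therefore
  export no modification row; they are reported as unmatched rather than
  silently dropped.
* Only the current flat-file feature dialect (`/note="..."` qualifiers) is
  parsed; the pre-2019 columnar dialect is rejected with a clear error
  rather than half-parsed.
* The package emits search-engine configuration but never runs a search
  engine, performs peptide-spectrum matching, or re-estimates search FDR.
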