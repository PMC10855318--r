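---
title: "Relating antiphage defense-system content to phage resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating antiphage defense-system content to phage resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedefense)
```

## The problem

Bacteria defend themselves against bacteriophage with dozens of
genetically encoded antiphage systems — restriction–modification,
CRISPR–Cas, abortive-infection modules such as CBASS, nucleases such as
Gabija, and many more — often clustered in defense islands that move
between strains by horizontal gene transfer. For phage therapy against
pathogens such as *Pseudomonas aeruginosa*, a practical question is
whether the *number and identity* of the defense systems a clinical
isolate carries predicts its phenotypic resistance to a diverse phage
panel.

`phagedefense` implements the comparative analysis that answers this
question for a strains-by-phages panel:

1. ingest per-locus defense-system annotations (the PADLOC tabular
   dialect), grouping subtypes under canonical system names;
2. score each strain's susceptibility from plaque formation, and its
   average efficiency of plating (EOP) from titers;
3. correlate defense-system burden with both phenotypes;
4. partition strains into four rank-based susceptibility groups and ask
   which systems are over-represented among resistant strains.

The package also ships a calibrated synthetic panel generator with
known ground truth, so that the whole pipeline can be validated without
any external data.

## Data model

A **defense call** is one annotated system locus in one strain. Raw
annotator labels carry subtype suffixes (`cbass_type_II`,
`zorya_type_I`); `canonicalize_system()` strips these using an editable
bundled rule table and maps the stem to a canonical display name, so
subtypes of one system are analysed together. Each canonical name has a
**system class** — `validated` (experimentally validated or published
systems), `PDC` (phage-defense candidates identified by
guilt-by-embedding in defense islands), the `DMS-other` catch-all, and
`HEC` (Hma-embedded candidates) — and a **mechanism category**
(nuclease degradation, abortive infection, nucleic-acid modification,
protein modification, other, unknown) looked up from a bundled
transcription of the published mechanism table. Unknown names are
accepted and passed through with a notice rather than rejected: the
annotator's catalog grows between releases and ingestion should not
fail on new systems.

The **interaction matrix** stores one cell per (strain, phage) pair
with an explicit tested/untested state. This matters because real
panels are ragged: strains swapped into a panel late may have been
assayed against a subset of the phages (the generator emulates two such
strains tested against 44 of 70 phages). All per-strain scores use the
per-strain number of tested cells as the denominator, never the panel
size; a percentage over the phages actually assayed is the only
meaningful quantity for a partially tested strain. "Lysis from
without" — cell lysis by mass adsorption without productive
replication — is scored as a negative (resistant) outcome, and the
readers accept an `LFW` token for it.

## Scores

**Susceptibility percentage** of strain $s$:
$100 \cdot n_{+}(s) / n_{\mathrm{tested}}(s)$, the share of tested
phages forming plaques.

**Efficiency of plating.** For phage $p$ on strain $s$ with titer
$T(s,p)$ (PFU/mL), $\mathrm{EOP}(s,p) = T(s,p) / \max_{s'} T(s',p)$:
each phage is normalized to its best host in the panel, so EOP is
scale-invariant per phage and equals 1 on at least one strain whenever
the phage plates productively anywhere. Negative or nonproductive cells
have EOP 0; a phage with no positive cell anywhere yields an all-zero
column with a warning rather than a division by zero. The **average
EOP** of a strain is the mean over its tested cells, a soft-resistance
readout that credits partial suppression of plating which a binary
plaque call misses.

**Correlation.** `pearson_cor()` computes the product-moment
coefficient with a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and the
ordinary least-squares line for plotting — the "XY correlation" of
desktop statistics packages. It is written out explicitly (two-pass
means, centered sums) and cross-checked in the test suite against
`stats::cor.test()` and `stats::lm()` as independent oracles. No
multiple-testing correction is applied to the handful of panel-level
correlations, matching standard practice for this design.

## Susceptibility groups and prevalence

`assign_groups()` is rank-based, not threshold-based: strains are
sorted by susceptibility (ties broken by strain identifier, so the
partition is deterministic), split at the median into a resistant and a
susceptible half, and the `round(k_fraction * n)` most extreme strains
of each half form the "most resistant" / "most susceptible" groups
(10/40/40/10 for n = 100 at the default `k_fraction = 0.10`). The
realized cut points between groups are reported as
`implied_thresholds` so they can be compared against published
threshold descriptions, but they are an output of the ranking, not an
input. With an odd panel the resistant half receives the extra strain.

`prevalence()` asks, for each system, what share of its carrier strains
lies in the resistant half. At the default threshold the system is
called `resistant_prevalent` when that share is at least 52.5%,
`susceptible_prevalent` when the complementary share is, and `neither`
otherwise; since the threshold exceeds 50%, at most one label can
apply. The 52.5% default is the published operating point for this
analysis; it is configurable, and the comparison is inclusive
(`>= 52.5`) following the operative description of the rule. Systems
with fewer than `min_encoding = 15` carriers are still computed but
flagged `low_n`, and the pipeline's emitted table drops them unless
asked for all systems — percentages over a handful of carriers are too
unstable to classify confidently.

**Counting policy.** Whether a strain's "number of systems" counts
annotated loci or distinct canonical systems is genuinely ambiguous in
the field's reporting. The default counts loci (`count = "loci"`),
because annotators report per-locus hits and per-strain totals in real
panels exceed plausible distinct-type counts; `count = "distinct"` is a
switch. PDC, DMS-other and HEC calls are included in the burden by
default (`include_classes`), since candidate systems plausibly
contribute to resistance; both choices are exposed rather than hidden.

## The synthetic panel generator

No public ground-truth panel links defense annotations, plaque calls
and titers cell by cell, so the package generates its own. The model is
deliberately the simplest mechanism that produces the qualitative
structure the analysis assumes:

* strain $i$ carries system $s$ independently with probability
  $p_s$ from a catalog of 111 systems (67 named validated systems plus
  44 PDCs) whose carriage probabilities follow the published per-system
  occupancy of a real 100-strain clinical diversity panel where a count
  was printed — a few near-universal systems, a long tail of
  singletons — scaled so the expected burden is 14.2 systems per
  strain;
* the strain's latent susceptibility log-odds are
  $\alpha - \sum_{s \in i} \beta_s + \varepsilon_i$, with
  $\varepsilon_i \sim N(0, \sigma_{\mathrm{strain}})$ absorbing
  receptor structure, prophage content and everything else the burden
  does not explain;
* cell $(i,j)$ is plaque-positive with probability
  $\mathrm{logit}^{-1}(\mathrm{logit}_i + \delta_j)$, where
  $\delta_j \sim N(0, \sigma_{\mathrm{phage}})$ gives phages broad or
  narrow host ranges;
* positive cells receive lognormal titers,
  $10^{N(8,\,1)}$ PFU/mL — titers span orders of magnitude and EOP is
  per-phage scale-invariant, so only the shape matters.

Defaults were calibrated once by forward simulation and then frozen:
$\beta_s = 0.19$ for every system, $\alpha = 2.02$,
$\sigma_{\mathrm{strain}} = 0.95$, $\sigma_{\mathrm{phage}} = 1.3$.
Under these conditions the panel mean susceptibility sits near 38.7%,
and the realized count–susceptibility $R^2$ averages ≈ 0.24 across
replicates — inside the 0.15–0.35 window that brackets the weak
association reported for real *P. aeruginosa* panels. The negative
association and its approximate strength are therefore *designed into*
the defaults; what the generator validates is that the pipeline
recovers a known signal with correct error rates, not that real
genomes behave this way.

What the generator does **not** emulate, and what passing tests
therefore cannot show: linkage between systems (real defense islands
travel together, so carriage is correlated across systems and with
lineage), phage–system specificity (here a system reduces
susceptibility to all phages equally; real systems have phage-type
preferences), receptor-driven host tropism, multi-locus carriage of one
system in one genome, and any phylogenetic structure among strains.
Conclusions about real panels still require real data; the generator's
role is mechanical validation with known truth.

`recovery_experiment()` wraps the generator in a power study: at effect
multiplier 0 the two-sided rejection rate of the burden–susceptibility
test is its empirical type-I error (near the nominal 5%), and at the
default effect the directional rejection rate (p below the level *and*
a negative slope) is its power. Both rates are reported separately
because a directional rejection rule has a nominal null level of only
half the two-sided one — conflating them would make a calibrated test
look conservative.

## Numerical and formatting choices

* Ties: susceptibility ties at group boundaries break by strain
  identifier; titer ties for a phage's maximum give every tied strain
  EOP 1 (no tie-break needed).
* Degenerate inputs: zero-variance vectors and n < 3 raise classed
  errors from `pearson_cor()`; `metadata_summary()` converts them to
  not-computable rows so one constant column does not abort a report.
* Reports print percentages to 1 decimal, EOP to 4 decimals and
  correlation statistics in full; internal computation is always full
  precision. Output tables have stable sort orders (per-system tables
  descending by occupancy, ties by name), so identical inputs give
  byte-identical files.
* Reproducibility: the generator seeds R's Mersenne–Twister through
  `withr::local_seed()`, so a configuration (including its seed)
  regenerates a panel bit-for-bit without disturbing the caller's RNG
  state.

## Problem sizes used in validation

The test suite validates the correlation engine against a brute-force
product-moment oracle on 1000 random vectors (agreement to 1e-12), EOP
invariants on 100 random matrices, the group partition and prevalence
mirror-symmetry properties on dozens of randomized panels, the type-I
error of the burden test on 1000 null replicates of a full 100 × 70
panel, and its power and realized $R^2$ on 200 replicates at the
default effect. These sizes keep the whole suite under a minute while
leaving Monte-Carlo error well inside the asserted windows;
`scripts/acceptance.R` recomputes the same quantities end to end from a
freshly simulated panel.

## Worked example

```{r example, eval = FALSE}
panel <- simulate_panel(synthetic_config(seed = 1))
dir <- tempfile()
write_panel(panel, dir)

res <- run_pipeline(
  calls_path = file.path(dir, "calls.csv"),
  hostrange_path = file.path(dir, "hostrange.csv"),
  metadata_path = file.path(dir, "strains.tsv"),
  outdir = file.path(dir, "results")
)
res$correlation$count_vs_susceptibility
res$group_means
head(res$prevalence)
```

## Limitations

The analysis is correlational: a system prevalent among resistant
strains may hitchhike with the true cause on the same defense island,
and no phylogenetic correction is attempted (appropriate for a
deliberately diverse panel, misleading for a clonal one). Annotation
is homology-based, so a detected system need not be expressed or
functional. Prevalence percentages for systems carried by few strains
are noisy even when flagged; and the binary plaque call undercounts
"soft" resistance, which is why the EOP track exists alongside it.
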