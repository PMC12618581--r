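---
title: "Discovering conserved sex markers in diatoms and calling sexual-reproduction events in metatranscriptomes"
author: "diatomsex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved sex markers in diatoms and calling sexual-reproduction events in metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomsex)
```

## The problem

Diatom sexual reproduction is rarely observed in the ocean, yet it is the
life-cycle stage that restores cell size and drives recombination. Because
sexual cultures of several diatom species show a strongly conserved
transcriptional response, gene families that are (i) upregulated during sex
in every species where they occur and (ii) essentially silent in vegetative
cells can serve as molecular flags: if a field population transcribes
several of them at once, sexual reproduction is likely under way.

`diatomsex` implements that idea as a pipeline with five stages:

1. **Expression core** — count containers, CPM/TPM, TMM normalization and
   the expression-presence filter.
2. **DE integration** — a fold-change-threshold differential-expression
   test per mating stage (S, P, GZ, A: pheromone signalling, gametangia,
   gametes/zygotes, auxospores), Sidak aggregation of stage p-values per
   gene, and stage-wise multiple testing (Benjamini–Hochberg screening,
   Holm confirmation) at an overall FDR of 5%.
3. **Marker discovery** — the five-step search for conserved sex-specific
   families, an atlas-based specificity filter, curated (flagella) marker
   selection for centric diatoms, and matched control markers.
4. **Homolog mapping** — HMMER hit filtering and automated phylogenetic
   selection of environmental homologs inside midpoint-rooted marker
   trees.
5. **Event calling** — MAG-level TPM, percentile-calibrated per-marker
   thresholds, and the co-expression rule (positive control SPO11-2 plus
   at least two markers) that declares a sexual-reproduction event in a
   MAG × sample cell, with a control-marker audit of the false-positive
   rate and a Mann–Whitney association of events with genus abundance.

Every input the pipeline consumes can be generated synthetically with
ground truth (`simulate_*`), which is how the package tests itself.

## Statistical model and procedures

### Normalization

CPM divides counts by the (optionally TMM-corrected) library size;
TPM additionally divides by transcript length and renormalizes to one
million within a sample, or within a MAG × sample cell for
metatranscriptomes (`mag_tpm()`), which corrects for the MAG's relative
abundance. TMM (`tmm_factors()`) follows the published trimmed-mean-of-M
definition: reference sample by 75th-percentile CPM closest to the mean,
two-sided trims of 30% on M and 5% on A, inverse-variance-weighted mean of
the surviving M-values, factors rescaled to unit geometric mean. The trim
fractions are configuration knobs because the original description names
only the method. A gene counts as *expressed* when its CPM exceeds 1 in at
least three samples (strict inequality, per the description "more than one
count per million"); the estuarine preset (`scheldt_config()`) relaxes
this to CPM > 0.1 in two samples.

### The stand-in DE engine

The original analysis fitted negative-binomial GLMs and tested against an
absolute log2 fold-change threshold of one (TREAT-style). GLM fitting is
out of scope here; `de_test_stage()` provides a documented stand-in on
log2(CPM + 0.5): the effect is the difference of group means, and the
statistic is t = max(|log2FC| − τ, 0)/se with τ = 1 by default, so p = 1
whenever the estimate does not clear the threshold.

The default standard error is an empirical-Bayes, trend-moderated pooled
variance: each gene's residual variance comes from the one-way layout over
all condition groups of the species, is squeezed towards a lowess trend of
the log-variance on average log-CPM (prior df by the standard moments
estimator), and the prior df is added to the residual df. The design
rationale: with three replicates per condition an unmoderated t statistic
has ~4 residual df, and its heavy tails cannot produce p-values small
enough to survive genome-wide Benjamini–Hochberg screening when only a
handful of genes carry signal — the discovery step would be structurally
powerless regardless of effect size. Moderation is the field-standard
remedy; it leaves the null approximately calibrated (slightly
conservative on discrete counts, which preserves FDR control) while
letting genuine 8–64-fold effects reach genome-wide significance. A
`var_mode = "welch"` switch provides the plain Welch statistic for users
who want the unpooled form. Externally produced DE tables (e.g. from a
NB-GLM engine) can be ingested with `read_de_tsv()` and used everywhere
downstream.

### Stage-wise testing

Per gene, stage p-values are aggregated with the Sidak rule
1 − (1 − min p)^k; aggregates are BH-adjusted and screened at α = 0.05;
for screened genes the stage p-values are Holm-adjusted and confirmed at
the adjusted level α·R/m (R genes screened of m tested). This is the
standard screening/confirmation scheme controlling the overall FDR; a
stage can only be significant in a gene that passed screening.
"Significantly upregulated" downstream means stage-significant with a
positive fold change.

### Marker discovery

Step 1 keeps diatom-specific families expressed in at least three of the
four species; step 2 keeps families in which *every* expressed member gene
is significantly upregulated (at least one significant stage, no
significant downregulation in any stage) in *every* species where the
family is expressed; step 3 ranks by the mean log2 fold change pooled over
all significant upregulated (gene, stage) observations across species
(ties by family id; a species-mean-of-means alternative was considered and
rejected as the more convoluted reading). Steps 4–5 verify the top-ranked
families against a vegetative expression atlas: a family passes when its
maximum TPM over non-sexual atlas samples is at most 2, or its
sexual-mean/atlas-max separation is at least 5-fold. The original
judgement of "negligible expression" was visual; the OR-rule is this
package's explicit, configurable operationalization, and candidates
missing from the atlas species are flagged untestable rather than passed.

Control families (for the false-positive audit) must occur in at least
three of four reference species, be single-copy apart from at most one
duplication in one species, and show no significant upregulation during
sex anywhere; each target marker is matched greedily to the nearest unused
eligible family in (log10 mean non-sexual TPM, CV) space.

### Homolog mapping

HMMER per-sequence hits are kept at bit score ≥ 50 and E-value strictly
below 1e−10, optionally restricted to diatom MAGs. Trees arrive as newick
with tip roles (reference / outgroup / query); after midpoint rooting
(longest tip-to-tip path halved), `select_marker_clade()` selects the
maximal clades that contain a reference tip and no outgroup tips, with an
optional support cutoff (default off — the original curation was manual
and stated no numeric cutoff), and returns the query tips inside them.
The rule is deterministic and invariant to child rotation and tip order.

### Event calling

MAG × sample cells with fewer than 10,000 reads or fewer than 1,000
expressed genes are dropped. Per marker family, the threshold is the 95th
percentile (linear interpolation between order statistics) of the TPM of
all member genes pooled over all vegetative samples of the reference
experiments; pooling across species is the default, with a per-species
mode available, because the original description lists per-species sample
counts without stating the pooling. A marker passes in a cell when any
assigned homolog has TPM strictly above the threshold with at least two
reads. A cell is an event when SPO11-2 passes and at least two panel
markers pass (panel by MAG clade: M1–M4 for raphid pennates; M3 plus the
flagella markers for centrics). SPO11-2 is gated by the same rule as
markers by default; a lenient mode (any read) exists because the original
wording ("expressed the positive control") is ambiguous. The control
audit reruns the identical machinery on the control panel.

### Abundance association

Genus abundances (fractions of total diatom reads) in samples with a
sexual signal are compared against the remaining samples with a two-sided
Mann–Whitney U test: exact null distribution when there are no ties and
n₁n₂ ≤ 10,000, tie-corrected normal approximation with continuity
correction otherwise; the effect size is the rank-biserial correlation
2U/(n₁n₂) − 1 with a percentile-bootstrap 95% CI (the original reports an
effect size and CI without naming formulas; these are this package's
choices). Signal-vs-rest uses disjoint groups — the group sizes printed in
the original results indicate disjoint comparison groups even where a
caption suggests otherwise. Bonferroni correction defaults to genera ×
amplicon regions. ASV tables are first cleaned by removing taxa
unidentified at kingdom/infrakingdom rank, Metazoa, Embryophyceae and
Streptophyta, and variants below 1e−5 % relative abundance.

## What the generators emulate — and what they do not

`simulate_multispecies()` draws ~500 gene families with log-normal
baseline expression (σ = 1.5 in log10 units, a realistic dynamic range),
negative-binomial counts (dispersion 0.1, typical bulk RNA-seq
overdispersion), four species each with the four stages at three sexual
replicates per stage plus three vegetative controls, and plants
diatom-specific single-copy marker families upregulated by a log2 fold
change drawn uniformly from [3, 6] in all stages of every species, plus
flat control families. `simulate_atlas()` adds ~40 vegetative conditions
in triplicate with clean markers at a noise floor and optional "leaky"
families expressing a configured fraction of their sexual mean.

`simulate_mag_dataset()` builds 20 MAGs × 40 samples (20 stations × two
depths) with ~1,200 background genes per MAG, one homolog per applicable
marker/control, multinomial reads at a log-normal depth (median ~1.2e5,
with 5% shallow cells that the retention filter must remove), and 10%
planted sexual cells whose panel markers draw from a high-TPM
distribution. Crucially, vegetative marker expression in MAG cells and in
the 140-sample calibration reference come from the *same* log-normal TPM
process at comparable depth, so the 95th-percentile threshold has a
designed ~5% per-draw exceedance — the hook that makes the control audit
interpretable. `simulate_marker_tree()` joins a reference subtree (with
inside queries) to an outgroup subtree (with outside queries) over long
stems so the reference clade survives midpoint rooting;
`simulate_hit_table()` draws true/decoy bit scores straddling the 50-bit
cutoff.

The generators do **not** emulate: mapping/quantification artifacts,
batch effects, mating-type asymmetries, phylogenetically realistic
sequence evolution, compositional coupling between markers and community
structure, or abundance–event correlation. Passing tests therefore
demonstrate that the *integration logic* behaves as designed under its
stated statistical model, not that the thresholds transfer unchanged to
any particular field dataset.

## Numerical choices and degenerate inputs

- log-CPM offset 0.5 before log2 (keeps zeros finite, standard practice).
- Percentile method: type-7 linear interpolation, recorded in the
  threshold table's provenance.
- TMM reference ties broken by lowest sample index; rank-based trimming.
- Comparisons at printed boundaries are exact: score ≥ 50 keeps 50.0;
  E-value < 1e−10 drops exactly 1e−10; TPM must strictly exceed its
  threshold; a 9,999-read cell is dropped; CPM filters are strict.
- Zero-library samples, all-zero TPM compositions, trees with all-zero
  branch lengths, empty candidate lists and missing thresholds raise
  errors naming the offending object; genes assigned to a marker but
  absent from a cell count as zero.
- All generators are pure functions of (config, seed).

## Problem sizes used by the test suite

The suite regenerates everything at the study-condition sizes: 20 seeds of
the four-species design (500 families) for marker recovery; a one-species
2,000-family complete null for screening FDR; 10⁴ uniform draws for the
Sidak uniformity check; 20 seeds of the 20 × 40 MAG survey (plus 20
no-signal replicas for the control audit); 100 generator trees for
phylogenetic selection. These sizes give the binomial/KS checks enough
resolution while keeping a full run to a few minutes on one core. The
control-audit check is centred on the designed exceedance of an estimated
percentile, (n + 1 − h)/(n + 1) with h the interpolation position, and its
bounds combine the per-draw binomial component with the
threshold-estimation component, since all draws of a seed share one
calibrated threshold.

## Known limitations

- The stand-in DE engine is not a negative-binomial GLM; with very low
  counts its moderated t is conservative. For production analyses of real
  data, import an external engine's records via `read_de_tsv()`.
- Automated clade selection is a deterministic surrogate for manual
  curation; sequences falling between the reference clade and the
  outgroups are excluded rather than adjudicated.
- The rank-biserial/bootstrap effect-size convention may differ from other
  software's choices; U and p match the standard definitions.
- Threshold calibration assumes the laboratory vegetative distribution is
  a fair null for field cells; the control audit quantifies, but cannot
  remove, violations of that assumption.
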