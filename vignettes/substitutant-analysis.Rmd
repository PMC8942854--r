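---
title: "Detecting tryptophan substitutants in proteomics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tryptophan substitutants in proteomics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substiscan)
```

## The biological model

Interferon-γ induces IDO1, which depletes intracellular tryptophan.
Translation across the tryptophan codon TGG can then proceed by codon
reassignment: the ribosome incorporates another amino acid — dominantly
phenylalanine, plausibly via mischarging of tryptophanyl-tRNA by WARS1 —
producing *substitutant* proteins. Because these events are
translational, they are invisible to DNA/RNA sequencing and must be
found in MS data by searching against a customised database in which
tryptophans have been substituted in silico.

`substiscan` covers the analysis around the search engine: database
construction, in-silico digestion, evidence filtering into calls, and
cohort statistics. The MS search itself (spectra, FDR, isobaric
quantification) is upstream and out of scope; the package consumes the
peptide-level report such a pipeline produces, with one
reference-normalized log2 intensity per peptide, sample and replicate.

## Database construction

`substitute_tryptophans()` replaces **all** tryptophans of a protein
simultaneously with one target residue, producing one variant proteome
per target. This all-sites scheme is the only static-database scheme
that can represent peptides carrying two or three W>F conversions, which
do occur in heavily starved proteins; single-site saturation is
available through `saturation_peptides()` / `residue_saturation_db()`
where a per-site design is wanted (the reporter databases use it).

The default target set excludes W (vacuous), and K and R: substituting
W with a cleavage residue would change the tryptic fragmentation of the
variant entry and create peptides whose termini do not match any
canonical digestion pattern. This leaves 17 variant proteomes. For
analyses that deliberately want K/R included, `default_targets(include_kr
= TRUE)` restores them.

Reporter constructs carrying a single tryptophan are handled by
`build_reporter_databases()`, which enumerates the five product classes
of a hungry codon: the in-frame protein, the +1 frameshift product
(translation switches to the +1 frame at the second nucleotide of the W
codon and runs to the first stop), the 19 single-residue reassignments
at the W position, the W-skipped protein, and the translational-bypass
products (W excision; restart at the first downstream in-frame GAA).
Translation uses the standard genetic code, stops before the first stop
codon and drops trailing incomplete codons. All residue and nucleotide
coordinates in inputs and reports are 1-based and inclusive.

## Digestion

`digest()` is strictly tryptic: cleavage C-terminal to K or R, no
semi-tryptic termini, the protein N-terminal methionine is not removed.
Defaults mirror common engine settings: at most 2 missed cleavages,
peptide length 7–50 residues, monoisotopic mass 500–5000 Da. The proline
rule (no cleavage when the next residue is proline) is **on** by
default, matching the usual behaviour of "strictly tryptic" search
configurations, and is exposed as a flag because engines differ.

Masses are sums of unmodified monoisotopic residue masses plus one water
(18.010565 Da). Isobaric labels and carbamidomethylation
(TMT 229.162932, iTRAQ 144.1021, CAM 57.021464 Da) are search-engine
concerns: intensities in the evidence table are already label-resolved,
so the mass model stays unmodified. Mass comparisons use an absolute
tolerance of 1e-4 Da.

Only digest peptides whose span covers at least one original tryptophan
position (`site_spanning_peptides()`) are informative about
reassignment; all others are identical to canonical sequence and are
discarded.

## Calling rules

`call_substitutants()` applies, in order:

* **Unique mapping.** A peptide must map to exactly one substituted
  locus. Peptides that also occur as a substring of any canonical
  protein are rejected (`require_unique_vs_canonical`, default on):
  this package consumes peptide lists rather than spectra, so the
  competitive-search uniqueness a search engine provides implicitly
  must be enforced explicitly. Identical sequences arising from several
  proteins or positions are `ambiguous` and dropped.
* **Positivity.** A sample is positive when its reference-normalized
  log2 intensity is strictly above 0 — a peptide observed at exactly
  the reference level carries no evidence of induction. By default
  every observed replicate of the sample must be positive (the
  conservative reading); `any_replicate = TRUE` relaxes this.
* **Reproducibility.** A call requires detection in at least
  `min_replicates = 2` biological replicates of at least one condition
  (an `exact_replicates` mode restricts to exactly that many). Rows
  with missing intensity count toward replicate detection only under
  `presence_counts = TRUE`; by default only positive rows count.

One call is emitted per (protein, site set, target residue, peptide); a
peptide spanning two or three substituted tryptophans yields a single
multi-site call. W>I and W>L calls are flagged `isobaric_pair` because
MS cannot distinguish leucine from isoleucine; counting utilities can
pool them (`substitution_enrichment(collapse_isobaric = TRUE)`).

Raising the positivity threshold or the replicate requirement can only
remove calls; this monotonicity is asserted property-style in the test
suite.

## Cohort statistics

* `sample_counts()` counts distinct calls positive per sample — the
  per-sample distinct-event unit is used consistently (an alternative,
  summing peptide detections, is deliberately not the default because
  distinct loci are robust to peptide redundancy).
* `ido1_stratified_test()` stratifies samples at IDO1 log intensity 0,
  strictly: > 0 is high, < 0 is low, exactly 0 is excluded and logged,
  since a boundary sample supports neither stratum. Strata are compared
  with a two-sided Wilcoxon rank-sum test; the implementation delegates
  to R's reference machinery, using exact enumeration for small
  tie-free samples (combined n ≤ 20) and the normal approximation with
  tie and continuity correction otherwise. Degenerate input (all values
  identical) returns p = 1 with a warning.
* `per_gene_high_low_counts()` computes, per gene, the total number of
  substitutant events in samples expressing the gene above versus below
  the reference (`delta = n_high - n_low`), excluding missing and
  exactly-zero expression per gene.
* `substitution_enrichment()` divides each target's distinct-call count
  by the mean over all configured targets (absent targets count zero),
  so enrichments average to 1 by construction and are invariant to
  uniform rescaling of counts.
* `classify_cohort()` calls a cohort W>F-enriched when the W>F/W>Y
  enrichment fold is at least 2 (boundary inclusive). The threshold
  value is a package default, surfaced as a prominent argument, because
  the fold rule is qualitative in origin; a W>Y enrichment of exactly 0
  classifies as enriched with an `infinite_fold` flag.

### GSEA

`gsea_score()` implements the weighted Kolmogorov–Smirnov statistic:
genes sorted by metric, descending, with ties broken alphabetically by
gene symbol so results are deterministic; hit increments
`|metric|^p / Σ_hits |metric|^p`; miss decrements `1/(N − N_hits)`; ES
is the signed maximum deviation. When every hit has metric zero the hit
weights fall back to `1/N_hits` so the statistic stays defined. The
null permutes gene labels with a caller-supplied seed; NES divides ES by
the mean |null ES| of matching sign; the empirical p-value is two-sided
on |ES| with add-one smoothing, hence bounded below by
`1/(n_permutations + 1)`. Defaults: exponent p = 1, 1,000 permutations.
The ranking metric used for the substitutant analysis is `delta` from
`per_gene_high_low_counts()`; the stratification defines the question
("which genes are high when substitutant burden is high") and the signed
count difference is its most direct metric. Across several gene sets,
`gsea_batch()` adjusts the empirical p-values with Benjamini–Hochberg.

An alternative running-sum convention decrements misses by `1/N`
instead of `1/(N − N_hits)`; we use the `1/(N − N_hits)` form, which is
the classical definition, keeps ES within [−1, 1], and matches the
independent `fgsea` statistic against which the implementation is
cross-checked in the tests.

## The synthetic-data generator

`simulate_proteome()` / `simulate_cohort()` emulate the statistical
structure the analysis assumes, with all parameters in `sim_config()`:

* proteome: 40 proteins of 200–400 residues; tryptophan at 1.2% (its
  natural abundance); K and R at 5% each so tryptic peptide lengths are
  realistic. This yields on the order of 100–130 digest-eligible W>F
  loci — sized, by a design-stage power calculation, so that the
  IDO1-stratified comparison of roughly 42 high versus 8 low tumours
  separates clearly under the planted effect.
* cohort: 50 tumour and 50 normal samples, IDO1 ~ N(1, 1) in tumours
  and N(−1, 1) in normals; 2 replicates per sample so the
  reproducibility filter is exercisable.
* W>F process: per locus and sample,
  `P(event) = plogis(-3 + 1.5 · IDO1)` in tumours and `plogis(-3)` in
  normals (log-odds units); each of the 16 non-F targets fires
  uniformly at 0.002 per locus and sample.
* intensities: detected peptides get log2 intensity ~ N(1, 0.5), so
  planted events sit above the positivity threshold with ~2% of
  replicate observations below it; canonical counterpart peptides are
  emitted at N(0, 0.5); each replicate observation drops out with
  probability 0.05.
* expression: per-protein genes are standard-normal noise; a 30-gene
  immune module (the packaged synthetic T-cell activation GMT) tracks
  the per-sample planted W>F burden with correlation ~0.8, giving the
  GSEA checks a planted signal.

Events are planted at the level of digest-eligible loci — the shortest
uniquely mapping tryptic peptide spanning each W site — because the
pipeline's input contract is peptide evidence; simulating spectra would
test nothing this package owns. The random streams for the proteome and
the cohort are split, so changing cohort parameters never perturbs the
proteome.

What the generator does **not** emulate: spectral noise and
interference, retention-time effects, structured missingness beyond
Bernoulli dropout, isobaric channel crosstalk, shared peptides between
homologous proteins, and real protein abundance distributions. Passing
tests therefore demonstrate that the *analysis logic* is correct under
its stated assumptions — not that those assumptions hold in any given
real dataset.

## Problem sizes and numerical choices

The test-suite defaults are chosen to keep the full run within a few
minutes on one CPU: digest-versus-oracle equivalence uses 500 random
proteins of up to 300 residues; GSEA oracle agreement uses 100 random
rankings at tolerance 1e-12; the cohort-level checks run 100 seeded
cohort draws for power/specificity (rejection at α = 0.01) and 200 for
type-I control (α = 0.05) against one fixed study proteome.

Fixed tie-breaks and degenerate-input rules, collected in one place:
strict inequalities at every 0 boundary (positivity, IDO1 and expression
stratification); exactly-zero values excluded, not binned; GSEA ties
broken by gene symbol; Wilcoxon on fully tied data returns p = 1 with a
warning; empty strata, empty gene-set intersections, full-ranking gene
sets, zero total enrichment counts and empty ground truth all raise
errors rather than returning silent defaults; an undefined precision
(no calls) is reported as 1 with an explicit flag.

## Known limitations

* Gene symbols are taken from FASTA `GN=` tokens; no external
  accession-to-symbol mapping is bundled, and per-gene analyses silently
  reflect whatever mapping the input carries.
* The caller cannot localise which tryptophan is substituted when a
  peptide covers several sites ambiguously; it reports the full covered
  site list.
* W>I/W>L cannot be distinguished by mass; they are reported separately
  but flagged.
* The enrichment denominator includes the W>F count itself; in strongly
  W>F-enriched cohorts this pushes the background targets' enrichment
  below 1 (a property of the definition, visible in the synthetic
  cohorts as W>Y enrichment centring near 0.8 rather than 1).
* No FDR modelling at any level: the package trusts the upstream
  search engine's peptide-level filtering.
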