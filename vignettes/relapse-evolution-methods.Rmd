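---
title: "Methods: scar scores, clonal architecture and signatures in paired primary/relapse tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scar scores, clonal architecture and signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapseEvo)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the thresholds and defaults with their rationale, the
assumptions behind the synthetic cohort, and the numerical choices that a
maintainer or reviewer would want spelled out. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate model

All genomic coordinates are 1-based, closed intervals, matching SEG-file
convention: a segment `[start, end]` has length `end − start + 1`. The
bundled assembly encodes hg19 autosome lengths and centromere intervals plus
chromosome X; any assembly can be supplied as a TSV. Only autosomes enter
scar, CIN and WGD computations — sex-chromosome rows are accepted on input
and dropped at scoring time, so all three scar components share one
denominator. Uncovered gaps contribute to no score and are excluded from the
CIN/WGD denominators (absence of evidence is not evidence of diploidy).

All thresholds live in `analysis_constants()` and are referenced by name,
never re-hardcoded:

| constant | default | meaning |
|---|---|---|
| `hrd_loh_min_bp` | 15 Mb | minimum extent of a counted LOH event |
| `lst_min_segment_bp` | 10 Mb | minimum flanking-region size for an LST |
| `lst_max_gap_bp` | 3 Mb | maximum gap at an LST breakpoint; also the merge gap |
| `hrd_phenotype_threshold` | 42 | HRD score at/above which a lesion is HR-deficient |
| `seem_dominant_ccf` | 0.45 | relapse CCF above which a survivor is dominant |
| `minor_surviving_ccf` | 0.15 | relapse CCF below which a survivor is minor |
| `cosine_match_threshold` | 0.70 | signature-to-catalog match threshold |
| `wgd_genome_fraction` | 0.50 | genome fraction for the WGD call (strict >) |
| `surviving_min_ccf` | 0.01 | CCF above which a subclone counts as present |

## Scar scores: definitions and dialect

The three scores operate on a merged profile: adjacent segments with
identical (major, minor) copy number separated by less than `lst_max_gap_bp`
of uncovered sequence are merged first (`merge_segments()`, idempotent; all
scorers merge internally, so scoring is invariant to pre-merging).

Where the one-line published definitions are silent, the package fixes a
dialect and the brute-force test oracles implement the same dialect
independently (per-megabase bins rather than segment tables):

- **LOH** is `minor_cn = 0` with `major_cn ≥ 1` — copy-neutral and amplified
  LOH count, homozygous deletions do not. A *run* of LOH segments tolerates
  internal uncovered gaps below `lst_max_gap_bp`; its extent is measured
  from first to last covered base (consistent with gap-absorbing merges).
  A run covering the chromosome's whole covered extent is not counted.
- **Allelic imbalance** is `major_cn ≠ minor_cn` — the only definition
  available from allele-specific integer copy numbers. A tAI event is an
  imbalance run that includes the chromosome's first or last covered base
  and whose span does not intersect the centromere interval; a run touching
  both telomeres necessarily crosses the centromere and counts zero.
- **LST** is computed per chromosome arm: merged segments are clipped at the
  centromere, and a breakpoint counts when both flanking regions span at
  least `lst_min_segment_bp`, the gap is below `lst_max_gap_bp`, and the two
  regions differ in allele-specific copy number. Arm-wise scoring follows
  the originating large-scale-transition method; a centromere-spanning
  junction is never counted.

`cell_frac` (the FACETS-style cellular fraction) is carried through I/O and
merging but deliberately ignored by every scorer: the upstream tools in this
domain score integer allele-specific states, and weighting by cellular
fraction would change the meaning of the published 42 threshold. CIN uses
total copy number ≠ 2 rather than ≠ ploidy, so a genome-doubled tumor has
CIN 1 — which is why the WGD flag is always reported alongside CIN.

## Bi-allelic HR-gene classification

Per lesion and gene, events are reduced to counts of six types (germline
LOF, germline VUS, somatic LOF, somatic VUS, somatic LOH, deep deletion) and
resolved to the highest-priority status:

1. bi-allelic LOF via (1) germline LOF + somatic LOH, (2) germline LOF +
   somatic LOF, (3) somatic LOF + somatic LOH, (4) two somatic LOF, or
   (5) deep deletion;
2. bi-allelic VUS via (6) germline LOF + somatic VUS, (7) somatic LOF +
   somatic VUS, or (8) somatic VUS + somatic LOH;
3. mono-allelic when a single protein-altering hit exists (germline/somatic
   LOF or somatic VUS);
4. none otherwise — in particular a lone germline VUS or a lone somatic LOH
   never contributes.

Case (4) does not require phasing evidence: exome sequencing cannot phase,
and two somatic LOF hits in one gene are counted bi-allelic as the field
does implicitly. Two germline LOF variants without somatic partners are
classified mono-allelic (compound inheritance cannot be established from a
tumor/normal pair) and flagged `compound_germline`. Bi-allelic VUS in a
lesion with the HRD phenotype is upgraded to *putative LOF* only when no
gene in that lesion is already bi-allelic LOF. The HR gene list ships as an
editable 102-symbol fixture (a constructed stand-in, see file name) and is
config-replaceable.

## Clone trees, diversity and evolution models

Trees are consumed, not inferred. Node CCFs are *inclusive* — a node's CCF
contains all of its descendants — matching both the abundance formula and
the "including its child clones" dominance rule. The root is the normal
clone and must have exactly one child, the founder; trees with several root
children are rejected at parse time. A child's CCF may exceed its parent's
by at most 0.02 (upstream tree inference is stochastic; hard equality would
reject real trees). Alterations assigned to the founder are *trunk*, to any
descendant *branch*; assignment to the root is an error.

Clonal abundance in a sample is `p_i = max(0, CCF_i − Σ_children CCF)` over
all clones except the root, renormalized over clones with positive
abundance. Diversity uses the Shannon index `H = −Σ p_i ln p_i` and the
Gini–Simpson index `D = 1 − Σ p_i²`. A patient's relapse shows *elevated*
diversification only when both indices strictly increase; discordant
directions are reported with a flag rather than forced into a call.

A primary subclone *survived* treatment when both its primary and relapse
CCFs exceed `surviving_min_ccf` (0.01 rather than 0, absorbing upstream
noise; configurable). The evolution model is classified by the first rule
that fires:

1. **SEEM** — some survivor's inclusive relapse CCF exceeds 0.45;
2. **HRDEM** — a survivor has inclusive relapse CCF below 0.15 *and* the
   relapse lesion carries the HRD phenotype;
3. **DNSEM** — no subclone survived;
4. **unclassified** — anything else (e.g. a survivor at CCF 0.15–0.45, or a
   minor survivor without HRD). The reference cohort happens to partition
   cleanly into the three models; arbitrary inputs need a total function,
   and guessing would silently misreport mixed cases.

Rule order matters: a dominant survivor in an HR-deficient relapse is SEEM,
not HRDEM, because dominance is the stronger, more specific observation.

## Mutational signatures

Catalogs are samples × 96 matrices over the canonical context order
(substitution class C>A, C>G, C>T, T>A, T>C, T>G; then 5' base; then 3'
base). Records with purine reference bases are reverse-complemented to the
pyrimidine strand — ref, alt and both flanks — before binning, so building a
catalog from fully reverse-complemented records is an involution (tested).

De novo extraction uses non-negative matrix factorization with
multiplicative updates minimizing generalized Kullback–Leibler divergence
(the classic Brunet scheme, matching the default of the R package family
used in this domain), best-of-`n_restarts = 30` seeded initializations,
`max_iter = 2000`, relative tolerance `1e-6`. Signature columns are rescaled
to sum to 1 with exposures absorbing the magnitude. The rank is a parameter:
no automatic rank selection is attempted because no defensible criterion is
stated for this problem class; three is the working default. Extracted
signatures are matched to a reference catalog by greedy per-signature argmax
cosine similarity (ties broken by reference order), flagged matched above
0.70. Exposure fractions are normalized per sample; group summaries are
exposure-weighted (samples contribute proportionally to their mutation
counts — the pooling convention is documented here because the alternative,
averaging per-sample fractions, gives different numbers for unequal
burdens). The signature–gene screen fits one ordinary-least-squares
regression per (signature, gene) pair of exposure on the 0/1 mutation
indicator and applies Benjamini–Hochberg step-up across all pairs; constant
exposures or indicators are skipped with a message rather than producing
undefined statistics.

### The bundled reference signatures and identifiability

The three constructed 96-vectors are: *age-like* (90 % of mass split evenly
over the four N[C>T]G contexts — clock-like CpG deamination), *APOBEC-like*
(94 % of mass over T[C>T]A/T and T[C>G]A/T) and *flat* (uniform). They are
constructed, not copied from any published catalog; their pairwise cosine
similarities are below 0.3 by design so that factorization recovery is
well-posed. Peak concentration was chosen with identifiability in mind: a
uniform component is only recoverable by NMF when the exposure design spans
the simplex — in a cohort whose lesions all mix the processes evenly, the
maximum-likelihood factorization legitimately reallocates the flat
signature's mass (its KL optimum can beat the planted factorization on
noisy counts). The recovery tests therefore use a 20-lesion design that
spans the mixing simplex and includes near-pure "anchor" lesions of each
process, which is also what real cohorts that support signature discovery
look like. A green recovery test establishes that the estimator finds
planted structure under that design, not that any cohort supports rank-3
extraction.

## The synthetic world

The generator's defaults state the simulated world:

- **Cohort**: 10 patients, model mix 0.4/0.3/0.3 (DNSEM/HRDEM/SEEM),
  mirroring the 4/3/3 split of the reference cohort.
- **Scar events**: planted non-overlapping, shielded by short spacer
  segments (below `lst_min_segment_bp`) and separated by baseline copy
  number, so planted counts are exact rather than approximate: a tAI event
  abuts a telomere with the centromere untouched, an LOH event is strictly
  interstitial, an LST pair is two abutting large regions differing in copy
  number. Event geometry scales with `analysis_constants()`, so scaled-down
  toy assemblies remain consistent. HRDEM relapse lesions draw each scar
  component from {14..16}, guaranteeing HRD ≥ 42; other lesions stay well
  below the threshold. 10 % of patients double their relapse genome.
- **Mutation burden**: primary lesions draw 1000–2000 SNVs; relapse burden
  multiplies by Uniform(1.3, 1.9) — about 57 % more mutations on average,
  the one burden statement available for this setting; per-lesion burdens
  are otherwise free parameters.
- **Signature mixtures** shift from age-like toward APOBEC-like at relapse
  in all models, most strongly in HRDEM, with SEEM APOBEC-dominated in both
  lesions — the qualitative pattern described for the three models.
- **HR variants**: ten scenarios cycle through the cohort, covering all
  eight bi-allelic mechanisms, a mono-allelic germline carrier whose relapse
  acquires somatic LOH (the second-hit progression pattern), and a quiet
  patient.
- **Reproducibility**: each patient derives a private RNG stream from
  `(master_seed × 7919 + index × 104729) mod 2×10⁹`, so patient-level output
  is independent of cohort size; every generator wraps its RNG use with a
  seed save/restore, and re-running a cohort with the same parameters is
  byte-identical on disk.

What the generator does **not** emulate: real segmentation noise (fractional
copy states, purity/ploidy estimation error), clustered mutational processes
(kataegis), indels and structural variants, sequencing depth effects, or
inter-patient correlation of any kind. A green test therefore establishes
correctness of the downstream algebra on well-formed inputs, not robustness
to caller artifacts.

## Statistics

The paired cohort comparison is implemented as the Wilcoxon signed-rank test
on within-pair differences. The source description ("one-tailed paired
Mann–Whitney U") is statistically ambiguous — a literal Mann–Whitney is a
two-sample test that ignores pairing — so the package implements the
standard paired nonparametric test and labels it as such in its output. Zero
differences are dropped (all-zero differences raise an explicit error
rather than returning an arbitrary p). For up to 15 nonzero pairs the null
distribution is enumerated exactly over all 2ⁿ sign assignments of the
midranks — valid under ties, unlike the classical no-ties exact tables —
via an integer convolution over doubled ranks; larger samples use the
normal approximation with tie correction and continuity correction. Pearson
correlation reports the product-moment coefficient with the usual
t-transform p-value (p = 0 at |r| = 1, where the transform degenerates).

Clinical summaries exclude missing values from each denominator, with one
deliberate exception: subtype percentages use all patients as denominator
(a missing subtype label is an observed absence, and the reference cohort's
printed 50.0 % is computed that way), while grade percentages are computed
among graded patients (matching the printed 77.8 %).

## Numerical and serialization choices

- Floats in TSV/JSON writers are serialized at 6 significant digits; tree
  CCFs are generated at 4 decimals, so write–read round trips are exact and
  golden-file tests are meaningful.
- Signature catalog columns must sum to 1 within `1e-6` (renormalized
  thereafter); the bundled fixture is written at 10 decimals to stay inside
  that tolerance. The tolerance is a parameter for coarser user catalogs.
- NMF divergence guards against zeros with machine epsilon; determinism
  comes from per-restart seeds derived as `seed + restart`.
- The WGD call uses a strict inequality (exactly 50 % is not doubled), and
  the HRD phenotype threshold is inclusive (score 42 qualifies).

## Known limitations

- Scar-score dialect choices (arm-wise LST, extent-based LOH runs, gap
  handling) follow the originating methods where published and are frozen
  here where not; other implementations may differ by small counts near
  thresholds.
- Whether chromosome X contributed to scar scores in the reference analyses
  is not stated; this package excludes it uniformly, which may shift scores
  slightly relative to tools that include it.
- The bi-allelic classifier trusts upstream LOF/VUS annotation; it performs
  no variant-effect prediction.
- `unclassified` evolution calls are a feature, not a failure: inputs
  outside the three archetypes are surfaced with their evidence instead of
  being forced into a model.
- The actionability rule table is a local fixture covering the genes of the
  bundled report; it is a stand-in for a versioned knowledge base, not a
  clinical resource.
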