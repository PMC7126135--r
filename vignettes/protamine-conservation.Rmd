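---
title: "Gap-weighted relative-entropy conservation analysis of protamine families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-weighted relative-entropy conservation analysis of protamine families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protascan)
```

## The problem

Protamines are extreme proteins: short, up to ~70% arginine, and under
strong selection for one job — neutralising and hypercondensing sperm DNA.
Ordinary conservation analysis is uninformative here, because *everything*
is conserved arginine. The interesting biology lives in the handful of
non-arginine positions (cysteines that form disulfide cross-links in
eutherian P1/P2, tyrosines and histidines in metatherian protamines) and
in how the charged-residue density is distributed along the sequence.

`protascan` implements a conservation score tailored to this situation and
the surrounding pipeline: building homologous groups from UniProt-style
records, handling the post-translational truncation of eutherian P2,
scoring alignment columns, and comparing group-level arginine–lysine
densities.

## The model

### Column score

For an alignment column with residue frequencies $P(a)$ (computed over
non-gap residues only) and background amino-acid frequencies $Q(a)$, the
raw score is the relative entropy in bits,

$$D_{KL}(P\,\|\,Q) = \sum_a P(a)\,\log_2 \frac{P(a)}{Q(a)},$$

over the 20 standard residues plus the ambiguity codes B (Asx), Z (Glx)
and X (unknown). Terms with $P(a)=0$ contribute zero. Gaps are penalised
multiplicatively:

$$G_W = D_{KL}(P\,\|\,Q)\times \text{(non-gap fraction of the column)}.$$

A column is **conserved** when $G_W$ strictly exceeds the score of a
hypothetical gapless 100%-arginine column,
$\log_2(1/Q(R)) \approx 4.1354$ bits. The threshold choice encodes the
domain logic: in an arginine-rich family, only positions more
statistically surprising than pure arginine are worth calling. The
inequality is deliberately strict — an actual all-arginine gapless column
realises the threshold *exactly* (the package computes both through the
same expression, so the tie is exact in floating point too) and is not
called conserved. This matters in practice: fish protamine alignments are
expected to produce all-arginine columns that tie the threshold and no
conserved calls at all.

### Conventions worth stating

* **Base-2 logarithms.** The printed threshold ~4.1354 is only consistent
  with $Q(R)\approx 0.0569$ under base 2; natural logs would require an
  arginine abundance of ~1.6%, far from any observed value. All scores
  are in bits.
* **$P(a)$ over non-gap residues.** Gaps are excluded from both numerator
  and denominator of the column frequencies; their cost is carried
  entirely by the multiplicative weight. Purities reported per column
  (e.g. "83.8% cysteine") are likewise gap-excluded.
* **Initiator methionine.** The first non-gap residue of each row, if M,
  is masked and treated as a gap in every column statistic (it counts on
  the gap side of the non-gap fraction). Mammalian protamines start
  MARYR…, so without masking the first column would be a spurious
  perfectly conserved M.
* **Ambiguity codes.** $Q(B)=Q(D)+Q(N)$, $Q(Z)=Q(E)+Q(Q)$, and $Q(X)=1$.
  The X convention is an explicit upper bound: any X in a column
  contributes a non-positive term, so unknown residues can only deflate a
  score. These assignments are configurable through the background table.
* **Threshold comparisons** are made in full precision; 4.1354 is a
  display rounding, never the comparison value.

### Background frequencies

The bundled background (`uniprot_background()`) is a reconstruction of
UniProtKB natural-abundance statistics with $Q(R)$ pinned at 0.0569 — the
value implied by the 4.1354-bit all-arginine threshold — and
representative UniProtKB abundances for the other residues (file
`inst/extdata/uniprotkb_2019_aa_frequencies_synthetic.tsv`; "synthetic"
because it is a reconstruction, not a redistributed release table).
Third-decimal differences in the non-arginine frequencies move typical
column scores by well under 0.05 bits and do not move the threshold at
all, since the threshold depends only on $Q(R)$. Any two-column
`symbol<TAB>frequency` table can be substituted via `read_background()`;
frequencies must be positive and sum to ~1 over the standard alphabet.

## Group construction

`protamine_rules()` encodes the four standard groups: eutherian P1
(lineage contains *Eutheria*, gene PRM1/Prm1), eutherian P2 (PRM2/Prm2),
metatherian P1 (*Metatheria*, PRM1/Prm1) and fish (*Actinopterygii*, any
gene, descriptions containing "like" excluded — dropping protamine-like
proteins). Decisions the records themselves do not fix:

* Gene-name matching is exact and case-sensitive against *all* synonyms a
  record lists (the rules name both PRM1 and Prm1 explicitly, which only
  makes sense under case-sensitive matching).
* The "like" exclusion is a case-insensitive substring test — the safer
  reading of the intent to drop protamine-like proteins.
* Per-organism deduplication prefers reviewed (Swiss-Prot) entries; among
  equally reviewed candidates the lexicographically smallest accession
  wins. The tie-break is arbitrary but deterministic, which makes the
  result invariant under permutation of the input and hence testable.
* Live database queries are out of scope; the package consumes an
  already-downloaded FASTA or tabular export. FASTA headers carry no
  lineage, so lineage-based rules need the tabular dialect.

## Alignment and P2 truncation

Alignment is an external, pluggable stage: `align_sequences()` shells out
to a configurable command template (MUSCLE's classic interface by
default, but any `{in}`/`{out}` template works) or accepts a pre-computed
alignment in passthrough mode. Either way the de-gapped rows are checked
against the input sequences. Gap characters are normalised to `-` (`.`
accepted on input); all coordinates are 1-based alignment columns.

Eutherian P2 is post-translationally processed: ~40% of the N-terminus is
cleaved, and the mature protein is what binds DNA. The analysis therefore
truncates the P2 alignment at the column holding the reference processing
site — mouse PRM2 residue 44, located via `map_residue_to_column()` rather
than hard-coded, so the pipeline survives different aligner outputs. The
truncation keeps the site's column itself and everything C-terminal of it
(the processed side); the first retained column is recorded in
provenance. Rows left all-gap by truncation are kept and flagged.

## Density analysis

`residue_frequency()` counts R+K per sequence (configurable residue set;
histidine excluded by default, and the set can be widened to reproduce
sensitivity analyses that include H or other residues). The leading
methionine is excluded from numerator and denominator, mirroring the
conservation masking. Processed (truncated) sequences are the right input
for P2.

Region densities (`region_residue_frequency()`) for the hypothesised
DNA-binding regions — eutherian P1 columns 17–46, metatherian columns
16–56 in the published alignments — divide by the row's **non-gap residue
count within the region**, not the region width. The records are silent on
this choice; gap-inflated denominators would make values incomparable
across species with different gap patterns, so the non-gap denominator is
used and stated here explicitly (exact third-decimal reproduction of
published region quartiles can depend on it).

Quartile summaries use linear rank interpolation (`stats::quantile`
type 7, the mainstream default — quartile conventions differ enough to
matter at n ≈ 16). Group comparisons use Welch's unequal-variance t-test
with Satterthwaite degrees of freedom, two-sided, without multiple-testing
correction (pairwise raw p-values are the published convention for this
analysis); the degenerate case of two zero-variance samples with equal
means returns p = 1.

## The synthetic generator

`simulate_family()` generates protamine-like families with known truth:
an arginine-rich background (default 70% R, fish-like — deliberately the
hardest case for an all-arginine threshold, since pure-R background
columns tie it and must never exceed it), planted columns emitting a
chosen residue with purity π, i.i.d. per-cell gaps at rate γ, and an
optional initiator-Met column. Cysteine, tyrosine, histidine and
methionine are absent from the default background so planted columns and
Met handling stay unambiguous. Gaps are i.i.d. rather than block-indels
because the score depends only on per-column gap fractions; realistic
indel structure would add nothing to what the tests can detect. The truth
table records each column's label, realized purity and realized gap
fraction, and `expected_column_score()` gives the closed-form score
$(1-\gamma)\,D(\pi)$ of the planted mixture for predicting calls.

`simulate_two_groups()` generates two ungapped groups with target R+K
probabilities (R:K at 4:1, reflecting the arginine bias), giving binomial
concentration of per-sequence densities around the targets.

What passing synthetic tests does **not** show: real protamine families
are phylogenetically correlated (not i.i.d. rows), gapping is indel-block
structured, and real backgrounds drift between databases and releases. The
generator validates the statistical machinery and its boundary behaviour,
not database- or aligner-specific reproductions, which additionally
require the exact UniProt release and MUSCLE 3.8.31.

## Verification sizes and numerical choices

The shipped test suite checks the scanner against an independent
brute-force oracle to 1e-9 bits on one hundred 10×30 random alignments
(both paths are double precision; agreement at 1e-9 rules out any
convention drift, not just rounding); planted-column recovery over 20
seeds at n = 50, length 60, π ∈ {0.8, 0.9, 1.0}, γ ∈ {0, 0.2}, requiring
every planted column whose closed-form score at its *realized* purity and
gap fraction clears the threshold by ≥0.3 bits to be called, none clearing
it by ≤ −0.3 to be called, and zero background false positives; and Welch
calibration over 200 null seeds (Kolmogorov–Smirnov distance to uniform
< 0.1) plus rejection at α = 0.05 for R+K 0.5 vs 0.7 at n = 50. The 0.3-bit
margin absorbs the multinomial noise of the non-planted residue remainder
at these sizes; evaluating the closed form at the *configured* π and γ
instead would make the boundary stochastic at any margin. These problem
sizes keep the whole suite under half a minute while leaving the binomial
bands comfortably narrow.

Degenerate inputs are defined, not errors, wherever a downstream stage
can meet them naturally: all-gap columns score 0 (empty profile), all-gap
truncated rows are flagged and kept, a region containing only gaps for a
row yields a missing value. Majority-symbol ties break alphabetically
(deterministic output ordering); conserved-position lists sort by
descending score.

## The pipeline interface

`run_pipeline(config)` composes ingest → group filters → exclusions →
alignment → truncation → masking → scan → density → tests → provenance
into a `report_bundle` whose tables all carry the configuration hash and
background label, and which writes TSV/FASTA reports when an output
directory is configured. Reruns on identical inputs are byte-identical.
`render_highlighted_alignment()` renders an alignment with conserved
columns marked (text marker row with a 10-column ruler, or an HTML table
with one highlighted `<col>` per conserved column). As an analysis
package the function surface *is* the interface; the repository's
`scripts/acceptance.R` shows the scripted entry point pattern.

## Known limitations

* No phylogenetic sequence weighting: column frequencies are unweighted,
  so oversampled clades pull scores their way. This matches the method
  the package implements, but it is a real bias on uneven taxon sets.
* The conservation score is relative entropy only; Jensen–Shannon or
  sum-of-pairs alternatives are out of scope.
* Alignment quality is taken as given; the package checks only that
  alignments are consistent with their input sequences.
* The bundled background is a pinned reconstruction (see above); analyses
  sensitive to third-decimal background values should supply their own
  table.
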