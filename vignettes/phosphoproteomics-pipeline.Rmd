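---
title: "Methods: models, conventions and design choices in phosflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in phosflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phosflow implements the downstream half of a site-level quantitative
phosphoproteomics study: everything after the search engine has produced a
phosphosite × sample intensity matrix. This vignette records the models the
package fits, the conventions it adopts where the field leaves room, and the
reasoning behind the choices that were genuinely open.

## Coordinates, windows and identifiers

Sites are addressed as `<protein>_<position><residue>` with 1-based,
inclusive positions (e.g. `P0123_97S`). The sequence context of a site is
its 13-mer window — six residues either side of the phosphoacceptor — with
terminal overhang padded by `_`. The pad is not a residue: it never matches
in motif counting, is excluded from background frequency denominators at its
offset, and scores 0 in kinase–substrate similarity. Windows are recomputed
from the FASTA at load time and validated against the table's claimed
residue; a mismatch is an error in strict mode and a logged drop otherwise.

## Differential phosphosites

Testing happens on the log2 intensity scale: TMT reporter intensities are
approximately lognormal, replicate variances are more homogeneous after the
transform, and the fold-change gate becomes symmetric
(`|log2fc| >= log2(1.5)`). Whether the original analyses of such studies
tested raw or log intensities is rarely stated; log2 is this package's
documented choice. The test is the two-sample Student's *t* with pooled
variance (Welch behind `var_equal = FALSE`), and a site is `up` iff ratio
≥ 1.5 **and** *p* < 0.05, `down` symmetrically, `ns` otherwise. The ratio
boundary is inclusive (a ratio of exactly 1.5 counts), the *p* boundary
exclusive; both thresholds are configurable but default to the values such
studies conventionally print. Benjamini–Hochberg *q*-values are always
reported but never used for selection by default — selection on raw *p* is
the convention the thresholds were defined under, and the *q* column lets a
user apply FDR control without re-running. Degenerate inputs are resolved
explicitly: zero pooled variance with equal means gives *t* = 0, *p* = 1;
zero variance with unequal means gives *p* = 0.

Summary accounting (S/T/Y percentages rounded to integers,
sites-per-protein percentages to one decimal, census percentages to one or
two decimals) uses round-half-up, matching how such tables are printed;
base R's round-half-even would disagree on exact .5 cases.

## Motif discovery

`motif_x()` is the iterative binomial enrichment scheme: at each step every
unfixed (offset, residue) pair is scored by the upper binomial tail
P(X ≥ k) with n = foreground windows valid (non-pad) at that offset and p0
= the residue's frequency at that offset among currently matching
background windows. The most significant pair below the step threshold
(default 10⁻⁶) is fixed, both window sets are restricted to matches, and
the loop repeats; a motif is accepted when no pair passes, at least one
position is fixed, and foreground support is at least `min_occurrences`.
The support default is 21 — the strict reading of the conventional "more
than 20 peptides" rule; set 20 if the inclusive reading is wanted. Accepted
motifs have their matched windows removed and the search restarts, so motif
*i* never depends on motifs discovered after it (prefix stability, which
the tests assert).

Ties at the minimal *p* are broken deterministically: larger foreground
count, then smaller |offset|, then lexicographic residue. Background
residue frequencies of exactly 0 or 1 make the binomial undefined or
degenerate; such pairs are skipped. The default background is every window
of the same central residue in the full proteome; "all identified
non-differential site windows" is available by passing those windows
instead. The default foreground is all identified site windows — motif
analysis describes the phosphoproteome, not one comparison — with
differential-only foregrounds left to the caller.

The position–residue heatmap reports log2((f_fg + ε)/(f_bg + ε)) with a
pseudo-count ε = 10⁻⁴, small enough that identical frequency profiles give
exactly 0 and a planted residue dominates its cell.

## Kinase–substrate prediction

The scorer keeps the structure of exemplar-based predictors: a site's score
for a kinase is the mean over the kinase's exemplar substrate windows of
the position-summed BLOSUM62 similarity. Thresholds are calibrated
per kinase as the empirical (1 − fpr) quantile of background-window scores
of the kinase's central-residue class, taking the smallest observed score
whose pass rate does not exceed the target — so the realised false-positive
rate approaches the target from below, and `fpr = 1` / `fpr → 0` reduce to
the min / max background score. The default fpr of 0.05 operationalises a
"medium" stringency; it is a declared default, not a value inferable from
any publication. Predictions then pass a PPI filter: the unordered (kinase
protein, substrate protein) pair must have a direct edge (path length 1),
with self-pairs always passing since a kinase can phosphorylate its own
protein. The filter is a pure subset operation and the score gate is
anti-monotone in fpr; both are asserted as properties in the tests.

A structural caveat the synthetic experiments make explicit: with a
single-determinant consensus (one fixed flank position, as in `[SP]`), one
BLOSUM62 position of signal competes with twelve positions of sequence
noise, and no threshold setting separates substrates from background
cleanly. Kinases with multi-position consensi (the rule rather than the
exception for real enzymes — compare the full CDK consensus S-P-x-K) are
separable; the package therefore ships two motif libraries for the
generator, a single-determinant one (`default_motif_library()`) under which
motif *discovery* is exercised, and a three-determinant one
(`multi_determinant_motif_library()`) under which substrate *prediction*
recovery (precision and recall ≥ 0.8 against planted truth) is exercised.

## Kinase activity (KSEA)

The ranked list is the per-comparison log2 fold changes, or per-sample
z-scores of log2 intensity across sites (the per-sample metric is not
uniquely pinned down by common usage; the z-score makes samples
comparable without changing within-sample ranks). Order is descending with
lexicographic site-id tie-break, so runs are reproducible.

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: substrates increment by their normalised |value|^w (w = 1 by default;
w = 0 gives the unweighted variant with its exact rank-invariance and
reversal antisymmetry, both tested), non-substrates decrement by
1/(N − n_hits), and ES is the signed extremum, taking the first extremum
when magnitudes tie. A substrate set covering the whole list gives ES = +1;
a bottom-of-list singleton at w = 0 gives ES = −1, the value the stated
running-sum formula produces.

Significance uses gene-set (site-label) permutation: a three-replicate
design cannot support phenotype permutation, so the null is built by
re-drawing random site sets of the same size. Because that null depends
only on set size, permutations are drawn once per distinct size within a
context — the standard efficiency of fast GSEA implementations — under a
single seed, so a fit is bit-for-bit reproducible. NES divides ES by the
mean magnitude of same-sign null scores; the *p*-value is the +1-corrected
same-sign exceedance fraction. ES = 0 maps to NES = 0, *p* = 1; a kinase
with no same-sign permutations is flagged with NES = NA rather than
silently dropped, and kinases whose substrate sets intersect the ranked
list in fewer than 3 sites are reported as skipped so row counts stay
auditable.

States follow the activity-score rule read symmetrically: NES ≥ +1
activated, NES ≤ −1 inhibited, otherwise indeterminate. The literal rule
("less than 1 means inhibited") would label NES = 0.5 inhibited; the
symmetric convention is adopted deliberately and flagged here rather than
guessing intent. Because |NES| ≥ 1 alone is weak evidence (a third of null
kinases can cross it), network assembly additionally requires permutation
*p* < 0.05; both gates are configurable.

## Networks and enrichment

The kinase-regulatory network keeps kinases with a determinate state and
*p* < 0.05, sites with status ≠ ns, and predicted relations whose endpoints
both survive; isolated nodes are dropped and an empty network is a valid
result. Edges are directed kinase → site with the SIF relation word
`regulates`; exports are sorted for stable diffs, and GraphML carries node
type/state/value and edge score attributes for Cytoscape.

Term enrichment is the two-tailed Fisher exact test per term, with the
universe defined as all quantified proteins of the relevant omic — not the
whole proteome, which would manufacture enrichment from detectability.
Selection is on raw *p* < 0.05 with BH *q* reported, mirroring the
differential convention.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions the rest of the package
is validated under: 1000 proteins (length ~N(300, 80²), min 50) giving
≈2000 sites; S/T/Y mix (0.83, 0.12, 0.05); a sites-per-protein pmf with
mass 0.561/0.217/0.222 on 1/2/≥3 and ~4% at ≥7; three conditions AC-MG,
AC-B4, rin-B4 × 3 replicates (the replicate count is a declared default —
such designs rarely state it); lognormal intensities, baseline log2
~N(20, 2²), replicate noise sd 0.25 on log2; 20 kinases, 30 substrates
each; and five kinases planted with activity ratios 2.0, 1.8, 1.6, 0.5,
0.55 on AC-B4 vs AC-MG, all |ratio| ≥ 1.5.

Two generator choices deserve their reasoning spelled out:

- **Substrate counts, not an assignment rate.** A natural parameterisation
  assigns each motif-matching site as a substrate with some probability.
  With single-determinant motifs, though, "matching" includes every
  same-residue site at background frequency, so a rate gives no control
  over the planted ground truth; a direct per-kinase substrate count makes
  recovery experiments well-posed. Planting overwrites the flanking
  residues of chosen sites to the consensus (after sequence generation, so
  the foreground signal is unambiguous and logged in the ground truth), and
  never overwrites another site's phosphoacceptor.
- **30 substrates per kinase.** Shared motif classes (3 kinases each for
  `[SP]` and `[RxxS]`) then carry 90 planted foreground windows. Against a
  ~5% background frequency in a ~1700-window foreground, that places the
  binomial enrichment roughly 9 standard deviations above the null, so the
  fixed step threshold of 10⁻⁶ is cleared with wide margin at any seed; a
  weaker plant (~60 windows, ~6 sd) leaves single seeds below the cutoff
  through ordinary sampling fluctuation. The detection thresholds
  themselves are never adjusted; the planted signal is designed to be
  detectable by them, as any power analysis would dictate.

Not emulated, deliberately: TMT ratio compression, co-isolation
interference, peptide-level missingness (the default missing-data policy —
drop a site from a comparison with an incomplete replicate set, optional
half-minimum imputation — exists for real data but the generator produces
complete matrices), shared peptides, isoform ambiguity, and any correlation
structure between sites of one protein beyond the planted effects. Passing
recovery tests on this generator therefore demonstrates the correctness of
the computations, not robustness to those real-data pathologies.

## Reproducibility and problem sizes

Every stochastic step is seeded. The pipeline derives per-stage sub-seeds
from the global seed by fixed small offsets, so any stage can be re-run
alone from its declared input files and reproduce byte-identical output;
the manifest records the full configuration and per-stage row counts.

The validation suite works at sizes chosen to make each check
statistically meaningful while staying comfortable on a single CPU:
distributional checks at 2000 proteins; t-test power against the
noncentral-*t* closed form at 2000 planted sites; ES oracle equivalence on
500 fuzzed 8-site lists; permutation-null calibration over 2000 trials of
500 permutations; motif argmin-oracle equivalence on 500 fuzzed instances;
and kinase-activity recovery over 20 seeded default studies with 1000
permutations each, requiring ≥80% of planted kinases recovered with the
correct state and significance, with false calls on null kinases
(*p* < 0.05 and |NES| ≥ 1) below 10% of null trials.

## Known limitations

Quantification is at site level throughout; studies that report both
peptide- and site-level units are ambiguous about which carried the
statistics, and this package documents the site-level choice rather than
resolving that ambiguity. The exemplar-similarity scorer preserves the
contract, not the internals, of closed-source kinase–substrate predictors,
so absolute scores are not comparable to theirs. The PPI filter treats the
edge list as given truth. Dataset-dependent identification counts of any
real study (total proteins, sites, motif counts, Venn cells) depend on the
upstream search and are reproduced here only as computation patterns on
synthetic data, with every count logged and auditable.
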