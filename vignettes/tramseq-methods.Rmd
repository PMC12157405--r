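---
title: "Methods: windowed structure calling, differential accessibility, and RBP enrichment from DMS mutational profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed structure calling, differential accessibility, and RBP enrichment from DMS mutational profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tramseq)
```

## The measurement model

Dimethyl sulfate methylates the Watson–Crick face of *unpaired* adenines and
cytosines. Under mutational profiling, a thermostable reverse transcriptase
reads through the methylated base and records it as a sequencing mismatch, so
the per-base mismatch rate of a deeply covered transcript is a quantitative
readout of base accessibility: high rate = accessible (usually unpaired), low
rate = protected (paired, or occluded by bound protein). `tramseq` starts
where the aligner ends — at a per-position base-call count table — and
implements everything downstream:

1. **Reactivity profiles** (`compute_mismatch_rates()`,
   `coverage_mask()`, `normalize_control()`, `join_profiles()`): mismatch
   rate = substitution calls / informative depth, positions kept only when
   every sample (treated and control alike) has ≥ 100 reads, the paired
   untreated control subtracted per replicate to cancel SNPs and endogenous
   modifications, negative values floored at zero, and only A/C reference
   bases retained (G/U carry no DMS signal).
2. **Windows and structure metrics** (`segment_windows()`, `gini()`,
   `replicate_correlations()`, `window_stats()`): non-overlapping windows of
   exactly *W* filtered A/C datapoints (50 for structure discovery, 20 to
   match a protein footprint); per window the mean rate, the Gini index, and
   all pairwise replicate Pearson correlations.
3. **Structure calls** (`call_structured_transcripts()`,
   `call_structured_windows()`, `annotate_windows()`,
   `region_enrichment()`): inclusive thresholds — transcripts at mean
   within-condition R ≥ 0.6 and Gini ≥ 0.4, windows at R ≥ 0.8 and
   Gini ≥ 0.5 — plus region annotation and hypergeometric enrichment.
4. **Differential accessibility** (`delta_score()`, `remodeling_test()`,
   `bh_adjust()`, `call_remodeled()`): the δ statistic and a
   within-vs-between replicate correlation t-test, Benjamini–Hochberg
   corrected, calls at p~adj~ ≤ 0.05.
5. **Folding support** (`normalize_for_folding()`, `write_shape()`,
   `fold_constrained()`, `fold_external()`, `auroc()`): SHAPE-style
   constraint export, a built-in reactivity-penalized folder, and AUROC
   scoring of structure/data agreement.
6. **RBP enrichment** (`map_sites_to_windows()`, `scrambled_null()`,
   `rbp_enrichment()`, `select_rbp_hits()`): CLIP-site enrichment among
   remodeled windows against a scrambled-location null.
7. **Synthetic data** (`sim_config()`, `generate_truth()`,
   `simulate_profiles()`, `end_to_end_fixture()`): a fully seeded generator
   so every step above is testable without sequencing data.

## Statistics, exactly as computed

**Gini index.** For a reactivity vector $x_1,\dots,x_n$,
$G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar{x})$ — half the relative mean
absolute difference, computed via the sorted-vector identity. No
small-sample correction by default (`unbiased = FALSE`), because the calling
thresholds are calibrated against the plain population form; the $n/(n-1)$
variant is a flag away. An all-zero window has no defined Gini and is
flagged rather than propagated as NaN. A structured region mixes protected
and exposed bases and scores high; a uniformly accessible region scores near
zero.

**Window segmentation.** Windows contain exactly *W* A/C datapoints; the
trailing remainder is discarded rather than merged so that Gini and R are
comparable across windows. Window nucleotide spans therefore vary with local
A/C density (about 2 × *W* nt at typical composition).

**δ score.** For conditions $a$ and $b$ with index-matched replicates,
$\delta = \frac{1}{N\,n_\mathrm{reps}} \sum_{i=1}^{N} \sum_{k=1}^{n_\mathrm{reps}}
\left| r^{a}_{ik} - r^{b}_{ik} \right|$.
The absolute value makes δ *bidirectional*: reciprocal reactivity shifts
within one window do not cancel. The signed companion
(`directional_change()`) omits the bars; negative values mean reduced
accessibility (more structure) in condition b, and
$|\mathrm{directional}| \le \delta$ always. Replicate k of condition a pairs
with replicate k of condition b — the definition shares a single replicate
index — with an all-pairs average available via `pairing = "all"`.

**Remodeling test.** The within-condition pairwise Pearson correlations
(R~within~) are compared with the between-condition ones (R~between~) by a
two-sided Student t-test with pooled variance (`welch = TRUE` switches the
variance treatment). With 2 + 2 replicates the sets have 2 and 4 members —
underpowered but computable; fewer than 2 valid members on either side
yields a missing p and the window is excluded. Zero-variance degenerate sets
resolve deterministically (equal means → p = 1, different means → p = 0).
P-values are corrected with the standard Benjamini–Hochberg step-up
(`stats::p.adjust`), missing entries passed through.

**A note on calibration.** The six pairwise correlations of a 2 + 2 design
share replicate columns and are positively dependent, so the t-test's
independence assumption does not hold. The package's null-calibration
check (`null_calibration()`, also run by `scripts/acceptance.R`) measures
the consequence: when replicate profiles are reproducible — the regime deep
probing data live in — the raw p-values are *conservative* (shifted away
from 0), and a Kolmogorov–Smirnov uniformity test rejects. The practically
important property holds in the same computation: the BH-adjusted call rate
under the null stays below α plus two binomial standard errors, i.e. the
test over-controls false calls rather than inflating them. Uniformity is
approached only when profiles are noise-dominated (near-zero correlations),
where the dependence between pairs vanishes.

**Folding constraints.** Reactivities are winsorized with an upper limit
only: values above the 95th-percentile *order statistic* are set to it, then
the vector is scaled to a maximum of 1. The order-statistic rule (rather
than an interpolated quantile) is the standard one-sided winsorization and
makes the operation idempotent — renormalizing a normalized vector is a
no-op, which an interpolated percentile provably is not (the interpolated
95th percentile of an already-clipped vector falls strictly below the clip
point whenever the flanking order statistics differ). Constraint files are
two-column text, 1-based index and value, −999 marking missing data.

**Built-in folder.** `fold_constrained()` is a Nussinov-style dynamic
program over non-crossing structures with allowed pairs
{AU, UA, GC, CG, GU, UG}, hairpin loops ≥ 3, maximizing
$\sum_{\text{pairs}(i,j)} \left( 1 - \mathrm{penalty}\,(c_i + c_j) \right)$:
pairing is rewarded, but pairing a base the probing data call accessible
costs reactivity. This is deliberately a combinatorial test folder, not a
thermodynamic nearest-neighbor model — its role is deterministic, dependency
free structure generation for scoring and simulation. Traceback is
deterministic: pairing the interval's left end is preferred over leaving it
unpaired, smallest admissible partner first. The external adapter
(`fold_external()`) writes FASTA + SHAPE files and parses dot-bracket
output, with ViennaRNA's `RNAfold --shape` as the default engine and the
tool's own SHAPE-to-pseudo-energy defaults (recorded on the returned
object).

**AUROC.** Predicted-*unpaired* bases form the positive class and
reactivity is the score, so AUROC = 1 means every accessible base is
unpaired in the structure and 0.5 is chance. Ties count half (Mann–Whitney
convention); scoring is restricted to A/C positions carrying data
(`auroc_structure()`), since G/U have no signal to agree or disagree with.

**RBP enrichment.** A 20-datapoint window is a target of an RBP when any of
its CLIP sites overlaps the window span by ≥ 1 base (half-open intervals,
strands matched). The null scrambles each RBP's target labels uniformly
*within windows bearing at least one CLIP site of any RBP* — controlling
for CLIP density rather than comparing against CLIP-free transcriptome —
preserving per-RBP target counts. Fold change divides the observed count of
significantly changing target windows by the null count (`--null-draws`
averages several scrambles; the default 1 is the literal single scramble);
the p-value is hypergeometric in (k, M, n~sig~, N~t~), upper tail for
enrichment, lower for depletion, with the point mass available as
`p_mode = "pmf"` for strict fidelity to pipelines that evaluate the pmf.
Hits require |log~2~FC| > 1.1 and p < 0.001, both strict; BH-adjusted
p-values are reported alongside but selection uses the raw threshold the
screen was designed around.

## The synthetic-data generator

The generator emulates the statistical structure of a deep mutational
profiling experiment, not its sequences' biology. Defaults
(`sim_config()`):

* 20 transcripts of ~1 kb (normal, sd 150, min 500), GC 0.5, each split
  15% 5′UTR / 50% CDS / 35% 3′UTR — the 3′UTR share matching the regional
  composition such datasets report;
* per-transcript coverage drawn lognormal around 2000× and constant along
  the transcript, mimicking expression-driven depth;
* planted stem-loops with complementary arms (so they are also
  sequence-foldable), tiled in ~120 nt segments, mostly in 3′UTRs
  (hairpin probability 0.45 vs 0.05 elsewhere);
* unpaired A/C modification probabilities Beta(2, 38) (mean 0.05), paired
  Beta(2, 398) (mean 0.005), G/U and untreated-control background 0.002 —
  mismatch rates ≪ 1 and on the order of a dozen modifications per
  kilobase, the regime this assay operates in;
* per-position, per-replicate lognormal noise (sdlog 0.2) so
  within-condition correlations sit realistically below 1 and the
  remodeling test has a non-degenerate null;
* condition b: 15% of 50-datapoint windows remodeled by flipping the
  pairing status of half their A/C positions — yielding a global
  significant-window rate near the ~11% such perturbation experiments
  report — plus one "released" RBP whose site occlusion is lifted;
* 8 RBPs × 20 sites of 30 nt placed on mostly-unpaired stretches (CLIP
  compilations are dominated by single-stranded-RNA binders), occluding
  modification by a factor 0.9 while bound.

Two knobs deserve comment. The RBP count and site budget keep the released
RBP a small fraction (~15%) of the CLIP-bearing window pool: the
scrambled-location null draws from exactly that pool, so a generator in
which one RBP dominates it would contaminate its own null — the real
compilation spans ~150 RBPs, where this is never an issue. And the total
occluded footprint is kept near a quarter of the transcriptome: protein
occlusion deliberately masks structural signal (as it does in cells), so an
over-occluded simulation would degrade planted-structure recovery for
reasons that have nothing to do with the algorithms under test.

Condition-b remodeling operates on per-position pairing *status* (the
reactivity class), not on the sequence, so flipped windows are no longer
sequence-foldable hairpins in condition b; planted-structure scoring is
therefore always done against the planted pairing. Everything flows from
one mandatory seed; all outputs are byte-reproducible.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: alignment and PCR-duplication artifacts,
position-dependent coverage within a transcript, sequence-dependent
modification biases, conformational ensembles (every position has one
pairing status), pseudoknots, and noncanonical pairs. The generator's
per-window independence also makes multiple-testing behavior cleaner than
in real transcriptomes, where neighboring windows are correlated.

## Validation design and problem sizes

The test-suite sizes are chosen to exercise every code path at desk scale:
oracle equivalence uses the naive \(O(n^2)\) pairwise Gini, exhaustive
AUROC pair counting (n ≤ 50), combinatorial hypergeometric sums (M ≤ 30),
a hand-written BH step-up, and full enumeration of non-crossing structures
(L ≤ 12). Null calibration uses 2000 windows at 2 + 2 replicates;
planted-effect recovery averages 3–5 default fixtures (each fixture's truth
set is only ~30 remodeled windows, so single-fixture estimates are noisy);
released-RBP detection is counted over 20 fixture seeds with a 10-scramble
null. `pROC::auc` serves as an independent cross-check of the AUROC
implementation in the unit tests.

## Degenerate inputs and tie-breaking, in one place

* zero-coverage positions: absent from profiles (undefined, not zero);
* zero-variance replicate columns: missing correlation, excluded from
  means; windows with no valid pair flagged and excluded from calls;
* all-zero reactivity windows: Gini missing, window flagged
  `all_zero`;
* region annotation ties: primary label is the alphabetically first
  majority region (deterministic `max.col` tie-break), with all overlapped
  labels retained in `regions_all`;
* folder traceback: pair-the-left-end preferred, smallest partner index
  first — reruns are byte-identical;
* `k_null` = 0 in RBP enrichment: fold undefined and flagged, p still
  reported;
* boundary semantics: calling thresholds and p~adj~ ≤ α are inclusive;
  RBP hit selection (|log~2~FC| > 1.1, p < 0.001) is strict.

## Known limitations

The built-in folder maximizes penalized pair counts, not free energy; use
the external adapter for thermodynamically meaningful structures. The
remodeling t-test is conservative under reproducible-signal nulls (above)
and underpowered at 2 + 2 replicates — windows whose accessibility change
is mostly a uniform rescaling (e.g. a footprint lifting over an entire
window) can escape it, since correlations are scale-invariant. δ has no
significance of its own; it ranks, the t-test gates. And the ≥ 100-read
intersection filter treats the input table's coverage column as
authoritative; upstream quality filtering is the caller's contract.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_experiment(cfg)
pl <- run_pipeline(sim, w = 50)

# structured elements within one condition
called <- call_structured_windows(pl$stats)
table(called$passed)

# remodeling between conditions
rem <- call_remodeled(pl$stats, alpha = 0.05)
head(rem[c("window_id", "delta", "dir_change", "p_adj")])

# RBP-site enrichment among remodeled 20-datapoint windows
pl20 <- run_pipeline(sim, w = 20)
targets <- map_sites_to_windows(sim$truth$sites, pl20$stats)
sig <- !is.na(pl20$stats$p_adj) & pl20$stats$p_adj <= 0.05
res <- rbp_enrichment(targets, sig, seed = 7, null_draws = 10)
select_rbp_hits(res)
```
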