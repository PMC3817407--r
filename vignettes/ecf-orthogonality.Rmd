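---
title: "Models and methods behind ecfortho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecfortho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecfortho)
```

## Scope

`ecfortho` implements the computational side of building an orthogonal
transcriptional toolkit from extracytoplasmic function (ECF) sigma
factors: bipartite promoter models and scanning, two-block motif
discovery, promoter mining from annotated genomes, host-exclusion and
UP-element redesign, crosstalk-matrix statistics with orthogonal-subset
selection, a sigma/anti-sigma sequestration model of threshold-gated
switches, and subgroup co-occurrence statistics.  Everything runs on
synthetic data produced by the package's own seeded generators, so every
claim in this vignette is reproducible from code.

## The bipartite promoter model

ECF sigma factors read promoters with two domains: domain 4 binds the
-35 element and domain 2 the -10 element, with a variable-length spacer
between the elements.  A promoter model couples

* a -35 position weight matrix (PWM),
* a -10 PWM, and
* a spacer-length penalty,

and optionally an A/T-richness UP bonus (below).  PWM probabilities use
Laplace smoothing with a pseudocount distributed by the background:
`p[b,i] = (count[b,i] + pc * bg[b]) / (n + pc)`; scores are log2-odds
(`log2(p/bg)`), so every score in the package reads in bits and the
per-position information content that sets sequence-logo letter heights
is the background-relative Kullback-Leibler term.  The default
pseudocount is 1.0 for PWMs and 1.0 over the support for spacer counts
-- plain Laplace smoothing; nothing in the data dictated another
choice.

The spacer penalty is normalised to the modal length:
`penalty(L) = log2(phat(L) / phat(mode))`, zero at the mode and negative
elsewhere, with `-Inf` outside the support (the placement is simply
disallowed).  Normalising at the mode makes the score of a perfect
promoter equal the sum of its two consensus block scores, which keeps
scores comparable across models; only the shape of the penalty, not its
normalisation, affects which placement wins a scan.

`scan_promoter()` maximises `score35 + score10 + penalty + up_term` over
every (-35 offset, spacer) placement.  Scanning is single-strand because
promoters are directional; callers reverse-complement minus-strand
regions (as `extract_upstream()` does).  Ties are broken by the leftmost
-35 offset, then the shortest spacer, so output is deterministic.  The
scan is tested against an independent brute-force enumeration oracle on
random sequences.

**The UP term.**  Promoters from GC-rich genomes often only function
after their -60..-36 segment is replaced with an A/T-rich UP element
that recruits the RNAP alpha subunits.  The full promoter score is
described as UP + PWM(-35) + PWM(-10) + spacer penalty, but no
functional form for the UP term is published with the main text.  We
ship it as a configurable bonus `up_beta * (#A/T in the up-to-23-nt
window upstream of the -35 block) / 23`, default `up_beta = 0` (off).
Counting A/T over whatever part of the window exists while dividing by
the fixed width means that adding flanking sequence can only add A/T
counts, which preserves the invariant that extending a sequence never
lowers its best scan score.

## Two-block motif discovery

`discover_two_block()` is a collapsed Gibbs sampler over one site per
sequence, where a site is a (-35 block, spacer length, -10 block)
triple.  Each sweep removes a sequence's site from the count matrices,
scores all feasible placements under the leave-one-out predictive model
(smoothed PWMs plus the smoothed spacer length distribution), and
resamples from the Boltzmann weights.  Two standard failure modes are
addressed explicitly:

* **Phase shifts.**  Like all Gibbs motif samplers, the chain can lock
  onto the planted motif shifted by one column.  Every tenth sweep (and
  once before finalisation) the sampler proposes shifting all sites
  together, or one block alone with the spacer absorbing the shift, and
  accepts greedily when the total information content (IC) increases.
* **Termination.**  After sampling, a greedy finalisation pass reassigns
  sites one sequence at a time, accepting a move only if total IC
  increases, so IC is non-decreasing across finalisation by
  construction.  The best of `n_restarts` restarts by final IC is
  returned, and the whole procedure is deterministic for a fixed seed.

Defaults (3 restarts, 60-100 sweeps, PWM pseudocount 1) recover planted
consensus sequences at mutation rate 0.1 from 30 sequences in 10/10
test seeds; the published search this reimplements conceptually
(a two-block search joined by a variable spacer) does not document its
parameterisation, so these defaults are the package's own.

## Mining promoters from genomes

`extract_upstream()` walks upstream across same-strand neighbours whose
intergenic gap is at most `operon_gap` (default 50 nt -- a common
operon-calling heuristic; no threshold is published for the original
extraction) and returns up to `max_len` (default 300 nt, a typical
bacterial regulatory window) upstream of the operon head, oriented with
the gene.  Candidate promoters are ranked by `assess_candidates()`:
host-flagged candidates last, then by descending orthogonality margin
(cognate score minus best off-target score), autoregulatory candidates
first among ties -- mirroring how the library favoured promoters found
immediately upstream of their own sigma.  The autoregulatory call is
made by the caller (in the toy-genome pipeline: the promoter window ends
within 150 nt of the cognate operon head).

The host-exclusion screen removes candidates resembling promoters of
the host machinery: an *E. coli* sigma70-like model built from the
textbook TTGACA/N17/TATAAT consensus and a FecI-like model whose
consensus is a synthetic stand-in (the study's actual FecI model lives
in unpublished supplementary material).  The default cutoff is each
model's consensus score minus 6 bits; no cutoff is published, and 6
bits keeps the false-positive rate on random 80-mers below ~5% while
always catching embedded host consensus sites.  The packaged 25-nt UP
element is likewise a documented synthetic stand-in.

## Crosstalk statistics and orthogonal subsets

Fold induction divides the reporter fluorescence with the sigma by the
reporter-only fluorescence; fold repression divides sigma-only by
sigma-plus-anti-sigma; both consume geometric-mean fluorescence after
gating out non-positive events.  Activity calls use strict thresholds
(>5-fold for sigmas, >2-fold for anti-sigmas); the boundary counts as
inactive, which is the literal reading of the published wording.

The off-target load of a cognate pair (sigma s, promoter p) sums
`max(fold - 1, 0)` over s's row (excluding p) and p's column (excluding
s).  Subtracting the neutral fold of 1 makes a silent cell contribute
exactly zero; clamping at zero keeps loads nonnegative when repression
pushes a cell below 1.  The ordering arithmetic behind the published
"most orthogonal" ranking is not defined there; this subtract-and-clamp
convention is the package's definition.

`select_orthogonal()` finds the k most orthogonal pairs by greedy
elimination (repeatedly dropping the worst-loaded pair, recomputing
within the survivors) followed by a deterministic local search that
exchanges one, then two, selected pairs for eliminated ones whenever the
subset's total load strictly drops.  Plain greedy elimination alone can
end several-fold off the optimum on sparse 8-pair toys whose optimum is
small; with the exchange step the test suite holds the gap to the
brute-force optimum under 10%, while the cost stays polynomial (the
search works on a precomputed pairwise excess matrix with O(k) swap
deltas), unlike exhaustive subset search.

`compare_predicted_measured()` reports the Spearman correlation between
model scores and log2 fold inductions over all matrix cells, the
package's analogue of the published score-versus-activity scatter.

Growth support: `growth_rate()` is the least-squares slope of ln(OD600)
versus time; when no window is given it uses the maximal-slope
contiguous 5-point window, a concrete stand-in for the undefined
"linear section".  `percent_of_wt()` flags toxicity strictly below 75%
of the wild-type mean.

## The sequestration switch model

Anti-sigmas inhibit their sigmas by 1:1 stoichiometric binding.  The
model is deliberately minimal: equilibrium binding with dissociation
constant `kd` (no RNAP competition, no kinetics), total sigma linear in
the input promoter activity, and a saturating promoter response
`output = basal0 + vmax * S/(k_half + S)` in free sigma `S`.  Free
sigma is the nonnegative root of
`S^2 + (anti_total + kd - sigma_total) S - kd sigma_total = 0`,
evaluated with the cancellation-free quadratic branch so the solution
is accurate to 1e-9 even at the equivalence point.  This molecular
titration creates the threshold: below `anti_total` the input is
absorbed; above it free sigma rises steeply.

`fit_hill()` characterises a transfer function phenomenologically:
least squares on log outputs (weighting the low-output regime where the
OFF state matters) for `y = basal + amplitude * x^n/(k^n + x^n)`,
multi-started over n in {0.5, 1, 2, 4, 8} and three threshold starts,
with n bounded in [0.2, 12]; flat data are flagged unidentifiable
rather than fitted.  Noiseless Hill-generated data are recovered to
0.1% relative.

`tuning_curve()` sweeps anti-sigma expression levels.  Its `basal`
column is the simulated output at the lowest input level -- the OFF
state of a switch whose uninduced input promoter still leaks -- which
is pointwise non-increasing in the anti-sigma level; the Hill fit's own
basal parameter is reported separately as `hill_basal`.  (At an input
of exactly zero, every anti-sigma level gives the same output `basal0`,
so demo input grids start at a small positive level.)  Under the
packaged demo parameters (`kd = 0.01`, `k_half = 0.5`, `vmax = 1000`,
`basal0 = 2`, anti levels 0-200, inputs 0.01-1000) the sweep shows the
three behaviours measured for real switches: the OFF state drops about
10-fold, the apparent Hill coefficient rises from 1 (pure
Michaelis-Menten without anti-sigma, a property the tests assert) to
above 3, and the activation threshold shifts by more than two orders of
magnitude.  The apparent n is not strictly monotone at saturating
anti-sigma levels: the true transfer function leaves the Hill family
there and the fitted n plateaus with drift of order 0.1, so trend
claims are asserted as rank correlations rather than per-step
inequalities.

## Co-occurrence statistics

`partner_count()` gives, for each subgroup, the mean number of other
subgroups present in the genomes containing it (all subgroups in the
matrix count as potential partners, not only those being compared).
`compare_groups()` tests the difference in mean partner counts between
two disjoint subgroup sets with a two-sided label-permutation test
(add-one Monte Carlo estimator, seeded).  The published comparison of
non-crosstalking versus crosstalking subgroups does not name its test
or define whether its headline numbers are means or medians, so
numerical agreement with the published P-value is not expected; the
package instead verifies that its own test is calibrated (null
p-values uniform by Kolmogorov-Smirnov) and powered against the biased
generator.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (parameters, seed): it runs under
`with_seed()`, restores the caller's RNG, and derives stage-local
substreams with `derive_seed()` (a stable string hash folded into the
run seed), so partial pipeline reruns reproduce stage by stage.

* `gen_subgroup_promoters()` plants a -35/spacer/-10 motif in an 80-nt
  -60..+20 window of i.i.d. background at a configurable GC fraction.
  Mutations always substitute to a *different* base chosen uniformly,
  so the per-position mismatch fraction equals the mutation rate
  exactly and planted information content is analytically predictable.
  The -35 block is anchored at position -35, matching the coordinate
  the window naming refers to.
* `gen_toy_genome()` builds operons whose promoter windows end at the
  operon head's +20 (the ORF starts at window position +1); alternating
  operons bury the sigma gene behind a leader gene with a 30-nt
  internal gap, and strands alternate, so upstream extraction is
  genuinely exercised.
* `gen_crosstalk_matrix()` multiplies a truth-table fold matrix by
  lognormal noise with mean 1 and a configurable CV.  Lognormal noise
  matches the multiplicative error of geometric-mean flow cytometry
  readouts.  Default promoter leak values span 10-fold, the spread the
  measured libraries showed.  The empirical distribution of off-target
  folds is not published; the truth table's off-target matrix is fully
  configurable and defaults to silent (fold 1).
* `gen_presence_matrix()` designates an "insulated" and a
  "crosstalking" subgroup quarter and tilts their presence toward
  subgroup-rich or subgroup-poor genomes on the logit scale; at zero
  bias all subgroups are i.i.d. Bernoulli.  No phylogenetic structure
  is modelled.

Passing tests on these generators show the algorithms recover planted
structure under calibrated noise; they do not show that real promoter
libraries satisfy the generators' independence assumptions (no
phylogenetic correlation between genomes, no sequence composition
beyond GC, no correlated measurement error across a plate).

## Numerical choices and degenerate inputs

* Log base 2 throughout; scores are bits.
* Promoter coordinates have no position 0; sequences are stored
  0-based internally with `window_index()` exposing the map, which
  avoids off-by-one arithmetic at the -1/+1 boundary.
* N is accepted in genome files only; scoring requires unambiguous
  bases and says so.
* A single promoter with a single model has no competitor: the best
  off-target score is `-Inf` and the margin `+Inf`, reported as such.
* `free_sigma()` at `anti_total = 0` returns `sigma_total` exactly; the
  tight-binding limit (`kd -> 0`) approaches
  `max(sigma_total - anti_total, 0)`.
* Selection and elimination ties break lexicographically by sigma id;
  load comparisons use a small absolute tolerance so that
  mathematically tied twins are not separated by floating-point
  summation order.

## Problem sizes used by the test suite

The suite runs motif discovery on 30 x 80-nt sequence sets (10 seeds),
orthogonal-subset recovery on 30-pair matrices (100 noise seeds),
permutation calibration on 200 simulated 12x30 presence matrices, and
the titration sweep on 20 parameter draws of 5 anti levels x 25 input
levels; these sizes give stable pass/fail behaviour for the stochastic
assertions while keeping a full run in minutes on one core.

## Known limitations

* The sampler fits one site per sequence; multi-copy promoters within
  one upstream region are not modelled.
* The switch model omits RNAP competition among sigmas and all
  kinetics; it cannot produce hysteresis or dynamic responses.
* The packaged roster is a synthetic reconstruction with placeholder
  organisms and sequences; it reproduces the published library *counts*
  and naming conventions, not the actual parts.
* Hill fits at strongly saturating anti-sigma levels are systematically
  mis-specified (the data leave the Hill family), which is why apparent
  n saturates; interpret n there as an effective sharpness, not a
  molecularity.
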