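# ecfortho

Tools for engineering orthogonal gene-expression channels from
extracytoplasmic function (ECF) sigma factors — the largest and most
diverse family of bacterial sigma factors, whose two domains read the
−35 and −10 promoter elements independently.  Because different ECF
subgroups recognise different −35/−10 combinations, a cell can in
principle host many sigma:promoter pairs that activate only each other.
`ecfortho` implements the computational workflow for building and
analysing such a toolkit:

* **Bipartite promoter models** — paired −35/−10 position weight
  matrices (PWMs) joined by an empirically penalised variable spacer.
  The score of a promoter fragment is
  `score = S₋₃₅ + S₋₁₀ + log₂(p̂(L)/p̂(L_mode)) + UP`,
  where each block score is a sum of per-position log₂-odds
  (`log₂(p/bg)`, bits), the spacer term penalises suboptimal −35/−10
  spacing relative to the modal length, and the optional UP term
  rewards A/T-richness upstream of the −35 (off by default).
* **Two-block motif discovery** — a collapsed Gibbs sampler (one site
  per sequence, variable spacer, phase-shift moves, IC-greedy
  finalisation) for finding −35/spacer/−10 motifs in upstream regions.
* **Promoter mining** — operon-aware upstream-region extraction from
  annotated genomes, candidate ranking by orthogonality margin,
  host-promoter (σ⁷⁰/FecI-like) exclusion, UP-element redesign, and
  chimeric sigma/promoter combinatorics.
* **Crosstalk analysis** — fold-induction/repression statistics,
  strict activity thresholds (>5-fold σ, >2-fold anti-σ), off-target
  loads, selection of the k most orthogonal σ:promoter pairs, and
  predicted-versus-measured rank correlation.
* **Threshold-gated switches** — a molecular-titration model of σ
  sequestration by anti-σ (free σ from the 1:1 binding mass balance,
  saturating promoter response), Hill-fit characterisation, and
  tuning-curve analysis of basal level, cooperativity, and threshold.
* **Co-occurrence statistics** — partner counts of ECF subgroups across
  genomes and a permutation test comparing subgroup sets.
* **Synthetic data generators** — seeded, reproducible generators for
  every input: promoter sets with planted motifs, toy genomes with σ
  operons, noisy crosstalk matrices, switch transfer functions, and
  presence/absence matrices.

The package ships a synthetic reconstruction of the study-scale library
roster (86 σs — two from each of 43 subgroups — 62 anti-σs, 29
promoters) with the field's naming conventions (`ECFXX_YYYY`,
`ASXX_YYYY`, `P_XX_YYYY`, `P_XX_UPYYYY`).

## Worked example

```r
library(ecfortho)

# the packaged library roster and its screen design
r <- packaged_roster()
#> ECF library roster: 86 sigmas, 62 anti-sigmas, 29 promoters
d <- screen_design(r)
# 29 x 86 = 2494 activity measurements; 16 x 10 = 160 possible chimeras

# discover a bipartite motif in synthetic promoters (10% mutation rate)
spec  <- motif_spec("GGAACTT", "GTCGTA", mutation_rate = 0.1)
proms <- gen_subgroup_promoters(spec, 30, seed = 42, subgroup = 11)
model <- discover_two_block(proms$sequence, w35 = 7, w10 = 6,
                            spacer_range = c(15, 17), seed = 1)
model
#> Promoter model (subgroup ?): -35 GGAACTT / spacer 15-17 (mode 16) / -10 GTCGTA
scan_promoter(model, proms$sequence[1])
#> Hit: -35 @25, spacer 15, -10 @47 | 8.21 + 7.38 -0.45 +0.00 = 15.14 bits

# select the 20 most orthogonal pairs from a noisy 30-pair crosstalk matrix
tt    <- truth_table(30, cognate_fold = 100,
                     offtarget_fold = {o <- matrix(1, 30, 30); o[21:30, ] <- 4; o})
noisy <- gen_crosstalk_matrix(tt, noise_cv = 0.3, seed = 7)
head(select_orthogonal(noisy, tt$cognate_map, k = 20), 3)
#>     sigma_id promoter_id offtarget_load
#> 1 ECF14_1014   P_14_1014       2.869194
#> 2 ECF08_1008   P_08_1008       2.961382
#> 3 ECF19_1019   P_19_1019       3.737203

# tune a sequestration switch by titrating the anti-sigma
p  <- titration_params(kd = 0.01, k_half = 0.5, vmax = 1000, basal0 = 2)
tc <- tuning_curve(p, anti_levels = c(0, 2, 10, 50, 200),
                   inputs = 10^seq(-2, 3, length.out = 25))
round(tc[c("anti_total", "basal", "k", "n")], 2)
#>   anti_total basal      k    n
#> 1          0 21.61   0.50 1.00
#> 2          2  2.10   3.38 2.89
#> 3         10  2.02  15.50 3.07
#> 4         50  2.00  68.62 3.36
#> 5        200  2.00 309.29 3.14
```

The discovered model matches the planted consensus exactly, and its
best placement on the first promoter recovers the planted site (−35 at
offset 25, the window's −35 position) at 15.1 bits.  The
orthogonal-subset selection returns the 20 planted clean pairs, ordered
by their residual off-target load (the summed above-baseline fold in
each pair's row and column).  In the switch sweep, raising the anti-σ
level drops the OFF-state output ~10-fold (21.6 → 2.0), raises the
apparent Hill coefficient from 1.0 to above 3, and shifts the
activation threshold k by over two orders of magnitude — the three
behaviours that make sequestration switches composable.

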