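---
title: "Modelling and quantifying UV photoproduct repair at yeast subtelomeres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying UV photoproduct repair at yeast subtelomeres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telorepair)
```

## The biological problem

UV light covalently links adjacent pyrimidines in DNA, producing cyclobutane
pyrimidine dimers (CPDs) and, less frequently, pyrimidine(6-4)pyrimidone
photoproducts (6-4PPs). Yeast removes these lesions by nucleotide excision
repair (NER), which operates through two sub-pathways: global genome repair
(GGR), active everywhere but hindered by compacted chromatin, and
transcription-coupled repair (TCR), which requires Rad26 and acts only on
the template strand of transcribed regions. Chromosome ends are a stringent
test case for both: subtelomeres carry Sir2-dependent silenced chromatin,
and they are pervasively transcribed into non-coding RNAs (TERRA toward the
telomere, with the C-rich strand as template; CUT-like transcripts toward
the centromere, templated by the G-rich strand).

Two gel assays quantify repair at this resolution:

* **T4 endonuclease V Southern blots.** T4 endo-V nicks DNA at CPDs (and
  only CPDs). Comparing a mock-treated lane with a T4-treated lane of the
  same restriction fragment, the surviving full-length signal is the
  fraction of molecules with *zero* CPDs on the probed strand. Under
  independent lesion placement that fraction is the Poisson zero class, so
  the mean CPD density is `D = -ln(I_T4 / I_mock) / L` CPDs per kb.
* **Primer-extension (polymerase stop) ladders.** Taq polymerase extends a
  strand-specific primer until it hits a photoproduct (CPD or 6-4PP) on the
  template; each stop position produces a band whose lane-normalized
  frequency tracks the lesion frequency at that position, at nucleotide
  resolution.

`telorepair` implements both quantifications together with a generative
simulator of the whole experiment, so every analysis stage can be verified
by parameter recovery: simulate with known lesion densities and repair
rates, analyze with the same formulas used on real gels, and check that the
generating values come back.

## The locus model

`build_synthetic_subtelomere()` constructs an annotated two-strand model of
a chromosome end from an ordered element plan (centromere to telomere):
upstream flank, X-element (XC + XR regions, ~730 bp total), optional Y'
elements, and the terminal repeat tract. Conventions:

* Coordinates are 1-based inclusive on the top strand, which is the G-rich
  strand written 5'->3' from centromere to telomere. C-rich strand
  positions are reported in that strand's own 5'->3' frame (which runs
  telomere to centromere) with a deterministic conversion; this matches the
  reading direction of each primer's gel ladder.
* Y' elements come in two size classes, long (6.7 kb) and short (5.2 kb),
  each with (`v1`) or without (`v2`) a ~0.3 kb small variable region. A
  `v2` element immediately followed by a Y'-short is rejected; that
  pairing does not occur in the strains this design mirrors.
* The terminal tract follows the C1-3A/TG1-3 motif family, with a 3'
  single-stranded overhang of 8-14 nt. Its length is drawn from a truncated
  normal (mean 325 bp, sd 50 bp, bounds 175-475 bp). Telomere length is
  heterogeneous *between molecules* of a population - this is why terminal
  restriction fragments run as broad smears - so the simulator draws a
  length per molecule from the same distribution, and terminal
  `Fragment$length_kb` stores the population mean. The repeat sequence is
  synthesized to the 475 bp upper bound so per-molecule draws above the
  locus draw remain covered.

Restriction sites are placed per element so that in-silico digestion
reproduces the fragment scheme of the real loci: each Y' carries an EcoRI
site 2.0 kb (+0.3 kb for `v1`) from its start, a HindIII site 2.4 kb
(+0.3 kb for `v1`) from its end, and an XhoI site 0.975 kb from its end.
HindIII/EcoRI double digestion of adjacent Y' pairs then yields junction
fragments of exactly 4.4, 4.7 or 5.0 kb (three classes over all allowed
variant pairings), HindIII releases a ~3.0 kb terminal fragment (2.7 kb of
Y' + ~0.3 kb of repeats) and XhoI a 1.3 kb terminal fragment. The exact
intra-Y' coordinates are not published; these placements are calibrated to
the published fragment lengths, which is what the downstream quantification
depends on. Real loci can be supplied as FASTA plus a YAML annotation
(`load_locus_fasta()`); degenerate bases are rejected rather than coerced.

```{r locus}
locus <- build_synthetic_subtelomere(
  yprime_locus_plan(c("long", "long"), c("v1", "v2")), seed = 11)
digest(locus, c("HindIII", "EcoRI"))
```

## Lesion formation

`scan_dipyrimidine_sites()` lists every adjacent pyrimidine pair per strand
(overlapping pairs both count). Site i forms a CPD with probability
`p_i = min(alpha * dose * w(dinuc_i), 1)`: linear in dose with a
dinucleotide weight. The default weights (CPD: TT 1.0, TC 0.5, CT 0.25,
CC 0.1; 6-4PP: TC 1.0, TT 0.3, CT 0.1, CC 0.05) encode the standard rank
order of photoreactivity; their absolute scale never matters because
`calibrate_scale()` always sets `alpha` so that the expected density on a
chosen fragment and strand equals a target (closed form in the linear
regime, `alpha = D * L / (dose * sum(w))`). Total 6-4PP yield defaults to
one third of CPD yield. Lesions are placed independently per site and
molecule, at most one per site - the assumption underlying the Poisson
zero-class estimator, so simulator and estimator are a matched pair by
construction, and recovery failures indicate implementation errors rather
than model mismatch.

The study conditions emulated by the defaults: 180 J/m^2, repair times 0,
0.5, 1, 2 and 4 h, and the published 0-h densities (0.67/0.56 CPD/kb on the
C-/G-rich strand of the ~4.7 kb junction cluster; 0.58/0.36 CPD/kb on the
1.3 kb terminal fragment) as calibration targets.

## Repair model

Each lesion is removed independently by time `t` with probability
`1 - exp(-k_site * t)`, where

```
k_site = k_GGR * c(site, strain) + tau(site, strand, strain) * k_TCR * [rad26]
```

and `k_site = 0` in a rad14 deletion (no NER at all). `c` is a chromatin
accessibility factor, 0.5 inside the Sir-silenced telomere-proximal domain
of SIR2+ strains and 1 everywhere in sir2 deletions; `tau` indicates the
template strand of a transcription unit active in that strain. TERRA-class
units are always templated by the C-rich strand; in sir2 deletions the
TERRA unit extends downstream of the mapped TSS (~350 nt upstream of the
repeats) and a centromere-directed CUT-like unit is enabled. The defaults
`k_GGR = 0.25 h^-1` and `k_TCR = 0.33 h^-1` were fixed once by inverting
the published 4-h removal extents (GGR alone ~63%; with TCR ~90%); they are
parameters of the generator, not fitted quantities. The exponential form
nests the only thing the assays report - fractional removal at fixed times
- and a single `k` is used for both photoproduct types (the data do not
separate them within the extension ladders).

This model reproduces the qualitative strain orderings that matter:
`WT >= rad26` and `sir2 >= WT` on TERRA-template segments, no repair in
`rad14`, and strand asymmetry concentrated where transcription is.

## Simulating the two assays

`simulate_t4v_lanes()` emits mock/+T4 lane pairs per repair time, plus a
-UV pair. Mock intensity is proportional to all molecules; +T4 intensity to
the zero-CPD molecules (6-4PPs are never cut). Because molecules are
i.i.d., the zero-CPD count is drawn exactly as a binomial with
`q0 = prod(1 - p_i * exp(-k_i t))` - distribution-identical to simulating
every molecule, which the `method = "molecule"` path does (and the tests
cross-check). For terminal fragments, `q0` is evaluated per molecule at its
sampled telomere length and the smeary band is integrated into a single
intensity.

`simulate_primer_extension_lanes()` walks each molecule from the primer 3'
end along the template and stops at the first event: a template photoproduct
(blockage probability 1 - the blockage is treated as complete), a natural
polymerase-arrest site (default per-encounter probability 0.02; these are
the bands that also appear in -UV lanes), or the fragment end (full-length
band). PCR amplification is treated as linear in stop counts.

Noise is multiplicative lognormal per band (sdlog 0.1) plus a per-lane
loading factor (sdlog 0.15); with both at zero the pipeline is
deterministic given the molecule counts. All randomness is drawn from named
substreams of a master seed (`derive_seed()`), one per strain, replicate,
time and purpose, so datasets regenerate bit-identically and adding a
replicate never perturbs existing ones.

## Quantification

The analysis functions mirror the gel quantification exactly:

* `cpd_density_from_bands(I_mock, I_t4, L)` - the zero-class estimate
  `-ln(I_t4/I_mock)/L`; ratios above 1 (noise) clip to density 0 and are
  flagged.
* `band_frequencies()` - each band divided by its whole lane, cancelling
  loading factors.
* `background_correct()` - per-band subtraction of the -UV lane
  frequencies, clipped at 0.
* `percent_repair(D0, Dt)` - `100 * (D0 - Dt) / D0`; the 0-h point is 0%
  by construction, negative values (noise) are reported rather than
  hidden, and clipping at zero damage means percent repair never exceeds
  100.
* `pd_repair_curves()` / `t4v_repair_curves()` - per-photoproduct and
  per-fragment curves; `aggregate_cluster()` averages member photoproducts
  per time, reporting a standard error only for clusters of at least 3
  members (smaller clusters are flagged and excluded from ANOVA).

Two numerical behaviours are worth knowing. First, the extension
percent-repair estimator inherits a *first-stop coupling*: as upstream
lesions are repaired, downstream bands gain visibility, which biases their
apparent repair downward. The default window calibration (0.15 CPD/kb)
keeps this coupling at about one percentage point; at ~1 CPD/kb it reaches
tens of points, so dense-damage simulations should not be interpreted
through per-band percent repair. Second, the 1.3 kb terminal fragment is
short enough that lane noise dominates single lane-pair density estimates
(~30% relative sd under default noise); per-replicate percent-repair values
there are honest but wild, exactly as the corresponding real measurements
carry the largest error bars. Recovery of the generating density is still
accurate in the mean over many lane pairs.

## Statistics

`two_way_anova_sidak()` fits a fixed-effects two-factor ANOVA (strain,
time, interaction) on percent-repair observations and contrasts the
strains at each time using the pooled residual variance, with Sidak
adjustment `p_adj = 1 - (1-p)^m` over the `m` compared time points
(default: the positive times; the 0-h point is identically 0 and is not
compared). Observations entering the ANOVA are per-replicate cluster means
(`per_replicate_cluster_means()`), not per-photoproduct values: member
photoproducts of a cluster share lanes and are not independent, so using
them as replicates would be pseudo-replication. A flagged alternative is
deliberately not offered as a default. With a single time point the
procedure reduces exactly to the pooled two-sample t-test (F = t^2).
`tcr_contribution()` differences the 4-h repair of genotype pairs with and
without TCR (WT vs rad26, or sir2 vs sir2 rad26) and classifies clusters
as TCR-assisted when the delta exceeds 10 percentage points (configurable)
and the adjusted contrast is significant; `strand_bias()` reports the
C-rich : G-rich repair ratio.

## What the simulations do and do not establish

The generator emulates: sequence-determined lesion placement, strand- and
strain-specific exponential repair with chromatin and transcription
effects, molecule-level telomere-length heterogeneity in Southern smears,
polymerase stop logic with natural arrests, and band/loading noise. It does
not emulate: gel image formation and densitometry, probe hybridization
kinetics or cross-hybridization, photoproduct interference or
sequence-context effects beyond the dinucleotide, PCR amplification bias,
per-molecule telomere variation within extension templates, or the real
(unknown) bracket used to integrate smeary bands. Passing recovery tests
therefore demonstrates that the quantification formulas are implemented
correctly and are consistent estimators under the model's assumptions -
not that real gels satisfy those assumptions.

Problem sizes used by the test-suite recovery runs were chosen for stable
statistics: 1,000-4,000 simulated lane pairs of 10,000 molecules for
zero-class recovery (estimator bias well under 1%, Monte-Carlo SE of the
mean 0.2-1.7%), 100,000-200,000 molecules for extension-band oracles, and
1,000 null simulations for the Sidak type-I check (adjusted per-time
contrasts are conservative: empirical rate ~0.01-0.02 at nominal 0.05).

## Reproducing an analysis end to end

```{r pipeline, eval = FALSE}
cfg <- list(
  master_seed = 1,
  locus = list(type = "synthetic", preset = "yprime", seed = 11),
  strains = c("WT", "rad26"), replicates = 3,
  times = c(0, 0.5, 1, 2, 4), n_molecules = 10000, dose = 180,
  noise = list(band_sigma = 0.1, loading_sigma = 0.15),
  assays = default_t4v_plan()$assays)
paths <- cmd_simulate(cfg, "run1")
res <- cmd_analyze("run1", cfg, "run1/analysis")
```

`cmd_simulate()` writes the tidy lane TSV (also the import format for real
densitometry tables), a provenance JSON naming every parameter and seed,
and BED annotation of the locus; `cmd_analyze()` writes per-photoproduct
curves, cluster summaries, Sidak-adjusted strain comparisons and a BED
track of 4-h percent repair per position. A thin command-line wrapper
around these two functions ships in `inst/cli/telorepair.R`.
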