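---
title: "Control-region phylogeography with dloopr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-region phylogeography with dloopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dloopr)
```

dloopr implements the standard desk workflow for human mitochondrial
control-region (D-loop) phylogeography: variants are called against the rCRS
coordinate system, motifs are assigned to haplogroups through a
motif-registry tree, clades are summarised as median-joining networks, founder
ages are estimated with the rho statistic under several clock calibrations,
and population structure is quantified with diversity statistics and
AMOVA-based PhiST. A seeded coalescent generator produces datasets with known
truth so every stage is testable without external data. This vignette
documents the models, the parameters that matter, and the design decisions
taken where conventions in the field are loose.

## The reference and coordinate system

All variants are expressed relative to rCRS numbering (1-based, 16,569
positions). The package cannot redistribute the rCRS itself, so
`rcrs_reference()` builds a **synthetic rCRS-like reference** at run time from
the older public human mtDNA sequence shipped with seqinr (NC_001807.4): the
homopolymer runs at 303–315 and 16183–16193 are normalised to the canonical
rCRS structure, the placeholder N at 3107 is inserted so numbering matches
rCRS exactly, and every position used by the clade registry, the variant
notation, or the PCR/RFLP assay is patched to its documented rCRS state (a
bare transition token such as `470` fixes the reference base at that
position). Positions not anchored this way may differ from the true rCRS;
because all motif arithmetic is relative and the package only interprets
anchored positions, this does not affect any computed result. The 8116
SmaI-assay context was verified on the scaffold itself: the forward and
reverse primers bind uniquely, 275 bp apart, and the reference carries
`CCCGGA` ending at 8116 so that only the A8116G transition creates the
`CCCGGG` SmaI site.

The default region is the two-segment control region 16032–16544 plus
51–555. These coordinates give 513 + 505 = **1018 bp**, and
`region_spec()` always sets `total_length` to the computed sum; publications
sometimes quote 1016 bp for this layout, but the segment coordinates are
taken as authoritative. Region segments, never circular arithmetic, handle
the origin-spanning nature of the D-loop, and per-sample regions are
supported for datasets sequenced with different range conventions.

## Variant notation and alignment

`parse_variant()` accepts the forensic dialect (`C16187T`, `16183C`, bare
`073`, `315+C`, `249d`, `@`-prefixed reversions); bare tokens denote
transitions whose derived base is the Watson–Crick transition partner of the
reference base. `align_and_call()` uses a global Biostrings alignment with
match +1, mismatch −1, gap open −5, gap extend −2 — the exact scores are not
a scientific claim, only a way to obtain a unique alignment; motif
extraction, not alignment art, is the contract. Indels are canonicalised to
their 3′-most equivalent placement on the forward strand (the EMPOP/forensic
convention), IUPAC ambiguity codes are treated as missing data rather than
mismatches, and an alignment identity below 70% is rejected as
not-a-control-region sequence. The round trip
`align_and_call(apply_motif(ref, m)) == m` holds for all indel-free motifs
and for indel motifs already in canonical placement, and is enforced by
property tests over seeded random motifs.

Two exclusion lists are applied: the 309 poly-C length variants (`309+C`,
`309+CC`) everywhere, and additionally positions 16519 and 152 (hypervariable
and homoplasic) before network building.

## Haplogroup classification

`default_registry()` encodes the classification tree: D1 (16223, 16325,
16362, 73, 263, 315+C, 489) with D1g adding 16187 and its coding-defined
subclades D1g1 (8116) and D1g2 (10202, 10724, 13020); B2 (16183C, 16189,
16217, 73, 263, 315+C, 499) with the Patagonian B2l (470) and the Andean
clusters B2+16188 and B2+146-215-455+T; C1b (the 14-variant nodal including
the 249 and 290/291 deletions and the 522/523 CA deletion) with C1b13 (258);
and D4h3a (16241, 16342) with D4h3a5 (16051). A2, C1c, C1d and C1d1e ship as
*provisional* placeholders with conventional control-region diagnostics, and
the registry is a plain TSV so users can extend or replace it.

`classify()` walks the tree and tolerates one missing defining variant along
the whole path (default), absorbing private back mutations. Among admissible
clades the winner maximises the matched-variant count, then minimises the
missing count, then depth. The pure "deepest admissible" rule would send a
parent's exact nodal motif into any one-variant child within tolerance; the
chosen ordering means extra depth must be earned by extra evidence, so nodal
motifs always classify to their own clade. Ties are reported as ambiguous
rather than resolved heuristically — ambiguity in real data is resolved by
extra typing (as with the 8116 RFLP), not by guessing. Control-region-only
mode is the default because most published datasets lack coding positions;
coding-defined clades are only assignable in `with-coding` mode.

## Median-joining networks

`condense()` collapses motifs into haplotypes with per-population counts and
site weights: default weight 10, down-weighted homoplastic sites 5, excluded
sites 0. The numbers mirror the conventional defaults of the widely used
network program; the down-weight list ships empty because no authoritative
list of "low weight" sites exists.

`build_mj()` iterates the median-joining scheme on weighted binary variant
characters: weighted pairwise distances; the epsilon-relaxed minimum spanning
network (an edge is feasible when its distance is within epsilon of the
minimax path distance between its endpoints); quasi-median generation from
every triplet spanned by a node and two of its feasible neighbours (the
majority-consensus vector); and admission of every new median that does not
increase the cost of a spanning tree of the node set. Weakly cost-neutral
medians are admitted deliberately: they carry the equally parsimonious
alternative paths that display as reticulations. The sweep repeats to a fixed
point (guarded by `max_nodes`), and stranded medians of degree ≤ 1 are
dropped. With `epsilon = Inf` every pair is feasible and the construction
approaches the quasi-median regime; with the default `epsilon = 0` it stays
close to the strict minimum spanning network, which is what routine datasets
want.

`mp_postprocess()` implements the maximum-parsimony cleaning step exactly for
up to 12 observed haplotypes: a Dreyfus–Wagner Steiner-tree dynamic programme
on the network graph finds the minimum cost of connecting the observed
haplotypes, and every median vector or edge that cannot be forced into *some*
minimum-cost tree at no extra cost is deleted. The reported `$cost` is that
Steiner minimum. Beyond 12 observed haplotypes the exact programme is skipped
(the DP is exponential in the number of terminals) and only unconnectable
medians are pruned, with the spanning-tree cost reported as an upper bound.
Equivalence with an independent exhaustive Steiner search over the full site
hypercube is asserted in the test suite for 100 seeded instances of up to 6
haplotypes over 8 sites, in the `epsilon = Inf` regime where exhaustive
parsimony comparison is meaningful (at `epsilon = 0` the sparse feasible-link
graph deliberately proposes fewer medians and need not reach the global
optimum).

## Rho dating and clocks

`rho_sigma()` computes rho as the count-weighted mean number of mutations
from the root (nodal) haplotype to each sampled individual, with the Saillard
error: sigma² = Σ over tree edges of (n_e/n)² m_e. On a reticulated network
the distances are taken along a minimum-cost spanning tree rooted at the
nodal haplotype, ties broken towards paths through higher-frequency nodes —
the resolution of reticulations is not standardised anywhere, so the package
picks the deterministic choice that favours frequent intermediates.
Individuals, not distinct haplotypes, carry the weights; every variant counts
as one mutation regardless of its network site weight. `rho_direct()` is the
star-form shortcut (mean symmetric difference from the founder) used in
replicate simulation studies where building hundreds of networks would be
wasteful.

`clock_registry()` ships four rate-based calibrations (0.45, 0.34, 0.302,
0.24 mutations/site/Myr) and `soares_cr`, the control-region rho calculator
expressed as its linear constant of 9,058 years per mutation. That constant
is the package's own derivation: dividing each published Soares-clock age by
its rho value gives 9,058 within a year in all four cases, so the linear
constant reproduces the published conversions exactly; the original
calculator's time-dependent correction is out of scope and would matter only
beyond the Holocene-scale ages used here. Ages are rounded half-up to the
nearest year; `rescale_age()` converts ages between rates by exact inverse
proportionality, which reproduces published cross-rate tables within ±1 year
(the limit imposed by printed rounding).

## Classic skyline

As a deterministic, desk-scale demographic reconstruction the package uses
the classic skyline: on an ultrametric genealogy with branch lengths in
years, the interval during which k lineages exist contributes
Nef = I_k(generations) × k(k−1)/2, with a generation time of 25 years by
default. `skyline_harmonic_nef()` (time-weighted harmonic mean) recovers the
effective size of a constant population, and `skyline_epoch_ratio()`
(youngest vs oldest tercile of coalescent intervals, time-weighted harmonic
means) separates growth from constancy; terciles rather than single intervals
are used because individual coalescent intervals have unit coefficient of
variation. This is *not* a Bayesian skyline: it operates on a single known
genealogy, carries no MCMC uncertainty, and is used where the genealogy is
available (simulations) rather than estimated from sequences.

## Diversity and structure

`summary_stats()` reports S, haplotype diversity with the Nei (1987)
variance, the mean number of pairwise differences K, and nucleotide diversity
pi = K/L with the Tajima (1983) total variance. Tamura–Nei distances with
gamma shape 0.26 (the standard control-region value) come from ape, with
pairwise deletion of gaps/ambiguities and a p-distance fallback when base
frequencies degenerate. PhiST follows the Arlequin convention for sequence
data: the molecular distance between two individuals is used as the squared
deviation in a two-level AMOVA, and PhiST = sigma²_a / (sigma²_a + sigma²_w);
a haplotype-identity mode provides the frequency-style alternative since the
original analysis could have used either. The estimator is reported
unclamped: on identical mixed populations it takes its exact small-sample
value −1/(n′−1) rather than 0, which the tests assert deliberately.
Permutation p-values shuffle individuals between the two populations (seeded,
1,000 permutations by default in the pipeline configuration, 200 in the
bundled pipeline default for speed; no multiple-testing correction is
applied). The NJ dendrogram uses ape's Saitou–Nei implementation with
negative branches clamped to zero and their excess moved to the adjacent
ancestral branch.

## The coalescent generator

`simulate_genealogy()` is a haploid (female-line) Kingman coalescent with
pair-coalescence rate 1/Nef per generation and closed-form time rescaling for
constant, exponentially interpolated and piecewise demographies; times are
stored in years and converted with the generation time (25 yr) only at the
boundary. `sprinkle_mutations()` adds finite-sites mutation: per-site rates
gamma-distributed (shape 0.26 by default) around a mean of
0.302 mutations/site/Myr, Poisson counts per branch, and state toggling so
that a second hit at a derived site reverts it; new mutations are transitions
with probability 0.95, which approximates control-region behaviour. By
default the founder-motif and registry-diagnostic positions are excluded from
the mutable site set so simulated clades classify unambiguously; switch
`mask_diagnostic` off to stress-test the classifier instead.

Scenario presets calibrate the narratives the package is designed around:
`b2l-like` is a constant Nef = 5,000 females; `c1b13-like` expands an order
of magnitude (500 → 5,000) beginning 5,000 years BP; `d1g-like` grows
500 → 5,000 beginning 9,000 years BP (the same expansion spread over nearly
twice the time, hence "slower"); `two-deme` splits one Nef = 1,000 population
into two isolated demes 10,000 generations ago for PhiST testing. The
pre-expansion sizes are the package's own choice of a plausible
hunter-gatherer female effective size; they were fixed once from that
reasoning, not tuned. What the generator emulates: genealogical noise,
site-rate heterogeneity, homoplasy through finite-sites toggling, founder
motifs, and clean population splits. What it does not: migration,
recombination (absent in mtDNA), selection, sequencing error, heteroplasmy
and ancient-DNA damage — so passing recovery tests demonstrates correctness
of the estimators under the model, not robustness to every artefact of real
data.

Problem sizes used by the automated checks were chosen to keep the full suite
within a few minutes on one core: 200 replicates of n = 30 for dating and
skyline recovery, 100 paired replicates for growth discrimination, 100 random
instances (≤ 6 haplotypes × ≤ 8 sites) for the Steiner equivalence, and 2,000
genealogy-only replicates for the coalescent expectations. At these sizes the
rho-based age recovers the true TMRCA within ~11% (the residual is the
finite-sites back-mutation bias, which the tests bound at 15%), the skyline
harmonic mean recovers Nef within a few percent, and the epoch-ratio test
separates the growth from the constant scenario in effectively every paired
run.

## Known limitations

- The packaged reference is a documented synthetic stand-in, not the rCRS;
  analyses that interpret unanchored positions against it should supply their
  own reference via the `reference` arguments.
- Exact maximum-parsimony cleaning is limited to 12 observed haplotypes;
  larger networks receive heuristic pruning and an upper-bound cost.
- The Soares calibration is linear; deep (pre-Holocene) ages would need the
  time-dependent correction.
- rho dating inherits the known biases of the statistic itself (sensitivity
  to demography and sampling); the simulation tests quantify only the
  no-heterogeneity, constant-size case.
- The classic skyline requires the true genealogy; it is a simulation-side
  instrument, not a substitute for Bayesian skyline estimation from sequences.
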