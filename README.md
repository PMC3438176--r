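# dloopr

Phylogeographic analysis of human mitochondrial DNA control-region (D-loop)
sequences in R — for population geneticists and forensic/anthropological
genetics labs working with rCRS-relative haplotype motifs.

Sequencing surveys of the mtDNA control region summarise each sample as a
*motif*: its list of differences from the revised Cambridge Reference
Sequence (e.g. `073-263-315+C-489-16187`). dloopr implements the complete
desk workflow built on that representation:

- **Variant and motif handling** — parsing/printing of the forensic notation
  (`C16187T`, `16183C`, `315+C`, `249d`, `@`-reversions), alignment-based
  variant calling against the rCRS coordinate system with 3′-most (EMPOP
  convention) indel placement, and the standard site exclusions (309 poly-C
  variants everywhere; 16519 and 152 before network analyses).
- **Haplogroup classification** — an extensible registry tree of clade-defining
  motifs, including the Southern Cone clades D1g (16187), B2l (470),
  C1b13 (258) and D4h3a5 (16051), with a tolerance for private back
  mutations and explicit ambiguity reporting; plus in-silico PCR/RFLP for
  coding diagnostics (the 275-bp 8116/SmaI assay).
- **Median-joining networks** — weighted haplotype networks with
  quasi-median generation, ε-relaxation and exact maximum-parsimony
  post-processing (a Steiner-tree dynamic programme prunes every median and
  edge that no most-parsimonious tree uses).
- **Founder ages** — the rho statistic ρ (mean mutations from the nodal
  haplotype to each individual) with the Saillard standard error
  σ² = Σ(nₑ/n)²mₑ, converted to years under named clock calibrations
  (0.45/0.34/0.302/0.24 mutations·site⁻¹·Myr⁻¹, or 9,058 yr/mutation for the
  control-region rho clock), and exact inverse-proportional rescaling of ages
  between rates.
- **Diversity and structure** — S, Hd (Nei variance), K, π (Tajima variance),
  Tamura–Nei distances with gamma 0.26, AMOVA-based pairwise ΦST with
  permutation tests, and neighbor-joining dendrograms.
- **Classic skyline** — deterministic Nef(t) reconstruction from coalescent
  intervals (Nef = Iₖ·k(k−1)/2 per generation, generation time 25 yr).
- **Coalescent simulator** — seeded female-line coalescent with constant /
  exponential / piecewise demographies, gamma site-rate heterogeneity and
  finite-sites mutation, emitting FASTA + population tables + truth JSON so
  every stage is testable without downloads.

The packaged reference is a documented *synthetic* rCRS-like sequence
(rCRS numbering, anchored at every position the package interprets); see the
methods vignette in `vignettes/control-region-phylogeography.Rmd`.

## Worked example

Simulate a constant-size clade carrying the B2l founder motif, classify it,
build its network and date it:

```r
library(dloopr)

sc  <- make_scenario("b2l-like", n = 40, seed = 7)
asn <- classify_all(sc$motifs)
table(asn$clade)
#> B2l
#>  40

nodal <- exclude_sites(parse_motif("16183C-16189-16217-073-263-315+C-499-470"),
                       dloop_exclusions("network"))
tab <- condense(exclude_sites(sc$motifs, dloop_exclusions("network")),
                include = list(nodal))
net <- mp_postprocess(build_mj(tab))
net
#> median-joining network: 69 nodes ( 31 observed ), 90 edges ; spanning cost 1860

est <- rho_sigma(net, root = format_motif(nodal))
sprintf("rho = %.2f +/- %.2f (n = %d)", est$rho, est$sigma, est$n)
#> "rho = 35.15 +/- 4.30 (n = 40)"

make_table1(list(B2l = est))
#>   clade   rho howell   kemp endicott santos soares_cr
#> 1   B2l 35.15  76730 101554   114333 143869    318389

sc$truth$tmrca_years
#> 146682.3
```

Forty samples all classify to B2l; the network condenses them to 31 observed
haplotypes plus inferred medians; ρ = 35.15 mutations from the nodal
haplotype converts to 114,333 yr BP under the 0.302 rate — within ~20% of
this replicate's true TMRCA of 146,682 yr BP, ordinary single-genealogy
noise for the rho statistic (the test suite averages 200 replicates and
bounds the bias at 15%). The rate-based columns differ by exact inverse
proportionality; the Soares column uses 9,058 yr/mutation.

Diversity for the same sample:

```r
summary_stats(sc$motifs, group = "b2l-like")
#>      group  n   S    Hd  Hd_se    K     pi  pi_se
#> 1 b2l-like 40 134 0.973 0.0158 30.2 0.0296 0.0147
```

`run_full(run_config(...))` chains all stages (motifs → assignments →
frequency table → per-clade GraphML networks → dating table → diversity →
ΦST matrix → NJ tree) into a deterministic report directory, and
`inst/scripts/dloopr-cli.R` exposes `simulate`, `classify` and `run-all`
subcommands for shell use.

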