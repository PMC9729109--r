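# sedaDNA

Authentication, taxonomic profiling and geochronology for **sedimentary
ancient DNA** (sedaDNA) shotgun studies.

Sediments preserve short, chemically damaged DNA fragments from past
plant, animal and plankton communities. Before such reads can support
palaeoecological claims, each putative taxon must be *authenticated* —
shown to carry the postmortem damage signature of ancient molecules — and
survive abundance and replication filters; and the deposit itself needs
independent age and preservation arguments. This package implements that
whole chain as reusable, tested R functions:

- **Windowed LCA assignment** — each read's competitive alignment hits
  with identity inside an absolute window (default 95–100%) vote by
  lowest common ancestor; profiles are `SummarizedExperiment` objects
  with direct and subtree-aggregated counts per taxonomy node.
- **Damage authentication** — per node, terminal C→T (5′) and G→A (3′)
  substitution tallies are fit by a beta-binomial model with positional
  mean `f(x) = A(1−q)^(x−1) + c` against a constant-rate null.
  The fitted terminal damage `D-max = A + c` and the likelihood-ratio
  statistic `λ-LR = 2Δlogℓ` drive the decision rule
  (`D-max ≥ 0.25` and `λ-LR ≥ 1.5` by default).
- **Filter cascade** — damage authentication, strict taxon-median/2 and
  sample-median/2 abundance rules, a ≥3-replicate rule, then proportion
  normalization; every removal is logged with its triggering rule.
- **Marine reference validation** — mean read ANI, breadth-of-coverage
  ratio against the Poisson expectation `1 − e^(−depth)`, coverage
  evenness, elbow-point ANI cutoff selection, and the retention filter
  (≥500 reads, ANI ≥93%, ratios ≥0.75, damage thresholds).
- **Record comparison** — synonym harmonization and the four-way
  DNA/macrofossil/pollen overlap categories.
- **Geochronology** — DNA thermal age by Arrhenius integration
  (Ea = 127 kJ/mol, 10 °C reference, lapse-rate altitude correction),
  expected fragment length `1/(k·τ)` under depurination, and ²⁶Al/¹⁰Be
  simple burial dating `t = ln(R0_eff/R)/(λ26 − λ10)` with Monte-Carlo
  uncertainty, per-sample age PDFs, joint (product) combination and an
  endmember midpoint-of-±3σ maximum-age summary.
- **Synthetic data** — seeded generators for every input: taxonomy and
  references, damaged reads with truth tables, hit tables, isotope
  pairs and temperature histories, and a full multi-replicate cohort.

## Worked example

```r
library(sedaDNA)

# a small damaged read set against one reference species
sim <- simulateTaxonomyRefs(1, 1, 8000, seed = 1)
cfg <- simulationConfig(setNames(1, sim$speciesNodes),
                        A = 0.4, q = 0.3, c = 0.01,
                        nReads = 5000, seed = 2)
rd  <- simulateReads(sim$refs, cfg)
ht  <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy,
                        seed = 3, includeRelatives = FALSE)
asg <- assignReads(ht, sim$taxonomy, assignConfig(window = c(0, 1)))
tal <- tallyMismatches(ht, asg, rd$reads, sim$taxonomy)
fitDamage(tal, node = 1)
#> DamageFit (node 1, 5000 reads)
#>   A=0.4026 q=0.3013 c=0.00956 phi=238614145.8
#>   D-max=0.4122 lambda-LR=157.590
```

The fit recovers the injected parameters (A = 0.4, q = 0.3, c = 0.01):
`D-max` ≈ 0.41 is the damage frequency at the terminal position, and a
λ-LR of ~158 says the decaying-damage model fits far better than a
constant-rate null — this node would be authenticated. An undamaged
(contaminant) node under the same fit yields `D-max` ≈ 0.01 and λ-LR
below 1.5, and is rejected.

The full cohort pipeline, from simulation to filtered proportions:

```r
res <- runPipeline(list(seed = 42), "out/")
res$summary$n_taxa_retained   # truth species surviving the cascade
res$filter$log                # one row per removal with the rule applied
```

A thin CLI wrapper with `run-all`, `simulate`, `thermal-age` and
`burial-age` subcommands lives at `inst/scripts/sedadna.R`.

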