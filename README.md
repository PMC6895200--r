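# mycorewire

Analysis of **rewiring in plant–mycorrhizal interaction networks** across
habitat fragments. Arbuscular mycorrhizal fungi are obligate root symbionts:
a fungal OTU disappears from a community once its last plant host does. When
the same plant and fungal species are surveyed across many fragments, the
bipartite network differs between fragments partly because species turn over
and partly because the *same* co-occurring partners interact in one fragment
but not another — rewiring. `mycorewire` implements, end to end:

* **Network β-diversity partition** — for every fragment pair, the overall
  interaction dissimilarity β\_WN (Whittaker form *S*/ᾱ − 1; Sørensen
  optional) is split into a rewiring component β\_OS, measured on the
  subnetwork shared by both fragments, and a turnover component
  β\_ST = β\_WN − β\_OS. The ratio β\_ST/β\_WN is the turnover share; its
  complement is an empirical rewiring probability.
* **Host-preference classification** — a plant species is a *preferred* host
  of an OTU if it harbored it in more than half of their co-occurrences
  across fragments, with at least four co-occurrences of support; species
  that harbor without support are excluded rather than miscalled (see the
  methods vignette for why this matters).
* **Phylogenetic-constraint test** — for each (OTU, fragment) presence with
  rewired interactions, the mean cophenetic distance from the non-preferred
  harboring hosts to their closest preferred host is compared against a
  randomization null (hosts redrawn uniformly from the fragment's species
  pool minus the preferred hosts), and the per-presence differences are
  tested with a paired two-sided t-test. A negative estimate means rewired
  interactions cluster near preferred hosts on the phylogeny.
* **Extinction-cascade simulation** — sequential random host-individual
  removal per fragment under three scenarios: `noRW` (no rescue), `RWphylo`
  (rewiring restricted to the removed host's family), `RWrand` (free
  rewiring), with per-step rewiring probabilities drawn from the fitted
  1 − β\_ST/β\_WN pool. Robustness *R* is the area under the survival curve,
  and the gain statistic 100·(R\_RWphylo − R\_noRW)/(R\_RWrand − R\_noRW)
  measures how much of the free-rewiring benefit survives the constraint.
* **Synthetic community generator** — family-structured phylogenies,
  Dirichlet-sampled fragment rosters and preference-driven interactions with
  a tunable phylogenetic rewiring kernel exp(−d/τ), with ground truth
  returned for every OTU, so each stage is testable and calibratable without
  any field data.

Inputs are four plain-text files: `interactions.csv` (`otu_id`,
`individual_id`), `individuals.csv` (`individual_id`, `fragment_id`,
`species`), `taxonomy.csv` (`species`, `family`) and `phylogeny.nwk`
(Newick, branch lengths required).

## Worked example

```r
library(mycorewire)

# a study-scale synthetic community (15 fragments x 15 individuals,
# 28 species / 13 families, 161 OTUs) with known ground truth
sim <- generate_community(seed = 42)
sim$dataset
#> Plant-mycorrhizal community dataset
#>   fragments:   15
#>   individuals: 225
#>   species:     28 in 13 families
#>   fungal OTUs: 161 (detected in >= 1 fragment)
#>   presences:  994 (OTU x fragment)

beta <- partition_all(sim$dataset)
attr(beta, "mean_ratio")          # 0.831 +/- 0.009 (SE) over 105 pairs

ct <- constraint_test(sim$dataset, n_iter = 199, seed = 1)
ct
#> Phylogenetic constraint on rewired interactions
#>   paired t-test on observed - expected minimum distances
#>   n = 57 presences (0 dropped), null draws per presence = 199
#>   estimate = -55.74, t = -7.767, df = 56, p = 1.872e-10

rob <- run_scenarios(sim$dataset, beta, n_reps = 100, seed = 1)
tapply(rob$mean_R, rob$scenario, mean)
#>    noRW RWphylo  RWrand
#>   0.636   0.652   0.681
attr(rob, "gain_mean")            # 36.6 +/- 2.3 (SE) percent
```

Reading: across the 105 fragment pairs about 83% of network change is
species turnover, the rest rewiring. The generator's default kernel
(τ = 25 Myr on a 100-Myr-deep tree) makes rewired hosts close relatives of
preferred hosts, and the test recovers that: observed minimum distances are
on average 55.7 Myr smaller than the randomization null (p ≈ 2e-10).
Allowing rewiring during host loss raises mean robustness from 0.636 (noRW)
to 0.681 (free); family-constrained rewiring lands in between at 0.652,
capturing ~37% of the free-rewiring gain in this synthetic community.

The same analysis runs from a configuration instead of code —
`run_pipeline(list(seed = 42, out_dir = "out"))` writes every stage's CSV and
JSON outputs plus a reproducibility manifest, and
`inst/scripts/mycorewire.R` wraps it for shell use
(`Rscript inst/scripts/mycorewire.R all --seed 42 --out out`). With real
data, point `input_dir` at the four input files instead.

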