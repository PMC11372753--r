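# monomix

Analysis of mixed fatty-acid Langmuir monolayers at aqueous interfaces —
the films that coat sea-spray aerosol and the sea-surface microlayer. The
package is aimed at simulators and physical chemists who work with
monolayer proxies built from lauric (LA, C12), myristic (MA, C14),
palmitic (PA, C16) and stearic (SA, C18) acids and need reproducible,
tested implementations of the standard post-processing analyses:

* **Surface protonation** — Henderson–Hasselbalch with *surface* pKa
  values: acid:base ratio `r = 10^(pKa − pH)`, protonated fraction
  `f = r/(1+r)`, mole-fraction-weighted mixture percentages, and integer
  acid/base residue assignment for building simulation systems.
* **Synthetic monolayers** — periodic hexagonal headgroup lattices at a
  chosen mean molecular area (lattice constant `a = sqrt(2·MMA/√3)`), with
  tunable lateral demixing (label-swap Metropolis Monte Carlo, compiled
  kernel), vertical headgroup staggering and stochastic desorption; every
  analysis can be validated against known ground truth.
* **Aggregation networks** — 2D-periodic radial distribution functions,
  first-shell cutoff selection at the minimum between the first two g(r)
  peaks, per-species distance-cutoff neighbour graphs, mean node degree
  and pair-averaged vertex connectivity.
* **Interface structure** — vertical headgroup deviations by species ×
  protonation state, z-density profiles, geometric hydrogen-bond counting.
* **PMF reconstruction** — the weighted histogram analysis method (WHAM)
  in the log domain over umbrella windows, with an overdamped Langevin
  sampler for generating synthetic windows with known free-energy
  surfaces, plus GRO/PDB/XYZ coordinate IO and a YAML-configured
  end-to-end pipeline.

## Worked example

```r
library(monomix)

## Protonation of the 1:2:4:3 LA:MA:PA:SA marine proxy at pH 7
proxy <- mixture_composition(c("LA", "MA", "PA", "SA"), c(1, 2, 4, 3))
mixture_protonation_percent(proxy, pH = 7)
#> [1] 93.21987
protonation_report(proxy, 7, totals = c(LA = 20, MA = 40, PA = 80, SA = 60))$table
#>   species  pKa  acid_base fraction_protonated n_acid n_base
#> 1      LA 7.44   2.754229           0.7336337     15      5
#> 2      MA 7.88   7.585776           0.8835283     35      5
#> 3      PA 8.34  21.877616           0.9562892     77      3
#> 4      SA 9.89 776.247117           0.9987134     60      0
```

The proxy film is 93.2% protonated at pH 7 (the control without LA: 95.4%),
and the per-species table shows how the integer acid/base split is derived
from each surface pKa.

```r
## A binary film: random mixing vs. demixing
mix <- mixture_composition(c("LA", "PA"), c(1, 1))
fr  <- build_hexagonal_monolayer(1024, 20, mix, seed = 1, assignment = "exact")
mean_node_degree(build_same_type_graph(fr, "LA", cutoff = 7.2))
#> [1] 2.988281
dem <- demix_labels(fr, J = 2, n_sweeps = 2000, seed = 2)
mean_node_degree(build_same_type_graph(dem, "LA", cutoff = 7.2))
#> [1] 5.664062
```

On the hexagonal lattice every molecule has 6 neighbours, so a randomly
mixed equimolar film has a same-type degree near 3; same-type affinity
J = 2 kT drives domain formation and pushes it toward 6.

```r
## WHAM recovery of a known harmonic free-energy surface
w <- langevin_windows(make_potential("harmonic", kappa = 2),
                      centers = seq(-3, 3, 0.5), k = 10,
                      n_steps = 60000, dt = 0.005, seed = 11)
pmf <- wham(w, grid = c(-3.2, 3.2, 64))
pmf
#> PMF profile: 64 bins on [-3.15, 3.15] Å, 64 defined; converged after 269 iterations (residual 9.83e-07)
delta_g(pmf, c(-0.1, 0.1), c(1.9, 2.1))
#>       kT   kJ_mol
#> 3.893118 9.650872
```

The recovered free-energy difference between x ≈ 0 and x ≈ 2 Å is close to
the analytic ½·κ·x² = 4 kT.

The packaged demo pipeline chains every stage (generation → RDF → graphs →
structure → WHAM) in a few seconds:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "monomix"),
             output_dir = "demo_out")
```

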