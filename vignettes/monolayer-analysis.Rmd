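---
title: "Models and methods in monomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in monomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monomix)
```

monomix analyses mixed fatty-acid Langmuir monolayers of the kind used as
laboratory proxies for the organic films that coat sea-spray aerosol and the
sea-surface microlayer: medium-chain lauric acid (LA, C12) mixed with the
long-chain myristic (MA, C14), palmitic (PA, C16) and stearic (SA, C18)
acids. The package covers four connected analyses — surface protonation
modelling, graph-network quantification of lateral aggregation, vertical
headgroup structure, and umbrella-sampling free-energy reconstruction —
together with a synthetic monolayer generator that produces test
configurations with known ground truth, so every analysis can be validated
without running molecular dynamics.

## Surface protonation model

A carboxylic headgroup at the air–water interface dissociates with an
effective *surface* pKa well above its bulk value; the packaged defaults are
LA 7.44, MA 7.88, PA 8.34, SA 9.89. The protonated:deprotonated population
ratio at subphase pH follows Henderson–Hasselbalch,

$$ r = 10^{\,\mathrm{p}K_a - \mathrm{pH}}, \qquad
   f_\mathrm{prot} = \frac{r}{1+r}, $$

and a mixture's overall protonation percentage is the mole-fraction-weighted
mean of the per-species fractions. For the marine proxy composition 1:2:4:3
LA:MA:PA:SA this gives 93.2% at pH 7, versus 95.4% for the 2:4:3 MA:PA:SA
control; at seawater pH 8.2 the pair is 60.6% and 65.6% (60% and 65% under
floor rounding, which is how such figures are usually quoted).

```{r}
proxy <- mixture_composition(c("LA", "MA", "PA", "SA"), c(1, 2, 4, 3))
mixture_protonation_percent(proxy, pH = 7)
acid_base_ratio(7.44, 5.6)   # lauric acid near microcosm pH: ~69:1
```

Two conventions deserve explanation. First, experimental work at pH 5.6 is
conventionally modelled at pH 7 fractions: at the scale of a simulated
monolayer (~100 molecules per species) the pH 5.6 ratios (69:1 and up) and
the pH 2 limit are indistinguishable — both round to "all protonated" — so
pH 7 serves as an intermediate protonation state between fully protonated
(pH 2) and substantially deprotonated (pH 8.2). The package keeps pH as a
free parameter and leaves this mapping to the caller. Second, converting
fractions to integer residue counts admits several defensible rounding
rules, and published residue tables do not follow any single one (counts
were adjusted per system geometry). `assign_residue_counts()` therefore
defaults to deterministic nearest-integer rounding (half away from zero),
and ships the published splits as an override table
(`reference_residue_counts()`) rather than pretending a rule reproduces
them.

## Synthetic monolayers

Condensed fatty-acid films pack hexagonally. `build_hexagonal_monolayer()`
places $n$ headgroup sites on a triangular lattice with constant
$a = \sqrt{2\,\mathrm{MMA}/\sqrt{3}}$ — 4.81 Å at the untilted-condensed
mean molecular area of 20 Å²/molecule, 5.15 Å at 23 Å² — embedded in a
rectangular periodic cell (rows $\sqrt{3}a/2$ apart, alternate rows offset
$a/2$; the row count must be even for the offset pattern to wrap). The
rectangular embedding was chosen over a rhombic cell because it keeps the
minimum-image arithmetic trivial; the price is a mild restriction on which
$n$ tile. Tilted-condensed films differ from untilted ones only in tail
orientation, which the single-site headgroup model does not represent; all
in-scope analyses depend on headgroup positions alone.

Ground-truth structure is then layered on:

* `demix_labels()` drives lateral phase separation by label-swap Metropolis
  Monte Carlo with energy $-J$ (in kT) per same-species neighbour pair.
  Swap dynamics conserve species counts exactly; $J = 0$ leaves every
  labelling equally likely, while $J \gtrsim 1.5$ produces connected
  same-species domains. The kernel is compiled (Rcpp) so the $10^4$-sweep
  runs used in validation take seconds.
* `apply_staggering()` offsets each headgroup's $z$ by a (species,
  protonation)-specific amount plus Gaussian jitter, emulating the vertical
  staggering that maximizes tail–tail dispersion contact: deprotonated and
  longer-chain headgroups sit toward the water.
* `desorb()` flags molecules as expelled from the interface. Flags rather
  than row deletion preserve molecular identity across frames, mirroring
  molecules that leave and rejoin the film; every analysis skips absent
  molecules.

All randomness flows from one explicit seed per operation, and the
caller's RNG state is restored afterwards. What the generator does *not*
emulate matters for interpreting green tests: there is no energetic
realism — no force field, water, ions, tails, or correlated dynamics — so
passing tests demonstrate that the *analyses* are correct on configurations
with known structure, not that any physical prediction is reproduced.

## Aggregation networks

`compute_rdf()` estimates the lateral pair correlation $g(r)$ with
minimum-image distances in the monolayer plane and the standard 2D
normalization (annulus area $2\pi r\,\mathrm{d}r$ times partner density),
averaging frames and leaflets; bins default to 0.1 Å. `select_cutoff()`
takes the neighbour cutoff at the $g(r)$ minimum between the first two
peaks, after a centred 5-bin moving average; peaks must clear an explicit
prominence threshold (default 0.1), plateaus collapse to their centre bin,
and a flat valley returns its midpoint. Profiles with fewer than two peaks
raise a typed condition instead of guessing. Condensed-film studies using
this convention land near 7.2 Å (high pressure) and 7.4 Å (low pressure),
packaged as `reference_cutoffs()`.

`build_same_type_graph()` joins present molecules of one species whose
periodic xy distance is within the cutoff, per leaflet. Distances
deliberately ignore $z$: lateral aggregation is the quantity of interest,
and staggered headgroup heights would otherwise distort neighbour shells.
Neighbour search uses a cell list (cell size = cutoff) for linear scaling,
with an all-pairs brute-force path retained as the test oracle.

Two per-species metrics summarize cohesion. Mean node degree is the average
edge count per node: exactly 6 on a pure film, about 3 for a random
equimolar binary labelling (the exact expectation is
$6(n/2-1)/(n-1)$), above 3 for a species that self-aggregates. "Mean
connectivity" in the aggregation literature is described verbally as the
number of edges that must be removed to disconnect a node from the network
— a reading that, taken per node, just reproduces the degree. monomix
therefore exposes both interpretations and defaults to the discriminating
one: the average over all unordered node pairs of the local vertex
connectivity (maximum number of internally vertex-disjoint paths, computed
by max-flow, adjacent pairs handled by removing the direct edge and adding
one), with pairs in different components contributing zero. This measure
collapses toward zero as a network fragments — the behaviour that makes
desorption visible — and equals $n-1$ on a complete graph. The per-node
edge-cut reading is available as `method = "min_node_cut"`.

```{r}
mix <- mixture_composition(c("LA", "PA"), c(1, 1))
fr <- build_hexagonal_monolayer(144, 20, mix, seed = 1, assignment = "exact")
g <- build_same_type_graph(fr, "PA", cutoff = 7.2)
c(degree = mean_node_degree(g), connectivity = mean_connectivity(g))
```

The pairwise metric costs one max-flow per node pair; at the few hundred
molecules per species typical of monolayer simulations this is seconds per
frame, which is why `metrics_over_trajectory()` lets it be switched off.

## Interface structure

`vertical_deviations()` measures each headgroup's $z$ against the mean
headgroup height of its own leaflet in its own frame — a per-frame,
per-leaflet reference, so slow drift of the whole film cannot masquerade as
staggering. Signs are oriented so negative deviations point toward the
aqueous phase on either leaflet ("more hydrated"). `density_profile()`
gives the complementary frame-averaged $z$ histograms, normalized so the
profile integrates to the mean molecule count.

Hydrogen bonds are counted from explicit donor–H–acceptor triples with a
geometric criterion: donor–acceptor distance ≤ 3.5 Å and donor–H–acceptor
angle ≥ 150° by default — a standard choice for carboxyl/water systems,
and fully user-overridable since no single criterion is canonical. Counts
are tallied per interaction class (same-species head–head, cross-species,
head–water).

## Umbrella sampling and WHAM

`wham()` reconstructs a 1D free-energy profile from biased windows by
fixed-point iteration of the standard WHAM equations,

$$ P(x_b) \propto \frac{\sum_i h_i(x_b)}{\sum_i n_i\,
     e^{-\beta(U_i(x_b) - f_i)}}, \qquad
   e^{-\beta f_i} = \sum_b P(x_b)\, e^{-\beta U_i(x_b)}, $$

with $U_i(x) = \tfrac{1}{2}k_i(x - x_{0,i})^2$. All accumulation is done in
the log domain (log-sum-exp), so the force constants used in practice for
interfacial extraction — up to hundreds of kJ mol⁻¹ nm⁻² — cannot
underflow. Numerical choices are deliberately plain and reproducible:
$f_i = 0$ initialization, Jacobi (simultaneous) updates, convergence at
$\max_i|\Delta f_i| < 10^{-6}$ kT, iteration cap $10^5$. Bins never visited
by any window stay `NA` — masking, never interpolation — and windows whose
histograms share no bins with any other window are flagged, since their
relative free energies are then set only by exponentially small tails.
Internally energies are in kT at 298.15 K; window files on disk use the
GROMACS conventions (kJ/mol, nm-referenced force constants) with exact
conversion.

Validation uses `langevin_windows()`, an overdamped Euler–Maruyama sampler
whose stationary distribution under potential-plus-bias is known exactly.
A harmonic surface ($\kappa = 2$ kT/Å², 13 windows, $k = 10$ kT/Å²,
$6\times10^4$ steps at $\mathrm{d}t = 0.005$) is recovered with RMSE below
0.1 kT on $[-2, 2]$ Å, and a double well $a(x^2-b^2)^2$ ($a = 0.5$,
$b = 1.5$; barrier $ab^4 = 2.53$ kT) has its barrier recovered within 5%
at $10^5$ steps per window. The sampler refuses time steps with
$\mathrm{d}t\,k/\gamma \ge 0.1$ (harmonic Euler stability) and reports
divergence explicitly. Steered-MD pulling and adaptive-bias samplers are
out of scope: only the downstream histogram-to-PMF mathematics is
implemented, so the absolute extraction free energies of real systems,
which require all-atom sampling, are deliberately not targets.

`delta_g()` reads differences off the profile using the mean (default) or
minimum of $G$ over each coordinate region; the mean was chosen because a
region minimum is biased low under statistical noise.

## The demo pipeline and problem sizes

`run_pipeline()` chains the stages from a versioned YAML config (unknown
keys are rejected outright) and archives every seed and parameter in the
run log; a re-run of the same config reproduces the summary byte-for-byte.
The packaged demo (`demo_config.yaml`) uses a 144-site binary film, five
frames, 13 umbrella windows of 4000 steps — sizes chosen so the full chain,
including the pairwise-connectivity metric, completes in a few seconds,
while the validation suite's larger runs (1024-site lattices over 50 seeds,
$10^5$-step windows) still finish in well under a minute each.

## Known limitations

* The generator's frames are static snapshots with optional i.i.d. jitter;
  there are no correlated dynamics, so time-correlation analyses are out of
  scope.
* Pairwise mean connectivity is $O(n^2)$ max-flow calls and becomes slow
  beyond a few thousand nodes per species; use the degree metric or
  `connectivity = FALSE` for large trajectories.
* The WHAM implementation is 1D, matching the single reaction coordinate of
  interfacial extraction; no 2D umbrella support.
* Binary trajectory formats (XTC/DCD) are not read natively; convert to
  GRO/PDB/XYZ, or ingest via an external trajectory reader into
  `monolayer_frame()` objects.
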