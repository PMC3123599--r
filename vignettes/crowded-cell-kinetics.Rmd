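---
title: "Reaction-diffusion kinetics in a crowded virtual cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-diffusion kinetics in a crowded virtual cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crowdcell` is an agent-based Brownian-dynamics simulator for reactions
inside a structured, crowded cell. This vignette explains the model, the
numerical choices behind it, what the synthetic geometry does and does not
emulate, and the design decisions taken where more than one reasonable
implementation exists.

## The model

### Geometry

The cell is a sphere (default diameter 7 µm) filled with two kinds of
immobile obstacles: cytoskeleton filaments, modelled as randomly oriented
cylinders (default 25,000 before calibration, 2.5 µm long, 35 nm diameter,
capsule distance test), and inert crowding spheres (default 100,000 before
calibration, 60 nm diameter), standing in for ribosome-scale particles.
Obstacle centres are uniform in the cell ball, orientations uniform on the
sphere; obstacles may overlap each other and may protrude through the
membrane. Only the in-cell portion matters, because every accessibility test
also enforces membrane containment.

A position is *accessible* to a molecule of radius $r$ when the sphere of
radius $r$ centred there lies inside the membrane and overlaps no obstacle.
Excluded volume fractions $\epsilon$ are measured by Monte-Carlo sampling
(uniform points in the cell ball, binomial standard errors). The *membrane
is containment, not crowding*: an empty cell reports $\epsilon = 0$ for any
probe.

**Calibration.** With the nominal counts the obstacles would occupy more
volume than the experimentally motivated 24%, because overlap and
protrusion interact with the (unpublished) placement convention. The
generator therefore exposes a single obstacle-count multiplier, fixed once
so that the excluded fraction for 2.5 nm tracers is $\epsilon = 0.305$, the
simulator's stated operating point. The packaged value (0.791) also lands
the bare obstacle occupancy at 24%. Because the 2.5 µm filaments protrude
more strongly from smaller cells, reduced-scale geometries are re-calibrated
at run time to the same operating point
(`calibrate_density_multiplier()`).

### Diffusion

Each mobile molecule performs a Gaussian random walk: per step $\Delta t$,
each coordinate receives an increment of zero mean and variance
$2 D_0 \Delta t$. A proposed step ending at an inaccessible position is
rejected wholesale - the molecule waits for the next step. This whole-step
rejection (rather than partial reflection) is the standard obstructed-walk
scheme; it converges to continuum obstructed diffusion as the rms step
length becomes small against the obstacle radii. With the default tracer
step of $\sqrt{6 D_0 \Delta t} \approx 2.7$ nm against the 17.5 nm filament
radius, the measured long-time mobility changes by less than the sampling
spread when the step is halved again.

The mean squared displacement of tracers in the crowded cell shows the
expected transient anomalous diffusion: short-lag slopes recover $D_0$,
long-lag slopes a reduced $D_{\mathrm{eff}}$. `estimate_Deff()` reports
either a window slope or the secant estimate $\langle r^2\rangle / (6t)$
averaged over a lag window; the secant form is preferred for the long-time
coefficient because it is insensitive to the residual curvature where the
crossover tail meets cell-scale confinement. The packaged analysis windows
(lags 4-14 ms for the full-size cell) correspond to displacements of a few
obstacle spacings - past the crossover - but well below the cell radius. In
the calibrated default cell this gives $D_{\mathrm{eff}}/D_0 \approx 0.76
\pm 0.01$, consistent with the published $0.77 \pm 0.01$ for this crowding
level. A fixed multiple-of-spacing window rule was considered and rejected:
at 10 obstacle spacings the displacement already feels the membrane, so the
window is instead pinned between the crossover and the confinement scale.

### Bimolecular reactions

The simulator reproduces macroscopic mass-action kinetics from pairwise
rules. For a channel with macroscopic rate constant $k$ between species of
radii $r_i, r_j$ and diffusion coefficients $D_i, D_j$:

* the diffusion limit is the collision rate constant
  $k_D = 4\pi (r_i + r_j)(D_i + D_j)$;
* the microscopic (per-collision) rate constant is
  $k_{\mathrm{micro}} = k\,k_D / (k_D - k)$, so that
  $k = k_{\mathrm{micro}} k_D / (k_{\mathrm{micro}} + k_D)$;
* two partners closer than the physical collision radius
  $R_{\mathrm{crit}} = r_i + r_j$ react, per step, with probability
  $P = k_{\mathrm{micro}} \Delta t / \left(\tfrac{4}{3}\pi
  R_{\mathrm{crit}}^3\right)$.

Using the *collision* radius with a *probability* keeps the physical
interaction surface (hence the correct diffusive flux) while scaling the
reaction volume to $k_{\mathrm{micro}}\Delta t$; the alternative of a
rate-derived radius with probability one (also provided, as
`pogson_reaction_radius()`) distorts the collision surface and fails for
diffusion-limited channels. Candidate pairs are found with spatial hashing,
visited in uniformly random order, and a molecule is consumed by at most one
reaction per step; catalytic educts (appearing on both reaction sides) are
left untouched. Products appear at the position of the first consumed educt.
Immobile catalytic species whose population never changes (fixed enzymes)
are indexed once in a static lookup grid; they may serve several partners in
one step, since the single-use rule exists to protect *consumed* reactants
from double booking.

Timestep selection (`auto_dt()`) imposes $P \le 0.1$ and, where the channel
is appreciably diffusion limited ($\beta = k/k_D \ge 0.1$), an rms step no
larger than $R_{\mathrm{crit}}$, so that the depletion zone around reactants
is resolved. Under these rules the measured bulk rate is invariant under
halving $\Delta t$ within sampling error and converges to $k$ from below as
$\Delta t \to 0$ (residual discretization is a few percent at the default
settings for $\beta = 0.3$).

### Other channels

* **Zero-order creation**: Poisson events at $k_1 V_{\mathrm{cell}}
  N_A/10^{15}$ per second, placed uniformly over the accessible volume
  (rejection sampling). Concentrations are defined per total cell volume;
  crowding then raises effective concentrations, which is exactly the
  $f_{\mathrm{vol}}$ effect below.
* **Unimolecular conversion**: per-step probability $k\,\Delta t$ (a
  warning is issued beyond 0.1, where first-order discretization bias
  appears).
* **Adsorption**: structures are impenetrable, so their reaction volume is
  a layer of height $\kappa\,\Delta t$ over the surface with reaction
  probability 1; a molecule whose surface comes within the layer is
  immobilized in place (species unchanged). The intrinsic surface velocity
  $\kappa$ (µm/s) relates to a bulk first-order binding rate by $k_b =
  \kappa A / V_{\mathrm{acc}}$; `kappa_from_kbind()` inverts this with
  Monte-Carlo estimates of the accessible contact area $A$ and volume. The
  flat-layer approximation requires $\kappa\,\Delta t \ll
  r_{\mathrm{structure}}$, which is enforced.
* **Dissociation**: bound molecules release with probability
  $k_{\mathrm{diss}}\Delta t$. At steady state the unbound fraction obeys
  detailed balance, $f_u = k_{\mathrm{diss}} / (k_{\mathrm{diss}} +
  k_b)$, and the ensemble mobility scales as $D_{\mathrm{eff}}(f_u) =
  f_u \, D_{\mathrm{eff}}(1)$.
* **Membrane transport**: influx places molecules uniformly in an
  accessible shell against the membrane; export removes molecules entering
  a capture layer of height $\kappa_{\mathrm{exp}}\Delta t$ at the
  membrane. The default $\kappa_{\mathrm{exp}}$ makes the layer one rms
  step high, so export is limited by diffusion towards the membrane and the
  late-time escape rate matches the first-passage eigenvalue $\pi^2 D /
  R^2$ of an absorbing sphere.

The step order is fixed: diffusion, adsorption/dissociation, bimolecular,
unimolecular, zero-order, influx, export, observation. Observation is
passive (consumes no randomness), so changing the observation interval does
not change the dynamics; runs are bit-reproducible for a fixed seed.

## The in-vivo correction calculus

For a bimolecular channel measured in vitro with rate constant $k$, the
crowded cell modifies the effective macroscopic rate by three factors:

$$f_{\mathrm{vol}} = \frac{1}{1-\epsilon}, \qquad
  f_{\mathrm{diff}} = \frac{\delta}{\beta + \delta(1-\beta)}, \qquad
  f_{\mathrm{access}} \;\; (\text{Monte-Carlo}),$$

with $\epsilon$ the excluded volume fraction, $\delta =
D_{\mathrm{eff}}/D_0$, $\beta = k / k_D$, and $f_{\mathrm{access}}$ the mean
accessible fraction of the pairwise interaction ball, sampled over molecule
positions (`sample_access_factor()`). $f_{\mathrm{diff}}$ is the exact
consequence of holding $k_{\mathrm{micro}}$ fixed while the collision rate
scales with $\delta$. Their product $f_{\mathrm{eff}}$ converts in-vitro to
in-vivo kinetics: the steady state of the source/consumption test model
shifts from $c_S = k_1/(k_2 c_E)$ to $c_S = k_1/(f_{\mathrm{eff}} k_2
c_E)$.

$\delta$ is an explicit argument rather than being hard-wired to the
long-time $D_{\mathrm{eff}}$, because the simulations themselves show the
reaction senses an *intermediary* effective diffusion - slower than $D_0$
but faster than the long-time coefficient: in the detailed crowded cell at
$\beta = 0.3$ the simulated steady state undershoots the long-time-$\delta$
prediction (the reaction runs hotter), while an obstacle-free "homogenized"
cell - volume scaled by $1-\epsilon$, mobility set to $\delta D_0$,
$k_{\mathrm{micro}}$ derived from the in-vitro $D_0$
(`homogenized_cell_config()`) - matches the prediction. At the package's
reduced test scale the ratios are $\approx 0.94$ (detailed) versus
$\approx 1.00$ (homogenized).

## Preset experiments and the scales they run at

The presets reproduce the standard experiments at sizes a desktop run can
afford; all headline numbers quoted here are recomputed by the test suite
and the acceptance script, not stored.

* **Test model** (`preset_in_vitro()`, `preset_in_vivo()`): substrate
  created at $k_1$, consumed by $S + E \to E$ (the inert product is not
  instantiated); enzymes 2.5 nm, $D = 1\ \mu\mathrm{m}^2$/s, $c_E = 2\times
  10^{-7}$ mol/L. The published enzyme count (20,600) fixes the volume
  convention ($V \approx 171\ \mu\mathrm{m}^3$, slightly below the nominal
  7 µm sphere; the count, not the nominal diameter, is taken as
  authoritative because it reproduces the printed steady states).
  `volume_scale` shrinks the cell at identical concentrations; the
  acceptance suite uses 1/10 of the full volume for the well-mixed
  equivalence check and a 0.7 µm-radius re-calibrated crowded cell for the
  in-vivo shift. The published $(k_1, k_2)$ pairs are rounded to three
  significant digits, so the three $\beta$ presets predict steady states
  agreeing only to about half a percent.
* **Transient binding** (`preset_binding()`): inert tracers with
  adsorption/dissociation tuned via the bulk-rate conversion to a target
  unbound fraction; all tracers start unbound and $f_u(t)$ relaxes at rate
  $k_b + k_{\mathrm{diss}}$.
* **Metabolic channeling** (`preset_channeling()`): influx of metabolite 2
  across the membrane, three immobilized enzyme stages converting
  metabolites 2 through 5 at $k = 3.78\times10^6$ L/(mol s), and
  diffusion-controlled export of metabolite 5. The pathway is described as
  four reactions with the final species indexed "metabolite 5", so the
  default chain is influx + three conversions + export with metabolites
  numbered 2-5 (metabolite 1 being the extracellular substrate). Layouts:
  ordered enzyme complexes in the membrane shell ("channel"), uniform
  membrane shell ("layer"), uniform volume ("random"), and a Gillespie
  well-mixed reference with identical totals ("wellmixed", export as the
  equivalent first-order rate $3\kappa_{\mathrm{exp}}/R$ - the same capture
  mechanism applied to a perfectly mixed population).

  Two channeling design points deserve emphasis. First, the "channel" is
  built as assembly-line complexes - each stage's enzyme a few collision
  radii from the previous stage's - rather than as three large ordered
  membrane segments: with segments, intermediates must diffuse between
  distant caps and the layout is *slower* than the unordered layer,
  contradicting its purpose. Second, the scaled defaults (cell radius
  1.75 µm, 3,600 enzymes per stage, influx 1,000/s, 1.5 s) put the enzyme
  surface density where membrane capture per pass is order one while the
  volume pathway remains cascade-limited; at lower densities the layout
  orderings exist but drown in Poisson noise at tractable run lengths.
  The exact published parameters for this experiment are not available, so
  the comparison is qualitative by construction: orderings and their
  compression at higher metabolite diffusivity, not curve-level numbers.

## Numerical choices and degenerate inputs

* Seeds: every sampler and run takes an explicit seed; a fixed seed
  reproduces results bit-exactly. Monte-Carlo standard errors are binomial
  (volume fractions) or across-centre (accessibility factor).
* The spatial index is a uniform grid with a conservative insertion margin;
  queries are exact for probes up to the margin (10 nm by default) and fall
  back to a full scan beyond it. Index and brute force agree exactly, by
  construction and by test.
* Steady-state averages use block means (8 blocks by default) so the
  standard error accounts for autocorrelation within the window.
* Degenerate inputs are rejected up front: rates above the diffusion limit,
  per-pair probabilities above one (with the maximal admissible $\Delta t$
  reported), adsorption layers thicker than the thinnest obstacle, empty
  averaging windows, recorded species participating in count-changing
  reactions, and geometries so dense that accessible-position sampling
  saturates.

## Known limitations

* Mobile molecules do not exclude volume against each other; only
  obstacles and the membrane reject steps. This is the intended dilute
  regime and fails at high copy numbers.
* The obstacle geometry is a random, isotropic stand-in: no filament
  branching, bundling, persistence length, or cortical anisotropy, and no
  moving or growing structures. Passing tests show the method's internal
  consistency at a matched excluded-volume operating point, not fidelity to
  any particular cell type's microstructure; in particular the long-time
  $D_{\mathrm{eff}}/D_0$ depends on microstructure beyond $\epsilon$, and
  slope-based estimates at long lags dip a few percent below the secant
  estimate because of the finite cell.
* The distance-resolved reaction-probability scheme (Fokker-Planck pair
  propagator with a lookup table) is intentionally not implemented; the
  collision-radius scheme is validated against its own small-$\Delta t$
  limit instead.
* Reversible binding uses independent adsorption/dissociation rules;
  diffusion-limited rebinding correlations are therefore only approximate,
  and targets for $f_u$ are reached approximately (the conversion helper
  hits them to within a few percent in the default geometry).
* Michaelis-Menten stage kinetics and directed hand-off inside enzyme
  complexes are out of scope for the channeling model.
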