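---
title: "Model and methods: a biophysical cone-pathway network in health and degeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

retisim simulates a parafoveal patch of the cone pathway — cone
photoreceptors (PR), horizontal cells (HRZ), ON/OFF bipolar cells (BP),
wide- and narrow-field amacrine cells (AMA), and ON/OFF retinal ganglion
cells (RGC) — as a conductance-based network that responds to both light
and extracellular electrical stimulation, and applies staged
retinal-degeneration transforms to it.  This vignette explains the model,
its numerical treatment, the calibrations the package performs, and the
limits of what the simulations show.

## Geometry

Each cell type occupies a triangular ("hexagonal") lattice with basis
vectors $(1,\sqrt3)\lambda$ and $(1,-\sqrt3)\lambda$, i.e.
nearest-neighbour spacing $2\lambda$, with the type-specific $\lambda$
between 2.5 µm (cones) and 8 µm (wide-field amacrines).  Somas are
spheres (26 µm for RGCs, 7 µm otherwise) scattered uniformly in
type-specific depth bands; $z$ runs from the vitreal surface (RGC layer,
25–39 µm) to the photoreceptors (170–205 µm), so the epiretinal electrode
sits at $z=-2$ µm and the subretinal one at $z=+135$ µm.

**Boundary rule.**  An ideal rectangular crop of a centered lattice can
only produce cell counts in coarse jumps (whole boundary rows or columns
enter at once), and no single crop margin reproduces the reference
per-type census of the 300 µm patch (e.g. 4,149 cones; two wide-field
amacrine mosaics of 390 and 389 cells at identical $\lambda$).  The
package therefore uses a quota rule: lattice nodes are ranked by how far
they overhang the patch rectangle (ties broken by $y$, then $x$) and
admitted up to a per-type target count — the census for the default
patch, scaled by patch area otherwise.  Admitted nodes overhang the
boundary by at most about $\lambda/2$ (≤ 2 µm in practice).  This is a
reconstruction: the original boundary convention is not derivable from
the census alone.

## Membranes

HRZ/BP/AMA cells are leaky integrators,
$C_m \dot v = -G_m (v - E_\mathrm{rest}) + \sum i_\mathrm{syn} + i_e$.
Cones carry an additional light-gated conductance
$g_\mathrm{light} = G_\mathrm{light}\,(1 - l(t))$ with reversal $-8$ mV:
the conductance is open in darkness (depolarizing) and closes with
light, so light hyperpolarizes the cone.  `run_simulation(light = NULL)`
means this conductance is shut, as under saturating light.

RGCs are single-compartment Hodgkin–Huxley somas with seven voltage- or
ligand-gated channels (Na, Ca, delayed-rectifier K, inactivating A-type
K, Ca-activated K, hyperpolarization-activated cation current
$I_h$, low-threshold T-type Ca) plus leak; densities (mS cm⁻²) are
referred to the soma surface $A = \pi d^2$.  The Ca reversal follows the
Nernst relation from an internal calcium pool
($\tau = 50$ ms, resting level $10^{-4}$ mM, influx from the Ca and CaT
channels; the KCa gate activates with dissociation constant $10^{-3}$ mM
as $(\mathrm{Ca}/K_d)^2/(1+(\mathrm{Ca}/K_d)^2)$).

**Gating kinetics.**  The source formulation of the rate functions for
these channels is not part of the published parameter set, so the
package ships its own documented rate-table component
(`rgc_rate_functions()`), chosen by an explicit numerical search with
four requirements at the published densities: no stable depolarization
block up to 250 pA injected; monotone F–I curves; full-height spikes
(crossing well above the −10 mV detection level); and tonic firing near
rheobase for both classes.  The Ca, delayed-rectifier K and A-current
activation follow the classic amphibian RGC five-channel forms; $I_h$
uses thalamic-relay-style kinetics; Na activation/inactivation are
sigmoid-rate pairs (midpoints −35/−50 mV) with a deliberately small
steady-state window, and the A-current inactivation retains a floor of
0.2 — the residual A-current is what prevents plateau ("depolarization
block") states at the very large ON-cell Na density.  The T-type channel
uses a two-state inactivation pair ($h_T$, $d_T$) whose kinetics keep
$h_T + d_T \le 1$ invariant.  All rates are tabulated on a 0.05 mV grid
and linearly interpolated by the engine; alternative kinetics can be
swapped in by replacing the component.

**Leak calibration.**  The RGC leak conductance is, by the model's own
definition, a tuned quantity: it is set so that the healthy network
fires spontaneously at about 2 Hz under uniform 0.5 light.  With the
package kinetics this requires one multiplier per RGC class
(`RGC_LEAK_SCALE`, ON 1.895 / OFF 0.645 on the printed per-class leak
densities); a single shared multiplier cannot bring both classes to
2 Hz.  The calibration was performed once on the full 300 µm patch and
is frozen; it is deliberately *not* revisited per experiment.

## Circuitry

Twelve typed projections connect the mosaics (cone→HRZ feedback loop,
cone→ON/OFF bipolar, bipolar→amacrine, bipolar→RGC, amacrine→RGC, and a
narrow-field ON-amacrine→OFF-RGC crossover).  Transmission is graded: the
presynaptic conductance is a sigmoid of the presynaptic voltage delayed
by the projection's $\tau$ (5–13 ms), bounded in $[G_\min, G_\max]$, and
sign-inverting ("D") only at the cone→ON-bipolar synapse.  A
postsynaptic cell pools presynaptic conductances with weights
$\propto e^{-D/\sigma}$ over lateral distance $D$, normalized to sum to
one over the pool, with a connection cutoff at $3\sigma$.  Lateral
(2-D) distance is used: depths within a band are random filler and the
$\sigma$ values match lateral receptive-field scales.

**Cell death and the pooling normalizer.**  When cells die, the package
keeps the healthy normalizer: a dead presynaptic cell simply contributes
zero conductance, so a postsynaptic cell's drive shrinks in proportion
to the killed weight (`prune_connectome(renormalize = FALSE)`).  The
alternative reading — renormalizing over survivors — makes cell death a
no-op for pooled drive in expectation, which leaves outer-segment
truncation as the only active mechanism and inverts the degeneration
phenomenology (ON rates then rise while OFF cells fall silent).  The
fixed normalizer is the reading consistent with the reference findings:
progressive loss of pooled excitation silences ON cells, and the fading
narrow-field ON-amacrine pathway disinhibits OFF cells, producing OFF
hyperactivity.  Both readings are implemented; the fixed normalizer is
the default.

## Degeneration transforms

Phase I/II is parameterized by $s \in [0,1]$: a nested random subset of
$\mathrm{round}(s N)$ cones is removed and the survivors'
$G_\mathrm{light}$ ceiling is scaled by $(1-s)$ (outer-segment
truncation).  The end of Phase I/II removes all cones and horizontal
cells.  Phase III ($t \in [0,1]$) removes bipolar and amacrine cells down
to fraction $(1-t)$ and migrates a fraction $0.5\,t$ of the surviving
bipolar, amacrine and RGC populations to their destination layers
(amacrines in thirds to the horizontal-cell, inner-plexiform and
ganglion-cell layers; bipolars in halves to the latter two; RGCs to the
horizontal-cell layer), redrawing only $z$; $x$, $y$, synaptic weights
and delays never change.  Nestedness is exact: every cell carries fixed
per-identity uniform draws (derived from the seed), and stage transforms
threshold the same draws, so the survivor set at a later stage is a
subset of any earlier one and removed counts are exactly
$\mathrm{round}(\cdot)$.  Migration applies to survivors.  Disease time
$u \in [0,2]$ maps linearly onto the two phases
(`progression_schedule()`).

## Stimulation

Light fields are rasterized onto the cones as piecewise-constant
segments (uniform fields, disks/annuli with onset, square-wave-modulated
disks, and the spatially filtered Gaussian "cloud" noise used for
receptive-field mapping; cloud frames are rescaled to the nominal
contrast after filtering, then clipped to $[0,1]$).

The disk electrode produces the classical equipotential-disk field
$v_e = \tfrac{2V_0}{\pi} \arcsin\!\big(2a/(\sqrt{(r-a)^2+d^2} +
\sqrt{(r+a)^2+d^2})\big)$ with $a$ the disk *radius* (40 µm for the
80 µm electrode).  A soma couples to the field through
$i_e = \tfrac12 G_\mathrm{ext} \langle |\Delta v_e| \rangle$, the
average absolute potential difference over 500 seeded antipodal point
pairs on the soma sphere; the absolute value destroys polarity, so the
magnitude is signed by the instantaneous sign of $V_0(t)$ — cathodic and
anodic phases drive opposite currents.  Pulse amplitudes are given in
µA and converted to the disk potential with a single access-resistivity
constant (`V0_PER_UA`, 400 mV µA⁻¹), chosen once so that a 60 µA
epiretinal train is suprathreshold for healthy RGCs under the electrode;
every reported threshold is *relative* (percent of healthy), which
cancels this constant exactly.

Activation thresholds use the criterion: smallest amplitude that evokes
a stimulus-locked spike (within 10 ms of a pulse onset) on at least half
of the repeated trials, which differ only in their initial-voltage
seeds.  The stimulus-locked window is needed because spontaneously
active cells would otherwise satisfy a naive any-spike criterion at
amplitude zero even in the healthy network; under this definition
strongly hyperactive OFF cells still reach threshold 0, as expected.
Cells never responding at the largest tested amplitude are excluded from
the population mean and counted separately.

## Numerics

The engine advances voltages and gates with exponential (Rush–Larsen)
updates for RGCs and forward Euler for the graded cells, at
$\Delta t = 0.025$ ms.  Forward Euler would be unstable for the RGC
equations (the Na conductance at spike peak puts the local membrane
time constant near 2 µs); the exponential update is unconditionally
stable and, for the graded cells' linear RC dynamics, forward Euler at
this step tracks the closed-form relaxation to well under 0.1 %.
Graded synaptic pooling and the delay buffers are refreshed on a coarser
synaptic grid (0.25 ms): every presynaptic cell is graded with a
membrane time constant of 8 ms or more, so sub-millisecond sampling of
presynaptic voltages is lossless in practice (halving the grid changes
spike counts by well under 2 %; this is tested).  Spikes are upward
crossings of −10 mV with a 1 ms lockout.  Initial voltages are
$\mathcal N(E_\mathrm{rest}, 2\,\mathrm{mV})$ per type (the original
initial-condition distributions are unavailable); gates start at their
fixed points for the drawn voltage, and rate analyses discard a 200 ms
settling transient.

## Receptive-field estimation

`fit_glm()` fits $r(t) = \mathrm{ReLU}(b + \sum_i k_i \cdot s_i(t))$
over five stimulus frames (0 to −200 ms at the 20 Hz refresh) to binned
spike counts by full-batch Adam on a mean-squared-error loss with a
Laplacian-square penalty on each spatial filter (replicated-edge
stencil, built as an explicit sparse operator so the penalty gradient
uses the exact adjoint).  Filters initialize at zero, making the fit
deterministic; stimuli are standardized internally.  A bias term is
included — without it a zero-mean standardized stimulus could not carry
the cell's baseline rate.  Defaults mirror the reference protocol
(3,000 epochs, learning rate $10^{-6}$ decayed by 10 % every 2,000
epochs); the penalty weight defaults to 1 on standardized stimuli and is
exposed, as only qualitative filter structure is asserted anywhere.

## Problem sizes and what the tests show

The package's own test battery runs the full 11,138-cell patch for the
census, spontaneous-rate and latency checks, a half-scale (150 µm) patch
for the degeneration sweeps, and a one-third-scale (100 µm) patch for
threshold protocols (with 4–10 trials per amplitude on a geometric
amplitude grid) — sizes chosen so the relative, within-patch comparisons
they make are meaningful while the battery stays fast.  Synthetic-data
checks (known receptive fields recovered from Poisson spikes, analytic
RC/field/sphere-average limits) validate the estimation and stimulation
machinery independently of the network.

Known limitations worth stating plainly: the model contains no rod
pathway, no gap junctions (hence no degenerative oscillations by
construction), no Müller glia or microneuromas, no RGC axons (so
epiretinal axonal activation is absent), and point-soma RGCs.  The RGC
gating kinetics are a reconstruction constrained by behavior, not a
published table; absolute latencies and absolute threshold currents
inherit that uncertainty, which is why the package reports relative
measures wherever the science allows.
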