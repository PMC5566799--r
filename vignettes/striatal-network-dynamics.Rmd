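---
title: "Bump dynamics in inhibitory networks with distance-dependent connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bump dynamics in inhibitory networks with distance-dependent connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatnet)
```

The striatum is, to first approximation, a large sheet of mutually
inhibitory projection neurons (medium spiny neurons, MSNs) driven by
excitatory cortical and thalamic input. `striatnet` models this system as a
purely inhibitory spiking network on a two-dimensional torus and asks one
structural question: *how does the shape of the distance-dependent
connection profile determine the spatiotemporal repertoire of the network?*
The package provides the spiking simulator, the wiring generator, a linear
stability analysis of the corresponding neural-field equation, and the
spike-train analysis (bump detection and tracking, rate/irregularity/
response statistics) needed to classify the dynamical state of a
simulation.

Three states organise the phenomenology:

* **AI** (asynchronous-irregular): spatially homogeneous, low-rate,
  irregular firing; no detectable activity bumps.
* **TA** (transition activity): spatially compact clusters ("bumps") that
  appear and dissolve within a few hundred milliseconds — the regime that
  resembles transient neuronal assemblies seen in striatal recordings.
* **WTA** (winner-take-all): a stable, spatially periodic lattice of
  high-rate bumps that persists for the whole simulation.

A network whose connection probability *decays monotonically* with distance
(Gaussian profile, on-centre inhibition) only ever shows AI activity. A
network whose connection probability *peaks at a nonzero distance* (gamma
profile, off-centre inhibition) traverses AI → TA → WTA as the excitatory
drive increases.

## Neuron and synapse model

Each neuron is a conductance-based leaky integrate-and-fire unit,

$$C_m \frac{dv}{dt} = -g_L\,[v - E_L] - g_{exc}(t)\,[v - E_{exc}]
  - g_{inh}(t)\,[v - E_{inh}] + I_{DC}(t),$$

with the MSN-like parameter set carried by `neuron_parameters()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `C_m` | 200 | pF | membrane capacitance |
| `g_L` | 12.5 | nS | leak conductance (so $\tau_m$ = 16 ms) |
| `E_L` | −80 | mV | leak reversal |
| `V_th` | −45 | mV | spike threshold |
| `V_reset` | −80 | mV | post-spike reset |
| `t_ref` | 2 | ms | absolute refractory period |
| `E_exc` / `E_inh` | 0 / −64 | mV | synaptic reversals |
| `tau_exc` / `tau_inh` | 5 / 10 | ms | alpha-synapse time constants |

Note that $E_{inh} = -64$ mV lies *above* rest: inhibition near rest is
shunting/depolarising, and hyperpolarising only for depolarised neurons.
This is a feature of MSN physiology, not an error, and the PSP calibration
below is therefore specified at explicit holding potentials.

Synaptic conductance transients are alpha functions
$g(t) = g_{peak}\,(t/\tau)\,e^{1-t/\tau}$. We normalise the alpha function
so that its *peak* equals the nominal conductance (reached at $t = \tau$);
since the peak conductances are subsequently calibrated to target PSP
amplitudes, the network is invariant to this normalisation choice.
`calibrate_psp()` root-finds the peak conductance such that a single spike
onto a neuron held by constant current (spiking disabled) produces the
reference unitary amplitudes of weak striatal synapses: a **0.8 mV IPSP at
−44 mV** holding and a **1.6 mV EPSP at −70 mV** holding, each to within
0.01 mV:

```{r}
g_inh <- calibrate_psp("inh", tau = 10, holding_mV = -44, target_mV = 0.8)
g_exc <- calibrate_psp("exc", tau = 5, holding_mV = -70, target_mV = 1.6)
c(g_inh = g_inh, g_exc = g_exc)
```

## Network architecture

10,000 neurons sit on a 100 × 100 grid folded as a torus (grid spacing
10 µm; all internal distances are in grid units, the spacing is only a
display conversion). Every neuron sends exactly `K = 1000` inhibitory
connections (10% connection probability), with no self-connections and
multapses allowed. Targets are drawn by polar sampling: an angle
$\phi \sim U(-\pi, \pi)$, a radius $r$ from the kernel's radial law (gamma
with shape $n$ and scale $\Theta$, or half-normal with width $\sigma$), then
$x = r\sin\phi$, $y = r\cos\phi$ rounded *to the nearest integer* grid
offset and wrapped; draws that land on the source are rejected and redrawn
(capped, with a diagnostic, for degenerate kernels). Rounding-to-nearest
was chosen over truncation as the least biased quantisation; at the kernel
scales used the difference is far below sampling noise.

### Why the default gamma kernel is a sharp ring

The shape of the kernel is the scientific crux, and the one place where
this package's defaults are a considered choice rather than a quoted
number. Two transforms of the same radial law matter:

* the **1D transform** $\tilde W(k)$ of the symmetric profile
  $W(x) = |x|^{n-1}e^{-|x|/\Theta} / (2\Gamma(n)\Theta^n)$, which has the
  closed form $\cos(n \arctan(\Theta k)) / (1+\Theta^2k^2)^{n/2}$ and is
  what the neural-field analysis below uses;
* the **2D radial (Hankel) transform**
  $\tilde W_{2D}(k) = \int_0^\infty \rho(r) J_0(kr)\,dr$ of the wiring
  profile actually realised on the torus
  (`kernel_fourier_radial2d()`).

Both must dip below zero for bumps to form, but the 2D dip is much
shallower than the 1D dip for broad rings. For $n = 3$ the 1D minimum is
−0.25 while the 2D minimum is only **−0.018**; with the calibrated synaptic
strengths and out-degree the recurrent loop gain per unit dip is roughly
12, so a 2D dip of −0.018 can never destabilise the homogeneous state — a
spiking network wired with a broad $n = 3$ ring stays spatially featureless
at any drive, which we confirmed in simulation. The dip deepens as the
ring sharpens (relative ring width $1/\sqrt n$):

```{r, eval = FALSE}
for (n in c(3, 8, 16, 24)) {
  ker <- kernel_spec("gamma", n, 2 / n) # fixed mode, varying sharpness
  print(min(kernel_fourier_radial2d(ker, seq(0.1, 6, 0.02))))
}
```

The package defaults are therefore `gamma(n = 24, theta = 0.4)` at full
scale: the connection-distance mode $(n-1)\Theta$ = 9.2 grid units = 92 µm
sits near the ~80 µm peak that paired recordings and morphology-based
estimates suggest for MSN pairs, the profile decays to zero well before
200 µm, nearest neighbours are effectively uncoupled, and the 2D dip
(−0.30) is deep enough for the bump instability to be reachable at
plausible drives. The price is a ring narrower than the experimental
profiles, which are broad; with biological ring widths the purely
inhibitory Turing mechanism is weak, and this tension should be read as a
model prediction (sharply tuned off-centre inhibition is *required* for
robust bumps at this network scale), not hidden in a default. All
functions accept any `kernel_spec`, and the analysis pipeline is tested
across a sweep of $(n, \Theta)$.

## Neural-field stability analysis

In the continuum limit the mean membrane potential $v(x,t)$ of the 1D ring
(the homogeneous, isotropic 2D case reduces to it) obeys

$$\frac{\partial v}{\partial t} = -v(x,t)
  - \int f(v(y,t))\, W(x-y)\, dy + I(x,t),$$

with $f$ the (nonnegative, nondecreasing) transfer function and the minus
sign on the integral encoding inhibition; connection strength is absorbed
into $f$. For constant input $I_0$ the homogeneous fixed point solves
$v_0 + f(v_0) = I_0$ (`homogeneous_fixed_point()`, residual < 10⁻¹⁰).
Linearising around $v_0$ gives, per spatial wavenumber $k$, the growth rate

$$\zeta(k) = -1 - f'(v_0)\, \tilde W(k),$$

so the homogeneous state destabilises exactly when
$f'(v_0)\,|\min_k \tilde W(k)| > 1$ with $\min_k \tilde W(k) < 0$. (Some
statements of this condition print the inverse of the *signed* minimum;
since that minimum is negative we implement the magnitude form, which is
what $\zeta > 0$ implies.) Three consequences, all tested:

* Gaussian kernels transform to Gaussians, $\tilde W > 0$ everywhere:
  never unstable, for any gain — Gaussian networks cannot form bumps.
* Gamma kernels with $n > 1$ have $\tilde W(k) < 0$ for large $k$: bumps
  become possible once the drive (which sets $f'(v_0)$ through the convex
  LIF transfer function) is strong enough.
* The fastest-growing mode is the argmin of $\tilde W$, at the critical
  wavenumber $k_c = \tan(\pi/(n+1))/\Theta$, predicting an inter-bump
  spacing of $2\pi/k_c$ grid units — increasing in both $n$ and $\Theta$.

```{r}
rep <- stability_report(field_model(transfer_sigmoid(f_max = 4, gain = 10),
                                    kernel_spec("gamma", 24, 0.2), I0 = 1))
glance(rep)
```

The transfer function is pluggable (`transfer_sigmoid()`,
`transfer_threshold_linear()`, or any user function; derivatives fall back
to central differences with step 10⁻⁶). The measured spacing in
winner-take-all simulations runs ~10–20% *below* $2\pi/k_c$, for two
understood reasons: the 2D argmin of $\tilde W_{2D}$ sits at slightly
larger $k$ than the 1D argmin, and hexagonal packing on a finite torus
compresses nearest-neighbour distances. The agreement (pointwise within
20%, correlation > 0.9 across a $(n, \Theta)$ sweep) is part of the
acceptance suite.

## Bump detection and tracking

Spike trains are cut into disjoint **100 ms frames** and arranged on the
grid. Detection runs on the *binarised* (any-spike) frames by default:
with raw counts, a single bursting neuron (CV ≈ 3, >10 spikes in a
window) produces a filtered peak indistinguishable from a genuine spatial
bump, and strongly driven Gaussian networks — which burst heavily but have
no spatial structure — would be misclassified. Binarising caps every
neuron's contribution at one. Count-frame detection remains available
(`analyze_bumps(binary = FALSE)`) and agrees with the binary variant on
well-formed test fixtures.

Each frame is convolved (circularly, on the torus, via FFT) with a 2D
Mexican-hat (Ricker) kernel built by `build_ricker()`: radially symmetric,
total integral 0, positive part +1 and negative part −1 after discrete
normalisation. A zero-integral kernel annihilates any spatially uniform
frame, which is what makes filtered activity comparable across input
levels. The default width is the field-theory length $1/k_c$ of the
network's own kernel (the predicted spacing over $2\pi$).

Thresholding the filtered image is where most of the numerical care lives.
A per-frame threshold of the form mean + 2·sd *always* marks ~2% of
pixels, so a featureless AI frame would always yield spurious components
and the AI state could never be diagnosed. Instead the threshold is

$$\text{median}(F) + \max\bigl(z \cdot \max(\text{MAD}(F),\;
  \sqrt{\bar c\, \textstyle\sum w^2}),\; 2.2\,\max(w)\bigr)$$

with $F$ the filtered image, $\bar c$ the mean frame count and $w$ the
kernel weights: a robust MAD noise floor (insensitive to the bumps, which
occupy a minority of pixels), a Poisson counting floor that takes over
when sparse frames drive the MAD to zero, and a minimum-evidence floor
requiring the peak to exceed anything two coincidently active sites can
produce. The multiplier default is $z = 5$; state classification is
robust over $z \in [4, 6]$ (tested). Connected components (8-neighbour,
torus-aware) of at least 3 pixels become bumps; centroids are
activity-weighted circular means, so a bump straddling the torus seam gets
the right centroid.

Tracking is greedy nearest-neighbour linking of centroids between
consecutive frames under the torus metric (closest pair first), with link
radius defaulting to one Ricker width and **no gap tolerance** — a bump
that vanishes for one frame and reappears counts as a new bump. Lifespans
are reported in frames and as fractions of the run.

`classify_state()` applies the defaults: **AI** if the mean per-frame bump
count is below 1; **WTA** if bumps are present and the median normalised
track lifespan exceeds 0.8; **TA** otherwise; runs shorter than 5 s are
refused. These thresholds are configurable; they are deliberately crude
cutpoints through what is really a continuum of lifespans.

## Spike-train and response statistics

`firing_rates()` (per-neuron rates, population mean/sd/skewness),
`cv_isi()` (undefined below 3 spikes; such neurons are excluded and
counted), `delta_response()` (evoked over pre-stimulus background rate of
the stimulated subset; undefined, not infinite, at zero background),
`fano_factor()` (across-trial variance/mean per 100 ms window) and
`correlation_spectrum()` (Pearson coefficients of trial-averaged 100 ms
binned counts, zero-variance neurons excluded) follow the standard
definitions. The stimulation protocol (`stimulus_protocol()`,
`run_two_stimulus_protocol()`) places two non-overlapping subsets of 45
neurons ("≈45" is implemented as exactly 45) at centres 10 grid points
apart inside a centrally placed 30 × 30 region of interest, sampled from a
2D Gaussian of width 2 grid points, and alternates 1 s current injections
(0–150 pA) separated by 2 s pauses, 20 trials each by default. Background
epochs for `delta_response` are the second immediately before each onset.

## Simulation engine and numerical choices

The integrator (C++ core) uses exact exponential propagation for the
two-stage alpha-conductance state and exponential-Euler for the voltage at
a fixed `dt = 0.1` ms; halving `dt` moves a unitary PSP peak by < 0.5%
(tested). Spikes are recorded at the end of the step in which threshold is
crossed; the neuron is reset and clamped for `t_ref`. Recurrent spikes are
delivered through a ring buffer after the synaptic delay (default 1 ms —
the delay is not a quoted biological number; it must be at least one
integration step for causal delivery, and results are insensitive to it
over 0.5–2 ms). Background drive is an independent homogeneous Poisson
stream per neuron at rate `nu_ext`, delivered through the calibrated
excitatory synapse; one stream per neuron of the stated rate (a
superposition of weaker streams would be statistically identical).
Initial membrane potentials are drawn uniformly in `[V_reset, V_th]` to
avoid artificial synchrony at $t = 0$.

Randomness is split into named streams — wiring, initial conditions,
background — derived deterministically from the user seed, so each can be
frozen independently and identical configurations reproduce byte-identical
results (tested). Wiring uses a single seeded vectorised stream rather
than per-source substreams; the package does not build networks in
parallel, and one stream keeps the generator simple and exactly
reproducible.

## Study conditions, problem sizes, and the reduced preset

The reference conditions (`full_preset()`) are the 100 × 100 torus,
`K = 1000`, gamma(24, 0.4) or Gaussian(σ = 8). Full-scale, 10 s runs are
minutes of compute, so tests and the acceptance analyses use
`reduced_preset()`: a 50 × 50 grid with `K = 250` and kernel scales halved
(gamma(24, 0.2), Gaussian(σ = 4)), which preserves the qualitative state
repertoire. Simulations in the test suite run 4–10 s of model time at
these sizes. The reduced network's drive grid was characterised once and
is fixed in the preset: AI at 600, TA at 1200, WTA at 3000 spikes/s. Two
reduced-scale effects are worth knowing: the AI band sits at much lower
rates than at full scale (with a quarter of the inhibitory inputs, the
bump instability is crossed at very low drive), and winners in the WTA
lattice are small clusters, so the 100 spikes/s "winner" population is
thinner than at full scale. The WTA preset drive (3 kspikes/s) is where
stable bumps with at least 20 neurons above 100 spikes/s and regular
winner firing (median CV ≤ 0.5) coexist; kernel-parameter sweeps use
5 kspikes/s so that every swept kernel is safely in its WTA regime.

## What the synthetic fixtures do and do not show

`generate_fixture()` produces data with exact ground truth: independent
Poisson rasters (known rate, CV = 1), perfectly periodic trains (CV = 0),
and frames with planted Gaussian blobs on Poisson noise (known centroids).
These validate the *analysis* pipeline — rate/CV/Fano recovery, blob
detection to sub-grid accuracy — independently of the simulator. They do
not validate the biology: passing them says nothing about real striatal
data, where rates are lognormal-ish and nonstationary, assemblies are not
circular Gaussians, imaging introduces its own point-spread, and the
network contains interneurons, D1/D2 subpopulations, neuromodulation and
short-term plasticity that this model deliberately omits. The model also
uses a single homogeneous Poisson drive (no spatially or temporally
structured cortical input) and fixed, plasticity-free synapses.

## Known limitations

* The bump instability at biological (broad) ring widths is marginal; the
  sharp-ring default is a modelling requirement, and quantitative bump
  statistics depend on the unquoted kernel parameters.
* The 1D spacing prediction is systematically ~10–20% above the measured
  2D nearest-neighbour spacing (2D argmin + hexagonal packing, see above);
  the package reports both numbers rather than folding a fudge factor into
  the theory.
* Greedy nearest-neighbour tracking with no gap frames undercounts
  lifespans when detection flickers; at the reduced scale this pushes the
  TA/WTA boundary upward in drive.
* Classification thresholds (count 1, lifespan 0.8) are stated defaults
  cutting a continuum; borderline drives near a regime boundary can
  legitimately flip label between seeds.
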