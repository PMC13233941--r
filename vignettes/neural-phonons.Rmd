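---
title: "Neural phonons: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural phonons: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(neurophonon)
```

## The model

Each EEG channel is modelled as a noisy Stuart–Landau oscillator, the
normal form of a Hopf bifurcation with a general complex cubic
coefficient:

$$\dot z = (\lambda + i\omega)\,z - (\zeta + i\chi)\,|z|^2 z + \eta(t),
\qquad \langle \eta(t)\eta^*(t')\rangle = 2D\,\delta(t-t').$$

The five parameters have direct electrophysiological readings:
$\lambda$ (1/s) is the linear growth rate — positive values sustain a
limit cycle of amplitude $r_e = \sqrt{\lambda/\zeta}$, negative values
give noise-driven quiescence; $\zeta$ (1/(µV² s)) is the cubic
saturation; $\omega$ (rad/s) the intrinsic rhythm; $\chi$ (1/(µV² s))
couples amplitude to phase velocity
($\dot\phi = \omega - \chi r^2 + \text{noise}$), which is the model's
mechanism for phase–amplitude coupling; and $D$ (µV²/s) is the noise
intensity.  Three archetypal parameter sets — *activated*
($\lambda{=}2, \zeta{=}1, \chi{=}0.8, D{=}0.01$), *suppressed*
($-0.5, 1, 0.2, 0.005$) and *exploratory* ($0.5, 5, 1.2, 0.05$) — are
shipped as `regime_preset()`; all default to a 10 Hz (alpha) intrinsic
frequency.

In polar coordinates the amplitude obeys a gradient flow in the drift
potential $U(r) = -\tfrac12\lambda r^2 + \tfrac14\zeta r^4$, whose
Boltzmann form $P_s \propto e^{-U/D}$ is the stationary amplitude
density.  The similarity transform $P = \psi\,e^{-U/2D}$ converts the
radial Fokker–Planck equation into an imaginary-time Schrödinger
problem with the sextic potential

$$V(r) = \frac{\hbar}{2}\Big(\lambda - 3\zeta r^2 +
  \frac{(\lambda-\zeta r^2)^2 r^2}{2D}\Big),$$

with curvature $V''(r_e) = 2\hbar\lambda^2/D - 3\hbar\zeta$ at the
limit cycle.  The fluctuation scale $\hbar$ (µV s) is a free model
input; it fixes the effective mass $m = \hbar/2D$ and the size of the
energy quanta, but cancels out of every dimensionless observable.  The
default is $\hbar = 1$ µV s, always recorded explicitly in configs.
Solving the radial eigenproblem numerically is out of scope here: the
package evaluates $V$, its curvature, and everything the harmonic
expansion needs, but not the full anharmonic spectrum.

## Phonon basis

For a network with symmetric complex coupling $K$ (diffusive term
$\sum_k K_{jk}(z_k - z_j)$), expanding the effective amplitude
Hamiltonian to second order around the per-site limit cycles gives the
mass-weighted dynamical matrix

$$\Phi_{jj} = \frac{V''(r_j^e) + \sum_{k\neq j} S_{jk}}{m_j},\qquad
  \Phi_{jk} = -\frac{S_{jk}}{\sqrt{m_j m_k}},\qquad
  S_{jk} = -\mathrm{Re}\,K_{jk}.$$

Its eigenpairs are the neural phonons: spatial patterns
$v^{(\ell)}$, frequencies $\Omega_\ell$, mode masses
$M_\ell = \sum_j m_j (v_j^{(\ell)})^2$.  There are always exactly $N$
modes for $N$ channels, so amplitude fluctuations reconstruct exactly
from the mode superposition; `project_recording()` /
`reconstruct_amplitudes()` realise the two directions and round-trip to
machine precision.

Choices made where the construction leaves room:

* **Degenerate eigenvalues.** Eigenvectors are orthonormalised by
  `eigen(symmetric = TRUE)` and sign-fixed deterministically (first
  component above 1e-8 made positive), so bases are reproducible.
* **Unstable modes.** Strong coupling (or the exploratory preset, whose
  curvature $2\lambda^2/D - 3\zeta = -5$ is already negative) can push
  eigenvalues of $\Phi$ below zero.  These are reported with
  $\Omega = \sqrt{|\Omega^2|}$ and an `unstable` flag plus a warning,
  never dropped: the harmonic expansion presumes stability but
  parameter scans will cross it.
* **Site vs mode masses.**  Projections use site masses $m_j$ (as the
  mode-superposition relation requires); mode energies use $M_\ell$.
  Where the closed-form cross-spectrum writes a per-site mass, we use
  $m_j$ and expose the eigenvector/mass weighting explicitly.
* **Energy accounting.**  `energy_report()` splits the total into the
  phonon term $\sum_\ell \hbar\Omega_\ell(n_\ell + \tfrac12)$ (clipped
  occupations, so a silent recording reports exactly the zero-point
  energy), the phase term with moment of inertia $I_j = m_j r_{e,j}^2$
  and momentum estimated from the mean unwrapped phase velocity, and
  the Josephson-like coupling term
  $-\sum_{j<k} J_{jk}\langle\cos\Delta\phi\rangle$ with
  $J_{jk} = -\tfrac12 r_{e,j} r_{e,k}\mathrm{Im}\,K_{jk}$ evaluated at
  equilibrium amplitudes (a time-resolved $J(t)$ would make the
  coupling energy depend on the envelope estimator; the equilibrium
  choice makes it well-defined per recording).

## Simulator

`simulate_network()` integrates the full complex system in Cartesian
coordinates — deliberately not in polar form, whose noise term carries
a $1/r$ singularity and Stratonovich subtleties that the Cartesian
additive-noise form sidesteps exactly.  The default scheme is
Euler–Heun (Stratonovich-consistent; for additive noise it shares the
Euler–Maruyama noise treatment and upgrades the drift to second
order — both facts are asserted in the tests).  Noise convention:
$\langle\eta\eta^*\rangle = 2D\delta$ means each real component of the
increment has variance $D\,dt$.  Stated bluntly because factor-of-2
conventions differ between sources; one consequence is documented under
*Known gaps* below.

Defaults: $dt = 1/2048$ s, initial amplitudes at $r_e$ (0.1 µV where no
limit cycle exists), initial phases uniform from the same seeded
stream, optional decimation to 256 Hz via a 4th-order Butterworth
low-pass at 0.8× the target Nyquist applied forward-and-backward
(8th-order zero-phase magnitude response) followed by subsampling.  A
step is refused, with a suggested value, when it exceeds one tenth of
the fastest local relaxation time including coupling row sums.  The
same `(model, config, seed)` triple reproduces recordings bit-exactly.

`make_fixture()` is the package's synthetic-data generator: an
N-channel ring lattice of one regime with complex edge coupling
$c(1+i)/\sqrt2$, returning model plus seeded recording.  What it
emulates is the *model's* study conditions — stationary band-limited
oscillations with controlled coupling — not real EEG: there is no 1/f
ensemble background (available separately as
`one_over_f_background()`), no artefacts, no nonstationarity, no
volume conduction.  Tests passing on these fixtures validate the
computational chain, not claims about recorded cortex.

## Observables

Closed-form route (`mode_psd()`, `cross_spectrum()`,
`analytic_coherence()`, `analytic_aac()`, `pac_strength()`): each mode
responds as a driven oscillator with Green's function
$(\Omega_\ell^2-\omega^2)^{-1}$ and flat noise floor $2\hbar$.  As
printed, that spectrum has non-integrable poles, so the package uses

$$S_{q_\ell}(\omega) = \frac{2\hbar}{(\Omega_\ell^2-\omega^2)^2 +
  \gamma^2\omega^2},$$

a damped form that reduces to the undamped one as $\gamma\to 0$ away
from resonance.  The default $\gamma$ is the linearised amplitude
relaxation rate $2\bar\lambda$ of the site-averaged oscillator
(`default_gamma()`), the physically natural linewidth; it is a
parameter, not a fit.  Envelope correlations use the zero-point
displacement variance $\hbar/2M_\ell\Omega_\ell$ unless a projected
trajectory supplies $\langle q_\ell^2\rangle$; because a correlation
must live in $[-1,1]$, the raw mode-overlap sum is returned alongside a
symmetrically normalised version with unit diagonal.

Empirical route (`analytic_band_signal()`, `welch_psd()`,
`band_power()`, `aac()`, `pac()`, `plv()`, `coherence_matrix()`,
`coherence_entropy()`): zero-phase 4th-order Butterworth band-pass,
FFT Hilbert transform, Welch PSD with 2 s Hann windows and 50% overlap
(one-sided density normalisation — stated here because no canonical
parameters exist), trapezoidal band power with alpha fixed at
8–13 Hz.  Filter transients: six periods of the lower band edge are
trimmed from each end before averaging (measured to bound the
zero-phase transient below 0.5%; three time constants proved too
short).  Coherence entropy sums over off-diagonal unordered pairs by
default — the unit self-coherences would otherwise dominate the
distribution — with the literal all-entries reading available via
`pairs = "all"`.  "Approximately zero" claims are always judged
against circular time-shift surrogates (`surrogate_bound()`, 200 draws,
seeded), never against an absolute threshold.

The PAC summary deserves a note.  The model predicts
$\dot\phi \approx \omega - \chi r_e^2 - 2\chi r_e q(t)$, so the
natural empirical index is the correlation between envelope and phase
velocity, with strength slope $2\chi r_e$ (`pac_strength()`).  At the
raw integration rate that correlation is diluted by the white phase
noise, so `pac()` offers an optional moving-average smoothing
(`smooth_s`), linear in both series and therefore unbiased.  Extracting
the phase *after* low-pass decimation of the complex signal is not
equivalent: it biases the correlation positive (about $+0.1$ even at
$\chi = 0$ in pilots), which is why the prediction tests work on the
full-rate analytic state.  The Tort modulation index is intentionally
not implemented.

## Predictions, as tested

* *Phase locking follows the imaginary coupling.*  With the full
  complex diffusive coupling and symmetric $K$, the Im-$K$ contribution
  cancels exactly in the phase-difference equation of two *identical*
  oscillators.  It survives when amplitudes differ, entering as a
  $\cos\Delta\phi$ term weighted by $r_1/r_2 - r_2/r_1$.  The test
  fixture therefore pairs $\lambda = 2$ with $\lambda = 0.5$
  ($r_e = 1.41$ vs $0.71$ µV): uncoupled PLV sits at chance
  (~0.04), strong imaginary coupling drives it above 0.9.
* *PAC scales with $\chi$.*  The signed envelope/phase-velocity
  correlation decreases monotonically across $\chi \in \{0, 0.4, 0.8\}$
  at fixed seed (amplitude fluctuations *depress* the instantaneous
  frequency, hence the negative sign).
* *Envelope correlations track shared mode loadings*, checked both on a
  constructed basis (two channels sharing a dominant mode vs a disjoint
  third) and empirically on an amplitude-coupled pair with an uncoupled
  bystander.

## Numerical choices and problem sizes

Quadratures (density normalisation, entropy, band power) are
trapezoidal on explicit grids; the default radial grid truncates at
$\max(3r_e,\,5\sqrt{D/\max(|\lambda|, \zeta D)})$ with a 10 µV
fallback, and entropy values converge to 1e-8 under grid halving.
Curvatures match central differences to 1e-6 across random parameter
sweeps.  Phases are stored unwrapped internally and only wrapped for
presentation.  Simulation-based tests use 30–60 s recordings at the
default step with fixed seeds — long enough that the slowest
correlation time (the ~0.25 s envelope relaxation of the activated
regime) is sampled a few hundred times over, chosen so the whole suite
completes in well under a minute.

## Known gaps and limitations

* **Factor-of-2 convention gap.**  The stated noise autocorrelation
  implies per-component increment variance $D\,dt$ (implemented), but
  the printed radial Fokker–Planck operator uses $D$ as the
  per-component diffusion coefficient, which corresponds to $2D\,dt$.
  The printed Boltzmann density inherits the larger value: simulated
  envelope fluctuations have variance $D/4\lambda$ where
  $e^{-U/D}$ implies $D/2\lambda$.  Both printed forms are kept as
  printed; the stationarity test therefore pins the *mean* amplitude
  tightly (<1%) and bounds the distributional distance (KS < 0.12,
  systematic component ≈ 0.09 from the width mismatch).
* **First-order envelope dynamics.**  The phonon equation of motion is
  second order, but the simulated mode displacement is an
  Ornstein–Uhlenbeck-type relaxation: its spectrum has no interior
  peak.  Since $\Omega \approx 2\lambda$ at small $D$, the honest
  empirical correspondence is that the half-power corner of the
  $q_\ell$ spectrum sits near $\Omega_\ell/2\pi$, which is what the
  property test checks.
* **The activated spectral peak sits at the $\chi$-shifted frequency**
  $\omega/2\pi - \chi\lambda/(2\pi\zeta) \approx 9.75$ Hz, one Welch
  bin below the 10 Hz intrinsic line — a feature of the model, not an
  artefact.
* Real-EEG preprocessing (surface Laplacian, artefact handling),
  vortex/topological-defect detection, Bose–Einstein thermodynamics
  beyond the single-parameter $1/\omega$ background, and numerical
  solution of the two-dimensional transformed operator are all out of
  scope.

## Personality map

`classify_personality()` makes the qualitative regime table
operational with explicit thresholds: high $\lambda/\zeta$ at
$\ge 1$ µV², low $D$ below 0.02 µV²/s (very low below 0.005), high
$\chi$ at $\ge 0.5$, very high at $\ge 1.5$, strong coupling at mean
$|K| \ge 0.5$ /s.  The defaults separate the three archetypal presets;
every threshold is a function argument, the rules are ordered and
deterministic, and anything outside all rule regions is returned as
`"unclassified"` rather than force-matched.  Coupling structure is
summarised by three scalars (mean $|\mathrm{Re}\,K|$, mean
$|\mathrm{Im}\,K|$, spectral radius); richer descriptors of the
coupling spectrum are a documented extension point.
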