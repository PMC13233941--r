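# neurophonon

Tools for modelling multichannel EEG as a network of noisy
Stuart–Landau (Hopf) oscillators and analysing it through its *neural
phonons* — the quantised normal modes of collective amplitude
fluctuation.

## The science

Each channel follows the stochastic Hopf normal form

    dz/dt = (λ + iω) z − (ζ + iχ)|z|² z + Σₖ K_jk (z_k − z_j) + η(t),

with complex white noise of intensity D.  For λ > 0 the channel
oscillates on a limit cycle of amplitude r_e = √(λ/ζ); the
amplitude–phase coupling χ shifts the instantaneous frequency by −χr²
and is the model's source of phase–amplitude coupling (PAC).  Mapping
the amplitude Fokker–Planck equation to an imaginary-time Schrödinger
operator gives an effective potential V(r) with curvature
V″(r_e) = 2ħλ²/D − 3ħζ and effective mass m = ħ/2D.  Second-order
expansion across the network yields a mass-weighted dynamical matrix
whose eigenpairs are the phonon modes: spatial patterns v⁽ℓ⁾,
frequencies Ω_ℓ, mode masses M_ℓ = Σⱼ mⱼ(vⱼ⁽ℓ⁾)².  From that basis the
package computes closed-form spectra S_q(ω) = 2ħ/((Ω²−ω²)² + γ²ω²),
cross-spectra, coherence, envelope correlations, and the PAC strength
2χr_e — alongside the standard empirical estimators (Welch PSD, band
power, PLV, PAC, AAC, coherence and coherence entropy) computed from
simulated or imported recordings, so model and data meet on the same
observables.

Intended users: computational neuroscientists studying oscillator
models of EEG/MEG, and methodologists who want a seeded, reproducible
generator of band-limited multichannel test signals with known ground
truth connectivity.

## Worked example

```r
library(neurophonon)

p <- regime_preset("activated")          # Hopf parameters of the regime
equilibrium_amplitude(p)                 # 1.414214  (= sqrt(2) uV)
potential_curvature(p, hbar = 1)         # 797

fx <- make_fixture("activated", n_channels = 4, coupling_strength = 0.5,
                   seed = 42, duration = 30)
build_basis(fx$model)
#> <phonon_basis> 4 mode(s); Omega = 3.9889, 3.9907, 3.9907, 3.9925 rad/s

psd <- welch_psd(fx$recording)
round(band_power(psd, "alpha"), 4)
#>    ch1    ch2    ch3    ch4
#> 0.9959 0.9976 1.0067 0.9895

zb  <- analytic_band_signal(fx$recording, "alpha")
zt  <- zb[(attr(zb, "trim") + 1):(nrow(zb) - attr(zb, "trim")), ]
plv_matrix(zt)[1, 2]                     # 0.997
coherence_entropy(coherence_matrix(zt))  # 1.792 (uniform max log(6) = 1.792)

classify_personality(fx$model)           # "activated"
```

Reading: the four ring-coupled activated oscillators concentrate
~1 µV² of power in the alpha band per channel, their phonon
eigenfrequencies sit near Ω ≈ 2λ ≈ 4 rad/s (the envelope relaxation
scale, not the 10 Hz carrier), the strong coupling locks the phases
(PLV ≈ 1), and the near-maximal coherence entropy says that synchrony
is spread evenly over all pairs rather than concentrated in one.

A command-line wrapper over the same functions is installed at
`system.file("cli", "neurophonon.R", package = "neurophonon")` with
subcommands `simulate`, `modes`, `spectra`, `observables`, `report`
(exit codes: 0 ok, 2 validation error, 3 numeric failure).

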