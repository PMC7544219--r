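# peldorna

PELDOR/DEER analysis of RNA kissing-hairpin dimerization.

The guanidine-II riboswitch regulates translation through two stem loops,
P1 and P2, that dimerize via loop-loop ("kissing") base pairing when
guanidinium binds. With one rigid nitroxide spin label per hairpin,
pulsed electron-electron double resonance (PELDOR, also known as DEER)
turns this equilibrium into two measurable quantities: the modulation
depth λ of the background-corrected dipolar trace — proportional to the
fraction of strands bound in dimers, f = λ/λ_max with λ_max ≈ 0.35 at
full dimerization — and the inter-label distance distribution P(r),
obtained by inverting

V(t) = [1 − λ + λ ∫ K(t,r) P(r) dr] · exp(−k t^(d/3)),
K(t,r) = ∫₀¹ cos[(3x² − 1) 2πν(r) t] dx,  ν(r) = 52.04 MHz·nm³ / r³,

whose peaks distinguish A-form duplexes from kissing dimers and
homodimers from the P1|P2 heterodimer.

The package provides, as testable modules:

* **Forward model** — powder-averaged dipolar kernel (Fresnel closed form
  with quadrature cross-check), form factor, homogeneous background,
  seeded noise.
* **Trace processing** — zero-time alignment, merging of
  frequency-offset traces, background fitting, modulation-depth
  estimation with kernel-based refinement (`process_trace()`).
* **Distance inversion** — non-negative Tikhonov regularization (NNLS on
  the stacked system), L-curve parameter selection, background-start
  validation bands, peak detection.
* **Dimer quantification** — depth→fraction conversion, Gaussian peak
  decomposition, component assignment against predicted references,
  two-reference superposition weights, statistical (binomial) pairing.
* **In-silico spin labeling** — accessible-volume rotamer sampling of the
  triazole-linked isoindoline nitroxide on PDB structures or generated
  A-form duplexes; N–N pair distance distributions.
* **Synthetic data** — a preset catalogue emulating every measured
  sample (both hairpins, three guanidinium conditions, the 1:1
  mixtures), with ground truth recorded in a manifest.
* **CLI** — `simulate`, `process`, `invert`, `quantify`, `label`,
  `pipeline` subcommands (`inst/cli/peldorna`).

## Worked example

Simulate the P2 hairpin at 0.4 mM guanidinium (observed depth 19 %,
kissing-dimer peak at 3.7 nm), then run the full pipeline:

```r
library(peldorna)
g   <- generate_scenario(preset("P2_Gdm"), seed = 1)
res <- process_trace(g$trace)   # align -> background -> invert -> refine

as.numeric(res$depth)           # 0.192  : recovered modulation depth
attr(res$depth, "percent")      # 19     : as reported in figures
f <- dimer_fraction(as.numeric(res$depth))
as.numeric(f)                   # 0.549  : fraction of strands in dimers
attr(f, "percent")              # 55     : ~54% printed for the real sample
find_peaks(res$distribution, 0.2)
#   position   height
# 1 3.698137 2.309313             : the kissing-hairpin distance, 3.7 nm
statistical_pairing(0.5)
#   AA   AB   BB
# 0.25 0.50 0.25                  : the 1:2:1 statistical dimer pool
```

A depth of 19 % against the 35 % full-dimer reference means roughly half
of the strands are dimerized; the sharp 3.7 nm peak identifies the
kissing conformation. The `mixU20_Gdm` preset reproduces the headline
three-peak experiment (3.6 / 4.4 / 5.2 nm, areas 1:2:1) that
demonstrates statistical homodimer/heterodimer formation.

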