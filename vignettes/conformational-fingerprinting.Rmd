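---
title: "Conformational fingerprinting of rare DNA states: models and methods"
author: "conformfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational fingerprinting of rare DNA states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformfp)
```

# The scientific problem

Watson–Crick base pairs transiently visit rare, short-lived conformations —
anionic Watson–Crick-like G•T⁻ mispairs, Hoogsteen base pairs, base-opened
states — that are plausible intermediates of replication errors and
chemical damage.  How often each state forms depends on the bases flanking
it.  `conformfp` implements a pipeline that (i) quantifies the propensity of
a rare state in each of the 16 trinucleotide contexts `ZTW` from biophysical
measurements, (ii) normalizes those propensities into a *conformational
fingerprint*, and (iii) scores the fingerprint against trinucleotide-resolved
(SBS96) cancer mutational-signature catalogs to nominate mutational processes
the state could drive.

Every experimental input has a synthetic twin (the `gen_*` generators), so
the full pipeline can be exercised and validated end to end without
laboratory data.

# Titration analysis

A two-state wobble ⇌ anionic equilibrium observed by 1D NMR gives peak areas
proportional to state populations.  Spectra are deconvolved into 1–3
Lorentzians parameterized by `(center, fwhm, area)` — area is the quantity
of interest, so it is a direct fit parameter rather than a derived one.
Populations are area ratios; their uncertainties come first-order from the
fit covariance (square roots of the diagonal, propagated through the ratio).

The apparent pKa follows Henderson–Hasselbalch,

$$\mathrm{p}K_a^{app} = \mathrm{pH} - \log_{10}\frac{p_{anion}}{1 - p_{anion}},$$

and the conformational free energy is $\Delta G = RT\ln 10\,(\mathrm{p}K_a -
\mathrm{pH})$ with $R = 1.987\times10^{-3}$ kcal/mol/K.  The default
temperature is 274.15 K (titrations at 1 °C); it is configurable.
Differences between contexts ($\Delta\Delta G$) are pH-independent because
the pH term cancels.

Per-pH pKa estimates are pooled by inverse-variance weighting: when the
two-state model holds, every pH point estimates the same pKa, and
inverse-variance weighting is the minimal-variance unbiased combination
under the Gaussian error model already assumed by the fits.  Points where
one state falls below the detection limit (the peak-count selector
prefers a single Lorentzian) are out-of-range titration points and are
rejected rather than propagated.

**Numerical choices.**  Peak initialization is deterministic and
sequential — each Lorentzian is seeded at the maximum of the previous fit's
residual — because a weak anion resonance beside a dominant wobble peak is
missed by naive local-maximum picking in noisy spectra.  Peak-count
selection uses BIC with the RSS floored at a numerical-noise level so that
on noiseless data extra peaks cannot win on round-off alone.  The mapping
of wobble/anion to the upfield/downfield resonance is sequence-dependent
and must be supplied by the user (`assign_peaks`); it is never guessed.

# Additivity cycles

With a full 4×4 table of per-context values, every rectangle
$\{Z,Z'\}\times\{W,W'\}$ yields two mutational cycles (one per diagonal
orientation): the double perturbation is predicted as the sum of the two
single perturbations.  There are $6 \times 6 \times 2 = 72$ cycles.  The
deviation of each cycle combines four table entries with signs
$(+1,-1,-1,+1)$, so i.i.d. table noise of SD $\sigma$ produces a deviation
SD of exactly $2\sigma$ — the property-based tests verify this with a
seeded simulation.  Observed-vs-predicted agreement is summarized by OLS
(slope, intercept, Pearson r) and the RMSD of the deviations.

The purine/pyrimidine partition of the 3′ neighbour is tested with an
exact two-sided rank-sum test: at $n = 8+8$ all $\binom{16}{8} = 12870$
relabellings are enumerated, so complete separation gives
$p = 2/12870 \approx 1.55\times10^{-4}$ with no normal approximation.

# Off-resonance R1ρ and the three-state Bloch–McConnell model

Chemical exchange between a ground state and two excited states (triangular
topology) is simulated with the 9×9 Bloch–McConnell generator: per-state
Bloch blocks with state offsets $\Omega_i = \Omega_{GS} + \Delta\omega_i$,
spin-lock $\omega_1$ along x, shared R1/R2, and first-order exchange rates
satisfying detailed balance $k_{i\to j} = k_{ex,ij}\, p_j/(p_i+p_j)$
(consistent with $k_{ex} = k_f + k_b$).  R1ρ at a grid point is obtained by
propagating the stacked magnetization with the matrix exponential
(eigendecomposition, compiled code), projecting onto the alignment axis,
and fitting a mono-exponential over the delay grid.

The initial alignment follows the $k_{ex}/|\Delta\omega|$ rule of the major
excited state: average-state effective field when the ratio exceeds 1
(threshold configurable), ground-state effective field otherwise.  The tilt
angle used for $R_2+R_{ex} = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta$
profiles is computed from the ground-state offset, matching the observed
resonance; a population-average option exists.

**A limit worth knowing.**  With no exchange, the dominant decay of
spin-locked magnetization equals $R_1\cos^2\theta + R_2\sin^2\theta$
*exactly* only when $R_1 = R_2$ or on resonance; off resonance the true
eigenvalue differs by $O\!\left(((R_2-R_1)/\omega_{eff})^2\right)$ — a few
parts in $10^5$ at typical spin-lock fields.  Tests assert machine-level
agreement in the exact regimes and the quadratic-order bound elsewhere.

**Fitting.**  The global fit shares populations and the three pairwise
exchange rates across nuclei, with per-nucleus $\Delta\omega$, R1 and R2;
populations and rates are fitted on the log scale by Levenberg–Marquardt.
The objective is multimodal, with long ridges along $p\,\Delta\omega^2$ in
the fast-exchange direction; restarts over log-spaced $k_{ex}$ values and
(optionally) sign-flipped $\Delta\omega$ are provided, but the supported
workflow is the field's standard one: start $\Delta\omega$ from prior
knowledge of the excited-state shifts (e.g. from chemical-shift mimics).
Uncertainties come from a seeded Monte-Carlo scheme — resample each R1ρ
from $N(\hat R_{1\rho}, \sigma)$, refit, report the SD over replicates.

**Noise pooling.**  Each decay series has five delays, so a per-series
noise estimate rests on 3 residual degrees of freedom; its sampling error
would distort the χ² weights of the global fit by a factor of ~3 in
expectation.  `reduce_to_r1rho` therefore pools the intensity-noise
estimate across all series of a nucleus by default.

# UV melting thermodynamics

A260(T) is modelled as baseline-weighted two-state melting,
$A_{260} = (m_{ss}T + b_{ss})\,p_{ss} + (m_{ds}T + b_{ds})\,p_{ds}$, with
the single-strand fraction in the closed form

$$p_{ss} = \frac{\sqrt{1+8x} - 1}{4x},\qquad
x = \exp\!\left[-\left(\tfrac{1}{T_m} - \tfrac{1}{T}\right)
\frac{\Delta H^\circ}{R}\right],$$

the van 't Hoff mass-action solution for duplex ⇌ two strands anchored at
$p_{ss}(T_m) = 1/2$.  The implementation is validated against an
independent mass-action root-finding oracle to $10^{-6}$ and is
overflow-guarded in log space.  Derived quantities use the printed
relations $\Delta S^\circ = \Delta H^\circ/T_m - R\ln(C_{total}/2)$ and
$\Delta G^\circ_{25} = \Delta H^\circ - 298.15\,\Delta S^\circ$.  Signs
follow the melting direction ($\Delta H^\circ > 0$); outputs are labelled.
Replicates are fitted independently and aggregated as mean ± SD (≥3
replicates in practice); co-fitting is deliberately not the default.
Contexts without reproducible melts are represented as missing values,
never imputed.

# Signature fingerprinting

Fingerprints are normalized propensity vectors over the available contexts
(missing contexts are dropped and recorded, not imputed).  For the anionic
G•T⁻ state the propensity of context `ZTW` is the Henderson–Hasselbalch
population at a reference pH (default 7.4).  Signature catalogs use the
COSMIC SBS96 dialect (`Type` column `A[C>A]A`, one probability column per
signature); rows are canonicalized and columns validated to sum to 1.

Similarity is the Jensen–Shannon divergence with base-2 logarithms,
$\mathrm{JSD}(P,Q) = H(M) - \tfrac{1}{2}(H(P)+H(Q))$, $M = (P+Q)/2$, which
is symmetric and bounded in [0, 1] (0 = identical).  Significance comes
from a resampled null: each draw samples the context values i.i.d. from
the pooled multiset of *all* channel probabilities across all signatures
and all six substitution classes, renormalizes, and computes the JSD
against the fingerprint.  P-values are left-tail with the add-one
correction $p = (1 + \#\{null \le obs\})/(1 + n)$, hence super-uniform
under the null; FDR is Benjamini–Hochberg across the scanned
(signature, substitution) pairs, since the source procedure names FDR
without specifying one.  A match is flagged *strong* when
$\mathrm{JSD} \le 0.090$ with both p and FDR < 0.05.

Each rare state is only compared with the substitution classes it can
mechanistically produce (`state_substitution_map`): G•T⁻ → {C>T, T>C};
A(syn)-T Hoogsteen → {T>A, T>C, T>G}; G(syn)-C⁺ Hoogsteen → {C>A, C>T,
C>G}; A-T opened → {T>A, T>G}.  Fingerprints are assumed to be expressed
on the pyrimidine strand of the SBS96 convention; purine-measured states
require the caller to reverse-complement contexts first.

The default null size is $10^6$ draws; the test-suite and examples use
$10^4$–$10^5$, which changes p-value resolution but not the ranking.

# What the synthetic generators emulate — and what they do not

* `gen_titration_series`: two Lorentzians whose areas follow the
  Henderson–Hasselbalch ratio $10^{\mathrm{pH}-\mathrm{p}K_a}$ with total
  area conserved, plus additive i.i.d. Gaussian noise (default 1% of
  maximum intensity — instrument noise is not reported for the real
  spectra, so this is a free parameter).  No solvent-exchange broadening,
  ring-current shifts, baseline roll or phase errors.
* `gen_r1rho_dataset`: the acquisition grid of the real experiments
  (spin-lock powers 500–2000 Hz, offsets ±3.5× the power — 20 per power,
  the spacing being unstated in the source — five delays to 120 ms) with
  intensities $e^{-R_{1\rho}t}(1+\varepsilon)$, $\varepsilon \sim N(0,
  0.01)$.  No pulse-sequence artifacts, off-resonance calibration errors
  or TROSY effects.
* `gen_melting_curve`: the two-state model with sloped baselines over a
  15–95 °C ramp and additive absorbance noise.  No heat-capacity change,
  multi-state melting or concentration error.
* `gen_signature_catalog`: background columns are symmetric-Dirichlet
  draws over 96 channels (concentration 0.5 — sparse, COSMIC-like, and
  exchangeable, matching the pooled-resampling null); the planted
  signature's channel is $(1-\varepsilon)\cdot$fingerprint
  $+\ \varepsilon\cdot$noise.  Real signature catalogs are neither
  independent nor exchangeable across signatures — passing the planted
  recovery test demonstrates correctness of the machinery, not power
  against real COSMIC structure.

Because the generators implement exactly the models the fitters assume,
green tests demonstrate correctness and calibration of the estimators
under their own assumptions — model misspecification on real data is out
of scope by construction.

# Parameter-recovery (coverage) study design

The R1ρ coverage experiment simulates a three-state system in the regime
where off-resonance R1ρ is most informative and such studies are actually
designed to operate: both excited states in slow-to-intermediate exchange
($k_{ex}/|\Delta\omega| < 1$) at populations of 1–2%
($p_{ES1} = 1.2\%$, $k_{ex,1} = 600$ s⁻¹, $\Delta\omega_1 = 3.5$ ppm;
$p_{ES2} = 2\%$, $k_{ex,2} = 1500$ s⁻¹, $\Delta\omega_2 = -7$ ppm at
70.96 MHz), with a substantial direct ES1–ES2 interconversion rate
(900 s⁻¹, e.g. proton transfer between tautomeric and anionic forms) so
that all three pairwise rates leave a measurable imprint.  Data for two
nuclei with distinct shift patterns (emulating the guanine and thymine
nitrogens of the same mismatch, the second with spin-lock powers up to
2500 Hz) are fit jointly with shared populations and rates — the
combined-fit protocol; a single nucleus does not by itself pin down the
triangular rate decomposition.  Fits follow
the standard constrained workflow: the excited-state shifts are fixed at
their independently known values ($\Delta\omega$ is available from
chemical-shift mimics before any dispersion fit), the alignment axis is
held at the ground-state effective field so the objective stays smooth
in the fitted parameters, and the fit is multi-started over $k_{ex}$.
Monte-Carlo replicate counts are kept modest (tens) to keep the full
50-replicate study inside a few minutes of CPU, with a t-quantile CI to
account for the SD being estimated from a finite number of draws; the
replicate counts set the precision of the coverage estimate, not its
validity.

The study's own outcome is instructive and is reported by the test suite
rather than asserted here: the excited-state populations and the dominant
ground-state exchange rate reach near-nominal CI coverage, but the
resample-and-refit Monte-Carlo scheme — refits warm-started from the
converged solution, as is conventional — measures only the local curvature
of the objective.  The triangular rate decomposition
($k_{ex,GS:ES1}$ vs $k_{ex,ES1:ES2}$) remains weakly determined at 1%
intensity noise, and on some noise realizations the point estimate shifts
along that trade-off further than the local Monte-Carlo spread, so those
rates undercover.  A full-protocol parametric bootstrap (a complete
multi-start refit per resampled dataset) would capture the excursions but
multiplies the cost by the number of draws.  Free-$\Delta\omega$ fits of
the same data are even further from a parameter-recovery setting: the
likelihood then has long $p\,\Delta\omega^2$ ridges and near-equivalent
basins (including a triangular-vs-linear topology ambiguity).  All of
this is a property of the experiment's information content, not of the
optimizer; it is why practitioners report such rates with caution and
constrain three-state fits with every independent observable available.

# Known limitations

* Lorentzian fitting assumes well-phased, baseline-corrected spectra; only
  a constant baseline term and a median-filter pre-corrector are offered.
* The Bloch–McConnell fit does not model exchange-induced shifts of the
  observed resonance, alignment imperfections, or per-state R2 differences
  (a single R1 and R2 are shared by construction).
* The pooled-resampling null treats channel probabilities as exchangeable
  across signatures and contexts; p-values inherit that assumption.
* Reproducing the published COSMIC matches requires the external COSMIC
  GRCh37 tables and the measured propensity tables; `read_signatures`
  accepts such files, but no COSMIC data ships with the package.
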