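---
title: "Spectrum-resolved LET quenching corrections for proton film dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-resolved LET quenching corrections for proton film dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmquench)
```

## The model and its assumptions

Radiochromic film darkens because ionising radiation polymerises the
monomers in its active layer. The bimolecular picture — two monomers must
interact to form a polymer — yields a saturating dose response

$$ o(D) = \frac{o_m D^a}{D_{1/2}^a + D^a}, $$

with net optical density $o$, saturation value $o_m$, half-saturation dose
$D_{1/2}$ and exponent $a$. The parameters are batch-specific and fitted
at a reference beam quality $Q_0$ (`fit_calibration()`); the set used
throughout this package's examples is $\{0.93, 8.99\,\mathrm{Gy}, 0.82\}$,
obtained in the entrance plateau (2 cm depth) of a 179.7 MeV proton beam
where the dose-averaged LET of primaries is 0.5 keV/um.

Quenching — the reduced response per unit dose at high LET — is modelled
as an LET dependence of the half-saturation dose alone ($o_m$ and $a$ kept
constant):

$$ D_{1/2}(S_w) = c_1 + c_2\left(1 - e^{-S_w^2 (2 c_3)^{-2}}\right), $$

with $S_w$ the unrestricted electronic stopping power in water of the
proton. The form is a smooth sigmoid in $S_w^2$: flat to within ~5% below
5 keV/um, rising steeply between 10 and 30 keV/um, saturating at
$c_1 + c_2$. Working on the $S_w$ axis rather than energy concentrates
resolution where the response varies: the quenching-relevant interval
1–5 MeV maps to 7.9–26.1 keV/um while the quiet interval 15–250 MeV maps
to only 3.3–0.4 keV/um. $S_w(E)$ has its maximum (~82 keV/um) near
0.08 MeV; protons below that energy are assigned the response of the
equal-$S_w$ proton on the fast branch. Their dose share in water fields is
below 0.3%, so the simplification is immaterial.

### Mixed fields: the spectrum integral

For a beam quality $Q$ — the fluence distribution differential in LET at
the measurement point — the net optical density follows from integrating
the per-quality response increments over dose. `integrate_net_od()`
implements the discrete update rule

$$ \delta o = \sum_j w_j\, o_m a\, \frac{1}{D_{1/2}(S_{w,j})}
   \left(\frac{o_m - o}{o_m}\right)^2
   \left(\frac{o}{o_m - o}\right)^{1 - 1/a} \delta D, $$

with $w_j$ the dose fraction of LET bin $j$ and a global dose step
$\delta D = 5\times10^{-5}$ Gy (halving the step changes the result by
less than $10^{-5}$ net-OD at 2 Gy — the convergence is asserted in the
test suite). Two numerical points deserve note:

* **Ordering.** The update could be applied bin-by-bin sequentially or
  simultaneously at the shared current $o$. We use the simultaneous
  convention: all spectral components irradiate the film at once, and a
  sequential scheme would make the result depend on an arbitrary bin
  order. Because the per-bin increment factorises as $g(o)/D_{1/2,j}$, the
  weighted sum equals $g(o)\sum_j w_j/D_{1/2,j}$; the compiled loop hoists
  the harmonic term out of the iteration (exact algebra). A corollary used
  by the tests as an independent oracle: the mixed-spectrum result equals
  the closed-form bimolecular curve evaluated at the dose-weighted
  *harmonic* mean of the per-bin half-saturation doses.
* **Singular start.** For $a < 1$ the response has unbounded slope at
  $o = 0$ ($o \sim D^a$), so the first $\delta D$ step is seeded with the
  closed form; the printed update rule is used from the second step on.

### Relative effectiveness and its inverse problem

The iso-dose relative effectiveness $\mathrm{RE} =
D_\mathrm{apparent}/D_\mathrm{true}$ decodes the (measured or calculated)
net optical density with the *reference* calibration; its reciprocal $g$
corrects apparent film doses. `fit_quench()` recovers
$\{o_m, c_1, c_2, c_3\}$ (with $a = 0.82$ adopted from literature to
reduce the number of free parameters) by minimising
$X^2 = \sum_i (g_i^\mathrm{calc} - g_i^\mathrm{meas})^2$ over a training
set combining a high-LET SOBP depth scan with reference-quality dose
levels. The optimiser is a bounded quasi-Newton method (L-BFGS-B) with
finite-difference step $10^{-5}$ on scaled parameters; bounds keep the
quench model in its physical domain ($c_1, c_3 > 0$, $c_2 \ge 0$,
$o_m \in (0,3)$). Convergence is declared on the optimiser's own criteria
or on a line-search stop without ascent (the start may already be
stationary). Local minima are a known hazard of this inverse problem;
`initial_guess()` provides the literature-based start — converting a
$g(S_w)$ curve to $D_{1/2}$ values via the low-dose sensitivity relation
$k = a D_{1/2}^{-a}$ with $k \propto g$, anchored at the reference
half-dose at the lowest $S_w$ — and the test suite refits from ten
perturbed starts and requires the recovered $D_{1/2}(S_w)$ curves to agree
within 2%. The curve, not the raw coefficients, is the meaningful
estimate: $c_2$ and $c_3$ trade off strongly when the training spectra do
not reach deep into the saturation region.

Identifiability note: when the fitted $o_m$ matches the reference
calibration's, RE reduces exactly to $D_{1/2}^{ref}/\bar D_{1/2}$
(harmonic mean) independent of dose; the dose levels in the training set
are what pin $o_m$ apart from the c's.

### The practical corrector

`spectrum_re_points()` evaluates the spectrum-resolved RE over the
nine-beam synthetic study set (`study_beams()`): four single layers (62,
148, 179.7, 252.7 MeV), the high-LET SOBP `b1`, its 50%-fluence and
50%-dose low-LET superpositions `b2`/`b3`, and two 5 cm box SOBPs centred
at 6 and 30 cm. `fit_re_ld()` then fits RE as a first- (or fourth-) order
polynomial of the dose-averaged LET, with points above 15 keV/um excluded
— clinically relevant Ld rarely exceeds 10 keV/um, and the quench model is
least constrained there. Evaluation beyond the fit domain clamps to the
boundary with a warning; the correction never extrapolates silently. On
the synthetic set the linear and quartic parameterisations agree within
1% over Ld of 1–8 keV/um; over the full 0–15 keV/um domain the quartic
departs by a few per cent at the unconstrained edges, which is why the
package reports but does not assert full-domain agreement. Fluence-averaged
LET is computed and reported (`lt_of()`) but never offered as a correction
axis: mixtures of a low-LET high-energy beam with a high-LET SOBP produce
pairs of spectra with equal Lt and RE differing by more than 5%.

## The synthetic beam model

The simulator replaces Monte Carlo transport with an analytic
primary-proton model; it is the package's data generator, not a treatment
planning tool.

* **Stopping powers.** An embedded ICRU49/PSTAR-consistent table of
  unrestricted electronic stopping power of liquid water (90 rows,
  0.01–300 MeV; single maximum at 0.08 MeV), interpolated log-log, with
  CSDA ranges by quadrature of $1/S(E)$ from a 0.1 MeV cutoff. The printed
  check values 3.3/7.9/26.1 keV/um at 15/5/1 MeV and 0.4 keV/um at
  250 MeV reproduce at one decimal.
* **Transport.** Mean energy at depth from the residual range; survivors'
  residual range is the truncated-normal conditional mean, which carries
  the distal falloff smoothly instead of pinning stopped protons at the
  energy floor. Range straggling is Bohr-like, $\sigma_R = 0.012 R_0$ at
  full range with variance growing linearly along the path; primary
  fluence is attenuated by nuclear interactions as $e^{-z/85\,\mathrm{cm}}$.
  Both constants are configuration parameters (`beam_settings()`), tuning
  knobs rather than physics claims.
* **LET spectra.** Energy bins map through $S_w$ onto the canonical
  equidistant 0.05 keV/um grid; the energy grid is the union of a
  Gaussian-resolving grid and the preimage of a quarter-bin $S_w$ grid, so
  the mapped bins stay finer than the LET grid below ~30 keV/um. Total
  fluence and fluence-weighted $S_w$ are conserved exactly in the
  rebinning. $L_t = \sum \Phi S / \sum \Phi$ and
  $L_d = \sum \Phi S^2 / \sum \Phi S$ use bin-centre $S$.
* **SOBP composition.** Layer weights solve a non-negative least-squares
  problem against a constant target dose on a 0.1 mm depth grid.
* **Commissioning.** Two facility parameters are not published and were
  set, once, so that the simulator reproduces the documented study
  geometry — the six lowest clinical layers (62.4–67.5 MeV) composing a
  flat 1 Gy SOBP over 30–35 mm: a beamline water-equivalent offset of
  2.6 mm (vacuum window, monitors, holder; with zero offset the CSDA
  ranges place the Bragg peaks at 33–38 mm and the documented window is
  geometrically unreachable) and a per-layer energy spread of 1% of the
  nominal energy, typical of clinical beam models at low synchrotron
  energies. With these values the non-negative least-squares plateau is
  flat to better than 2% at every 0.1 mm grid point.

### What the generator does and does not emulate

It emulates: the slowing-down and widening of the primary energy
distribution with depth, range straggling, the composition of SOBPs from
weighted layers, the b1/b2/b3-style fluence/dose superpositions (the
50%-dose case takes 87–88% of the initial fluence, matching the
experimental bookkeeping), and LET spectra on the canonical grid. It does
not emulate: secondary protons and heavier fragments (the reference-field
Ld of 0.5 keV/um is the primaries-only figure; with secondaries it would
be roughly twice that), nuclear-interaction dose deposition, lateral
transport, or scanner/readout effects. Tests passing on this generator
therefore validate the *formalism* — integrator, inverse optimisation,
averaging laws, Ld collapse — not the absolute RE values of any particular
facility; the fitted linear coefficients of the synthetic set differ from
published experimental ones for exactly this reason.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `delta_d` | 5e-5 | Gy | integrator dose step; halve to check convergence |
| `sw_bin` | 0.05 | keV/um | LET histogram bin width |
| `a` | 0.82 | — | bimolecular exponent, fixed in the quench fit |
| `dose_window` | 0.5–2.5 | Gy | validity window of the quench characterisation; outside it RE drifts by several per cent with dose and the package warns |
| `k_strag` | 0.012 | — | range straggling fraction of full range |
| `lambda_cm` | 85 | cm | nuclear attenuation length of primary fluence |
| `beamline_wet_mm` | 2.6 | mm | upstream water-equivalent thickness |
| `sigma_e` | 1% of E | MeV | per-layer energy spread |
| `ld_max` | 15 | keV/um | RE(Ld) fit-domain limit |

## Degenerate inputs and tie-breaks

Empty spectra integrate to zero net-OD; all-zero spectra have undefined
LET averages and error. Saturated net optical densities ($o \ge o_m$)
cannot be decoded and error rather than returning infinite dose. Curves
confined to low $S_w$ leave $c_2/c_3$ unresolved in `initial_guess()`; it
falls back to a heuristic start with a warning, relying on the subsequent
optimisation. Zero-dose SOBP targets yield zero weights; plateau windows
beyond every layer's range are rejected. Points above `ld_max` are
*excluded* from RE(Ld) fits but *clamped* (with a warning) in evaluation —
exclusion keeps the fit honest, clamping keeps the correction defined.

## Problem sizes

The shipped tests and the acceptance computations use: 16 SOBP depths plus
11 reference dose levels for the inverse optimisation (27 training
points, 0.5% multiplicative noise on $g$, fixed seed); ~100 positions
across the nine-beam set for the RE(Ld) collapse; 0.1 mm depth grids for
SOBP weighting. These sizes were chosen to estimate every quantity the
package asserts while keeping a full run in the minutes range.

## Known limitations

* Primary protons only; Ld and RE of real mixed fields including
  secondaries will differ, most visibly in entrance regions.
* The quench parameterisation is tied to the bimolecular calibration;
  other calibration forms would change the extrapolated RE.
* The corrector is restricted to 0.5–2.5 Gy and Ld up to 15 keV/um; dose
  dependence of RE outside that window is real and not modelled.
* The embedded stopping-power table is interpolated, not computed; below
  1 MeV its values are consistent with published tables only to a few per
  cent, which is immaterial for dose-weighted quantities but should not
  be mistaken for reference data.
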