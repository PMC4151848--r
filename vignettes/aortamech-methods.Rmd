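---
title: "Methods: tensile rheology, histomorphometry and group statistics in aortamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensile rheology, histomorphometry and group statistics in aortamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamech)
```

aortamech quantifies how the wall of the developing thoracic aorta behaves
mechanically and what it is made of. It was built around a classic study
design in vascular physiology: longitudinal wall strips from three arms of
a rat flight experiment — spaceflight (FLT), asynchronous ground control
(AGC) and vivarium control (VIV) — run through a two-phase uniaxial tensile
protocol, with stained sections of the same strips quantified by color
segmentation. This vignette explains the models and conventions the package
uses, the tunable parameters, what the synthetic-data generator does and
does not emulate, and the numerical choices behind each stage.

## 1. Tensile rheology

### Strain, stress, and units

A strip of just-taut initial length $L_0$ (cm) stretched by a crosshead
displacement $\Delta$ (mm) carries engineering strain

$$\varepsilon = \frac{\Delta}{L_0},$$

the fractional extension beyond the just-taut length. The wall is treated
as incompressible (Poisson's ratio 0.5) with density
$\rho = 1.06\ \mathrm{g/cm^3}$, so the unstressed cross-section is
recovered gravimetrically from the strip weight $W$ (g) as
$A_0 = W / (\rho L_0)$ and shrinks by $1/(1+\varepsilon)$ under stretch.
Stress over the current section is therefore

$$\sigma = \rho\, L_0 (1 + \varepsilon)\, \frac{T}{W}
        = (1+\varepsilon)\,\frac{T}{A_0},$$

with tension $T$. Internally force is stored in newtons and stress in kPa;
the conversion runs through the classical gram-force formulation with
exact constants (1 gf = 9.80665 mN, 1 gf/cm² = 0.0980665 kPa), which
collapses to $\sigma[\mathrm{kPa}] = 10\,(1+\varepsilon)\,T[\mathrm{N}] /
A_0[\mathrm{cm^2}]$. Wall thickness is recovered from the same gravimetric
argument, $h = W / (\rho L_0 W_d)$ with strip width $W_d$, and the vessel's
internal radius from the circumferential length $l$ of the excised strip as
$l / 2\pi$. Two useful algebraic identities follow and are asserted in the
test suite at $10^{-9}$ relative tolerance: the wall weight per unit
luminal area (mg/cm²) equals $0.106 \times h(\mu m)$, and $W$ round-trips
exactly through $(h, W_d, L_0)$.

A note on the strain convention: some instrument reports express "strain"
as the stretch ratio $(\Delta + L_0)/L_0$, which equals 1 at rest. That
convention is incompatible with the $(1+\varepsilon)$ incompressibility
factor above and with quoting moduli "at a strain of 0.25–0.75"; aortamech
uses engineering strain throughout, which makes a 50% stretch correspond
to $\varepsilon = 0.5$ exactly.

### Onset detection

On the bench, the initial length is set as the maximum length at which
tension just exceeds 0 N — an operator judgement. `build_stress_strain()`
reproduces it as the first sample whose force exceeds a configurable
threshold (default 1 mN) and re-zeroes displacement there. The same
threshold is the default for plastic-deformation detection, for symmetry:
both questions are "where does the strip become load-bearing?".

### Incremental modulus

`incremental_modulus()` returns the mean gradient of the stress–strain
curve over a symmetric window, $(\sigma(c+w) - \sigma(c-w)) / 2w$, with
endpoint stresses linearly interpolated between samples (for duplicated
strain values the last occurrence wins; on a monotone ramp this is
unambiguous). The conventional centres are 0.25, 0.50 and 0.75 — low,
medium and high physiological strain — with half-window $w = 0.05$. On an
affine curve the estimator returns the slope to machine precision; on an
exponential backbone it matches the closed-form secant, and both
properties are frozen as tests.

### Relaxation strength and plastic deformation

After the rapid stretch to 50% strain, stress decays from its peak
$\tau_0$ toward a plateau. `relaxation_strength()` reports the percentage
drop over a 5-minute hold, $(\tau_0 - \tau_{5min})/\tau_0 \times 100$,
taking $\tau_0$ as the maximum stress in the trace and $\tau_{5min}$ at
exactly peak time + 300 s by linear interpolation (if the trace ends
within one sample of the nominal end, the last sample is used with a
warning). `plastic_deformation()` reads the residual elongation off the
slow re-stretch recorded after the recovery period: the displacement at
which force first exceeds the threshold, interpolated between the
straddling samples; 0 when the strip is taut immediately, and `NA` ("not
detected", deliberately distinct from 0) when the force never crosses the
threshold.

## 2. The synthetic tensile protocol

No raw traces are published for studies of this kind at this scale, so the
package carries a quasi-linear viscoelastic (QLV) simulator whose output
is analyzed by exactly the same functions as instrument data. The
constitutive model combines a two-term exponential elastic backbone

$$\sigma_e(\varepsilon) = A_1(e^{B_1 \varepsilon} - 1) +
  A_2(e^{B_2 \varepsilon} - 1)$$

(a compliant elastin-dominated term and a steep collagen-recruitment term)
with a reduced relaxation function
$G(t) = g_\infty + \sum_i g_i e^{-t/\tau_i}$ through the hereditary
convolution $\sigma(t) = \int_0^t G(t-s)\, \dot\sigma_e(s)\, ds$. The
discretization uses piecewise-linear increments of $\sigma_e$ with an
exact exponential-decay recursion per Prony term, at the instrument
sampling interval (default 10 Hz); this is unconditionally stable and
introduces no numerical relaxation of its own.

The default backbone constants $A = (20.312, 0.0068285)$ kPa,
$B = (2.4133, 10.2468)$ were fitted once, by least squares on the
simulator itself with a mean-geometry control strip, so that the measured
moduli sit at the physiological anchors for 3-week-old rat aorta:
$E(0.25) \approx 100$ kPa, doubling at 0.50 and tripling again at 0.75.
The Prony defaults $g = (0.055, 0.045)$, $\tau = (15, 250)$ s yield a
5-minute relaxation strength near 8%, the value typical of the proximal
(elastic) thoracic aorta; the two time constants bracket the hold so that
decay is neither exhausted at the peak nor still linear at 5 minutes.

Two bench conventions are built into the simulator deliberately:

* **Just-taut pre-tension.** The initial length is defined by tension just
  exceeding 0 N, so the simulated strip carries a small pre-tension
  (default 1.5 mN) at zero displacement, found by solving
  $g_\infty \sigma_e(\varepsilon_0) A_0 / 10 = T_{pre}$ for the pre-strain
  $\varepsilon_0$. This makes onset detection and plastic-deformation
  detection behave exactly as on the instrument: a control strip reads 0 mm
  residual deformation because it is load-bearing at zero displacement.
  A side effect worth knowing: because $\varepsilon_0$ depends on $A_0$,
  two strips differing only in thickness have their measured stress–strain
  curves offset by a few percent, not perfectly superimposed — as on the
  real bench.
* **Plastic offset.** A programmed residual elongation $p$ shifts the
  zero-force length for every phase after the first loading: the strip is
  slack (zero force) below displacement $p$. The recovery probe therefore
  crosses the detection threshold within one sample interval of $p$.

Measurement noise is multiplicative Gaussian on force (default SD 0.5%)
plus one additive offset per trace (default SD 20 µN, the scale of load
cell drift in this force range); both seeded, both disable-able. The
additive term was sized so its back-projection through the toe-region
stiffness stays below the displacement sampling resolution, keeping
plastic-deformation readings unbiased.

## 3. Group profiles

`default_group_profiles()` encodes the three study arms. Means follow the
tabulated group values (body weight 40.0/77.5/83.0 g; internal diameter
1.08/1.32/1.31 mm; wall thickness 133.3/193.4/188.4 µm for FLT/AGC/VIV);
the strip is 3 mm wide and nominally 8 mm long. Between-specimen SDs for
tabulated variables derive from the reported standard errors via
$SD = SE\sqrt{6}$, with one exception: wall thickness, whose SD is set to
half that value. The observed between-pup spread of thickness includes the
gravimetric measurement chain (weighing a milligram-scale wet strip),
which the generator does not re-add on top of true biological variation;
with the full $SE\sqrt{6}$ spread a 6-animal-per-arm design detects the
thickness difference only about half the time under a Scheffé test,
whereas the study design this generator emulates treats that difference as
reliably detectable. The halved SD calibrates the effect size so the
qualitative significance pattern — thickness and smooth-muscle fraction
flagged for FLT versus both controls, elastin and collagen fractions not
flagged — reproduces in ≥90% of simulated studies, which the test suite
checks over 20 studies.

The FLT arm differs from the controls only in geometry (thinner, lighter,
narrower), a nonzero plastic offset (0.12 ± 0.07 mm, truncated positive),
a smaller smooth-muscle area fraction (35% versus 45%) and a lower nucleus
density (134 versus 179/166 per frame). Constitutive stress parameters are
shared by all arms; consequently stress–strain curves and moduli are
statistically indistinguishable across arms while tensile force is
systematically lower in FLT — the central decoupling of force (an
extensive quantity) from stress (an intensive one). Between-specimen
constitutive variability is multiplicative and modest: CV 0.10 on the
backbone scale (chosen so 6-specimen group means of $E$ vary by a few
percent) and CV 0.20 on the Prony weights (producing relaxation-strength
SEs of the same order as those reported for such preparations, roughly
0.5–1.5 percentage points).

## 4. Histomorphometry

### Color segmentation

Elastica-van Gieson renders elastin near-black, collagen red and smooth
muscle yellow; hematoxylin-eosin renders nuclei blue-violet on pink. The
package's computable analogue of "intensity, hue and purity" is HSV space.
Default bands (`default_color_thresholds()`, all configurable):

| class    | rule                                        |
|----------|---------------------------------------------|
| elastin  | value < 0.25                                 |
| collagen | hue ∈ [330°, 20°] (wrapping), saturation > 0.3 |
| smc      | hue ∈ [40°, 70°], saturation > 0.2           |
| nuclei (HE) | hue ∈ [200°, 290°], saturation > 0.25     |

Precedence: the elastin intensity test wins over the hue tests, because
hue is numerically unstable for near-black pixels; collagen is tested
before smooth muscle. Every pixel ends in exactly one class (including
background), a mask-exclusivity invariant the tests assert. There are no
published numeric thresholds for the original analyzer; these bands are
engineering choices validated against the synthetic renderer only.

### Nuclei

`segment_nuclei()` thresholds the blue-violet band, labels 8-connected
components (4-connected labeling plus a union–find merge of diagonal
contacts) and discards components under 30 px at the default render
scale. There is deliberately no watershed declumping: the frame-level
convention counts visibly distinct nuclei, so two touching nuclei count as
one — a documented limitation, exercised in the tests. Area fractions are
percentages of the sectional area (by default the whole frame), averaged
over fields per specimen with a warning when fewer than the conventional
2 (EVG) or 3 (HE) fields are supplied.

### Synthetic fields

The EVG renderer paints a sinusoidally warped lamellar banding pattern —
wavy near-black lamellae, yellow interlamellar muscle bands, red collagen
strands, pale background — with band widths proportional to the requested
fractions, then reports the exact painted pixel count per class as ground
truth (rasterization moves painted fractions at most ~1 pp from the
request). The HE renderer places Poisson-distributed elliptical nuclei
(semi-axes 3.5–6 px) by rejection sampling with a 3 px separation margin,
so rendered nuclei never touch and the labeled count equals the placed
count exactly; placement failure beyond 10⁴ attempts raises a
density-too-high error rather than silently overlapping. Per-channel
Gaussian pixel noise (SD 4 of 255) keeps every reference color safely
inside its band: the worst-case hue excursion of the yellow class at this
noise level is about 7°, against a 7°+ margin to the band edge.

The renderer emulates the *measurement* problem — can color segmentation
recover known composition and counts — not the tissue. Real sections have
stain variability, out-of-focus light, anti-aliased edges, overlapping
nuclei and genuine texture; passing the recovery tests therefore
demonstrates correctness of the segmentation arithmetic and thresholds
under controlled conditions, not robustness to real-slide artefacts. The
frame is 256 × 256 px at a nominal 1.6 µm/px, sized so control-density
fields hold ~150–180 nuclei; the original analyzer's printed frame area is
not usable (its stated unit is physically impossible for that count), so
frame geometry is a configuration parameter, not a constant.

## 5. Group statistics

`one_way_anova()` partitions sums of squares explicitly; `mean_se()` uses
the $n-1$ sample standard deviation (which reproduces the reference
table's printed SEs). The F upper tail is evaluated through the
regularized incomplete beta function,
$P = I_{d_2/(d_2 + d_1 F)}(d_2/2,\, d_1/2)$, keeping the test's arithmetic
explicit end to end; the tests cross-check it against the standard F
distribution to $10^{-12}$ and the full ANOVA against a brute-force oracle
on 100 random datasets to $10^{-10}$ relative.

Scheffé's procedure refers each pairwise contrast
$F_c = (\bar x_i - \bar x_j)^2 / (MS_W (1/n_i + 1/n_j))$ to $(k-1)$ times
the F distribution with the ANOVA's degrees of freedom, which makes it
valid for any contrast chosen after seeing the data and hence conservative
for simple pairs (a property the tests verify against the planned-contrast
p-value, along with the $k = 2$ degeneracy where Scheffé and ANOVA
coincide). Stars use strict thresholds: `***` p < 0.001, `**` p < 0.01,
`*` p < 0.05. No correction beyond Scheffé is applied.

The packaged per-pup table (`reference_pup_data()`) carries the 72 printed
per-animal values of the reference study's summary table, so the entire
statistical surface is testable with zero synthesis: all 24 mean/SE cells
reproduce to the printed rounding, body weight is flagged at the 0.001
level for FLT against both controls, and aorta weight per cm² is flagged
for no pair (its smallest Scheffé p is ≈ 0.059 — a near miss that the
per-pup values fully determine).

## 6. Problem sizes and runtime choices

The package's own validation runs at desk scale, chosen to keep the full
suite fast while leaving the statistics well-posed: 6 specimens per arm
(the reference design), 10 Hz traces (~130 s of ramp, ~310 s of hold),
256 px fields, 20 rendered seeds for fraction recovery, 20 simulated
studies for the significance-pattern calibration and 12 for the
group-ordering check. The modulus and relaxation oracles run noise-free;
stochastic checks fix their seeds and assert bands, not point values.

## 7. Known limitations

* The QLV simulator is a stand-in calibrated to published group-level
  anchors, not a fit to any raw trace; within-group modulus variance in
  particular is an assumption (CV 0.10), not a measurement.
* Constitutive parameters are not estimated from experimental curves
  anywhere in the package — the rheology stage is descriptive, matching
  its scope.
* Color segmentation has no stain-vector deconvolution and no declumping;
  it is faithful to frame-level analyzer workflows, not to modern
  whole-slide pipelines.
* Significance testing is per variable; force-versus-strain band
  comparisons (a curve-level question) are out of scope.
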