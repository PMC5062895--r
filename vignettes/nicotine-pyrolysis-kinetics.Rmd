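---
title: "Kinetic modelling of nicotine destruction and formation in mainstream smoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of nicotine destruction and formation in mainstream smoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicokin)
```

## The problem

When a cigarette burns, the tobacco column acts as a flow reactor: a gas
parcel spends roughly one puff (~2 s) in a zone whose temperature sweeps
from a few hundred to nearly a thousand kelvin. Nicotine is both formed
(released from the tobacco matrix) and destroyed (pyrolysed, among other
routes to pyridine via a pyridinyl radical) in that window. Neither the
radical intermediate nor the instantaneous rates are observable; what a
GC--MS experiment gives is the *yield* of each analyte — an integrated
chromatographic peak area, in arbitrary "GC-area counts" — as a function of
the furnace temperature, or as a function of puff duration. Because
first-order kinetics only ever uses *ratios* of concentrations, area counts
work as concentration units without calibration.

`nicokin` turns those yield tables into kinetic parameters, and provides a
seeded generator of synthetic yield tables with known ground truth so every
stage of the analysis can be validated by parameter recovery.

## The destruction model

Above the temperature at which the yield of nicotine peaks, the yield
decline is attributed to pseudo-first-order destruction of a fixed
precursor pool \(C_0\):

\[ C(T) = C_0\, e^{-k(T)\,t}, \qquad
   k(T) = \frac{1}{t}\ln\frac{C_0}{C(T)}, \]

with \(t\) the residence time. The peak yield itself is taken as \(C_0\):
at the peak, the rates of formation and destruction balance, so the peak is
the best available estimate of the precursor pool fed into the destruction
regime. This "peak-as-\(C_0\)" convention is implemented in
`find_peak()`; ties on the maximum are broken toward the *lowest*
temperature (the earliest point at which the pool is full), and the choice
is logged in the result.

The per-temperature rate constants are then regressed as an Arrhenius plot,

\[ \ln k = \ln A - \frac{E_a}{R\,T}, \]

by unweighted ordinary least squares of \(\ln k\) on \(1/T\)
(`fit_arrhenius()`). With the handful of temperatures a pyrolysis sweep
provides there is no basis for weighting, and the plot-linearity itself is
part of what is being assessed (reported as \(r^2\)). Activation energies
are carried internally in J mol\(^{-1}\) against
\(R = 8.314\) J K\(^{-1}\) mol\(^{-1}\); only the report layer prints
kJ mol\(^{-1}\). Mixing the kJ-scale \(E_a\) with an SI \(R\), as informal
write-ups sometimes do, is a silent thousand-fold error this package rules
out by construction.

Because a strict \(\ln k\) vs \(1/T\) line rarely holds over a 300 K
window, the modified (Kooij-type) Arrhenius form

\[ k = A\,T^{\,n} e^{-E_a/(RT)} \]

is also supported. At a fixed temperature the exponent has the closed form

\[ n = \frac{\ln k - \ln A + E_a/(RT)}{\ln T}, \]

which is monotone in \(n\), so `solve_temperature_exponent()` needs no
iteration and round-trips exactly through `modified_arrhenius_k()`. The
pipeline reports \(n\) at every destruction-window temperature.

### Window selection and exclusions

Only points strictly above the peak temperature enter the destruction
window. A post-peak point whose yield is at or above \(C_0\) cannot be a
destruction observation (it would imply \(k \le 0\)); such points are
*excluded and logged*, never clamped — clamping would fabricate \(k = 0\)
values and bias the regression. `strict = TRUE` turns any exclusion into an
error. No smoothing or interpolation is applied before peak detection: with
~6--11 temperatures per sweep, smoothing would invent data.

The window-average rate constant is the arithmetic mean over the retained
points. Note that an average over an unstated temperature set is not
reproducible from its endpoints alone: the mean of 0.31 and 2.12 s\(^{-1}\)
is 1.215, so a published average of 1.11 s\(^{-1}\) implies intermediate
temperatures that were never tabulated. The package documents its
mean-over-window convention and does not attempt to match such a value.

## The consecutive reaction model

Destruction is modelled as a two-step series reaction

\[ \mathrm{Nic} \xrightarrow{k_1} \mathrm{I} \xrightarrow{k_2}
   \mathrm{Product}, \]

whose linear rate equations have the classical closed-form solution

\[ [\mathrm{Nic}] = N_0 e^{-k_1 t}, \qquad
   [\mathrm{I}] = \frac{k_1 N_0}{k_2 - k_1}
     \left(e^{-k_1 t} - e^{-k_2 t}\right), \]

with the product obtained from mass conservation,

\[ [\mathrm{Product}] = N_0 \left[1 +
   \frac{k_2 e^{-k_1 t} - k_1 e^{-k_2 t}}{k_1 - k_2}\right]. \]

One sometimes sees the product solution printed with a stray factor of
\(k_1\) inside the bracket; that variant violates
\([\mathrm{Product}](0) = 0\) and breaks conservation, so this package uses
the standard mass-conserving form above — its \(k_2 \ll k_1\) limit,
\(N_0(1 - e^{-k_2 t})\) (`product_simplified()`), is exactly the
rate-determining-step expression the inversion
`invert_k2_from_product()` is based on. Conservation
\([\mathrm{Nic}] + [\mathrm{I}] + [\mathrm{Product}] = N_0\) is enforced by
tests at \(10^{-9}\) relative at every time point, and all three closed
forms are cross-checked against numerical integration of the differential
system (`consecutive_trajectory()`, via `deSolve::lsoda` at
`rtol = 1e-10`) to \(10^{-6}\) relative.

This is the package's route to the unobservable intermediate: with \(k_1\)
from the destruction window, \(k_2\) from the product yield, and \(N_0\)
from the peak, `intermediate_at()` evaluates \([\mathrm{I}]\) at the
residence time. `derived_summary()` then reports the ratios practitioners
quote: product/precursor, precursor/(intermediate + product), and the
percentage of nicotine transferred intact,
\(100\,(1 - P_{max}/N_0)\).

```{r consecutive}
m <- consecutive_model(k1 = 1.11, k2 = 0.13, nic0 = 8.0e8, t = 2.0)
derived_summary(m, product_max = 4.4e8)
```

### A deliberate inconsistency, reported rather than hidden

For the ES1 cigarette the published inputs are internally inconsistent:
inverting the simplified product law with \(N_0 = 8.0\times10^8\),
\(P_{max} = 4.4\times10^8\) and \(t = 2\) s gives
\(k_2 = -\ln(0.45)/2 \approx 0.40\) s\(^{-1}\), not the quoted
0.13 s\(^{-1}\) (which coincides numerically with the *formation* rate
constant). The package computes and reports both numbers and forces no
agreement; when reproducing the quoted intermediate concentration it uses
the quoted 0.13 as the input, since that is how the value was derived.
Similarly, the ES1 exponent at 673 K recomputes to \(n \approx 0.572\) from
the printed \(k = 0.31\), \(A = 2.1\times10^6\), \(E_a = 108.85\)
kJ mol\(^{-1}\), slightly above the printed 0.55 — a consequence of rounding
in the printed inputs; the recomputed value is what the package reports.

## Formation kinetics

At fixed furnace conditions, yields measured at increasing puff durations
(2, 5, 10 s) decay approximately exponentially: longer residence promotes
secondary reactions that consume nicotine. `fit_formation()` regresses
\(\ln(\text{yield})\) on puff time; the negative slope is the formation
rate constant and the exponentiated intercept is the amount extrapolated to
zero puff time — the "original" nicotine amount, directly comparable (via
`compare_initial_amount()`) to the peak \(C_0\) of the temperature sweep.
The regression is deliberately on logged *amounts*: that is the only
reading under which the intercept is an amount, even though such plots are
sometimes labelled as if rate constants were on the ordinate. Puff times
are absolute durations, not cumulative counts, and with three points no
weighting is attempted.

## The synthetic generator

`synthetic_config()` describes a simulated pyrolysis sweep with known
ground truth. The noise-free curve is piecewise:

* below the peak temperature, a normalized saturating formation ramp
  \(\propto 1 - e^{-k_f(T)\,t}\), with \(k_f\) Arrhenius
  (default \(E_a = 60\) kJ mol\(^{-1}\), \(A = 4.5\times10^4\)
  s\(^{-1}\), chosen so the ramp rises visibly across 473--673 K);
* at the peak (default 673 K, where ES1 nicotine peaks; 773 K for the SM1
  fixture), the yield equals the pool `y_scale` — the \(C_0\) convention;
* above the peak, the surviving pool \(C_0 e^{-k_d(T)\,t}\), with \(k_d\)
  from the destruction Arrhenius parameters.

This shape was chosen over the superficially attractive fully
multiplicative form
\(y\,(1 - e^{-k_f t})\,e^{-k_d t}\) for an identifiability reason: the
estimator defines \(C_0\) as the *observed peak yield*, so under the
multiplicative form the recovered rate constants are
\(k_d(T) - k_d(T_{peak})\) plus a residual formation term, and the
generating \(E_a\) is *not* recoverable even from noise-free data (the
bias is several percent on the default grid, concentrated at the window's
low-temperature end). A generator whose destruction branch is exactly the
survival model the estimator assumes makes the noise-free end-to-end
round trip an identity — the test suite checks recovery of
\((E_a, A)\) to numerical precision for both fixtures — while still
realizing all three qualitative assumptions of the peak model: formation
prevails below the peak, the rates balance at the peak, destruction
overwhelms formation above it.

Noise is multiplicative lognormal with median 1 and relative standard
deviation `noise_sd` (GC-area counts are positive and heteroscedastic;
additive Gaussian noise would be neither), applied with
`withr::with_seed` so the global RNG stream is untouched. A single integer
seed drives everything; replicate \(r\) uses the documented sub-seed
`seed + 7919 * (r - 1)` (mod \(2^{31}-2\)). The default
`noise_sd = 0.02` reflects the few-percent repeatability of averaged
replicate GC injections.

What the generator does **not** emulate: the true (unknown) peak sharpness
of real sweeps; independent formation routes to pyridine (real
intermediate+product sums can exceed the nicotine pool, which is why the
precursor/(I+product) ratio is informative); oxygen chemistry; baseline or
integration artefacts of chromatograms. Passing recovery tests therefore
demonstrate the *estimator* is correct and stable, not that real smoke
obeys the model.

### What recovery can and cannot achieve at t = 2 s

One property of the study conditions deserves emphasis. Just above a 673 K
peak, the destruction rate is small — \(k(723\,\mathrm{K})\,t \approx
0.06\) for the ES1 parameters — so a 2 % yield error is roughly a 35 %
relative error in that point's rate constant, and the Arrhenius slope
inherits an \(E_a\) standard deviation near 8--9 %. The acceptance suite
measures this directly: over 100 seeded replicates at `noise_sd = 0.02`
roughly half recover \(E_a\) within 5 %. That is a structural property of
two-second residence kinetics near the peak, not an implementation defect;
noise-free recovery is exact, and the median recovery error is verified to
grow monotonically with the noise level.

## Numerical choices

* **Equal rate constants.** The intermediate and product formulas divide by
  \(k_2 - k_1\); when \(|k_1 - k_2| \le 10^{-6}\max(k_1,k_2)\) the code
  switches to the analytic limits \(N_0 k t e^{-kt}\) and
  \(N_0[1-(1+kt)e^{-kt}]\). Continuity across the switch is tested at a
  relative gap of \(10^{-8}\).
* **Time of maximum intermediate.** \(\ln(k_1/k_2)/(k_1-k_2)\), symmetric
  in its arguments, with limit \(1/k\); confirmed against a grid search on
  the integrated trajectory.
* **Flat fits.** A table of identical rate constants has zero total sum of
  squares; the regression is exact, so \(r^2\) is defined as 1 (and
  \(E_a = 0\), \(A = k\)).
* **Unit boundary.** Celsius input is converted with the exact offset
  273.15 at the I/O layer; everything internal is kelvin. (Nominal
  "400 °C = 673 K" equalities common in this literature are 0.15 K off;
  reports carry the exact values.)
* **Determinism.** Counts are never rounded internally; JSON reports are
  serialized at full precision with fixed formatting, so identical inputs
  produce byte-identical reports, and the markdown rendering regenerated
  from a report JSON is identical to the one written alongside it.

## Problem sizes

The shipped tests and the acceptance script use the sizes of the emulated
experiment: 11-point temperature grids (473--973 K in 50 K steps), 3-point
puff series (2, 5, 10 s), 100 seeded replicates for the noisy
\(E_a\)-recovery study, 500 for the formation-rate noise study, and
\(10^3\)-point time grids for the trajectory cross-checks. The full suite
runs in well under a minute on one CPU.

## Limitations

Beyond the generator caveats above: the pipeline fits a single global
pseudo-first-order destruction channel (no multi-peak deconvolution, no
isoconversional analysis, no heating-rate dependence); regression
uncertainty is summarized by \(r^2\) only, with no error propagation onto
derived ratios; and the SM1 fixture's precursor pool is an assumption (one
tenth of ES1, matching the ~10-fold total-nicotine difference between the
two cigarettes), because no SM1 pool value was ever published — quantities
that depend on it are flagged accordingly and are not reproduction targets.
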