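---
title: "Single-marker quantification of Panax vietnamensis saponins: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of Panax vietnamensis saponins: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsvg)
```

## The problem

Quality control of Vietnamese ginseng (*Panax vietnamensis*, VG) requires
quantifying saponins from three skeleton classes — protopanaxadiol
(G-Rb1, G-Rd), protopanaxatriol (G-Rg1) and ocotillol (majonoside R2,
vina-ginsenoside R2) — but reference standards for every analyte are
expensive and, for the ocotillol saponins, hard to source. The
single-marker approach (QAMS, *Quantitative Analysis of Multi-components
by Single-marker*) replaces per-analyte external standards with one (or
two) markers plus fixed *relative conversion factors* relating each
analyte's detector response to the marker's. This package implements that
calculus for the two detectors involved, together with the
external-standard method (ESM) it is validated against.

## Response models

The two detectors respond in different domains:

* **PDA** (photodiode array): linear, `A = a·C + b`, with `C` in mg/mL.
  Requires a chromophore, so V-R2 (no side-chain double bond) is
  invisible here.
* **ELSD** (evaporative light scattering): a power law, fitted as a
  straight line in log-log coordinates, `log10 A = a·log10 C + b`, with
  `C` in **µg/mL**. All five saponins respond; G-Rd is excluded
  downstream because its curve linearity and working concentration are
  inadequate.

The µg/mL convention for ELSD is load-bearing: the inverse formula
`C = 10^((log10 A − b)/a − 3)` carries the `−3` exactly because the curve
was fitted in µg/mL and results are reported in mg/mL. Changing the
fitting unit shifts a log-log intercept by `3·a` and leaves the slope
untouched; the test suite pins this algebra down, and base-10 logs are
used throughout (natural logs would break the `−3`).

## Conversion factors and the quantification identities

Two constructions of the conversion factor `F_x` are implemented:

* **slope ratio**: `F_x = a_x/a_s`, from the two fitted calibration
  slopes;
* **response ratio**: the arithmetic mean over matched dilution levels of
  `(A_x/C_x)/(A_s/C_s)` (linear domain) or
  `(log10 A_x/log10 C_x)/(log10 A_s/log10 C_s)` (log domain).

Matched-level pairing — level *i* of the analyte series against level *i*
of the marker series — with an arithmetic mean over the six levels
reproduces the published log-domain factors for this system at two
decimals (0.94, 0.93, 1.04), which is the main evidence that this is the
right reconstruction of the response-ratio definition.

Quantification then proceeds per analyte either by the analyte's own
curve (ESM) or from a fresh marker measurement `(A_s, C_s)`:
intercept-free (`C_x = A_x·C_s/(F·A_s)` and its log-domain analogue) or
intercept-corrected, using the stored intercepts of previously
established curves (`C_x = (A_x − b_x)·C_s/((A_s − b_s)·F)` and its
log-domain analogue). Contents are reported as percent dry weight,
`H(%) = V·C/m·100` (V = 5 mL, m = 100 mg by default).

**The central identity.** When `F` is the slope ratio, the stored
intercepts come from the same curves as `F`, and the marker's
concentration is itself read off the marker's own curve, the
intercept-corrected QAMS equations collapse algebraically onto the ESM
equations — the standard method difference (SMD,
`|H_ESM − H_QAMS|/H_ESM·100`) is zero to machine precision, for every
analyte/marker pairing and in both domains. The intercept-free
equations do not enjoy this identity: for cross-compound pairings they
carry a systematic bias (of order 10–40% in this system, largest where
intercepts are large relative to the signal), which is why the
slope-ratio/intercept-corrected route is the recommended operating mode
and the intercept-free route serves as the contrast.

**Where the marker measurement comes from.** By default
`quantify_samples()` takes the marker's *own peak in the same
chromatogram* as the fresh single-marker measurement, converting its area
through the marker's stored curve — the one curve a single-marker
practitioner actually possesses. This choice makes the marker's QAMS
result coincide exactly with its ESM result (replicating the `0.00`
SMD behaviour of the marker columns even under noise) and is what a lab
applying this method would do: marker and analytes are in the same
injection. An external standard observation can be supplied instead via
`marker_obs`, which reintroduces marker-measurement noise and day-drift
into the QAMS result; SMD then becomes nonzero in proportion to the
drift between the stored curves and the fresh measurement.

## The synthetic-data generator

No instrument data ship with the package; the generator provides data
with the statistical structure the analysis assumes:

* **Dilution design**: six levels, factor 0.75, per-compound stock
  concentrations (0.36, 0.17, 1.39, 2.30, 0.81 mg/mL for G-Rb1, G-Rd,
  G-Rg1, M-R2, V-R2) — the lowest level reproduces the calibrated-range
  lower bounds of the reference curves at two decimals.
* **Truth**: the bundled regression parameters
  (`vg_reference_calibration()`) act as the generating response curves.
* **Noise**: Gaussian in the domain in which each detector is fitted —
  additive on area for PDA, additive on log10(area) for ELSD (hence
  multiplicative on area, keeping ELSD areas strictly positive). The
  `noise_rel` convenience maps a relative spread (default 2%, matching
  the 0.3–3% replicate RSDs typical of this assay) onto each domain. For
  PDA the relative noise scales the *net* response `a·C` above the
  intercept: the fitted intercepts of this system are large relative to
  the in-range signal term (they represent a baseline contribution, not
  analyte response), and scaling noise by the gross area would imply
  concentration RSDs of tens of percent, inconsistent with any working
  assay. This makes PDA calibration noise heteroscedastic across levels,
  which is physically realistic and is accounted for where the tests
  check sampling distributions.
* **Sample truth**: default contents (1.46, 0.96, 3.96, 5.51, 2.67% dry
  weight) sit at the center of the reported ranges for this material;
  they map to solution concentrations through the inverse of the content
  formula. G-Rd's nominal content corresponds to a concentration
  slightly above its calibrated range; results are flagged out-of-range
  but never clamped, mirroring how such exclusions are handled in
  practice.
* **Day drift**: an optional multiplicative per-(day, compound) response
  factor. Real inter-day variability has no published mechanism or
  magnitude for this assay; drift is therefore a free knob (default
  off), used to study how stored-parameter mismatch inflates SMD.
* **Spikes**: exact 0.8/1.0/1.2 multiples of the nominal content, three
  preparations per level (nine records per compound).

What the generator does **not** emulate: chromatographic peak shapes,
retention behaviour, integration error, carry-over, matrix effects, or
any correlation between compounds within an injection. Passing tests on
these data therefore demonstrate the correctness of the calculus and the
internal consistency of the method chain, not instrument-level
robustness.

## Calibration diagnostics

Fits are unweighted ordinary least squares in each detector's fitting
domain (weighting is never mentioned for this assay, and the narrow
0.75^5 ≈ 4.2-fold range gives weighting little leverage). The linearity
statistic reported is the correlation coefficient *R*, not *R²*.
LOD/LOQ use the residual-SD formulation (3.3·s/a and 10·s/a) — with no
raw noise traces in the data model, a signal-to-noise construction is not
available; for log-log fits the s/a ratio is formed in the log domain and
converted under the fit's µg/mL convention. These estimates are
convention-dependent and are treated as diagnostics, not as reproductions
of any published limit. Replicate structure for calibration is a single
injection per level per day; the published curves give no within-day
replication to emulate.

## Validation battery

* **Precision**: RSDs per (compound, detector, method) — intra-day per
  (day, lab) cell; inter-day and inter-laboratory on the pooled
  individual replicates (the simplest reading of a 2×6 design; RSD of
  cell means is available via `pooled = FALSE`). Note the Bessel factor:
  pooling two identical six-replicate days gives √(10/11) times the
  within-day sample RSD, so "equal sets ⇒ equal RSD" holds only
  approximately.
* **Recovery**: `(found_spiked − found_base)/added·100`, the standard
  spiked-standard formulation, computed per spiked record against the
  mean base content of the same compound/detector/method.
* **Method comparison**: SMD per replicate, then mean ± SD per
  (compound, detector, QAMS variant) with a 5.00% pass rule. Averaging
  per-replicate SMDs is deliberate (it differs from the SMD of mean
  contents in the second decimal), and matches how the ± columns behave
  in the published comparisons.

## Problem sizes and determinism

The default workflow simulates 3 calibration days × (4 + 4) curves × 6
levels, 6 sample replicates and 36 spiked records per detector — a few
hundred rows, fitting and quantifying in well under a second. Every
random draw descends from one integer seed in the scenario or config;
identical seeds give bit-identical peak tables, and the pipeline bundle
carries an MD5 hash of its configuration so artifacts can be traced to
the exact settings that produced them.

## Known limitations

* The intercept-corrected equations consume *stored* analyte intercepts;
  if the stored curves come from a different day than the sample
  measurement and the response has drifted, slope-factor QAMS degrades
  gracefully but is no longer exact — the inter-day factor provenance
  (`fx_provenance = "inter_day_mean"`) quantifies this.
* The log-domain QAMS equations are sensitive to factor error: a
  relative error ε in `F` propagates to roughly `ln(10)·log10(C_µg)·ε`
  relative error in concentration (about 7ε at 1 mg/mL), so inter-day
  averaged factors on the ELSD need tight day-to-day slope
  reproducibility.
* The response-ratio factor in the *linear* domain divides by gross
  specific response `A/C` including the intercept; for curves whose
  intercept dominates the in-range signal this construction is unstable
  and is retained only as the documented contrast to the slope-ratio
  route.
* Purity correction of standard concentrations (certified purities
  0.9448–0.9917) is available (`purity_correct()`, config flag) but off
  by default; whether published stock concentrations are purity-corrected
  is not stated, so the package follows the nominal reading.
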