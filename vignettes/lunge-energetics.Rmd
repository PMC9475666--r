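---
title: "Lunge-feeding biomechanics and energetics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lunge-feeding biomechanics and energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungeforge)
```

## The problem

A rorqual foraging lunge is a burst event: several seconds of powered
acceleration toward a krill patch, mouth opening near maximum speed, a
steep deceleration of order 1–5 s while the buccal cavity engulfs a water
mass that can exceed the whale's own body mass, mouth closure, and a slow
recovery. From a 10 Hz animal-borne tag record (depth, body pitch, forward
speed, y-axis gyroscope) plus aerial morphometrics of the same individual,
`lungeforge` estimates what each lunge engulfed, what it cost, what it
returned, and how all of those scale with body size.

## Kinematic segmentation

Field protocols pick six event times per lunge, traditionally with analyst
assistance. The package's detector is a reproducible proxy for those picks:

1. **Candidate decelerations** are maximal runs where the 0.5 s-smoothed
   speed slope falls below −`a_thresh` (default 0.35 m s⁻²); candidates
   must drop at least 0.6 m s⁻¹, last at least 0.3 s, and be preceded by a
   ≥0.6 m s⁻¹ speed rise within 15 s (the standard
   accelerate-then-decelerate profile; anything else is rejected).
2. **Mouth opening and closure** (`T_MO`, `T_MC`) are corners of the speed
   trace. Coarse guesses come from fractional-steepness crossings walking
   out from the steepest point of the run; refinement uses iterated
   two-line intersection fits, which are unbiased for a corner between
   near-linear segments even after smoothing, followed by a joint
   piecewise-linear fit of the deceleration / post-closure decline /
   recovery triplet on the raw speed.
3. **Maximum speed** (`T_max`) is the corner between the fluking ramp and
   the optional adjustment phase, found by a hinge scan with a second hinge
   fixed at the known `T_MO` (continuity lets the deceleration data pin the
   gentle adjustment line). When no corner passes the significance gates
   the lunge has no adjustment phase and `T_max = T_MO`; ties in the
   earliest-maximum search break to the earliest sample.
4. **Acceleration onset** (`T_accel`) is the glide-to-ramp corner. The
   ramp carries a tailbeat speed ripple, so the ramp-side arm regression
   includes sine/cosine columns at the tailbeat period (estimated from the
   gyro), which absorb the ripple exactly rather than letting it tilt the
   fitted line.
5. **Fluking onset** (`T_fluke`) comes from the gyro amplitude envelope:
   the last quiet span of at least 1.5 s ending near `T_accel` marks the
   glide, and the onset is refined by phase back-extrapolation of the first
   stroke (the crossing level and stroke amplitude give the elapsed phase).
6. **The speed minimum** (`T_min`) is searched within a fixed 5 s window
   after `T_MC` (the field protocol's definition) and refined as the V
   corner between the post-closure decline and the recovery.
7. **The final oscillation** is the last zero-crossing-bounded gyro cycle
   of significant amplitude (two opposite-sign half-cycles with peaks above
   0.1 rad s⁻¹) intersecting `[T_MO, T_MC]`, refined by a single-cycle
   sine fit.

Masked data gaps longer than 1 s split the trace; shorter gaps are bridged
by interpolation and never contribute events. All thresholds live in
`detection_thresholds()` and every random choice in the package flows from
an explicit integer seed.

## Engulfment model

The gape schedule is prescribed: linear opening to `max_gape` (default 75°)
over the first third of ΔT_decel, a plateau, and linear closing over the
final third. The posterior volume integrates the projected mouth area
times speed from mouth opening to maximum gape,

`V_pos = ∫ U(t) A_jaw sin(G(t)) dt`,

with the integration endpoint `T_MG = T_MO + ΔT_decel/2` (maximum gape
"halfway through engulfment"). The schedule holds maximum gape over the
middle third, so a defensible alternative endpoint is `2ΔT_decel/3`; the
`vpos_end` switch exposes that reading, and the default follows the
halfway definition. The anterior volume is the ellipsoid wedge
`V_ant = 2π W_bz L_rbh²/3 · 75/360`, evaluated exactly as printed even
though a "two quarter-ellipsoids" description would suggest a different
prefactor; the printed formula is the authority. Engulfed mass is
`M_W = ρ V_total` with seawater density ρ = 1025 kg m⁻³ (configurable; the
source text does not state a value).

Jaw area can come from direct aerial measurement or the isosceles-triangle
model `(W_bz L_rbh/2) · O_jaw` with the jaw-rotation factor O_jaw = 1.0514
(a 5.14% outward-rotation offset). Direct measurement is preferred when
present; a flag overrides.

## Energetics

Work terms are computed in joules and converted to kJ exactly once each:

- fluke work `W_flukes = ½(1+k) M_kg (U²_MO − U²_MC) + W_parasite`, with
  the added-mass coefficient k = 0.05 for humpbacks and 0.03 otherwise.
  The printed equation uses the mouth-opening/closure speed pair even
  though it describes acceleration-phase work; the package implements it
  verbatim by default and offers `accel_speed_pair = "max_accel"` to
  substitute (U_max, U_accel).
- parasitic work: the flat-plate-with-form-factor expression, evaluated
  verbatim with `Re_MO = U_MO L_body/ν` and ν = 1.05 × 10⁻⁶ m² s⁻¹. At the
  (out-of-domain) point U_MO = U_MC the continuous limit is returned.
- VGB work `W_VGB = ½ M_W U_MO U_MC (1 + U_MC/U_MO)`, independent of body
  mass at fixed engulfed mass (the body-mass factors cancel algebraically,
  and a test asserts it).
- ceteral term: the basal expenditure of tissues outside the locomotor and
  engulfment musculature, `f_Met · 4.1 · M_kg^0.75`. **Interpretation:**
  this Kleiber-form quantity is treated as a *rate in watts* and multiplied
  by the lunge duration (ΔT_accel + ΔT_decel). Treating it as a total in
  kJ — a reading the source text permits typographically — produces a
  ceteral cost several times the *total* published per-lunge cost for
  every species (e.g. ≈5,570 kJ against a published minke total of
  ≈835 kJ), so the rate reading is the only physically consistent one.
  f_Met defaults to 2 (a field-metabolic multiple of basal; the source
  value is uncited) and is configurable.

Phase costs are `E_accel = W_flukes/(μ_prop μ_met)` and
`E_decel = W_VGB/μ_met` (the deceleration-phase fluke term is omitted, as
in the source model), with μ_prop = 0.80 and μ_met = 0.25. Total cost is
either `E_accel + E_decel + cet` (`cost_mode = "ceteral"`, the default) or
the averaged approximation `1.5 (E_accel + E_decel)`.

Gain is `E_gain = M_W E_prey μ_prey` with digestive efficiency
μ_prey = 0.84. The default prey energy content per kg of engulfed water,
`E_prey` = 3.01118 kJ kg⁻¹, is calibrated with
`calibrate_prey_density()` so the minke species-mean engulfed volume
reproduces the minke species-mean gain; that single calibration then
predicts the humpback, fin, and blue species-mean gains within 0.5%
(asserted in the acceptance suite).

Dive- and day-scale efficiencies multiply per-lunge gain and cost by the
lunge count and add the ceteral rate times the non-lunging seconds — a
direct consequence of the rate interpretation above, with no auxiliary
"reference duration" needed. Daily lunge counts are configuration
(defaults minke 1000, humpback 300, fin 250, blue 200 — order-of-magnitude
values in line with published daily feeding rates; they only enter the
day-scale ratio).

## Allometric defaults

Body mass, VGB length, and wetted area are power laws of body length whose
coefficients the source cites to external literature without printing.
Shipped defaults are explicit calibrations:

- mass exponents are within-species log-log slopes through the published
  per-species length and mass range endpoints (minke 1.83, humpback 2.34,
  blue 3.54; the single fin whale uses the 2.06 cross-species slope), each
  anchored so the species-mean length reproduces the species-mean mass
  exactly. A single cross-species line misses the minke mean by 17%, and a
  shallow cross-species exponent applied within species makes large
  individuals too light relative to their engulfment capacity, flipping
  force-residual signs.
- `L_VGB = 0.45 L` (isometric; the VGB spans roughly 45–55% of a rorqual).
- `S_wet = 0.08 M^0.65` (the standard cetacean wetted-area relation),
  re-expressed per species as a power of length through the mass relation.

Provenance strings in `default_allometry()` mark all of these as
calibration defaults.

## The synthetic world

`simulate_deployment()` builds what a krill-feeding deployment looks like:
surface interval, steep descent, a bottom phase of lunges, ascent. Each
lunge is a glide (4–6 s, slightly decelerating — an unpowered glide cannot
gain speed), a fluking ramp with a sinusoidal speed ripple (0.15 m s⁻¹ at
the tailbeat frequency, which scales as 1/L against a 0.25 Hz blue-whale
anchor) and matching gyro tailbeats, an optional gently-decelerating
adjustment phase, a linear steep deceleration spanned by a single
long-period gyro oscillation, a post-closure decline to the speed minimum,
and a brief recovery stroke. Channel noise is Gaussian (depth 0.05 m,
speed 0.05 m s⁻¹, gyro 0.02 rad s⁻¹). Draws are truncated at ±3 sd and
physical floors. Everything is bit-reproducible from (profile, seed).

Species profiles are calibrated to the published species means where those
exist (body length, jaw areas, U_MO, phase durations, final-oscillation
periods, per-species mass ranges). Three generator choices deserve
explicit justification:

- **Mouth-closure speed.** The published table's post-lunge minimum speeds
  are incompatible with the published force-residual statistics for the
  three large species: with the tabulated masses and engulfed volumes,
  momentum balance requires U_MC ≈ 1.5–2.0 m s⁻¹, not ≥ 2.5. Profiles
  therefore set U_MC from residual/momentum consistency (minke 3.28,
  humpback 1.52, fin 1.97, blue 1.65 m s⁻¹), which reproduces the
  published residual signs (minke negative, humpback/blue positive, fin
  near zero) as emergent behaviour of the pipeline.
- **Fluking ends half a tailbeat before maximum speed**, consistent with
  the field observation that the final full tailbeat completes just before
  mouth opening.
- **A recovery stroke after the minimum.** The speed minimum is defined as
  a minimum within 5 s of mouth closure, so the stated world must contain
  a genuine local minimum; a brief +0.3 m s⁻¹ recovery over 1.5 s provides
  it (for minke, whose closure speed exceeds cruise speed, a monotone
  decline would leave the event undefined).

What a green test on this world establishes: that the estimators recover
known structure under realistic noise, timing, and allometry. What it does
not establish: performance on real tags with orientation artefacts,
speed-sensor biases, non-Gaussian noise, prey-driven behavioural
modulation of gape or timing, or fish-feeding kinematics — none of which
the generator emulates.

## Numerical choices

- Engulfment integrals use the trapezoid rule on the native 10 Hz grid,
  with nodes inserted exactly at the gape-schedule phase boundaries and
  the integration endpoint (the integrand is only piecewise smooth, and
  letting a trapezoid cell straddle the kink costs up to ~0.5% on short
  decelerations). A 1000 Hz adaptive-quadrature oracle bounds the error in
  tests.
- Breakpoint estimators never trust a single noisy crossing: corners are
  refined by arm regressions and SSE scans as described above; extrema
  ties break to the earliest sample.
- The `T_min` search window is fixed at 5 s after `T_MC`.
- All randomness (morphometric draws, lunge draws, noise, middle-lunge
  sampling, bootstrap) is governed by explicit integer seeds, and seeded
  helpers restore the caller's RNG state.

## Known limitations

- At the stated 0.05 m s⁻¹ speed noise, several kinematic corners of the
  large species have slope contrasts of only 0.2–0.3 m s⁻², for which even
  a full maximum-likelihood piecewise fit has ~0.1–0.15 s breakpoint
  uncertainty. Recovering *all six* event times within ±0.2 s therefore
  succeeds for ~95% of minke lunges but only ~60–75% of humpback, fin, and
  blue lunges; detection itself (and mouth-opening timing) is essentially
  always successful. The acceptance suite states the strict joint
  criterion and reports it honestly.
- The published per-species lunge-scale efficiency means are means of
  per-lunge ratios and cannot be recovered from the published mean costs
  and gains alone; no target is placed on them.
- The published minke final-oscillation statement ("344% longer" than a
  0.67 s deceleration, yet a 2.29 s mean period) cannot be reconciled
  internally; the generator uses the printed period means.
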