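# lungeforge

Biomechanics and energetics of rorqual lunge feeding, from animal-borne tag
kinematics and aerial morphometrics to per-lunge energy budgets and
allometric scaling.

Rorqual whales (Balaenopteridae) feed by lunging: they accelerate toward a
krill patch, open the mouth at high speed, engulf a prey-laden volume of
water comparable to their own body volume, decelerate sharply as the
ventral groove blubber (VGB) inflates, then filter. `lungeforge` implements
the full analysis chain a biologging study of this behaviour needs:

- **Kinematic segmentation.** A 10 Hz tag trace (time, depth, pitch,
  forward speed, y-axis gyroscope) is segmented into lunges. For each lunge
  the six canonical event times and speeds are extracted — fluking onset
  `T_fluke`, start of steep acceleration `T_accel`, maximum speed `T_max`,
  mouth opening `T_MO`, mouth closure `T_MC`, and the post-lunge speed
  minimum `T_min` — along with the three phase durations
  (ΔT_accel, ΔT_adjust, ΔT_decel), the travel distance during engulfment,
  and the long-period gyroscope oscillation (`T_gyr1..3`, ΔT_finOs) that
  spans the deceleration. Lunges are classified by position in their dive
  and "middle" lunges (neither first, last, nor solitary) are randomly
  sampled for unbiased kinematic means.
- **Engulfment model.** The mouth opens linearly to a 75° gape over the
  first third of ΔT_decel, holds, and closes over the last third. The
  engulfed volume is `V_total = V_pos + V_ant` with
  `V_pos = ∫ U(t) · A_jaw sin G(t) dt` from mouth opening to maximum gape
  and `V_ant = 2π W_bz L_rbh² / 3 · 75/360` (ellipsoid wedge). Engulfed
  mass `M_W = ρ V_total`, engulfment drag `D_engulf = M_W U_MC / ΔT_decel`,
  and the force residual
  `D_shape − Th = M_kg (U_MO − U_MC)/ΔT_decel − D_engulf` diagnose whether
  shape drag or residual tail thrust dominates the deceleration.
- **Energetics.** Per-lunge metabolic cost combines fluke work
  `½(1+k) M (U²_MO − U²_MC)` plus parasitic drag work, VGB work
  `½ M_W U_MO U_MC (1 + U_MC/U_MO)`, the efficiencies μ_prop = 0.80 and
  μ_met = 0.25, and a Kleiber-form ceteral term `f_Met · 4.1 · M^0.75` (W).
  Gain is `E_gain = M_W E_prey μ_prey` and foraging efficiency
  `FE = E_gain/E_cost` is evaluated at lunge, dive, and day timescales.
  The minimum momentum speed
  `U_mom = sqrt(2 L_VGB (U_MO − U_MC)/ΔT_decel)` gives the slowest lunge
  that can fill the buccal cavity on momentum alone.
- **Scaling.** log₁₀–log₁₀ OLS regressions of any output against body
  length or speed, with slope-equality tests between fits.
- **Synthetic deployments.** A seeded generator builds multi-dive tag
  deployments with known ground truth, calibrated to published
  species-level means for Antarctic minke, humpback, fin, and blue whales,
  so the entire pipeline is testable without field data.

## Worked example

```r
library(lungeforge)
deps <- simulate_cohort(c(minke = 2, humpback = 2, blue = 2),
                        n_dives = 3, seed = 42)
tab <- analyze_cohort(deps, seed = 42)
summarize_individuals(tab)
```

```
     individual_id  species n_lunges U_MO dT_decel V_total E_cost E_gain   FE
1     blue_sim0576     blue        3 3.89    4.381   93.91   5469 243486 44.7
2     blue_sim6056     blue        4 3.97    4.432   83.05   4618 215323 46.7
3 humpback_sim4506 humpback        9 3.34    2.987   25.61   1205  66387 55.4
4 humpback_sim7924 humpback        1 3.27    2.970   17.12    847  44380 52.4
5    minke_sim2037    minke        9 4.44    0.680    3.22    479   8345 17.5
6    minke_sim5497    minke       13 4.36    0.967    4.10    527  10625 20.5
```

Each row is one synthetic individual: mouth-opening speed (m s⁻¹),
deceleration duration (s), engulfed volume (m³), per-lunge cost and gain
(kJ), and lunge-scale foraging efficiency. Minke whales engulf a few m³ and
recover ~20× their lunge cost; blue whales engulf ~80–90 m³ and, despite
costs an order of magnitude higher, recover ~45×: efficiency rises with
body size. Fitting the allometries on this cohort:

```r
tab$L_body <- sapply(deps, function(d) d$morph$L_body)[
  match(tab$individual_id, sapply(deps, function(d) d$morph$individual_id))]
loglog_ols(tab$L_body, tab$E_gain)
loglog_ols(tab$L_body, tab$E_cost)
loglog_ols(tab$L_body, tab$FE)
```

```
<loglog_fit> log10(E_gain) = 3.147 log10(L_body) +1.230  (R^2 0.941, p 2.24e-24, n 39)
<loglog_fit> log10(E_cost) = 2.159 log10(L_body) +0.774  (R^2 0.988, p 2.61e-37, n 39)
<loglog_fit> log10(FE)     = 0.988 log10(L_body) +0.456  (R^2 0.555, p 5.26e-08, n 39)
```

Energetic gain scales much faster with body length than cost, so foraging
efficiency has a positive allometric exponent (the difference of the two
slopes, exactly) — the energetic advantage of being a large engulfment
filter feeder.

## Command line

```sh
lungeforge simulate --species blue --seed 7 --n-dives 3 --out sim/
lungeforge detect   --trace sim/blue_sim0007.csv --seed 1 --out det/
lungeforge analyze  --species minke,blue --n-per-species 2 --seed 5 --out run/
lungeforge stability --species minke --seed 1 --out stab/
```

`analyze` writes `lunges.csv`, `energetics_by_individual.csv`,
`regressions.csv`, the resolved `config.json`, and a `MANIFEST`.

## Vignette

`vignettes/lunge-energetics.Rmd` documents the model assumptions, the
parameter defaults and their provenance, what the synthetic-data generator
does and does not emulate, and the package's numerical choices and known
limitations.
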