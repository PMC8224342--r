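---
title: "Comparing thermal comfort indices for sow housing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing thermal comfort indices for sow housing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowtherm)
```

## The problem

Heat stress depresses sow fertility, milk yield and survival, and the index
used to quantify it decides when a barn's ventilation or cooling intervenes.
Many scalar indices are in use: eight historical variants of the
temperature-humidity index (THI1-THI8), the black globe-humidity index
(BGHI), effective temperature (ET, calibrated for growing pigs), the
equivalent temperature index of sows (ETIS), and moist-air enthalpy (H).
They weight temperature, humidity and (in two cases) air velocity very
differently, so they disagree about which environments are equivalent.
`sowtherm` implements all twelve on a common interface and compares them
four ways: an equivalent-temperature-change analysis, velocity response
curves, iso-index lines on the psychrometric plane, and a ranking against
per-sow convective heat dissipation in a simulated barn.

## The indices and their inputs

Every index is a closed-form function of the dry-bulb temperature $T$
(degC), relative humidity $RH$ (%), and for ET/ETIS the air velocity $v$
(m/s); H additionally divides by barometric pressure $P_m$ (mmHg, default
760, a standard atmosphere — no source value is stated for it). Wet-bulb,
dew-point and black-globe temperatures inside the formulas come from three
empirical regressions:

* dew point: $(0.198 + 0.0017T)\,RH + 0.84T - 19.2$ — linear, finite even
  at $RH = 0$ (physically wrong in that limit, but the index definitions
  use it as printed);
* wet bulb: a rational fit, one cubic numerator over one cubic denominator,
  evaluated as a single fraction (this reading gives 18.28 degC at
  22 degC / 70 % RH, a realistic value, and reproduces the downstream THI8
  results; splitting the fraction does not). The fit can exceed the
  dry-bulb temperature by a few tenths of a degree near saturation;
* black globe: $0.567T + 0.393e + 3.94$ with Magnus-form vapour pressure
  $e$.

The fits are applied inside a declared validity window of $[-10, 50]$ degC;
outside it every conversion warns rather than errors, since the regressions
are merely uncalibrated there, not undefined.

Two formula readings deserve comment, because the published typography is
ambiguous:

* **ET** is evaluated as
  $T + 0.0015\,(RH-50)\,T - (42 - T)(v^{0.66} - 0.2^{0.66})$. This
  parenthesisation reproduces the winter reference value (21.2 degC at
  10 degC / 60 % / still air) and both published crossing-velocity ranges,
  so it is adopted.
* **ETIS** is evaluated literally, including the term
  $-4.79\,(1.0086 \cdot 38 - T)$ as a product (not $1.0086^{38-T}$) and the
  additive quartic radiation term
  $4.8957\times10^{-8}\,(311.15^4 - (T+273.15)^4)$. The literal reading
  reproduces the winter reference (18.56 vs the published 18.6), the upward
  velocity slope at 40 degC, and the steep growth of the
  equivalent-temperature change toward 40 degC. Whether the originating
  index definition intended an exponent is unknowable from this source; the
  exponent reading produces values nowhere near the published ones.

Six indices carry published heat-stress threshold zones (THI1, THI2, THI3,
THI5, THI6, ETIS); `classify_index()` encodes the printed intervals exactly,
including boundary openness and the published *gap* in the THI5 table
(78-83 classifies as `"unclassified"` rather than being interpolated). The
single THI3 rule is printed against the symbol THI2 but sits in the THI3
row; it is read as THI3.

```{r indices}
compute_all_indices(22, 70, vel_ms = 0)
classify_index("THI2", c(73.9, 78, 82))
```

## Equivalent temperature change

To ask "how much heating is a 10 % humidity rise worth?", hold an index
constant while $RH$ goes from 50 % to 60 % and solve
$I(T_2, RH_2) = I(T_1, RH_1)$ for $T_2$; the equivalent change is
$T_{equ} = T_1 - T_2$. The root is found by bisection to a residual below
$10^{-9}$ index units on the bracket $[T_1 - 15,\ T_1 + 15]$ degC. The upper
end is capped at 42 degC for ETIS only: its quartic radiation term turns the
temperature derivative over (at ~35.7 degC in still air, ~41 degC at 1 m/s,
later at higher velocities), and 42 keeps every solve used here on a bracket
with a single sign change. The other eleven indices are monotone in
temperature far beyond the analysis range, so their bracket is capped only
at the 50 degC validity-window edge; capping them at 42 would spuriously
fail the THI6 solve at $T_1 = 40$ degC, whose root lies near 42.1 degC.

ET and ETIS take $v = 1$ m/s in this comparison so they can sit in the same
table as the velocity-free indices.

```{r equiv}
tab <- equivalence_table()
xtabs(t_equ ~ index + t1, tab)[c("H", "THI6", "ETIS"), ]
```

Humidity acts like *heating* (positive $T_{equ}$) for every index except
THI6, whose humidity term is decreasing in $RH$ whenever $T > 14.4$ degC —
a sign defect, since high humidity suppresses latent heat loss. H, THI8 and
BGHI overreact (more than 1.5 degC per 10 % RH at 25 degC, more than
1.73 degC at 30 degC), while ETIS's response grows with temperature, the
physiologically expected pattern.

## Velocity response

At fixed 60 % RH, sweep $v$ from 0 to 4 m/s and compare against the winter
reference (each index at 10 degC / 60 % / still air, always recomputed from
the formula). ET falls with velocity at every temperature below its 42 degC
body reference, so its warm-weather curves eventually cross the winter
line — at 0.45 m/s for 25 degC and 1.18 m/s for 30 degC — implying a
25 degC breeze "equals" a still winter barn, which overstates the chill
effect. ETIS falls more gently below its 38 degC body temperature, is
exactly velocity-independent at 38 degC, and rises with velocity above it
(hot air blowing heat *into* the sow).

```{r velocity}
winter_reference("ET")
find_crossing_velocity("ET", 25, 60, winter_reference("ET"))
find_crossing_velocity("ETIS", 30, 60, winter_reference("ETIS")) # no crossing
```

One discrepancy is documented rather than hidden: the source figure shows
no intersection for its 20 degC ETIS curve, but under the printed formula
the convective term $0.3132\,(38-20)\,u^{0.6827}$ is large enough to pull
that curve through the winter baseline at about 2.70 m/s. The non-crossing
statement does hold at 25, 30 and 35 degC — the test-temperature set the
methods text states (its figure caption says 20 degC instead; the two
cannot both be right, and only the 25 degC version is consistent with the
formula). The tests assert the 25/30/35 non-crossings and, separately, the
20 degC crossing as a property of the formula as printed.

## Iso-index lines

Fix each index at its value in a reference state (22 degC, 70 % RH, still
air) and trace the $(RH, T)$ locus holding it there, by bisection in $T$ on
$[0, 50]$ degC (42 for ETIS) per 1 % RH grid step. The slope
$dT/dRH = -\partial_{RH} I / \partial_T I$ summarises how an index trades
humidity against temperature:

```{r iso}
iso_temperature_at("H", 0)    # dry-air intercept, degC
iso_temperature_at("THI8", 0)
iso_temperature_at("THI7", 0)
```

H, THI8 and BGHI will call a bone-dry 46 / 37.4 / 37 degC barn "equivalent"
to 22 degC at 70 % RH — temperature differences an animal plainly feels.
THI6's line slopes upward (the same sign defect as above). ETIS's line is
the flattest (under 2 degC of temperature spread across the full humidity
range): it neither ignores humidity nor lets it dominate.

Three published anchor points are *not* reproducible from the printed
formulas and are reported as discrepancies, not silently corrected: BGHI at
(31.6 degC, 0 %) — the printed dew-point and globe fits give ~37.2 degC;
THI6 at (25.4 degC, 100 %) — literal THI6 gives ~24.8; ETIS at
(23.34 degC, 100 %) — the literal formula gives ~21.5 there. Curiously, the
literal ETIS line meets 0 % RH at 23.34 degC, the very temperature the
source attaches to its 100 % anchor.

## The zonal barn surrogate

The reference analysis ranked the indices against per-sow convective heat
dissipation computed by a 3-D CFD simulation. A desk-scale package cannot
(and should not) re-run CFD, so the simulation is replaced by a transparent
1-D zonal energy balance with the same boundary conditions: a
7.15 x 3 x 3 m barn, ten sows (surface 2.775 m^2 at 38 degC) spaced 0.65 m
apart, inlet air at 30 degC / 60 % RH, outlet velocity 1 m/s through a
3 x 0.75 m opening. The sow row is centred along the barn (equal margins at
both ends), the package's own choice — the source states only the spacing.

The scheme: ventilation mass flow $\dot m = \rho v A$ (1.164 kg/m^3,
2.25 m^2, 1 m/s); local velocity decays exponentially from the inlet jet,
$u_i = e^{-x_i/3\,\mathrm{m}} + 0.05$ m/s, spanning the 0-1 m/s contour
range of the reference fields; convective coefficient
$h_i = \max(2.8,\ 3.2\,u_i^{0.66})$ W/m^2/K (the same velocity exponent as
the ET chill law); dissipation $Q_i = h_i A_{sow} (38 - T_i)$; and the zone
air warms by $Q_i / (\dot m c_p)$ between sows, clamped at the 34 degC
contour bound (never reached at the default mass flow). Four sampling
points around each sow receive seeded Gaussian noise (sd 0.1 degC on
temperature, clamped to the 30-34 degC bounds; sd 0.02 m/s on velocity,
truncated at zero) and are averaged into the sow's local air state — the
stand-in for CFD's spatial heterogeneity, without which every
temperature-only index would correlate perfectly and the ranking would be
degenerate. Humidity is held at 60 % throughout, as in the reference
boundary conditions. By construction $\sum_i Q_i$ equals the enthalpy
carried out by the air stream (the tests require closure within 1 %).

```{r barn}
sim <- simulate_barn(barn_config(), seed = 1)
head(sim$sows[, c("sow_index", "temp_c", "vel_ms", "q_conv_w")], 4)
```

What the surrogate does *not* emulate: recirculation, buoyancy, turbulence,
radiative exchange, latent (evaporative) heat loss, and vertical gradients.
Consequently the published R^2 values (0.9883 for ET, etc.) are
CFD-dependent and are not reproduced numerically; what carries over — and
what the tests assert — is the *ordering*: the dissipation is driven by the
local velocity through $h(u)$, which only ET and ETIS can see, so both must
outrank all ten temperature-humidity-only indices.

```{r corr}
report <- heat_dissipation_correlation(sim$sows)
rank_indices(report)[1:3]
```

## Numerical choices

* Bisection everywhere (equivalence, iso-lines, crossing velocities):
  robust to the rational wet-bulb fit, deterministic, tolerance $10^{-9}$
  index units (velocity crossings also stop at $10^{-9}$ m/s bracket
  width). Tests cross-check every default-experiment root against a
  brute-force 0.001-step grid scan and against Brent's method.
* Absence of a root is data, not an error: velocity curves that never reach
  the winter line return `NA`, iso-line grid points with no solution in the
  temperature bracket are kept as gaps, and equivalence-table rows whose
  root escapes the bracket are flagged `"no root"` rather than dropped.
* Ties in the R^2 ranking break by the canonical index order
  (`index_ids()`), documented and tested.
* Problem sizes: 0.01 m/s velocity grids, 1 % RH grids, ten sows with four
  sampling points each — the full study conditions; every analysis runs in
  seconds.

## Limitations

The empirical psychrometric fits are regressions, not physics: the dew
point at 0 % RH is finite, the wet bulb can slightly exceed the dry bulb,
and nothing here is pressure-corrected beyond H's explicit $P_m$ divisor.
The barn surrogate is a one-dimensional caricature of a ventilated barn,
adequate for ordering indices by whether they carry velocity information,
not for predicting absolute heat loss. Threshold tables are reproduced as
published, gaps included; they are species-, stage- and climate-specific
and should not be transplanted to other livestock.
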