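---
title: "Methods: census data lifecycle for permanent sample plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census data lifecycle for permanent sample plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspcensus)
```

## Scope and model of the data

`pspcensus` implements the data lifecycle of a long-term tropical forest
permanent sample plot (PSP) network of the M'Baiki type: ten 4-ha plots
(each four 1-ha subplots) in three blocks (Boukoko1, Boukoko2, LaLole),
censused nearly annually from 1982 to 2022 with campaigns skipped in 1997,
1999, 2001, 2013, 2014 and 2016 — 35 campaigns in all. Every stem above 30
cm girth at breast height (gbh) is mapped, numbered within its subplot,
measured and followed individually: girth, height of measurement (hom),
mortality with cause (standing death, primary or secondary treefall), and
recruitment.

The package covers, in order: the relational flat-file archive (eight CSV
tables plus two GeoJSON layers), the observation model (girth/diameter
conversion and its rounding rules), post-campaign quality-control
screening, the deterministic correction engine that produces an
analysis-ready diameter series per tree, stand-level dynamics statistics,
and a synthetic census generator with exhaustive ground truth that makes
every stage testable without field data.

## The archive schema

An archive is ten files: `tree.csv`, `taxonomy.csv`, `vernacular.csv`,
`trees_context.csv`, `measures.csv`, `inventories.csv`,
`observation_codes.csv`, `mortality_codes.csv`, `plots.geojson`,
`subplots.geojson`. File names follow the released-archive convention;
column names and types are this package's own data dictionary
(`census_dictionary()`) because the upstream column dictionary is not part
of the published description — they are a documented convention, not a
transcription.

Numbers are written with fixed per-column decimals and missing values as
empty strings, which makes `write_archive()` deterministic:
`read_archive(write_archive(x))` equals `x` field for field, and a second
write is byte-identical. All content must be ASCII (the fixture of the 36
valuable timber species transliterates accented commercial and Issongo
names for that reason). Referential integrity is checked on read; all
schema rules are also available as data via `validate_archive()`, which
returns one row per violation rather than failing.

Plot geometry is stored in WGS84. Each plot feature carries the
georeferenced position of its (0;0) South-West corner, and the mapping
between the 0–200 m local frame and longitude/latitude is the local
equirectangular affine anchored at that corner (`local_to_lonlat()`,
`lonlat_to_local()`); at a 200 m scale its distortion is orders of
magnitude below the 0.1% area tolerance we enforce. Area validation uses
the inverse affine plus the shoelace formula; the test suite cross-checks
with an independent geodesic area computation (`geosphere`).

## Measurement model

Girth is taped to the nearest 0.5 cm in the field; the database stores the
diameter `gbh/pi` rounded to 0.1 cm. Both roundings are half-up (field
sheets round ties upward) and share one utility, `round_half_up()`, so the
convention is changeable in one place. The 30 cm gbh field threshold
corresponds to 9.5 cm dbh; database recruitment happens at 10 cm dbh, so
trees at 9.5–9.9 cm are present but unrecruited (`not_yet_recruited`).

Very large trees (girth over 250 cm) were binned into 10-cm diameter
classes during 1982–1990; `class_to_dbh()` assigns the class midpoint,
which is unbiased if diameters are uniform within the class — whether the
original database stores midpoints, bounds or codes is not documented, so
the midpoint is an explicit convention here. Relascope readings, taken
every five years for stems that cannot be taped even at 4.50 m, are
carried forward to intermediate campaigns (`carry_forward_relascope()`).

The hom is 1.50 m by default, raised above deformations, and stored per
measurement (not per tree) because it changes over time.

## Quality control

`screen_archive()` reproduces the three post-campaign check families, each
comparing a campaign to its predecessor:

1. living-tree inconsistencies — annualized diameter increment above
   +2 cm/yr (`EXCESS_GROWTH`) or below −0.6 cm/yr (`EXCESS_DECLINE`), and
   re-born trees (`REBORN`);
2. unauthorized or doubtful values — recruits entering below 10 cm dbh
   (`RECRUIT_UNDER_10`), a diameter that increases although the hom was
   raised (`HOM_RAISE_INCREASE`), non-positive diameters or hom below
   1.50 m (`UNAUTHORIZED_VALUE`);
3. missing data (`MISSING_DATA`), both valueless records and trees absent
   from a campaign after being recorded living.

Increments are annualized with decimal-year census intervals, which
matters across the skipped years: a 4.5 cm step over the 2012–2015 gap is
1.5 cm/yr and legitimate. Threshold comparisons are strict, following the
operational wording ("greater than", "less than"). Two choices were
genuinely open and are resolved as follows: increment checks are skipped
when the hom changed between the two campaigns, because girths at
different homs are not comparable — the raise case has its own dedicated
rule; and severities model the human triage (anomalies are sent back to
the field crew, not auto-corrected): `REBORN`, `RECRUIT_UNDER_10` and
`UNAUTHORIZED_VALUE` block, increment and missing-data flags are review.
Screening is read-only and order-invariant.

## Correction engine

`correct_tree()` runs, in order: manual overrides → re-born back-fill →
taper-ratio conversion of hom raises → increment-sign-dependent gap
filling → status recomputation. Raw data are immutable; every corrected
value carries a provenance (`raw`, `manual_override`, `reborn_backfill`,
`taper_converted`, `interpolated`, `carried_forward`, `unfilled`).

**Taper ratio.** When the hom is raised, the ratio of the diameter at the
raise campaign (new hom) to the previous campaign's diameter (old hom)
converts all subsequent raised-hom measurements to original-hom
equivalents; successive raises chain multiplicatively. At the raise
campaign itself the converted value equals the previous campaign's value
by construction. The upstream description applies the conversion "from
t+1" and is silent about t; we convert t as well, which keeps the
equivalent series hole-free and continuous (zero apparent increment at the
raise year) — this is the package's documented choice.

**Gap filling.** For a run of missing values between valid measurements
`d_a` and `d_b`: positive increment → linear interpolation in decimal
time (not campaign index, so skipped years interpolate correctly);
negative increment with a hom raise inside the gap → the taper procedure
between the two flanking measurements at different homs, with the ratio
propagated to all later raised-hom values; negative increment without a
raise → the last valid value is reported (also at `d_b`); equal values →
constant fill. The equality case is unaddressed upstream; constant fill is
the package's choice. A raise inside a gap whose increment is
*positive* is treated as ordinary interpolation — the sign rule governs,
and no conversion factor can be estimated from such a pair. Leading and
trailing runs have no flanking pair and stay `unfilled`. Derived values
are re-rounded to 0.1 cm to stay at database resolution.

**Re-born trees.** A dead-then-alive pattern annuls the death and fills
the presumed-dead campaigns with the diameter at the re-born date; each
dead interval uses its own re-born value. A re-born tree with no
subsequent measurement is an error.

**Overrides and idempotence.** Expert diameter corrections live in a
sidecar table (`tree_id`, `campaign_year`, `dbh_cm`, `note`) applied
before the automated procedures, which then re-run around them. The
corrected archive stores corrected diameters plus provenance while keeping
raw girths; corrected values are original-hom equivalents, so re-running
the engine on an already-corrected series (recognized by its provenance
column) returns it unchanged rather than re-detecting raises against the
raw hom record — that is what makes the pipeline idempotent, a property
the test suite checks on a thousand simulated series.

## Forest dynamics

`dynamics_table()` computes, per 4-ha plot or 1-ha subplot and campaign:
stem density N (ha⁻¹) and basal area G = Σ π(d/200)² per hectare
(m² ha⁻¹) over alive recruited trees, and per census interval the
annualized demographic rates. With N₀ alive recruited trees at the start,
S survivors, and R recruits alive at the end (N_b = S + R):

- mortality = (1 − (S/N₀)^(1/Δt)) × 100 %/yr
- recruitment = (1 − ((N_b − R)/N_b)^(1/Δt)) × 100 %/yr

The survival-fraction power form is the standard annualization for
multi-year census gaps; the upstream description gives only the unit
(%/yr), so the estimator is labelled as this package's choice and the
simple count estimators D/(N₀Δt) and R/(N_bΔt) are available via
`estimator = "simple"` for comparison. Rates with zero denominators are
reported missing, never zero. The recruitment threshold defaults to
10 cm dbh with a 9.5 cm option mirroring the field-threshold analyses;
which of the two underlies the published trajectories is not stated, so
both are exposed. Two documented edge rules: corrected re-born trees
count as continuously alive (they inflate neither rate), and a tree that
would be recruited and die within the same interval never enters the
recruited-alive population at a census, so it counts in neither R nor D.

## Synthetic census generator

`simulate_archive()` is first-class, tested code: an individual-based
stand simulator behind an observation layer, with an exhaustive log of
every divergence between truth and emission.

Demography and growth: annual time steps over the calendar span; lognormal
diameter increments (mean 0.2 cm/yr, sd 0.15 — a typical shade-tolerant
tropical increment distribution); Bernoulli mortality with cause
assignment (probabilities 0.5/0.3/0.2, configurable — the causes are
documented upstream but not their frequencies); Poisson recruitment
entering at the field threshold in proportion to the standing ≥ 10 cm
population. Defaults describe an intact control stand: three 4-ha control
plots (12 ha), a touch above 500 stems/ha initially, mortality and
recruitment both 1 %/yr — the regime reported for undisturbed plots,
where both rates fluctuate around 1 %/yr.

The initial state is a reverse-J truncated exponential above 10 cm dbh
(scale 13 cm, giving a basal area near 27 m²/ha at 520 stems/ha), plus an
in-transit pool in [9.5, 10) sized at its stationary value — recruitment
inflow times mean transit time, with the triangular depth profile implied
by uniform entry and steady drift. Without that pool the first campaigns
under-produce threshold crossings and the recruitment estimator would
carry a warm-up bias that has nothing to do with the estimator itself;
with it, the stationary crossing flux equals the configured rate, which is
precisely the quantity parameter-recovery tests must recover. The residual
recruitment bias (about −0.04 percentage points at the defaults) is real
estimator behaviour: mortality in transit, and same-interval recruit
deaths that the edge rule above deliberately excludes.

Observation layer: girth = true dbh × π × taper, plus Gaussian noise (sd
0.1 cm), rounded to 0.5 cm; diameter derived at 0.1 cm; trees enter the
records at the first campaign their rounded girth reaches 30 cm; hom
raises (annual probability 0.005, multiplicative taper factor in
[0.85, 0.98], raised to 4.50 m); missing records (1%); optional false-dead
episodes of one or two campaigns (off by default, because a re-born
pattern is a blocking anomaly and the clean-archive contract is zero
blocking flags); optional disturbance pulses that remove stems with
probability proportional to basal-area share until a target basal-area
fraction is gone (a stylized logging event, not a logging model).
Relascope and 1982–1990 diameter-class observation paths are not emulated;
both conversions exist and are tested in the measurement module.

What passing tests on this generator do *not* show: real censuses have
spatially clustered mortality, correlated growth (size, crowding,
climate), observer drift, and identification churn; none of that is
modelled. The generator's purpose is contract testing of the pipeline —
schema, screening, correction, estimation — under a known truth, not
ecological realism.

### Harness conventions

Two test harnesses fix additional knobs, chosen a priori:

- The QC injection round-trip simulates its base archive with zero
  measurement noise, no missing records, no false deads and no hom raises,
  so the 200 injected anomalies are the only observation-layer threshold
  violations; injections are persistent level shifts so exactly one
  interval violates the planted rule. Precision is assessed on trees whose
  *true* increment series never violates the thresholds, with the
  violation classification widened by the 0.5 cm girth quantization
  half-width (a true increment within half a rounding step of the
  threshold is not decidable from rounded data).
- Parameter recovery uses 100 stands at the default conditions and
  computes rates directly on the simulated archives: demographic rates are
  count-based and do not depend on diameter gap-filling, and the
  correction engine's accuracy is measured separately against true
  trajectories (corrected series must be at least as close to truth as raw
  ones, and strictly closer for hom-raised trees).

## Numerical choices and degenerate inputs

- Half-up rounding everywhere, with a 1e-9 guard so exact decimal halves
  stored in binary round upward.
- Decimal years via calendar dates (nominal census date 15 May, midpoint
  of the April–June field window) — so intervals across leap years are
  slightly different from integers, deliberately.
- Empty archives are valid (vacuous integrity); single-campaign archives
  run only single-campaign QC rules; zero-denominator rates are `NA`.
- Taper ratios must be positive; values above the 1.5 sanity bound are
  applied but warned about. A hom *decrease* (not part of the protocol)
  restarts the conversion chain rather than inventing an inverse ratio.

## Known limitations

- The correction engine is rule-based; it does not model measurement error
  statistically and will faithfully propagate a consistent bias.
- `correct_archive()` loops over trees (milliseconds per tree); archives
  of ~10⁴ trees correct in tens of seconds, which is fine for the intended
  scale but not for national-inventory volumes.
- GeoJSON geometries are plain polygons with the documented affine; no CRS
  machinery beyond WGS84 is provided.
- The package reproduces no published data values: all numbers in its
  tests are closed-form constants, transcribed metadata (the 36-species
  table, the campaign calendar) or quantities computed from its own
  simulations.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations to keep a
full run in a few minutes on one core: the idempotence suite corrects
1,000 series twice; the QC round-trip plants 200 anomalies in a 4-ha
stand; parameter recovery averages 100 stands of 12 ha (≈ 6,800 trees
each) over the 35-campaign calendar.
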