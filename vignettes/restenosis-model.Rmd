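---
title: "An agent-based model of in-stent restenosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of in-stent restenosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The process being simulated

After balloon angioplasty and bare-metal stent deployment, the treated
artery mounts a wound-healing response that can re-narrow the vessel
(in-stent restenosis, defined here as loss of more than 50% of the
post-procedural lumen cross-sectional area). `restenosim` simulates a
two-dimensional cross-section of the stented vessel as a lattice
agent-based model. The causal chain is the classical injury cascade:

1. The procedure denudes the endothelial monolayer and embeds stent
   struts in the wall. Exposed subendothelium activates circulating
   platelets, which aggregate into a thrombus and activate newcomers on
   contact.
2. Activated platelets, smooth muscle cells (SMCs) and endothelial cells
   (ECs) in injured territory release the anti-inflammatory cytokine
   TGF-beta.
3. Detectable intimal TGF-beta recruits circulating monocytes and
   neutrophils. Neutrophils attach to the thrombus; monocytes cross it,
   mature into macrophages in the wall, and a large fraction takes up
   residence at the stent struts (the foreign-body response).
4. Monocytes, neutrophils and macrophages release the pro-inflammatory
   cytokine TNF-alpha wherever TGF-beta is present.
5. Both cytokines diffuse and decay. Local TGF-beta at or above 3 ng/ml
   triggers SMC/EC proliferation; local TNF-alpha at or above 4 ng/ml
   triggers apoptosis, capped at 15% of the local population per
   exposure step. Proliferating medial SMCs migrate lumen-ward and, with
   crowding displacement (at most 15 SMCs per patch), build the
   neointima that narrows the lumen.

The simulation starts at the moment the procedure ends and runs until
the lumen diameter stabilizes: TGF-beta release has ceased for a full
simulated day, confirmed by 60 further days in which the minimum lumen
diameter moves by no more than one patch.

## Lattice, units, clock

The cross-section lives on a 150 x 150 patch grid (22,500 patches); one
patch side is 0.05 mm, one time step is 6 hours (4 steps per simulated
day). The vessel axis sits at the geometric centre of the grid, and the
post-procedural lumen is assumed circular. The wall is partitioned into
concentric intima (innermost 10% of the wall thickness, at least one
patch), media (next 60%) and adventitia; media and adventitia are seeded
with 5 SMCs per patch, the intima with roughly one SMC per three patches
beneath a single-cell EC ring. When no wall thickness is supplied it
defaults to the lumen radius (a 1:1 radius-to-wall ratio). A plaque
deposit sits between intima and media in the bottom-left quadrant (a
30-degree arc, four patches deep, by default); because the cross-section
is circular its angular position does not affect outcomes, which the
test suite verifies by rotation. Struts (0.1 mm square, 20 per stent by
default) are evenly spaced in angle and pressed flush into the wall at
the lumen boundary; a second, overlapping stent adds a radially adjacent
interior ring, angle-aligned or staggered by half a pitch. Struts and
plaque never move or change.

An agent's *local environment* is its patch plus the 8 adjacent patches;
all cytokine concentrations used by the behavioural rules are measured
over this 9-patch window.

## Cytokine fields and the measurement protocol

Both cytokines are represented by discrete quanta that random-walk one
patch per step (8 directions, moves off the tissue/lumen-boundary band
rejected) and expire after 24 h. Local concentration follows the
V = C x AP protocol: the quantum count in the 9-patch window divided by
the window volume, where C is the patch-thickness constant. Cells
release 0.02 pg per 10 hours each - exactly 0.012 pg per 6-h step.

Two constants in this protocol are not physically observable and serve
as the model's calibration anchors:

* the quantum mass (0.003 pg, so a cell at the nominal rate emits 4
  quanta per step - fine enough granularity that extreme-value noise in
  the local maxima stays small relative to the mean), and
* C = 2.4 mm, which makes one local quantum 1/18 ng/ml; the
  proliferation and apoptosis thresholds of 3 and 4 ng/ml then
  correspond to exactly 54 and 72 local quanta.

The serum concentration (total grid mass over the whole-grid reference
volume) drives no behaviour; it is a physiology checkpoint expected to
stay within 0-10 ng/ml.

### Who releases, and how much

Only cells at the wound surface are signalling-active: per patch, at
most one SMC/EC emits (`surface_release_cap`), and only on patches in or
adjacent to injured territory. Deeper cells are quiescent. Activated
platelets release only during their first 1.5 days in the thrombus
(degranulation is transient); each replaced platelet draws a 5-10 day
lifespan at creation and the circulating pool is held at its nominal
size. Release in injured territory is amplified by
`wound_release_factor` (1.132) and, within one patch of an unhealed
strut, by `injury_factor` (1.22) - the deeper procedural injury releases
more.

### Hoop-stress modulation

TGF-beta release is modulated by circumferential wall stress, which
under the thin-wall approximation is proportional to lumen radius over
wall thickness. The exact stress-to-release coupling is a calibration
element of this model; we use a saturating power law applied per angular
sector: release is at its full rate while the local lumen radius is
above `hoop_knee` (72%) of its post-procedural value and falls as
`(r/r0 / 0.72)^12` below it. The sharp knee makes deep neointimal bumps
self-limiting at a fixed *fraction* of the vessel radius, which is what
ties the model's endpoint to vessel size: the three validation vessels
(2.39-3.19 mm) lose comparable fractions of their area rather than a
fixed absolute thickness.

## Cellular rules and their numerical forms

* **Division probability.** A population doubling every 30 h gives a
  per-6-h-step division probability of 2^(6/30) - 1 = 0.1487 for cells
  whose local TGF-beta is at or above threshold. Injured intimal SMCs
  produce two daughters per division; all others one.
* **Contact inhibition.** Intimal/neointimal SMCs divide only at the
  free (lumen-facing) surface; medial and adventitial SMCs divide only
  in injured territory. Without these gates the bulk wall tissue joins
  the positive feedback loop (more cells, more TGF-beta, more division)
  and the population diverges.
* **Migration.** Daughters of medial divisions join a migrating pool
  that moves 20 um/h (2.4 patches per step, the fractional patch applied
  stochastically) toward the lumen and converts to intimal on reaching
  the wound frontier. Struts are impenetrable: displacement and
  migration route around them.
* **Crowding.** A patch holds at most 15 SMCs. Surplus cells seek free
  capacity among the three most lumen-ward neighbours, least-occupied
  first - displaced tissue therefore spreads along the ring instead of
  spiking radially. Adventitial SMCs never move; their surplus is lost
  to contact inhibition.
* **Apoptosis.** Where local TNF-alpha is at or above 4 ng/ml, SMC
  deaths per patch are binomially sampled and capped at 15% of the
  9-patch population; ECs die with the same capped probability.
* **Leukocytes.** Mobile leukocytes move 1 um/min (7.2 patches per
  step) as a biased random walk toward the wall (80% radial, 20%
  random). Monocytes mature on reaching tissue; 85% of new macrophages
  reside at the nearest unhealed strut for 15 days before rejoining the
  wandering tissue population, the rest wander immediately (a slow walk
  within tissue). Lifespans: monocytes 3 days, neutrophils 5 days,
  macrophages 45 days from maturation.
* **Recruitment.** While any frontier patch holds detectable TGF-beta,
  monocytes and neutrophils are spawned at `recruit_rate` (3 of each per
  step) scaled by the remaining wound burden (injured bins plus
  twice-weighted open struts, as a fraction of the circumference), so
  inflammation subsides as re-endothelialisation proceeds rather than
  smouldering indefinitely.
* **Endothelium.** The EC ring is re-seated on the lumen-facing tissue
  frontier every step; it advances when the SMC mass advances. Gaps and
  damaged ECs recover with probability 0.021 per step where TGF-beta is
  detectable (plus a 0.01 baseline); TNF-alpha kills ECs and re-opens
  the injury. A strut stops acting as an injury when a restored EC
  monolayer covers its angular extent and no macrophage is resident on
  it.

The per-step order is: platelets, TGF-beta release, recruitment,
leukocytes, TNF-alpha release, diffusion/decay, SMCs, ECs, metrics.

## Measurement

The lumen boundary is read from EC positions (the innermost tissue patch
per angular sector, 360 sectors). The minimum lumen diameter casts 180
diameters through the vessel axis and takes the smallest - the
worst-case obstruction. Percent area change is
100 x (A0 - A)/A0 with circular areas on the initial and current minimum
diameter; restenosis is a strict >50% loss. The angular resolution is
configurable; halving it changes the measured diameter by less than one
patch.

## Stopping rule

Stabilization is declared when no TGF-beta has been emitted for four
consecutive steps; the stabilization day is the last day with release,
rounded to the nearest day. The run then continues for a 60-day
confirmation window in which the minimum diameter must stay within one
patch; drift or resumed release restarts the window. Full occlusion
(no diameter wider than two patches) terminates a run with 100% area
loss. A hard cap of 400 simulated days guards against non-termination;
runs hitting it are flagged non-convergent and excluded from replicate
summaries with a warning.

## Calibration and what the defaults represent

All Table-derived biology (release rate, thresholds, doubling time,
migration speeds, lifespans, apoptosis cap, patch capacity, strut
defaults) is fixed at its published value. The open constants - the
measurement constant C, quantum granularity, surface release cap, wound
and strut release amplification, hoop knee and exponent, EC recovery
probabilities, platelet pool and degranulation window, recruitment rate,
macrophage strut fraction and residence - were calibrated once, jointly,
against the single-stent study conditions (initial lumen diameters 2.9,
3.19 and 2.39 mm, 20 struts, default wall thickness, 10 replicates) and
then frozen as the package defaults. They are exposed through
`vessel_config()` for sensitivity analysis, not for per-scenario
retuning.

Three emergent timescales matter. Early (days 0-10) the denuded ring is
fully injured: platelet degranulation and surface release push local
TGF-beta to its peak and recruitment to its maximum. In the middle phase
the inter-strut ring re-endothelialises while strut neighbourhoods stay
inflamed - resident macrophages keep TNF-alpha high enough to re-open
the local endothelium stochastically. The endgame is set by the
foreign-body response: a strut can only heal in a window when its
residents have rotated away and its monolayer is intact, so the last
strut closures - and with them the cessation of TGF-beta release -
happen in the 60-110-day range, driven by the 45-day macrophage lifespan
and the decaying recruitment. Run-to-run variation in those last
closures, and in how deep the neointimal bumps grow before the
hoop-stress knee stalls them, produces the clinically realistic spread
in outcomes: most runs settle near half the lumen area lost, a
substantial minority stay below the restenosis threshold, and
occasional runs run away toward occlusion.

## What the simulated conditions do and do not capture

The generator reproduces the study conditions: a circular post-stent
cross-section, a single cross-sectional plane, default 1:1
radius-to-wall ratio, uniform cell behaviour within a type, two
cytokines standing in for the full signalling milieu, and plaque as
inert filler. It does not model extracellular-matrix deposition, vessel
remodelling, plaque rupture or thrombosis therapy, drug elution,
non-circular lumens, or 3-D stent geometry. Passing validation therefore
shows that the rule set reproduces the population statistics of lumen
narrowing under these idealised conditions - not that it predicts an
individual patient's course, and not that the calibrated constants are
biologically measured quantities.

## Numerical choices and degenerate inputs

* One RNG stream per run, seeded from `base_seed + replicate - 1`; equal
  (configuration, seed) pairs reproduce bit-identically.
* Poisson emission, binomial division/death sampling; fractional
  migration steps and fractional recruitment rates are realised by
  Bernoulli rounding.
* Crowding displacement iterates to a fixed point each step (the cap is
  an invariant, not an average); ties among equally occupied
  lumen-ward neighbours resolve by first index.
* The lattice frame (distances, angular sectors, inward-neighbour maps)
  is memoised per grid size.
* Degenerate configurations: zero release collapses to the null model
  (stabilization day 0, no leukocytes, static diameter); a strut spacing
  wider than the circumference clamps to one strut with a warning;
  vessels that do not fit the grid with their wall are rejected at
  configuration time.

## Problem sizes used by the packaged checks

The validation harness runs 10 replicates per scenario on the full
150 x 150 grid; the heterogeneity analysis uses 60 replicates of the
2.9 mm scenario; micro-fixtures for rule-level tests use a 40 x 40 grid
with a 0.8 mm vessel. A full-size run to stabilization plus confirmation
takes a few seconds on one core.

## Known limitations

* The stabilization-day distribution has a long right tail (late strut
  closures), so its replicate SD is larger than the reference values;
  means are stable.
* The overlapping-stent configuration reproduces the directional
  effects (smaller final diameter, later stabilization by roughly a
  quarter, higher peak cytokines) but the sharp hoop-stress knee caps
  how much deeper than a single stent it can grow, so the final-diameter
  deficit is smaller than the reference comparison reports.
* Replicate SDs of the final diameter (about 0.1-0.2 mm) exceed the
  reference model's printed 0.02-0.05 mm; the heterogeneity of outcomes
  (including occasional occlusions) is irreconcilable with SDs that
  small, and we chose to reproduce the heterogeneity.
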