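---
title: "Thermodynamically gated methane cycling in sediment microcosms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically gated methane cycling in sediment microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptomethane)
```

## The scientific problem

When anoxic estuarine sediment is sealed in a bottle with its natural
porewater, the microbial community walks through the same succession that
plays out over metres of sediment depth in the field: sulfate reducers
(SRB) consume sulfate while holding porewater hydrogen at sub-nanomolar
levels; once sulfate runs low they lose that control, hydrogen rises,
hydrogenotrophic methanogens bloom and methane accumulates; a period of
"cryptic" methane cycling can follow in which methanogenesis and the
anaerobic oxidation of methane (AOM) run concurrently with little net
methane change; and finally, with sulfate fully depleted, net
methanogenesis resumes and the methane pool drifts toward the strongly
13C-depleted biogenic end-member.

The hinge of the whole succession is a single thermodynamic quantity: the
Gibbs free energy of hydrogenotrophic methanogenesis,

$$\Delta G = \Delta G^\circ + RT \ln \frac{[\mathrm{CH_4}]}
{[\mathrm{CO_2}]\,[\mathrm{H_2}]^4},$$

for the reaction $4\,\mathrm{H_2} + \mathrm{CO_2} \rightarrow
\mathrm{CH_4} + 2\,\mathrm{H_2O}$ with unit water activity and aqueous
concentrations standing in for activities (the uncharged species involved
have activity coefficients close to 1). The package evaluates it with
$\Delta G^\circ = -194.53$ kJ/mol (a standard tabulation at 18 °C, used
unchanged at the incubation temperature of 21 °C), $R = 0.0083145$
kJ/(mol K), and CO₂ held at a configured 10 mM. Because hydrogen enters
the quotient to the fourth power, a factor-of-two change in [H₂] moves
ΔG by more than 16 kJ/mol: the same methanogen population can sit on
either side of equilibrium within a narrow nanomolar hydrogen window, and
the **hydrogen threshold**

$$[\mathrm{H_2}]^* = \left( \frac{[\mathrm{CH_4}]}{[\mathrm{CO_2}]}
\, e^{\Delta G^\circ / RT} \right)^{1/4}$$

is the concentration at which ΔG = 0. `h2_threshold()` evaluates it in
log space (the quotient spans ~35 orders of magnitude) and
`gibbs_hydrogenotrophic()` returns ΔG with the logarithm computed as a
sum of logs for the same reason. Note on stoichiometry: the 4-H₂ form of
the reaction is the one consistent with both the fourth-power hydrogen
term of the quotient and the magnitude of ΔG°, and is the convention used
throughout this package. At the study's conditions (CO₂ = 10 mM, 21 °C)
the threshold stays between 0.3 and 7 nM for any methane between 0.01 and
5.11 mM — precisely the band that incubation hydrogen measurements
bracket, which is what makes the sign of ΔG an informative classifier of
the ongoing process direction (`classify_direction()`, sign-based by
default with an optional dead band for a minimum energy quantum).

## What the analysis stages compute

**Gas partitioning.** Headspace gas chromatography measures a partial
pressure, not a porewater concentration. Methane is deliberately *not*
assumed to equilibrate with the aqueous phase: the total headspace
inventory is expressed per litre of porewater, $n = pV_{hs}/(R_{gas}T)$
divided by $\phi V_{sed}$ (`headspace_methane_to_porewater()`, with
$R_{gas} = 0.08206$ L atm mol⁻¹ K⁻¹). This reproduces the multi-millimolar
scale of reported methane concentrations, which Henry equilibrium cannot.
Hydrogen, by contrast, *is* assumed equilibrated, so
`hydrogen_headspace_to_aqueous()` applies Henry's law with a default
solubility of 7.8×10⁻⁴ mol L⁻¹ atm⁻¹ near 21 °C (configurable; no
salinity or temperature correction is applied). GC calibration against
premixed standards is ordinary least squares (`calibrate_gc()`), through
the origin when requested.

**Rates, peaks, plateaus, phases.** `window_rate()` regresses
concentration on day over an inclusive time window (10⁻⁶ day comparison
tolerance), pooling all bottles and replicates rather than averaging them
— three timepoints of triplicate bottles give n = 9, matching how such
rates are reported. R² is defined as 0 when the response is constant
(avoiding 0/0). `detect_peak()` works on replicate means with
earliest-day tie-breaks, mirroring how maxima are reported (mean ± sd on
a day); `detect_plateaus()` works on pooled points, growing maximal runs
of consecutive timepoints left-to-right while the pooled coefficient of
variation stays below `cv_max`, because plateau summaries average "all 9
measurements". `segment_phases()` applies ordered rules: the
sulfate-reduction/AOM phase lasts while replicate-mean sulfate exceeds
`s_mc` (default 5 mM); net methanogenesis is called at the first of
`k_confirm` (default 3) consecutive timepoints with sulfate at or below
`s_mg` (default 0.1 mM), non-decreasing mean methane and — when measured
— declining δ¹³C-CH₄; methane cycling fills the gap. The thresholds come
from how the transition is described in the field (control lost below
~5 mM; depletion below 0.1 mM) but are deliberately exposed as
configuration, because phase assignment in incubation studies is
narrative, not algorithmic; this rule set is one consistent
formalisation.

**Isotopes.** Mass balance is linear in δ-space by default
(`mix_delta()`): at methane-like δ magnitudes the error against the exact
ratio-space balance is below 0.1 ‰, and the exact form is available via
`exact = TRUE`. `rayleigh_residual()` implements the linearised Rayleigh
form $\delta_0 + \varepsilon \ln f$, and `biogenic_fraction()` inverts
two-end-member mixing between seed methane (default −34.9 ‰, the
composition of the amended methane) and biogenic methane (default −80 ‰),
clamped to [0, 1] with an out-of-range flag.

**Amplicon quality control.** The QC rules are applied in a fixed order
because the order changes the result: samples under 20 000 reads are
dropped *first*, then ASVs present in fewer than three of the surviving
samples (`qc_filter()`). Chloroplast, eukaryote and domain-unassigned
lineages are removed (`remove_nontarget()`). "Scaled to even depth" is
implemented as proportional scaling by default — the phrasing is
ambiguous between proportional scaling and rarefaction, so both are
provided and the seeded rarefaction (`mode = "rarefy"`) is exactly
reproducible. `agglomerate_rank()` sums counts over shared lineage
prefixes, grouping rank-unassigned ASVs under `unclassified_<parent>`.
Guilds are named sets of (rank, taxon) patterns (`default_guilds()`
ships the methane-cycling archaea and the SRB families of this system);
guild trajectories are fractions of total library reads, and
`consistent_increase()` formalises "consistently increases in all
bottles" as a strict per-bottle window comparison summarised by a
two-sided exact sign test — chosen because the claim in the literature is
narrative, and a sign test is the assumption-free way to score
cross-bottle consistency at n = 3 (where the smallest attainable p is
0.25; the test conveys consistency, not significance, at that n).

## The box-model simulator

`simulate_microcosm()` is a forward kinetic model of one sealed bottle,
built so that every analysis stage can be tested against known ground
truth. State: sulfate, aqueous hydrogen, the two methane isotopologue
pools (¹²CH₄, ¹³CH₄), free sulfide, reactive iron, a sulfide-reoxidation
oxidant, labile carbon, and three biomasses (SRB, methane-cycling
archaea, background community). Process rates follow Monod kinetics:

* fermentation `r_f = k_f · L` releases 2 H₂ per labile-carbon unit, plus
  a small constant baseline supply (`h2_bg`) representing slow necromass
  turnover;
* sulfate reduction `r_sr = v_sr · B_srb · S/(S+K_S) · H/(H+K_Hsr)`
  consumes 4 H₂ per sulfate and produces sulfide;
* the thermodynamic gate `F = 1 − exp((ΔG + dG_min)/(χ R T))`, clipped to
  [−1, 1], drives methanogenesis when positive and AOM (the same
  catalytic machinery run in reverse by the same guild) when negative —
  so the net methane flux sign always equals the sign of F;
* produced methane carries δ = δ_DIC − ε_mg (defaults −10 ‰ and 70 ‰, so
  biogenic methane is ≈ −80 ‰); AOM consumes ¹²CH₄ preferentially by
  ε_aom (default 8 ‰, at the low end of reported AOM fractionations —
  larger values make the oxidation interlude so ¹³C-enriched that the
  final biogenic mixture can no longer undercut the bloom-era minimum,
  which contradicts the late δ¹³C minimum this system shows);
* methanogen biomass grows **only** from forward methanogenesis; SRB grow
  from sulfate reduction and, once sulfate is below `s_syn`,
  syntrophically from the methanogens' hydrogen turnover in *either* gate
  direction — during AOM the SRB are the hydrogen-consuming partner of
  the consortium. Without AOM-coupled growth the SRB hydrogen sink cannot
  sustain a months-long net-AOM interlude; the observation that specific
  SRB lineages partner anaerobic methane oxidizers in these sediments
  motivates it.

**The cryptic sulfur loop.** Sulfide has two fates: iron-gated
pyritization (burial; consumes the reactive-iron pool 1:1) and
reoxidation back to sulfate by a finite "cryptic" oxidant pool. Early in
the incubation iron is plentiful, most sulfide is buried, and the primary
sulfate pool drains; because iron is consumed in lockstep with net
sulfate drawdown, the initial iron inventory sets — almost exactly — the
small sulfur inventory left cycling when the primary pool is gone. After
iron exhausts, recycling is nearly lossless and that residual inventory
(~0.1 mM) sustains a sulfate-reducing hydrogen sink fed by reoxidation;
when the growing (syntrophy-fed) SRB population pushes that sink above
the declining fermentative hydrogen supply, the gate flips and the
methane peak is consumed — the cryptic-cycling interlude. The oxidant
pool is consumed 1:1 by reoxidation, and its exhaustion (sized to occur
around day 500) crisply terminates the loop: sulfate crosses below
0.1 mM, hydrogen settles just above the threshold, and the final
net-methanogenic month begins with δ¹³C-CH₄ declining to its minimum at
the end of the run. A finite oxidant is the simulator's concrete stand-in
for whatever re-oxidizes sulfide in these incubations, which remains
unidentified in the field.

**Numerics.** The slow pools are integrated by explicit Euler (default
dt = 0.1 day) with a shared flux-rescaling step: if any pool would go
negative, all fluxes in that step are scaled by a common factor so the
limiting pool lands exactly at zero, preserving stoichiometric coupling.
Hydrogen cannot be treated that way: it is a ~10⁻⁹ M pool with ~10⁻⁴
M/day throughput (turnover ~1 second), the stiffest variable in the
system by five orders of magnitude. The default `h2_mode = "qss"`
therefore solves hydrogen quasi-statically at each step — the unique root
of supply(H) = demand(H), found by bisection in log₁₀ space (the balance
is monotone in H because demand rises and AOM-side supply falls with H) —
which is the standard treatment of a fast intermediate. The fully
explicit update (`h2_mode = "dynamic"`) is retained and is the mode used
by the stoichiometric unit tests, where rates are small enough for it to
be exact.

**Default scenario.** Three bottles, 11 mM initial sulfate, 21 °C, 586
days, monthly sampling, and a 1.7 mM methane amendment at −34.9 ‰ on day
44. The amendment matters for the isotopes: a ¹³C-heavy seed pool is what
keeps mid-incubation δ¹³C-CH₄ near −35 ‰ while gross methane cycling
turns the pool over, so that the plunge toward the biogenic end-member
is expressed only in the final net-methanogenic phase; without it, the
first bloom would drive δ¹³C to −80 ‰ immediately and the late decline
that characterises this system could not occur. The default amount is
kept below the bloom size so that the biogenic methane peak — not the
amendment — is the global methane maximum whose position the
event-ordering property tests. Kinetic constants were chosen to
reproduce the qualitative event sequence and magnitudes (sulfate below
1 mM around day 250–300; a transient hydrogen peak of a few nM; a
methane peak of ~2 mM about 80 days later, followed by a ~40% oxidation
dip and a final rise; early hydrogen at ~0.1 nM and late hydrogen within
a factor of ~2 of the threshold) and are not identified by any data —
they are documented study conditions, not estimates. Bottle-to-bottle
variability jitters the population kinetic constants (`v_sr`, `v_mg`,
`y_mca`; 5% CV, log-normal) but not the slurry chemistry (labile carbon,
iron, oxidant), because triplicates drawn from one homogenised slurry
share their substrate budgets — consistent with the tight replication of
sulfate depletion times observed in such experiments. Measurement noise
is multiplicative log-normal with CVs anchored to reported triplicate
errors (sulfate and methane ~6%, hydrogen ~20%, cell counts ~35%,
δ¹³C ±1 ‰ additive), with detection floors.

```{r events}
sim <- simulate_microcosm(sim_config(seed = 1))
sim_events(sim$truth)
```

**What the simulator does and does not emulate.** It reproduces the
transition's event sequence, the nanomolar hydrogen window around the
thermodynamic threshold, plateau structure, guild relative-abundance
shifts, and the isotopic signature of seed-pool replacement. It does not
attempt spatial structure or diffusion, oxygen-intrusion artifacts,
separate acetoclastic/methylotrophic pathways, DIC evolution (CO₂ is
fixed, as in the ΔG calculation it supports), or a distinct AOM-specialist
guild (the single methane-cycling guild reverses direction, reflecting
the inference that the same clades catalyze both directions while
canonical AOM specialists remain rare). Passing tests on simulated data
therefore demonstrate that the analysis stages recover what this model
generates under realistic noise — not that the model is a validated
description of any real incubation.

## Design choices and limitations

* **Temperature.** Incubations report both 21.4 °C (room) and 21 °C (the
  ΔG section); the package defaults to 294.15 K (21 °C) everywhere and
  carries one temperature per experiment in the bottle geometry. ΔG° is
  used as tabulated at 18 °C without temperature correction, exactly as
  the calculation it reproduces does.
* **Phase rules are a formalisation.** Incubation studies assign phase
  bars narratively; the rule set here is one defensible formalisation
  and all thresholds are configuration, not constants.
* **Sign test at n = 3.** With three bottles the exact two-sided sign
  test cannot go below p = 0.25; `consistent_increase()` reports the
  fraction of bottles increasing alongside p for that reason.
* **Problem sizes.** Tests and examples run the full 586-day scenario at
  dt = 0.1 day (a few seconds per bottle) and use 20-seed ensembles for
  recovery statistics, 100–1000-case property sweeps elsewhere; these
  sizes give stable medians while keeping the suite quick to run.
* **Known limitation.** The amended methane quantity "5.11 mM when
  equilibrated with porewater" for a 4 ml addition to a 40 ml headspace
  cannot be reproduced from the stated volumes with the ideal-gas law and
  standard Henry constants; the package does not attempt to, and the
  simulator's default amendment is an independent choice. Likewise the
  late-methane end-member is quoted as both −79 ‰ and −80 ‰ in the
  source material; −80 ‰ is used as the default biogenic end-member.
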