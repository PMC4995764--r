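---
title: "Skill learning and social learning in group foragers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skill learning and social learning in group foragers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skillforage)
```

## The model in brief

`skillforage` simulates foragers that must learn both *what* to eat and
*how* to eat it, in a spatially explicit, patchy environment, over
evolutionary time. Each forager carries eight heritable traits governing
movement, food choice and learning; energy gained through foraging feeds
an energy-weighted birth lottery, so trait combinations that support
better learning and foraging spread through the population. Social
influences on learning enter through three mechanisms that can be
switched on separately:

* **Local enhancement (LE)** is never programmed explicitly: it emerges
  because cohesive groups drag every member to the places where group
  mates forage.
* **Stimulus enhancement (SE)**: seeing a neighbour consume a resource
  type raises the observer's probability of choosing that type
  (strength `gamma`, with a 30-minute short-term memory; only one type
  is primed at a time).
* **Observational learning (OL)**: deliberately watching a more
  experienced neighbour process a resource transfers a fraction of the
  experience lead (probability `omega` of observing, duration up to
  `tau`, effectiveness `K`).

### Environment

The world is a continuous square (about 40 km² at full scale) with
toroidal boundaries and minimum-image distances. It holds 250 resource
species, partitioned exclusively over 50 patch types (5 species each);
each of the 24,500 patches is a 20 m disc carrying 1,200 items of 3
species drawn from its patch type's set. A species is defined by its
maximal per-item reward `Q` (drawn from Normal(0.1, 0.1); negative draws
redrawn by default), the practice time `H` to half-maximal processing
skill, and an integer sigmoid shape `S` in 1–4. All species share the
run's global `H`: task difficulty is an experimental condition, not
per-species noise. Consumed items reappear at the exact same positions
at each year boundary. Environmental change retires a uniformly chosen
living species with per-minute probability `EC / (360 × 720)` and
replaces all of its items with a freshly drawn, unknown species; a
sensitivity mode instead redraws only `Q` so that memories stay valid.

### Behaviour

Foragers act asynchronously through an event queue keyed by
action-completion times. After every completed action a forager runs the
decision cascade: *Am I safe?* (at least 9 group mates within 17 m;
groups too small to ever satisfy that count as safe when fully
gathered) — if not, step 1 m towards the group centroid. If safe, it may
observe a neighbour (probability `omega`), rest if its 20-item stomach
is full (1 minute), eat or approach a chosen item, continue or start a
relocation of `delta` meters (1 m steps at 0.5 m/s), or search. A search
assesses up to 20 random available items within 2 m, accepting an item
of type r with probability

$$P_F = \min\left[1, \left(\frac{a_{ir}}{a_{ie}}\right)^{\sigma_i}
 + \varepsilon_i (1 - c_{ir}) + d\,\gamma_i\right],$$

the sum of a selectivity term (expected reward relative to the
forager's self-tuned environmental expectation $a_{ie}$), exploration
damped by certainty, and stimulus enhancement. Eating takes one minute,
yields $e_{ir} = Q_r s_{ir} + N(0, Z)$ with skill
$s_{ir} = t_{ir}^{S}/(H^{S}+t_{ir}^{S})$, adds one minute of processing
experience, and reinforces the reward expectation and its certainty
(Rescorla–Wagner, rate `lambda`). Digestion every 100 minutes credits
stomach contents to energy, clears the stomach, expires satiation
aversions (a forager that fills up on one species ignores it for the
next 100 minutes), and nudges $a_{ie}$ up after a full stomach and down
otherwise (rate `phi`), so selectivity equilibrates where intake is just
about maximal.

### Demography

Metabolism debits energy every minute; foragers die of old age
(20 years), starvation, or an optional stochastic hazard. Every death
triggers an immediate replacement birth: the parent is sampled with
probability $h_i^W / \sum_j h_j^W$ (W = 3, negative energies clamped to
zero), pays 5,000 energy, and passes each unfrozen trait on with a 0.05
chance of mutation (normal kernel, s.d. one fifth of the trait maximum,
truncated to the bounds). Offspring are born at the parent's position in
the parent's group; groups exceeding 20 members split randomly into
equal halves, and a group vanishes with its last member.

## Design choices where the design was open

Several details are not pinned down by the model description above;
the package resolves them as follows (all are exposed as parameters).

* **SEARCH duration**: 1 s per item actually assessed, so an empty scan
  costs 1 s and a full one 20 s.
* **Relocation granularity**: MOVE covers `delta` meters as 1 m steps.
  Safety is re-checked between steps — cohesion is monitored
  continuously — but the other decision gates run only when a new action
  is chosen. (For solitary foragers there is nothing to re-check and no
  gate runs mid-move, so the engine coalesces the steps into a single
  action of the same total duration; state and random-number
  trajectories are identical.) An interrupted relocation (or pursuit of a chosen item) is
  abandoned: once a forager must regroup it forgets its food target.
  Without this, a straggler can ping-pong between its distant group and
  a stale target, and groups stretch into the hundreds of meters; with
  it, realised group spread sits in the tens of meters.
* **Safety boundaries** are inclusive; groups smaller than 10 are safe
  when fully within 17 m (otherwise small groups would be permanently
  "unsafe" and never forage).
* **Demonstrators** are sampled among the forager's own group mates
  within 20 m; stimulus enhancement claims at every safety check, with
  the newest observation displacing the previous one.
* **Observation without a demonstrator** still costs `tau` minutes and
  yields nothing: the direct effect of observational learning is a time
  cost.
* **Satiation threshold**: an aversion forms when a full stomach's worth
  (20 items) of a single species is consumed within one digestion
  cycle.
* **Processing-experience increment**: one minute (the EAT duration) per
  item consumed.
* **Initial state**: newborns know nothing (all $a_{ir} = c_{ir} =
  t_{ir} = 0$), start with $a_{ie} = 0.01$ (small and positive, so early
  choices are exploration-driven and the division in the food-choice
  rule is defined) and reserves of half the reproduction cost. Founders
  get twice the reproduction cost — enough to fund one replacement birth —
  because with newborn-level reserves an early death would force the
  richest founder into an energy debt and set off a starvation cascade;
  founder ages are spread uniformly over the lifespan so that mortality
  and replacement operate from the first simulated day.
* **Metabolism** defaults to `0.8 × (20 × 0.05) / 100` energy per
  minute: 80% of the income of a forager eating a full stomach of
  average-quality items each cycle, leaving a modest surplus for
  reproduction. The stochastic death hazard defaults to zero. Both are
  plain parameters.
* **Trait ranges** for movement distance (`delta` 1–20 m), selectivity
  (`sigma` 0–10) and the expectation-update rate (`phi` 0–1) bracket the
  values at which the food-choice rule shows its typical behaviour while
  keeping moves within patch scale.
* **Numerical guards**: $a_{ie}$ is kept within $[10^{-12}, 10^{6}]$.
  The update is multiplicative, and while young foragers can fill their
  stomachs by exploration alone the expectation grows geometrically;
  the cap merely truncates that transient overshoot before it overflows
  (dynamics near the equilibrium, at $a_{ie}$ of order 0.1, are
  unaffected). A realised reward of exactly zero makes the relative
  surprise in the certainty update undefined; it is treated as maximal,
  so certainty decays. Ties in the event queue resolve clocks first,
  then lower forager index.

## What the generator emulates — and what it does not

`generate_world()` reproduces the structured patchy landscape (and its
`pure`-patch and `random` sensitivity variants) with quality variation
across species but identical difficulty within a run. Real diets differ
in ways the generator deliberately omits: seasonal phenology, resource
depletion beyond the yearly consume/regrow cycle, spatial
autocorrelation of quality, and per-species differences in difficulty.
Passing tests therefore demonstrate the internal consistency of the
learning and evolutionary machinery under the stated ecology, not
calibration to any empirical foraging system.

### Satiation and diet diversity

The satiation threshold deserves a note. Read literally, a forager is
"satiated with a type" when a full stomach's worth (20 items) of that
single type is consumed within one digestion cycle; that is the package
default. In mixed patches (three species per patch) this threshold
almost never binds, so satiation then exerts no diversity pressure. A
binding operationalization — an aversion after a quarter of the stomach
(5 items of one type per cycle) — makes satiation enforce diverse diets
the way the mechanism is intended to. Both are the same configuration
parameter (`satiation_threshold`); the switch experiment below uses the
binding value.

## Scales used in tests and experiments

Full-scale runs (40 km², 29.4 M items, 1,000 years, 10 replicates per
condition) are cluster-scale. The package's own experiments and tests
use reduced worlds that keep every density and all structure intact
while dividing the area and patch count by a common factor
(`desk_params(scale)`):

One consequence of this scaling is worth keeping in mind: it divides
the total item count but not the population, so per-capita supply
shrinks by the same factor. At full scale each forager has about
294,000 items per year against a theoretical maximum consumption of
about 52,000; at `scale = 50` with 100 foragers the whole world can be
consumed in a fraction of a year, after which foraging is pulsed by the
yearly regrowth. Demographic results (constant population size under
death–replacement) are unaffected — replacement is instantaneous and
independent of the food supply — but experiments that need a
functioning foraging ecology throughout must pick the scale so that
items per forager-year comfortably exceed maximal consumption.

The sizes used:

* the demographic invariance run: `scale = 5` (8 km², 5.88 million
  items — about 59,000 per forager-year, a sustainable supply for the
  default population of 100 foragers), 5 simulated years;
* the switch experiment: `scale = 12` with 12 foragers (one group; about
  200,000 items per forager-year, roughly four times maximal
  consumption), 2 years with the mechanism switch at year 1,
  10 replicates, `H = 5` (slow skill acquisition), founders aged 17–20
  years so the population turns over during the run and naive learners
  are present on both sides of the switch;
* the evolutionary exploration-rate contrast
  (`scripts/epsilon_contrast.R`): `scale = 250`, 30 foragers, 30 years
  per run — far shorter than the canonical 1,000 years, so it shows the
  direction of selection rather than the equilibrated attractor.

These sizes are the package's documented desk-scale conditions; results
at full scale differ quantitatively (longer runs equilibrate $a_{ie}$,
trait means and group-size distributions more completely).

## The stimulus-enhancement switch at desk scale

The switch protocol equilibrates a grouping population without social
cues (local enhancement only), then imposes an evolved-strength
stimulus enhancement (`gamma` 0 → 0.1) on every living forager. Under
the source model the expectation is an immediate rise in diet
repertoire quality with a transient dip in consumed skill, because the
newly copied types are better than average but unpracticed.

The desk-scale runs in this package consistently show the *opposite*
sign for quality, and the acceptance test that asserts the expected
directions is deliberately left failing rather than weakened. The
mechanism, diagnosed from meal logs, is instructive. Stimulus
enhancement only changes behaviour towards types the observer would not
already choose (for a type valued above $a_{ie}$ the food-choice
probability is saturated and the social cue is redundant). After a year
of equilibration at desk scale, every group member has sampled
essentially every species, so the "demonstrated but not valued" set is
dominated by low-quality types that neighbours eat through residual
exploration — and local depletion leaves the *available* items inside a
foraged patch enriched in exactly those types. The copying loop then
multiplies consumption of rejected types: the most-consumed species
flip from qualities around 0.22 to around 0.02 within weeks of the
switch. For the social cue to point at good-but-unknown types, as in
the source model's full-scale runs, individual repertoires must remain
strongly idiosyncratic (the familiarity-bias lock-in of 1,000-year,
40 km² simulations); desk-scale worlds homogenize repertoires within a
year. This was robust across every configuration explored (SE strength,
expectation-update rate, selectivity, exploration rate, environmental
change rate, satiation threshold, task difficulty, and populations with
and without turnover).

## A worked miniature

```{r example, fig.width = 6, fig.height = 4}
params <- desk_params(scale = 1000, N = 10)
world <- generate_world(params, seed = 1)
pop <- init_population(params, evolvable_specs("SOL"), "SOL",
                       side = world$side, seed = 1)
sim <- simulate_foragers(world, pop, params, "SOL",
                         minutes = 2 * 720, seed = 1)
glance(sim)
```

The trace records population means every simulated day by default;
`tidy()` returns it in long form and `autoplot()` draws the standard
panels:

```{r plot, fig.width = 6, fig.height = 4}
autoplot(sim, vars = c("mean_energy", "items_consumed"))
```

The learning rules themselves are exported as vectorised functions
(`skill()`, `reinforce()`, `choose_food_probability()`, ...), so the
behaviour of a single rule can be examined — or tested — in isolation:

```{r rules}
skill(c(0, 1, 5, 50), H = 5, S = 2)
choose_food_probability(0.05, 0.1, sigma = 5, P_E = 0.01)
```

## Known limitations

* The asynchronous engine is single-threaded; replicates parallelise
  trivially at the R level but a single long run does not.
* Diet summaries weight each consumed type by the forager's *current*
  skill; in `replace_type` environmental-change mode the experience for
  a retired species is dropped, so lifetime diet summaries in rapidly
  changing worlds undercount skill for species that no longer exist.
  The per-interval trace statistics (used for the switch transient) are
  computed from skill at the moment of consumption and do not have this
  issue.
* Inheritance is asexual and groups are closed (no migration), as in
  the underlying model; the evolutionary dynamics are
  mutation-selection balance plus drift in lineages, not recombination.
* Desk-scale evolutionary runs show the direction of selection on the
  social-learning traits; equilibrated "evolved values" require
  full-scale horizons.
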