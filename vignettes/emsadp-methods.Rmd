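---
title: "Methods: two-tiered EMS dispatch and redeployment with monotone ADP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tiered EMS dispatch and redeployment with monotone ADP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsadp)
```

## The operating problem

An urban emergency medical service runs a *two-tiered* ambulance fleet:
advanced life support (ALS) units carry paramedics and can treat a
high-acuity patient from the moment they reach the scene, while basic life
support (BLS) units provide only basic care, so an actually high-risk
patient transported by a BLS unit effectively begins proper treatment only
at the hospital door. The call-taker assigns each incoming call a severity
class, but triage at call time is error-prone: an actually high-risk
patient is classified low-risk with probability $\alpha$ (undertriage) and
an actually low-risk patient is classified high-risk with probability
$\beta$ (overtriage). The true severity is revealed only when an ambulance
reaches the scene.

Two operational decisions recur. When a call arrives and at least one
ambulance is idle or relocating, one of them **must** be dispatched
immediately (no deliberate delay is allowed). When an ambulance finishes
its hospital handover and no patient is waiting, it must be **redeployed**
to a waiting base with a free slot (at most two ambulances per base).
Waiting patients form two FIFO queues; a classified-high patient always
pre-empts classified-low patients regardless of arrival order. Transport
always goes to the hospital nearest the scene.

## The objective: risk level index

Per served patient the package scores the *time to proper care*
$\mathrm{RT}_{PC}$: the response time (report to scene arrival), except
that a BLS transport of an actually high-risk patient extends it to
hospital arrival. The risk level index is

$$
f(\mathrm{RT}_{PC}, S) =
\begin{cases}
C_H \cdot \mathrm{RT}_{PC} + \mathrm{Penalty}\cdot
  \mathbf{1}\{\mathrm{RT}_{PC} > \mathrm{RTT}\} & S = \text{high}\\
C_L \cdot \mathrm{RT}_{PC} & S = \text{low}
\end{cases}
$$

with defaults $C_H = 1$ /min, $C_L = 0.25$ /min, Penalty $= 30$,
RTT $= 7$ min. The indicator is strict ($>$), so a response at exactly the
threshold is not penalised. Under the defaults, one high-risk minute is
worth four low-risk minutes and breaching the threshold costs as much as a
30-minute delay. Episode scores average $f$ over all patients whose calls
arrive in the post-warm-up horizon.

Because the dispatcher sees only the classified severity, policies value a
dispatch by the *posterior-weighted expected* index. With prior
$p = \Pr(\text{actually high})$, Bayes' rule gives
$\Pr(H\mid H^C) = (1-\alpha)p / [(1-\alpha)p + \beta(1-p)]$ and
$\Pr(L\mid L^C) = (1-\beta)(1-p) / [\alpha p + (1-\beta)(1-p)]$
(`posterior_probs()`). The expected immediate contribution of sending an
ambulance to a patient (`expected_contribution()`) mixes the high and low
branches with these weights, uses the deterministic expected response time
(accrued wait plus travel time for the distance), and — for a BLS unit —
measures the high branch to expected hospital arrival, adding the mean
on-scene service time ($\theta_s k_s = 22.13$ min) and the travel time from
patient to nearest hospital. Redeployments contribute zero immediately;
their worth is entirely in the future.

## Policies

* **Myopic**: nearest available ambulance; nearest feasible base.
* **Greedy**: dispatch minimising the expected immediate contribution;
  nearest feasible base for redeployment (it wants the ambulance idle again
  as soon as possible).
* **ADP**: minimises contribution plus $\gamma \bar V(\text{post-decision
  aggregate})$ for both decision kinds, with $\bar V$ a learned lookup
  table and $\gamma = 0.9$ per decision epoch (constant per epoch, not per
  elapsed minute, since epoch lengths are random).

All argmins break ties by shorter travel time, then lower ambulance/base
id, so paired runs are exactly reproducible.

## The semi-MDP simulator

The engine (C++ via Rcpp) advances event to event: call arrival, scene
arrival, hospital arrival, handover completion, base arrival. Decision
points are call arrivals with a nonempty candidate set (idle or relocating
ambulances; units already en route to a patient or hospital cannot be
diverted) and handover completions (queue head dispatch if anyone waits,
else redeployment). A relocating ambulance that is dispatched frees its
reserved base slot at that instant; its position is interpolated linearly
along the current leg. Events tie-break on (time, fixed kind order, id);
a superseded base-arrival event (its ambulance was dispatched mid-leg) is
recognised by a per-ambulance sequence number and discarded.

Travel time is Euclidean distance divided by the hourly speed in effect at
departure, held for the whole leg — legs are a few minutes long against
one-hour speed bins, so the error is small. Road-network routing is out of
scope.

Every stochastic input of an episode — call epochs, locations, actual and
classified severities, and both gamma service durations — is drawn up
front by `sample_calls()` on six named substreams derived from one master
seed. The simulator itself is deterministic given that call table. Common
random numbers (CRN) across policies therefore hold *by construction*:
`crn_compare()` hands the identical table to every policy and verifies a
checksum. Call epochs come from thinning a homogeneous Poisson process at
the profile's maximum rate, which is exact for piecewise-constant
intensities.

## The synthetic default scenario

`default_scenario()` emulates a dense urban EMS district: a 6 × 6 km
box, six two-slot bases on a regular grid, three hospitals, six
ambulances (ALS share 0.83 by default, i.e. 5 ALS + 1 BLS, the count being
`round(ratio × 6)`), 127.9 calls/day of which 24.8% are actually
high-risk, gamma on-scene service (scale 3.57, shape 6.2; mean 22.13 min)
and gamma handover (scale 5.02, shape 3.0; mean 15.06 min), a diurnal call
profile (night trough ≈ 0.4× the daily mean, late-morning and evening
peaks ≈ 1.25×) and a diurnal speed profile (38–42 km/h at night, 21–26
km/h in congested hours). Demand spreads over a 3 × 3 district grid with a
centre-heavy weight surface; within a district, call locations are
uniform.

Two calibration notes. First, the box size: with ~37 minutes of fixed
(non-travel) service per call, 127.9 calls/day over six ambulances leaves
roughly 0.55 erlangs per ambulance before travel. On a much larger box,
travel pushes sustained peak utilisation above one and the queue — which
the modelled system treats as a rare event — dominates every metric. The
6 × 6 km box (matching the ~34 km² of a dense district of this
population) keeps the non-queued mean response time near 5 minutes while
still producing meaningful peak-hour contention. Second, the peak
multiplier: 1.25× is typical of observed EMS diurnal profiles and keeps
peak utilisation below saturation. Both were fixed once, from these
considerations, as the package's study conditions.

What the generator does **not** emulate: real road networks and
travel-time asymmetries, spatially varying speeds, inter-day demand
heterogeneity (weekday/weekend), multi-patient incidents, hospital
diversion, and the empirical district shapes of any real city. Passing
tests on this generator show the algorithms behave as designed under a
plausible urban regime — not that the absolute numbers transfer to any
particular city.

## The learner: mini-batch monotone ADP

**Aggregation.** The value table is indexed by a 19-dimensional key: for
each cell of the 3 × 3 spatial grid, the number of available (idle or
relocating) ambulances and the number of patients awaiting assignment,
plus a time zone — 1 for [01:00, 08:00), 2 for [08:00, 11:00), 3 for the
remainder (half-open; the zones reflect demand regimes). Idle ambulances
count in the cell of their current position. A relocating ambulance counts
in the cell of its **destination base**: at the post-decision instant of a
redeployment no time has elapsed, so counting it at its current
(hospital) position would map every candidate base to the same key and
make redeployment invisible to the value function. Destination counting
keeps the "a redeployment leaves the available total unchanged" identity
while giving each destination a distinct post-decision key — it is what
lets the learner express a preference for relocating toward future demand.

**Updates.** At every decision point the learner evaluates each feasible
action's contribution plus $\gamma \bar V$ of its post-decision key, takes
the minimum $\hat v$ as a sample of the pre-decision value, acts by the
argmin, and applies $\hat v$ to the *previous* decision's chosen
post-decision key with the harmonic step $\delta = 1/n$ ($n$ = cumulative
visits): the first visit stores the sample exactly, repeated constant
samples are a fixed point, and the schedule satisfies the
stochastic-approximation conditions ($\sum\delta = \infty$,
$\sum\delta^2 < \infty$). Updates are online within the episode. Unseen
states default to zero, which is optimistic under minimisation and drives
the early exploration; no explicit $\varepsilon$-scheme is used.

**Monotone projection.** State $s$ dominates $s'$ (same zone) when it has
at least as many available ambulances and at most as many pending patients
in every cell; a dominating state should never have the larger value. The
projection operator, given a reference $(s^r, z^r)$, sets
$\bar V(s^r) = z^r$, caps every state dominating $s^r$ at $z^r$ and floors
every state dominated by $s^r$ at $z^r$. Applying it to every stored state
after each update would be quadratic, so at the end of each iteration the
package samples up to ten visited states per time zone, with probability
proportional to visit count and without replacement (distinct references
maximise coverage), and applies the operator sequentially, re-reading each
reference value after the previous projection.

The projection's soundness rests on the dominance relation actually
ordering the *true* values. That assumption can fail when aggregation
hides where the busy ambulances are headed: in a single-ambulance world,
the post-redeployment state (one available ambulance, committed to base
$b$) dominates the everyone-busy post-dispatch state, yet its true
cost-to-go is strictly higher whenever responses have positive cost
($V_{kb} = c + \gamma V_e$ with $V_e = \gamma V_{kb}$ forces
$V_{kb} > V_e$). Under that violation the projection squeezes the
redeployment keys onto the post-dispatch value and erases the learned
ordering between destinations. The package's enumerable verification world
therefore schedules its single daily call so that dispatch decisions fall
in time zone 2 and redeployment decisions in zone 3: the two families of
keys are pairwise incomparable, the projection runs but binds nothing, and
the learner's fixed point can be compared to the exhaustively enumerated
optimum. In the six-ambulance default scenario the assumption is a far
milder idealisation — no base is catastrophically placed and availability
genuinely orders outcomes — but users adding extreme geographies should
keep this failure mode in mind.

**Richer dominance.** A four-condition order (per-base idle ALS, per-base
idle total, per-region pending high, per-region pending total) would be
strictly finer but needs a 37-dimensional key that splits counts by
ambulance type and severity class; the 19-dimensional key cannot express
it. The package implements dominance on the stored 19 dimensions — a sound
weakening (any 19-dimensional dominance implies the finer one whenever
both are defined).

**Training loop.** `train_adp()` runs one warm-up-plus-horizon episode per
iteration (defaults 1 + 7 days, matching evaluation), with a fresh call
stream per iteration derived from the master seed, and the mini-batch
projection at each iteration's end. Termination is by iteration budget;
wall-clock limits are hardware-dependent and therefore not part of the
study conditions. The learning curve records each iteration's mean RLI
(`learning_curve()` averages it in 100-iteration windows).

## Numerical and design choices

* **Tie-breaks** everywhere: value, then travel time, then lower id.
  Event queue: time, then kind (arrivals before completions), then id.
* **Strict penalty inequality** ($\mathrm{RT}_{PC} > \mathrm{RTT}$).
* **Zone boundaries half-open**; 08:00 belongs to zone 2, 11:00 to zone 3.
* **One queue-head assignment per handover completion**; the candidate
  ambulance for a queued patient is exactly the ambulance that completed
  the handover.
* **Actual severity becomes known at the scene** and determines
  $\mathrm{RT}_{PC}$ and the RLI; the classified label is never revised
  and there is no re-dispatch.
* **Degenerate inputs**: zero demand yields an empty, zero-RLI episode;
  a travel leg of zero distance takes zero time; `posterior_probs()`
  signals an error when a classified class has probability zero.
* **$\gamma = 0$ reduction**: with a zero discount the learner's decisions
  coincide exactly with greedy (the table cannot influence any argmin).
  With $\gamma > 0$ the *first* iteration is only approximately greedy,
  because online updates within the episode can reuse a key.
* **Problem sizes** used by the test-suite verification runs: 2,000
  training iterations and 30 CRN replications of 1 + 7-day episodes for
  the policy comparison; 15 replications per cell for factor sweeps; 100
  iterations for the toy world; $10^6$ draws for service-time means;
  1,000 random tables (≤ 200 states) for the projection oracle.

## Known limitations

* Euclidean travel on a planar box; no routing, no turn or dispatch
  overhead times.
* The dominance assumption can be violated by aggregation (see above);
  the projection is then a biasing regulariser rather than a sound
  constraint.
* No patient abandonment, call cancellation, multi-patient incidents or
  hospital congestion.
* The factorial machinery reports main-effect and interaction cell means,
  not a formal multiway ANOVA.
* Absolute metric levels depend on the synthetic geography and profiles;
  only directional and paired contrasts are meaningful claims.
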