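---
title: "An artificial immune–tumor ecosystem under thermoradiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An artificial immune-tumor ecosystem under thermoradiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itesim)
```

`itesim` simulates an *artificial* immune–tumor ecosystem: a deliberately
simplified, fully specified dynamical system in which one can study how
fractionated radiotherapy (RT) and mild hyperthermia (HT, 42 °C sessions)
interact with an adaptive immune response. It is a laboratory for dynamics,
not a patient model: every mechanism is an explicit ordinary differential
equation, every treatment event is a scheduled switch, and the whole system
is deterministic.

## The ecosystem

Nine tumor sub-clones $T_{ik}$ (generation $i$, branch $k$) and host tissue
$H$ compete in one tissue compartment, with populations normalized to
$10^9$ cells. Each sub-clone obeys

$$\frac{dT_{ik}}{dt} = \Bigl(k_T - k_{eT} - r_{ik} k_{IT} - k_{HT} H -
k_{TT} T - (\alpha_T + 2\beta_T \Gamma_T) R \Bigr) T_{ik}
+ k_{mut} q_{il} T_{lk},$$

i.e. logistic-type growth against the *total* tumor burden $T=\sum T_{ik}$,
baseline cell death $k_{eT}$, immune-mediated kill $r_{ik} k_{IT}$,
host interference $k_{HT}H$, radiation kill (below), and mutation along a
tree encoded by the routing matrix $q$. As printed in the model's
formulation, only the founder clone carries an explicit mutation outflow
$-k_{mut}T_{11}$; a per-clone outflow for every parent is available as a
switch (`mut_outflow_all`) and off by default. The host follows the same
structure with its own growth, self-inhibition $k_{bH}H^2$ and competition
$k_{TH}T$ terms.

Without immune kill the equilibria are
$T_{eq} = (k_T - k_{eT})/k_{TT} = 306$ and
$H_{eq} = (k_{aH} - k_{eH})/k_{bH} = 249.92$ (about 250), which
`equilibrium_levels()` returns analytically and the engine reproduces in
free evolution. Note a structural property of the default constants: since
$k_{TH} T_{eq} = 0.067 > k_{aH} = 0.03$, a fully grown tumor competitively
excludes the host, so by treatment start the host population is tiny and
recovers only after the tumor is cleared (from roughly day 800 on). The
host-directed immune response during treatment is correspondingly weak.

## Dying cells, danger and antigens

Eliminated cells (baseline death, immune kill, radiation kill — and only
those terms; growth, competition and mutation do not kill) enter a
pre-immune-stimulatory pool $N_p$, transform at $k_{pn}$ into an
immune-stimulatory pool $N$ (cleared at $k_n$), and only host cells can
additionally exit silently (non-immunogenic apoptosis, $k_{ap}$). The
danger signal is a squared sigmoid of the total immune-stimulatory pool,
$D = S^2/(L_{act}^2 + S^2)$, with half-activation at $S = L_{act}$.

Every population bears a binary antigen pattern (a column of the matrix
$P$). The signal of component $n$ pools the effective antigen-presenting
mass $\tilde T = T + \eta N_p + \chi N$ of all bearers and passes it
through the same squared sigmoid with level $X_{act}$. Dead cells therefore
keep presenting antigen, down-weighted by $\eta$ and $\chi$.

## The perceptron and effector cells

The adaptive immune system is a single trainable unit. Weights evolve by a
continuous-time delta rule gated by antigen presence,
$\dot w_i = a (D - Y) X_i$, and the response is
$Y = \Sigma^\xi/(Y_{act}^\xi + \Sigma^\xi)$ with $\Sigma = \sum_i w_i X_i$.
Two interpretation choices were open and are resolved as follows
(both were genuinely underdetermined by the printed equations):

* **Negative drive.** With odd $\xi$ a negative $\Sigma$ would give a
  negative $Y$; a negative production rate is meaningless, so $Y$ is
  clamped to 0 for $\Sigma \le 0$. This is what makes the
  "immune-suppressive" negative-weight regime after host regrowth
  well-defined: the perceptron simply stops driving effector production.
* **Effector consumption.** Effector cells are consumed by the elimination
  events they mediate. The printed consumption term
  $k_{IT}(\sum_{i,k} r_{ik} T_{ik})_n$ does not spell out the component
  attribution; because $r_{ik} = \sum_n I_n P_{n,ik}$, the total matched
  kill decomposes exactly into per-component shares
  $I_n \sum_{ik: P_{n,ik}=1} T_{ik}$, and that per-effector form is the
  default (each component's effectors pay for the kills they mediated). The
  literal matched-total variant is available via
  `consume_per_effector = FALSE`.

Effector production is $k_I Y X_n$, elimination $k_{eI}$, plus radiation
kill through the effector dose equivalent.

## Radiation: a dynamic linear-quadratic law

Radiation enters as an instantaneous death rate
$(\alpha + 2\beta\Gamma) R$ driven by the transient biological dose
equivalent $\dot\Gamma = R - \gamma \Gamma$, separately for tumor, host and
effector cells. For an acute fraction this integrates to the classic
$\alpha d + \beta d^2$; protraction at the machine dose rate (0.14 Gy/min)
with $\gamma_T = 3\,\mathrm{d}^{-1}$ reduces the quadratic term slightly
(by about 1 % per 2-Gy fraction), and incomplete repair between close
fractions raises it. Fractions are square pulses: dose at constant rate
$R_0 = 201.6$ Gy/d for $d/R_0$ days.

An important quantitative consequence of the default coefficients
($\alpha_T = 0.28$ Gy$^{-1}$, $\beta_T = 0.05$ Gy$^{-2}$): one 2-Gy
fraction kills $\approx 0.76$ ln units ($SF_2 \approx 0.47$), so a 32 × 2 Gy
course delivers $\approx 24$ ln of gross kill against at most
$\approx 1.4$ ln of intra-course regrowth. The post-treatment tumor nadir
is therefore of order $10^{-13}$–$10^{-11}$ (in units of $10^9$ cells) in
every protocol, and the tumor control probability
$TCP = e^{-T_{min}}$ is 1.000 to ten decimals across the board. Protocol
*differences* remain well-resolved in floating point (the nadirs differ by
orders of magnitude), so protocol rankings and effect orderings are
meaningful; absolute TCP values near 0.8–0.99 are not reachable with these
coefficients. This is a property of the parameter set, reproduced here
as given; no coefficient was adjusted to move TCP toward any particular
value.

## Hyperthermia

Sessions are fixed: 60 min at 42 °C, ending 30 min before the paired
fraction. Temperature is never a state variable; the entire HT effect is
carried by two first-order kinetic states and one fixed factor pair:

* **Radio-sensitization.** During beam-on of an HT-paired fraction
  (a fraction starting within 2 h after a session ends), $\alpha_T$ is
  multiplied by 1.96 and $\beta_T$ by 0.34. Host and effector
  sensitivities are never modified, and $\gamma_T$ stays at 3/d.
* **Fast process (perfusion).** $\dot\theta = k_{perf1} - k_{perf2}\theta$
  while heating (rates 200/d, time constant 7.2 min), pure relaxation
  otherwise; $PEF = 1+\theta \in [1,2]$. It scales the effector
  production/migration rate: $k_I' = PEF \cdot k_I$.
* **Slow process (immune stimulation).** Same structure at 7/d, but its
  drive switches on one day after a session starts and stays on for 24 h,
  so $ISF = 1+\phi$ peaks near 2 about 48 h after heating and is back
  below 1.05 by 72 h. It lowers the activation levels:
  $X_{act}' = X_{act}/ISF$, $L_{act}' = L_{act}/ISF$ (a fast, $PEF$-based
  variant of both is a per-run switch, `mode = "fast"`).

All modifications are pure functions of the base parameters and
$(\theta,\phi)$ — they never compound.

## Treatment schedules

All protocols deliver 32 fractions of 2 Gy from day 570. `RT1` places 5
fractions per week (weekdays); `RT2` places 6 per week and finishes about a
week earlier. The HT protocols pair sessions with fractions: `HT1` — 4
weekly sessions (fractions 1, 6, 11, 16); `HT2` — 10 sessions on the first
10 fractions (front-loaded); `HT3` — 10 sessions, two per week over five
weeks. The RT2 pattern and the session placements are this package's own
concrete realizations of the qualitative protocol descriptions (front-loaded
vs. spread vs. sparse); they are data, not code — any explicit fraction-day
or session-start list can be supplied instead, in code or in the config
file.

The default topology is likewise a constructed realization of the stated
pattern constraints (see `?default_topology`): component 1 shared by
exactly the four first-generation clones, one private neo-antigen per
deeper clone, three host-only components so that host-directed effector
populations behave identically. It ships as a YAML file
(`inst/extdata/topology_default.yaml`) and alternative topologies can be
loaded without code changes.

## Numerics

* Classical fixed-step RK4 at $dt = 10^{-3}$ d over 1800 simulated days
  (1.8 million steps), implemented in compiled code; an R composition of
  the module right-hand sides (`ecosystem_rhs()`) mirrors it term by term
  and is checked against it and against an adaptive `deSolve::lsoda`
  reference in the tests (agreement to $10^{-6}$ relative over a 30-day
  window; in practice $\sim 10^{-8}$).
* Treatment events are realized as per-step flags. Beam windows are
  snapped to whole grid steps and the in-window dose rate rescaled so each
  fraction delivers exactly 2 Gy regardless of $dt$ — TCP is exponential
  in integrated kill, so dose bookkeeping must be exact. Halving $dt$
  changes the TCP by far less than $10^{-4}$.
* RK4 can undershoot zero during steep kill phases; populations are
  clipped to zero after each step and the clipped mass is reported
  (`summary$clipped_mass`; zero in the default runs). $\theta,\phi$ are
  clipped to $[0,1]$, their invariant range.
* Initial conditions (not part of the published account): host at
  $H_{eq}$, founder clone at $10^{-2}$ ($10^7$ cells), everything else
  zero. The tumor then reaches its carrying capacity to within about
  0.1 % by treatment start (day 570). With this start the single-clone
  logistic is still 0.11 % away from 306 at day 560 — convergence checks
  against the analytic equilibrium are therefore asserted long-run
  (day 650) rather than at day 560.
* Everything is deterministic: identical configurations give bit-identical
  trajectories.

Problem sizes used by the test-suite: module tests run on closed forms and
short windows; the property and acceptance tests use a handful of full
1800-day runs at the default step (a few seconds each in compiled code)
plus one half-step run for the grid-refinement check.

## What the simulations do and do not show

The engine generates all study inputs itself (parameters, topology,
schedules); there is no external data. Passing tests show that the
implementation integrates the stated model faithfully — equilibria,
sigmoid activations, LQ limits, HT kinetics, orderings across protocols
(front-loaded HT best, sparse HT worst, HT effect larger than the
fractionation-scheme effect). They do not show anything about real
tumors: the model has no immunological memory, no systemic immunity, no
spatial structure, no thermo-tolerance, a one-compartment host, and an
abstract single-layer learner in place of an immune repertoire. The
absolute TCP scale is additionally sensitive to the radio-sensitivity
coefficients in a way the printed parameter set does not resolve (see the
radiation section above); quantitative TCP values from this package should
be read as properties of the artificial system only.

## Worked example

```{r example, eval = FALSE}
rt <- build_rt_schedule("RT1")
sim0 <- simulate_ecosystem(rt = rt, ht = build_ht_schedule("HT0", rt))
sim2 <- simulate_protocol("RT1HT2", flag_set = "all")
dplyr::bind_rows(glance(sim0), glance(sim2))
autoplot(sim2)                      # tumor and host burden, log scale
autoplot(sim2, "effectors")         # per-component effector populations
```
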