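---
title: "Homeostatic reinforcement learning: model, tasks, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic reinforcement learning: model, tasks, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrlsim)
```

## The model

`hrlsim` simulates an agent whose motivation is a *drive*: the distance
between its internal nutrient state $H_t$ and a physiological setpoint
$H^*$ in a homeostatic space,

$$D(H_t) = \Big(\sum_{i=1}^{N} \eta\,\lvert H^*_i - H^i_t \rvert^{\,n}\Big)^{m/n},$$

with distance exponents $(m, n) = (3, 4)$ by default and an interoceptive
gain $\eta \ge 0$. The reward of an action is the *reduction in drive* the
agent predicts it will cause:

$$r_t = D(H_t) - D\!\big((1 - \tfrac{1}{\tau})H_t + \hat K_t - c\big),$$

where $(1 - 1/\tau)$ is the natural per-step nutrient decay, $\hat K_t$ is
the agent's learned prediction of the nutrient content of the chosen action,
and $c$ is any direct cost (climbing, below). Negative rewards are
*punishments*. The actual intake $K$, not the prediction, drives the state
transition $H_{t+1} = (1 - 1/\tau)H_t + K - c$; the prediction is updated by
a delta rule $\hat K \leftarrow \hat K + \alpha^{\hat K}(K - \hat K)$, so
its error contracts geometrically. Behavior is ordinary tabular Q-learning:
TD errors $\delta = r + \gamma \max_{a'} Q(a') - Q(a)$, updates
$Q \leftarrow Q + \alpha^Q \delta$, and a softmax policy with inverse
temperature $\beta$. Feeding therefore *emerges* from reward maximisation:
eating is valuable exactly when, and only as long as, it moves the internal
state toward the setpoint.

The gain $\eta$ models interoception — how strongly the deviation from the
setpoint is felt by the time it reaches the reward system. $\eta = 1$ is
veridical; $\eta < 1$ blunted; $\eta > 1$ exaggerated. Because $\eta$ enters
the drive inside the sum, in one dimension it rescales every drive and
reward by the constant $\eta^{m/n}$; its behavioral effect is therefore
equivalent to rescaling the softmax inverse temperature, while its effect on
the *reported* reward stream is a direct change of gain. Both faces matter
below.

### Perceived versus veridical quantities

Every trajectory records two parallel streams:

* the **modulated** drive and reward (with the agent's $\eta$) — the signal
  the agent learns from, an analogue of reward-system activity;
* the **veridical** drive and reward (recomputed with $\eta = 1$) — what
  actually happened to the internal state.

The condition-level metrics split accordingly, and this is a deliberate
design decision. `avg_reward_per_intake()` uses the modulated reward: it
quantifies how strongly the reward system responds per feeding event, and
it scales with $\eta$. `sum_drive()` and `sum_punishment()` use the
veridical stream: they quantify homeostatic *failure* — cumulative time
spent away from the setpoint and transitions that genuinely worsened the
state. If all three metrics used the modulated stream, the multiplicative
factor $\eta^{m/n}$ (0.41 at $\eta = 0.3$) would mechanically dominate any
dwell-time effect of dysregulated behavior, and a blunted-interoception
agent would appear to accumulate *less* drive simply because it feels less —
the opposite of what its actual internal state does. With the split, a
blunted agent shows smaller rewards per intake (gain effect) *and* larger
accumulated drive and punishment (behavioral effect), which is the
scientifically meaningful pattern. At $\eta = 1$ the streams coincide, so
control, low-$\beta$ and low-$\gamma$ conditions are unaffected by the
distinction.

## The two tasks

**Intake after food restriction.** One external state, two actions (`intake`
delivers $K$, `nothing` delivers 0), a fixed 100-step horizon, and a
deficit start $H_0 = 100$ against $H^* = 200$. The agent must first learn
that eating closes the deficit, then learn to stop near the setpoint — with
a single external state the Q-table cannot condition on $H$, so homeostasis
is maintained by continuous relearning as the state crosses the point where
eating stops being beneficial.

**Mountain climbing.** Eight states $S_0..S_7$. At the bottom the agent can
take a small intake (staying put) or move to $S_1$; at $S_1..S_6$ it climbs
(paying a nutrient cost on top of decay) or goes back down; at the summit a
large intake ends the episode and resets the agent to $S_0$ with $H = 100$,
carrying its tables over. A trial is 15 consecutive episodes; a 5000-step
cap per episode marks censoring. The task opposes a small immediate reward
(snacking at the bottom) to a large delayed one behind a run of punishments.

## Default parameters and why

| parameter | intake task | mountain task | rationale |
|---|---|---|---|
| $H^*$, $H_0$ | 200, 100 | 200, 100 | deficit start equal to half the setpoint |
| $(m, n)$ | (3, 4) | (3, 4) | standard homeostatic-space exponents |
| $\tau$ | 25 | 100 | see below |
| $K$ | 12 (intake) | 20 (small), 120 (large) | see below |
| climb cost | — | 10 | punishment on the path to the summit |
| $\alpha^Q$, $\alpha^{\hat K}$ | 0.05, 0.5 | 0.1, 0.5 | slow value tracking, fast intake prediction |
| $\beta$ | 1.6e-5 | 2e-7 | rewards reach $10^5$–$10^6$, so useful $\beta$ is of order $1/\mathrm{reward}$ |
| $\gamma$ | 0.9 | 0.9 | control value; 0.2 in the myopic condition |
| conditions | $\eta \in \{0.3, 1, 1.7\}$, $\beta/4$, $\gamma = 0.2$ | same | blunted/exaggerated gain inside the explored $0 < \eta < 2$ range |
| replicates | 40 episodes | 30 trials × 15 episodes | condition-level sample sizes |

The two tasks use different $(\tau, K)$ regimes on purpose. The pair
$(\tau, K)$ fixes two structural quantities: the *ceiling* $K\tau$ (the
internal state an always-eating agent converges to) and the sustainable
intake probability at the setpoint, $H^*/(K\tau)$. For the intake task we
use $K\tau = 300$, slightly above $2H^*$: a non-learning (random) agent then
drifts to $K\tau/2 = 150$ and stays mildly deficient, while a learned policy
holds the setpoint with intake chosen about two-thirds of the time — so
$Q(\mathrm{intake}) > Q(\mathrm{nothing})$ at equilibrium, feeding is the
default interrupted by pauses, and blunted gain visibly degrades regulation.
Regimes with slow turnover ($K\tau \gg 2H^*$) make the sustainable intake
rate so low that doing nothing must dominate the Q-table, and regimes with
$K\tau/2$ near $H^*$ make random behavior indistinguishable from regulation;
both were rejected after systematic exploration. The mountain task keeps
slow turnover ($\tau = 100$) so that a trial's climbs drain the state
gradually and the climb cost, not decay, is the operative punishment.

## What the simulations show, and a caveat the reader should know

The packaged study conditions reproduce the intended intake-task pattern
(verified by the test suite): blunted interoception lowers the reward per
intake, raises accumulated punishment and drive, and lowers total intake;
exaggerated interoception shifts all three the other way (directions
reproduce; at $N = 40$ the punishment/drive improvements of the exaggerated
model are small relative to between-seed variance, because the control agent
already regulates well).

The mountain task behaves differently from what one might expect from the
intake task alone, and the package reports what the model actually does.
Drive-reduction rewards telescope: over any state path the summed reward
equals the net drive reduction plus losses, so *total* return cannot favor
costly climbing per se; what makes the summit valuable is episode
termination (a fresh, reward-rich deficit episode follows, which value
iteration sees through the carried-over tables). Against this stands the
bottom-state snack, which is immediate, always available at the deficit
episode start, and — through the $\gamma$-bootstrap — inflates the value of
staying at the bottom long before the eight-state summit chain has
propagated. Across a wide parameter exploration (snack sizes 5–40, summit
intakes 120–165, $\beta$ over three orders of magnitude, all learning
rates), summit attainment in this architecture *decreases* monotonically
with the weight the policy puts on learned values: a near-random explorer
reaches the summit sooner than an exploiting learner, and amplifying the
reward stream (exaggerated interoception) strengthens the snack attractor
and the felt climb punishments, impairing summit pursuit. The packaged
conditions therefore show: exaggerated gain — lower summit rate, longer
trials, more snacking; blunted gain — the lean opposite, with fewer small
intakes than control. This matches the interpretation of exaggerated
interoception as overestimating the immediate punishments and small rewards
on the way to a large delayed reward, and it is asserted as such in the
test suite; the myopic ($\gamma = 0.2$) and noisy ($\beta/4$) variants
differ from control mainly in trajectory detail rather than in summit
attainment under these conditions.

## Numerical and design choices

* **Softmax** is computed with max-subtraction, so $\beta Q$ products up to
  the overflow limit are safe; $\beta = 0$ is exactly uniform.
* **No clamping** of the internal state: the dynamics impose no bounds and
  clamping would distort drive gradients near the boundary.
* **Operation order** in a step: decay, then intake, then cost — the cost
  is thereby independent of $\tau$.
* **Cost in the reward**: the climb cost enters the predicted next state in
  the reward, so the punishment of climbing is felt at decision time, not
  only through the later state.
* **Terminal bootstrap**: the summit intake bootstraps from $S_0$ (the next
  episode's start state) rather than a zero terminal value, because tables
  are carried across episodes.
* **Ties** in $\max_{a'} Q$ need no tie-breaking: only the maximum value
  enters the TD target.
* **$\eta$ placement**: the gain multiplies
  $\lvert H^* - H\rvert^{\,n}$ inside the sum (not the deviation before
  exponentiation). In one dimension the two readings differ only in the
  effective exponent of the rescaling ($\eta^{m/n}$ vs $\eta^{m}$); we use
  the first and do not expose a switch.
* **Bottom-state wiring**: the small intake self-loops at $S_0$ (repeatable
  minor feeding); $S_1$'s second action is the horizontal move back to
  $S_0$; the summit's second action descends to $S_6$ by symmetry with the
  middle states.
* **$\hat K$ initialisation** is 0, matching the Q-tables; the first
  predicted reward of an untried intake is therefore conservative.
* **Censoring** (step-cap exhaustion) is recorded on the trajectory and
  counted per condition, never raised as an error. The control conditions
  run censoring-free.
* **Replicates** are fully independent: fresh agent, fresh environment,
  seed `base_seed + i`; condition arms get disjoint seed blocks.

## Statistical protocol

Between-condition comparisons follow the variance-gated protocol:
Levene's test on absolute deviations from the group means
(`car::leveneTest(center = mean)`, the classical centering) decides at
$\alpha = 0.05$ between Student's pooled t-test and Welch's t-test;
the Wilcoxon rank-sum test is available as an alternative for count-like
metrics. Reported p-values are two-sided, with the direction of the mean
difference carried separately, and replicates with undefined metric values
(no intake in an episode) are dropped pairwise with the count reported.
No multiple-testing correction is applied.

## What the simulator does and does not emulate

The simulator generates the study's own data; it does not ingest external
data. It emulates nutrient homeostasis as a one-dimensional, deterministic
drive with exponential decay, deterministic intake amounts, and a constant
interoceptive gain. Real feeding involves multiple interacting nutrient
axes, stochastic and state-dependent intake, hormonal and circadian
modulation of the gain, and bounded physiology — none of which are modelled.
Passing tests therefore show that the *mechanism* (gain-modulated
drive-reduction learning) produces the documented behavioral contrasts
under these idealised conditions, not that the parameter values describe
any organism.

## Known limitations

* The single-state intake task aliases all internal states onto one
  Q-table row; homeostasis is oscillatory relearning, and about one seed in
  ten shows final-window excursions beyond 30 nutrient units under the
  default conditions.
* Mountain-task learning does not surpass random exploration in summit
  attainment under these dynamics (see above); conclusions about the
  $\beta$ and $\gamma$ manipulations there are accordingly weak.
* Rewards span six orders of magnitude across an episode, so a single
  $\beta$ cannot be simultaneously sensitive near the setpoint and
  unsaturated at the deficit start.
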