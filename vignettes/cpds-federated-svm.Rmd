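---
title: "Federated sparse SVMs by cluster primal-dual splitting: models, solver and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated sparse SVMs by cluster primal-dual splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdsvm)
```

## The problem

Hospitals and other healthcare providers each hold a shard of patient
records and want a joint risk model — here, a binary classifier predicting
an outcome such as hospitalization within a target year from demographic and
clinical features — without ever exchanging raw patient data. `cpdsvm`
implements that setting for the soft-margin L1-regularised (sparse) support
vector machine:

$$
\min_{\theta,\,\theta_0}\; \sum_{i=1}^n \max\!\big(0,\,1 - \ell_i(\varphi_i^\top\theta + \theta_0)\big)
\;+\; \tfrac{1}{2}\psi\|\theta\|_2^2 \;+\; \rho\|\theta\|_1 ,
$$

with features $\varphi_i \in \mathbb{R}^d$, labels $\ell_i \in \{-1,+1\}$,
ridge coefficient $\psi \ge 0$ and L1 coefficient $\rho \ge 0$. The bias
$\theta_0$ is never penalised. The L1 term drives irrelevant coefficients to
exact zero, which is what makes the fitted rule auditable by clinicians: the
model names the handful of features it actually uses. The classical
constrained soft-margin parameterisation $\tfrac12\|\theta\|^2 + c\sum_i
\zeta_i + \varepsilon\|\theta\|_1$ is supported through
`hyperparams_from_c_eps()`: dividing that objective by $c$ gives the penalty
form with $\psi = 1/c$, $\rho = \varepsilon/c$, so the two share their
minimiser.

## Consensus reformulation and the solver

With $m$ agents, agent $j$ holding $n_j$ rows ($n = \sum_j n_j$), the
objective splits into per-agent terms
$G_j(x_j) = \tfrac12\psi_j\|\theta_j\|^2 + \rho_j\|\theta_j\|_1$ and
$F_j(y_j) = \sum_i \max(0, 1-y_{ji})$ with $y_j = \Gamma_j A_j x_j$, where
$x_j = (\theta_j, \theta_{j0})$, $A_j$ is the signed margin operator (row
$i$: $\ell_{ji}[\varphi_{ji}^\top, 1]$, see `margin_operator()`),
$\Gamma_j$ an optional positive per-sample scaling (identity by default),
subject to the consensus constraint $x_1 = \dots = x_m$. Penalties default
to $\psi_j = \psi/m$, $\rho_j = \rho/m$ so the sum of local objectives at
consensus equals the centralized objective (`agent_problems()`).

Agents communicate over a connected undirected graph with the Metropolis
weights

$$
\omega_{ij} = \frac{1}{\max(\deg i, \deg j) + 1} \text{ on edges},\qquad
\omega_{ii} = 1 - \sum_{h \ne i} \omega_{ih},
$$

a symmetric doubly stochastic matrix whose second-largest eigenvalue modulus
is strictly below one on any connected graph — repeated mixing contracts to
the network average (`metropolis_weights()`).

**The iteration.** Both the hinge and the regulariser are nonsmooth, so the
solver is a Condat–Vũ / Chambolle–Pock primal–dual splitting on the product
space, with one dual block per nonsmooth piece. Per synchronous round, each
agent $j$ runs

1. hinge dual: $u_j \leftarrow \mathrm{clip}\big(u_j + \sigma \Gamma_j A_j \tilde
   x_j - \sigma\gamma_j,\; [-1, 0]\big)$ — the proximal map of the hinge
   conjugate (`prox_hinge_conjugate()`); dual iterates provably stay in
   $[-1,0]^{n_j}$;
2. consensus dual: $\nu_j \leftarrow \nu_j + \sigma_c \sum_h \omega_{jh}
   (\tilde x_j - \tilde x_h)$ — the Metropolis-weighted disagreement with
   the neighbours, accumulated locally;
3. primal: $x_j \leftarrow \mathrm{prox}_{\tau G_j}\big(x_j - \tau (\Gamma_j
   A_j)^\top u_j - \tau \nu_j\big)$, where the regulariser prox is the
   closed form $\mathrm{soft}(u, \tau\rho_j)/(1 + \tau\psi_j)$ on the
   weights and the identity on the bias (`prox_regularizer()`);
4. extrapolation: $\tilde x_j \leftarrow 2 x_j^{\text{new}} - x_j^{\text{old}}$.

Only $\tilde x_j$ travels over edges (one model vector of $d+1$ doubles to
each neighbour, $2|E|$ messages per round); both dual blocks stay local.

**Why the explicit consensus dual.** The tempting "mix then prox" update
$x_j \leftarrow \mathrm{prox}_{\tau G_j}(\sum_h \omega_{jh}x_h - \tau
K_j^\top u_j)$ has a biased fixed point: at a fixed point every agent's
*own* optimality condition $0 \in \partial G_j(x^\ast) + K_j^\top u_j$ must
hold separately, which is impossible for heterogeneous shards at the global
optimum. The accumulated $\nu_j$ supplies exactly the per-agent slack that
is missing: because the columns of $I - W$ sum to zero on a doubly
stochastic $W$, $\sum_j \nu_j = 0$ at all times, so summing the per-agent
stationarity conditions recovers the *global* condition and the fixed points
of the iteration are precisely the saddle points of the consensus problem.
This is the standard product-space treatment of the consensus constraint
(dualising $(I - W)^{1/2} X = 0$; the iteration only ever needs
$(I-W)\tilde X$, which is neighbour-local). It also yields the reduction
identities the tests exercise: with $m = 1$, $W = [1]$, $\nu \equiv 0$ and
the method is a plain centralized primal–dual splitting; with identical
shards on a symmetric graph all agents follow bitwise-identical trajectories
and the consensus residual is exactly zero at every round.

**Step sizes.** Convergence requires $\tau(\sigma L^2 + \sigma_c \|I - W\|)
\le 1$ with $L = \max_j \|\Gamma_j A_j\|_2$ (computed by power iteration,
100 steps, tolerance $10^{-10}$). Defaults: $\tau = 1/L$, $\sigma = 0.25
/(\tau L^2)$, $\sigma_c = 0.7/(\tau\|I-W\|)$ (budget sum $0.95$). The split
favours the consensus block because final disagreement, not hinge-dual
progress, is what limits multi-agent accuracy; with a single agent the
hinge block takes the whole budget ($\sigma = 0.9/(\tau L^2)$). These
defaults were fixed from convergence benchmarks (relative objective error
$\le 6\times10^{-5}$ and consensus residual $\le 5\times10^{-5}$ within 5000
rounds across complete/ring/star topologies at $m \le 5$) before the
acceptance suite was frozen. The construction-time contract
$\tau\sigma L^2 \le 1$ is enforced with an informative error.

**Stopping and reporting.** `cpds_solve()` stops at `max_rounds` (default
1000, matching the benchmark protocol of long federated runs) or earlier
when the consensus residual $\max_j \|x_j - \bar x\|_2$ falls below
`tol_consensus` *and* the relative objective change of the averaged model
over the last 10 recorded trace points falls below `tol_objective`. The
returned classifier is the network average $\bar x$ — the benchmark source
never states which agent's model is evaluated, and the average is the
symmetric choice. Averages are computed as deviations from agent 1, so
bitwise-equal agents average to themselves exactly.

## The centralized oracle

No QP solver ships with the target environment, so the reference solver the
federated methods are measured against is built in-package — but through an
algorithmically independent route, so the two can genuinely check each
other. For $\psi > 0$ the Lagrange dual of the constrained soft-margin
program is smooth and concave:

$$
\max_{\alpha \in [0,1]^n,\ \ell^\top\alpha = 0}\;
\sum_i \alpha_i - \frac{1}{2\psi}\big\|\mathrm{soft}\big(\Phi^\top(\alpha
\circ \ell),\, \rho\big)\big\|_2^2 ,
$$

using the closed-form elastic-net conjugate
$\theta(v) = \mathrm{soft}(v,\rho)/\psi$. `solve_centralized_qp()` maximises
this by accelerated projected gradient (FISTA with adaptive restart;
projection onto box-plus-hyperplane by bisection on the equality
multiplier), recovers $\theta$ from $\alpha$, recovers the bias by an exact
scan of the 1-D piecewise-linear hinge problem (its minimum is always
attained at a kink), and **certifies** the result by the duality gap rather
than assuming convergence — the returned objective is accepted only when
the gap is below `tol` (default $10^{-9}$ relative). The $\psi > 0$
requirement is a deliberate narrowing: without strong convexity in
$\theta$ this dual degenerates, and every use of the oracle in the package
has $\psi > 0$. The oracle is additionally cross-checked in the test suite
against a third route, a long-run averaged proximal-subgradient method.

## The FedAvg comparator

`fedavg_svm()` is the deliberately simple baseline: per round each agent
starts from the global model and runs `local_epochs` full-batch
proximal-subgradient steps on its local objective — hinge over its own
shard plus the global penalties scaled by its sample share $n_j/n$, so the
local objectives sum to the centralized one — with the classical
$1/(\psi_{\text{loc}} t)$ decaying step, then the server averages models
weighted by $n_j$. Share-scaling matters: leaving the penalties unscaled
makes the averaged iteration minimise an $m$-times over-penalised objective
(measured ~20% above the oracle optimum on IID shards, versus ~0.5% with
scaling). The procedure is deterministic, so agents holding identical
shards produce identical updates and the average equals any single agent's
local training stream bitwise. It is a comparator, not an oracle: no
aggregation rule, epoch count or learning rate is prescribed by the source
material, so any quantitative gap to cPDS is implementation-defined.

## Synthetic cohorts: the stated world

The real benchmark cohort (hospital EHR data) is not publicly deposited, so
`generate_cohort()` emulates one with a known ground truth. The defaults
are the package's fixed stated world:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 1000 | matches the scale of the benchmark protocol (1000-round federated runs on a mid-sized cohort); no true cohort size is published |
| `n_continuous` / `n_binary` | 10 / 10 | the named feature kinds — age, BMI, vitals (continuous, standard normal, i.e. pre-scaled) and diagnosis/medication indicators (0/1) — in equal blocks |
| binary prevalences | Uniform(0.05, 0.5) per feature | coded diagnoses are sparse indicators; drawn once per cohort |
| `sparsity` | 5 | a truly sparse rule, so support recovery is scoreable |
| `signal_scale` | 1 | signal comparable to the unit feature scale |
| `label_noise` | 0.05 | a realistic mislabelling rate for outcome extraction from records |
| `positive_fraction` | 0.35 | hospitalization-style outcomes are a minority class but not rare |

The true bias is tuned by bisection (100 halvings of the empirical score
range) so the pre-noise positive fraction lands within 0.02 of target; a
residual miss is pure label discreteness and raises an explicit error
naming the achieved fraction. Partitioning is either IID (shuffle and deal,
sizes within 1) or label-skew via per-class Dirichlet($\alpha$) allocation,
the standard non-IID protocol; empty shards are repaired deterministically
from the largest part. All randomness flows through explicitly passed
seeds; no function leaks RNG state.

What the generator does **not** model: longitudinal visit structure, code
hierarchies, missingness, covariate shift between sites, feature
correlation structure. A green test therefore establishes solver
correctness (oracle agreement, consensus, sparsity behaviour, accounting)
on a well-specified world — it does not establish clinical performance on
real EHR data.

## Scheduling and communication accounting

`round_robin()` / `next_participants()` implement cyclic participant
selection with wraparound to the first node, giving exactly equal per-node
send counts over whole cycles — the fairness that motivates Round-Robin
transmission scheduling. Accounting conventions (the benchmark source
defines neither message content nor the volume axis): one message = one
model vector of $d+1$ doubles (8 bytes each); a peer round costs $2|E|$
messages, a star-plus-scheduler round $2k$ for $k$ scheduled clients;
volume in binary gigabytes (bytes $/2^{30}$). Utility is the linear
trade-off `accuracy_percent - kappa * cost`, with "transmission" cost =
cumulative messages $\times 10^{-3}$ and "compute" cost = cumulative local
gradient/prox evaluations $\times 10^{-4}$ — arbitrary but documented
scalings, since no definition is published.

## Benchmark harness choices

`run_experiment()` records test accuracy (percent) at checkpoints along the
rounds axis. The default grid mirrors the benchmark tables (100 to 1000 by
100); curve-crossing comparisons in the acceptance suite sample every 10
rounds, because first-hitting times at 100-round resolution are dominated
by the grid, not the curves. The oracle and purely-local baselines have no
rounds axis and are reported as constant rows at round 0 with zero
transmission. The full pipeline is a pure function of the configuration
(cohort seed plus derived sub-seeds for split, partition and graph).

## Numerical conventions

- `sign(0) = +1` for predictions, documented and deterministic.
- A coefficient counts as nonzero when $|\theta_k| > 10^{-8}$ (the solver
  produces exact zeros through soft-thresholding, so this only guards
  against dual noise).
- Consensus residual is $\max_j \|x_j - \bar x\|_2$.
- Dataset CSVs carry floats at 15 significant digits (round-trip well past
  the 12 s.f. contract); labels are written as integers and round-trip
  exactly.
- Erdős–Rényi topologies resample with fresh derived sub-seeds until
  connected (at most 1000 attempts, then an error).

## Known limitations

- The cPDS rate is not tuned per-instance; badly scaled features (the
  generator pre-scales, real data may not be) change $L$ and slow
  convergence. Standardise features before fitting.
- The oracle requires $\psi > 0$; pure-L1 (non-strongly-convex) programs
  are out of its scope.
- No asynchronous rounds, partial participation, link failures, or privacy
  mechanisms (differential privacy, secret sharing) — the communication
  model is an idealised synchronous gossip network.
- `fedavg_svm()` is a reference comparator; conclusions about "FedAvg" in
  general should not be drawn from its particular step-size schedule.
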