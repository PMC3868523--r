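---
title: "Inferring executable signaling-network models from perturbation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring executable signaling-network models from perturbation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pertnet)
```

## The problem

Targeted drugs perturb signaling networks; quantitative proteomics (for
example reverse-phase protein arrays) measures how protein and
phospho-protein levels, and phenotypes such as cell viability, respond. From
a modest panel of drugs applied singly and in pairs one obtains a response
matrix: for each node $i$ and perturbation condition $\mu$, the steady-state
log2 ratio $x_i^{\mu*}$ of the perturbed measurement over the untreated
control. `pertnet` infers, de novo, an *executable* model of the network
from such data — one that can then be simulated under perturbations never
tested, to predict combination effects and nominate drug targets.

## The dynamical model

Each node obeys

$$\frac{dx_i}{dt} \;=\; \epsilon_i\,
\tanh\!\Big(\sum_{j \neq i} w_{ij}\, x_j + u_i\Big) \;-\; \alpha_i x_i ,$$

where $w_{ij}$ is the signed influence of node $j$ on node $i$ (the edge
$j \to i$), $u_i$ a constant external force encoding a drug, $\alpha_i > 0$
the restoration rate towards the unperturbed state ($x = 0$) and
$\epsilon_i > 0$ the saturation scale. The sigmoid captures saturation of
biochemical responses; self-interactions are excluded because the decay term
already plays that role. The force enters *inside* the sigmoid: an isolated
node under constant force settles at $(\epsilon/\alpha)\tanh(u)$, which is
exactly the worked quantification used for drug activity nodes (a 55%
residual effector level gives $u = \log_2 0.55 = -0.863$ and node value
$-0.697$ at $\alpha = \epsilon = 1$). Both placements of $u$ appear in
informal renderings of such models; this package fixes the inside-the-sigmoid
form because it is the one the activity-node arithmetic implies, and records
it as the contract.

Unmeasured drug-target activities are represented by *activity nodes*: they
receive the drug force, may regulate measured nodes, but are forbidden any
upstream regulators (there is no measurement that could constrain them).
Genetic-alteration-style interventions are expressed by clamping a node to a
fixed value during simulation.

## From cost function to marginals

A model configuration is scored by

$$C(W) = \beta \sum_{i,\mu} \big(\hat x_i^{\mu} - x_i^{\mu*}\big)^2
 + \lambda\, \#\{w_{ij} \neq 0\},$$

an error term plus an L0 complexity penalty, and configurations are weighted
by $e^{-C}$ — a Boltzmann distribution with inverse temperature $\beta$.
Two simplifications make inference tractable:

* **Steady-state decoupling.** At steady state
  $x_i = (\epsilon_i/\alpha_i)\tanh(\sum_j w_{ij} x_j + u_i)$. Substituting
  the *observed* values $x_j^{\mu*}$ for the neighbours on the right-hand
  side decouples the rows of $W$: each row is inferred independently from
  the data. (During inference $\alpha_i = \epsilon_i = 1$; both are
  re-estimated later by gradient descent.)
* **Discretization.** Edge values are restricted to a symmetric grid
  $\Omega$ containing zero — by default 11 values on $[-1, 1]$ in steps of
  0.2. A 3-value grid forces overconfident (near-zero-entropy) marginals;
  11 values balance restriction and exploration. Benchmarks whose
  generating weights reach 2 use a 41-value grid on $[-2, 2]$. Even so the
  discrete space is astronomic ($K^{N^2}$; about $10^{190}$ configurations
  for 20 nodes and $K = 3$), which is what rules out enumeration and
  Monte Carlo at scale, and motivates message passing.

**Belief Propagation.** For each row $i$, a factor $\rho^\mu(w_{ij})$ holds
condition $\mu$'s evidence about edge $j \to i$. A cavity update isolates
one edge and one condition: all other edges contribute through the aggregate
field $h = \sum_{t \neq i,j} w_{it} x_t^{\mu*}$, whose distribution is
approximated as Gaussian (central limit theorem) with moments taken under
the cavity marginals $P^{\setminus\mu}(w_{it}) \propto
e^{\lambda\delta(w=0)} \prod_{\nu \neq \mu} \rho^\nu(w_{it})$. The update

$$\rho^\mu(\omega) \;\propto\; \int\! N(h;\bar h,\sigma_h^2)\;
e^{-\beta\,(x_i^{\mu*} - \tanh(h + \omega x_j^{\mu*} + u_i^\mu))^2}\,dh$$

is evaluated by Gauss–Hermite quadrature (order 20 by default; the order is
configurable, and a degenerate field $\sigma_h^2 = 0$ is evaluated at the
point $\bar h$). One sweep visits every (edge, condition) cavity of a row in
a seeded random permutation; convergence is declared when the final
marginals $P(w_{ij}) \propto e^{\lambda\delta(w=0)} \prod_\mu \rho^\mu$
change by less than $10^{-6}$ between sweeps. Products are accumulated in
log space, and the per-source factor sums are rebuilt from scratch at each
sweep to stop incremental floating-point drift. Structural constraints
(no self-edges, no edges into activity nodes, optionally none out of
phenotypes) are frozen point masses, not post-hoc filters. Optional damping
(default 0) mixes old and new factors as a rescue for non-convergent runs.
The sweep engine is compiled (Rcpp); a pure-R reference engine with
identical arithmetic and schedule backs it in the test suite.

## Hyperparameters

$\beta$ scales the evidence, $\lambda$ the sparsity prior; together they set
the expected connectivity. For real perturbation data the shipped operating
point is $\beta = 2$, $\lambda = 5$, which targets the ~1.5 edges per node
typical of curated signaling maps; `select_hyperparameters()` implements the
general procedure — scan $(\beta, \lambda)$, build the representative
network (most probable value per edge, ties to the smallest magnitude,
then zero out $|w| < 0.2$), and keep the lowest-error configuration within a
connectivity band. The synthetic drug-panel benchmark runs at the shipped
operating point, whose connectivity target matches its generators' density
(1.5 edges per node); the rich-data recovery benchmark relaxes the prior to
$\lambda = 2$ because its 60 information-rich conditions support all 1.5
edges per node without the strong sparsity push.

## Model instantiation and refinement

Marginals summarize a solution *ensemble*; executable models are drawn from
it by **BP-guided decimation**: sample an (edge, value) pair with
probability proportional to the joint marginal mass, freeze it, re-run BP to
full tolerance (warm-started), and repeat until every edge is fixed. Because
rows decouple, decimation proceeds row-independently — an exact
factorization of the sampling process. Sampling the pair jointly subsumes
both the "edge first, then value" and the joint reading of the procedure.

Each discrete model is then **refined**: the grid values relax to continuous
weights (the zero pattern is preserved exactly) and $\alpha_i$,
$\epsilon_i$ are fitted, minimizing the squared error of the *fully
simulated*, self-consistent steady states. Gradients are central
differences on the simulated objective; steps use backtracking halving (up
to 20), and a step whose simulation fails to settle is rejected.
$\alpha, \epsilon$ live in $[0.05, 20]$ (log-parameterized) to prevent
degenerate dynamics. The recurrent-backpropagation literature offers exact
gradient schemes; with the system sizes involved here, numeric gradients
are simpler and fast enough, and correctness is defined by the objective,
not the update formulas. The refinement inner loop solves steady states
with a damped fixed-point iteration (equivalent to adaptive explicit Euler)
and falls back to the adaptive ODE integrator when it fails to settle.

Ranked ensembles (`generate_ensemble()`; the real-data protocol generates
1000 models and keeps the top 100 by training error) feed three consumers:
the **average network** (entry-wise mean and edge frequency — a summary for
interpretation and export, not executable, since mutually exclusive edges
average toward zero), **leave-k-out cross-validation** (withhold every
condition involving one drug except its low-dose single, retrain, predict
the withheld profiles by simulation, pool over drugs), and the **in silico
screen** (virtually inhibit each candidate node in every ensemble model and
record the phenotype response distribution).

Three choices there deserve a note. The cross-validation error is defined
as the root-mean-square prediction error per data point — the natural
errors-per-data-point scale for pooled profiles — with the mean absolute
error logged alongside. The high-dose single-agent condition of the held-out drug is
withheld along with the pairs, because the protocol keeps "only the single
low-dose condition"; a flag restores it. Screening clamps the target to
$x = \log_2 0.5 = -1$ rather than applying a force, because with
$\epsilon/\alpha = 1$ the saturating response cannot reach $-1$ under any
finite force; force mode (calibrated so an isolated node lands at the
requested value) is available.

## Simulation and oscillation handling

`steady_state()` integrates the ODE with the adaptive `lsodar` integrator
and a root function on $\max_i |dx_i/dt| - 10^{-8}$, so integration stops
the moment the steady state is reached ("machine precision" is impractical
as a literal criterion; $10^{-8}$ on the largest rate of change is the
declared tolerance, with $t_{\max} = 10^4$ pseudo-time units). Integration
proceeds in stages (to $t = 100$, $10^3$, $t_{\max}$); if a stage ends
without a root and the trajectory's recent amplitude exceeds $10\times$ the
tolerance long after all decay timescales $1/\alpha_i$ have passed, the run
is declared oscillatory and stopped early. Limit cycles are genuinely
reached by strong multi-step negative feedback (a three-node repressor ring
destabilizes its fixed point); weakly damped two-node spirals that outlive
$t_{\max}$ are flagged the same way, which is the intended behaviour — the
data-generation protocol simply excludes conditions that have not settled,
and keeps their labels in the dataset manifest.

## What the synthetic benchmarks emulate — and what they do not

`toy_topology()` builds cascade-like hierarchical generators: a serial
backbone through an ordered node hierarchy, extended with parallel chains,
feed-forward closures, multi-step feedback loops (a path $a \to b \to c$
gains the returning edge $c \to a$; direct reciprocal pairs are not
generated, since signaling feedback acts through intermediates and
steady-state data cannot orient a bare 2-cycle), and multiple-input motifs.
Weight magnitudes are uniform on $(0, 2]$; a quarter of edges are
inhibitory. Scale-free wiring is deliberately not emulated — it is typical
of transcriptional, not signal-transduction, networks.

`drug_panel()` and `design_perturbations()` emulate an inhibitor panel:
each drug applies $u = -1$ to its main target (a 50% reduction of the
presumed downstream effector — the scale at which real panels are dosed,
via protein-IC40-style calibration) and up to four weaker off-target
effects of either sign (uniform up to half the main strength). Combinations
add force vectors. The off-target forces can be hidden from the inference
(`known_off_targets = FALSE`) to mimic drugs with unknown off-target
behaviour. Measurement noise is multiplicative Gaussian,
$x \to x(1 + g)$, $g \sim N(0, \gamma)$, because $\gamma$ is specified as a
coefficient of variation (15% realistic, 30% worst case); an additive mode
exists behind a flag.

Passing benchmarks on these generators shows that the inference machinery
recovers the structures it was designed for under controlled conditions. It
does not establish performance on real arrays: the generators have no
biological variability, no shared-antibody cross-reactivity, no
normalization artifacts, and their dynamics are, by construction, the same
model family the inference assumes.

The shipped benchmark scales are chosen to complete comfortably on a
laptop-class machine. The recall/precision benchmark uses 40-node, 60-edge
generators — 1.5 edges per node, the connectivity of empirical signaling
maps, at which oscillating conditions are rare — with 14 strong inhibitors
($|u| = 2$, up to 105 conditions) over 3 seeds, scored at the 0.2
threshold. The parameter-correlation benchmark pools generators of 10–40
nodes (twice as many edges as nodes) with as many random 3-target
perturbation patterns as nodes, on the 41-value grid. The rich-data
recovery check uses 10-node generators whose 15 edges all carry weights
above the calling threshold (a weaker edge is unrecoverable by
definition), trained on 60 random 5-target patterns. Larger experiments
(the originals extend to 100-node generators) work unchanged.

Under the sparse drug design the reconstruction is intentionally hard:
pair forces are sums of the 14 single-drug force vectors, so the design
has low effective rank relative to the 39 candidate regulators per node,
and a substantial fraction of identifiable edges is lost to compensatory
ambiguity. The in-package benchmark recovers roughly a third of the true
edges at about 40% precision while calling ~2 edges per node; the
rich-perturbation regime, by contrast, is near-perfect. Both numbers are
recomputed from scratch by `scripts/acceptance.R` and the acceptance test
suite.

## Known limitations

* **Mean-field overconfidence.** With one free parameter per row the cavity
  update is exact and BP marginals match brute-force enumeration to
  $10^{-6}$. With several free parameters at operating $\beta$, rows whose
  generating weights fall between grid points have multi-modal posteriors;
  the factorized updates then collapse onto one self-consistent mode, and
  the full marginal can deviate substantially from the enumerated one even
  though the marginal *means* remain accurate (in our checks, means agree
  with enumeration within 0.05 while worst-case total variation grows
  roughly linearly in $\beta$). Weak coupling ($\beta \lesssim 0.5$ on
  tanh-bounded responses) restores distribution-level agreement within
  total variation 0.05.
* **Correlation vs causation.** Steady-state data cannot always orient
  influences; false positives concentrate in compensatory motifs (upstream
  shortcuts, reversed edges, co-regulation), which
  `classify_compensatory_motifs()` makes explicit.
* **The average network is descriptive.** Simulation-based claims must use
  ensemble members, never the averaged matrix.
* **Constant forces only.** Time-dependent $u(t)$ and time-series
  likelihoods are out of scope.
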