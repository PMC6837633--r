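---
title: "Modeling the competition between genetic adaptation and epigenetic switching"
author: "epievolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the competition between genetic adaptation and epigenetic switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epievolve)
```

## The circuit and its phenotypes

`epievolve` models the simplest genetic network that can both adapt by
mutation and switch phenotypes epigenetically: a single self-activating
gene. The protein copy number `A` changes by one molecule at a time,
with synthesis propensity

$$f(A) = k\left(\alpha + (1-\alpha)\frac{A^{n_H}}{A^{n_H} + K_D^{n_H}}\right)$$

and degradation propensity $\gamma A$. Time is non-dimensionalized by
the degradation rate, so $\tau = t\gamma$, $\gamma = 1$, and $k$ is in
proteins per protein lifetime. The *genotype* is the evolvable triple
$\theta = \{k, n_H, K_D\}$; the basal fraction $\alpha = 0.25$ and
$\gamma$ are fixed. Parameters are clamped to a physiological range for
a bacterial transcription factor ($10^{-2} \le k \le 10^3$,
$10^{-2} \le n_H \le 16$, $10^{-2} \le K_D \le 120$); see
`genotype_bounds()`.

The deterministic flow $dA/d\tau = f(A) - A$ has one or three fixed
points. `stability_profile()` brackets all roots on a combined
linear/log grid of more than 2000 points over $[0, 1.05\,k/\gamma]$ and
refines each bracket by bisection to $10^{-6}$ proteins; a root is
stable when the flow crosses from positive to negative. The grid+bisection
scheme was chosen over derivative-based root polishing because it is
robust for the near-tangent (saddle-node) genotypes that delimit the
bistable region, exactly where the analyses need reliable
classification. A tangency that produces no sign change is deliberately
not counted as a stable state: stability is defined by sign changes
only, so the measure-zero saddle-node genotypes classify consistently
with their monostable neighbours.

In the sharp-activation limit ($n_H \to \infty$) the system is bistable
when $\alpha k \le K_D \le k$. At the parameter bound $n_H = 16$, which
the package uses as the practical proxy for that limit, the band is
narrower (about $K_D \in [30, 62]$ for $k = 80$): the limit statement
is asymptotic, so tests of the limit law probe well inside the band and
10% outside its edges.

### Solution genotypes

For a target steady state $A^*$ and given $(n_H, K_D)$, the synthesis
rate that places a fixed point at $A^*$ is unique:

$$k^* = \frac{\gamma A^* (A^{*n_H} + K_D^{n_H})}{A^{*n_H} + \alpha K_D^{n_H}}.$$

`solution_k()` additionally certifies the result: the genotype is a
*solution genotype* for an environment only when $A^*$ is a **stable**
fixed point and $k^*$ lies within the physiological range. The
stability condition matters: for $K_D$ near $A^*$ (at high $n_H$) the
fixed point sits on the unstable branch, and such cells form a hole in
the solution manifold.

A mutual-repression ("toggle switch") variant is provided for
generality (`toggle_genotype()`, `toggle_stability_profile()`,
`toggle_solution_kA()`). It is analysed through the quasi-steady-state
reduction of the repressor, the same reduction used to derive its
solution genotypes; no stochastic toggle simulation is included, since
all toggle-level claims are deterministic.

## Stochastic kinetics and the master equation

`simulate_cell()` implements the exact Gillespie direct method:
exponential waiting times with rate $f(A) + \gamma A$ and synthesis
probability $f(A)/(f(A)+\gamma A)$. The default life span is
$\tau = 4$ protein lifetimes, the value used throughout the
evolutionary simulations. A guard aborts any life span beyond $10^7$
events (reachable only at pathological parameter combinations near the
$k$ bound).

All randomness — in the SSA core (C++) and in the evolutionary engine —
flows through R's own RNG, so a single `set.seed()` (or the `seed`
field of a configuration) makes every result bit-reproducible. We chose
this over bespoke per-cell counter-based streams because the iteration
order is fixed, R's generator is of high statistical quality, and
reproducing any published RNG stream bit-for-bit is not a scientific
claim of the model.

The distributional side is handled by finite state projection (FSP):
the chemical master equation is truncated to states $0..A_{\max}$ with
an absorbing boundary (the birth transition out of $A_{\max}$ is
dropped but its rate stays in the outflow, so truncated probability is
*lost* and tracked as leak). `propagate_fsp()` applies the matrix
exponential of the tridiagonal generator by uniformization, split into
segments with $\Lambda \tau \le 64$ so Poisson weights stay in
floating-point range; the series truncation error is below $10^{-12}$
in the 1-norm. $A_{\max}$ starts at $\max(150, 2k/\gamma)$ and doubles
until the leak at $\tau = 4$ falls below $10^{-8}$. The stationary law
is computed independently through the product form
$\pi(a) \propto \prod_{j\le a} f(j-1)/(\gamma j)$ (detailed balance for
one-dimensional birth-death chains, evaluated in log space), which
serves as a cross-check oracle for both the SSA and the FSP paths.

### Noise load and epimutation probability

The *noise load* of a genotype in environment $E$ is the expected
fitness decay over one life span starting from the optimal phenotype:
$1 - \sum_a \omega^{(E)}(a)\,\rho(a, \tau{=}4)$ with $\rho$ propagated
from a point mass at $A^{(E)}$. It equals the fitness loss of an
infinite isogenic population under perfect selection and no mutation —
pure cost of biochemical noise. The *epimutation probability* is the
mass of states whose fitness in the **other** environment is at least
0.5, i.e. $P[\omega^{(E_{alt})}(A_{\tau=4}) \ge 0.5]$. The
$\omega \ge 0.5$ state set uses integer states and the exact Lorentzian
(for HIGH this is $A \in [76, 84]$, for LOW $A \in [18, 22]$); no
interpolation, since phenotypes are integer counts. Raw probabilities
are always returned, however small.

## Fitness, selection, mutation

Fitness is Lorentzian, $\omega = \epsilon^2/(\epsilon^2 + (A -
A^{(E)})^2)$ with $\epsilon^2 = 0.2\,A^{(E)}$; the optima are
$A^{(L)} = 20$ and $A^{(H)} = 80$. Two width-matched variants are
available: a Gaussian with the same full width at half maximum
($\sigma = \epsilon/\sqrt{2\ln 2}$) and a step function equal to 1 on
$|A - A^{(E)}| \le 2\epsilon$ with a $10^{-6}$ floor ("similar width"
made concrete: the step spans the Lorentzian's FWHM on each side).

Selection defaults to tournament selection: each of $N$ offspring slots
takes the fittest of $s_t$ cells drawn *without* replacement within the
tournament, tournaments independent across slots, ties broken uniformly
at random. $s_t = 1$ is drift; $s_t = N$ clones the single fittest
cell. Truncation (uniform cloning from the top $\lceil N/s_t \rceil$)
and fitness-proportional selection are provided as pressure-matched
alternatives, reusing $s_t$ as the truncation knob because no separate
parameter is defined for it.

Mutation is multiplicative and spherically symmetric in log-parameter
space: with $r \sim U(0,1)$, $\phi_1 \sim U(-1,1)$,
$\phi_2 \sim U(0, 2\pi)$,

$$k' = k\,M^{r\sqrt{1-\phi_1^2}\cos\phi_2},\quad
  n_H' = n_H\,M^{r\sqrt{1-\phi_1^2}\sin\phi_2},\quad
  K_D' = K_D\,M^{r\phi_1},$$

so the displacement norm in log-$M$ coordinates is exactly $r \le 1$ —
one mutation can traverse at most one unit of mutational distance,
which is what makes the genetic-potential maps interpretable in
"number of mutations" units. Out-of-range results are clamped to the
physiological bounds (the simplest scheme consistent with a hard
physiological range; users can audit boundary pile-up through the run
records). The `homogeneous_spherical` ($r \to r^{1/3}$), `cubic`
(three independent $U(-1,1)$ exponents) and `1d` (one random
coordinate) schemes cover the standard robustness variants.

## The evolutionary engine

`run_evolution()` starts from an isogenic population whose phenotypes
sit at the deterministic stable state nearest the starting
environment's optimum (rounded to an integer for stochastic runs) — a
founder choice that removes an arbitrary burn-in transient without
biasing the subsequent dynamics. Each generation simulates every cell
for $\tau$ from its inherited protein level, scores fitness on the
end-of-life count (or the exact time-weighted trajectory average when
`phenotype_mode = "time_average"`), selects, mutates each clone with
probability $u$, and advances the environment. The environment
alternates every $1/\nu$ generations (the epoch; $1/\nu$ must be an
integer), or switches with probability $\nu$ per generation in the
stochastic mode; a cycle is one epoch of each environment, starting
with LOW by default so that a cycle reads "LOW epoch then HIGH epoch"
(configurable).

The per-cycle fitness summary is the geometric mean
$W_{cycle} = (\prod_g w_g)^{1/L}$ over the $L$ generations of the
cycle; the raw product is also recorded, so either convention can be
recovered downstream.

CONTROL runs replace the SSA by the deterministic steady state: each
cell jumps to the stable fixed point whose basin contains its inherited
level (basins delimited by the unstable points; a level exactly at an
unstable point resolves to the lower state by convention). Bistable
CONTROL cells therefore display hysteresis and can never switch
spontaneously, which isolates the contribution of biochemical noise to
the evolutionary outcome.

## Lineage analysis

Genealogy (parent links, mutation flags, genotype references) is
recorded every generation; bistability is evaluated once per genotype
and cached. At the end of each cycle with at least two completed cycles
of history, every surviving cell is traced to its 1-cycle and 2-cycle
ancestors and the window between them is classified:

- **ES** — every genotype bistable, no mutation;
- **BA** — every genotype bistable, at least one mutation;
- **GA** — at least one monostable genotype, with mutations;
- **STATIC** — monostable path, no mutations.

STATIC matches none of the three named strategies; it is reported as a
fourth category rather than silently folded into GA, so the three-way
picture stays auditable (it is typically rare because unmutated windows
of monostable lineages are short-lived under fluctuating selection).
Fractions are progeny-weighted: each surviving cell counts once,
regardless of shared ancestry. Transition statistics compare the
current window against the window one cycle earlier (3-cycle history).
The archive is pruned to the last three cycles, which is sufficient for
every statistic defined here.

## Analysis grids and problem sizes

The genotype-space maps default to a log-spaced grid of 40 points in
$n_H \in [1, 16]$ by 48 in $K_D \in [1, 120]$ (the axes ranges of the
map analyses; the exact resolution is a package choice guarded by a
refinement-stability test: away from the validity boundary of the
solution manifolds, halving the grid spacing changes the reported
minima by under 5%, while cells on that boundary can jump because a
finer grid adds newly valid target genotypes).

The packaged study conditions (`generate_fixtures()`, the test suite)
run at reduced scale — populations of 500–1000 cells for 2000–3000
generations, a handful of seeds — rather than the 10^4-cell, 10^4-
generation populations of the full-scale study. The deterministic
quantities (fixed points, manifolds, FSP maps) are scale-free, and the
reduced stochastic runs preserve $u N \ge 1$ and all rate parameters
($\nu = 0.1$, $s_t = 40$, $u = 0.03$, $M = 1.1$). One consequence is
worth stating plainly: the *timescale* of the evolutionary transition
to high nonlinearity grows as the population shrinks, because the climb
is driven by the supply ($uN$) of rare beneficial mutations against a
noise-dominated fitness signal. At small $N$ the characteristic rise of
$\langle n_H\rangle$ into the bistable regime takes longer than at
$N = 10^4$, so short scaled-down runs probe the direction of selection,
not its full endpoint. The CONTROL model, which removes the expression
noise that dilutes the fitness signal, is expected to make that climb
at smaller population sizes than the stochastic model.

## What the generator does and does not emulate

The synthetic-data side of the package *is* the model: configurations
generate populations, trajectories and genealogies from the mechanism
itself, under the stated study conditions. What passing tests therefore
establish is internal consistency of the machinery — SSA versus
product-form and FSP oracles, selection and mutation versus closed
forms, lineage classification versus its definitions — not fidelity to
any particular organism. Real gene circuits have cell-cycle structure,
partitioning noise at division, extrinsic noise, and mutation spectra
with indels and duplications, none of which are represented; the model
also fixes $u$, $M$ and $\alpha$ and keeps the population size
constant.

## Known limitations

- The toggle switch is analysed only through its deterministic
  reduction.
- Overlapping-generations (Moran) reproduction and evolvable basal
  activity are out of scope.
- FSP leak control assumes $k \lesssim 10^3$ (the physiological bound);
  the doubling scheme aborts if $A_{\max}$ would grow unreasonably.
- Tournament sampling is the standard without-replacement reading; the
  original scheme's exact cohort convention is not documented, and
  other readings would shift selection pressure slightly at small $N$.
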