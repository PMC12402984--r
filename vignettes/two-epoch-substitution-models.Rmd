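---
title: "Two-epoch reduced-alphabet substitution models with resubr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-epoch reduced-alphabet substitution models with resubr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resubr)
```

## The model

Standard amino acid substitution models (LG, WAG, BLOSUM-derived) assume a
constant 20-letter coding alphabet across all of evolutionary time. For
proteins whose history reaches back toward the origin of translation —
above all the aminoacyl-tRNA synthetases (aaRS), the enzymes that operate
the genetic code — that assumption is hard to defend: early coding systems
almost certainly used fewer amino acid types.

`resubr` implements the *refinement–expansion substitution* (resub) model
family, which relaxes the fixed-alphabet assumption minimally: time is cut
into a **young epoch** $E_1 = [0, t_e]$ with the full $m = 20$ alphabet,
and an **old epoch** $E_2 = (t_e, t_h]$ with $m - 1$ effective states,
where $t_h$ is the root age and the boundary age $t_e$ is estimated.
Attention focuses on one *cherry* $(\alpha, \beta)$ — a pair of amino
acids whose aaRS families share an immediate ancestor, e.g. Trp/Tyr. A
model indicator $I_s \in \{0, 1, 2, 3\}$ selects among four hypotheses
about the old alphabet:

* $I_s = 0$ — **null**: both epochs share the full alphabet;
* $I_s = 1$ — **refinement** (subfunctionalisation): $\alpha$ and
  $\beta$ were one merged, low-specificity state $\alpha/\beta$, assumed
  at equilibrium between its sub-states;
* $I_s = 2, 3$ — **expansion** (neofunctionalisation): one cherry member
  ($\beta$ or $\alpha$ respectively) was absent from the old alphabet.

Within an epoch, substitution is the usual reversible Markov process
$Q = r\,\mathrm{diag}(\pi)$ with symmetric exchangeabilities $r$ and
equilibrium frequencies $\pi$, normalized so that
$-\sum_i \pi_i Q_{ii} = 1$ (one expected substitution per site per unit
of genetic distance), and $P(\tau) = e^{Q\tau}$. The old-epoch basis
$(r', \pi')$ is derived from the young one by `reduce_alphabet()`:
merging pools the cherry frequencies and frequency-averages the merged
exchangeability rows; deletion removes the discarded state and
renormalizes $\pi$.

The model's distinctive ingredient is the **saltation matrix** $\Xi$, a
row-stochastic $(m-1) \times m$ matrix applied instantaneously, tree-wide,
when a lineage crosses the boundary from $E_2$ into $E_1$: a fraction
$\nu$ of the retained state's characters jumps into the newly coded state,
and every other state leaks mass $\pi_{\gamma_0}$ (and, under refinement,
$\pi_{\gamma_1}$) into the new (and retained) state. A branch spanning the
boundary with distances $\tau_2$ (old side) and $\tau_1$ (young side) has
transition matrix

$$P(\tau_2, \tau_1) \;=\; e^{q(r'\pi')\tau_2}\; \Xi \; e^{q(r\pi)\tau_1},$$

with each factor normalized by its own frequencies. Rows index the
old-epoch (parent-side) states and columns the young-epoch (child-side)
states; the pruning code respects this rectangular shape, holding partial
likelihood vectors above the boundary in the reduced state space and
applying the reduced frequencies $\pi'$ at the root when it lies in the
old epoch. One non-obvious consequence of the refinement form of $\Xi$ is
that non-cherry states leak probability into $\gamma_1$ — a pre-existing
state — at the boundary; the matrix is implemented exactly in that
printed form, without any "intuitive" correction, because the form itself
is the model definition.

```{r worked}
basis <- substitution_basis(
  r = matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3),
  pi = c(0.6, 0.1, 0.3), states = c("x", "W", "Y"))
cfg <- resub_config("W", "Y", Is = 3, te = 0.5, nu = 0.25)
round(epoch_transition_matrix(basis, cfg, 0.5, 0.5), 3)
```

## Inference

The posterior over the tree $T$ and parameters $\theta$ is sampled by
Metropolis–Hastings (`resub_mcmc()`), with the four hypotheses compared by
Bayesian model averaging: `Is` is a sampled state variable and
`model_support()` reads off its posterior frequencies. A Bayes factor of
10 (posterior support 10/11 when the alternatives are equal a priori) is
the "strong support" threshold used by `classify_support()`, with strict
inequalities so the boundary value itself returns `"?"`.

Priors follow the model's intended use:

* $t_e - t_{\alpha\beta} \sim \mathrm{Laplace}(0, \delta)$, truncated to
  non-negative ages; the anchor $t_{\alpha\beta}$ can be the root, a named
  clade's MRCA, or a fixed age. The default $\delta = 0.05$ (in the
  tree's time units) encodes the biological premise that the alphabet
  changed close to the cherry's bifurcation; the paper-scale analyses use
  the same value in Ga. Internally the sampler stores the *offset*
  $d = t_e - t_{\alpha\beta}$ rather than $t_e$ itself, so tree moves
  carry the boundary along with its anchor — without this
  reparameterization the tight Laplace coupling makes root moves
  nearly immobile.
* $\nu \sim \mathrm{Uniform}(0, 1)$ (the least-informative choice for a
  proportion; no prior is otherwise implied by the model).
* `Is` uniform on $\{0,1,2,3\}$ by default. Because the classifier always
  divides posterior odds by prior odds, the Bayes-factor threshold is
  honoured for any mass split.
* A birth–death tree prior conditioned on the number of sampled extant
  taxa, with birth rate $\lambda$, reproduction number $R_0 = \lambda/\mu$
  and sampling fraction $\rho$. The $\rho$-thinned process is mapped to an
  equivalent complete-sampled one ($\lambda^* = \rho\lambda$,
  $\mu^* = \mu - \lambda(1-\rho)$); conditioned on $n$ tips, node ages are
  iid with a closed-form density and the ranked labelled topology is
  uniform. The sampler targets exactly this product density, so the
  simulator and the MCMC prior agree — the property that makes coverage
  studies meaningful.
* Lognormal node-age calibrations given as real-space mean $M$ and
  standard deviation $S$; `default_calibrations()` ships the deep
  calibration set (root 4.49 Ga, LUCA 4.25 Ga, LACA/LBCA/LMCA/LECA) and
  `cross_brace_log_prior()` implements the exponential (mean 0.01 Ga)
  bracing of equivalent nodes across two co-estimated trees.
* Flat Dirichlet on $\pi$, iid exponentials on $r$, exponential (mean 1)
  on the gamma site-shape, lognormal on the strict clock rate.

Trans-model sampling uses a pseudo-prior construction: $\nu$ and $t_e$
stay in the state under $I_s = 0$, where the likelihood ignores them, so
no reversible-jump dimension matching is required and no marginal of
interest changes. Site-rate heterogeneity is the standard four-category
discrete gamma (equal category weights, category means via the
closed-form incomplete-gamma expression); there is no
proportion-invariant class.

The operator mix pairs random-walk/scale moves (boundary offset, $\nu$,
shape, clock rate, node heights, root and whole-tree scaling, per-element
exchangeability scaling, a frequency-exchange simplex move) with
independence proposals from the prior (for `Is`, the boundary offset,
$\nu$, shape, clock, and — in prior-only chains — a rank-preserving
redraw of all node ages from the birth–death density). The independence
moves make likelihood-free chains mix essentially perfectly, which is what
the prior-recovery tests rely on; with data they are simply rejected most
of the time. Two independent chains with a combined effective sample size
above 200 (Geyer initial-monotone-sequence estimator, summed across
chains) are the recommended protocol, wrapped by `resub_mcmc_chains()`.

## Simulation

`simulate_bd_tree()` draws conditioned birth–death time-trees (default
$\lambda = 2$, $R_0 = 2$, $\rho = 1$; these give trees of height ~1–2 for
the tree sizes used in the studies below). A forward mode conditions on an
origin height instead and can retain dated non-extant tips.
`simulate_alignment()` evolves sites down the tree: old-epoch segments use
the reduced process, the boundary applies one categorical draw from the
appropriate row of $\Xi$, young segments use the full process. Extant
leaves always emit full-alphabet characters. The simulator is validated
against the pruning likelihood by comparing empirical site-pattern
frequencies with per-pattern likelihoods on the three-state toy model —
the strongest cross-module consistency check in the test suite, since any
disagreement in the boundary bookkeeping shows up immediately.

## Study harnesses and the problem sizes used

Three experiment harnesses reproduce the simulation studies at reduced
scale, chosen so the full suite runs comfortably on a single CPU:

* `coverage_experiment()` — the well-calibrated-Bayes check: truth from
  the prior, data simulated, inference under the same priors, 95%
  credible-interval coverage compared with its binomial band. The
  validation suite runs 50 replicates at $N = 10$ taxa and $L = 100$
  sites (the function default is 20 replicates), with
  $\pi$, $r$ and the site shape drawn fresh each replicate and supplied
  to inference as known. Replicates whose chains miss an ESS floor are
  flagged, excluded and counted rather than silently included.
* `model_recovery_experiment()` — data simulated 50/50 under null and
  resub truths, classified with the Bayes-factor-10 rule; run at
  $N = 20$ with $L = 50$ and $L = 200$ to show the classifier's
  confidence growing with data.
* `age_bias_experiment()` — data simulated under resub with internal
  nodes calibrated at their true ages and the root left free, then
  analysed under (a) the fixed-alphabet null and (b) resub. Under the
  null, the substitutions injected by the saltation burst and the slower
  state turnover of the reduced alphabet can only be explained by longer
  branches above the calibrations, so the old-epoch duration
  $t_h - t_e$ (and with it $t_h$) is overestimated; resub absorbs them at
  the boundary. Reduced scale: $N = 20$, $L = 100$, the strict clock held at
  the known simulation rate (with the clock free, rate-time confounding
  dominates the root-age posterior at this size; the full-scale design
  would pin the clock with serially sampled tips instead), topology fixed
  at truth with node ages sampled; the paper-scale setting
  ($50$ replicates, $L = 200$, $N = 40$) is a flag away.

## Numerical choices, degenerate inputs, limitations

* Matrix exponentials use the spectral decomposition of the symmetrized
  reversible generator, which is stable for any $\tau \ge 0$; tiny
  negative round-off entries are clamped and rows renormalized. The dense
  Padé exponential (`Matrix::expm`) serves as the independent oracle in
  the tests and as the fallback for non-reversible inputs.
* Per-node partial-likelihood rescaling with accumulated log scalers
  guards against underflow on deep alignments.
* A boundary exactly at a node height assigns the node to the young
  side, following the half-open epoch definition $E_2 = (t_e, t_h]$; a
  boundary at or above the root (or origin) leaves the old epoch empty
  and the model degenerates gracefully to null behaviour — legal, and
  made rare by the Laplace prior rather than forbidden.
* Gaps and `X`/`?` are fully ambiguous (all-ones leaf partials);
  `B`, `Z`, `J` expand to their standard state sets. Gap-only columns
  therefore contribute likelihood 1 exactly.
* Simulated dated tips that sit above the boundary under refinement
  would carry the merged state; they are emitted as the retained cherry
  label, since merged labels are not single characters. This only arises
  in fossil-tip simulations.
* On small alphabets whose cherry carries a large share of the
  equilibrium mass, the boundary-plus-saltation machinery has enough
  generic flexibility that model averaging can favour resub even on data
  generated under the null — the in-silico analogue of unexpected support
  on negative-control cherries in empirical screens. Hypothesis tests on
  toy alphabets should therefore be read with care; at realistic
  20-letter frequencies the false-positive control holds in the
  model-recovery study.
* The package deliberately covers two epochs and one cherry per
  analysis; multiple simultaneous cherries, more than two epochs,
  birth–death skylines, punctuated-spike clock models and marginal
  likelihood estimators are out of scope. The synthetic data emulate the
  substitution process, the boundary saltation, rate heterogeneity and
  calibrated dating, but not alignment error, indels (gaps are missing
  data), selection, or lineage-specific compositional drift — passing
  tests demonstrate internal correctness and calibration of the method,
  not that any particular empirical dataset satisfies the model.
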