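---
title: "Automated backbone resonance assignment by Bayesian simulated annealing"
author: "bbanneal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated backbone resonance assignment by Bayesian simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assignment problem

Backbone resonance assignment maps the crosspeaks of triple-resonance NMR
spectra onto specific residues of a protein sequence. Every backbone
experiment used here is rooted in an amide H–N pair: an HNCA peak, for
example, correlates an amide with the Cα of its own residue *or* of the
preceding one, and the full experiment set (HSQC, HNCO, HN(CA)CO, HNCA,
HN(CO)CA, HNCACB, CBCA(CO)NH) reports the Cα, Cβ and CO shifts of residue
*i* and *i−1* through the amide of residue *i*. Two sources of information
then determine an assignment:

* **adjacency** — the (*i*) carbon shifts of the spin system at residue
  *n* should match the (*i−1*) carbon shifts of the spin system at
  residue *n+1*; and
* **chemical-shift plausibility** — the observed shifts should agree with
  per-residue predictions (from a structure-based predictor, a
  random-coil model, or plain residue-type statistics) within the
  prediction error.

`bbanneal` turns both into a pseudo-energy and searches the space of
(spin system → residue, resonance-type set) assignments by Metropolis
simulated annealing.

## Spin-system assembly

Crosspeaks whose amide H and N shifts agree within tolerance (defaults
0.03 ppm for ¹H, 0.3 ppm for ¹⁵N/¹³C, `default_tolerances()`) are
gathered into spin systems, seeded in input order so assembly is
deterministic. Ambiguous carbon dimensions (HNCA: Cα or Cα(i−1)) are
resolved against resonances already established in the system; a
candidate label is eliminated when its shift violates the tolerance
against an established resonance of that label. A peak that matches an
amide but clashes on a further resonance starts a *sibling* spin system
in the same overlap group; the crosspeaks of multi-member groups remain
exchangeable during annealing, which is how genuinely overlapped amides
are disentangled.

Residual ambiguity is enumerated as *resonance type sets*: every
internally consistent labeling of the still-ambiguous dimensions, found
by a depth-first search that prunes a branch as soon as some label's
shift range exceeds its tolerance. Each type set carries its own
arithmetic-mean shift per label. Even noise-free data leaves real
ambiguity — when CO(*i*) and CO(*i−1*) happen to fall within 0.3 ppm of
each other (roughly 8% of residues for a ~2 ppm CO dispersion) both
labelings are consistent and both are kept.

## The energy model

The total energy is the sum over placed spin systems of an adjacency and
a chemical-shift term; cached (unplaced) systems contribute zero.

**Adjacency.** For spin system *m* at residue *n* and *l* at *n+1*,

$$E^{adj} = \sum_{k \in \{C\alpha, C\beta, CO\}}
  c_0\,\exp\!\Big(-\tfrac12\big[(\delta_k^m - \delta_{k(i-1)}^l)/\sigma_k\big]^2\Big) + c_1$$

with defaults $c_0 = -100$, $c_1 = +50$: a perfect match contributes −50
per resonance, a gross mismatch +50, and the term crosses zero at a
0.2 ppm difference, which fixes $\sigma_k = 0.2/\sqrt{2\ln 2} \approx
0.170$ ppm for all three nuclei. A resonance missing from either side
contributes exactly zero, as does an unoccupied neighbour. The exponent
is negative — the term is a sum of inverted Gaussians; the stated
limits (−50 at zero difference, +50 asymptote, 0.2 ppm intercept) force
this sign.

**Chemical shift.** For each spin system the package computes a Bayesian
posterior over all (residue position *n*, type set *i*) combinations.
The prior is 0 at impossible combinations — an amide-bearing type set at
a proline; optionally (off by default) a Cβ-bearing type set at a
glycine — and uniform $1/C$ over the $C$ possible ones. The likelihood
is the survival function of a $\chi^2_R$ variable at

$$X^2 = \sum_{r=1}^{R}
  \big[(\delta_{obs,r} - \delta_{pred,r})/\sigma_r\big]^2,$$

summed over the $R$ resonances present in both the observation and the
predictions, among H, N, Cα, Cβ, CO and the (*i−1*) carbons, the latter
compared against the predictions of residue *n−1* (at *n = 1* they drop
out of $R$; missing predictions — glycine Cβ, proline H — silently
reduce $R$). The posterior is the normalized product, and the energy

$$E^{cs} = \frac{E^{cs}_{min}}{\log(I^m N)} \log\big(p\, I^m N\big),
  \qquad E^{cs}_{min} = -50,$$

clamped from above at $E^{cs}_{max} = +100$: posterior 1 is worth one
perfect connectivity (−50), the uninformative value $1/(I^mN)$ is worth
0, and posterior 0 costs +100 — so two perfect or three reasonable
connectivities can overrule even a hopeless shift prediction. The log
base cancels. If every likelihood underflows to zero (e.g. an artifact
spin system), the posterior is defined as identically zero, the energy
clamps to $E^{cs}_{max}$ everywhere, and the annealer learns to cache
the system.

Prediction errors are part of the model, not a nuisance: in `table` mode
they default to structure-predictor RMSDs (0.45, 2.4, 0.8, 0.95,
0.9 ppm for H, N, Cα, Cβ, CO); random-coil errors (0.16, 1.0, 0.42,
0.37, 0.43 ppm) suit intrinsically disordered proteins; in
`residue_stats` mode the per-type BMRB-style standard deviation is the
error. Because the error is a standard deviation, about 32% of correct
assignments are *expected* to sit outside one error unit — a property
the test suite checks against the generator.

## The annealing engine

The state holds a placement (each spin system at exactly one residue or
in a cache), an active type set per system, and the total energy,
maintained incrementally and verified against full recomputation to
1e−6. Proposals are: relocate a system to an empty legal position, swap
two placed systems, move a system to the cache, change a type set in
place (each placement draws a random type set legal at the target), or —
with probability 0.01 per proposal — a crosspeak move within an overlap
group (move to a sibling, swap with a sibling's peak, or park a
low-intensity peak in the crosspeak cache when that option is enabled).
A crosspeak move re-derives the affected systems' type sets, means and
posteriors; any clash rejects it outright. The Metropolis criterion
accepts downhill moves always and uphill moves with probability
$\exp(-\Delta E/T)$.

Cooling starts at $T_0 = 1000$ and is guided by the specific heat
estimated from the energy variance of post-swap samples,
$C_v = (\langle E^2\rangle - \langle E\rangle^2)/T^2$ (population
moments; at the sample sizes used the n/n−1 distinction is negligible).
Equilibration at each temperature is declared when a two-tailed pooled
Student's t-test between the two most recent disjoint samples gives
p > 0.5 (Welch's test is available behind a flag). The next temperature
targets a mean-energy drop of −2000, $T_{next} = T - 2000/C_v$, with the
decrease capped at 10 units; sample sizes follow
$S = \min(\max(N C_v^{1.5}/300, 10^4), 10^5)$. A run stops when
$T < 1$, when $T\,C_v < 200$, or when the failed/successful swap ratio
of the last sample exceeds 10 000, and finishes with greedy local
minimization (100 sweeps, decreases only) of every system over every
position, every type set, and every crosspeak over its group.

### Numerical choices

Several choices are the package's own engineering, documented here:

* **Bounded sampling.** The t-test assumes independent samples; on a
  correlated Markov chain at low temperature it can keep failing on
  drift too slow to matter. Sampling at one temperature is therefore
  bounded: at most 12 consecutive samples, and at most 50·S proposals
  per sample. Twelve consecutive failed equilibration comparisons are
  treated as evidence of such drift.
* **Arming the $T C_v$ stop.** $T\,C_v$ estimates the energy separating
  the ensemble from the ground state, which is meaningful only past the
  specific-heat peak. On small problems the quantity starts *below* 200
  at $T_0$ and would stop the very first step, so the criterion is
  armed with hysteresis: it can fire only after $T\,C_v$ has first
  exceeded twice the threshold. For problems of realistic size
  ($T_0 C_v > 400$ from the start) behaviour is unchanged.
* **Pair type-set refinement.** The CO/COm labeling of two neighbouring
  spin systems couples through their shared adjacency term; no
  single-element move can cross it. The minimization therefore also
  jointly re-optimizes the type sets of each adjacent pair
  (decreases only).
* **Crosspeak-move element selection.** The 1% crosspeak draw picks
  uniformly over *all* crosspeaks; a peak with no productive move is a
  no-op counted as an unsuccessful proposal. Restricting the draw to
  exchangeable peaks would amplify exchange moves on clean data sets
  where few peaks overlap.
* **Determinism.** Assembly seeds in input order; one seeded stream
  drives each run (the compiled kernel re-seeds a fast internal
  generator from R's RNG each call), so a fixed seed reproduces a
  trajectory bit for bit. Ensemble run *k* uses `seed + k − 1`.
* **Degenerate inputs.** A spin system placeable nowhere ($C = 0$) is a
  validation error; a peak-move that would empty a spin system is
  rejected; zero successful swaps over a sample count as equilibrated
  and feed the termination ratio.

## Consensus and curation

The procedure is repeated from 20 independent random initializations.
A residue is tentatively assigned the spin system placed there in a
strict majority of runs (an exact 10/20 tie stays unassigned). The
tentative assignment is kept only if (1) it has at least two
connectivities with adjacent consensus spin systems — a connectivity
being a matching Cα/Cβ/CO vs (i−1) resonance pair within the carbon
tolerance — or (2) at least one connectivity and a posterior of at
least $3/N$, or (3) a posterior above 0.5. Curation only removes.
The posterior and connectivities reported for a consensus assignment
are computed against the input spin-system set; individual runs may
have exchanged crosspeaks, and their mutated systems need not agree, so
the input enumeration is the deterministic, well-defined choice.

Scoring against a reference labels each non-proline residue *matched*
(same amide group, identified by H/N shifts within tolerance, or both
unassigned), *missing* (reference assigned, result not), or
*mismatched* (result assigned something the reference contradicts or
lacks).

## The synthetic data generator

`simulate_dataset()` draws each residue's true H, N, Cα, Cβ, CO shifts
from per-type Gaussians (the packaged BMRB-like table — a synthetic
stand-in with realistic means and SDs), then emits the seven standard
peak lists with Gaussian position noise of 0.003 ppm (¹H) and 0.04 ppm
(¹⁵N, ¹³C). Prolines emit no amide-rooted peaks, glycines no Cβ, and
residue 1 nothing that references a residue 0. The predictions handed
to the solver in `residue_stats` mode are exactly the generating means
with the generating SDs as errors, which matches the Bayesian model's
assumptions and makes recovery a fair test of the search, not of the
predictor. `synthetic_predictions()` complements this with a
structure-predictor analogue — each residue's true shift plus Gaussian
error of the predictor's reported accuracy, with that accuracy as the
prediction error — the informative regime in which sparse data remain
assignable; database-only type statistics degrade much faster under
depletion, so the sparse-data validations run with the predictor
analogue. Degradation transforms reproduce sparse-data conditions:
per-peak-class Bernoulli retention (keyed on whether a peak carries
Cα-, Cβ- or CO-type information), whole-spin-system deletion either at
random or in disjoint stretches of five consecutive residues, and
artifact injection until a chosen fraction of all carbon peaks are
artifacts — each artifact drawn from the residue-type Gaussians of a
random amide-bearing residue and given its list's maximum intensity so
it can never be cached.

What the generator does *not* emulate: real linewidths and peak overlap
in the spectral dimensions beyond amide degeneracy, intensity patterns
that encode Cα/Cβ sign information, side-chain NH₂ spin systems,
systematic (non-Gaussian) prediction bias, and missing peaks that
correlate with dynamics. Passing the recovery tests therefore
demonstrates that the search engine and the statistical model work as
designed, not that every experimental data set of equal nominal quality
will assign as completely.

## Scale of the validation experiments

The test suite exercises the full pipeline at sizes a laptop solves in
minutes, chosen as representative rather than impressive: exact
enumeration against a subset dynamic program at 8–9 placeable residues,
recovery of complete noise-free data at 60 residues over 5 generator
seeds and 20-run ensembles, and 40% spin-system deletion at 60
residues. Proteins of a few hundred residues are within the design but
take correspondingly longer.

## A worked example

```{r}
library(bbanneal)

truth <- simulate_dataset(length = 60, seed = 1)
fit <- assign_backbone(truth, n_runs = 20, seed = 1)
print(fit)
head(as.data.frame(fit))
plot(fit)          # annealing trajectories
```

## Known limitations

* Amide-degenerate overlap groups are resolved by crosspeak exchange,
  but heavily overlapped spectra (many groups of 3+) will slow the
  search and can leave residues uncurated.
* The posterior treats prediction errors as independent Gaussians;
  correlated predictor bias violates this and is mitigated only by the
  energy clamp.
* The consensus stage assumes runs explore the same spin-system
  inventory; extreme crosspeak exchange could in principle make run
  inventories diverge, which curation then treats conservatively.
* Termination constants (the 200-unit $T C_v$ threshold in particular)
  are calibrated for protein-sized problems; the arming hysteresis
  keeps toy problems sound but very small inputs rely on the $T < 1$
  and swap-ratio criteria.
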