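---
title: "Methods: ancestral reconstruction and kinetic deconvolution in paleofmo"
author: "paleofmo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral reconstruction and kinetic deconvolution in paleofmo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofmo)
```

paleofmo reconstructs ancestral flavin-containing monooxygenase (FMO)
sequences on a fixed phylogeny, prioritizes the historical substitutions
along a branch of interest, and analyzes the enzyme kinetics used to
characterize resurrected ancestors. This vignette is the package's own
account of the statistical machinery, the defaults, and the design choices
made where more than one defensible option existed.

## The substitution model

Sequence evolution is modeled as a reversible continuous-time Markov chain
on the 20 amino acids. An empirical exchangeability matrix $S$ (Jones/JTT
by default; WAG and LG are available) is combined with equilibrium
frequencies $\pi$ into the generator

$$Q_{ij} = S_{ij}\,\pi_j \quad (i \neq j),$$

with the diagonal set so rows sum to zero and the whole matrix rescaled so
that $-\sum_i \pi_i Q_{ii} = 1$: branch lengths are expected substitutions
per site. Reversibility ($\pi_i Q_{ij} = \pi_j Q_{ji}$) holds by
construction and is verified to $10^{-10}$ in the tests. Transition
probabilities $P(t) = e^{Qt}$ come from the eigendecomposition of the
symmetrized generator $\Pi^{1/2} Q\, \Pi^{-1/2}$, which is exact and stable
for reversible models; entries below $-10^{-12}$ from round-off are clamped
and rows renormalized.

Two frequency modes are provided because empirical-matrix reconstructions
are run both ways in practice: `matrix_default` (the frequencies
distributed with the matrix — the default) and `observed` (+F, counted
from the alignment with gaps and `X` excluded). Zero observed frequencies
are floored at $10^{-10}$ so the symmetrization stays nonsingular.

Among-site rate variation uses the discrete-gamma approximation: $K$
equal-probability categories of a $\mathrm{Gamma}(\alpha, \alpha)$
distribution (mean 1). The category rate is the conditional mean within
each quantile bin, computed in closed form from the incomplete-gamma
identity and renormalized to average exactly 1; bin medians are available
behind `rate_mode = "median"`. The default settings, $\alpha = 1.114$ with
$K = 4$ and the JTT matrix, are the study conditions this package is built
around. The tests pin the mean-based rates against an adaptive-quadrature
oracle at $10^{-6}$.

## Marginal ancestral reconstruction

Site likelihoods are computed by Felsenstein pruning, post-order over the
tree, with per-node per-site scaling factors accumulated in log space to
prevent underflow. Gap and `X` characters contribute all-ones conditional
vectors (missing data): the likelihood never decides whether an ancestor
*had* a residue, only which residue it had. Categories are integrated with
equal weights $1/K$.

Marginal posteriors at an internal node $v$ combine inside (subtree below
$v$) and outside (rest of the tree) conditional likelihoods per category;
the per-category posteriors are weighted by each category's share of the
site likelihood and normalized. Because the model is reversible, the same
quantity can be obtained by rerooting the tree at $v$ and reading the root
posterior; both implementations exist, the inside–outside pass is the
default, and their agreement (to $10^{-8}$) is a standing test, alongside
exact agreement (to $10^{-10}$) with brute-force enumeration over all
internal-state assignments on trees with two internal nodes.

Ancestral presence/absence is decided separately from the likelihood, by
Fitch parsimony on the binary gap character observed at the leaves: a
bottom-up intersection/union pass followed by top-down refinement. Two
documented conventions apply. `X` counts as presence (conservative for
ancestor length). Ties — a node whose refined state set still contains
both presence and absence — resolve to **present** by default
(`tie = "absent"` is available); a consistent resolution is what makes a
set of ancestors along one backbone come out the same length.

Per site the profile records the MAP state with its posterior probability
(PP), the second-best state with its PP, and an ambiguity flag set when
the second-best PP is strictly above 0.2. MAP ties (never observed in
realistic posteriors, but possible in degenerate inputs) break to the
alphabetically first one-letter code, with a warning.

Three sequence-level summaries follow. The **MAP ancestor** concatenates
MAP states over present columns. The **AltAll ancestor** carries the
second-best state at every ambiguous present site and the MAP state
elsewhere — it never introduces gaps, considers only the single
second-best state even if a third state also exceeds the threshold, and
differs from the MAP sequence exactly at the flagged sites (a property the
tests enforce). The **mean PP** averages the MAP PP *over present sites
only*; averaging over all alignment columns would mix reconstruction
confidence with length inference, so the all-columns variant is
deliberately not used.

## The substitution-prioritization funnel

Substitutions along a branch are the columns, present at both ends, where
the two MAP states differ; positions are reported in the descendant's
ungapped residue numbering (the frame in which mutants are named), and the
parent frame is available through the same coordinate map — the package
reports both frames rather than adjudicating between nomenclatures when
they disagree.

Three filters follow, each with explicit, configurable thresholds:

1. **Reconstruction confidence.** A substitution is *true* when the MAP PP
   exceeds 0.8 at both nodes. When one node is weak (PP < 0.8) but its
   credible alternative state (PP > 0.2) differs from the other node's MAP
   state, the substitution cannot be an artifact of picking the wrong
   state and is *included as ambiguous*; otherwise it is excluded. All
   comparisons are strict; threshold equality excludes (and is logged).
2. **Conservation.** A transparent score replaces server-based conservation
   analysis: per column, over a clade subset, the modal residue frequency
   (gaps excluded) with Shannon entropy as a diagnostic. A column is
   conserved when the modal frequency is at least 0.8 (inclusive,
   configurable). Records survive when conserved across the whole dataset
   or within either daughter lineage, and the label records which.
3. **Structural triage.** Records carry a structural category
   (active site, tunnel, FAD-proximal, NADPH shells, other) and a
   surface/core call from a user-supplied annotation table. The drop rule
   is records that are simultaneously *surface* and *other* — residues
   with no annotated functional environment on the protein surface are the
   ones a structural inspection would set aside as likely playing no
   role. The rule is explicit and configurable precisely because manual
   structural judgment cannot be reproduced mechanically; every drop is
   logged with its failing stage.

Mutant sets nest by construction: `4x` is the active-site survivors, `12x`
adds the next-priority environments (tunnel, FAD-proximal, first NADPH
shell), `16x` is all survivors. Which sites belong to the middle tier is a
documented reconstruction — the tier rule, not a claimed itemization.
Explicit user-defined subsets (e.g. a reduced set of three positions) are
validated against the survivors.

## Kinetics

**Steady state.** Michaelis–Menten fits are plain nonlinear least squares
of $v = V_{max} S/(K_M + S)$, seeded from a Hanes–Woolf linearization plus
fixed restarts; standard errors come from the covariance at the optimum,
and fits are unweighted by default (replicate-level weighting would demand
replicate variance estimates the typical three-replicate design cannot
support). Convergence to a negative parameter is reported as a flagged fit
failure rather than silently returned. Designs that never approach the
fitted $K_M$ earn a low-information warning. With an enzyme concentration
supplied, $k_{cat} = V_{max}/[E]$ and the efficiency $k_{cat}/K_M$ is
always converted to s$^{-1}$ mM$^{-1}$. Initial rates from 340-nm traces
use $\varepsilon_{340} = 6.22$ mM$^{-1}$cm$^{-1}$; the window is the
longest prefix with linear $R^2 \ge 0.995$ and $\le 10\%$ absorbance
depletion, and the slope is the linear coefficient of a quadratic fit in
that window, which removes the bias a straight line picks up from early
curvature. Oxygen affinity is the same hyperbolic fit against after-mixing
O$_2$ concentrations; these are user configuration (defaults 0.13, 0.31,
0.61, 0.96 mM), and a fit whose $K_M^{O_2}$ falls below the tested range
with an uncertainty as large as the estimate is flagged saturated rather
than trusted.

**Pre-steady state.** Single phases fit
$A(t) = A_\infty + \Delta A\, e^{-kt}$; a Wald–Wolfowitz runs test on the
residuals flags systematic structure and suggests the sequential model.
The photodiode-array deconvolution fits the two-step scheme
$a \xrightarrow{k_1} b \xrightarrow{k_2} c$ by variable projection: at
fixed $(k_1, k_2)$ the closed-form concentration profiles

$$c_a = e^{-k_1 t},\qquad
  c_b = \tfrac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),\qquad
  c_c = 1 - c_a - c_b$$

make the species spectra linear, solved by least squares; the outer
optimization runs over $(\log k_2, \log(k_1 - k_2))$ — which enforces the
$k_1 > k_2$ labeling convention — from a grid of restarts spanning the
measured time decades, polished by BFGS. Near-degenerate rates
(relative gap below $10^{-6}$) switch to the confluent limit
$c_b = k_1 t\, e^{-k_1 t}$. Standard errors come from the numerical
Jacobian of the profiled residual. The intermediate spectrum's wavelength
of maximal absorbance is reported because a $\sim$380-nm peak is the
diagnostic signature of the C4a-(hydro)peroxyflavin. One caution the tests
encode: when the data contain only a single kinetic phase (the $k_2 \to 0$
limit), which of the two rates carries it is not identifiable with free
spectra — the fit reproduces the data and one rate matches the
single-exponential estimate, and that is all that can be asserted.

Conversions are substrate depletion normalized by an internal standard
against a no-enzyme control, clamped to $[0, 100]$% with a warning.
Melting temperatures are the tallest interior maximum of the smoothed
first derivative of the melt curve (moving average, default 5-point
window), refined below grid resolution by parabolic vertex interpolation;
a secondary transition is reported when present. Holoenzyme is quantified
from flavin absorbance with
$\varepsilon_{450} = 11.3$ mM$^{-1}$cm$^{-1}$.

## What the synthetic generators emulate — and what they do not

`simulate_alignment` draws the root from $\pi$, assigns each site one
gamma category for the whole tree (the same site-rate assumption the
reconstruction makes), and evolves each branch under $P(Qtr)$. Indels are
clade-restricted contiguous block deletions inherited below the branch
they occur on — enough to exercise the Fitch machinery, deliberately not a
full insertion–deletion process (no TKF-style model, no independent gap
events, no alignment error). The kinetic generators produce exactly the
rate laws the fitters assume, with Gaussian noise. Passing the recovery
tests therefore demonstrates *internal correctness* — the estimators
recover what generated the data — and calibration of the reported
uncertainties; it does not demonstrate robustness to model violations real
data carry (alignment error, rate-matrix misspecification, correlated
instrument noise, baseline drift).

One calibration experiment is worth singling out: on a 16-leaf balanced
tree with branch lengths 0.05 and 500 sites under JTT + Γ(1.114, 4), the
root MAP sequence recovers at least 90% of the true states and, within
PP bins holding at least 100 sites, the mean PP sits within 0.1 of the
observed accuracy. Those thresholds are regression guards for this
benchmark, not universal claims.

## Problem sizes and numerical choices

The test and demonstration sizes are chosen so every stage runs
comfortably on a single CPU: quartets for the exhaustive oracles (the
$20^2$ enumeration is exact and instant), 16 leaves × 500 sites for the
calibration benchmark, 200 log-spaced times × 51 wavelengths for the
deconvolution, and three-replicate saturation designs matching common
bench practice. Posterior normalization is enforced to $10^{-8}$;
likelihood scaling is per node and per site; the deconvolution declares
rate degeneracy below a relative gap of $10^{-6}$.

## Known limitations

- The tree, its branch lengths and the gamma shape are inputs; nothing is
  re-estimated. A misspecified tree propagates silently into posteriors.
- Marginal (not joint) reconstruction: per-site posteriors are exact, but
  the MAP sequence as a whole is not the jointly most probable ancestor.
- The conservation score is frequency-based and treats clades as given; it
  does not model phylogenetic correlation within a clade.
- The structural triage encodes one explicit drop rule; a human structural
  analysis would weigh more context than surface-and-unannotated.
- The sequential deconvolution assumes exactly three spectrally distinct
  species and first-order steps; more complex mechanisms (reversible
  steps, spectral intermediates beyond one) need a different model.
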