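---
title: "Models and methods behind fluctspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluctspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctspec)
```

fluctspec analyses a classic experimental design in microbial mutation
research: many parallel bacterial cultures are grown without selection,
plated on rifampicin, and the distribution of resistant-mutant counts
across cultures is used to infer the spontaneous mutation rate; the
resistant isolates are then Sanger-sequenced over the rifampicin
resistance determining region (RRDR) of *rpoB* to classify each mutation,
giving the mutational *spectrum*. The package covers both halves — rate
inference and spectrum inference — plus the statistics used to compare
conditions (two glucose concentrations) and strains (a wild type and a
deletant), and a synthetic-study generator with known ground truth.

## The mutant-count model

A culture grows from a tiny inoculum to `Nt` cells. Mutations to
rifampicin resistance occur during growth; a mutation that happens early
founds a large resistant clone, so mutant counts are heavy-tailed
("jackpots"). fluctspec uses the Lea–Coulson formulation: the number of
mutation events per culture is Poisson with mean `m`, and each event
founds a clone whose final size `K` follows

$$q_k = \Pr(K = k) = \rho\,\frac{\Gamma(k)\,\Gamma(\rho+1)}{\Gamma(k+\rho+1)},
\qquad k \ge 1,$$

where $\rho$ is the fitness of the mutant relative to the wild type
during the assay. With $\rho = 1$ this is the familiar
$q_k = 1/(k(k+1))$. The count pmf is the compound-Poisson distribution of
the sum of clone sizes, computed by the Panjer-type recursion

$$p_0 = e^{-m}, \qquad p_n = \frac{m}{n}\sum_{k=1}^{n} k\,q_k\,p_{n-k}.$$

The survival function of the clone-size law telescopes to the closed form
$S_k = \Gamma(\rho+1)\Gamma(k+1)/\Gamma(k+\rho+1)$, which the simulator
inverts exactly (binary search on $k$), so simulation and recursion are
two independent routes to the same distribution — the test suite checks
that they agree bin by bin.

Model assumptions worth keeping in mind: no cell death, no phenotypic
lag, no post-plating growth, and every cell plated (plating efficiency
1, matching a design in which the whole culture volume is plated).
Extensions covering those effects are deliberately out of scope.

## Estimating m and the mutation rate

`fluctuation_ml()` maximises the likelihood of the counts under the
recursion. Two modes are provided because published analyses often do
not state which was used: the default holds $\rho$ fixed at 1; the
`"joint"` mode estimates $(m, \rho)$ together (Nelder–Mead on the log
scale). Standard errors come from the inverse observed information —
a central second difference in the fixed mode, the numerical Hessian in
the joint mode. Counts are winsorized at `winsor_cap` (default 1024)
before likelihood evaluation: jackpot cultures carry almost no
information about `m` beyond "large", and capping makes the likelihood
finite-cost and the estimate invariant to how extreme the jackpot is.

Degenerate inputs are handled, not rejected: an all-zero count vector
returns the boundary estimate `m = 0` with an undefined (NA) standard
error and an explanatory note. The classical P0 estimator
(`fluctuation_p0()`, $m = -\ln \hat p_0$ with a delta-method standard
error) is included as a cross-check; it is less efficient but
assumption-light.

The rate is `mu = m / Nt`, with `Nt` the arithmetic mean of the
replicate CFU totals. By default `Nt` is treated as a known constant
(`se_mu = se_m / Nt`) because typical analyses do not propagate plating
error; `propagate_nt = TRUE` adds the CFU sampling variance by the delta
method for users who want it.

## Comparing rates: the low-to-high ratio

The response of the mutation rate to glucose is summarised by the ratio
of the low-glucose rate to the high-glucose rate. `sigma_ratio()`
implements the first-order delta method ("sigma method") for a ratio of
independent estimates,

$$\operatorname{var}(R) = R^2\!\left(\frac{se_a^2}{a^2} +
\frac{se_b^2}{b^2}\right),$$

with a normal 95% interval $R \pm 1.96\sqrt{\operatorname{var}(R)}$.
Independence holds by design (different cultures per condition), so no
covariance term is needed. `z_ratio_vs_1()` tests $R = 1$;
`z_ratio_diff()` contrasts two strains' ratios with
$z = (R_1 - R_2)/\sqrt{v_1 + v_2}$.

Sidedness defaults: the test against 1 is two-sided; the strain contrast
defaults to one-sided (upper tail), reflecting a directional hypothesis
that the wild type responds more strongly than the deletant — at a
contrast of $Z = 2.69$ the one-sided tail is 0.0036, which rounds to the
conventional 0.004, while the two-sided tail would be 0.007. Both
sidednesses are available and every result records which was used.

A note on precision: a single 182-culture experiment per condition
yields ratio standard errors of roughly 0.1–0.2, so confidence intervals
from one desk-scale run are necessarily much wider than intervals
reported from designs that pool more information. The package computes
the sigma-method definitions as stated and does not attempt to
reverse-engineer any particular published interval.

## Calling rpoB mutations

Reads are Sanger-derived consensus sequences of an amplicon covering
RRDR clusters I and II. `orient_and_align()` aligns the read and its
reverse complement semi-globally against the CDS (whole read, free end
gaps; Biostrings dynamic programming) and keeps the better strand.
Scores are match +2, mismatch −3, gap open −5, gap extend −2 — chosen to
favour substitution calls over spurious gaps at the low divergence of a
single-mutation Sanger read. Reads whose best identity falls below 80%
are rejected as unalignable rather than silently producing calls.

`extract_variants()` walks the aligned columns: each mismatching base
column is a substitution call; each gap run is one insertion or deletion
call. `N` columns are uninformative and never become calls. Indels are
left-normalized (shifted to the smallest CDS position that preserves the
altered sequence), the usual VCF convention, so calls are comparable
across alignments that place a gap differently within a repeat.

Annotation: codon number is `ceiling(cds_pos / 3)`; the amino-acid
change is translated under the standard genetic code; cluster membership
uses the published inclusive nucleotide ranges (cluster I 1520–1598,
II 1687–1715, III 2060–2062). For indels the cluster is assigned by
overlap of the affected interval rather than the normalized start
position alone: a whole-codon deletion at a cluster boundary can
left-normalize to a start one or two bases before the cluster while
still deleting cluster bases, and should not be misfiled as outside the
RRDR. Isolates with no call in clusters I/II are reported as
`none_detected` — in the real assay such isolates may carry resistance
mutations elsewhere — and isolates with multiple calls are flagged for
review rather than reduced to one call silently.

The packaged reference (`rpob_reference()`) is a deterministic
*synthetic* 4029-nt CDS with the geometry of the *E. coli* K-12 rpoB
window (1343 codons, genomic offset 4181245 on NC_000913.3). All
positional arithmetic is exact; only the base content is synthetic,
because the package ships no third-party sequence data. Users analysing
real reads should load the real CDS with `read_reference()`.

## The spectrum and its models

Substitutions collapse to the six strand-symmetric SNV classes
(AT>GC, GC>AT, AT>CG, AT>TA, GC>CG, GC>TA); insertions and deletions are
pooled into one category each, giving eight categories. Because
conditions yield unequal isolate numbers, comparisons use relative
frequencies within each strain-by-glucose condition.

Two model families are fitted on the categorized counts:

* **Multinomial** baseline-category logit over all eight categories
  (`fit_multinomial()`), fitted by Newton–Raphson with step halving on
  grouped counts. Convergence is declared when the log-likelihood moves
  by less than 1e-8 and the gradient is below 1e-6; Newton converges
  quadratically, so the single-predictor likelihood ratio reproduces the
  closed-form G statistic well inside the 1e-6 relative tolerance the
  tests assert. The
  baseline is the first observed canonical category (AT>GC); likelihood
  ratios are invariant to this choice, and a test verifies that.
  Categories with zero total count contribute nothing to the likelihood
  and are dropped (recorded in the fit); degrees of freedom scale with
  the number of observed categories. Coefficients larger than 15 in
  absolute value trigger a separation flag — the likelihood-ratio
  statistics remain usable because the deviance difference converges
  even when a coefficient diverges.

* **Per-class binomial** logistic models (`fit_binomial_class()`), "this
  category vs all others", via `stats::glm` with a tightened convergence
  tolerance (1e-12).

Both are tested with **Type-II likelihood-ratio chi-square tests**
following the marginality principle: each main effect is tested by
dropping it from the additive model (no interaction present), and the
interaction by dropping it from the full model. With eight categories
and binary predictors every multinomial term has 7 df; binomial terms
have 1 df. P-values are reported without multiplicity correction — each
model answers a single planned comparison. A category never observed
yields a flagged degenerate result rather than an error.

## The synthetic-study generator

`study_config()` fixes the study conditions; the generators are pure
functions of `(config, seed)`. Defaults emulate the design the package
targets:

| parameter | default | why |
|---|---|---|
| cultures per condition | 182 | the experimental design size |
| CFU replicates | 3, lognormal CV 0.1 | replicate plating of a subset |
| `Nt` | 1e8 cells | typical minimal-medium culture |
| rates (wild type) | 1.6e-8 / 1.0e-8 (low/high) | ratio preset 1.60 |
| rates (deletant) | 1.06e-8 / 1.0e-8 | ratio preset 1.06 |
| mutant fitness | 1 | simplest reproducible choice |
| isolates per condition | 68 | 272 total, matching a ~274-isolate study |
| detection probability | 214/274 | fraction with an RRDR cluster I/II hit |
| spectrum presets | AT>GC 0.45 (low) vs 0.25 (high); GC>TA elevated in the deletant | the effect sizes the analysis should detect |
| read window | CDS 1400–1900 | covers clusters I and II |
| read error rate | 0 | inputs are base-called consensus reads |

Planted mutations are placed at sites inside clusters I/II compatible
with their category (AT sites for AT>x classes, GC sites for GC>x
classes; indels are whole-codon, frame-preserving events). Planted indel
truth records are left-normalized with the same routine the caller uses,
so recovery is compared in canonical coordinates.

What the generator does **not** emulate: chromatogram noise and
base-calling uncertainty, PCR artefacts, selection dynamics on the
plate, the real distribution of resistance sites (>80 distinct SNVs;
the generator uses any compatible site uniformly), death/lag extensions
of the count model, and partial plating. Tests passing on synthetic data
therefore demonstrate correctness of the inference machinery under the
stated model, not robustness to these real-data complications.

## Numerical choices and test problem sizes

* ML optimisation of `m` is on the log scale (`optimize`, tolerance
  1e-9); the optimum matches a brute-force 0.001-step grid search to
  three decimals on all fixtures.
* Clone-size sampling is exact inverse-CDF via the closed-form survival
  function; no truncated-table approximation enters the simulator
  (clones are capped only at the culture size, default 1e9).
* The recursion-vs-simulation check uses 1e5 cultures per
  `(m, fitness)` combination over counts 0–20 at three Monte-Carlo
  standard errors; estimator recovery uses 200 replicates of the
  182-culture design; ratio calibration uses 1e6 draws (sd agreement
  within 5%) and 1000 simulated experiments (CI coverage within
  93–97%); the multinomial size check uses 2000 null tables of 200
  isolates per condition (rejection rate within 0.035–0.065); the
  caller round-trip uses 520 zero-error reads. These sizes keep the
  whole suite reproducible on a single CPU in minutes while leaving the
  Monte-Carlo bands meaningful.
* Seeds: every generator takes an integer seed and restores the
  caller's RNG state; derived seeds stay within 32-bit range.

## Configuration and interfaces

Stage functions consume and produce plain data frames mirrored as CSV;
reports are JSON with a provenance block (package and R versions, seed,
config hash — timestamps are excluded from determinism comparisons).
Study configuration files are YAML with keys equal to `study_config()`
arguments. A thin command-line wrapper with per-stage subcommands ships
in `inst/scripts/fluctspec-cli.R`; the R functions are the primary
interface.

## Known limitations

* The count model excludes death, lag, phenotypic delay and plating
  dilution; rates from systems where those matter will be biased.
* The caller assumes one isolate = one read = (at most) one causal
  mutation; multi-mutation reads are reported in full but flagged,
  matching a design that isolates one colony per culture.
* The synthetic reference sequence is a stand-in: analyses that depend
  on the real rpoB base composition (e.g. enumerating true resistance
  alleles) require loading the real CDS.
* Published cluster III is given as nt 2060–2062 for codon 687, but
  codon 687 arithmetically spans 2059–2061; the package follows the
  published inclusive range for cluster membership, so position 2062
  (codon 688) is counted as cluster III.
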