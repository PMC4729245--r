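---
title: "Methods: codon-level tests of selection effectiveness in social versus subsocial lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level tests of selection effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Permanently social spiders of the genus *Stegodyphus* inbreed through
sib-mating, have strongly female-biased sex ratios and high reproductive
skew. All three traits depress the effective population size Ne, which
weakens selection relative to drift. Two genome-wide signatures are expected
if selection has been less effective in the social lineages than in their
outcrossing, subsocial congeners:

* a higher dN/dS ratio (more nonsynonymous substitutions fix by drift), and
* weaker codon usage bias, i.e. a higher effective number of codons (ENC),
  because selection on synonymous codon choice is weak to begin with.

`socialsel` implements both tests on a fixed, labeled phylogeny, together
with the positive-selection screen that must precede the dN/dS comparison
and a synonymous-distance molecular clock for dating, and couples them to a
codon-alignment simulator so every stage can be validated against known
truth. The `analysis/` scripts chain the stages on a simulated study
fixture; the same functions accept any user-supplied alignment, rooted
Newick tree and species-to-mating-system label map.

# Models and procedures

## Effective number of codons

ENC is Wright's measure of how far synonymous codon usage departs from
uniformity, from 20 (one codon per amino acid) to 61 (all synonymous codons
equally used). For each degeneracy class k (2-, 3-, 4-, 6-fold; Met and Trp
excluded, Ile the only 3-fold family, Leu/Ser/Arg treated as whole 6-fold
families) the mean codon homozygosity $\bar F_k$ is estimated and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Two homozygosity estimators are available: the bias-corrected
$\hat F = (n\sum \hat p^2 - 1)/(n-1)$ (default) and the plain
$F = \sum \hat p^2$ (`plain_f = TRUE`), which realises the analytic 20/61
endpoints exactly and is the estimator used for the endpoint checks.
Families observed fewer than twice are dropped; a degeneracy class with no
usable family is imputed from the observed classes (the 3-fold class from
the mean of the 2- and 4-fold classes when both exist). Each class's
effective-codon contribution is capped at its degeneracy and the total is
clamped to [20, 61].

Group inference follows the comparative study design this pipeline
emulates: 1000 bootstrap replicates drawn over codon columns give
percentile 95% intervals for the social and subsocial mean ENC, and the
group difference is tested by randomly re-splitting the ten species into
groups of three and seven. The permutation p-value is one-sided in the
direction "social mean higher" — the direction predicted by reduced
selection — with the add-one correction $(1 + \#\{T^\ast \ge T\})/(1+B)$;
when $\binom{n}{k}$ does not exceed the requested replicates the 120
distinct splits are enumerated and the exact fraction is reported instead.
One caveat we verified empirically: codon-column bootstrapping duplicates
codons, which inflates within-family homozygosity and biases replicate ENC
*downward* at short alignment lengths (about ten ENC units at 120 codons,
mild at the study scale of ~1600 codons). The percentile interval is
therefore an interval for the resampling distribution, as in the original
design, not a bias-corrected interval.

## Branch-class codon models

The substitution process is a Goldman–Yang-style Markov model on the 61
sense codons: the rate from codon *i* to *j* is zero unless they differ at
exactly one position, and otherwise
$\pi_j \,\kappa^{[\mathrm{ts}]}\, \omega^{[\mathrm{nonsyn}]}$, scaled so one
unit of branch length is one expected substitution per codon site.
Stationary frequencies default to F3×4 (position-specific nucleotide
frequencies multiplied and renormalised); `f61` uses empirical codon
frequencies. Four nested models assign $\omega$ = dN/dS to branch classes of
the labeled tree:

| model | classes | free $\omega$ |
|---|---|---|
| A | all branches | 1 |
| B | internal / external | 2 |
| C | internal / external-social / external-subsocial | 3 |
| D | internal + one per external branch | 1 + #tips |

Model C is the mating-system test; D relaxes its equal-within-group
assumption; the regrouping check refits the 3-class model with the focal
social tip classed alongside subsocial partners instead of the other social
tips. Nested pairs are compared by likelihood-ratio tests with df equal to
the difference in $\omega$ counts, using unadjusted $\chi^2$ p-values
(no multiple-testing correction is applied, matching the emulated design; the report
footer says so).

Likelihoods come from Felsenstein pruning over the unrooted tree (the model
is reversible, so the root placement is immaterial; we verify root
invariance by test). Ambiguous codons are marginalised over all 61 states.
Transition matrices are computed by eigendecomposition of the symmetrised
generator, with probabilities floored at 1e-16 so reconstruction noise can
never produce a zero partial. Optimisation is bounded quasi-Newton (`nlminb`)
on log-transformed parameters, jointly over branch lengths, $\kappa$ and the
model's $\omega$ set. Branch-length gradients are analytic (the standard
two-pass pruning algorithm, with $\partial P/\partial t = QP$); $\kappa$ and
$\omega$ gradients use central finite differences on the log scale, which
costs little because a perturbed $\omega$ touches only its own class's
transition matrices. Initial branch lengths project log-corrected pairwise
codon mismatch distances onto the topology by non-negative least squares;
richer models are warm-started from the optimum of the model they nest,
which both speeds convergence and guarantees the nesting monotonicity
lnL(A) ≤ lnL(B), lnL(C) ≤ lnL(D) numerically. `n_starts` adds jittered
restarts (default 3 for standalone branch-model fits; the replicated
simulation experiments use single warm starts, which we verified reproduce
the multi-start optima to numerical tolerance).

## Site models M7/M8

The positive-selection screen compares M7 — $\omega$ beta-distributed on
(0,1), discretised into 10 equal-probability categories at quantile
midpoints — against M8, which adds one category with $\omega_s > 1$ and
weight $1-p_0$. Following the standard two-step site-model workflow, branch
lengths are estimated once under the single-ratio model and held fixed while
$\kappa$ and the distribution parameters are optimised; the M8 fit includes
a start at the M7 optimum with the extra class switched off, so M8 can never
fit worse than M7. Categories share one rate normalisation (the
mixture-averaged expected rate), so a branch length is expected
substitutions per codon averaged over site classes. The M7-vs-M8 LRT is
referred to $\chi^2$ with 2 df; this is
conservative for testing on the $p_0$ boundary, and the fit output notes it.

## Synonymous distances and the molecular clock

Pairwise synonymous distances use Nei–Gojobori (1986) counting: synonymous
site counts by degeneracy (changes to stop codons excluded from the
numerator while each position keeps weight 3), differences averaged with
equal weight over minimal mutational pathways (pathways through stops
discarded; if every pathway is blocked, all are used with stop-crossing
steps scored nonsynonymous), and Jukes–Cantor correction
$d = -\tfrac34\log(1-\tfrac43 p)$, flagged infinite when $p \ge 3/4$.
Codons missing in either sequence are dropped pairwise.

Each internal node's synonymous depth is the mean pairwise dS over all tip
pairs whose most recent common ancestor is that node, and its age is
$d_S/(2\mu)$ generations (two lineages each accumulate $\mu$ per synonymous
site per generation), times the generation time. Defaults are
$\mu = 8.4\times10^{-8}$ — the Drosophila per-site per-generation estimate —
and a 1-year generation time, matching the implicit equation of generations
with years common in this literature; both are knobs, and the divisor 2 is
stated in the report because the dating formula is easy to mis-remember.
Clock violations (a node dated older than the root) are warned about, never
silently reordered.

# The simulator and what it does (not) emulate

`make_study_fixture()` generates the desk-scale stand-in for the deposited
data: 10 taxa (3 social), a rooted topology in which each social tip is
sister to a subsocial tip, social terminal branches about a quarter the
length of subsocial ones (echoing the young, non-speciating social
lineages), 13 loci totalling 1583 codons = 4749 coding nucleotides, evolved
under model C with $\omega$ = 0.17/0.25/0.10 and $\kappa = 2$, plus an
optional 11th (undescribed, subsocial) taxon and a 589-nt neutral non-coding
partition. The two named social–subsocial sister pairs follow the published
topology; the rest of the fixture topology is synthetic (the full tree
cannot be transcribed from text), and any analysis can be re-run on a
user-supplied alignment and Newick tree for accession-based benchmarking.
Codon frequencies default to uniform, which makes the fixture's expected
ENC difference zero — useful for null calibration of the permutation test;
`simulate_skewed_codon_usage()` then induces a known, amino-acid-preserving
usage skew to give the test something to detect.

What passing these simulations does *not* show about real data: the
simulator has no indels, no recombination, no within-species polymorphism
(segregating sites inflate terminal-branch dN/dS in real data — the
internal-vs-external model B exists precisely to flag that), no base-composition
heterogeneity across lineages, and no among-locus rate variation beyond what
the single set of branch lengths implies.

# Numerical and design choices

* **Problem sizes.** The replicated experiments are sized for a single CPU:
  parameter recovery runs 20 replicates at the full fixture size (1583
  codons); the LRT null calibration runs 200 replicates of 300 codons on a
  6-taxon tree. The calibration tree has *equal* terminal branch lengths
  (0.08) rather than the fixture's short social terminals: a $\chi^2$
  calibration experiment must give every $\omega$ class enough expected
  substitutions for the asymptotics to apply, and we verified that with the
  fixture's 0.02-length social branches the A-vs-C test is conservative
  (2% empirical rejection at nominal 5%) while the balanced design is exact
  to binomial error. The conservatism with short social branches is worth
  knowing when interpreting borderline p-values on real data.
* **Clock simulations.** Time is converted to branch length through the
  model's own synonymous rate (`years_to_branch_length()`), so that the
  simulated process accumulates exactly $\mu$ synonymous substitutions per
  Nei–Gojobori synonymous site per generation; a naive "3·mu·t per codon"
  conversion leaves a ~10% systematic bias in recovered ages.
* **Optimizer.** Convergence is declared by `nlminb`'s relative-tolerance
  test (1e-10 on the objective); bounds are wide (branch lengths
  1e-7–20 substitutions/codon, $\omega$ 1e-4–50, $\kappa$ 0.05–100) and fits
  report convergence flags and a per-start trace rather than hiding them.
* **Degenerate inputs.** Stop codons abort loading by default
  (`mask_stops` masks them); codons with any non-ACGT character are missing
  and marginalised in likelihoods, dropped pairwise in counting; polytomies
  are rejected unless explicitly resolved with zero-length branches;
  single-column bootstraps warn and return degenerate intervals; saturated
  NG86 distances are flagged infinite and the corresponding nodes left
  undated.
* **Seeds.** Every resampling and simulation function takes an explicit
  integer seed and records it in its output; a full pipeline run is
  byte-identical under a fixed config and seed.

# Known limitations

Replicating printed values from PAML- or INCA-based analyses is
approximate by nature: codon-frequency treatment, optimiser details and
branch-length handling differ between implementations, so comparisons
against published fits should be read at tolerances of roughly 0.02 on
$\omega$ and half a log-likelihood unit. The M7/M8 screen fixes branch
lengths at the single-ratio estimates instead of re-optimising them per site
model — the standard workflow, but a difference from a fully joint fit.
Only the universal nuclear code is supported, there is no branch-site model,
no Bayes empirical Bayes site identification, no relaxed clock, and the only
distance flavour is NG86 with Jukes–Cantor correction. Strict-clock ages
inherit every caveat of a single borrowed mutation rate, and should be read
as order-of-magnitude statements.
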