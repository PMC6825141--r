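---
title: "Methods: tissue-specificity profiling and the branch-site selection scan"
author: "tauselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specificity profiling and the branch-site selection scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauselect)
```

`tauselect` re-implements, as a tested and reusable toolkit, the analysis
stack used to characterize a six-tissue bulk transcriptome of a wild bird
(brain, blood, ovary, spleen, liver, muscle) and to scan its protein-coding
genes for lineage-specific positive selection. This vignette documents the
models, the tunable parameters and their defaults, the design choices that
were genuinely open, and what the synthetic-data experiments do and do not
demonstrate.

## Expression quantification and presence calls

Counts are converted to transcripts per million with the standard
length-then-composition normalization,
$\mathrm{TPM}_{g} = 10^6 \, (c_g/L_g) / \sum_h (c_h/L_h)$ per tissue, so each
tissue column sums to $10^6$ exactly. TPM is compositional: values are
relative to the set of genes quantified, which matters for simulated subsets
(see below).

A gene is *present* in a tissue when its TPM is at least 1; values strictly
below 1 are absences. Present cells are further binned as low
($[1, 10)$), medium ($[10, 50]$) or high ($(50, \infty)$) expression. The
bin boundaries at exactly 10 and 50 are assigned to medium — the bin
definitions used in this field leave the boundary open, and inclusive-medium
is the unique choice that keeps the three bins a partition.

Exclusive tissue intersections (the quantities behind an UpSet plot) count
each present-somewhere gene in exactly one subset, its exact presence
pattern, so subset counts always sum to the number of present genes; that
conservation property is tested against a full $2^6$ enumeration.

## The tissue-specificity index tau

For a profile $x_1, \dots, x_n$ over $n$ tissues,
$$\tau = \frac{\sum_{i=1}^{n} (1 - \hat x_i)}{n - 1}, \qquad
  \hat x_i = \frac{x_i}{\max_j x_j},$$
computed after flooring every value at 2 TPM. The floor suppresses sampling
stochasticity in tissues with little or no detected expression: without it,
a gene detected at 0.01 TPM versus 0 TPM in two silent tissues would swing
$\tau$ for no biological reason. $\tau$ is 0 for uniform profiles and
approaches 1 for single-tissue expression; with the floor the maximum
attainable value is $1 - \mathrm{floor}/\max_j x_j$. A profile entirely at
or below the floor is reported as $\tau = 0$ with a `no_expression` flag
rather than an arbitrary number.

Genes are classed *broad* ($\tau < 0.3$), *high* ($\tau > 0.8$) or
*moderate* (the closed band between). Whether $\tau$ should be computed on
raw or log-transformed expression is not settled usage; raw floored TPM is
the default here because the floor is stated on the TPM scale, and a
`log2 = TRUE` variant is provided. Similarly, the "summed expression"
covariate reported alongside $\tau$ is $\log_{10}(\sum_t \mathrm{TPM}_t+1)$;
summing before the log is the default because the alternative (summing logs)
double-penalizes absent tissues that the floor already handles.

The broad/high cut-offs can be sanity-checked on data with
`calibrate_cutoffs()`, a two-sample Kolmogorov–Smirnov test (asymptotic
two-sided p) contrasting the most abundant unique gene per tissue with a
housekeeping panel.

Per-tissue summaries (`tau_by_max_tissue()`) assign each gene to its
maximal-expression tissue (ties go to the first tissue in column order and
are flagged) and report the group mean with a normal-approximation 95%
confidence interval ($\pm 1.96\,\mathrm{SE}$), matching the symmetric
intervals conventionally reported for such tables.

## Annotation confidence filtering

Transcript-to-protein hits in BLAST tabular form are retained when
$e < 10^{-10}$, percent identity $\ge 70$ and coverage of the full-length
subject protein $\ge 0.5$ — "at least" thresholds are inclusive, and
coverage is measured against the subject length, i.e.
$\mathrm{alignment\ length}/\mathrm{subject\ length}$. Best-hit assignment
is deterministic: lowest e-value, then highest bit score, then the
lexicographically smallest subject id.

Redundancy collapse follows the greedy incremental scheme of cd-hit-style
tools: sequences are processed longest-first and join the first existing
cluster whose founder shares estimated identity at or above the threshold
(default 0.95, configurable — the exact parameters used by redundancy
removal in assembly pipelines are rarely reported). Identity is estimated
by canonical 8-mer containment, which scores identical strings exactly 1
and unrelated strings near 0; full short-word indexing as in cd-hit proper
is out of scope and unnecessary at the scale this package targets.

N50 is computed by the cumulative-sum definition over descending lengths;
GC% counts unambiguous A/C/G/T only.

## Orthology and the branch-site selection scan

### Markov clustering

All-vs-all similarity (edge weight $-\log_{10} e$, capped at 200 to absorb
underflowed e-values of 0) is clustered with the canonical Markov cluster
algorithm: self-loops at each node's maximum incident weight,
column-normalization, then alternating expansion (matrix squaring) and
inflation (elementwise power 1.5, pruning below $10^{-5}$, renormalization)
to convergence; clusters are the connected components of the limit matrix's
support. The implementation is dense, which is appropriate for the
few-thousand-node graphs of single-copy orthology screens; the result is
invariant to node input order. Groups are then restricted to single-copy
families: exactly one member per required species and no extras.

### The codon model

Both the simulator and the likelihood use the Goldman–Yang codon
substitution model on the 61 sense codons: the instantaneous rate from
codon $i$ to $j$ is 0 unless they differ at one position, and otherwise
$\pi_j$, $\kappa \pi_j$, $\omega \pi_j$ or $\omega \kappa \pi_j$ for
synonymous transversions/transitions and nonsynonymous
transversions/transitions respectively. Branch-site model A adds four site
classes — 0: $\omega_0 \le 1$ everywhere; 1: neutral everywhere; 2a/2b:
$\omega_0$/neutral on background branches but $\omega_2 \ge 1$ on the
single tagged foreground branch — with proportions
$(p_0, p_1, p_{2a}, p_{2b})$, where
$p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0+p_1)$.

All class matrices are scaled jointly by the class-proportion-weighted mean
*background* rate at stationarity, so one unit of branch length is one
expected substitution per codon on background branches; the simulator and
the likelihood share this convention, which is what makes simulation
parameters recoverable by the fit. Transition probabilities come from the
symmetrized eigendecomposition of the reversible generator
($P(t) = D^{-1} V e^{\Lambda t} V^{\top} D$ with $D = \mathrm{diag}\sqrt\pi$),
computed once per (branch, $\omega$) pair per likelihood evaluation; rows of
every cached $P(t)$ sum to 1 within $10^{-10}$ (a tested contract). The
per-site likelihood is the class-proportion mixture of Felsenstein-pruning
likelihoods (site classes do not switch within a site along the tree);
gapped or ambiguous codons enter as missing data with unit partial
likelihood; site patterns are compressed before evaluation. The pruning
kernel is implemented in C++ (RcppArmadillo), as is conventional for
likelihood-heavy phylogenetics packages.

Codon frequencies default to F1x4 estimated from the alignment being
tested, with `equal` and `F3x4` variants — reported analyses rarely state
the frequency model, and F1x4 is the least-parameterized choice that still
respects composition.

### Maximum likelihood and the LRT

The null ($\omega_2 \equiv 1$) and alternative ($\omega_2 \ge 1$ free)
models are maximized over $\kappa$, $\omega_0$, the proportions and
$\omega_2$ on transformed scales (logs; a softmax-type transform for the
proportions) with a bounded quasi-Newton routine and seeded random
restarts; the alternative is warm-started from the null optimum with
$\omega_2$ just above 1, which both accelerates convergence and guarantees
the nesting inequality numerically. Boundary optima ($\omega_2 \to 1$,
$p_{2} \to 0$) are common under null data, so the transformed bounds
confine the search to the numerically distinguishable region
($\omega_2 \in [1.0005, 100]$, proportion ratios within $e^{16}$).

Branch lengths are re-optimized under each hypothesis as a global scale
factor of the supplied gene-tree lengths plus a free foreground branch
length (default `branch_mode = "scale"`). This keeps the null and
alternative strictly nested with identical branch parameterizations — so
the LRT remains valid — at a fraction of the cost of freeing every branch;
`"full"` (every branch free) and `"fixed"` modes are available when the
extra degrees of freedom are wanted. The LRT statistic
$2(\ell_1 - \ell_0)$ is clamped at 0 and referred to $\chi^2_1$ by default,
the conservative convention for branch-site tests; the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture reference is available by
flag.

The scan accepts one masked alignment per aligner variant per gene (gene
trees, not a species tree, carry the foreground tag — per-gene trees absorb
gene-tree/species-tree discordance), applies Benjamini–Hochberg FDR within
each variant at $q < 0.05$, and reports the intersection of the significant
sets, so an alignment-method artifact in either aligner removes a gene from
the final list.

### Alignment masking

Before testing, codon columns whose gap fraction exceeds the threshold
(default 0: any gap) are removed, and surviving runs shorter than 5 codons
are removed with them — short islands between gap-ridden regions are
exactly the segments alignment-trimming tools distrust. Output length
always stays a multiple of 3, and a fully masked alignment is an error
rather than an empty success.

## Synthetic data: what it emulates and what it does not

The generators provide every pipeline input with known ground truth.

**Expression.** Six tissues, one deeply sequenced pooled library each, and
three gene classes: housekeeping genes (log-normal baseline, per-tissue
log-jitter 0.05), tissue-specific genes (log-normal on-target expression;
off-target tissues drop to zero with probability `dropout`, otherwise a
0.2-TPM leak, deliberately well below the presence threshold), and
intermediate genes occupying 2–4 tissues. Counts are negative-binomial
around TPM- and length-proportional means with dispersion 0.005
(`dispersion = 0` gives the exact noise-free limit). The low dispersion
models technical-scale variation of single pooled libraries, not biological
replicates: it is chosen so that a truly uniform gene's post-quantification
$\tau$ stays in the broad regime, which is the regime housekeeping genes
occupy in real multi-tissue data. With replicate-level biological
dispersion (an order of magnitude larger), the noise floor alone pushes
uniform genes' $\tau$ near the broad/moderate boundary — a caveat to keep
in mind when applying the 0.3 cut-off to noisy designs. Because TPM is
compositional, the absolute TPM scale of a 1,000-gene simulation is
inflated relative to a 15,000-gene transcriptome; class recovery depends
only on profile shape, not that scale.

The class-recovery experiment (1,000 genes, dropout 0) checks that at least
95% of housekeeping genes classify broad and at least 95% of
tissue-specific genes classify high after quantification. Passing it shows
the index, floor and cut-offs interlock correctly on data matching the
generator's assumptions; it does not validate the cut-offs for tissues with
correlated composition shifts or for lowly expressed genes near the floor.

**Codon alignments.** Site classes are drawn per site; the root codon comes
from $\pi$; each branch evolves by $P(t) = e^{Qt}$ with the
class-and-role-appropriate $\omega$. Stop codons cannot be emitted (the
state space excludes them). Alignments are generated gap-free — gaps enter
only through masking tests — and indels are out of scope. The default
fixture tree is a symmetric 9-leaf topology (balanced 8-leaf core plus
outgroup; terminal branches 0.1, internal 0.05, outgroup 0.2) with a longer
(0.3) tagged focal terminal branch, sized like the passerine-scale
divergences the method is used on; a data-derived species tree is
deliberately not reproduced. Default simulation parameters are
$\kappa = 2$, $\omega_0 = 0.2$, $p_0 = 0.7$, $p_1 = 0.15$, 300 codons, and
$\omega_2 = 4$ for positive-selection alignments.

**BLAST hits.** A two-component mixture of confident and spurious hits with
Beta-distributed identity/coverage; each row's truth records whether it
passes the reference filter, so filter implementations are checked against
generator bookkeeping rather than re-derived expectations.

All generators are bit-reproducible under their mandatory seeds.

## Calibration experiments and problem sizes

Two simulation experiments back the selection test:

* **Type-I error.** Genes simulated under the null ($\omega_2 = 1$,
  300 codons, the 9-taxon fixture tree), tested at $\alpha = 0.05$ against
  $\chi^2_1$. The empirical rejection rate must not exceed 0.05 beyond its
  binomial 95% bound at the replicate count used; with the conservative
  reference it typically lands well below 0.05.
* **Power.** The same conditions with $\omega_2 = 4$; the rejection rate
  must exceed the null rate by at least 0.3.

The test suite runs 25 null and 25 alternative replicates and the
acceptance script 20 of each, with single-start fits warm-started as
described above; these are scaled-down replicate counts chosen as a
practical single-CPU problem size, and the binomial bounds are computed at
the actual count. The exhaustive-enumeration check of the pruning
likelihood runs 20 random parameter draws on 3- and 4-taxon trees at up to
10 codons, where summing over all internal-node codon assignments
($61^2$–$61^3$ states) is feasible; agreement is required to $10^{-8}$.

## Numerical choices and degenerate inputs

* Optimizer: `nlminb` (PORT), relative tolerance $10^{-8}$, at most 200
  iterations / 400 objective evaluations per fit; non-convergence is
  flagged on the result, never silently dropped.
* Transition matrices: eigendecomposition of the symmetrized generator;
  tiny negative entries from round-off are clamped at 0 (and rows
  renormalized in the simulator).
* Ties: best-hit ties break by bit score then subject id; maximal-tissue
  ties take the first tissue in column order and are flagged; unique-gene
  ranking ties break by gene id; isoform clustering is deterministic in
  input row order.
* Degenerate inputs that error loudly: empty FASTA, duplicate ids,
  negative expression values, all-zero count columns, trees with two
  foreground tags or missing branch lengths, alignments with internal stop
  codons, fully masked alignments, constant vectors in rank correlation,
  groups too small for ANOVA.
* The bootstrap p-value is floored at $2/B$ (nothing is ever reported as
  exactly zero) and capped at 1; percentile intervals use type-7 quantiles.

## Steroidogenic panel

The panel orders the pathway as synthesis (StAR, P450scc, CYP17, 3bHSD1)
→ conversion (SRD5A1, SRD5A2, AROM) → receptor binding (AR, ESR1, ESR2,
GPER1), with the 17bHSD isoforms kept separate because their substrate
specificity is uncertain in birds. Symbol matching is case-insensitive with
a user-extensible synonym map (AROM = CYP19A1, P450scc = CYP11A1, ...),
since annotation sources disagree on names; genes missing from the
expression matrix are flagged, never imputed. The stagewise trend is the
Spearman correlation of stage index against per-gene $\tau$. Isoform
clustering uses complete-linkage hierarchical clustering on Euclidean
distances of $\log_2(\mathrm{TPM}+1)$ profiles cut at $k = 2$; the log
transform keeps a single dominant tissue from swamping the distance, and
complete linkage plus deterministic tie handling makes the two clusters
reproducible (raw-TPM and other linkages are available). Whether a
partitional method on raw TPM would group isoforms identically is untested.

## Known limitations

* The branch-site machinery tests a single tagged foreground branch and
  does not do Bayes-empirical-Bayes site identification.
* The redundancy collapse's k-mer identity estimate can over-merge
  repetitive sequences where containment overestimates identity; the exact
  banded-alignment verification used by cd-hit proper is not implemented.
* GO terms are flat labels; annotations must be pre-propagated if ontology
  ancestors should count.
* Procedures that upstream pipelines perform before this package's inputs
  exist — read trimming, assembly, BLAST searches, codon alignment
  construction, tree inference, intron removal — are out of scope; their
  outputs are this package's inputs.
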