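---
title: "Causal multi-omics integration: model, optimization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal multi-omics integration: model, optimization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalomics)
```

# The problem

Transcriptomics, phosphoproteomics and metabolomics each see a different
layer of cellular regulation. `causalomics` connects them mechanistically:
it estimates which regulators (transcription factors, kinases,
phosphatases) changed activity, which metabolites changed abundance, and
then searches a multi-layer causal prior-knowledge network (PKN) for the
smallest sign-consistent, loop-free subnetworks that causally link the
deregulated regulators to the deregulated metabolites. The output is not a
single network but a pool of equally optimal networks, summarized by
per-edge frequencies — a measure of how necessary each mechanistic
hypothesis is.

# The prior-knowledge network

The meta PKN is a signed directed graph over four node kinds: proteins,
metabolites (namespaced `metab__<id>` so the two identifier universes can
never collide), reaction-specific enzyme instances, and enzyme complexes.
Three interaction layers feed it:

* **Signaling / transcription**: signed directed protein–protein and
  TF–target interactions. Only rows flagged as stimulation or inhibition
  are used; a row carrying both flags contributes one edge of each sign.
  TF–target edges carry the `transcriptional` provenance tag, which the
  contextualization step treats specially.
* **Allosteric regulation**: metabolite–protein links kept above a
  combined confidence score (default 900 on the 0–1000 scale used by
  metabolite–protein databases), with activation mapping to +1 and
  inhibition to −1.
* **Metabolic reactions**: a reaction table with gene–protein–reaction
  (GPR) boolean rules. Each rule is expanded to minimal disjunctive
  normal form: every disjunct (an isozyme or an AND-complex) becomes one
  catalytic node named `<genes>__<reaction>`, with `reactant → enzyme`
  and `enzyme → product` activation edges. Naming catalytic nodes per
  reaction is essential: a promiscuous enzyme must not create causal
  shortcuts between the substrates of one reaction and the products of
  another, and we verify this by exhaustive path search in the tests.
  Exchange reactions additionally carry the exchanged metabolite in the
  node name so transport between compartments is never read as chemical
  transformation. Coenzymes are removed before conversion, and
  metabolites with more than `degree_threshold` connections (default 338,
  chosen so the most connected central-carbon metabolite survives) are
  removed afterwards — both guard against biologically meaningless
  shortcuts through ubiquitous species.

The DNF expansion applies absorption, so the catalytic nodes equal the
minimal models of the monotone rule; the test suite checks this against a
brute-force truth-table oracle for random rules.

# Footprint activities

A regulator's activity is estimated from the measured response of its
targets (its footprint), never from its own abundance. Given differential
statistics \(t_f\) for all measured features, we convert ranks to normal
scores \(z_f = \Phi^{-1}((\mathrm{rank}(t_f) - 0.5)/n)\) (average ranks
for ties) and score a regulon with targets \(i\), modes
\(m_i \in \{-1,+1\}\) and weights \(w_i\) as

\[
\mathrm{NES} = \frac{\sum_i w_i m_i z_i}{\sigma_z\sqrt{\sum_i (w_i m_i)^2 -
  \frac{(\sum_i w_i m_i)^2 - \sum_i (w_i m_i)^2}{n-1}}},
\]

where \(\sigma_z\) is the population standard deviation of the \(z\)-grid.
The denominator is the exact standard deviation of the numerator under a
random permutation of the statistics (sampling target scores without
replacement), so the NES is the z-score of the permutation null in closed
form. The tests confirm agreement with an empirical 100,000-permutation
null to within 0.05 in practice (0.15 required), and that 1,000 null
regulons give mean ≈ 0, sd ≈ 1. The rank universe is always all measured
features. Regulators need a minimum number of measured targets (default
25 for TF regulons and 5 for kinase/phosphatase regulons, following the
reference protocol; both overridable). This is a one-statistic analytic
counterpart of regulon-enrichment methods; multi-tail refinements and
pleiotropy correction are deliberately out of scope.

Per-sample activities scale each feature across samples
(\((x-\bar x)/s\), zero-variance rows dropped, at least 3 samples) and
apply the same score column-wise, yielding activities relative to the
across-sample distribution.

# Input selection

Regulators with \(|\mathrm{NES}| > 1.7\) (strict) are deregulated and
enter the optimization with their sign; metabolites with uncorrected
\(p < 0.05\) (strict) enter with the sign of their statistic. Both
cutoffs are configuration. Measurement weights default to 1 for
metabolites and \(|\mathrm{NES}|\) for regulator measurements in the
backward run — the relative weighting of mismatches is genuinely open, so
it is exposed as configuration rather than hidden.

# Contextualization

Three steps shrink the meta PKN to the experiment before optimization,
each only ever removing edges:

1. **Filtering**: every edge touching a gene product whose mean count
   across all provided samples is below 50 (or absent from the count
   matrix) is removed; a complex dies if any member gene fails;
   metabolite-only edges are untouched.
2. **Reduction**: keep exactly the nodes within \(k\) directed steps of
   some input (defaults: 8 forward, 7 backward) and the edges among
   them. This drops modules that cannot be causally influenced and bounds
   the plausible path length.
3. **Correction**: a transcriptional edge \((\mathrm{TF}, s, g)\) is
   removed iff the TF has a known activity sign \(a\), the transcript
   \(g\) changed significantly (uncorrected \(p < 0.05\); the magnitude
   is not thresholded), and \(\mathrm{sign}(\log FC) \ne a \cdot s\).
   After a first correction using estimated activities, a pre-run of the
   forward optimization refines it: TF states that are identical across
   the whole pre-run solution pool (the consensus) are taken as known
   activities and the correction is applied again. An infeasible or
   empty pre-run leaves the PKN unchanged.

An edge with mixed provenances is treated as transcriptional if any of
its provenances is.

# The optimization core

For each node \(u\) the ILP has binaries \(u^+, u^-\)
(\(u^+ + u^- \le 1\)) encoding up/down state; for each edge
\(e = (u, s, v)\) an activation carrier \(e^+\) and inhibition carrier
\(e^-\) gated by the source state (\(e^+ \le u^+\) if \(s=+1\), etc.);
state support \(v^+ \le \sum_{\text{in}} e^+\),
\(v^- \le \sum_{\text{in}} e^-\) for non-input nodes; inputs fixed; and
per-node order variables \(d_u \in [0, N]\) with big-M constraints
\(d_v \ge d_u + 1 - N(1 - e^+ - e^-)\) that forbid cycles. The objective
is

\[
\sum_{\text{measurements } v} w_v\,\bigl|t_v - (v^+ - v^-)\bigr| \;+\;
\beta \sum_u (u^+ + u^-),
\]

linear because \(t_v = \pm 1\). Fixed inputs are stated nodes and pay
\(\beta\) like any other. `build_ilp()` materializes this model; the
tests enumerate its binaries on small instances and recover the solver
optimum exactly.

**Solver.** The production backend is an exact branch-and-bound over
*closed sets* of signed nodes: sets grown from the inputs in which every
non-input member is supported by an in-edge from a member. Branching
includes or permanently forbids the first new signed node on a shortest
signed path toward the heaviest unsatisfied measurement; the lower bound
adds, per unsatisfied measurement, \(\min(w, \beta)\) if reachable
(\(\beta d\) when only one remains, \(d\) the path node count) and \(w\)
if not. The bound is admissible and the include/forbid scheme partitions
the space, so for \(\beta > 0\) the search provably enumerates every
optimal state assignment; an explicit time limit returns the best pool
found with status `time_limit`.

**Solution identity.** Because edges are free in the objective,
variable-level optima are degenerate. A solution is therefore defined as
a node-state assignment plus a *minimal supporting edge set*: each
non-input stated node keeps exactly one incoming active edge, no active
edge enters an input, and every stated node is reachable from an input —
which makes the active subgraph an acyclic forest rooted at the inputs.
Two parallel length-1 explanations of one measurement thus give a pool
of two solutions with both edges at weight 50, not one solution with
both edges active. Edge weights are pool frequencies scaled to 0–100.

`brute_force_solve()` enumerates all edge subsets (capped at 20 edges),
applies exactly this definition, and is the in-repo ground truth: on 50
random instances per run the branch-and-bound reproduces its objective
*and* its full solution set identically. Solutions are ordered by a
canonical key, so pools are deterministic; the pool is capped at
`pool_cap` (default 100) and the cap is flagged.

Measurements absent from the PKN are recorded on the instance and leave
the objective; measurements present but unreachable stay in the
objective at full mismatch and are reported. Input signs are hard
constraints. An instance whose inputs are all absent is infeasible.

# Pipeline, merge and ORA

The forward run goes from deregulated regulators to deregulated
metabolites; the backward run swaps the roles (metabolites become fixed
inputs) to capture allosteric feedback, with \(k = 7\). The merged
network is the union of the two summary networks; each edge carries both
runs' weights plus a display-only combined weight (their maximum), and
nodes assigned opposite signs by the two runs are deliberately *not*
resolved — they are kept with both attributes and listed in a
sign-conflict report, since such incoherences are findings, not errors.

Over-representation of the solution genes uses the hypergeometric upper
tail with Benjamini–Hochberg adjustment across sets. Enzyme-instance ids
map back to gene symbols (reaction suffix stripped, complexes split);
the default universe is the gene complement of the contextualized PKN,
since that is the population from which solution genes can be drawn.

# Evaluation harnesses

*Co-regulation TPR*: nodes sharing an active parent should have
correlated per-sample activities. For thresholds \(t = 0, 0.01, \dots,
1\), the TPR is the fraction of predicted pairs with \(|r| \ge t\)
(Pearson by default, Spearman by flag), always reported against a
random-pair baseline (mean and 2.5/97.5 percentiles over 1,000 draws by
default). *Robustness*: a fraction of PKN edges is selected uniformly
and their targets permuted among themselves (signs stay with their
rows; full rewiring available by flag), the pipeline is re-run, and
per-edge absolute weight differences are summarized (median, fraction
zero, fraction flipped 0↔100) over the edge union with absent edges at
weight 0.

# The synthetic-data generator

All inputs are generated with planted ground truth, at three preset
scales (tiny/small/medium). `generate_planted_study()` plants disjoint
causal chains TF → gene → enzyme gene → enzyme instance → metabolite
with random signs, plus: decoy nodes receiving edges (never sending any
into planted nodes), decoy transcriptional targets half of which are
measurably incoherent (exercising the correction step), unexpressed
genes below the count filter, and an allosteric feedback edge from each
planted metabolite to the next chain's TF, signed coherently, so the
backward run has a planted truth as well. Because no distractor edge
enters a planted node, every planted non-input node has a unique
supporting in-edge, which makes the planted network the provably unique
minimal zero-mismatch solution — recovery tests therefore do not depend
on the solver to define their own truth. Planted activities are ±3 for
input TFs and 0 for null regulators; with noise-free target statistics
the selection step recovers exactly the planted inputs at the default
1.7 cutoff. `plant_causal_instance()` plants on an *arbitrary* PKN; it
guarantees a zero-mismatch solution and stores the minimal explanation
(computed exactly), since on arbitrary graphs a shorter alternative
path can legitimately undercut the planted tree.

The co-regulation generator gives siblings a shared latent factor with
loading \(\sqrt{r}\) (pairwise correlation \(r = 0.8\) by default);
parents are measured with extra noise (loading \(r\)) so sibling pairs
are the strongest signal in the matrix, and extra independent
regulators populate the baseline.

What the generator does *not* emulate: measurement error structure of
real MS/RNA-seq pipelines, correlated regulons, compartment biology,
batch effects, or realistic network degree distributions. Passing the
planted-recovery suite therefore shows the machinery is correct, not
that real-data solutions are biologically right.

# Numerical choices and problem sizes

* Ties in ranks: average; the z-grid uses \((r - 0.5)/n\).
* Objective comparisons use an absolute tolerance of \(10^{-9}\);
  equally optimal solutions are all retained.
* \(\beta = 0.2\) by default; run time limits default to 7,200 s
  (forward) and 21,800 s (backward) but tests and presets use 60–120 s.
* Determinism: every generator takes a mandatory seed; solver pools are
  canonically ordered; with the exhaustive backend the tiny-preset
  pipeline is byte-identical across runs.
* Test problem sizes are deliberately desk-scale: random instances of
  ≤ 12 edges for oracle equivalence (the exhaustive oracle enumerates
  \(2^{|E|}\) subsets), ≤ 25 edges for validity sweeps, planted studies
  of ~30 nodes, 100,000 permutations for the NES oracle, 100-seed TPR
  sweeps. These sizes make every property checkable exactly while the
  algorithms themselves have no such limits (the branch-and-bound scales
  with pruning, not enumeration).

# Known limitations

* The branch-and-bound is exact but exponential in the worst case;
  very large contextualized PKNs need the time limit, which degrades
  the pool to "best found".
* Reversible reactions are not modeled; encode them as two reactions.
* The pool cap truncates deterministic but arbitrary tails of large
  optimal families; edge weights are then frequencies over the capped
  pool.
* Compartment handling for allosteric matching is the caller's choice
  of identifiers; the package treats ids as opaque.
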