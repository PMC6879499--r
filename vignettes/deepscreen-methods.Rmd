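---
title: "Methods: three-axis deep screening of compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-axis deep screening of compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening model

`deepscreen` treats a compound panel as a set of items to be clustered
three times, on feature matrices of increasing biological depth, and
reads the scientific signal out of the *disagreements* between the three
dendrograms.

**Structure axis.** The default similarity is the overlap coefficient
of the maximum common connected substructure (MCS): for molecules with
heavy-atom counts $c_1, c_2$ sharing an MCS of $n$ atoms,
$$\mathrm{overlap} = \frac{n}{\min(c_1, c_2)}.$$
Dividing by the *smaller* molecule makes the coefficient 1 whenever one
molecule is contained in the other. That containment bias is the point:
a small active scaffold buried inside a large natural product scores 1,
where Tanimoto-style indices would be diluted by the size difference.
The cost is that a single shared atom saturates the score when one
molecule is a single heavy atom; users screening panels with very small
fragments should read the structure dendrogram with that in mind. A
hashed circular (Morgan-style) fingerprint with Tanimoto similarity is
provided as the alternative method; it trades the containment
sensitivity for robustness to partial rearrangements.

**Docking axis.** A compound × protein matrix of docking scores on the
0–10 pKd/pKi scale (the negative log10 of a predicted binding constant)
is consumed as-is from an external docking service; the package
validates the range and never re-scores.

**Network axis.** Docking scores grow with compound size through
additive enthalpic terms, so raw profiles of differently sized compounds
are not comparable. Scores are therefore replaced per compound by
descending ranks (1 = the compound's strongest predicted target; ties
receive the average of the positions they span). Ranking is the entire
normalization — any strictly increasing transform of a compound's scores
leaves its profile unchanged. Each rank is then multiplied by the target
protein's node degree in a protein–protein interaction network,
$$\mathrm{effect}(c, p) = \mathrm{rank}(c, p)\times \deg(p),$$
so proteins that are hubs of the interaction network dominate the
profile. Degree is deliberately the only topology weight entering the
score; betweenness centrality is computed and reported for inspection
but never multiplied in, because mixing two centralities would make the
weight uninterpretable.

Each axis is clustered on the correlation-based dissimilarity
$d(i,j) = 1 - \mathrm{cor}(x_i, x_j)$ (range $[0,2]$) with average
linkage by default, and every internal cluster of the observed tree gets
multiscale-bootstrap support.

## Multiscale bootstrap and AU p-values

For relative scales $r \in \{0.5, 0.6, \dots, 1.4\}$ the feature columns
are resampled with replacement to size $\mathrm{round}(r \cdot m)$ ($m$
= number of features), items are re-clustered, and
$\mathrm{BP}_r$ = fraction of $B$ replicates in which the cluster's
exact leaf set reappears. The probit-transformed scaling curve is fitted
by weighted least squares,
$$\Phi^{-1}(1-\mathrm{BP}_r) = v\sqrt{r} + c/\sqrt{r},$$
with weights $B\,\phi(z_r)^2 / (\mathrm{BP}_r(1-\mathrm{BP}_r))$ from
the binomial variance of each $\mathrm{BP}_r$. In terms of the
theoretical scale $\sigma = 1/\sqrt{r}$, $v$ (the coefficient of
$1/\sigma$) estimates the signed distance of the cluster boundary and
$c$ (the coefficient of $\sigma$) its curvature; then
$$\mathrm{AU} = 1 - \Phi(v - c), \qquad
  \mathrm{BP}_{\mathrm{smooth}} = 1 - \Phi(v + c).$$
Two sign/labelling conventions for this fit circulate; we use the
parametrization of the pvclust implementation, under which a cluster
whose BP grows toward 1 as replicates get larger receives a *high* AU.
The opposite assignment (swapping which coefficient multiplies
$\sqrt{r}$) silently reports $1-\mathrm{AU}$ — an easy mistake to make,
which the test suite pins down with planted-block data.

Numerical choices:

* BP values are clipped to $[1/(2B), 1 - 1/(2B)]$ before the probit
  transform; clipped scales get near-zero weight automatically through
  the $\phi(z)^2$ factor.
* A cluster whose BP sits on the same $\{0, 1\}$ boundary at every scale
  gets AU fixed to that boundary with a `degenerate` flag; no fit is
  attempted.
* With a single scale ($r = 1$) the model is unidentifiable; we set
  $v = z_1, c = 0$, which makes both AU and the smoothed BP equal the
  raw bootstrap probability — the classical bootstrap as the single-scale
  limit.
* The root cluster (all leaves) is assigned support 1 by convention.
* Replicates whose resample leaves an item with zero feature variance
  contribute maximal dissimilarity (1) for the affected pairs rather
  than aborting the replicate.
* One root seed drives everything; per-scale streams are derived
  deterministically from it, so results are bit-reproducible and
  independent of evaluation order.

Items are always the compounds and features are the columns of the
axis matrix (similarity profiles, docking scores, network effects);
resampling is over feature columns. For the structure axis this means
the bootstrap perturbs the similarity *profile*, not the underlying MCS
computation — re-deriving MCS matrices per replicate would be both
prohibitively expensive and conceptually different (there is no
replicate-able "feature" in a single MCS number). This orientation is
recorded in the run report metadata.

## The MCS search

The MCS engine is an exact branch-and-bound over connected common
subgraph mappings: mappings grow atom-by-atom along bonds present in
both molecules (equal order; aromatic bonds count as order 1.5), each
search-tree node either maps the lowest-index frontier atom to a
compatible partner or excludes it, and a reachability bound prunes
branches that cannot beat the incumbent. Matching rules:

* Atom identity is the element. Aromaticity does not enter atom
  identity (a flag can enable that), but it constrains the mapping
  through bond orders, so an aromatic ring never maps onto an aliphatic
  one under strict bond-order matching. Element-only matching guarantees
  $n \ge 1$ whenever the element sets intersect; molecules sharing no
  element at all get overlap 0 with a logged message.
* Hydrogens are stripped on input; $n$, $c_1$, $c_2$ count heavy atoms
  only (the standard cheminformatics convention).
* Kekulized input (SDF and the OpenBabel SMILES round-trip) is
  re-aromatized before comparison: rings of length 5–7 over C/N/O/S
  whose in-ring π-electron count satisfies the 4n+2 rule are marked
  aromatic. The rule is ring-local, so fused aromatic systems
  (naphthalenes) may stay kekulized — a documented limitation; the
  screening panels this package targets are dominated by isolated rings.
* Mismatch budgets (`atomMismatch`, `bondMismatch`) optionally tolerate
  a counted number of element or bond-order mismatches, in the spirit of
  flexible-MCS algorithms that recover local similarity between
  molecules of very different size. Published flexible-MCS
  implementations each define their own mismatch search; our budgets are
  simple global counts, defaulting to 0 (strict matching).
* Each pair has a wall-clock budget (default 10 s). On expiry the best
  size found so far is returned with a `timedOut` flag and the
  similarity-matrix builder emits a warning — never silently.

The test suite checks the search against an independent exhaustive
enumerator (connected subsets × brute-force injective embeddings) on
every pair of a 10-molecule panel, so the branch-and-bound's pruning is
verified exactly where exhaustion is feasible.

## Input handling

* Structures: SDF (V2000), MOL, SMILES lines (`SMILES[ \t]id`, `#`
  comments); parsing is delegated to ChemmineR/OpenBabel, with a direct
  V2000 molblock fallback for bond-less molecules, which the SDF
  container class rejects as invalid. Unparseable entries are skipped
  with a warning (strict mode: error); zero parseable molecules is an
  error.
* Docking CSV: header row of protein ids, first column of compound ids;
  empty cells/`NA`/`NaN` are missing; scores outside [0, 10] abort with
  the offending cell named. Orientation can be forced (`transpose`) or
  auto-detected against the structure file's compound ids.
* PPI: STRING exports (`protein1 protein2 combined_score`; the 0–1000
  integer scores are divided by 1000 so the default `minConfidence =
  0.7` equals STRING's "high confidence" 700), SIF, or plain 2-column
  TSV. Self-loops and duplicate edges are removed with logged counts;
  isolated nodes can be injected from a node list file and carry
  degree 0.
* Ranks are computed over the non-missing entries of each compound row
  (at least 2 required; an all-missing row aborts naming the compound).
  Proteins absent from the degree table follow a policy: `zero`
  (default — no interaction evidence means no network effect), `drop`,
  or `error`. Columns with missing values are excluded from the
  clustering feature set with a logged count.
* Compound ids are joined across files by exact string match; an
  optional two-column id map reconciles aliases. Mismatches abort with
  the symmetric difference listed.

## The synthetic fixture generator

`generateFixtures()` emulates the shape of a published ageing-compound
screen — 12 compounds, 45 docked proteins — with known ground truth:

* **Compounds** come from four scaffold families (alkanols, phenols,
  cycloalkanes, pyrans) in contiguous blocks; the family is the
  structure-axis truth. Members are small (≤ 12 heavy atoms) so MCS
  matrices are exact and fast.
* **PPI graph**: an undirected preferential-attachment graph (2 edges
  per new node), giving the heavy-tailed degree distribution real PPI
  networks show. Kept edges get confidences in [0.70, 0.999]; ~30%
  decoy edges below 0.7 exercise the confidence filter.
* **Docking scores**: two planted groups with mirrored profiles over
  the 5 highest-degree (hub) proteins — group X high (8.5–9.5 before
  noise) on hubs and low (2.0–3.0) elsewhere, group Y the mirror —
  plus Gaussian noise (sd 0.5) and clipping to [0, 10]. The group is
  the docking/network-axis truth.
* **Planted discordance**: one compound swaps out of its block's group
  and one swaps in, so exactly one structurally similar pair splits
  across network groups and one structurally dissimilar pair shares a
  profile — the screen's headline behavior as a testable property.

The noise level (sd 0.5 on a 0–10 scale) keeps within-group profile
correlations near 1 while leaving visible score scatter, a deliberately
easy regime: the end-to-end tests assert *recovery* of the planted
truth (adjusted Rand ≥ 0.8 at the true cut in ≥ 8/10 seeds), which is a
statement about pipeline correctness, not about power on hard data. What
the generator does **not** emulate: correlated docking errors across
related proteins, missing cells, batch effects between docking runs,
id-mapping noise, or PPI false positives — passing tests therefore
demonstrate mechanical and statistical correctness of the pipeline, not
performance on real screens.

Problem sizes used by the tests and the reproduction script (B = 100
bootstrap replicates per scale, 10–12 compounds, 45 proteins, 10 seeds
end-to-end; B = 1000 for the single-scale classical-bootstrap check)
were chosen so the full suite re-runs in a couple of minutes while
keeping every binomial comparison inside its stated tolerance; B = 1000
remains the analysis default mirroring pvclust.

## Other design decisions

* **Linkage default = average**, pvclust's default; complete, single and
  Ward (`ward.D2` on unsquared dissimilarities) are available. Merge
  ties are resolved by the deterministic internal scan order of
  `stats::hclust`, so trees are reproducible across runs and platforms;
  we deliberately delegate rather than re-implement agglomeration for
  the sake of a custom tie rule.
* **Newick export** uses the ultrametric convention (leaf depth = half
  the merge height) with AU values as internal node labels; trees
  round-trip through standard parsers.
* **Tree comparison**: adjusted Rand (via mclust) and Fowlkes–Mallows on
  flat cuts, plus Pearson correlation of cophenetic distance vectors.
  Cutting both trees into all-singletons leaves no co-clustered pairs;
  agreement on that empty set is reported as 1.
* **Determinism contract**: rerunning the pipeline with the same config
  and seed reproduces every CSV and Newick output byte-for-byte (the
  JSON report differs only in its timestamp).

## Known limitations

* The MCS search is exponential in the worst case; for large natural
  products the timeout turns exact results into flagged lower bounds.
  Pairs of ~65-heavy-atom macrolides can exhaust a 10 s budget.
* Aromaticity perception is ring-local (no fused-system Hückel
  accounting) and charge is ignored in atom matching.
* The circular fingerprint hashes our own atom invariants; bit
  positions are internally stable but not interchangeable with other
  ECFP software.
* AU p-values are asymptotic in both B and the number of scales; with
  B = 100 their standard errors (reported per cluster) are a
  substantial fraction of the distance to common thresholds, so cluster
  calls at B = 100 should be treated as screening-grade.
* No identifier mapping between gene symbols and database-specific
  protein ids is attempted; inputs must use consistent symbols.
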