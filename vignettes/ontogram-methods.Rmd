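---
title: "Reconstructing growth series by parsimony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing growth series by parsimony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontogram)
```

## The ontogram model

An ontogram treats ontogeny the way a cladogram treats phylogeny. Each
specimen of a single species is scored for growth characters — suture
closures, bone surface textures, ornamentation development — with the
nascent (most juvenile) condition coded 0 and progressively or
alternatively mature conditions coded 1 and higher. If growth characters
accumulate roughly in sequence across the population, the most
parsimonious arrangement of specimens, polarized by an all-zero
hypothetical embryo at the root, is a growth series: specimens branch off
in order of cumulative character acquisition, and character changes shared
by all more mature specimens (*synontomorphies*) mark the stages of
development. The method makes two biological assumptions worth keeping in
mind: that character acquisition is (mostly) unidirectional, and that
individual variability and missing data are noise around a common
sequence, not structure.

The pipeline mirrors how such analyses are run in practice:

1. **Matrix construction** (`read_nexus`, `add_hypothetical_embryo`,
   `deduplicate_specimens`, `to_additive_binary`, `subset_specimens`).
2. **Search** for most parsimonious trees (`heuristic_search`,
   `branch_and_bound`, `exhaustive_search`), with all characters equally
   weighted and unordered.
3. **Summary** over the optimal set (`strict_consensus`,
   `semistrict_consensus`, `adams_consensus`, `majority_rule`).
4. **Character optimization** under ACCTRAN and DELTRAN
   (`optimize_states`, `synontomorphies`).
5. **Support** (`bremer_decay`, `bootstrap_support`) and **fit**
   (`consistency_index`, `cumulative_ci`).
6. **Maturity ranking** and its correlation with an external size proxy
   (`ontogenetic_ranks`, `spearman_rank`).

`run_ontogram()` orchestrates all stages from one configuration object and
writes trees, tables and a JSON report.

## Coding conventions

**Missing and inapplicable data.** Both `?` and `-` are read as missing
and scored as full ambiguity (any state). A single ambiguity semantics
keeps tree lengths well defined; nothing in the scoring distinguishes
"not preserved" from "not applicable".

**Additive-binary recoding.** A `k+1`-state ordered character becomes `k`
binary columns, state `s` mapping to `s` leading 1s. This forces the
ordered interpretation (partial fusion precedes full fusion) that
unordered multistate coding leaves free. Characters whose non-nascent
states are *alternative* adult morphologies (e.g. inflated versus
resorbed supraorbital horns) use branching coding instead: one column per
alternative, scored 1 only in that state, so the alternatives cancel on
internal branches. Missing stays missing in every expansion column, and
expansion columns remember their source character — the bootstrap uses
this to refuse resampling linked columns independently.

**Deduplication.** Rows identical across all characters (missing symbols
compared literally, never wildcarded) collapse to one representative, and
rows whose every *coded* cell is 0 are removed as redundant with the
embryo. We read "all-zero coding" as all-zero-where-codeable: an isolated
element scored 0 for everything observable carries exactly the embryo's
signal for tree building.

## Scoring and search

Tree length is the minimum number of unordered state changes: the Fitch
two-set rule on binary nodes, and Hartigan's generalized minimum-mutation
count on polytomies, so consensus trees can be scored directly as hard
polytomies. State sets are bitmasks (codes 0–9), vectorized across
characters; one ~50-tip, 80-character tree scores in well under a
millisecond, which is what makes heuristic search and bootstrapping
feasible in pure R.

Searches run on binary trees rooted on the embryo's terminal edge — a
representation score-equivalent to the unrooted tree in which forbidding
insertions on the root edge makes stepwise enumeration visit each
unrooted topology exactly once. The heuristic search uses random-addition
replicates polished by NNI or SPR hill climbing, then collects the
plateau of equally optimal trees connected by NNI moves, up to `maxtrees`
(first-found retention with a `cap_hit` flag, mirroring the saved-tree
limits of desktop parsimony programs). SPR gives better optima on rugged
data but costs roughly `n` times more per sweep; the plateau walk always
uses NNI because exhaustive SPR sweeps over thousands of stored trees buy
little and cost minutes. Branch-and-bound prunes partial trees at the
current bound and is exact; it carries an explicit node-expansion budget
and *errors* when exhausted rather than returning a silently incomplete
tree set. Exhaustive search (≤ 9 tips) enumerates topologies via
`phangorn::allTrees` and is the reference the other searches are tested
against, alongside a brute-force enumeration of ancestral assignments
that is independent of all package scoring code.

Ties everywhere resolve deterministically: stepwise insertion takes the
first best edge in a fixed ordering, and all randomness flows from a
single user seed, so every search is bit-reproducible.

**Zero-length branches and MPT counts.** Optimal trees are stored fully
resolved as found. Counts of "distinct MPTs" are convention-dependent
when branches of minimum length zero are involved, and unordered
multistate characters whose intermediate states are each held by a single
specimen are genuinely uninformative about local resolution — a
noise-free multistate staircase can therefore have several equally
parsimonious resolutions, all collapsing to the same growth sequence.
Binary staircase characters do not suffer this (every acquisition is an
informative split), which is why the package's exact-identifiability
tests use binary generators and the multistate tests assert optimality of
the true tree rather than uniqueness.

## ACCTRAN and DELTRAN

Per character, a unit-cost dynamic programme over the rooted tree yields
each node's minimal subtree cost per state; states are then fixed
root-to-tip, each node choosing among cost-minimizing states given its
parent. Where a change-now and a change-later resolution tie, ACCTRAN
takes the change (pulling transformations rootward, favouring reversal
over convergence) and DELTRAN keeps the parent's state (pushing
transformations tipward, favouring convergence). Residual ties resolve to
the lowest state code and are flagged `ambiguous`. Both flavours always
realize exactly the tree length; they move changes, never add them. The
synontomorphy table intersects the two change lists per branch: a change
is *unambiguous* only if both flavours place the same transformation on
the same branch, which is the set used to define growth stages. Exact
per-node lists for ambiguous characters depend on undocumented
tie-resolution details of legacy software, so list-level agreement with
published tables is best-effort, not an invariant.

## Support and fit

**Bremer decay** is the extra length needed before a clade leaves the
optimal set. Below `exact_max_taxa` (default 12) taxa it is computed
exactly from a branch-and-bound sweep retaining all trees within `max_k`
(default 10, reported as `">10"` beyond) steps; larger problems use a
reverse-constraint heuristic search per clade, with candidate trees
containing the clade penalized out of contention.

**Bootstrap** resamples characters with replacement (implemented as
column weights, so no matrix copies), runs a reduced-effort heuristic
search per replicate — effort is an explicit knob, defaulting to one
addition replicate with NNI — and scores each clade by the share of
replicates whose MPT strict consensus contains it. Additive-binary
matrices are refused by default because expansion columns of one
character are not independent observations; `force = TRUE` resamples
linked groups as units instead.

**Consistency index.** Ensemble CI is Σm/Σs with m the per-character
minimum (distinct observed states − 1) and s the realized steps; 1 means
no homoplasy. The default includes parsimony-uninformative characters,
matching the convention of the desktop programs whose published values
practitioners compare against; the cleaner informative-only value is
always reported alongside. Per-category cumulative CI partitions the same
m and s sums by proxy category (fusion, texture, ornamentation, other) or
skull region; the mean of per-character CIs is emitted as a flagged
alternative convention, since published "cumulative CI" tables are
ambiguous between the two.

## Ranks and the size correlation

`ontogenetic_ranks` ranks specimens by divergence depth from the root —
how many branching events precede the tip's own split. Tips diverging at
equal depth have no internal order: on consensus trees (`tie_siblings =
TRUE`) they share mid-ranks, the robust choice when many MPTs were
summarized; on a single MPT equally deep sisters are ordered by
cumulative coded maturity when the matrix is supplied, and declared tie
groups (e.g. an oversampled growth stage) always receive their common
mid-rank. `spearman_rank` then computes P = 1 − 6ΣD²/(n(n²−1)) against
mid-ranked proxy values, deliberately *without* the tie-correction term:
the published worked example this reproduces uses the uncorrected
arithmetic, and the package matches it exactly (ΣD² = 10.5, P = 0.952 on
the bundled frill-length table).

## The synthetic generator

`growth_model()` defines the generating process the analysis assumes:
latent maturity uniform on [0, 1]; per-character acquisition thresholds
(one per state transition) drawn uniformly; branching characters with a
per-specimen alternative morphology; ±1-state deviations with per-cell
probability ε (mistimed acquisition, not scoring error — a deviation at a
boundary state clamps and may be invisible); "isolated element"
specimens that retain a single skull region and are missing elsewhere;
and a size proxy linear in maturity with Gaussian noise. The defaults are
the study design the package emulates: 47 specimens × 80 characters (38
binary, 34 three-state of which 4 branching, 8 four-state — expanding to
exactly 130 additive-binary columns), regions sized 11/11/34/4/20
(nasal/supraorbital/frill/frontal/other) and categories 21/6/12/41
(fusion/texture/ornamentation/other), ε = 0.05, 20% isolated specimens,
and sizes spanning 225–695 units with noise sd 30. Maturity is drawn
uniform rather than from a survivorship curve — the simplest null, since
no population model is being tested — and the hook accepts any
alternative by editing the model object.

What passing synthetic tests do and do not show: the generator produces
exchangeable specimens with independent characters and block missingness;
real matrices have correlated characters within anatomical units,
non-uniform maturity sampling, and taphonomic missingness that is not
independent of maturity. Recovery results here validate the machinery,
not the biology.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen to exercise each claim meaningfully: exhaustive oracles at ≤ 7
tips (≤ 945 topologies), exact Bremer at ≤ 12 taxa, recovery experiments
at the full 47 × 80 design over 20 seeds with 2 addition replicates and
NNI swapping (a deliberate effort level — on near-staircase data greedy
addition already lands near the optimum and NNI polishes; SPR is
reserved for smaller or harder instances). Bootstrap examples use tens
of replicates in tests; the default `n_reps = 1000` matches standard
practice for real analyses. All tolerances in tests are exact except
sampling-error bands, which use 3-standard-error binomial bounds at the
simulated sizes.

## Known limitations

- TBR swapping is not implemented; NNI and SPR are. For matrices of this
  shape SPR plus plateau collection recovers the exhaustive optimum in
  every tested instance, but harder landscapes may need more replicates.
- The heuristic plateau walk collects NNI-connected equal-length trees
  only; an MPT set disconnected under NNI would be undercounted
  (`cap_hit` and replicate logs make the retention behaviour visible).
- Polymorphic cells (`{01}`), step matrices and continuous characters are
  out of scope.
- Reverse-constraint Bremer values are heuristic upper-bound estimates on
  large matrices; the exact route is used automatically when feasible.
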