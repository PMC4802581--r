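---
title: "Diagnosing rapid radiations with gene-tree congruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing rapid radiations with gene-tree congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(congrue)
```

## The problem

A rapid radiation compresses many speciation events into a short span of
time. On the species tree this leaves a run of short internal branches; in
the data it leaves discordance: because each locus coalesces on its own
genealogy, a branch of length $t$ coalescent units gives two lineages only
probability $1 - e^{-t}$ of coalescing before the next divergence down. When
they fail to coalesce (incomplete lineage sorting, ILS), the locus may
support a topology other than the species tree. `congrue` quantifies this
pattern from three standard inputs — per-locus gene trees, a reference
species tree, and an ultrametric chronogram — and ships a coalescent
simulator so the whole pipeline can be validated against closed-form
expectations.

## The congruence procedure

The unit of analysis is the **taxon bipartition**: the split $A\mid B$ of the
full taxon set induced by deleting one internal edge of the reference
species tree (`tree_bipartitions()`). All split work treats trees as
unrooted, because single-locus trees carry arbitrary roots.

For each (gene tree, bipartition) pair:

1. **Prune** the bipartition to the taxa present in the gene tree
   (`prune_constraint()`). Sequence-capture gene trees routinely miss taxa;
   each side of the split is intersected with the gene tree's leaf set. If
   either side retains fewer than two taxa the constraint is **trivial** —
   a monophyly constraint on at most one taxon is vacuously satisfied by
   every tree.
2. **Test** whether the restricted split is *literally present* among the
   gene tree's splits (`gene_tree_supports()`). This is the hard-constraint
   semantics of filtering trees through a monophyly constraint: an
   unresolved gene tree (polytomy) that is merely *compatible* with the
   split does not count as support. A `mode = "soft"` compatibility test is
   provided for sensitivity analysis, since the choice matters exactly when
   gene trees contain polytomies.
3. **Tally** verdicts per bipartition (`tally_congruence()`). The
   denominator is fixed at the total number of gene trees, so fractions are
   comparable across bipartitions; per-row counts of trivial verdicts let
   any other rate be recomputed. Under the default
   `trivial_policy = "count_as_support"` a trivial verdict counts toward
   the supporting fraction, replicating vacuous satisfaction of the pruned
   constraint; `"exclude"` counts strict support only. Both are exposed
   because the two conventions genuinely differ whenever dropout is heavy,
   and reports always carry all three counts.

Support conserves the denominator by construction
($n_\text{support} + n_\text{trivial} + n_\text{other} = N$ on every row),
and restriction preserves display: deleting taxa from a gene tree can turn
support into triviality but never into conflict. Both properties are
enforced in the test suite, the latter as a randomized property, the former
on every synthetic run.

## Branch durations and the radiation signature

`node_ages()` reads ages off an ultrametric chronogram (leaves at age 0,
ages increasing toward the root; ultrametricity enforced within a relative
tolerance, default $10^{-6}$ of the root age, configurable). A branch's
**duration** is its parent's age minus its own — how long that bipartition
persisted as a unit before the next divergence. `add_branch_durations()`
joins durations onto the tally by split identity. One subtlety: when the
root is a dichotomy its two child branches subtend complementary clades and
carry the *same* bipartition; they are the two halves of a single unrooted
edge, so their durations are summed for that split.

`congruence_duration_fit()` then regresses support on duration. The default
response is the raw support count; a `fraction` mode is provided for
datasets whose denominators differ. Whether terminal branches enter the
duration table is exposed as `include_tips` (default `FALSE`): terminal
branches subtend single-taxon clades, which never form testable splits, so
the default analyses internal branches only.

The regression itself (`linear_fit()`) is ordinary least squares with the
two-sided slope $t$-test on $n - 2$ degrees of freedom, and
$R^2_\text{adj} = 1 - (1 - R^2)(n-1)/(n-2)$. Degenerate inputs are defined,
not left to float: a constant response gives slope 0, $R^2 = 0$, $p = 1$; a
constant predictor is an error; p-values are clamped into $(0, 1]$ so an
exact fit never underflows to 0.

## Per-locus profiles

`classify_site()` partitions alignment columns into four exhaustive
classes. Only unambiguous nucleotides `A`, `C`, `G`, `T` count as states;
IUPAC ambiguity codes are excluded from state counts (but *not* counted as
missing), and `-`, `N`, `?` are missing. A column is parsimony-informative
iff at least two states each occur at least twice; with one state it is
constant; with none, all-missing; otherwise variable-uninformative. Under
this rule `(A, A, R, R)` is constant — an ambiguity code never creates
signal.

Percent variation is variable sites over the full alignment length by
default; an alternative denominator excluding all-missing columns is
available (`variation_denominator = "scored_columns"`), since either
convention is defensible and published tables rarely say which was used.
Percent missing counts `-`, `N` and `?` cells over all cells; `?` is
included for robustness even though capture data mostly shows gaps and `N`.

`summarize_profiles()` renders the per-class `mean (min–max)` table, and
`length_vs_informative()` fits PIC on alignment length — the standard check
that longer loci carry more signal.

## The synthetic-data generator

`sim_gene_tree()` implements the standard multispecies coalescent: within
each species-tree branch, $k$ lineages coalesce with exponential waiting
times at rate $k(k-1)/2$ per coalescent unit; survivors pass rootward, and
the root branch is infinite. Chronogram branch lengths are converted to
coalescent units by a single global `scale` factor — no effective
population size or generation time machinery is built, because the
analyses here only need control over ILS intensity, and per-branch
coalescent lengths can be set directly by building the chronogram in
coalescent units (e.g. `pectinate_chronogram()`).

The generator is validated jointly with the tally: for a four-taxon
pectinate species tree whose relevant internal branch has length $t$, the
probability that the gene tree displays the species-tree split is
$1 - \tfrac{2}{3}e^{-t}$ (independent of the other branch lengths), and the
two minor topologies are equifrequent at $\tfrac{1}{3}e^{-t}$. The
acceptance suite checks the tallied fractions at
$t \in \{0, 0.5, 1, 2\}$ over 10{,}000 loci within three binomial standard
errors.

**Dropout** (`apply_dropout()`) retains each taxon independently with
probability $p$ per locus, pruning the induced tree and discarding loci
with fewer than `min_taxa` leaves. Dropout is i.i.d. across taxon–locus
pairs by default — published capture studies report occupancy but not a
per-taxon bias model — with an optional named per-taxon probability vector
for structured missingness. The fixture defaults target the occupancy
structure of a large capture study: 585 loci in a 541:44 UCE:coding split,
retention $121/131$ per taxon per locus, UCE lengths drawn uniformly on
284–713 bp and coding lengths on 355–664 bp.

**Sequences** evolve under Jukes-Cantor (via `phangorn::simSeq()`) with
gene-tree coalescent-unit branch lengths times a substitution-rate scalar
(default 0.01 per coalescent unit for UCE-like loci, 0.02 for the coding
class, reflecting the higher variation of protein-coding capture loci), and
a per-cell `N`-masking probability (default 0.05) emulating low-coverage
cells. The Jukes-Cantor expectation
$p = \tfrac{3}{4}\left(1 - e^{-4d/3}\right)$ for the observed proportion of
differing sites at distance $d$ is asserted in the tests.

**Reproducibility.** `make_fixture_dataset()` draws one sub-seed per locus
from the root seed (`sample.int(2^31 - 2, n_loci)` after `set.seed(seed)`),
and simulates each locus entirely under its own sub-seed; a fixed seed
therefore fixes every output byte, and any single locus can be regenerated
in isolation.

What the simulator does *not* emulate: migration and introgression,
hybridization, indels, rate variation across sites, non-stationary base
composition, alignment error, and estimation error in the input gene trees
(simulated gene trees are the true genealogies). Passing tests therefore
validate the pipeline's logic and its coalescent arithmetic, not robustness
to gene-tree estimation error in real data — on real data, discordance
conflates ILS with low signal and reconstruction error, which this tally
deliberately does not decompose.

## Numerical choices

- Newick dialect: quoted labels (with `''` escapes) and bracketed comments
  are accepted; comments are stripped; underscores are literal; internal
  node labels are retained as text. Written edge lengths use 15 significant
  digits, so parse–write round trips are exact well below the $10^{-9}$
  documented tolerance.
- Split identity is a canonical orientation-free key (both sides sorted,
  smaller side first), making bipartition equality independent of rooting
  and input order.
- Labels are compared after whitespace normalization; duplicate labels
  within a tree are rejected at parse time.
- Example and test problem sizes (10,000 quartet loci for the closed-form
  check; 300 loci × 20 replicates for slope-sign stability; 585-locus
  fixtures for the end-to-end runs) were chosen to put Monte-Carlo error
  well inside the assertion tolerances while keeping a full run in the
  order of a minute.

## Known limitations

- Gene trees are taken at face value; no support thresholds, collapsing of
  weak branches, or gene-tree error correction is applied.
- Quartet concordance factors, internode certainty and related statistics
  are out of scope; the tally is exact-split support with a fixed
  denominator.
- NEXUS reading covers `data` blocks; tree blocks with translate tables are
  not parsed (trees are expected as newick).
- The duration regression is a two-variable OLS, as in the analyses it
  reproduces; it makes no phylogenetic correction for non-independence of
  branches.
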