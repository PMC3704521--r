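---
title: "Discriminating ancient introgression from paralogy and lineage sorting"
author: "hybridtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating ancient introgression from paralogy and lineage sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A handful of plant specimens in one section of a large genus carry *two*
divergent copies of a low-copy nuclear gene: the expected copy (the
"a-copy"), and an extra copy (the "b-copy") whose sequence places it deep
inside a section of the *other* subgenus, across a split some 9–13 Ma old.
Three histories can produce such a pattern:

1. **Introgression** — a temporary fertile hybrid carried one gene copy
   across the subgenus boundary, millions of years after divergence;
2. **Gene duplication and loss** — the gene duplicated before the
   subgenus split and differential losses erased most descendants;
3. **Incomplete lineage sorting (ILS)** — ancestral alleles persisted
   across several speciation events.

`hybridtrace` implements the eliminative argument that separates these,
plus the laboratory-facing side computations (copy-distance concordance
against contamination, diagnostic-SNP scoring of amplified sequences,
allele-specific primer-site discovery), and a synthetic-data generator
that produces labelled datasets under each competing history.

## The discrimination logic

Three node designations on the dated gene tree drive the verdict, supplied
by the caller as MRCAs of named leaves (never inferred):

* **c** — divergence origin of the recipient section's a-copies;
* **d** — divergence origin of the b-copies together with the donor
  section's copies;
* **e** — the node grouping all ingroup copies that are not part of the
  donor subgenus.

Each carries a 95% highest-posterior-density (HPD) age interval from a
Bayesian dating analysis (the package consumes dated trees; it does not
produce posterior samples). Two interval comparisons follow:

* **Introgression consistency**: under a single introgression event, both
  copies retained in one species coalesce with their parental lineages at
  compatible times, so hpd(c) and hpd(d) must overlap. Overlap uses the
  closed-interval convention — a shared endpoint counts — which is the
  conservative choice for a consistency claim.
* **Paralogy/ILS rejection**: if node d truly represented the subgenus
  split (as a duplication or deep-coalescence reading requires), it would
  have to be older than every node nested under it in that reading,
  including node e. The readings are rejected exactly when hpd(e) lies
  strictly above hpd(d) (disjoint intervals). Both readings rest on the
  same comparison, so the two rejection flags are always equal. Rejection
  demands strict disjunction — no Bayes factors, mirroring the
  interval-disjunction argument the test formalizes.

The verdict is deliberately modal ("consistent with", "rejected under the
HPD-disjunction rule"), never a probability: the inference is eliminative.

Elapsed-divergence arithmetic supports the headline number: given a split
interval $[s_1, s_2]$ and an event interval $[e_1, e_2]$, the lineages had
been separated for $[\max(0, s_1 - e_2),\; s_2 - e_1]$ at the event. With
the 9–13 Ma split and the 2.9–6.0 Ma event window this gives 3.0–10.1 Ma,
midpoint 6.6 at one decimal (rounding half-up, the reporting convention
for ages; R's default banker's rounding would give 6.5 here).

## Reconciliation: the cost of the paralogy explanation

The duplication/loss cost is computed by least-common-ancestor (LCA)
reconciliation, the unique duplication-minimizing mapping. Each gene-tree
node maps to the species-tree LCA of the species hosting its descendant
copies; a gene node is a duplication iff it maps to the same species node
as one of its children; the gene edge $(v, c)$ contributes $k$ losses when
$v$ is a duplication and $k - 1$ (floored at 0) otherwise, where $k$ is
the number of species-tree edges from $\mathrm{map}(v)$ down to
$\mathrm{map}(c)$.

The focal-copy protocol isolates what matters: the species tree is the
gene-taxon tree with the focal (b-copy) leaves removed, non-focal leaves
map to themselves, and each focal leaf maps to its host species — so the
counts measure only what a duplication/loss history would need in order
to accommodate the focal copies. Polytomies are rejected rather than
silently resolved, because a resolution strategy would change the counts
invisibly. Multiple copies per species are expressed through distinct
leaf labels plus an assignment table, never label mangling.

One property often assumed of such costs is false, and the test suite
documents it: adding an extra focal leaf can *decrease* the total
duplication-plus-loss cost (an extra copy placed sister to its host's
copy can "repair" discordance elsewhere). What is provable, and tested,
is that grafting an extra copy as the sister of an existing copy of the
same species raises the cost by exactly one duplication.

## Distances, diagnostic sites, primers

**Jukes–Cantor distances** use pairwise deletion: only columns where both
sequences carry an unambiguous base are compared (IUPAC ambiguity codes
count as missing, since heterozygous chromatograms would otherwise
inflate distances), and $d = -\tfrac34 \ln(1 - \tfrac43 p)$. The distance
is undefined — reported `NA`, never silently zero — when $p \ge 3/4$ or no
valid columns remain. The contamination argument compares the distance
structure among the b-copies with that among the a-copies of the same
specimens: concordance (small maximum absolute difference across the
shared pairs) is what a genuine vertically-inherited extra copy produces,
while cross-sample contamination would decouple the two.

**Site statistics** treat gaps, `?`, `N` and ambiguity codes as missing; a
column is constant with exactly one unambiguous state among non-missing
cells, parsimony-informative with at least two states each in at least
two sequences.

**Diagnostic sites** between two reference sets are columns where each
reference is fixed for a different unambiguous base (indel-touched
columns are pruned first). Query classification calls each site as
matching the a-state, the b-state, both (an IUPAC code covering the two
states — the signature of a heterozygote), other, or missing. A single
contradictory site never flips the class; it is reported as an
"other-clade diagnostic" count, following the treatment of such isolated
sites as homoplasy. Polymorphic (BOTH) queries can be split into their
two component haplotypes; re-superposing the outputs reproduces the query
at every diagnostic column, and that inverse property is what the
simulate-then-recover tests check.

**Primer-site discovery** implements the allele-specific design rules: a
candidate window must be invariant, gap-free and unambiguous across all
target sequences; its 3′-terminal base must mismatch every off-target
sequence, with a configurable minimum number of mismatches among the
three 3′-terminal columns (forward ≥ 1, reverse ≥ 2 by default, matching
the published design); windows overlapping off-target gap columns are
flagged as anchored on an insertion site. Window lengths default to
18–25 columns — standard primer practice; the source computation does not
state lengths. Thermodynamics (melting temperature, self-complementarity)
is deliberately out of scope. An off-target ambiguity code covering the
target base is counted as a match — the conservative choice for a
specificity claim, since such a template may amplify.

## The synthetic-data generator

The generator's defaults encode the study conditions: a subgenus split
drawn uniformly from 9–13 Ma; two sections per subgenus, five species per
section, one sampled copy per species (the sampling scheme is not fixed
by the source study; these are configurable defaults a systematist would
call typical for a section-level study); subgenus crowns at 0.75 of the
split age and section crowns at 0.45 (matching the roughly 4.5/11
crown-to-split proportion the dated tree displays); Jukes–Cantor sequence
evolution at 0.004 substitutions/site/Ma over 1000 columns (chosen so
between-copy distances land near the observed ~0.08); and a coalescent
parameter of 0.3 Ma (mean pairwise coalescence waiting time, a
plant-typical effective size at a few-year generation time).

Gene trees follow the multispecies coalescent: lineages coalesce pairwise
at rate $\binom{k}{2}/\theta$ within each species-tree branch and join
the parent branch at each divergence. Focal copies form a separate group
that coalesces only among itself — they are a distinct gene copy — until
a single *transfer event*:

* **introgression**: the transfer age is drawn from the 2.9–6.0 Ma
  window, further constrained to lie above the recipient clade's MRCA
  (one lineage is transferred into the recipients' common ancestor, not
  several into its descendants) and below the donor section's crown (the
  transferred copy must nest *within* the donor section, which is the
  defining observation of the scenario). The recipient set itself is a
  clade of the recipient section, sized as close as possible to the
  configured count — it emulates a species group that inherited the
  introgressed copy from a common ancestor.
* **duplication_loss**: the duplication sits at 1.25 × the split age
  (predating the subgenus split); the duplicate copy then descends the
  species tree with per-branch loss probability $1 - e^{-\mu t}$
  (µ = 0.12/Ma by default), resimulated until at least three copies
  survive. Nested secondary duplications are not simulated; the verdict
  logic consumes a single-duplication history.
* **ils**: no transfer; extra alleles are sampled from the recipient
  clade and the coalescent parameter is enlarged (6 Ma) so that deep
  coalescence alone generates discordance.

HPD intervals are emulated as symmetric relative-width brackets
$[a(1-w),\, a(1+w)]$ around each internal node age (default $w = 0.1$),
optionally jittered with parent–child midpoint ordering enforced; the
verdict consumes intervals, not posteriors, so no posterior sampling is
pretended. What the generator does **not** emulate — rate heterogeneity
across sites and lineages, alignment error, recombination, asymmetric or
multimodal posteriors — bounds what passing tests show about real data:
they validate the decision logic and its bookkeeping, not the upstream
Bayesian dating.

## Numerical choices and conventions

* All column and node coordinates are 1-based and inclusive, the
  convention of R and of every package in this stack (ape, Biostrings).
* Trees whose leaf depths differ by more than 10⁻⁶ load as *undated*
  (ages absent) rather than being rejected — gene trees from non-clock
  analyses must still be usable for reconciliation.
* Both `height_95%_HPD={lo,hi}` and `height_95_HPD={lo,hi}` NEXUS
  annotation keys are accepted (FigTree/BEAST output varies); the first
  matching key wins.
* Unrooted input with a basal trifurcation is accepted, treated as rooted
  there, with a warning; reconciliation subsequently rejects polytomies.
* Ages are reported rounded half-up at one decimal (Ma).
* Tree text is written with 15 significant digits; round-trips are exact
  to well below the 10⁻⁹ tolerance asserted in tests.

## Problem sizes used by the tests

The suite checks reconciliation against an independent leaf-set-
containment oracle over *all* rooted binary gene-tree shapes on 2–5
leaves over a fixed 4-taxon species tree, with every leaf-to-species
assignment enumerated exhaustively up to 4 leaves and a seeded sample of
60 assignments per 5-leaf shape; site statistics against a per-column
classifier on 1,000 simulated alignments (8 × 60); scenario recovery on
100 introgression plus 100 ancient-duplication datasets at the default
configuration; heterozygote splitting on 200 replicates; and the primer
scan against an exhaustive window oracle on 200 random alignments of at
most 60 columns. These sizes give each stochastic check a comfortable
margin while keeping the default run brisk.

## Known limitations

* The verdict is only as good as the supplied node designations and HPD
  intervals; the package never infers which nodes play the c/d/e roles.
* LCA reconciliation minimizes duplications; it is not a general
  duplication-transfer-loss model, and alternative rootings are not
  searched.
* The ILS scenario is a coarse single-parameter emulation of deep
  coalescence, used for smoke testing rather than calibrated power
  analysis.
* Distances are Jukes–Cantor only, matching the published comparison; no
  other substitution models are offered.
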