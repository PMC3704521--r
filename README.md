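# hybridtrace

Tools for deciding whether a divergent extra copy of a nuclear gene found
inside a clade arose by **introgressive hybridization** rather than by
**gene duplication and loss** or by **incomplete lineage sorting (ILS)**.

The motivating situation comes from plant molecular systematics: a few
species of one *Silene* section carry, besides their expected *NRPA2*
copy (the "a-copy"), an extra "b-copy" whose sequence nests deep inside a
section of the *other* subgenus — across a subgenus split 9–13 Ma old.
`hybridtrace` is for systematists who face such a pattern and want the
full eliminative argument as reusable, tested code: it consumes rooted
dated trees (Newick, or BEAST/FigTree-annotated NEXUS with node-height
95% HPD intervals), alignments (FASTA/NEXUS) and a leaf-assignment table,
and returns a structured verdict.

## What it computes

* **LCA reconciliation** (`lca_map`, `count_duplications`, `count_losses`,
  `reconcile_focal`) — the duplication-minimizing gene-tree/species-tree
  mapping. A gene node *v* is a duplication iff map(*v*) = map(*c*) for a
  child *c*; edge (*v*, *c*) contributes *k* losses when *v* is a
  duplication and *k* − 1 otherwise, *k* being the species-tree path
  length from map(*v*) to map(*c*). The focal-copy protocol measures only
  the cost of accommodating the extra copies.
* **Relative node-age tests** (`hpd_overlap`, `elapsed_divergence`,
  `interval_midpoint`, `evaluate_hypotheses`) — introgression is
  *consistent* when the HPD ages of the two copies' divergence origins
  (nodes c and d) overlap; paralogy and ILS are *rejected* when a node
  (e) that both readings require to be nested under the clade split is
  strictly older than node d (disjoint HPDs). Elapsed-divergence
  arithmetic: split [s₁, s₂], event [e₁, e₂] →
  [max(0, s₁ − e₂), s₂ − e₁].
* **Copy-distance concordance** (`jc_distance`, `jc_matrix`,
  `distance_concordance`) — Jukes–Cantor distances,
  d = −(3/4)·ln(1 − (4/3)p) under pairwise deletion, compared between the
  extra copies and the primary copies of the same specimens: concordance
  argues against cross-sample contamination.
* **Diagnostic-SNP scoring** (`find_diagnostic_sites`, `classify_query`,
  `split_polymorphic`, `tabulate_report`) — classify amplified sequences
  against two clade references, including IUPAC-superposed heterozygotes
  and their haplotype splitting.
* **Allele-specific primer sites** (`find_specific_primers`,
  `check_specificity`) — target-invariant windows whose 3′-terminal
  mismatches against all off-target copies suppress their amplification.
* **A synthetic-data generator** (`simulate_dataset`, `sim_species_tree`,
  `sim_msc`, `evolve_jc`, `attach_hpd`) — multispecies-coalescent gene
  trees under introgression / duplication-loss / deep-coalescence
  histories, with Jukes–Cantor alignments and emulated HPD intervals, so
  the whole pipeline is testable without any downloads.

See `vignettes/hybridtrace-methods.Rmd` for the model, its assumptions
and all numerical conventions.

## Worked example

Simulate a labelled introgression dataset under the default study
conditions (9–13 Ma split, 2.9–6.0 Ma event window) and run the full
analysis:

```r
library(hybridtrace)

ds <- simulate_dataset("introgression", scenario_config(), seed = 3)
report <- run_analysis(dataset = ds)
print(report)
```

```
analysis_report
  - Distances among 3 focal copies vs the host copies of the same species: max |diff| = 0.01037 over 3 pairs (r = 0.809); concordant, so cross-sample contamination is an unlikely source of the focal copies.
  - Accommodating the 3 focal copies under duplication/loss alone requires 4 duplication(s) and 15 loss(es); a single introgression event requires one.
  - hpd(c) = [4.451, 5.44] Ma; hpd(d) = [4.664, 5.701] Ma; the intervals overlap, consistent with a single introgression event at the age of node d.
  - hpd(e) = [6.562, 8.021] Ma vs hpd(d) = [4.664, 5.701] Ma: node e is strictly older, so a duplication (or lineage-sorting) history placing the clade split at node d is rejected under the HPD-disjunction rule.
```

Reading the report: contamination is implausible (the b-copy distances
mirror the a-copy distances of the same specimens to within 0.011
substitutions/site); a duplication/loss history would need 4 duplications
and 15 losses where introgression needs one event; and the interval tests
are consistent with introgression while rejecting the paralogy and
lineage-sorting readings.

The headline arithmetic:

```r
iv <- elapsed_divergence(c(9, 13), c(2.9, 6.0))
iv                        # 3.0 10.1  — Ma of separation at the event
interval_midpoint(iv, 1)  # 6.6
```

A thin command-line wrapper over the same functions ships in
`inst/cli/hybridtrace.R` (subcommands `analyze`, `simulate`, `reconcile`,
`agetest`, `classify`, `primers`, `distances`).

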