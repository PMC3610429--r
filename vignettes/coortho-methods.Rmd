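---
title: "Methods: consolidating co-orthologue inventories"
author: "coortho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidating co-orthologue inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coortho)
```

## Scope and model

`coortho` formalizes the orthologue-inventory procedure used to transfer a
curated list of protein translocation factors from model organisms (yeast,
*Arabidopsis thaliana*) to another plant genome. The statistical structure
of the problem is set by palaeoploidisation: the Arabidopsis lineage went
through two additional whole-genome duplications and the Solanaceae lineage
through a triplication, so a single curated factor frequently corresponds
to a *set* of co-orthologues in each genome, with independent loss on both
sides. The pipeline therefore (i) consolidates two independent orthogroup
predictions per factor, and (ii) resolves residual many-to-many ambiguity
with evidence that duplication histories leave behind: conserved domain
architecture, conserved local gene order, proportional protein lengths, and
correlated tissue expression.

Each stage is an exported function with a documented contract; the
`run_pipeline()` orchestrator wires them together and is deterministic
given a configuration (which carries the master seed).

## Quality filters

Two filters mirror the eligibility rules of the upstream predictors:

* **CDS:protein relation** (`validate_pgap_inputs()`): an entry is eligible
  when its CDS length is `3L` or `3(L+1)` for protein length `L` — the
  second form tolerates an annotated terminal stop codon, since annotation
  conventions differ. A `strict` flag accepts only `3L`. Identifiers must
  be unique and every protein needs exactly one CDS partner; violations are
  reported per record, never silently dropped, and a global flag notes
  unequal file totals. By default the mismatched entries are removed from
  the eligible set; callers who prefer to only flag them can keep the
  report and proceed with the full universe.
* **Sequence quality** (`filter_quality()`): proteins shorter than 10
  residues or with more than 20% `*` symbols are removed. Both thresholds
  are read as strict inequalities, so a length-10 protein or one with
  exactly 20% stops is kept; the suite pins these boundary cases.

## The surrogate orthology engines

The two external predictors are emulated by two self-contained engines so
that the pipeline runs end-to-end at desk scale. Both consume the same
all-vs-all similarity graph: Smith–Waterman local alignment (BLOSUM62, gap
open 10, extend 1 — fixed and versioned in `aa_scoring()`), normalized by
the length of the shorter sequence so that scores are comparable across
protein sizes, and thresholded at a minimum normalized score of 1 (about
one fifth of a typical per-residue self-score) to suppress spurious short
local matches.

* **RBH + inparalogs** (`infer_rbh_groups()`): seed pairs are mutually
  best-scoring cross-species pairs; a same-species gene joins a seed
  cluster when its score to the seed member of its species is at least the
  seed pair's score; overlapping clusters merge transitively. All
  tie-breaks are lexicographic on (species, gene id) for determinism.
  Multi-species merging is plain transitive closure — a deliberate
  simplification of the external tool's undocumented merge step.
* **Markov flow** (`infer_mcl_groups()`): a column-stochastic matrix is
  iterated through expansion (squaring) and inflation (elementwise power
  1.5, column renormalization) until stationary (tolerance 1e-6); groups
  are connected components of the limit thresholded at 1e-8. Self-loops are
  weighted by each gene's strongest incident edge (1 for isolated genes):
  without them pure expansion oscillates with period 2 on bipartite
  subgraphs. Column sums are asserted to be within 1e-9 of 1 after every
  iteration. Flow cannot cross connected components, so the output always
  refines the input components — a property the suite checks against a
  union-find oracle.

Both engines are explicitly surrogates: every downstream function accepts
`orthology_groups` objects read from external files interchangeably.

## Consolidation statistics

For each factor, the orthologue set per method and species is the union of
the bait genes' group-mates in that species, with the factor's own baits
excluded (a bait is not its own orthologue). The consensus is the
per-species union over methods. Three statistics summarize an inventory:

* **overlap** — the fraction of factors whose per-method sets are
  *identical in every target species*. The published procedure never
  defines the granularity of "overlap in findings"; exact set equality per
  factor is the strictest reading and is what this package computes.
* **missing** — factors whose set in the target species is empty under
  every method ("by either procedure" is read as "by neither").
* **multiplicity** — factors whose consensus set in the target species has
  more than one member.

Since a gene may serve two factors, the inventory size is counted both as
distinct genes and as factor–gene assignments (`orthologue_counts()`).

## Domain architectures and split genes

Architectures are ordered domain-name lists (N→C by envelope start). When
two hits overlap by more than half of the shorter hit, only the
higher-scoring survives (ties: lower start) — resolved greedily from the
top score down, which the suite checks against an independent recursive
formulation of the same rule. Tandem repeats are kept distinct (three
consecutive WD40 hits stay `WD40, WD40, WD40`); whether the original
automated comparison collapsed repeats is unknown, so this is flagged as a
divergence risk. Architecture identity compares mapped class sequences
only — never domain lengths, since orthologous domains routinely differ by
tens of residues. The bundled equivalence map ships as an editable TSV and
contains a single entry pair: the two zinc-finger RING variants
(`zf-RING_2`, `zf-C3HC4_2`) fold into one class, which is exactly what the
cpSecA2 worked example requires.

`detect_fusion()` covers the split-gene situation: a gene in one species
whose architecture equals the concatenation (in either order) of two genes
in the other species that lie on one chromosome within a configurable rank
gap (default 1, i.e. adjacent annotations — the known case genes are
adjacent, separated by 140 bp, which generalizes to rank adjacency in a
gene-order model).

## The shared-synteny score

Gene order is modelled as a per-chromosome 0-based rank — the synteny unit
of the procedure is genes, not base pairs. For a candidate pair, the window
of half-width `w = 7` around each gene (focal gene excluded, truncated at
chromosome ends, strand ignored) is compared: per method, the count is the
number of window-A genes with at least one group-mate inside window B.
Window truncation makes the two directions differ, so the symmetric
per-method count is the minimum of the two directional counts; both
directions are retained in the output, and a `pairs` counting unit (all
co-orthologous window pairs) is available behind `count_unit`. The total
accumulates the per-method counts — on a verbatim-duplicated genome with
two agreeing methods an interior true pair scores exactly 14 + 14 = 28.

`assign_by_synteny()` matches candidates greedily by descending total
(lexicographic ties), which is transparent and deterministic at the tiny
candidate-set sizes that occur per factor; an exhaustive optimal matching
is available behind `method = "optimal"` and the suite verifies the greedy
result is rarely below the optimum at those sizes. A pair is flagged `+`
only when its total is positive and strictly exceeds every competing
candidate sharing an endpoint — ties flag nothing.

## Length fit and expression correlation

The protein-length model is proportionality through the origin,
`y = a·x`, fitted in closed form `a = Σxy / Σx²`; no intercept is offered
because the model claim is proportionality of orthologue lengths.

Expression profiles cover four tissues (leaves LE, flowers & pollen F&P,
shoots & stems S&S, roots RO) on two platforms whose conventional display
scales differ (microarray ×100, RNA-seq ×1000). Correlation is Pearson on
`log2(1 + scale·value)` over shared tissues (at least 3; otherwise the
evidence is reported missing). The published procedure inspected patterns
visually and states no transform; the log transform is this package's
declared choice (a raw-scale option and Spearman are retained), and the
platform scale cancels under correlation of logs except through the +1
offset — exactly for the raw option, approximately for values ≫ 1.
`assign_by_expression()` flags `#` only for a unique maximum with
`r ≥ 0.8` and a margin of at least 0.1 over the runner-up; both thresholds
are artifact choices (the original assignment was expert inspection) and
are exposed as parameters.

## The evidence cascade

`integrate_evidence()` resolves each factor in the order consensus →
architecture (including split genes) → synteny → expression, mirroring the
narrative order in which the additional strategies were applied; the order
is a configuration of the bundle, not a hard-coded constant. A 1:1
candidate situation is flagged `consensus`; mutually unique architecture
matches are flagged `architecture`; split-gene matches emit one row per
partner gene sharing a fusion-event id (the gene universe is never mutated
by merging partners into a pseudo-gene); synteny-dominant pairs get `+`,
expression-dominant pairs `#`; everything left is emitted as honest
unresolved candidate rows — the cascade formalizes, but cannot replicate,
expert judgment. `categorize_factor()` maps each factor onto the six
display categories with precedence: no plant orthologue at all →
`absent_in_plants`; found in plants but not in species B → `absent_in_B`;
no non-plant bait → `plant_only`; otherwise the count comparison decides
`equal` / `more_in_B` / `fewer_in_B`. Placing `absent_in_B` above
`plant_only` means a plant-specific factor missing from species B reports
the more informative absence.

## The simulator

`generate_dataset()` produces everything the pipeline reads, plus planted
truth. Defaults encode the reference study conditions used throughout the
tests: 150 ancestral genes on 3 chromosomes, lineage A with two WGD rounds
at per-duplicate retention 0.3, lineage B with one triplication at
retention 0.4, loss probability 0.1, substitution rate 0.05 per site, 20
adjacent-transposition rearrangement ops, fission probability 0.02, 40
curated factors, and method-disagreement rate 0.18. Design notes:

* **Duplication layout.** A duplication copies each chromosome onto a new
  mirror chromosome preserving gene order (retention applied per gene).
  This is what palaeoploidy leaves in real genomes and what gives the
  7-gene window a conserved signal between a gene and its orthologue while
  paralogous mirrors degrade with retention. Rearrangement is composed
  adjacent transpositions, so local synteny decays gradually with the op
  count.
* **Loss** applies to every post-duplication gene, original or copy; the
  expected descendant count under one duplication is `n(1+p)(1−q)`, which
  the suite checks within 3 binomial standard deviations. Losing originals
  is what generates factors with no orthologue under any method.
* **Fission** splits a gene (architecture length ≥ 2) into two adjacent
  annotations, dividing architecture and sequence; the event is logged with
  both partners, so split-gene detection can be audited against truth. The
  mirror view — an intact gene in the other lineage corresponding to the
  combination — is the planted analogue of the cpSecA2 case.
* **Substitution** is uniform random replacement per site, no
  matrix-weighted mutation and no indels: sufficient to rank similarities,
  and stated as such. Expression profiles are a shared ancestral lognormal
  base times per-gene lognormal noise, so co-orthologues are co-regulated
  up to the noise SD.
* **Method emulation.** Method 1 reproduces the planted groups; method 2
  perturbs each group independently with probability `d` (drop a random
  member, or exchange members between two perturbed groups). Perturbations
  are contained to the selected groups, so the factor-level overlap
  statistic centres on `1 − d` with binomial noise — the structural echo of
  the published 82% at `d = 0.18`.
* **Determinism.** Every sub-process draws from a stream derived from the
  master seed by fixed small offsets; identical config yields a
  byte-identical on-disk bundle, which the suite asserts file by file.

What the simulator does *not* emulate — real substitution processes,
indels, unequal gene spacing, tandem (as opposed to whole-genome)
duplication, annotation noise other than the planted QC violators —
bounds what passing tests show about real genomes: they validate the
*logic* of every stage and its behaviour under the assumed duplication
structure, not performance on any particular assembly.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full inferred pipeline at
the default 150 ancestral genes (≈ 220–250 descendant proteins per
lineage), all-vs-all alignment included; oracle-equivalence checks use 100–
200 random instances of each primitive at sizes where exhaustive oracles
are exact (≤ 30-residue sequences, ≤ 12-gene windows, ≤ 4×4 matchings,
≤ 8-hit architectures). Convergence and thresholds: MCL inflation 1.5,
tolerance 1e-6, component threshold 1e-8, stochasticity assertion 1e-9;
length-fit oracle agreement 1e-10; alignment oracle agreement to machine
precision. Degenerate inputs are defined, not accidental: empty sequences
score 0 with a warning, zero-length proteins are removed as too short
(their stop fraction is undefined), an empty factor list makes the
statistics error rather than return NaN, and a query without an
architecture yields an empty fusion result with a warning.

## Known limitations

* The engines are surrogates; their agreement rate with each other is not
  calibrated to the published 82%, which derived from two specific external
  tools on versioned assemblies. The emulated-disagreement path exists
  precisely to test the statistic at a controlled rate.
* Exact set equality makes the overlap statistic conservative; a per-gene
  Jaccard variant would be less brittle for large co-orthologue sets.
* Tandem-repeat counts in architectures are compared exactly; a repeat
  miscount in domain prediction breaks identity.
* The greedy synteny matching can be suboptimal on adversarial score
  matrices; the optimal matcher is exponential and intended for the small
  per-factor candidate sets.
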