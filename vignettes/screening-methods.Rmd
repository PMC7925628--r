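---
title: "Screening drug combinations for interaction-free sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug combinations for interaction-free sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiscreen)
```

## The model

`ddiscreen` treats drug–drug interactions as a symmetric, irreflexive
relation over a finite drug universe: an *interaction graph* whose
vertices are canonical drug names and whose edges are the unordered pairs
with any documented interaction. A combination of $k \ge 2$ drugs is
**interaction-free** when none of its $\binom{k}{2}$ member pairs is an
edge — equivalently, when it is an independent set of the interaction
graph. The screen enumerates every combination of sizes $k_{\min}$ through
$k_{\max}$ (defaults 2 and 4) and keeps the interaction-free ones.

Three consequences of this purely pairwise definition drive the design:

* **Hereditary family.** Every size-$\ge 2$ subset of a survivor is itself
  a survivor, so the screened family is downward closed. The package
  validates this invariant whenever a family is condensed; a violation can
  only mean the family was not produced by a pairwise screen.
* **Condensation is lossless.** A hereditary family is fully determined by
  its maximal members (those not strictly contained in another member).
  `condense_maximal()` and `expand_maximal()` are mutually inverse, which
  is both the compact reporting format and a strong internal check.
* **Reconstruction from the condensed list is exact.** Declaring every
  pair that co-occurs in some published maximal set non-interacting, and
  every other pair interacting, recovers the pair relation exactly — and
  pairs are all the screen consults. This is how the bundled dataset
  rebuilds its interaction graph offline from the published condensed
  list rather than from any remote source.

No higher-order (three-way) interaction model is attempted, and severity
is stored but deliberately ignored by the default screen: the screen is an
upper bound on interaction risk, counting every documented interaction
however minor. A severity-aware filter can be layered on the stored
records without touching the engine.

## The reference dataset

The bundled dataset (`abortives_fixture()`) covers 44 non-opioid,
non-barbiturate headache abortive medications. Two further drugs that
practitioners would recognize (mefenamic acid, rimegepant) are absent
because the interaction source had no data for them at acquisition time —
the package distinguishes *no data for a drug* (the drug cannot be
screened and is pruned, see `prune_uncovered()`) from *no interactions
found for a pair* (the drug is screened and may appear in many
survivors). Ergotamine, for example, has zero inclusions yet stays in the
universe.

Screening the reconstructed graph yields 192 interaction-free
combinations — 123 pairs, 67 triples, 2 quadruples — out of the 946 +
13,244 + 135,751 candidates:

```{r screen}
fx <- abortives_fixture()
family <- screen_combinations(fx$universe, fx$graph)
family
size_distribution(family, fx$universe)
```

Raw ratios are always reported alongside counts; rendered percentages are
presentation only, since different rounding conventions at the third
decimal are not a scientific claim worth encoding.

The dataset also carries a reference class map and per-drug reference
inclusion counts. The NSAID class is fixed as 20 named members — the
unique membership under which the NSAID tally equals the reference total
of 133 — while the non-NSAID labels (gepant, ditan, triptan, neuroleptic,
corticosteroid, ergot, …) are a pharmacological convenience for the
tally report, not a claim of the source data. Class tallies sum member
inclusion counts, so a combination holding two same-class drugs would
count twice; the reference family happens to contain no such combination.

```{r classes}
counts <- inclusion_counts(family, fx$universe)
head(class_tally(counts, fx$classes), 4)
```

The 12-drug evidence-based primary-care allow-list restricts the family to
combinations drawn entirely from that subset:

```{r allow}
family_keys(filter_allowlist(family, fx$allow))
```

## Algorithms and numerical choices

**Canonical names.** All matching happens on lowercase, whitespace-
collapsed names, because real drug lists mix casings freely. Combination
identity is the lexicographically sorted name vector; every output is
sorted (families by size then name, maximal sets by descending size then
name), so repeated runs produce byte-identical files.

**Enumeration.** `combination_stream()` generates $k$-subsets in
lexicographic order by the standard index-successor rule, in constant
memory per item — the 135,751 four-drug subsets of the reference universe
never need materializing at once.

**Screening.** `screen_combinations()` walks a depth-first extension tree:
a partial combination is only ever extended with drugs that interact with
none of its members, so subtrees containing an interacting pair are never
visited and runtime scales with the number of interaction-free sets (192
on the reference data) rather than with $\binom{44}{4}$. Maximality is
defined within the enumerated window $[k_{\min}, k_{\max}]$: a
$k_{\max}$-set is reported maximal even if a larger independent set exists,
because the screen stops at four drugs by construction.

**The oracle.** `brute_force_screen()` is the independent correctness
anchor: it materializes every subset with `utils::combn()` and rechecks
every pair against the adjacency relation, sharing no code with the
pruned search. It is capped at 20 drugs, which is ample for the property
tests and keeps its cost trivial. The test suite asserts exact agreement
of the two routes on 200 seeded random graphs of 4–12 drugs with edge
probabilities 0.1–0.9.

**Degenerate inputs.** `k > |universe|` yields an empty enumeration, not
an error; an edgeless graph keeps everything; a complete graph keeps
nothing; an empty family has well-defined (zero) shares. Requesting
combinations of size below 2 is an error — a "combination" of one drug is
not a polypharmacy question.

**Remote sources.** The interaction-source contract
(`interaction_source()`) is a single `lookup(drug)` function returning
either *unknown drug* or the drug's interaction list; `fetch_pairwise()`
collapses per-drug lists to unordered pair records, reads a JSON-backed
cache before every lookup (a warm cache performs zero remote calls), and
retries transient failures a bounded number of times. Tests exercise the
contract exclusively through deterministic mocks; source data drift means
a live re-query is not expected to reproduce the bundled graph, and the
bundled files are the ground truth.

## What the synthetic generators do and do not emulate

`random_interaction_graph(n, p, seed)` draws Erdős–Rényi graphs over
synthetic drugs `d01..dNN`: every pair interacts independently with
probability `p`. Real interaction graphs are not Erdős–Rényi — the
reference data's edges are highly structured (823 of 946 pairs interact,
with near-universal interactors like haloperidol and near-isolates like
ubrogepant) — so these graphs serve one purpose only: exercising the
engine across densities so the pruned search and the brute-force oracle
can disagree if either is wrong. Passing those tests demonstrates
algorithmic correctness on arbitrary pair relations, not any clinical
property of real formularies.

`planted_family_graph()` inverts known interaction-free sets into a graph,
which must then be recovered exactly by screen-plus-condense; the recovery
tests use disjoint planted sets (plus nested cases), where exact recovery
is the ground truth by construction. Overlapping planted sets may
legitimately merge into larger independent sets and are therefore not a
recovery benchmark.

Test problem sizes (12-drug oracle universes, 200 + 50 seeded cases) keep
the full suite to a few seconds while covering every density regime; the
reference screen itself runs in well under a second.

## Known limitations

* The screen is as conservative as its source: it counts pharmacokinetic
  footnotes and serious contraindications alike, so it over-estimates
  clinically meaningful risk. Severity classification of free-text
  interaction descriptions is out of scope.
* Results are only as complete as the drug universe; the reference list is
  a curated formulary of oral abortives and bridge therapies, not a
  complete pharmacopoeia, and no synonym or brand-name resolution is
  attempted beyond case folding.
* Maximal sets are reported within the size-4 window; the package does not
  enumerate larger independent sets.
* The condensed published list contains one redundant line (a pair nested
  in a triple). Strict condensation therefore yields 81 maximal sets, not
  82; the loader keeps the published transcription verbatim and the
  redundancy is absorbed on recomputation, never forced back in.
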