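# ddiscreen

Combinatoric screening of drug combinations for pairwise interaction-free
sets.

## The problem

Patients with refractory headache are often treated with several acute
("abortive") medications at once, and most haphazardly chosen pairings
carry some documented drug–drug interaction (DDI). `ddiscreen` answers the
question a prescriber planning rational polypharmacy actually has: *which
combinations of 2, 3, or 4 drugs from a given formulary contain no
interacting pair at all?*

The model is deliberately simple and conservative. Let the drug universe
have *a* members and let *c* be the set of unordered drug pairs with any
documented interaction, regardless of severity — the edge set of a
symmetric, irreflexive interaction graph. The screen enumerates the
lists L₂, L₃, L₄ of all ₐC₂, ₐC₃, ₐC₄ combinations and keeps exactly those
containing no pair from *c*. Because the defining property is purely
pairwise, the surviving family is *hereditary* (every sub-combination of a
survivor survives), so it is fully described by its *maximal* sets — the
survivors not strictly contained in another survivor — which is the
compact form a clinician can read.

The package ships a curated reference dataset: 44 non-opioid,
non-barbiturate headache abortives, the DrugBank-derived condensed list of
their interaction-free sets (from which the full interaction graph is
reconstructed), a reference class map (20 NSAIDs, one gepant, one ditan,
seven triptans, …), and the 12-drug evidence-based primary-care
allow-list. It also provides a mockable remote interaction-source contract
with a local JSON cache, synthetic Erdős–Rényi and planted-set graph
generators for property testing, and a brute-force screening oracle.

## Worked example

```r
library(ddiscreen)

fx <- abortives_fixture()          # 44-drug universe + interaction graph
family <- screen_combinations(fx$universe, fx$graph, k_min = 2, k_max = 4)
family
#> <ddi_family> 192 interaction-free combinations (sizes 2-4)
#>   2 drugs: 123
#>   3 drugs: 67
#>   4 drugs: 2

condense_maximal(family)
#> <ddi_maximal> 81 maximal interaction-free sets

head(inclusion_counts(family, fx$universe), 4)
#>               drug count
#> 1       ubrogepant    96
#> 2 prochlorperazine    41
#> 3       tizanidine    37
#> 4       prednisone    31

family_keys(filter_allowlist(family, fx$allow))
#> [1] "acetaminophen,aspirin"     "acetaminophen,ibuprofen"
#> [3] "acetaminophen,naratriptan"
```

Of the 946 two-drug, 13,244 three-drug, and 135,751 four-drug combinations
of the 44 reference drugs, only 192 are free of any pairwise interaction —
123 pairs, 67 triples, and 2 quadruples. Ubrogepant appears in 96 of them,
more than any other drug; restricting to the 12 evidence-based
primary-care abortives leaves just three viable pairs, all involving
acetaminophen.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/ddi-screen screen --fixture abortives --out results/
Rscript inst/scripts/ddi-screen screen --fixture abortives --allowlist steiner --out results-steiner/
Rscript inst/scripts/ddi-screen screen --drugs my_drugs.txt --interactions my_interactions.tsv --out my_results/
```

`screen` writes `family.csv`, `maximal_sets.csv`, `inclusion_counts.csv`,
`size_distribution.csv`, `class_tally.csv`, and a run manifest;
`condense`, `expand`, `report`, `filter`, and `fixture` expose the
individual stages. Interaction files are TSV with columns
`drug_a, drug_b, description, severity`, where a description of `None`
means looked-up-but-non-interacting; drugs the source has no data for at
all are pruned from the universe before screening.

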