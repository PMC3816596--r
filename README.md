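# eqonto

Entity–quality phenotype ontology formalisation and lethal-phase reasoning
in R.

## The problem

Model-organism phenotype vocabularies (the *Drosophila* FBcv id space is
the motivating case) historically grew as hand-maintained `is_a`
hierarchies: no textual definitions, no formal semantics, and a
classification that drifts out of sync with the entity ontologies it
implicitly references. The modern cure is the **entity–quality (EQ)
pattern**: a phenotype class is formalised as a PATO quality that
`inheres_in` some entity — a GO process, a CL cell type, an anatomical
structure — optionally qualified as `abnormal` and optionally directed
`towards` a second entity:

```
'radiation resistant'  EquivalentTo
    'decreased sensitivity of a process' that inheres_in some 'response to radiation'

'stress response defective'  EquivalentTo
    quality that inheres_in some 'response to stress' and qualifier some abnormal
```

Once phenotypes are defined this way, most of their classification needs no
curation at all: it is *inferred* by structural subsumption against the
imported entity DAGs. `eqonto` implements that machinery end to end for
anyone building or releasing a pattern-defined phenotype ontology:

* **OBO 1.4 I/O** including genus-differentia (`intersection_of`) patterns,
  a header-registered union tag, necessary-only definitions, and the
  pre-reasoned `-simple` release flavour (inferred, transitively reduced
  `is_a` links only).
* **A structural reasoner** for the existential-conjunctive fragment plus
  top-level unions, with asserted-vs-inferred provenance and statistics
  (`n_inferred / n_direct`, the headline "percent inferred" figure).
* **Automated textual definitions** for terms matching the simple
  quality/`inheres_in`/`abnormal` pattern, generated from the entity term's
  label and definition.
* **Paths-to-root module extraction** for imports, ancestor/descendant
  queries, transitive closure and reduction.
* **The lethal-phase system**: a seven-relation Allen interval subset over
  a chain of life stages, mortality-rate bands with the 5/50/98 percent
  quantifier cutoffs, automatic generation of the flat lethal-phase term
  set ("some/majority/all die during/before the end of stage S", 'lethal',
  'partially lethal - majority die', 'increased mortality'), its
  classification into a nested DAG, a finite-population model-checking
  oracle, and an annotation helper mapping per-stage mortality observations
  to the most specific applicable terms.
* **A release pipeline** (`run_release()`, plus a thin CLI in
  `inst/cli/eqonto`): validate, roll textual definitions, classify, and
  emit full/simple artifacts with TSV reports.

Miniature PATO/GO/CL/stage fixtures ship with the package (and are rebuilt
in code), so everything is testable offline.

## Worked example

```r
library(eqonto)

fixtures <- make_named_fixtures()
imports  <- fixture_imports(fixtures)

h <- classify(fixtures$mini_dpo, imports)
h
#> <inferred_hierarchy: 23 terms, 25 direct edges (22 inferred), 0 equivalence group(s)>

subclasses_of(h, "FBcv_0000408")   # stress response defective
#> [1] "FBcv_0000423" "FBcv_0000684" "FBcv_0000686" "FBcv_0000687" "FBcv_0000688"
#> [6] "FBcv_0000689" "FBcv_0000690" "FBcv_0000691"

inference_stats(h)
#> 22/25 direct classifications inferred (88%)
```

Eight subclasses of 'stress response defective' are inferred, none
asserted — among them 'DNA repair defective' (FBcv_0000423), which reaches
it through 'cellular response to DNA damage stimulus', and 'cold stress
response defective' (FBcv_0000684), which also lands under 'temperature
response defective' because 'response to cold' has both GO parents. Of the
25 direct edges in the reduced hierarchy only 3 are asserted (the terms
whose printed axioms lack the `abnormal` qualifier and are therefore
classified under the root by hand), so 88% of this fixture's
classification is inferred.

The lethal-phase system:

```r
chain <- stage_chain_from_obo(fixtures$fly_stages)
terms <- generate_lethal_phase_terms(chain)   # 21 flat terms
lh    <- classify_lethal(terms, chain)        # nested DAG, one top

obs <- c(FBdv_00005289 = 100, FBdv_00005336 = 0, FBdv_00005342 = 0)
annotate_mortality(obs, terms, chain)
#> [1] "LP_5634243"      # 'lethal - all die during embryonic stage'
```

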