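---
title: "Methods: EQ formalisation and lethal-phase reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EQ formalisation and lethal-phase reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqonto)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what its tests do and
do not establish.

## The EQ model and the structural reasoner

A phenotype class is formalised as a conjunction over four slots: a PATO
quality (the genus), an optional `inheres_in` entity filler, an optional
`towards` filler (used with relational qualities such as 'has extra parts
of type'), and an optional `qualifier some abnormal` conjunct. The
phenotype root itself is the pattern `quality and qualifier some abnormal`,
so every definition carrying the abnormal qualifier is entailed to sit
under the root. Two variants extend the plain conjunctive pattern: unions
(needed for classes like 'cell death defective', which covers defects in
either programmed cell death or its regulation) and necessary-only
definitions (for classes like 'jumping defective', where the pattern gives
necessary but not sufficient conditions).

`eq_subsumes()` decides subsumption in this fragment structurally: each
conjunct of the subsumer must be entailed by a conjunct of the subsumee
with the same role, where filler entailment is reflexive ancestor
containment in the imported `is_a` DAGs. Unions distribute in the usual
way. This fragment is deliberately existential-conjunctive (EL-style) plus
top-level unions; the lethality patterns' universal quantification and
data ranges are handled by the dedicated lethality module rather than
here, because the two kinds of axiom never need to mix.

Assumptions worth making explicit:

* **Only `is_a` edges classify.** Other relationship types (`part_of` and
  friends) are parsed and re-serialised but ignored by the reasoner.
  Propagating classification over part-of would be unsound for these
  patterns, and the printed axioms only ever lean on subclass structure.
* **Necessary-only definitions generate ancestors only.** A term whose
  pattern states necessary conditions gains inferred superclasses but
  never gains descendants through its definition.
* **Mutual subsumption is curator feedback, not an error.** Distinct ids
  with equivalent definitions are reported as an equivalence group with a
  warning, collapsed onto their lexicographically least member for the
  reduced edge set, and surfaced in release findings.
* **The comparative (versus wild-type) nature of phenotypes is not
  formalised**; the abnormal qualifier carries that burden, as is standard
  across phenotype ontologies.

The classifier merges inferred edges with asserted `is_a` links, takes the
transitive reduction, and annotates every surviving direct edge with
asserted/inferred provenance. `inference_stats()` reports
`n_inferred / n_direct` with half-up percentage rounding; on counts of
258 inferred out of 305 direct classifications this yields 85%.

### Counting "subclasses"

A figure caption's subclass count can mean direct children or all
descendants. The API exposes both (`subclasses_of(h, id, direct = )`); the
worked stress-response example counts **all** inferred subclasses in the
closure (eight, two of them reached through intermediate inferred
parents), which matches the depicted panel, while the direct-children
reading of the same fixture gives six.

## Automated textual definitions

Terms matching the simple pattern (bare `quality` genus, an `inheres_in`
filler, the abnormal qualifier, equivalence semantics, no `towards`) and
lacking a manually supplied definition get generated text of the exact
shape:

```
A phenotype that is a defect in '<label>' (<short form id>). The GO term
'<label>' is defined as: '<definition>'
```

Definitions using more specific qualities (e.g. 'decreased sensitivity of
a process') are refused: reliable readable text cannot be derived for
them, so they keep curated definitions. Quote characters are plain ASCII
apostrophes — typographic quotes in print are typesetting, not content.
Auto-text is regenerated on every release run rather than cached, so a
deleted manual definition simply re-enables generation at the next
release.

## OBO encoding choices

The target dialect is OBO 1.4; OWL translation is out of scope. Plain OBO
has no encoding for union equivalents or necessary-only genus-differentia
patterns, so the writer uses two custom tags, both registered in the
header via a `subsetdef` line so conforming parsers skip them:

* `equivalent_union_of: <id1> <id2> ...`, whose operands are auxiliary
  anonymous pattern stanzas (`is_anonymous: true`) in the same document;
* `necessary_intersection_of:`, with the same grammar as
  `intersection_of` but subclass rather than equivalence semantics.
  Reusing `intersection_of` itself would silently change meaning under
  third-party OBO semantics, which read it as an equivalent-class axiom.

Output is deterministic — terms sorted by id in C collation, tags in fixed
order — so a release run is byte-reproducible, and `parse -> write` is a
fixed point after one normalisation. Dangling references are warnings by
default and fatal only under `--strict`: imported-module workflows
legitimately carry references resolved elsewhere. Module extraction for
imports uses the paths-to-root strategy (every used term plus everything
on its `is_a` paths to any root, with all axioms among retained terms —
including non-`is_a` relationships whose endpoints are both retained);
locality-based module extraction is deliberately not implemented.

## The lethal-phase system

Lethal-phase terms pair a **mortality band** — a closed integer percentage
interval, wild-type baseline excluded — with an **age window** over a
linear chain of major life stages. Mortality values are whole numbers in
[0, 100]; printed strict bounds normalise losslessly (`>50` becomes
`>=51`, giving 'partially lethal - majority die' the band [51, 98]).

The quantifier cutoffs are tunable but default to the community
rules-of-thumb: `some` ≥ 5% (a hard non-zero floor below which increased
mortality is not recorded), `most` ≥ 50%, `all` ≥ 98% (absorbing rare
escaper survivors into 'lethal'). Two printed-boundary quirks are
preserved deliberately rather than smoothed over: the `most` bands use
≥ 50 while 'partially lethal' uses > 50, and the 'lethal' band is
[98, 100] even though one printed axiom reads `<= 98` — that reading would
make 'lethal' and 'partially lethal' nearly synonymous and contradicts the
nested classification the system is built to produce, so it is treated as
an erratum. 'short lived' carries no published axiom at all; it is
generated only behind `with_short_lived = TRUE`, encoded as increased
mortality during the adult stage, and explicitly marked as this package's
reading.

**Death timing is a single stage index per organism**; within-stage timing
is not represented, because every axiom in the system discriminates only
at stage granularity. An age constraint denotes a set of permitted
death-stage indices (`index_set()`): `during(S_k)` is {k},
`precedes(S_k)` is {0..k−1}, and `before_end_of(S_k)` is their union —
the package's definition, chosen because it is what makes the
during/before-end nesting come out. One consequence worth knowing:
for the *first* stage, die-during and die-before-the-end-of coincide, so
those pairs are reported as equivalence groups rather than as a strict
nesting, and `'lethal'` is equivalent to 'all die before the end of the
last pre-adult stage'. Both are correct under the index-set semantics.

### Allen relations

Stage timing uses the subset precedes/preceded_by/meets/met_by/during/
starts/finishes plus explicit equality ('starts' is abbreviated `s`; an
abbreviation `(e)` seen in print is taken as a typo for it).
`allen_compose()` implements the **standard** composition table — computed
analytically from endpoint order relations in the point algebra, not
hard-coded — and reports base relations outside the subset as the marker
`"other"`. A claim sometimes seen that 'meets' is transitive is false in
the standard algebra (`m ; m = p`) and is not implemented; the
grid-enumeration tests would catch any deviation. Composition beyond what
the lethality patterns need is kept for validation value.

### The model-checking oracle

`model_check_subsumption()` is an independent semantic check on
`lethal_subsumes()`: it enumerates finite populations (each of up to 3–4
members assigned a death-stage index, the adult stage doubling as
survival) crossed with mortality rates from a coarse grid covering every
band boundary — refined with the two compared terms' own endpoints — and
tests whether every satisfying population of one term satisfies the
other. Population sizes above 4 are refused as intractable; sizes up to 3
already realise every distinction the subset-containment semantics can
make. The oracle-equivalence test runs all ordered pairs of generated
terms over chains of length 2–5 (about 1,500 pairs).

### Annotation

`annotate_mortality()` maps a per-stage observation table to terms by
accumulating mortality over each term's age window and testing band
membership, then returns the most specific applicable classes — the
antichain under subsumption, with mutually equivalent classes reported
once by their lexicographically least id, matching the classifier's
collapse.

## Fixtures and generators

The bundled fixtures transcribe the fragments the worked examples need: a
PATO fragment (qualities and the abnormal value), a GO fragment with the
stress-response subtree (including the dual-parent placement of 'response
to cold' and 'response to heat' under both stress and temperature
stimulus, and the DNA-damage path to 'DNA repair'), the
behavior/perception/circadian split, the programmed-cell-death terms, a
CL/FBbt fragment, a four-stage life-stage chain (embryonic, larval,
pupal, mature adult) linked by `immediately_preceded_by`, and the
phenotype terms whose printed pattern definitions exercise every variant
(plain, specific-quality, relational with `towards`, union,
necessary-only). The fixture files under `inst/extdata/` are written by
`fixtures_write_all()` and the in-code constructors are their source of
truth; the stress-response fixture is likewise the single source of truth
for the eight-subclass worked example.

The random generator (`random_instance()`) produces seeded rooted DAG
imports and random definitions over them — a pure function of its
`fixture_spec`. It emulates the *structural* shape of the problem
(multiple inheritance, definition variety, occasional mutual
subsumption), not the content of real ontologies: real GO releases are
three orders of magnitude larger, carry non-`is_a` axioms the reasoner
ignores by design, and their textual content cannot be conjured. Passing
the property tests therefore establishes correctness of the algorithms on
DAG-shaped inputs, not fidelity to any particular ontology release;
full-scale figures (such as an ontology-wide inferred percentage) depend
on versioned releases and are replaced by golden values on the bundled
fixture (22 of 25 direct edges inferred, 88%).

Problem sizes used by the test suite, chosen to exercise every code path
at desk scale: 200 random DAGs (≤ 30 nodes) for closure oracles, 1,500+
random definition pairs and 100+ random ontologies (≤ 12 phenotype terms)
for the reasoner-versus-brute-force checks, 300 generator seeds for the
acyclicity/validity sweep, and chains of length 2–5 for the lethality
oracle.

## Numerical and determinism choices

* All iteration is in id-sorted order under C collation; artifacts are
  byte-identical across runs and platforms.
* Transitive reduction is computed on DAGs (unique result); cycles raise
  an error naming a witness cycle, except that definition-induced mutual
  subsumption is collapsed first.
* Lethal-phase stage-term ids are minted with a deterministic polynomial
  hash of (quantifier, mode, stage id) in a reserved `LP` namespace, with
  a collision check; the three core terms keep their fixed FBcv ids.
* Half-up rounding for the inferred percentage (`floor(100 f + 0.5)`).
* Degenerate inputs: an empty `used` set extracts an empty module; a
  single-term document classifies with zero edges; an all-zero mortality
  observation annotates to the empty set (below the 5% floor);
  `before_end_of` on the first stage degenerates to `during`.

## Known limitations

* The reasoner covers the pattern fragment only: no disjointness,
  negation, role chains, or general OWL consistency checking.
* One linear chain of major life stages; overlapping stage subdivisions
  (instars within the larval stage) are not representable.
* The OBO parser targets the tags the toolkit uses plus verbatim
  preservation of the rest; it is not a general OBO 1.4 validator.
* Union definitions are only supported at top level and with
  equivalent-class semantics.
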