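---
title: "Enzymatic reaction SMILES, curation and route planning: methods"
author: "retrozyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzymatic reaction SMILES, curation and route planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(retrozyme))
```

# The problem

Retrosynthetic planning with biocatalysis asks: given a target molecule,
which sequence of enzyme-catalysed reactions produces it from purchasable
starting materials, and which enzyme class catalyses each step?
Sequence-to-sequence reaction models can learn this from data, but they need
(i) a textual reaction representation that carries the enzyme annotation,
(ii) a rigorously curated single-product reaction corpus, (iii) evaluation
protocols that do not reward memorisation, and (iv) a search procedure that
assembles single-step predictions into multi-step routes.  `retrozyme`
implements those four ingredients as a model-agnostic toolkit: any
single-step forward/backward predictor satisfying a small contract can be
plugged in, and deterministic lookup/template stubs plus a synthetic fixture
generator make the whole pipeline testable without a trained model.

# Enzymatic reaction SMILES and the EC token scheme

A reaction is written as a reaction SMILES, `reactants>reagents>products`
or `reactants>>products`, with molecules dot-separated.  The enzymatic
extension appends the Enzyme Commission (EC) number to the reactant side:

```
CC(=O)OCC.O|3.1.1>>CC(=O)O
```

EC numbers are hierarchical with up to four levels
(class.subclass.sub-subclass.serial); level 1 is the enzyme class (1
oxidoreductases through 7 translocases).  A *token scheme* ECk truncates
the annotation to its first k levels; EC0 removes it entirely.  Both the
ASCII `|` and the typographic divides character U+2223 are accepted on
input; ASCII is always emitted.  The enzymatic two-part grammar has no
agents field, so converting a three-part reaction folds the reagents into
the reactants (`asEnzymatic()`).

For sequence models the reaction is tokenised at the atom level (bracket
atoms, `Cl`/`Br` and `%nn` ring closures stay whole).  Because bare digits
already mean ring closures in SMILES, EC levels become bracketed tokens
with a level prefix: `v`, `u`, `t` for levels 1–3, e.g. EC 5.4.99 becomes
`[v5] [u5.4] [t5.4.99]`.  Two choices here were genuinely open and are
package decisions:

* **Cumulative paths.**  Each EC token carries the full field path down to
  its level (`[u5.4]`, not `[u4]`).  Per-level digits alone would alias
  subclasses under different parents (subclass 4 of class 5 versus subclass
  4 of class 1) and destroy the hierarchy the tokens exist to expose.
* **Level-4 prefix.**  The published prefix set covers levels 1–3 only; we
  adopt `s` for level 4 so the EC4 scheme is expressible.  The prefix is a
  constant in one place and trivially changeable.

The `>>` arrow is emitted as two `>` tokens; seq2seq file writers split the
sequence at the arrow (source = reactant + EC tokens, target = product
tokens), so the arrow itself never appears inside either file
(`writeTokenFiles()`).  Detokenisation strips token-joining spaces and is
the exact inverse on every well-formed sequence; this round trip is
property-tested over generated corpora at all five schemes.

# Canonicalisation

Uniqueness claims ("unique reaction–EC combinations", product-disjoint
splits, stock membership) are meaningless without one fixed canonical
molecular form.  `canonicalize()` applies OpenBabel canonical SMILES (via
ChemmineOB) everywhere a molecule is compared, stored or deduplicated, and
is memoised per session.  Stereochemistry is preserved verbatim —
stereo-bearing and stereo-free SMILES of the same constitution remain
distinct — because stereochemical failure modes are exactly what the
evaluation metrics need to see; a separate `ignoreStereo` switch
re-canonicalises stereo-stripped strings when a stereo-insensitive accuracy
is wanted.  Heavy-atom counts are taken from the package's own token
stream (atom tokens that are not explicit hydrogens), which is invariant
under SMILES rewriting.

# Curation rules

`curate()` canonicalises each record, folds reagents, applies four filter
rules in a fixed order, truncates the EC to the target scheme, and
deduplicates:

1. products that also occur among the reactants are removed;
2. in reactions with **more than one product**, products listed as known
   co-enzymes or common byproducts are removed — the rule is gated on the
   product count *before* its own removals, so a reaction reduced to one
   product by rule 2 is not re-entered;
3. products with fewer than 4 heavy atoms are removed (a 4-atom product is
   kept: the cut is "< 4");
4. only reactions with exactly one product and at least one reactant are
   kept.

The shipped default cofactor list covers the ubiquitous redox and
group-transfer species (NAD(P)(H), ATP/ADP/AMP, coenzyme A, phosphate,
diphosphate, water, CO2, O2, ammonia, H+) and is fully overridable from a
file; source-database supplementary lists vary, so the set is configuration,
not code.  The deduplication key is the canonical extended reaction SMILES
with reactants sorted lexicographically — record order and molecule
spelling cannot split a duplicate.  Truncating EC levels merges records
(the EC is part of the key), so unique-record counts are monotone
non-decreasing from EC0 to EC4; this inequality is asserted across many
generated datasets.  Deduplication happens after truncation to the target
scheme; unparseable inputs are counted and reported, never silently
dropped.

# Product-disjoint splits and the multitask corpus

Random splits of reaction data leak products between train and test, and a
backward model is then rewarded for memorising.  `productDisjointSplit()`
therefore groups records by canonical product and assigns whole groups to
train/validation/test (default 0.90/0.05/0.05): no product occurs in more
than one split.  Groups are placed largest-first into the split with the
greatest remaining record deficit, with seeded tie-shuffling, which is
deterministic given (dataset, seed) and lands within one product-group of
the target fractions.  The published description of which sets must not
share products is self-contradictory in one sentence; we enforce the
reading consistent with its stated intent: validation and test products
never occur in training, and test products never occur in validation.

Small enzymatic corpora are trained jointly with a large general-chemistry
corpus under integer sampling weights (9:1 by default).
`prepareMultitaskCorpus()` emits a manifest declaring the weights and can
materialise an interleaved sample in which corpus *i* contributes lines
with probability proportional to its weight; a 10,000-line 9:1 sample is
checked against the 99% binomial band around 0.9.
`emitTrainingConfig()` writes the intended downstream trainer
configuration (transformer, 6 layers, size 512, token batches of 4096,
gradient accumulation 8, adam with beta1 0.9 / beta2 0.998, learning rate
2.0 with noam decay, dropout 0.1, label smoothing 0.1) as YAML; this
package never trains a model.

# Predictors and evaluation

A forward model maps (reactants, EC) to ranked candidate products; a
backward model maps a product to ranked (precursors, EC) disconnections.
The contract — ranks 1..k without gaps, confidences in [0,1] non-increasing,
deterministic — is what the metrics and the planner rely on, and
`checkPredictionContract()` validates any external adapter
(`functionForwardModel()` / `functionBackwardModel()`).  The shipped stubs
define confidence constructively: normalised record multiplicity for the
exact-match forward lookup, normalised rule priority for the template
backward model, so planner and round-trip tests have reproducible
probabilities.

Metrics:

* **Top-k accuracy** — exact canonical match of the full payload within the
  top k.  Backward matching requires both the precursor *set*
  (order-insensitive) and the EC to match; a flag relaxes to
  substrates-only, and `ecOnlyAccuracy()` scores the EC alone (a strictly
  weaker predicate, hence always ≥ the full backward accuracy).
* **Round-trip accuracy** — a backward proposal counts iff the forward
  model's rank-1 product on the proposed (precursors, EC) regenerates the
  target; a target is correct iff any of its top-k proposals round-trips.
  One published caption reads as the opposite composition order
  ("a forward prediction followed by a backward prediction"); only the
  backward-then-forward direction evaluates the validity of a
  retrosynthetic proposal, so that is what is implemented, and this
  ambiguity is deliberately resolved here.
* **Per-class breakdowns** (levels 1 and 3) and the **7×7 level-1 confusion
  matrix** of true versus rank-1 predicted class, with a "none" column for
  empty predictions.
* **EC randomisation** — replacing test-set ECs within or across level-1
  classes while keeping substrates and products fixed measures how much of
  the signal is carried by the EC token.  The replacement pool is the
  empirical set of ECs in the dataset (mirroring "randomising the EC
  numbers in the test set"), a record's own EC is excluded within-class
  whenever an alternative exists, and singleton classes are left unchanged
  with a warning.

# Route planning

`planRoutes()` searches backwards from the target until every leaf of a
route is in the stock (solved) or a depth limit is reached.  Each
disconnection proposed by the backward model passes through a **round-trip
filter**: the forward model's rank-1 product on the proposed precursors and
EC must regenerate the parent molecule, otherwise the step is discarded.
Filtering hard (rather than down-weighting) keeps step scores in [0,1] and
mirrors the round-trip validity notion used in evaluation.  Surviving steps
are scored by the forward confidence reweighted by precursor complexity:

$$ s = p_\mathrm{fwd} \cdot \exp\!\big(-\lambda\,(\overline{c} - 1)\big) $$

where $\overline{c}$ is the mean synthetic-complexity score of the
precursors on the 1–5 scale and $\lambda \ge 0$ (default 0.25).  The
published description fixes only the ingredients (forward confidence,
complexity reweighting), not a closed form; this form is the package's
choice because it is smooth, monotone in both arguments, reduces to the
raw forward confidence at $\lambda = 0$, and never penalises minimally
complex precursors.  The default complexity scorer is a documented
heuristic on the same 1–5 scale as learned synthetic-complexity models —
$\min(5,\ 1 + 3.2(1 - e^{-(n-1)/25}) + 0.25r + 0.15 s)$ in heavy atoms
$n$, rings $r$ and stereocentres $s$ — and is pluggable, so a trained
scorer can replace it without touching the search.

The search itself is a **level-synchronous beam over whole partial
routes**: at each depth every unsolved leaf of every beam candidate is
expanded, child routes are formed from all per-leaf candidate combinations,
and the `beamWidth` best by route score are kept.  The route score is the
**product** of its step scores (an independence-style reading of the
per-step confidences; the published method does not state the
aggregation).  A molecule may not reappear on its own ancestor path, which
eliminates trivial A→B→A loops.  Ties in step and route ordering break
lexicographically on serialised precursors, making the whole search
deterministic; with the beam wide enough the returned solved set provably
equals exhaustive enumeration on toy instances, which is how the planner is
oracle-tested.  Routes serialise to nested JSON and parse back unchanged.
An interactive CLI mode (`retrozyme plan --interactive`) prints the scored
expansions one level at a time and follows a chosen branch.

# The fixture generator

`makeRawRecords()` emulates the input conditions of a multi-source
enzymatic reaction collection: seven template families (oxidation,
transamination, ester hydrolysis, decarboxylation, aldose–ketose
isomerisation, amide ligation, and a translocase-labelled oxidation) over a
closed alphabet of small aliphatic acids, alcohols and amines; four-level
EC labels whose family paths are consistent with the class chemistry
(labels only — no biochemical accuracy is claimed); duplicate emission
across named pseudo-sources; strippable cofactor products; and sub-4-atom
products, each at a configurable rate.  Defaults (60 reactions, uniform
class mix, 10% cofactor, 10% small-product, 15% duplicate injection) keep
every filter rule exercised at rates typical of raw multi-source exports
while staying desk-scale.  The generator emits its own ground truth — the
curated survivor keys per scheme, computed from its clean templates — so
tests compare curation output against an expectation the curation code
never touched.  `makeRouteScenario()` plants exactly one solvable route of
a chosen depth plus dead-end decoy disconnections, with matched stub
models, and is verified against brute-force enumeration.

What the generator deliberately does **not** emulate: the heavy class
imbalance of real collections, cofactors on the reactant side, multi-step
pathway structure in the raw records, stereochemistry-rich metabolites,
and real database identifiers.  Passing tests therefore demonstrate the
correctness of the machinery (grammar, rules, splits, metrics, search) on
controlled inputs, not the chemical coverage of any real data set.

# Numerical choices and problem sizes

Equality of molecules and reactions is exact canonical-string equality;
there are no floating-point comparisons in curation.  Confidences and
scores are plain doubles; route ordering uses exact products of step
scores.  Test and acceptance runs use desk-scale sizes chosen to keep the
whole suite fast while exercising every code path: 200-reaction corpora
for the 1,000-sequence tokenisation round trip, 25–120-reaction datasets
for curation and splits, 50 seeds for the monotonicity and disjointness
properties, 10,000-line corpus samples, and planted route scenarios of
depth 1–4 with branching 3 (well under 50 reachable states, so brute-force
enumeration stays instantaneous).

# Limitations

The package ships no trained models: lookup/template stubs define the
contract and make every protocol testable, but chemical generalisation
comes only from an external predictor plugged in through the adapters.
OpenBabel canonical SMILES is the single canonical form; mixing output
with another toolkit's canonical strings requires re-canonicalising.  The
complexity heuristic is a proxy with the right monotonicities, not a
learned synthesizability estimate.  The planner's level-synchronous beam
expands all open leaves per level; for very wide AND-branching this is
more rigid than per-molecule best-first search, in exchange for
determinism and oracle-checkable semantics.
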