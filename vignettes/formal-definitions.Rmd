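---
title: "Learning formal concept definitions from text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning formal concept definitions from text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldef)
```

## The problem

Large curated medical terminologies such as SNOMED CT define concepts
*formally*, in a tractable description logic, so that a reasoner can verify
consistency and derive implicit knowledge. Most biomedical vocabularies,
however, define concepts only by free text. `eldef` implements a pipeline
that converts such textual definitions into SNOMED CT-style formal
definitions: it learns to recognize a small set of relations (roles) between
concept mentions in definitional sentences, and assembles the predicted
relation instances into description-logic axioms.

The running example throughout the package is the disorder *baritosis*:

> "Baritosis is pneumoconiosis caused by barium dust."

from which the pipeline should recover the axiom

$$
\mathsf{Baritosis} \sqsubseteq \mathsf{Pneumoconiosis} \sqcap
\exists\,\mathsf{Causative\_agent}.\mathsf{Barium\_dust}.
$$

## The logical fragment

The package works in a deliberately restricted fragment of the description
logic $\mathcal{EL}$, which matches the shape of SNOMED CT concept
definitions:

* only *primitive inclusions* $A \sqsubseteq C$ (necessary conditions),
  never equivalences — every generated definition uses $\sqsubseteq$;
* the right-hand side is a conjunction of concept names and existential
  restrictions $\exists R.B$;
* definitions are *flat*: every filler $B$ is a concept name, never a
  compound.

The TSV dialect read by `parseTBox()` can only express this fragment, so
more general axioms (equivalences, nested fillers) are rejected at load
time by construction. Role hierarchies are supported (a role may declare a
parent) but default to flat, and the package treats the three classic
disorder roles — `Finding_site`, `Causative_agent`,
`Associated_morphology` — as unrelated.

In this fragment, entailment of an existential relationship has a closed
form: $\mathrm{TBox} \models A \sqsubseteq \exists R.B$ holds iff some
ancestor $A'$ of $A$ (in the reflexive-transitive closure of the
named-parent taxonomy) carries an explicit conjunct $\exists R'.B'$ with
$R'$ below $R$ in the role hierarchy and $B'$ below $B$ in the taxonomy.
`inferredRelationshipBase()` materializes exactly this set; `entailsTriple()`
decides single triples without materializing it. Rather than assuming the
closure rule complete, the test suite checks it against a brute-force
oracle (path enumeration over the taxonomy with an independent graph
library) on two hundred random terminologies; monotonicity — the explicit
base is a subset of the inferred base — is asserted on every generated
input. Whether role groups or richer $\mathcal{EL}^{++}$ machinery would
contribute additional inferred triples on real terminologies is outside
this fragment; the package documents the gap rather than approximating it.

```{r reasoner}
tb <- baritosisFixture()
triples(explicitRelationshipBase(tb))
triples(inferredRelationshipBase(tb))
entailsTriple(tb, "Baritosis", "Causative_agent", "Dust")
```

## Distant supervision

Manually labeled relation corpora are rare, so training data are created by
*distant supervision*: a sentence mentioning concepts $A$ and $B$ (in that
order) is aligned with every role $r$ for which $A|r|B$ is in a
relationship base, and the sentence fragment *between* the two mentions
becomes the lexical evidence for $r$. Because every emitted label is a
member of the base, aligning against the inferred base can only add
training instances relative to the explicit one — the mechanism by which
formal reasoning enlarges the training set.

Design choices where the method leaves room:

* only subject-before-object mention pairs are aligned by default, matching
  the worked examples; `bothOrders = TRUE` additionally aligns the reverse
  order and records the direction;
* a pair matching several roles emits one instance per role by default
  (`dropAmbiguous = TRUE` removes them), and there is no "no relation"
  class by default (`withNoneClass = TRUE` adds one) — the classifier
  discriminates among the target relations only;
* empty between-strings (adjacent mentions) are kept: their lexical
  features are empty but the type features remain informative;
* no cap is applied to the distance between mentions.

Concept mentions come either with the corpus (pre-annotated JSON-lines) or
from `annotateWithDictionary()`, a deterministic dictionary annotator that
matches concept labels case-insensitively at word boundaries,
longest-match-first, with ties broken by leftmost start and then
lexicographic concept id. It deliberately isolates the pipeline from the
behavior of external annotation services; word-sense disambiguation among
concepts sharing a label is out of scope (the first id wins, with a note).

## Features

Each relation instance is encoded as a set of boolean features:

* **lexical** features of the between-string — bag-of-words, word
  $n$-grams, or character $n$-grams. Character trigrams are the default:
  they capture stems, morphemes and word-order cues while keeping the
  model small. The string is lowercased and internal whitespace collapsed
  before windowing; there is no boundary padding, and `ngramScope =
  "exact"` (only length-$n$ grams) is the default, with `"up_to"`
  available. Weighted (frequency) variants and combinations of word and
  character grams are deliberately not offered;
* **semantic-type** features — exactly two per instance, the semantic type
  of the subject (`ltype:`) and of the object (`rtype:`). They impose the
  domain/range constraints of the relation on its arguments.
  `typeAssignment()` takes the types from the terminology (one type per
  concept, as in SNOMED CT) and can be overridden from a file or coarsened
  through a grouping map, emulating alternative type systems of different
  granularity.

Feature names are namespaced (`bow:`, `w2:`, `c3:`, `ltype:`, `rtype:`), so
the two channels can never collide. `writeArff()` exports instances as
sparse Weka-dialect ARFF, byte-deterministically; the tokenizer and
punctuation rules are fixed and documented here, though any external
preprocessing pipeline may differ in detail.

```{r features}
between <- "is pneumoconiosis caused by"
bow(between)
wordNgrams(between, 2)
head(charNgrams(between, 3), 8)
```

## Learning and evaluation

The reference classifier is a linear-kernel SVM with complexity $C = 1.0$
(`e1071`/libsvm, native one-vs-one multiclass); logistic regression
(`nnet::multinom`), naive Bayes (`e1071`) and random forests
(`randomForest`) are available behind the same interface, since the choice
of learner matters far less than the choice of features. The configured
SMO-style epsilon of $10^{-12}$ is recorded with the model for provenance;
libsvm's own termination tolerance is a different parameter and is left at
its default. No feature selection or hyper-parameter search is performed.

Evaluation is macro-averaged F-measure under stratified 10-fold
cross-validation. Folds are derived from the seed only; per-class
precision/recall/F1 are computed over the *pooled* predictions of all
folds (per-fold averaging is the other defensible choice; pooling is used
because it is stable for small classes). A class with no true and no
predicted positives scores F1 = 0. If the smallest class has fewer
instances than folds, the fold count is reduced with a warning.

## From predictions to definitions, and DefPre

Predicted triples are grouped by subject and assembled with
`assembleDefinition()`: triples of the designated is-a role become named
parents, all others existential conjuncts,
$\{A|R_i|B_i\} \rightarrow A \sqsubseteq \sqcap_i\, \exists R_i.B_i$.
`readBackTriples()` is the exact inverse after deduplication.
`simplifyDefinition()` optionally prunes conjuncts subsumed within the same
definition (a parent above another parent; a filler above another filler of
the same role) — a lightweight pruning, not a full redundancy-elimination
procedure — and never changes the entailed consequences.

Candidate definitions are scored against a reference terminology by
*definition precision*:

$$
\mathrm{DefPre} = \frac{|\{A|R|B \in \mathrm{Cands} :
\mathrm{TBox} \models A \sqsubseteq \exists R.B\}|}{|\mathrm{Cands}|}.
$$

Entailment, not explicit assertion, decides correctness: the candidate
`Baritosis|Causative_agent|Dust` is never asserted in the fixture yet
scores as correct, because the asserted filler `Barium_dust` is subsumed by
`Dust`. Besides this global (triple-pooled) precision, the report carries
two per-concept averages: the unweighted mean over all concepts with at
least one candidate (zero-precision concepts included) and the same mean
excluding them — both aggregations are standard ways of summarizing
per-concept quality and they can differ substantially when many concepts
yield only unusable candidates. Concepts are weighted equally, not by
candidate count. Candidates mentioning unknown ids score as not entailed
(out-of-vocabulary predictions), with a warning.

## The synthetic benchmark

Licensed terminologies and their corpora cannot ship with the package, so
`simulateTBox()` / `simulateCorpus()` / `simulateBenchmark()` generate
seeded synthetic stand-ins reproducing the statistical structure the
pipeline exploits:

* a random taxonomy tree whose first `nTypes` nodes are *type roots*;
  every descendant inherits its root's type, mirroring the use of a
  terminology's top-level classes as semantic types. A consequence worth
  noting: inferred triples preserve the argument types of their explicit
  ancestors, so type-based separability statements hold under inferred-base
  alignment too;
* each role receives a (domain type, range type) signature;
  `typeOverlap` ($\theta \in [0,1]$) sets the fraction of role pairs
  sharing their signature, realized by the partition of roles whose
  pairwise-collision fraction is closest to $\theta$ (for three roles the
  achievable values are 0, 1/3 and 1);
* `triplesPerRole` explicit axioms per role connect type-compatible
  concepts (the count is a generator parameter because some number must be
  fixed; 12 per role with 2 sentences per triple gives classes comfortably
  above the 10-fold floor);
* each role owns `patternsPerRole` short English-like connective templates
  ("is caused by", "was observed in", ...); a sentence verbalizes a triple
  as `<subject label> <template> <object label>.` with exact mention
  offsets, and with probability `patternNoise` the template is drawn from a
  different role. Noise enters the lexical channel only; type assignments
  are always correct, as they would be when types come from a curated
  resource.

Defaults — 60 concepts, 6 types, 3 roles, $\theta = 0$, 3 templates per
role, no pattern noise, 12 triples per role, 2 sentences per triple — are
the package's study conditions: three dominant disorder roles, types
disjoint across roles, and a corpus of a few hundred definitional
sentences, small enough that the whole suite runs in well under a minute.
The generated corpus verbalizes the *inferred* base, so aligning against
the explicit base yields a strict subset of the training instances.

What the generator does **not** emulate: real linguistic variation
(syntax, anaphora, discontinuous mentions), annotation errors of concept
recognizers, and the empirical frequency distribution of relations in real
corpora. Passing tests therefore demonstrate the correctness of the
machinery and the direction of the semantic-type and training-size effects,
not performance figures transferable to real corpora.

```{r benchmark}
bench <- simulateBenchmark(simConfig(seed = 1))
bench$tbox
inst <- alignCorpus(bench$corpus, bench$infrb, bench$tbox)
cv <- crossValidate(
  vectorizeInstances(inst, featureSpec(lexicalMode = "none"),
                     typeAssignment(bench$tbox)),
  config = learnerConfig(seed = 1))
cv$macro_f
```

With disjoint signatures ($\theta = 0$) the two type features alone
separate the classes and macro-F reaches 1; as signatures collapse
($\theta \to 1$) type-only performance degrades toward chance while
lexical features recover part of the signal — the qualitative finding the
benchmark is designed to reproduce. The comparison of per-concept DefPre
under inferred- versus explicit-base training is reported in the pipeline
logs rather than asserted as a hard test, since at desk scale the
difference is subject to sampling variation.

## Numerical and degenerate-input choices

* All orderings that affect output files (vocabularies, class lists,
  triple sets, instance rows) use locale-independent radix sorting, making
  every export byte-deterministic for identical inputs and seeds.
* Character offsets are 0-based and half-open everywhere.
* Ties in the annotator are broken by match length, then start offset,
  then concept id.
* An axiom must carry at least one conjunct; a definition must have at
  least one parent or existential; empty corpora and empty axiom files are
  valid inputs.
* A training fold that collapses to a single class raises an error rather
  than silently degrading.
* `simulateTBox()` refuses configurations whose `typeOverlap` demands more
  distinct signatures than `nTypes^2` provides.

## Problem sizes used in the shipped checks

The reasoner is cross-checked against the brute-force oracle on 200 random
terminologies of up to 15 concepts and 3 roles; assembly/read-back
round-trips run over 1,000 random triple sets; the learning experiments use
the default benchmark (about 200 instances at $\theta = 0$, about 1,000 at
$\theta = 1$) with 10-fold cross-validation. These sizes were chosen so
that each property is exercised well past its edge cases while the whole
suite stays fast.

## Limitations

* The reasoner covers only the flat primitive-inclusion fragment: no role
  chains, role groups, nominals, concrete domains, GCIs or bottom, and no
  OWL serialization or external reasoner bridge.
* The dictionary annotator requires literal label matches; it does not
  model the recall/precision profile of a statistical concept recognizer.
* Whole-definition quality is summarized per triple (as DefPre is defined);
  a whole-definition-correct flag is reported alongside but not aggregated
  further.
* Synthetic results are qualitative evidence about the mechanisms, not
  projections of performance on licensed terminologies.
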