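Package: eldef
Title: Learning Formal Concept Definitions from Textual Definitions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for converting textual definitions of biomedical concepts
    into formal, SNOMED CT-style description-logic definitions. Implements a
    reasoner for a restricted EL fragment (flat primitive concept inclusions
    with named existential fillers): subsumption, entailment of existential
    relationships, and explicit/inferred relationship bases. On top of it,
    distant-supervision alignment of concept-annotated sentences against a
    relationship base, lexical (bag-of-words, word and character n-gram) and
    semantic-type featurization with sparse ARFF export, multi-class relation
    classification with cross-validated macro-averaged F-measure, assembly of
    predicted relation triples into description-logic axioms, and
    entailment-based definition precision (DefPre) scoring. Includes a seeded
    generator of synthetic ontologies and definitional corpora for
    end-to-end benchmarking without licensed terminologies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, tools, jsonlite, e1071
Suggests: testthat (>= 3.0.0), nnet, randomForest, igraph, optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
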