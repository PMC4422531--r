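#' A four-concept demonstration ontology
#'
#' The classic pneumoconiosis example: Baritosis is a pneumoconiosis caused
#' by barium dust, and barium dust is a kind of dust. Two axioms:
#' \deqn{Baritosis \sqsubseteq Pneumoconiosis \sqcap
#'       \exists Causative\_agent.Barium\_dust}
#' \deqn{Barium\_dust \sqsubseteq Dust}
#' The explicit relationship base holds `Baritosis|Causative_agent|Barium_dust`
#' only; the inferred base additionally entails
#' `Baritosis|Causative_agent|Dust` because barium dust is subsumed by dust.
#'
#' @return a [TBox-class] with 4 concepts, 1 role and 2 axioms.
#' @examples
#' tb <- baritosisFixture()
#' triples(inferredRelationshipBase(tb))
#' @export
baritosisFixture <- function() {
  TBox(
    concepts = data.frame(
      id = c("Baritosis", "Pneumoconiosis", "Barium_dust", "Dust"),
      label = c("Baritosis", "pneumoconiosis", "barium dust", "dust"),
      semantic_type = c("disorder", "disorder", "substance", "substance"),
      stringsAsFactors = FALSE),
    roles = data.frame(id = "Causative_agent", label = "caused by",
                       parent = NA_character_, stringsAsFactors = FALSE),
    axioms = list(
      axiom("Baritosis", parents = "Pneumoconiosis",
            existentials = data.frame(role = "Causative_agent",
                                      filler = "Barium_dust",
                                      stringsAsFactors = FALSE)),
      axiom("Barium_dust", parents = "Dust")))
}
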