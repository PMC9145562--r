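# Canonical 21-trait registry for Temnothorax worker morphometry.
# Order is fixed: it defines the column order of specimen tables, the trait
# factor levels in the ANOVA models, and the layout of the classifier model
# matrix.

.TRAIT_CODES <- c(
  "CL", "CWb", "EL", "FRS", "ML", "MW", "NOH", "NOL", "PEH", "PEW",
  "PoOC", "PPH", "PPL", "PPW", "SL", "SPL", "SPBA", "SPST", "SPTI",
  "SPWI", "PEL"
)

.TRAIT_DESCRIPTIONS <- c(
  CL   = "maximum cephalic length in median line",
  CWb  = "maximum head capsule width behind the eyes",
  EL   = "maximum eye diameter",
  FRS  = "distance between the frontal carinae",
  ML   = "mesosoma length",
  MW   = "maximum mesosoma width",
  NOH  = "maximum petiolar node height",
  NOL  = "petiolar node length",
  PEH  = "maximum petiole height",
  PEW  = "maximum petiole width",
  PoOC = "postocular distance",
  PPH  = "maximum postpetiole height",
  PPL  = "maximum postpetiole length",
  PPW  = "maximum postpetiole width",
  SL   = "maximum straight-line scape length",
  SPL  = "propodeal spiracle to subspinal excavation distance",
  SPBA = "smallest distance between lateral spine margins at their base",
  SPST = "propodeal stigma centre to spine tip distance",
  SPTI = "distance between spine tips in dorsal view",
  SPWI = "maximum distance between outer spine margins",
  PEL  = "diagonal petiolar length in lateral view"
)

#' Canonical trait codes
#'
#' The 21 linear worker measurements used throughout the package, in their
#' fixed canonical order. All trait values are in micrometres.
#'
#' @return Character vector of 21 trait codes.
#' @export
#' @examples
#' trait_codes()
trait_codes <- function() .TRAIT_CODES

#' Trait registry
#'
#' @return A data frame with one row per trait: `code` (canonical order) and
#'   `description`.
#' @export
#' @examples
#' head(trait_registry())
trait_registry <- function() {
  data.frame(
    code = .TRAIT_CODES,
    description = unname(.TRAIT_DESCRIPTIONS[.TRAIT_CODES]),
    stringsAsFactors = FALSE
  )
}
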