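#' Small worked-example models
#'
#' `example_chain_model()` is the three-reaction linear chain used across
#' the documentation: an exchange `EX_A` admitting up to 10 units of
#' nutrient A, a conversion `R1: A -> B` gated by gene `g1`, and a biomass
#' drain `BIOMASS: B ->`. Its maximal biomass flux is 10, the uptake limit.
#'
#' @return A [metabolic_model].
#' @export
example_chain_model <- function() {
  metabolic_model(
    "chain",
    metabolites = c("A[c]", "B[c]"),
    reactions = list(
      list(id = "EX_A", stoich = c("A[c]" = -1), lb = -10, ub = 1000),
      list(id = "R1", stoich = c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 1000,
           gpr = "g1"),
      list(id = "BIOMASS", stoich = c("B[c]" = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}
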