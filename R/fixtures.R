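#' Built-in example networks
#'
#' `example_fan_network()` is the seven-reaction, three-metabolite network
#' used throughout the documentation: an import feeds metabolite B, three
#' reactions consume two molecules of B each (one export, one conversion to
#' A, one conversion to C), A and C are exported as dimers, and a
#' first-order export of B completes the fan. Reactions R3 and R5 share
#' their substrate column, so they are fully coupled under mass action with
#' ratio `theta3/theta5`; R3-R4 and R5-R6 are structurally fully coupled;
#' and R7 lacks one substrate molecule of B in comparison to R2 (and to R3
#' and R5). B is the single SCC metabolite, certified from the ODEs of both
#' A and C with relevant flux ratios `v4/v7` and `v6/v7` and relevant rate
#' constants `{theta3, theta7}` and `{theta5, theta7}`.
#'
#' `example_chain_network()` is the three-reaction chain
#' `0 -> A -> B -> 0` whose unique positive steady state is
#' `x_A = theta1/theta2`, `x_B = theta1/theta3`; both metabolites are SCC.
#'
#' @return A [metabolic_network()].
#' @export
example_fan_network <- function() {
  metabolic_network(tibble(
    id = paste0("R", 1:7),
    substrates = c("", "2 B", "2 B", "2 A", "2 B", "2 C", "B"),
    products = c("B", "", "A", "", "C", "", "")
  ), tibble(id = c("A", "B", "C")))
}

#' @rdname example_fan_network
#' @export
example_chain_network <- function() {
  metabolic_network(tibble(
    id = paste0("R", 1:3),
    substrates = c("", "A", "B"),
    products = c("A", "B", "")
  ), tibble(id = c("A", "B")))
}
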