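test_that("constructor builds consistent split stoichiometric matrices", {
  net <- example_chain_network()
  expect_equal(dim(stoich(net)), c(2L, 3L))
  expect_equal(stoich(net), n_plus(net) - n_minus(net))
  expect_true(all(n_plus(net) >= 0) && all(n_minus(net) >= 0))
  # three-reaction chain: 0->A, A->B, B->0
  expect_equal(unname(n_minus(net)["A", ]), c(0, 1, 0))
  expect_equal(unname(n_plus(net)["B", ]), c(0, 1, 0))

  fan <- example_fan_network()
  expect_equal(nrow(fan$mets), 3L)
  expect_equal(nrow(fan$rxns), 7L)

  expect_error(
    metabolic_network(tibble::tibble(id = "R1", substrates = "Z", products = ""),
                      tibble::tibble(id = "A")),
    "undeclared metabolite"
  )
  expect_error(
    metabolic_network(tibble::tibble(id = c("R1", "R1"),
                                     substrates = c("", ""),
                                     products = c("A", "A"))),
    "duplicated"
  )
})

test_that("TSV dialect round-trips bit-for-bit", {
  net <- example_fan_network()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path, format = "tsv")
  # metabolite order follows first appearance in the file; align rows
  expect_identical(n_plus(back)[rownames(n_plus(net)), ], n_plus(net))
  expect_identical(n_minus(back)[rownames(n_minus(net)), ], n_minus(net))
  expect_identical(back$rxns$lb, net$rxns$lb)
  expect_identical(back$rxns$ub, net$rxns$ub)
  # and a second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("fractional and repeated coefficients parse", {
  s <- sccnet:::parse_side("0.5 A + B + 2 A")
  expect_equal(s[["A"]], 2.5)
  expect_equal(s[["B"]], 1)
  expect_equal(sccnet:::parse_side(""), setNames(numeric(0), character(0)))
})

test_that("BiGG JSON and SBML readers recover the same network", {
  json <- jsonlite::toJSON(list(
    metabolites = list(
      list(id = "A", name = "met A", compartment = "c"),
      list(id = "B", name = "met B", compartment = "c")
    ),
    reactions = list(
      list(id = "R1", metabolites = list(A = 1), lower_bound = 0, upper_bound = 10),
      list(id = "R2", metabolites = list(A = -1, B = 1), lower_bound = -10, upper_bound = 10),
      list(id = "R3", metabolites = list(B = -1), lower_bound = 0, upper_bound = 10)
    )
  ), auto_unbox = TRUE)
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines(json, jpath)
  netj <- read_network(jpath)
  expect_equal(netj$rxns$id, c("R1", "R2", "R3"))
  expect_equal(netj$rxns$lb, c(0, -10, 0))
  expect_equal(unname(n_minus(netj)[, "R2"]), c(1, 0))

  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="c" name="met A"/>
   <species id="B" compartment="c"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb_rev" value="-10"/><parameter id="ub10" value="10"/>
   <parameter id="zero" value="0"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="R1" reversible="false" lowerFluxBound="zero" upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R2" reversible="true" lowerFluxBound="lb_rev" upperFluxBound="ub10">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R3" reversible="false" lowerFluxBound="zero" upperFluxBound="ub10">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  spath <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, spath)
  nets <- read_network(spath, format = "sbml")
  expect_identical(n_minus(nets), n_minus(netj))
  expect_identical(n_plus(nets), n_plus(netj))
  expect_equal(nets$rxns$lb, netj$rxns$lb)
})

test_that("reversible splitting produces irreversible halves with swapped sides", {
  net <- metabolic_network(tibble::tibble(
    id = c("Rin", "Rrev", "Rout"),
    substrates = c("", "A", "B"),
    products = c("A", "B", ""),
    lb = c(0, -10, 0), ub = c(20, 10, 20)
  ))
  sp <- split_reversible(net)
  expect_equal(sp$rxns$id, c("Rin", "Rrev_f", "Rrev_b", "Rout"))
  expect_true(all(sp$rxns$lb >= 0))
  expect_equal(sp$rxns$ub[sp$rxns$id == "Rrev_b"], 10)
  expect_equal(unname(n_minus(sp)[, "Rrev_b"]), unname(n_plus(sp)[, "Rrev_f"]))
  expect_equal(sp$split_map$original, c("Rrev", "Rrev"))

  # irreversible-only network is untouched
  chain <- example_chain_network()
  expect_identical(split_reversible(chain), chain)

  # reversible exchange splits into an import and an export column
  ex <- metabolic_network(tibble::tibble(
    id = c("Rex", "Rout"), substrates = c("", "A"), products = c("A", ""),
    lb = c(-5, 0), ub = c(5, 10)
  ))
  sp2 <- split_reversible(ex)
  expect_equal(unname(n_plus(sp2)[, "Rex_f"]), 1) # import 0 -> A
  expect_equal(unname(n_minus(sp2)[, "Rex_b"]), 1) # export A -> 0
  expect_equal(unname(n_minus(sp2)[, "Rex_f"]), 0)
})

test_that("blocked-reaction removal drops dead ends and orphans", {
  # chain plus dangling A -> D with D never consumed
  net <- metabolic_network(tibble::tibble(
    id = c("R1", "R2", "R3", "Rdead"),
    substrates = c("", "A", "B", "A"),
    products = c("A", "B", "", "D")
  ))
  blocked <- find_blocked(net)
  expect_equal(blocked, "Rdead")
  red <- suppressMessages(remove_blocked(net, blocked))
  expect_equal(red$rxns$id, c("R1", "R2", "R3"))
  expect_false("D" %in% red$mets$id) # orphaned metabolite dropped
  expect_gt(max_uniform_flux(red), 0)

  # fully connected chain unchanged
  chain <- example_chain_network()
  expect_identical(remove_blocked(chain, find_blocked(chain)), chain)

  # everything blocked -> empty network with a warning
  all_blocked <- metabolic_network(tibble::tibble(
    id = c("Ra", "Rb"), substrates = c("A", "B"), products = c("B", "D")
  ))
  expect_warning(
    empty <- suppressMessages(remove_blocked(all_blocked, find_blocked(all_blocked))),
    "all reactions"
  )
  expect_equal(nrow(empty$rxns), 0L)
})

test_that("preprocessed networks admit a strictly positive flux", {
  for (net in list(example_chain_network(), example_fan_network(),
                   diamond_network())) {
    pp <- preprocess_network(net)
    expect_gt(max_uniform_flux(pp), 0)
    expect_equal(stoich(pp), n_plus(pp) - n_minus(pp))
  }
})
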