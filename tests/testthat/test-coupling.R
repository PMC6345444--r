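test_that("blocked detection matches hand analysis on small fixtures", {
  chain <- example_chain_network()
  expect_equal(find_blocked(chain), character(0))

  dangling <- metabolic_network(tibble::tibble(
    id = c("R1", "R2", "R3", "Rdead"),
    substrates = c("", "A", "B", "A"),
    products = c("A", "B", "", "D")
  ))
  expect_equal(find_blocked(dangling), "Rdead")

  # pinching R2 to zero blocks the whole chain (Nv = 0 forces v1 = v2 = v3)
  fs <- flux_space(chain, ub = c(R2 = 0))
  expect_setequal(find_blocked(chain, fs), c("R1", "R2", "R3"))
})

test_that("ratio ranges agree with the flux-cone geometry", {
  chain <- example_chain_network()
  expect_equal(ratio_range(chain, "R1", "R3"), c(min = 1, max = 1),
               tolerance = 1e-8)
  expect_equal(ratio_range(chain, "R2", "R2"), c(min = 1, max = 1))

  dm <- diamond_network()
  rr <- ratio_range(dm, "Rb1", "Rin")
  expect_equal(rr[["min"]], 0, tolerance = 1e-8)
  expect_equal(rr[["max"]], 1, tolerance = 1e-8)

  # the ratio of a branch to the other branch is unbounded above
  rr2 <- ratio_range(dm, "Rb1", "Rb2")
  expect_equal(rr2[["min"]], 0, tolerance = 1e-8)
  expect_true(is.infinite(rr2[["max"]]))
})

test_that("structural couplings: chain is one class, branches split classes", {
  chain <- example_chain_network()
  cls <- coupling_classes(structural_couplings(chain))
  expect_length(cls, 1L)
  expect_setequal(cls[[1]], c("R1", "R2", "R3"))
  sc <- structural_couplings(chain)
  expect_equal(coupling_coefficient(sc, "R1", "R3"), 1, tolerance = 1e-8)

  # two independent chains -> two classes
  two <- metabolic_network(tibble::tibble(
    id = c("R1", "R2", "R3", "S1", "S2", "S3"),
    substrates = c("", "A", "B", "", "C", "D"),
    products = c("A", "B", "", "C", "D", "")
  ))
  expect_length(coupling_classes(structural_couplings(two)), 2L)

  dm <- diamond_network()
  cls_dm <- coupling_classes(structural_couplings(dm))
  expect_length(cls_dm, 1L)
  expect_setequal(cls_dm[[1]], c("Rin", "Rout"))
})

test_that("structural couplings match the extreme-ray oracle on fixtures", {
  fixtures <- list(example_chain_network(), example_fan_network(),
                   diamond_network())
  for (net in fixtures) {
    sc <- structural_couplings(net)
    oracle <- oracle_coupled_pairs(stoich(net))
    got <- tidy(sc)
    got_pairs <- if (nrow(got)) {
      lapply(seq_len(nrow(got)), function(k) sort(c(got$reaction_a[k], got$reaction_b[k])))
    } else list()
    expect_setequal(got_pairs, lapply(oracle, sort))
  }
})

test_that("structural couplings match the oracle on random small networks", {
  set.seed(42)
  for (trial in 1:10) {
    gen <- generate_network(synthetic_spec(
      seed = trial, n_chain = sample(1:2, 1), chain_len = sample(1:2, 1),
      n_dimer = sample(0:1, 1), n_background = sample(0:1, 1)))
    net <- gen$net
    if (ncol(stoich(net)) > 8) next
    sc <- structural_couplings(net)
    oracle <- oracle_coupled_pairs(stoich(net))
    got <- tidy(sc)
    got_pairs <- if (nrow(got)) {
      lapply(seq_len(nrow(got)), function(k) sort(c(got$reaction_a[k], got$reaction_b[k])))
    } else list()
    expect_setequal(got_pairs, lapply(oracle, sort))
  }
})

test_that("kinetic couplings hold at arbitrary (off-steady) states", {
  net <- example_fan_network()
  theta <- setNames(c(3, 0.5, 2, 1.5, 1, 0.8, 1.2), paste0("R", 1:7))
  kc <- kinetic_couplings(net, theta)
  expect_setequal(coupling_classes(kc)[[1]], c("R2", "R3", "R5"))
  lam35 <- coupling_coefficient(kc, "R3", "R5")
  expect_equal(lam35, theta[["R5"]] / theta[["R3"]])
  set.seed(7)
  for (k in 1:5) {
    x <- setNames(runif(3, 0.1, 5), c("A", "B", "C"))
    v <- mass_action_rates(net, theta, x)
    expect_equal(v[["R5"]] / v[["R3"]], lam35, tolerance = 1e-12)
    expect_equal(v[["R2"]] / v[["R3"]], theta[["R2"]] / theta[["R3"]],
                 tolerance = 1e-12)
  }

  # zero-order imports are mutually coupled; different orders are not
  imp <- metabolic_network(tibble::tibble(
    id = c("Ia", "Ib", "Da", "Db", "Dc"),
    substrates = c("", "", "A", "B", "2 A"),
    products = c("A", "B", "", "", "")
  ))
  kci <- coupling_classes(kinetic_couplings(imp))
  expect_length(kci, 1L)
  expect_setequal(kci[[1]], c("Ia", "Ib"))
})

test_that("merging is transitive, idempotent and detects inconsistency", {
  net <- example_fan_network()
  sc <- structural_couplings(net)
  kc <- kinetic_couplings(net)
  mc <- merge_couplings(sc, kc)
  expect_setequal(coupling_classes(mc)[[1]], c("R2", "R3", "R4", "R5", "R6"))

  # commutative + idempotent (same classes and coefficients)
  mc2 <- merge_couplings(kc, sc)
  expect_identical(mc$class_rep, mc2$class_rep)
  mc3 <- merge_couplings(mc, mc)
  expect_identical(mc$class_rep, mc3$class_rep)
  expect_equal(coupling_coefficient(mc, "R3", "R4"),
               coupling_coefficient(mc3, "R3", "R4"))

  # merging with an edge-free relation concatenates the partition unchanged
  two <- metabolic_network(tibble::tibble(
    id = c("R1", "R2", "R3", "S1", "S2", "S3"),
    substrates = c("", "A", "B", "", "C", "D"),
    products = c("A", "B", "", "C", "D", "")
  ))
  trivial <- sccnet:::new_coupling_relation(two$rxns$id, NULL)
  m2 <- merge_couplings(structural_couplings(two), trivial)
  expect_length(coupling_classes(m2), 2L)
  # while the kinetic relation joins them: the two zero-order imports are
  # constant-rate, hence fully coupled, bridging the chains
  m3 <- merge_couplings(structural_couplings(two), kinetic_couplings(two))
  expect_length(coupling_classes(m3), 1L)

  # an inconsistent coefficient cycle (2 * 3 * 1/5 != 1) raises
  rxns <- c("Ra", "Rb", "Rc")
  e1 <- tibble::tibble(a = c("Ra", "Rb"), b = c("Rb", "Rc"),
                       lam = list(sccnet:::lam(2), sccnet:::lam(3)),
                       provenance = "structural")
  e2 <- tibble::tibble(a = "Ra", b = "Rc", lam = list(sccnet:::lam(5)),
                       provenance = "structural")
  r1 <- sccnet:::new_coupling_relation(rxns, e1)
  r2 <- sccnet:::new_coupling_relation(rxns, e2)
  expect_error(merge_couplings(r1, r2), "inconsistent")
})

test_that("coupling coefficients satisfy reciprocity and transitivity", {
  net <- example_fan_network()
  theta <- setNames(c(3, 0.5, 2, 1.5, 1, 0.8, 1.2), paste0("R", 1:7))
  mc <- merge_couplings(structural_couplings(net), kinetic_couplings(net, theta))
  cls <- coupling_classes(mc)[[1]]
  for (a in cls) for (b in cls) {
    lab <- coupling_coefficient(mc, a, b)
    lba <- coupling_coefficient(mc, b, a)
    expect_equal(lab * lba, 1, tolerance = 1e-9)
  }
  l34 <- coupling_coefficient(mc, "R3", "R4")
  l45 <- coupling_coefficient(mc, "R4", "R5")
  l35 <- coupling_coefficient(mc, "R3", "R5")
  expect_equal(l34 * l45, l35, tolerance = 1e-9)
})
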