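test_that("weighted ATP/total-flux objective matches the hand LP on the chain", {
  chain <- example_chain_network()
  cond <- condition_constraints(eps = 1e-7)
  fs <- flux_space(chain, ub = setNames(rep(10, 3), paste0("R", 1:3)))
  # v_atp := R3; maximizer is v = (10, 10, 10): z = 10 - 0.01 * 20
  opt <- optimize_weighted_objective(chain, cond, atp_rxn = "R3",
                                     w_atp = 1, w_flux = 0.01, fs = fs)
  expect_equal(opt$z_star, 10 - 0.01 * 20, tolerance = 1e-9)
  expect_equal(unname(opt$v), rep(10, 3), tolerance = 1e-7)

  # w_flux = 0 reduces to plain FBA on the ATP flux
  opt2 <- optimize_weighted_objective(chain, cond, atp_rxn = "R3",
                                      w_atp = 1, w_flux = 0, fs = fs)
  expect_equal(opt2$z_star, 10, tolerance = 1e-9)

  # fixing an exchange above its bound is an error
  expect_error(
    optimize_weighted_objective(
      chain, condition_constraints(fixed = c(R1 = 20)), atp_rxn = "R3", fs = fs),
    "outside its bounds"
  )
  # mutually exclusive interval constraints are infeasible
  expect_error(
    optimize_weighted_objective(
      chain,
      condition_constraints(box = tibble::tibble(reaction = c("R1", "R3"),
                                                 min = c(5, 0), max = c(10, 1))),
      atp_rxn = "R3", fs = fs),
    "feasible|inconsistent"
  )
})

test_that("ratio ranges at the optimum respect couplings and identity", {
  chain <- example_chain_network()
  cond <- condition_constraints()
  fs <- flux_space(chain, ub = setNames(rep(10, 3), paste0("R", 1:3)))
  opt <- optimize_weighted_objective(chain, cond, atp_rxn = "R3", fs = fs)
  # fully coupled pair: point interval at the coupling coefficient
  rr <- ratio_range_at_optimum(chain, cond, opt$z_star, c("R1", "R3"), "R3",
                               fs = fs)
  expect_equal(rr$min, 1, tolerance = 1e-6)
  expect_equal(rr$max, 1, tolerance = 1e-6)
  # identical pair: trivially one
  rr2 <- ratio_range_at_optimum(chain, cond, opt$z_star, c("R2", "R2"), "R3",
                                fs = fs)
  expect_equal(c(rr2$min, rr2$max), c(1, 1))
})

test_that("degenerate optimal faces give non-degenerate ratio intervals", {
  # diamond: two parallel branches; maximizing the export leaves the split
  # between branches free, so the branch/export ratio spans [0, 1]
  dm <- diamond_network()
  fs <- flux_space(dm, ub = setNames(rep(10, 4), dm$rxns$id))
  cond <- condition_constraints()
  opt <- optimize_weighted_objective(dm, cond, atp_rxn = "Rout", w_flux = 0,
                                     fs = fs)
  expect_equal(opt$z_star, 10, tolerance = 1e-7)
  rr <- ratio_range_at_optimum(dm, cond, opt$z_star, c("Rb1", "Rout"), "Rout",
                               w_flux = 0, fs = fs)
  # brute force on the optimal face {v_in = v_out = 10, vb1 + vb2 = 10}:
  # vertices vb1 = 0 and vb1 = 10 - eps-floored
  expect_equal(rr$min, 0, tolerance = 1e-5)
  expect_equal(rr$max, 1, tolerance = 1e-5)

  # with the total-flux penalty the optimum still has the same structure
  # (penalty is branch-symmetric), and the interval persists
  opt2 <- optimize_weighted_objective(dm, cond, atp_rxn = "Rout",
                                      w_flux = 0.01, fs = fs)
  rr2 <- ratio_range_at_optimum(dm, cond, opt2$z_star, c("Rb1", "Rout"), "Rout",
                                w_flux = 0.01, fs = fs)
  expect_equal(rr2$min, 0, tolerance = 1e-5)
  expect_equal(rr2$max, 1, tolerance = 1e-5)
})

test_that("scaled and literal objective-pinning modes agree when t = 1", {
  chain <- example_chain_network()
  cond <- condition_constraints(fixed = c(R1 = 1))
  fs <- flux_space(chain, ub = setNames(rep(10, 3), paste0("R", 1:3)))
  opt <- optimize_weighted_objective(chain, cond, atp_rxn = "R3", fs = fs)
  # the fixed exchange forces v = (1,1,1): the optimal face is the single
  # point with v_den = 1, so the Charnes-Cooper scaling sits at t = 1 and
  # the literal (unscaled) objective constraint is consistent
  for (mode in c("scaled", "literal")) {
    rr <- ratio_range_at_optimum(chain, cond, opt$z_star, c("R2", "R3"), "R3",
                                 mode = mode, fs = fs)
    expect_equal(rr$min, 1, tolerance = 1e-6)
    expect_equal(rr$max, 1, tolerance = 1e-6)
  }
})

test_that("shrinking exchange boxes never widens the ratio interval", {
  dm <- diamond_network()
  fs <- flux_space(dm, ub = setNames(rep(10, 4), dm$rxns$id))
  boxes <- list(c(1, 10), c(2, 8), c(4, 6))
  widths <- vapply(boxes, function(b) {
    cond <- condition_constraints(box = tibble::tibble(
      reaction = "Rin", min = b[1], max = b[2]))
    opt <- optimize_weighted_objective(dm, cond, atp_rxn = "Rout", w_flux = 0.01,
                                       fs = fs)
    rr <- ratio_range_at_optimum(dm, cond, opt$z_star, c("Rb1", "Rout"), "Rout",
                                 w_flux = 0.01, fs = fs)
    rr$max - rr$min
  }, numeric(1))
  expect_true(all(diff(widths) <= 1e-7))
})

test_that("LP-estimated ranges recover the fan's point prediction", {
  fan <- example_fan_network()
  theta <- setNames(c(3, 0.5, 2, 1.5, 1, 0.8, 1.2), paste0("R", 1:7))
  ss <- integrate_to_steady_state(fan, theta, c(A = 1, B = 1, C = 1))
  certs <- find_scc(fan, merged_couplings(fan))
  # constrain every exchange to its simulated value: the relevant ratio is
  # then pinned, and the prediction must equal the simulated concentration
  ex <- fan$rxns$id[fan$rxns$exchange]
  cond <- condition_constraints(fixed = ss$v_star[ex])
  rng <- lp_concentration_ranges(certs, theta, cond, atp_rxn = "R3",
                                 w_atp = 1, w_flux = 0.01)
  expect_equal(rng$metabolite, "B")
  expect_equal(rng$lower, ss$x_star[["B"]], tolerance = 1e-4)
  expect_equal(rng$upper, ss$x_star[["B"]], tolerance = 1e-4)
})
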