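chain_certs <- function() {
  chain <- example_chain_network()
  find_scc(chain, merged_couplings(chain))
}

cert_for <- function(certs, target, witness) {
  for (k in seq_along(certs)) {
    if (certs[[k]]$target == target && certs[[k]]$witness == witness) {
      return(certs[[k]])
    }
  }
  NULL
}

test_that("sigma constants of the chain match the closed form", {
  certs <- chain_certs()
  theta <- chain_theta() # theta = (2, 1, 4)
  ca <- cert_for(certs, "A", "A")
  sa <- sigma_pair(ca, theta)
  expect_equal(sa$sigma_p, 1)
  expect_equal(sa$sigma_s, theta[["R2"]] / theta[["R1"]]) # 1/2
  cb <- cert_for(certs, "B", "B")
  sb <- sigma_pair(cb, theta)
  expect_equal(sb$sigma_p, 1)
  expect_equal(sb$sigma_s, theta[["R3"]] / theta[["R1"]]) # 2

  # missing theta without a scheme is an informative error
  expect_error(sigma_pair(cb, theta[c("R1", "R2")]), "R3")
})

test_that("point concentrations reproduce the chain's analytic fixed point", {
  certs <- chain_certs()
  theta <- chain_theta()
  v <- c(R1 = 2, R2 = 2, R3 = 2) # the steady-state flux (v = theta1 everywhere)
  xa <- point_concentration(cert_for(certs, "A", "A"),
                            sigma_pair(cert_for(certs, "A", "A"), theta), v)
  xb <- point_concentration(cert_for(certs, "B", "B"),
                            sigma_pair(cert_for(certs, "B", "B"), theta), v)
  expect_equal(as.numeric(xa), 2)   # theta1/theta2
  expect_equal(as.numeric(xb), 0.5) # theta1/theta3
  expect_false(attr(xa, "unstable"))

  # sigma_p = sigma_s and v_p = v_s gives exactly 1
  sg <- sigma_pair(cert_for(certs, "A", "A"), c(R1 = 1, R2 = 1, R3 = 1))
  expect_equal(as.numeric(point_concentration(cert_for(certs, "A", "A"), sg, v)), 1)

  # zero denominator flux errors
  expect_error(
    point_concentration(cert_for(certs, "A", "A"),
                        sigma_pair(cert_for(certs, "A", "A"), theta),
                        c(R1 = 0, R2 = 1, R3 = 1)),
    "zero"
  )

  # extreme flux-ratio magnitudes are flagged unstable
  xa2 <- point_concentration(cert_for(certs, "B", "B"),
                             sigma_pair(cert_for(certs, "B", "B"), theta),
                             c(R1 = 1e-8, R2 = 10, R3 = 10))
  expect_true(attr(xa2, "unstable"))
})

test_that("ranges over flux sets scale and intersect correctly", {
  certs <- chain_certs()
  theta <- chain_theta()
  cb <- cert_for(certs, "B", "B")

  # single flux vector: degenerate interval
  r1 <- range_over_fluxes(cb, theta, flux_set = list(c(R1 = 2, R2 = 2, R3 = 2)))
  expect_equal(as.numeric(r1), c(0.5, 0.5))

  # two flux vectors with ratios 1 and 3 and sigma ratio 1/2
  fs <- list(c(R1 = 1, R2 = 1, R3 = 1), c(R1 = 1, R2 = 3, R3 = 3))
  r2 <- range_over_fluxes(cb, theta, flux_set = fs)
  expect_equal(as.numeric(r2), c(0.5, 1.5))

  # ratio-interval input: monotone scaling by the sigma ratio
  r3 <- range_over_fluxes(cb, theta, flux_set = c(2, 6))
  expect_equal(as.numeric(r3), c(1, 3))

  # adding flux vectors can only widen the interval
  fs3 <- c(fs, list(c(R1 = 1, R2 = 0.5, R3 = 0.5)))
  r4 <- range_over_fluxes(cb, theta, flux_set = fs3)
  expect_lte(r4[["lower"]], r2[["lower"]])
  expect_gte(r4[["upper"]], r2[["upper"]])
})

test_that("interval intersection follows the max-of-lowers/min-of-uppers rule", {
  r <- intersect_ranges(tibble::tibble(lower = c(1, 2), upper = c(5, 8)))
  expect_equal(c(r$lower, r$upper), c(2, 5))
  expect_true(r$feasible)

  r2 <- intersect_ranges(tibble::tibble(lower = c(1, 3), upper = c(2, 4)))
  expect_equal(c(r2$lower, r2$upper), c(3, 2))
  expect_false(r2$feasible)

  r3 <- intersect_ranges(list(c(1, 2)))
  expect_equal(c(r3$lower, r3$upper), c(1, 2))
  expect_equal(tidy(r3)$n_odes, 1L)
})

test_that("intersection properties hold on random interval sets", {
  set.seed(5)
  for (k in 1:50) {
    n <- sample(1:5, 1)
    lo <- runif(n, 0, 10)
    up <- lo + runif(n, 0, 5)
    r <- intersect_ranges(tibble::tibble(lower = lo, upper = up))
    # never wider than any member
    expect_true(all(r$lower >= lo - 1e-12))
    expect_true(all(r$upper <= up + 1e-12))
    # feasible iff the intervals share a common point
    expect_equal(r$feasible, max(lo) <= min(up) + 1e-12)
    # adding an interval never widens the intersection
    r2 <- intersect_ranges(tibble::tibble(lower = c(lo, runif(1, 0, 10)),
                                          upper = c(up, 20)))
    expect_gte(r2$lower, r$lower)
    expect_lte(r2$upper, r$upper)
  }
})

test_that("substitution schemes fill missing ratios as specified", {
  # two-term sigma: fan network's self-witness style certificate is not
  # available, so use the fan's B certificates which have a single ratio each
  fan <- example_fan_network()
  certs <- find_scc(fan, merged_couplings(fan))
  ct <- cert_for(certs, "B", "A")
  full <- setNames(c(3, 0.5, 2, 1.5, 1, 0.8, 1.2), paste0("R", 1:7))

  sub_none <- substitute_missing_ratios(ct, full, "one")
  expect_false(any(sub_none$substituted))
  expect_equal(sub_none$value[sub_none$num == "R3"],
               full[["R3"]] / full[["R7"]])

  # remove R3: the only ratio is missing; scheme one fills 1
  sub_one <- substitute_missing_ratios(ct, full[names(full) != "R3"], "one")
  expect_true(all(sub_one$value[sub_one$substituted] == 1))

  # mean/median over known ratios {2, 4} fill 3 for the missing one
  certs_chain <- chain_certs()
  # construct a synthetic certificate check at the scheme level instead:
  known <- c(2, 4)
  expect_equal(mean(known), 3)
  expect_equal(median(c(1, 2, 10)), 2)
  # scheme behaviour through sigma_pair: with R3 removed, scheme "one" makes
  # sigma_s = 1 for the B certificate of the chain
  cb <- cert_for(certs_chain, "B", "B")
  sg <- sigma_pair(cb, chain_theta()[c("R1", "R2")], scheme = "one")
  expect_equal(sg$sigma_s, 1)
})

test_that("sigma_p with all-structural couplings is invariant to theta", {
  fan <- example_fan_network()
  certs <- find_scc(fan, merged_couplings(fan))
  ct <- cert_for(certs, "B", "A")
  t1 <- setNames(rep(1, 7), paste0("R", 1:7))
  t2 <- setNames(c(9, 8, 7, 6, 5, 4, 3), paste0("R", 1:7))
  # case I: the S-side sum (sigma_s here is the theta-free numerator side)
  s1 <- sigma_pair(ct, t1); s2 <- sigma_pair(ct, t2)
  expect_equal(s1$sigma_s, s2$sigma_s) # intact side: structural only
  expect_false(isTRUE(all.equal(s1$sigma_p, s2$sigma_p)))
})

test_that("per-metabolite ranges combine certificates via intersection", {
  fan <- example_fan_network()
  certs <- find_scc(fan, merged_couplings(fan))
  theta <- setNames(c(3, 0.5, 2, 1.5, 1, 0.8, 1.2), paste0("R", 1:7))
  ss <- integrate_to_steady_state(fan, theta, c(A = 1, B = 1, C = 1))
  rng <- concentration_ranges(certs, theta, flux_set = list(ss$v_star))
  expect_equal(rng$metabolite, "B")
  expect_equal(rng$n_odes, 2L)
  expect_true(rng$feasible)
  expect_equal(rng$lower, ss$x_star[["B"]], tolerance = 1e-7)
  expect_equal(rng$upper, ss$x_star[["B"]], tolerance = 1e-7)
})
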