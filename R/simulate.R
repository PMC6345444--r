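#' Mass-action reaction rates
#'
#' `v_i = theta_i * prod_j x_j^(Nminus[j, i])`. Reactions with no substrates
#' (zero-order imports across the system boundary) return `theta_i`.
#'
#' @param net A [metabolic_network()].
#' @param theta Named positive rate constants, one per reaction.
#' @param x Named non-negative concentration vector, one per metabolite.
#' @return Named flux vector.
#' @export
mass_action_rates <- function(net, theta, x) {
  ids <- net$rxns$id
  if (!all(ids %in% names(theta))) {
    abort(sprintf("missing rate constants: %s",
                  paste(setdiff(ids, names(theta)), collapse = ", ")))
  }
  x <- x[net$mets$id]
  v <- vapply(seq_along(ids), function(k) {
    col <- net$N_minus[, k]
    nz <- which(col > 0)
    if (length(nz) == 0L) return(theta[[ids[k]]])
    theta[[ids[k]]] * prod(x[nz]^col[nz])
  }, numeric(1))
  stats::setNames(v, ids)
}

# analytic Jacobian of dx/dt = N v(x): J = N %*% dv/dx with
# dv_i/dx_j = v_i * Nminus[j, i] / x_j
mass_action_jacobian <- function(net, theta, x) {
  v <- mass_action_rates(net, theta, x)
  xs <- pmax(x[net$mets$id], 1e-300)
  dv <- t(net$N_minus) * outer(v, 1 / xs) # n x m
  stoich(net) %*% dv
}

#' Integrate a mass-action network to steady state
#'
#' Stiff integration of `dx/dt = N v(x)` with the analytic Jacobian, run in
#' geometrically growing time chunks until the relative steady-state
#' criterion `max_j |dx_j/dt| <= tol * max(1, x_j)` is met or `t_max` is
#' exhausted. The relative criterion guards metabolites whose concentrations
#' span orders of magnitude.
#'
#' @param net A [metabolic_network()].
#' @param theta Named rate constants.
#' @param x0 Named positive initial concentrations.
#' @param tol Steady-state tolerance (default 1e-10).
#' @param t_max Maximum integration time (default 1e7).
#' @param guard Divergence guard: integration stops non-converged when any
#'   concentration exceeds this value (default 1e12).
#' @return A `steady_state` object: `x_star`, `v_star`, `converged`,
#'   `residual`, `time`.
#' @export
integrate_to_steady_state <- function(net, theta, x0, tol = 1e-10,
                                      t_max = 1e7, guard = 1e12) {
  mets <- net$mets$id
  if (!all(mets %in% names(x0))) abort("x0 must name every metabolite")
  x <- x0[mets]
  if (any(x <= 0)) abort("initial concentrations must be > 0")

  deriv <- function(t, y, parms) {
    names(y) <- mets
    list(as.numeric(stoich(net) %*% mass_action_rates(net, theta, pmax(y, 0))))
  }
  jac <- function(t, y, parms) {
    names(y) <- mets
    mass_action_jacobian(net, theta, pmax(y, 1e-12))
  }
  residual_of <- function(y) {
    d <- abs(as.numeric(stoich(net) %*% mass_action_rates(net, theta, y)))
    max(d / pmax(1, y))
  }

  t_end <- 1
  converged <- FALSE
  t_total <- 0
  while (t_total < t_max) {
    sol <- deSolve::ode(y = x, times = c(0, t_end), func = deriv,
                        parms = NULL, jacfunc = jac, jactype = "fullusr",
                        method = "lsoda", rtol = 1e-10, atol = 1e-14)
    x <- pmax(sol[nrow(sol), -1], 0)
    names(x) <- mets
    t_total <- t_total + t_end
    if (any(!is.finite(x)) || any(x > guard)) {
      return(structure(list(x_star = x, v_star = NULL, converged = FALSE,
                            residual = Inf, time = t_total),
                       class = "steady_state"))
    }
    res <- residual_of(x)
    if (res <= tol) { converged <- TRUE; break }
    t_end <- t_end * 10
  }
  v <- mass_action_rates(net, theta, x)
  structure(
    list(x_star = x, v_star = v, converged = converged,
         residual = residual_of(x), time = t_total),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %s (residual %.3g after t = %g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$time))
  invisible(x)
}

#' @export
tidy.steady_state <- function(x, ...) {
  tibble(metabolite = names(x$x_star), concentration = as.numeric(x$x_star))
}

#' Perturbed initial-condition ensembles
#'
#' Multiplies each entry of `x0` by `(1 +/- p/100)` with the perturbation
#' level `p` and sign drawn independently per metabolite from the seeded
#' generator; reproducible for a fixed seed.
#'
#' @param x0 Named positive base initial condition.
#' @param pct_levels Perturbation percentages to draw from (default
#'   `c(1, 5, 10, 20)`).
#' @param n Number of perturbed vectors.
#' @param seed Integer seed.
#' @param single_metabolite If `TRUE`, perturb one randomly chosen metabolite
#'   per vector instead of all of them.
#' @return List of `n` named vectors.
#' @export
perturb_initials <- function(x0, pct_levels = c(1, 5, 10, 20), n = 10,
                             seed = 1, single_metabolite = FALSE) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    lapply(seq_len(n), function(k) {
      m <- length(x0)
      p <- sample(pct_levels, m, replace = TRUE)
      s <- sample(c(-1, 1), m, replace = TRUE)
      fac <- 1 + s * p / 100
      if (single_metabolite) {
        pick <- sample(m, 1)
        fac[-pick] <- 1
      }
      x0 * fac
    })
  })
}

# ---- synthetic networks with planted SCC motifs --------------------------

#' Specification for a synthetic mass-action network
#'
#' The generator plants motifs whose metabolites provably have structurally
#' constrained concentrations, optionally extends motif exports into
#' background conversion chains, and samples rate constants log-uniformly.
#' Every generated network converges to a unique positive steady state from
#' positive initial conditions, which makes the ensemble a clean oracle for
#' the certificate identity.
#'
#' @param seed Integer seed.
#' @param n_chain Number of linear chain motifs (`0 -> M1 -> ... -> 0`).
#' @param chain_len Number of interior metabolites per chain motif (scalar or
#'   range to sample from; default 2).
#' @param n_dimer Number of dimerization motifs (`0 -> A, 2A -> B, B -> 0`).
#' @param n_fan Number of shared-substrate fan motifs (the seven-reaction
#'   pattern with one SCC metabolite certified from two witness ODEs).
#' @param n_background Number of background conversion reactions appended to
#'   randomly chosen motif exports (each rewires an export `X -> 0` into
#'   `X -> G -> 0` through a fresh metabolite).
#' @param theta_decades Rate constants are drawn log-uniformly over this many
#'   decades centred on 1 (default 2).
#' @param x0_range Range of initial concentrations, drawn log-uniformly
#'   (default `c(0.1, 10)`).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1, n_chain = 1, chain_len = 2, n_dimer = 0,
                           n_fan = 0, n_background = 0, theta_decades = 2,
                           x0_range = c(0.1, 10)) {
  structure(list(seed = seed, n_chain = n_chain, chain_len = chain_len,
                 n_dimer = n_dimer, n_fan = n_fan,
                 n_background = n_background, theta_decades = theta_decades,
                 x0_range = x0_range),
            class = "synthetic_spec")
}

#' Generate a synthetic mass-action network
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `net` (a [metabolic_network()]), `theta` (named rate
#'   constants), `x0` (named initial concentrations), and `n_planted` (the
#'   number of metabolites guaranteed to be SCC by construction).
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed)
  rxn_rows <- list()
  met_ids <- character(0)
  n_planted <- 0L
  mk_id <- local({
    counter <- 0L
    function(prefix) {
      counter <<- counter + 1L
      sprintf("%s%d", prefix, counter)
    }
  })
  add_rxn <- function(subs, prods) {
    id <- mk_id("R")
    rxn_rows[[id]] <<- tibble(id = id, substrates = list(subs),
                              products = list(prods), lb = 0, ub = 1000)
    id
  }
  new_met <- function() {
    id <- mk_id("M")
    met_ids <<- c(met_ids, id)
    id
  }

  exports <- character(0) # (reaction id, metabolite) candidates for rewiring
  export_met <- character(0)

  chain_lens <- if (length(spec$chain_len) > 1) {
    sample(seq(min(spec$chain_len), max(spec$chain_len)), spec$n_chain, replace = TRUE)
  } else rep(spec$chain_len, spec$n_chain)

  for (c_i in seq_len(spec$n_chain)) {
    len <- chain_lens[c_i]
    ms <- replicate(len, new_met())
    add_rxn(stats::setNames(numeric(0), character(0)), stats::setNames(1, ms[1]))
    if (len > 1) {
      for (k in seq_len(len - 1)) {
        add_rxn(stats::setNames(1, ms[k]), stats::setNames(1, ms[k + 1]))
      }
    }
    ex <- add_rxn(stats::setNames(1, ms[len]), stats::setNames(numeric(0), character(0)))
    exports <- c(exports, ex); export_met <- c(export_met, ms[len])
    n_planted <- n_planted + len # every chain metabolite is SCC
  }

  for (d_i in seq_len(spec$n_dimer)) {
    a <- new_met(); b <- new_met()
    add_rxn(stats::setNames(numeric(0), character(0)), stats::setNames(1, a))
    add_rxn(stats::setNames(2, a), stats::setNames(1, b))
    ex <- add_rxn(stats::setNames(1, b), stats::setNames(numeric(0), character(0)))
    exports <- c(exports, ex); export_met <- c(export_met, b)
    n_planted <- n_planted + 1L # b is SCC (a is not: no column matches {a})
  }

  for (f_i in seq_len(spec$n_fan)) {
    a <- new_met(); b <- new_met(); cc <- new_met()
    add_rxn(stats::setNames(numeric(0), character(0)), stats::setNames(1, b))
    add_rxn(stats::setNames(2, b), stats::setNames(numeric(0), character(0)))
    add_rxn(stats::setNames(2, b), stats::setNames(1, a))
    add_rxn(stats::setNames(2, a), stats::setNames(numeric(0), character(0)))
    add_rxn(stats::setNames(2, b), stats::setNames(1, cc))
    add_rxn(stats::setNames(2, cc), stats::setNames(numeric(0), character(0)))
    add_rxn(stats::setNames(1, b), stats::setNames(numeric(0), character(0)))
    n_planted <- n_planted + 1L # b is SCC from the ODEs of a and cc
  }

  # background: rewire randomly chosen exports X -> 0 into X -> G -> 0;
  # preserves every planted certificate and adds further SCC metabolites
  if (spec$n_background > 0 && length(exports) > 0) {
    for (g_i in seq_len(spec$n_background)) {
      pick <- sample(length(exports), 1)
      g <- new_met()
      rid <- exports[pick]
      rxn_rows[[rid]]$products <- list(stats::setNames(1, g))
      ex <- add_rxn(stats::setNames(1, g), stats::setNames(numeric(0), character(0)))
      exports[pick] <- ex; export_met[pick] <- g
    }
  }

  if (length(rxn_rows) == 0L) abort("empty synthetic specification")
  reactions <- list_rbind(rxn_rows)
  net <- metabolic_network(reactions, tibble(id = met_ids))
  half <- spec$theta_decades / 2
  theta <- stats::setNames(10^stats::runif(nrow(reactions), -half, half),
                           reactions$id)
  x0 <- stats::setNames(exp(stats::runif(length(met_ids), log(spec$x0_range[1]),
                                         log(spec$x0_range[2]))),
                        met_ids)
  list(net = net, theta = theta, x0 = x0, n_planted = n_planted)
}

#' Simulate a steady-state ensemble from perturbed initial conditions
#'
#' Integrates the network to steady state from `n` perturbed copies of the
#' base initial condition and collects concentrations and fluxes of the
#' converged runs.
#'
#' @param net A [metabolic_network()].
#' @param theta Named rate constants.
#' @param x0 Named base initial condition.
#' @param n Ensemble size (default 10).
#' @param pct_levels Perturbation percentages (default `c(1, 5, 10, 20)`).
#' @param seed Integer seed.
#' @param ... Passed to [integrate_to_steady_state()].
#' @return List with `conc` (metabolites x runs), `flux` (reactions x runs),
#'   `ranges` (tibble metabolite/lower/upper over the ensemble),
#'   `n_converged`.
#' @export
simulate_ensemble <- function(net, theta, x0, n = 10,
                              pct_levels = c(1, 5, 10, 20), seed = 1, ...) {
  inits <- perturb_initials(x0, pct_levels, n, seed)
  states <- lapply(inits, function(z) integrate_to_steady_state(net, theta, z, ...))
  conv <- map_lgl(states, "converged")
  states <- states[conv]
  if (length(states) == 0L) abort("no ensemble member converged")
  conc <- do.call(cbind, lapply(states, function(s) s$x_star))
  flux <- do.call(cbind, lapply(states, function(s) s$v_star))
  rownames(conc) <- net$mets$id
  rownames(flux) <- net$rxns$id
  ranges <- tibble(
    metabolite = rownames(conc),
    lower = unname(apply(conc, 1, min)),
    upper = unname(apply(conc, 1, max))
  )
  list(conc = conc, flux = flux, ranges = ranges, n_converged = sum(conv))
}
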