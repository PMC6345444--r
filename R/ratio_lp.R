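#' Condition constraints for constraint-based flux estimation
#'
#' Experimental knowledge about a growth condition: fixed exchange rates
#' (e.g. growth, O2 and substrate uptake, CO2 release) and/or interval
#' constraints on exchange fluxes, plus the minimal flux floor applied to
#' every reaction.
#'
#' @param fixed Named numeric: reaction id -> fixed flux value
#'   (mmol/gDW/hr; growth in 1/hr).
#' @param box Data frame with columns `reaction`, `min`, `max` for interval
#'   constraints.
#' @param eps Minimal flux floor applied to all lower bounds (default 1e-7).
#' @return A `condition_constraints` list.
#' @export
condition_constraints <- function(fixed = NULL, box = NULL, eps = 1e-7) {
  if (eps <= 0) abort("eps must be > 0")
  structure(list(fixed = fixed, box = box, eps = eps),
            class = "condition_constraints")
}

# apply a condition to bounds: returns list(lb, ub)
condition_bounds <- function(net, fs, cond) {
  lb <- pmax(fs$lb, cond$eps)
  ub <- fs$ub
  if (!is.null(cond$box)) {
    for (k in seq_len(nrow(cond$box))) {
      r <- cond$box$reaction[k]
      if (!r %in% names(lb)) abort(sprintf("unknown reaction in condition box: %s", r))
      lb[r] <- max(lb[[r]], cond$box$min[k])
      ub[r] <- min(ub[[r]], cond$box$max[k])
    }
  }
  if (!is.null(cond$fixed)) {
    for (r in names(cond$fixed)) {
      if (!r %in% names(lb)) abort(sprintf("unknown reaction in condition: %s", r))
      if (cond$fixed[[r]] > fs$ub[[r]] + .tol_zero ||
          cond$fixed[[r]] < fs$lb[[r]] - .tol_zero) {
        abort(sprintf("condition fixes %s = %g outside its bounds [%g, %g]",
                      r, cond$fixed[[r]], fs$lb[[r]], fs$ub[[r]]))
      }
      lb[r] <- ub[r] <- cond$fixed[[r]]
    }
  }
  if (any(lb > ub + .tol_zero)) abort("condition constraints are mutually inconsistent")
  list(lb = lb, ub = pmax(ub, lb))
}

# objective vector: w_atp on the ATP reaction, -w_flux on every other flux
weighted_objective <- function(net, atp_rxn, w_atp, w_flux) {
  ids <- net$rxns$id
  if (!atp_rxn %in% ids) abort(sprintf("unknown ATP-synthesis reaction '%s'", atp_rxn))
  obj <- rep(-w_flux, length(ids))
  obj[match(atp_rxn, ids)] <- w_atp
  stats::setNames(obj, ids)
}

#' Maximize a weighted average of ATP synthesis and (negated) total flux
#'
#' Solves `max z = w_atp * v_atp - w_flux * sum_{i != atp} v_i` subject to
#' `Nv = 0`, the condition constraints, and the flux bounds with the epsilon
#' floor. The weighted objective balances ATP production against total flux;
#' the weighting reduces the effect of order-of-magnitude differences in the
#' two individual optima.
#'
#' @param net A split [metabolic_network()].
#' @param cond A [condition_constraints()].
#' @param atp_rxn Reaction id of the ATP-synthesis objective.
#' @param w_atp,w_flux Objective weights (default 1 and 0.01).
#' @param fs Base [flux_space()].
#' @return List with `z_star` (optimal value) and `v` (one optimal flux
#'   vector).
#' @export
optimize_weighted_objective <- function(net, cond = condition_constraints(),
                                        atp_rxn, w_atp = 1, w_flux = 0.01,
                                        fs = flux_space(net)) {
  bounds <- condition_bounds(net, fs, cond)
  obj <- weighted_objective(net, atp_rxn, w_atp, w_flux)
  N <- stoich(net)
  res <- lp_solve(obj, Aeq = N, beq = numeric(nrow(N)), lb = bounds$lb,
                  ub = bounds$ub, maximize = TRUE)
  if (res$status == -1) {
    abort("no feasible flux distribution under the given condition constraints")
  }
  if (res$status == 0) warn("LP iteration limit reached; optimum may be inexact")
  list(z_star = res$objective, v = res$x)
}

#' Range of a flux ratio at the weighted optimum
#'
#' Given the optimal objective value `z_star`, computes the exact range of
#' `v_num / v_den` over the optimal face by the Charnes-Cooper transformed
#' program: optimize `v_num` subject to `Nv = 0`, `v_den = 1`, the t-scaled
#' bounds, and the objective pinned to its optimum. In `mode = "scaled"`
#' (default) the objective constraint is scaled by `t`
#' (`w_atp*v_atp - w_flux*sum v = t*z_star`), the form consistent with the
#' change of variables; `mode = "literal"` keeps the unscaled constraint
#' `... = z_star`.
#'
#' @inheritParams optimize_weighted_objective
#' @param z_star Optimal value from [optimize_weighted_objective()] under the
#'   identical constraints.
#' @param pair Character vector `c(num, den)` of reaction ids.
#' @param mode `"scaled"` or `"literal"`.
#' @param t_min Lower bound for the scaling variable (default 0; the epsilon
#'   floor can be used instead).
#' @param z_tol Relative slack with which the objective is pinned
#'   (default 1e-6), guarding against solver round-off at a degenerate
#'   optimum.
#' @return A `ratio_lp_result` list: `min`, `max`, `z_star`, `t` (scaling
#'   values at the two optima), `unbounded` flag.
#' @export
ratio_range_at_optimum <- function(net, cond = condition_constraints(),
                                   z_star, pair, atp_rxn,
                                   w_atp = 1, w_flux = 0.01,
                                   mode = c("scaled", "literal"),
                                   t_min = 0, fs = flux_space(net),
                                   z_tol = 1e-6, t_cap = 1e6) {
  mode <- match.arg(mode)
  bounds <- condition_bounds(net, fs, cond)
  N <- stoich(net)
  ids <- net$rxns$id
  n <- length(ids)
  num <- pair[[1]]; den <- pair[[2]]
  stopifnot(num %in% ids, den %in% ids)
  if (num == den) {
    return(structure(list(min = 1, max = 1, z_star = z_star, t = c(NA, NA),
                          unbounded = FALSE), class = "ratio_lp_result"))
  }
  obj_row <- weighted_objective(net, atp_rxn, w_atp, w_flux)
  slack <- z_tol * max(1, abs(z_star))

  # variables (v, t)
  Aeq <- rbind(cbind(N, 0))
  beq <- numeric(nrow(N))
  eden <- numeric(n + 1); eden[match(den, ids)] <- 1
  Aeq <- rbind(Aeq, eden); beq <- c(beq, 1)

  zrow <- c(obj_row, if (mode == "scaled") -z_star else 0)
  zrhs <- if (mode == "scaled") 0 else z_star
  # pin objective within +/- slack (two inequality rows)
  A1 <- rbind(cbind(diag(n), -bounds$ub),        # v <= t*ub
              zrow,                              # obj - [t]z* <= +slack
              c(numeric(n), 1))                  # t cap
  b1 <- c(numeric(n), zrhs + slack, t_cap)
  A2 <- rbind(cbind(diag(n), -bounds$lb),        # v >= t*lb
              zrow)                              # obj - [t]z* >= -slack
  b2 <- c(numeric(n), zrhs - slack)
  if (t_min > 0) {
    A2 <- rbind(A2, c(numeric(n), 1)); b2 <- c(b2, t_min)
  }
  obj <- c(stats::setNames(numeric(n), ids), 0)
  obj[match(num, ids)] <- 1
  run <- function(maximize) {
    res <- simplex_call(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                        A3 = Aeq, b3 = beq, maximize = maximize)
    if (res$status == -1) {
      abort(sprintf("ratio program infeasible at the fixed optimum for pair %s/%s",
                    num, den))
    }
    list(val = res$objective, t = res$x[n + 1])
  }
  lo <- run(FALSE); hi <- run(TRUE)
  unbounded <- hi$t >= 0.99 * t_cap
  structure(
    list(min = lo$val, max = if (unbounded) Inf else hi$val,
         z_star = z_star, t = c(min = lo$t, max = hi$t),
         unbounded = unbounded),
    class = "ratio_lp_result"
  )
}

#' @export
print.ratio_lp_result <- function(x, ...) {
  cat(sprintf("<ratio_lp_result> ratio in [%g, %g] at z* = %g%s\n",
              x$min, x$max, x$z_star, if (x$unbounded) " (unbounded above)" else ""))
  invisible(x)
}

#' Concentration ranges from LP-estimated flux ratios
#'
#' For every certificate, estimates the relevant flux-ratio range at the
#' weighted optimum and converts it to a concentration range; per-metabolite
#' ranges are the intersections over witness ODEs.
#'
#' @param certs An `scc_certificates` object.
#' @param theta Named rate constants.
#' @param cond A [condition_constraints()].
#' @param atp_rxn,w_atp,w_flux,mode,t_min Passed to the LP layer.
#' @param cr Coupling relation (defaults to the certificates').
#' @param scheme Optional substitution scheme for missing rate constants.
#' @return A tibble as from [concentration_ranges()].
#' @export
lp_concentration_ranges <- function(certs, theta, cond, atp_rxn,
                                    w_atp = 1, w_flux = 0.01,
                                    mode = "scaled", t_min = 0,
                                    cr = attr(certs, "coupling"),
                                    scheme = NULL) {
  net <- attr(certs, "network")
  opt <- optimize_weighted_objective(net, cond, atp_rxn, w_atp, w_flux)
  rows <- list_rbind(lapply(seq_along(certs), function(k) {
    ct <- certs[[k]]
    res <- lapply(seq_along(ct$q_choices), function(qi) {
      rp <- cert_ratio_pair(ct, qi)
      rr <- tryCatch(
        ratio_range_at_optimum(net, cond, opt$z_star, rp, atp_rxn,
                               w_atp, w_flux, mode, t_min),
        error = function(e) NULL
      )
      if (is.null(rr)) return(NULL)
      sg <- sigma_pair(ct, theta, cr, q_choice = qi, scheme = scheme)
      c(sg$ratio * rr$min, sg$ratio * rr$max)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res) == 0L) {
      return(tibble(metabolite = ct$target, witness = ct$witness,
                    lower = NA_real_, upper = NA_real_))
    }
    tibble(metabolite = ct$target, witness = ct$witness,
           lower = min(map_dbl(res, 1)), upper = max(map_dbl(res, 2)))
  }))
  rows |>
    group_by(.data$metabolite) |>
    summarise(
      lower = if (any(!is.na(.data$lower))) max(.data$lower, na.rm = TRUE) else NA_real_,
      upper = if (any(!is.na(.data$upper))) min(.data$upper, na.rm = TRUE) else NA_real_,
      n_odes = sum(!is.na(.data$lower)),
      witnesses = paste(sort(unique(.data$witness[!is.na(.data$lower)])), collapse = ","),
      .groups = "drop"
    ) |>
    mutate(feasible = !is.na(.data$lower) & .data$lower <= .data$upper + .tol_zero) |>
    arrange(.data$metabolite)
}
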