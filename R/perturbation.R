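#' Minimization of metabolic adjustment (MOMA) knockout flux
#'
#' Predicts the mutant flux distribution after removing a reaction as the
#' feasible steady-state flux of minimal squared Euclidean distance to the
#' wild-type reference: `min ||v - v_ref||^2` subject to `Nv = 0`, the flux
#' bounds, and `v_ko = 0`. The strictly convex objective makes the solution
#' unique. When the named reaction is a split half of a reversible reaction,
#' both halves are knocked out jointly.
#'
#' @param net A split [metabolic_network()].
#' @param v_ref Named reference (wild-type) steady-state flux vector.
#' @param ko Reaction id to remove (an original id from before splitting is
#'   accepted and zeroes both halves).
#' @param fs A [flux_space()].
#' @return List with `status` (`"ok"` or `"infeasible"`), `v` (mutant flux
#'   or `NULL`), `distance` (Euclidean distance to the reference), `ko`
#'   (the reaction ids actually zeroed).
#' @export
moma <- function(net, v_ref, ko, fs = flux_space(net)) {
  ids <- net$rxns$id
  ko_ids <- if (ko %in% ids) ko else net$split_map$id[net$split_map$original == ko]
  if (length(ko_ids) == 0L) abort(sprintf("unknown reaction '%s'", ko))
  v_ref <- v_ref[ids]
  if (max(abs(stoich(net) %*% v_ref)) > 1e-6 * max(1, max(abs(v_ref)))) {
    abort("v_ref is not a steady-state flux (N v_ref != 0)")
  }
  if (all(abs(v_ref[ko_ids]) <= .tol_zero)) {
    return(list(status = "ok", v = v_ref, distance = 0, ko = ko_ids))
  }
  lb <- fs$lb; ub <- fs$ub
  lb[ko_ids] <- ub[ko_ids] <- 0
  if (any(lb > ub)) {
    return(list(status = "infeasible", v = NULL, distance = NA_real_, ko = ko_ids))
  }
  N <- stoich(net)
  res <- qp_project(v_ref, Aeq = N, beq = numeric(nrow(N)), lb = lb, ub = ub)
  if (res$status != 1) {
    return(list(status = "infeasible", v = NULL, distance = NA_real_, ko = ko_ids))
  }
  v <- res$x
  v[abs(v) < .tol_zero] <- 0
  list(status = "ok", v = v, distance = sqrt(sum((v - v_ref)^2)), ko = ko_ids)
}

#' SCC concentrations from a mutant flux distribution
#'
#' Applies the certificate closed form to a (predicted) mutant flux vector;
#' certificates whose relevant fluxes vanish in the mutant are reported as
#' undefined (the mutant admits no positive steady state with respect to
#' that metabolite).
#'
#' @param certs An `scc_certificates` object.
#' @param theta Named rate constants.
#' @param v_mut Named mutant flux vector.
#' @param cr Coupling relation (defaults to the certificates').
#' @return A tibble: metabolite, concentration (NA when undefined), defined.
#' @export
knockout_concentrations <- function(certs, theta, v_mut,
                                    cr = attr(certs, "coupling")) {
  if (length(certs) == 0L) {
    return(tibble(metabolite = character(0), concentration = numeric(0),
                  defined = logical(0)))
  }
  rows <- list_rbind(lapply(seq_along(certs), function(k) {
    ct <- certs[[k]]
    sg <- sigma_pair(ct, theta, cr)
    x <- tryCatch(as.numeric(point_concentration(ct, sg, v_mut)),
                  error = function(e) NA_real_)
    if (!is.na(x) && v_mut[[sg$num_rxn]] <= .tol_zero) x <- NA_real_
    tibble(metabolite = ct$target, concentration = x)
  }))
  rows |>
    group_by(.data$metabolite) |>
    summarise(concentration = if (all(is.na(.data$concentration))) NA_real_
              else mean(.data$concentration, na.rm = TRUE),
              .groups = "drop") |>
    mutate(defined = !is.na(.data$concentration))
}

#' Default logarithmic fold-change bin edges
#'
#' Twelve half-open bins on the log2 fold-change axis:
#' `(-Inf, -2.5], (-2.5, -2], ..., (2, 2.5], (2.5, Inf)`, treating up- and
#' down-regulation symmetrically.
#'
#' @return Numeric vector of 13 break points on the log2 scale.
#' @export
fold_change_edges <- function() c(-Inf, seq(-2.5, 2.5, by = 0.5), Inf)

#' Bin fold changes of SCC concentrations
#'
#' @param x_mut,x_ref Named concentration vectors (mutant, reference); `NA`
#'   mutant entries count as undefined and are excluded from the bins.
#' @param edges Break points on the log2 scale (default
#'   [fold_change_edges()]).
#' @return A tibble: metabolite, fold_change, log2_fc, bin (integer index,
#'   NA for undefined).
#' @export
fold_change_bins <- function(x_mut, x_ref, edges = fold_change_edges()) {
  mets <- names(x_ref)
  if (any(x_ref <= 0, na.rm = TRUE)) abort("reference concentrations must be > 0")
  fc <- as.numeric(x_mut[mets]) / as.numeric(x_ref[mets])
  l2 <- log2(fc)
  bin <- as.integer(cut(l2, breaks = edges, right = TRUE))
  tibble(metabolite = mets, fold_change = fc, log2_fc = l2, bin = bin)
}

#' Knockout screen with MOMA-predicted SCC responses
#'
#' For each reaction knockout: MOMA projection of the reference flux,
#' certificate-based mutant concentrations, and fold-change bins relative to
#' the reference concentrations. Optionally the kinetic knockout steady
#' state is also simulated (wild-type concentrations as initial conditions)
#' and the per-metabolite bin agreement between prediction and simulation is
#' reported, mirroring how the MOMA assumption is validated against kinetics.
#'
#' @param certs An `scc_certificates` object.
#' @param theta Named rate constants.
#' @param v_ref Named reference steady-state flux.
#' @param x_ref Named reference SCC concentrations.
#' @param kos Reaction ids to knock out (default: all reactions).
#' @param simulate If `TRUE`, also integrate the knockout kinetics and
#'   report simulated bins.
#' @param edges Fold-change bin edges (log2 scale).
#' @return A tibble with one row per (knockout, SCC metabolite).
#' @export
knockout_screen <- function(certs, theta, v_ref, x_ref, kos = NULL,
                            simulate = FALSE, edges = fold_change_edges()) {
  net <- attr(certs, "network")
  kos <- kos %||% net$rxns$id
  scc_mets <- unique(map_chr(seq_along(certs), function(k) certs[[k]]$target))
  x_ref_scc <- x_ref[scc_mets]
  out <- list()
  for (ko in kos) {
    mm <- moma(net, v_ref, ko)
    if (mm$status != "ok") {
      out[[ko]] <- tibble(ko = ko, metabolite = scc_mets, status = "infeasible",
                          fold_change = NA_real_, bin = NA_integer_,
                          sim_fold_change = NA_real_, sim_bin = NA_integer_)
      next
    }
    kc <- knockout_concentrations(certs, theta, mm$v)
    x_mut <- stats::setNames(kc$concentration, kc$metabolite)[scc_mets]
    fb <- fold_change_bins(x_mut, x_ref_scc, edges)
    sim_fc <- rep(NA_real_, length(scc_mets))
    sim_bin <- rep(NA_integer_, length(scc_mets))
    if (simulate) {
      theta_ko <- theta
      theta_ko[mm$ko] <- 0 # removing the reaction kinetically
      net_ko <- net
      keep <- !(net$rxns$id %in% mm$ko)
      net_ko$N_minus <- net$N_minus[, keep, drop = FALSE]
      net_ko$N_plus <- net$N_plus[, keep, drop = FALSE]
      net_ko$rxns <- net$rxns[keep, ]
      ss <- tryCatch(
        integrate_to_steady_state(net_ko, theta[net_ko$rxns$id], x_ref),
        error = function(e) NULL
      )
      if (!is.null(ss) && ss$converged) {
        sb <- fold_change_bins(ss$x_star[scc_mets], x_ref_scc, edges)
        sim_fc <- sb$fold_change
        sim_bin <- sb$bin
      }
    }
    out[[ko]] <- tibble(ko = ko, metabolite = scc_mets, status = "ok",
                        fold_change = fb$fold_change, bin = fb$bin,
                        sim_fold_change = sim_fc, sim_bin = sim_bin)
  }
  list_rbind(out)
}
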