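#' Compare predicted and simulated concentration bounds
#'
#' Computes, across metabolites: Pearson and Spearman correlations of the
#' lower bounds, upper bounds, and range widths; Euclidean distances between
#' the bound vectors in three variants (raw, log-transformed, and normalized
#' by the respective maximum, the latter two guarding against domination by
#' large metabolite pools); and the containment classification per
#' metabolite (predicted range inside the simulated one, overlapping it, or
#' disjoint from it).
#'
#' @param predicted Data frame with columns `metabolite`, `lower`, `upper`.
#' @param simulated Data frame with columns `metabolite`, `lower`, `upper`
#'   (simulated min/max per metabolite).
#' @return A `comparison_record` list with a [glance()] method; fields
#'   `correlations` (tibble), `distances` (tibble), `containment` (tibble),
#'   `per_metabolite` (tibble).
#' @export
compare_bounds <- function(predicted, simulated) {
  p <- as_tibble(predicted); s <- as_tibble(simulated)
  merged <- dplyr::inner_join(
    select(p, "metabolite", p_lower = "lower", p_upper = "upper"),
    select(s, "metabolite", s_lower = "lower", s_upper = "upper"),
    by = "metabolite"
  )
  if (nrow(merged) == 0L) abort("no shared metabolites to compare")
  ok <- stats::complete.cases(merged)
  m <- merged[ok, ]

  cor_or_na <- function(a, b, method) {
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  correlations <- tibble(
    quantity = rep(c("lower", "upper", "width"), each = 2),
    method = rep(c("pearson", "spearman"), times = 3),
    value = c(
      cor_or_na(m$p_lower, m$s_lower, "pearson"),
      cor_or_na(m$p_lower, m$s_lower, "spearman"),
      cor_or_na(m$p_upper, m$s_upper, "pearson"),
      cor_or_na(m$p_upper, m$s_upper, "spearman"),
      cor_or_na(m$p_upper - m$p_lower, m$s_upper - m$s_lower, "pearson"),
      cor_or_na(m$p_upper - m$p_lower, m$s_upper - m$s_lower, "spearman")
    )
  )
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  safe_log <- function(x) log10(pmax(x, 1e-300))
  maxnorm <- function(x) x / max(x)
  distances <- tibble(
    quantity = rep(c("lower", "upper"), times = 3),
    variant = rep(c("raw", "log", "maxnorm"), each = 2),
    value = c(
      euclid(m$p_lower, m$s_lower), euclid(m$p_upper, m$s_upper),
      euclid(safe_log(m$p_lower), safe_log(m$s_lower)),
      euclid(safe_log(m$p_upper), safe_log(m$s_upper)),
      euclid(maxnorm(m$p_lower), maxnorm(m$s_lower)),
      euclid(maxnorm(m$p_upper), maxnorm(m$s_upper))
    )
  )
  class_of <- function(pl, pu, sl, su) {
    if (pl >= sl - .tol_zero && pu <= su + .tol_zero) "inside"
    else if (pl <= su + .tol_zero && pu >= sl - .tol_zero) "overlap"
    else "disjoint"
  }
  per_met <- mutate(m, class = map_chr(seq_len(nrow(m)), function(k) {
    class_of(m$p_lower[k], m$p_upper[k], m$s_lower[k], m$s_upper[k])
  }))
  containment <- tibble(
    inside = sum(per_met$class == "inside"),
    overlap = sum(per_met$class == "overlap"),
    disjoint = sum(per_met$class == "disjoint"),
    undefined = sum(!ok)
  )
  structure(
    list(correlations = correlations, distances = distances,
         containment = containment, per_metabolite = per_met),
    class = "comparison_record"
  )
}

#' @export
print.comparison_record <- function(x, ...) {
  ct <- x$containment
  cat(sprintf("<comparison_record> %d metabolites: %d inside, %d overlap, %d disjoint\n",
              nrow(x$per_metabolite), ct$inside, ct$overlap, ct$disjoint))
  invisible(x)
}

#' @export
glance.comparison_record <- function(x, ...) {
  g <- function(q, m) x$correlations$value[x$correlations$quantity == q &
                                             x$correlations$method == m]
  tibble(
    pearson_lower = g("lower", "pearson"),
    pearson_upper = g("upper", "pearson"),
    spearman_lower = g("lower", "spearman"),
    spearman_upper = g("upper", "spearman"),
    dist_log_lower = x$distances$value[x$distances$quantity == "lower" &
                                         x$distances$variant == "log"],
    dist_log_upper = x$distances$value[x$distances$quantity == "upper" &
                                         x$distances$variant == "log"],
    inside = x$containment$inside,
    overlap = x$containment$overlap,
    disjoint = x$containment$disjoint
  )
}

#' Coefficient of variation per metabolite over an ensemble
#'
#' @param conc Matrix (metabolites x samples) of simulated steady-state
#'   concentrations.
#' @return A tibble: metabolite, cv.
#' @export
concentration_cv <- function(conc) {
  tibble(metabolite = rownames(conc),
         cv = apply(conc, 1, function(z) stats::sd(z) / mean(z)))
}

#' Robustness of predictions to missing rate constants
#'
#' Emulates partial kinetic knowledge: a given fraction of the relevant rate
#' constants (those entering any certificate's sigma constants) is removed
#' uniformly at random, the missing ratios are substituted per scheme, the
#' ranges recomputed over the flux set, and the result compared to the
#' simulated ranges. Removal operates on the rate-constant level, so a
#' constant shared between certificates disappears from all of them at once.
#' Only relevant rate constants are candidates, which avoids bias from
#' removing information in parts of the network with no effect on the
#' predictions.
#'
#' @param certs An `scc_certificates` object.
#' @param theta Full named rate constants.
#' @param flux_set Flux vectors (matrix or list) over which ranges are
#'   computed.
#' @param simulated Simulated ranges: tibble `metabolite`, `lower`, `upper`.
#' @param fractions Removal fractions in percent (default
#'   `c(10, 30, 50, 70, 90)`).
#' @param schemes Substitution schemes (default all three).
#' @param reps Random removals per fraction (default 100).
#' @param seed Integer seed.
#' @return A tibble: fraction, scheme, rep, metric, value.
#' @export
rate_constant_robustness <- function(certs, theta, flux_set, simulated,
                                     fractions = c(10, 30, 50, 70, 90),
                                     schemes = c("one", "mean", "median"),
                                     reps = 100, seed = 1) {
  cr <- attr(certs, "coupling")
  relevant <- sort(unique(unlist(lapply(seq_along(certs), function(k) {
    relevant_thetas(certs[[k]], cr)
  }))))
  if (length(relevant) == 0L) abort("no relevant rate constants in the certificates")
  set.seed(seed)
  # the flux-ratio intervals do not depend on theta: compute them once
  ratio_cache <- lapply(seq_along(certs), function(k) {
    ct <- certs[[k]]
    lapply(seq_along(ct$q_choices), function(qi) {
      cert_flux_ratio_interval(ct, flux_set, qi)
    })
  })
  ranges_for <- function(theta_part, sch) {
    rows <- list_rbind(lapply(seq_along(certs), function(k) {
      ct <- certs[[k]]
      vals <- unlist(lapply(seq_along(ct$q_choices), function(qi) {
        iv <- ratio_cache[[k]][[qi]]
        if (is.null(iv)) return(NULL)
        sigma_pair(ct, theta_part, cr, q_choice = qi, scheme = sch)$ratio * iv
      }))
      if (is.null(vals)) {
        return(tibble(metabolite = ct$target, lower = NA_real_, upper = NA_real_))
      }
      tibble(metabolite = ct$target, lower = min(vals), upper = max(vals))
    }))
    rows |>
      group_by(.data$metabolite) |>
      summarise(lower = max(.data$lower), upper = min(.data$upper),
                .groups = "drop")
  }
  rows <- list()
  for (frac in fractions) {
    n_rm <- max(1L, round(length(relevant) * frac / 100))
    n_rm <- min(n_rm, length(relevant))
    for (r in seq_len(reps)) {
      removed <- sample(relevant, n_rm)
      theta_part <- theta[setdiff(names(theta), removed)]
      for (sch in schemes) {
        pred <- ranges_for(theta_part, sch)
        cmp <- compare_bounds(pred, simulated)
        gl <- glance(cmp)
        rows[[length(rows) + 1L]] <- tibble(
          fraction = frac, scheme = sch, rep = r,
          metric = c("pearson_lower", "pearson_upper", "spearman_lower",
                     "spearman_upper", "dist_log_lower", "dist_log_upper"),
          value = c(gl$pearson_lower, gl$pearson_upper, gl$spearman_lower,
                    gl$spearman_upper, gl$dist_log_lower, gl$dist_log_upper)
        )
      }
    }
  }
  list_rbind(rows)
}

#' Robustness of predictions to LP-estimated flux ratios
#'
#' With full knowledge of the rate constants, replaces the simulated flux
#' ratios by ranges estimated from constraint-based optimization (weighted
#' ATP/total-flux objective constrained by the ensemble's exchange-flux
#' ranges) and compares the resulting concentration ranges with the
#' simulated ones.
#'
#' @param certs An `scc_certificates` object.
#' @param theta Named rate constants.
#' @param cond A [condition_constraints()] (typically exchange fluxes
#'   bounded by their simulated min/max).
#' @param atp_rxn,w_atp,w_flux Passed to the LP layer.
#' @param simulated Simulated ranges: tibble `metabolite`, `lower`, `upper`.
#' @return List with `prediction` (tibble) and `comparison`
#'   (a `comparison_record`).
#' @export
flux_ratio_robustness <- function(certs, theta, cond, atp_rxn,
                                  w_atp = 1, w_flux = 0.01, simulated) {
  pred <- lp_concentration_ranges(certs, theta, cond, atp_rxn, w_atp, w_flux)
  list(prediction = pred, comparison = compare_bounds(pred, simulated))
}

#' Exchange-flux box constraints from a simulated ensemble
#'
#' Builds the condition constraints used by the flux-ratio robustness
#' analysis: each exchange reaction is bounded by its minimum and maximum
#' flux over the ensemble.
#'
#' @param net A [metabolic_network()].
#' @param flux_set Matrix (reactions x samples) of steady-state fluxes.
#' @param eps Minimal flux floor.
#' @return A [condition_constraints()].
#' @export
ensemble_exchange_condition <- function(net, flux_set, eps = 1e-7) {
  ex <- net$rxns$id[net$rxns$exchange]
  box <- list_rbind(lapply(ex, function(r) {
    tibble(reaction = r, min = min(flux_set[r, ]), max = max(flux_set[r, ]))
  }))
  condition_constraints(box = box, eps = eps)
}
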