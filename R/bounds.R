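# ---- rate-constant ratios used by a certificate --------------------------

# unique theta-ratio pairs (num, den) appearing in the sigma constants of a
# certificate, across all representative combinations: the explicit
# lack-pair ratios plus ratios inside kinetic coupling coefficients
cert_ratio_pairs <- function(cert, cr = attr(cert, "coupling")) {
  pairs <- list()
  add <- function(p) {
    if (p[1] == p[2]) return()
    key <- paste(p, collapse = "\r")
    pairs[[key]] <<- p
  }
  for (qi in seq_along(cert$q_choices)) {
    tt <- sigma_terms(cert, cr, qi)
    for (term in c(tt$num, tt$den)) {
      if (!is.null(term$ratio)) add(term$ratio)
      for (p in lam_pairs_canonical(term$lam)) add(p)
    }
  }
  unname(pairs)
}

#' Complete the rate-constant ratios needed by a certificate
#'
#' When some rate constants are unknown, the missing theta ratios entering
#' the sigma constants are substituted by (i) one (all relevant rate
#' constants assumed equal), (ii) the mean, or (iii) the median of the
#' ratios that are present in the same certificate's equation. With no known
#' ratio available for mean/median, the value one is used as fallback.
#'
#' @param cert A certificate from [find_scc()].
#' @param theta Named rate constants (possibly partial).
#' @param scheme One of `"one"`, `"mean"`, `"median"`.
#' @param cr Coupling relation (defaults to the one stored on the
#'   certificate).
#' @return A tibble with columns `num`, `den`, `value`, `substituted`.
#' @export
substitute_missing_ratios <- function(cert, theta,
                                      scheme = c("one", "mean", "median"),
                                      cr = attr(cert, "coupling")) {
  scheme <- match.arg(scheme)
  pairs <- cert_ratio_pairs(cert, cr)
  if (length(pairs) == 0L) {
    return(tibble(num = character(0), den = character(0),
                  value = numeric(0), substituted = logical(0)))
  }
  vals <- map_dbl(pairs, function(p) {
    if (all(p %in% names(theta))) theta[[p[1]]] / theta[[p[2]]] else NA_real_
  })
  known <- vals[!is.na(vals)]
  fill <- switch(scheme,
                 one = 1,
                 mean = if (length(known)) mean(known) else 1,
                 median = if (length(known)) stats::median(known) else 1)
  tibble(
    num = map_chr(pairs, 1),
    den = map_chr(pairs, 2),
    value = ifelse(is.na(vals), fill, vals),
    substituted = is.na(vals)
  )
}

# lookup helper: pair value table -> function(num, den) -> numeric
pair_lookup <- function(ratios) {
  key <- paste(ratios$num, ratios$den, sep = "\r")
  function(p) {
    if (p[1] == p[2]) return(1)
    i <- match(paste(p, collapse = "\r"), key)
    if (is.na(i)) NA_real_ else ratios$value[i]
  }
}

#' Sigma constants of a certificate
#'
#' Evaluates the two structural sums of the witness ODE for one lack-set
#' representative combination. In Case II, `sigma_p` sums
#' `Nplus[j, k] * v_k / v_p` over the producers and `sigma_s` sums
#' `Nminus[j, l] * (theta_l / theta_rep(l)) * v_rep(l) / v_rep` over the
#' consumers; the flux ratios are replaced by the (constant) coupling
#' coefficients. Case I mirrors the two sides. Both constants are strictly
#' positive; `sigma_p` is theta-free whenever the intact-side couplings are
#' all structural.
#'
#' @param cert A certificate from [find_scc()].
#' @param theta Named rate constants.
#' @param cr Coupling relation (defaults to the certificate's).
#' @param q_choice Index of the representative combination (default 1).
#' @param scheme Optional substitution scheme for missing theta ratios
#'   (see [substitute_missing_ratios()]); with `NULL`, missing ratios are an
#'   error.
#' @return A `sigma_constants` object with fields `sigma_p`, `sigma_s`,
#'   `ratio` (the factor multiplying the relevant flux ratio), `num_rxn`,
#'   `den_rxn` and `q_choice`.
#' @export
sigma_pair <- function(cert, theta = NULL, cr = attr(cert, "coupling"),
                       q_choice = 1, scheme = NULL) {
  if (is.null(scheme)) {
    pairs <- cert_ratio_pairs(cert, cr)
    missing <- unique(unlist(keep(pairs, function(p) !all(p %in% names(theta)))))
    missing <- setdiff(missing, names(theta))
    if (length(missing) > 0L) {
      abort(sprintf("missing rate constants for reactions: %s (supply theta or a substitution scheme)",
                    paste(sort(missing), collapse = ", ")))
    }
    ratios <- substitute_missing_ratios(cert, theta, "one", cr) # nothing missing
  } else {
    ratios <- substitute_missing_ratios(cert, theta, scheme, cr)
  }
  look <- pair_lookup(ratios)
  term_value <- function(term) {
    val <- term$coef * term$lam$coef
    if (!is.null(term$ratio)) val <- val * look(term$ratio)
    for (p in lam_pairs_canonical(term$lam)) val <- val * look(p)
    val
  }
  tt <- sigma_terms(cert, cr, q_choice)
  s_num <- sum(map_dbl(tt$num, term_value))
  s_den <- sum(map_dbl(tt$den, term_value))
  rp <- cert_ratio_pair(cert, q_choice)
  structure(
    list(
      sigma_p = if (cert$case == "II") s_num else s_den,
      sigma_s = if (cert$case == "II") s_den else s_num,
      ratio = s_num / s_den,
      num_rxn = rp[["num"]], den_rxn = rp[["den"]],
      q_choice = q_choice, case = cert$case
    ),
    class = "sigma_constants"
  )
}

#' @export
print.sigma_constants <- function(x, ...) {
  cat(sprintf("<sigma_constants> case %s: sigma_p = %g, sigma_s = %g; x = %g * v[%s]/v[%s]\n",
              x$case, x$sigma_p, x$sigma_s, x$ratio, x$num_rxn, x$den_rxn))
  invisible(x)
}

#' Concentration of an SCC metabolite from a flux distribution
#'
#' `x_i = (sigma_num / sigma_den) * (v_num / v_den)` for the certificate's
#' relevant flux ratio. The value is flagged unstable when the two relevant
#' fluxes differ by more than `instability` orders of magnitude (numerical
#' instabilities arise when they do).
#'
#' @param cert A certificate from [find_scc()].
#' @param sigma A `sigma_constants` from [sigma_pair()].
#' @param v Named flux vector (steady state of the same network).
#' @param instability Decades of flux-ratio magnitude beyond which the value
#'   is flagged (default 6).
#' @return The concentration, with attribute `unstable`.
#' @export
point_concentration <- function(cert, sigma, v, instability = 6) {
  vn <- v[[sigma$num_rxn]]; vd <- v[[sigma$den_rxn]]
  if (!is.finite(vd) || vd <= .tol_zero) {
    abort(sprintf("flux of denominator reaction %s is zero; relevant ratio undefined",
                  sigma$den_rxn))
  }
  x <- sigma$ratio * vn / vd
  unstable <- is.finite(vn) && vn > 0 && abs(log10(vn / vd)) > instability
  attr(x, "unstable") <- unstable
  x
}

#' Concentration range of a certificate over a flux set
#'
#' Minimum and maximum of `sigma_ratio * flux_ratio` jointly over the
#' members of a flux set and over all lack-set representative combinations
#' attached to the certificate. The flux set is either a collection of
#' steady-state flux distributions (matrix with reactions in rows) or a
#' precomputed interval for the relevant flux ratio.
#'
#' @inheritParams sigma_pair
#' @param flux_set Either a numeric matrix (reactions x samples, rownames =
#'   reaction ids), a list of named flux vectors, or a length-2 numeric
#'   `c(min, max)` interval for the relevant flux ratio.
#' @param instability Passed to [point_concentration()].
#' @return `c(lower =, upper =)` with attribute `unstable`.
#' @export
range_over_fluxes <- function(cert, theta = NULL, cr = attr(cert, "coupling"),
                              flux_set, scheme = NULL, instability = 6) {
  sigmas <- lapply(seq_along(cert$q_choices), function(qi) {
    sigma_pair(cert, theta, cr, q_choice = qi, scheme = scheme)
  })
  vals <- numeric(0)
  unstable <- FALSE
  if (is.numeric(flux_set) && is.null(dim(flux_set)) && length(flux_set) == 2L) {
    if (any(flux_set < 0)) abort("ratio interval must be non-negative")
    for (sg in sigmas) vals <- c(vals, sg$ratio * flux_set)
  } else {
    ratio_iv <- lapply(seq_along(cert$q_choices), function(qi) {
      cert_flux_ratio_interval(cert, flux_set, qi, instability)
    })
    for (k in seq_along(sigmas)) {
      iv <- ratio_iv[[k]]
      if (is.null(iv)) next
      unstable <- unstable || attr(iv, "unstable")
      vals <- c(vals, sigmas[[k]]$ratio * iv)
    }
  }
  if (length(vals) == 0L) {
    abort("no member of the flux set admits the certificate's relevant flux ratio")
  }
  out <- c(lower = min(vals), upper = max(vals))
  attr(out, "unstable") <- unstable
  out
}

# min/max of the relevant flux ratio of one representative choice over a
# flux set (matrix reactions x samples or list of named vectors); NULL when
# no member has a positive denominator flux. The sigma factor is constant
# over the set, so the concentration range is sigma * this interval.
cert_flux_ratio_interval <- function(cert, flux_set, q_choice = 1,
                                     instability = 6) {
  rp <- cert_ratio_pair(cert, q_choice)
  if (is.list(flux_set)) {
    vn <- map_dbl(flux_set, rp[["num"]])
    vd <- map_dbl(flux_set, rp[["den"]])
  } else {
    if (is.null(dim(flux_set))) abort("flux_set must be a matrix or list of flux vectors")
    vn <- flux_set[rp[["num"]], ]
    vd <- flux_set[rp[["den"]], ]
  }
  ok <- is.finite(vn) & is.finite(vd) & vd > .tol_zero
  if (!any(ok)) return(NULL)
  r <- vn[ok] / vd[ok]
  out <- c(min(r), max(r))
  attr(out, "unstable") <- any(vn[ok] > 0 & abs(log10(r)) > instability)
  out
}

#' Intersect per-ODE concentration ranges
#'
#' When a metabolite's SCC can be derived from several witness ODEs, its
#' concentration must lie in the intersection of the per-ODE ranges: the
#' lower bound is the largest of the per-ODE lower bounds and the upper
#' bound the smallest of the per-ODE upper bounds. An empty intersection
#' (lower > upper) means the system of ODEs admits no positive steady state
#' for that metabolite; the range is retained with `feasible = FALSE` for
#' reporting.
#'
#' @param per_ode A data frame with columns `lower`, `upper` (one row per
#'   witness ODE; extra columns such as `witness` are carried through), or a
#'   list of length-2 numeric vectors.
#' @return A `concentration_range`: list with `lower`, `upper`, `feasible`,
#'   and the `per_ode` tibble.
#' @export
intersect_ranges <- function(per_ode) {
  if (!is.data.frame(per_ode)) {
    per_ode <- list_rbind(lapply(per_ode, function(r) {
      tibble(lower = r[[1]], upper = r[[2]])
    }))
  }
  per_ode <- as_tibble(per_ode)
  if (nrow(per_ode) == 0L) abort("need at least one per-ODE interval")
  if (any(per_ode$lower > per_ode$upper)) {
    abort("malformed per-ODE interval with lower > upper")
  }
  lower <- max(per_ode$lower)
  upper <- min(per_ode$upper)
  structure(
    list(lower = lower, upper = upper, feasible = lower <= upper + .tol_zero,
         per_ode = per_ode),
    class = "concentration_range"
  )
}

#' @export
print.concentration_range <- function(x, ...) {
  cat(sprintf("<concentration_range> [%g, %g]%s from %d ODE(s)\n",
              x$lower, x$upper, if (x$feasible) "" else " (infeasible)",
              nrow(x$per_ode)))
  invisible(x)
}

#' @export
tidy.concentration_range <- function(x, ...) {
  tibble(lower = x$lower, upper = x$upper, feasible = x$feasible,
         n_odes = nrow(x$per_ode))
}

#' Concentration ranges for all SCC metabolites
#'
#' Applies [range_over_fluxes()] per certificate and intersects the per-ODE
#' ranges per metabolite.
#'
#' @param certs An `scc_certificates` object.
#' @param theta Named rate constants (possibly partial if `scheme` given).
#' @param flux_set As in [range_over_fluxes()] (a ratio interval is only
#'   meaningful for a single certificate; pass flux vectors here).
#' @param scheme Optional substitution scheme for missing rate constants.
#' @param cr Coupling relation (defaults to the certificates').
#' @param instability Instability threshold in decades (default 6).
#' @return A tibble: metabolite, lower, upper, feasible, n_odes, witnesses,
#'   unstable.
#' @export
concentration_ranges <- function(certs, theta = NULL, flux_set, scheme = NULL,
                                 cr = attr(certs, "coupling"),
                                 instability = 6) {
  if (length(certs) == 0L) {
    return(tibble(metabolite = character(0), lower = numeric(0),
                  upper = numeric(0), feasible = logical(0),
                  n_odes = integer(0), witnesses = character(0),
                  unstable = logical(0)))
  }
  rows <- list_rbind(lapply(seq_along(certs), function(k) {
    ct <- certs[[k]]
    r <- tryCatch(
      range_over_fluxes(ct, theta, cr, flux_set, scheme, instability),
      error = function(e) NULL
    )
    if (is.null(r)) {
      return(tibble(metabolite = ct$target, witness = ct$witness,
                    lower = NA_real_, upper = NA_real_, unstable = NA))
    }
    tibble(metabolite = ct$target, witness = ct$witness,
           lower = r[["lower"]], upper = r[["upper"]],
           unstable = isTRUE(attr(r, "unstable")))
  }))
  rows |>
    group_by(.data$metabolite) |>
    summarise(
      has_range = any(!is.na(.data$lower)),
      lo = if (any(!is.na(.data$lower))) max(.data$lower, na.rm = TRUE) else NA_real_,
      up = if (any(!is.na(.data$upper))) min(.data$upper, na.rm = TRUE) else NA_real_,
      n_odes = sum(!is.na(.data$lower)),
      witnesses = paste(sort(unique(.data$witness[!is.na(.data$lower)])), collapse = ","),
      unstable = any(.data$unstable, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(feasible = .data$has_range & .data$lo <= .data$up + .tol_zero) |>
    select(metabolite = "metabolite", lower = "lo", upper = "up",
           "feasible", "n_odes", "witnesses", "unstable") |>
    arrange(.data$metabolite)
}
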