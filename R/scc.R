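#' Does one reaction lack one substrate molecule of a metabolite versus
#' another?
#'
#' Reaction `k` lacks one substrate molecule of metabolite `i` in comparison
#' to reaction `l` when their substrate columns satisfy
#' `Nminus[i, l] - Nminus[i, k] = 1` and agree on every other metabolite.
#' Under mass action the two rates then differ in order by exactly one, so
#' `v_l / v_k = (theta_l / theta_k) * x_i` at any state of the system.
#'
#' @param net A [metabolic_network()].
#' @param k,l Reaction ids (`k` is the one lacking the molecule).
#' @param i Metabolite id.
#' @return Logical scalar.
#' @export
lacks_one_substrate <- function(net, k, l, i) {
  d <- net$N_minus[, l] - net$N_minus[, k]
  near(d[[i]], 1, rel = 0, abs_floor = .tol_zero) &&
    all(abs(d[setdiff(names(d), i)]) <= .tol_zero)
}

# all reactions lacking one substrate molecule of i versus l
lack_partners <- function(net, l, i) {
  if (net$N_minus[i, l] < 1 - .tol_zero) return(character(0))
  target <- net$N_minus[, l]
  target[i] <- target[i] - 1
  key <- col_key(target)
  ids <- net$rxns$id
  ids[ids != l & apply(net$N_minus, 2, col_key) == key]
}

# producers / consumers of a metabolite
producers <- function(net, j) net$rxns$id[net$N_plus[j, ] > .tol_zero]
consumers <- function(net, j) net$rxns$id[net$N_minus[j, ] > .tol_zero]

#' Detect metabolites with structurally constrained concentrations
#'
#' Scans, for every metabolite `x_i`, the witness metabolites `x_j` adjacent
#' to the reactions consuming `x_i` and tests the SCC conditions on the ODE
#' of `x_j`: (i) every reaction on the examined side of the ODE has a
#' non-empty set of reactions lacking one substrate molecule of `x_i`
#' relative to it; (ii) the chosen lack-set union is mutually fully coupled;
#' (iii) all reactions on the opposite side are mutually fully coupled.
#' Case I examines the producing side `P_j` (witnesses drawn from products of
#' the consumers of `x_i`), Case II the consuming side `S_j` (witnesses drawn
#' from substrates, which always includes `x_i` itself).
#'
#' Every certificate pins the closed form
#' `x_i = (sigma_num / sigma_den) * (v_anchor / v_rep)`
#' where the anchor is a reaction of the intact side, the representative a
#' member of the chosen lack set, and the sigma constants depend only on
#' stoichiometry, coupling coefficients, and the relevant rate-constant
#' ratios.
#'
#' @param net A split, blocked-free [metabolic_network()].
#' @param cr The merged `coupling_relation` (structural + kinetic), from
#'   [merge_couplings()].
#' @param q_cap Maximum number of lack-set representative combinations
#'   attached per certificate (default 64; a warning reports truncation).
#' @return An object of class `scc_certificates`: a list of certificates
#'   with a [tidy()] method.
#' @export
find_scc <- function(net, cr, q_cap = 64) {
  mets <- net$mets$id
  certs <- list()
  seen <- character(0)

  for (i in mets) {
    S_i <- consumers(net, i)
    if (length(S_i) == 0L) next # never consumed: scan preconditions unmet

    M_i_P <- unique(unlist(lapply(S_i, function(r) mets[net$N_plus[, r] > .tol_zero])))
    M_i_S <- unique(unlist(lapply(S_i, function(r) mets[net$N_minus[, r] > .tol_zero])))

    for (j in M_i_P) { # Case I: lack sets on the producing side P_j
      cc <- scc_case(net, cr, i, j, case = "I", q_cap = q_cap)
      for (ct in cc) {
        key <- paste(ct$target, ct$witness, ct$case, ct$class)
        if (!key %in% seen) { certs[[length(certs) + 1L]] <- ct; seen <- c(seen, key) }
      }
    }
    for (j in M_i_S) { # Case II: lack sets on the consuming side S_j
      cc <- scc_case(net, cr, i, j, case = "II", q_cap = q_cap)
      for (ct in cc) {
        key <- paste(ct$target, ct$witness, ct$case, ct$class)
        if (!key %in% seen) { certs[[length(certs) + 1L]] <- ct; seen <- c(seen, key) }
      }
    }
  }
  structure(certs, class = "scc_certificates", network = net, coupling = cr)
}

# test conditions (i)-(iii) for one (target i, witness j, case) and build the
# certificates (one per qualifying coupling class of the lack-set union)
scc_case <- function(net, cr, i, j, case, q_cap = 64) {
  P_j <- producers(net, j)
  S_j <- consumers(net, j)
  if (length(P_j) == 0L || length(S_j) == 0L) return(list())

  lack_side <- if (case == "I") P_j else S_j   # side whose reactions need lack sets
  intact_side <- if (case == "I") S_j else P_j # side that must be mutually coupled

  if (!mutually_coupled(cr, intact_side)) return(list())

  partners <- lapply(lack_side, function(r) lack_partners(net, r, i))
  names(partners) <- lack_side
  if (any(lengths(partners) == 0L)) return(list())

  # a qualifying class must offer at least one partner for every origin
  classes_per_origin <- lapply(partners, function(p) unique(cr$class_rep[p]))
  qualifying <- Reduce(intersect, classes_per_origin)
  if (length(qualifying) == 0L) return(list())

  lapply(qualifying, function(cls) {
    q_sets <- lapply(partners, function(p) sort(p[cr$class_rep[p] == cls]))
    n_comb <- prod(lengths(q_sets))
    truncated <- n_comb > q_cap
    if (truncated) {
      warn(sprintf("certificate for %s via %s: %d representative combinations truncated to %d",
                   i, j, n_comb, q_cap))
    }
    grid <- expand.grid(q_sets, stringsAsFactors = FALSE)[seq_len(min(n_comb, q_cap)), ,
                                                          drop = FALSE]
    q_choices <- lapply(seq_len(nrow(grid)), function(r) {
      stats::setNames(as.character(grid[r, ]), names(q_sets))
    })
    anchor <- min(intact_side)
    structure(
      list(target = i, witness = j, case = case,
           P_j = sort(P_j), S_j = sort(S_j),
           lack_sets = q_sets,
           union_set = sort(unique(unlist(q_sets))),
           anchor = anchor,
           q_choices = q_choices,
           q_truncated = truncated,
           class = unname(cls)),
      class = "scc_certificate",
      network = net, coupling = cr
    )
  })
}

# denominator representative of a q choice (a member of the chosen lack set)
cert_rep <- function(cert, q_choice = 1) {
  q <- cert$q_choices[[q_choice]]
  min(q)
}

# the relevant flux ratio (numerator, denominator reaction ids)
cert_ratio_pair <- function(cert, q_choice = 1) {
  c(num = cert$anchor, den = cert_rep(cert, q_choice))
}

# symbolic sigma terms for one q choice.
# Case II: num = sigma_p over P_j (coupling coefficients only),
#          den = sigma_s^{-i} over S_j (theta ratios * coupling coefficients).
# Case I mirrors the two sides.
sigma_terms <- function(cert, cr, q_choice = 1) {
  net <- attr_net_of(cert)
  j <- cert$witness
  q <- cert$q_choices[[q_choice]]
  rep_den <- cert_rep(cert, q_choice)
  if (cert$case == "II") {
    num_side <- cert$P_j; num_coef <- net$N_plus[j, ]
    den_side <- cert$S_j; den_coef <- net$N_minus[j, ]
  } else {
    num_side <- cert$S_j; num_coef <- net$N_minus[j, ]
    den_side <- cert$P_j; den_coef <- net$N_plus[j, ]
  }
  num_terms <- lapply(num_side, function(k) {
    list(origin = k, coef = num_coef[[k]], ratio = NULL,
         lam = coupling_coefficient(cr, from = cert$anchor, to = k, numeric = FALSE))
  })
  den_terms <- lapply(den_side, function(l) {
    list(origin = l, coef = den_coef[[l]], ratio = c(l, q[[l]]),
         lam = coupling_coefficient(cr, from = rep_den, to = q[[l]], numeric = FALSE))
  })
  list(num = num_terms, den = den_terms)
}

# every certificate carries its parent network as an attribute
attr_net_of <- function(cert) attr(cert, "network")

#' @export
print.scc_certificates <- function(x, ...) {
  cat(sprintf("<scc_certificates> %d certificate(s) for %d metabolite(s)\n",
              length(x), length(unique(map_chr(x, "target")))))
  invisible(x)
}

#' All rate constants relevant to a certificate
#'
#' The theta ids entering the sigma constants: the explicit lack-pair ratios
#' plus any theta ratios inside the kinetic coupling coefficients used.
#'
#' @param cert A certificate from [find_scc()].
#' @param cr The coupling relation used for detection.
#' @return Character vector of reaction ids whose rate constants matter.
#' @export
relevant_thetas <- function(cert, cr = attr(cert, "coupling")) {
  ids <- character(0)
  for (qi in seq_along(cert$q_choices)) {
    tt <- sigma_terms(cert, cr, qi)
    for (term in c(tt$num, tt$den)) {
      if (!is.null(term$ratio) && term$ratio[1] != term$ratio[2]) {
        ids <- c(ids, term$ratio)
      }
      ids <- c(ids, names(lam_expo(term$lam)))
    }
  }
  sort(unique(ids))
}

#' @export
tidy.scc_certificates <- function(x, ...) {
  if (length(x) == 0L) {
    return(tibble(target = character(0), witness = character(0),
                  case = character(0), ratio_num = character(0),
                  ratio_den = character(0), relevant_thetas = character(0),
                  n_q = integer(0)))
  }
  cr <- attr(x, "coupling")
  list_rbind(lapply(seq_along(x), function(k) {
    ct <- x[[k]]
    rp <- cert_ratio_pair(ct)
    tibble(
      target = ct$target, witness = ct$witness, case = ct$case,
      ratio_num = rp[["num"]], ratio_den = rp[["den"]],
      relevant_thetas = paste(relevant_thetas(ct, cr), collapse = ","),
      n_q = length(ct$q_choices)
    )
  }))
}

#' Per-metabolite summary of SCC certificates
#'
#' @param certs An `scc_certificates` object.
#' @return A tibble with one row per SCC metabolite: certificate count,
#'   witnesses, number of relevant rate constants, relevant ratio pairs, and
#'   the metabolite's in-/out-degree in the network.
#' @export
certificate_summary <- function(certs) {
  if (length(certs) == 0L) {
    return(tibble(metabolite = character(0), n_certificates = integer(0),
                  witnesses = character(0), n_relevant_thetas = integer(0),
                  ratio_pairs = character(0), in_degree = integer(0),
                  out_degree = integer(0)))
  }
  net <- attr(certs, "network")
  cr <- attr(certs, "coupling")
  td <- tidy(certs)
  td |>
    group_by(.data$target) |>
    summarise(
      n_certificates = n(),
      witnesses = paste(sort(unique(.data$witness)), collapse = ","),
      ratio_pairs = paste(paste0(.data$ratio_num, "/", .data$ratio_den),
                          collapse = ";"),
      .groups = "drop"
    ) |>
    rename(metabolite = "target") |>
    mutate(
      n_relevant_thetas = map_dbl(.data$metabolite, function(m) {
        ths <- unlist(lapply(seq_along(certs), function(k) {
          if (certs[[k]]$target == m) relevant_thetas(certs[[k]], cr) else character(0)
        }))
        length(unique(ths))
      }),
      in_degree = map_dbl(.data$metabolite, function(m) length(producers(net, m))),
      out_degree = map_dbl(.data$metabolite, function(m) length(consumers(net, m)))
    ) |>
    select("metabolite", "n_certificates", "witnesses", "n_relevant_thetas",
           "ratio_pairs", "in_degree", "out_degree") |>
    arrange(.data$metabolite)
}
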