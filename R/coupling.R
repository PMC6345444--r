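#' Blocked reactions of a flux space
#'
#' A reaction is blocked when its flux is zero in every feasible steady
#' state. Each reaction's maximal flux over
#' `F = {v : Nv = 0, lb <= v <= ub}` is computed by linear programming; a
#' maximum below `tol` marks the reaction blocked.
#'
#' @param net A split, irreversible [metabolic_network()].
#' @param fs A [flux_space()].
#' @param tol Absolute flux tolerance (default 1e-9).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked <- function(net, fs = flux_space(net), tol = .tol_zero) {
  N <- stoich(net)
  n <- ncol(N)
  blocked <- character(0)
  for (k in seq_len(n)) {
    obj <- numeric(n); obj[k] <- 1
    res <- lp_solve(obj, Aeq = N, beq = numeric(nrow(N)), lb = fs$lb,
                    ub = fs$ub, maximize = TRUE)
    if (res$status == -1) {
      abort("flux space is infeasible: inconsistent bounds (Nv = 0 has no solution within lb/ub)")
    }
    if (res$objective <= tol) blocked <- c(blocked, colnames(N)[k])
  }
  blocked
}

#' Range of a flux ratio over the feasible flux space
#'
#' Computes the exact range of `v_i / v_j` over all feasible flux
#' distributions with `v_j > 0`, via the Charnes-Cooper transformation of the
#' linear-fractional program: optimize `v_i` subject to `Nv = 0`, `v_j = 1`,
#' `t*lb <= v <= t*ub`, `t >= t_min`.
#'
#' @inheritParams find_blocked
#' @param i,j Reaction ids (numerator, denominator).
#' @param t_min Lower bound on the scaling variable (default 0).
#' @param t_cap Large upper bound on the scaling variable used to detect an
#'   unbounded ratio, reported as `Inf`.
#' @return Named numeric `c(min =, max =)`; entries may be `Inf`.
#' @export
ratio_range <- function(net, i, j, fs = flux_space(net), t_min = 0,
                        t_cap = 1e6) {
  if (identical(i, j)) return(c(min = 1, max = 1))
  N <- stoich(net)
  ids <- colnames(N)
  stopifnot(i %in% ids, j %in% ids)
  n <- ncol(N)
  # variables (v_1..v_n, t)
  Aeq <- cbind(N, 0)
  beq <- numeric(nrow(N))
  ej <- numeric(n + 1); ej[match(j, ids)] <- 1
  Aeq <- rbind(Aeq, ej); beq <- c(beq, 1)
  # v_k - t*ub_k <= 0 ; t*lb_k - v_k <= 0 ; t <= t_cap ; t >= t_min
  A1 <- cbind(diag(n), -fs$ub)
  A1 <- rbind(A1, c(numeric(n), 1)); b1 <- numeric(n + 1); b1[n + 1] <- t_cap
  pos_lb <- which(fs$lb > 0)
  A2 <- NULL; b2 <- NULL
  if (length(pos_lb)) {
    A2 <- cbind(diag(n)[pos_lb, , drop = FALSE], -fs$lb[pos_lb]) # v_k - t*lb_k >= 0
    b2 <- numeric(length(pos_lb))
  }
  if (t_min > 0) {
    A2 <- rbind(A2, c(numeric(n), 1)); b2 <- c(b2, t_min)
  }
  obj <- numeric(n + 1); obj[match(i, ids)] <- 1
  solve_dir <- function(maximize) {
    res <- simplex_call(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                        A3 = Aeq, b3 = beq, maximize = maximize)
    if (res$status == -1) {
      abort(sprintf("no feasible flux with v[%s] > 0; ratio v[%s]/v[%s] undefined", j, i, j))
    }
    list(val = res$objective, t = res$x[n + 1])
  }
  lo <- solve_dir(FALSE)
  hi <- solve_dir(TRUE)
  hi_val <- hi$val
  # optimum leaning on the artificial t cap indicates an unbounded ratio
  if (hi$t >= 0.99 * t_cap) hi_val <- Inf
  c(min = lo$val, max = hi_val)
}

# ---- coupling relation container ----------------------------------------

# edges: tibble(a, b, lam = list of lam(), provenance); lam maps v_b = lam * v_a
new_coupling_relation <- function(reactions, edges, theta = NULL) {
  parent <- stats::setNames(seq_along(reactions), reactions)
  lam_to_parent <- stats::setNames(rep(list(lam(1)), length(reactions)), reactions)

  find_root <- function(r) {
    path <- character(0)
    l <- lam(1)
    while (parent[[r]] != match(r, reactions)) {
      path <- c(path, r)
      l <- lam_mul(l, lam_to_parent[[r]])
      r <- reactions[parent[[r]]]
    }
    list(root = r, lam = l) # v_r(start) = lam * v_root? see below
  }
  # invariant: v_x = lam_to_parent[[x]] (*) v_parent(x)
  # find(): v_start = l (*) v_root
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$a[k]; b <- edges$b[k]; l_ab <- edges$lam[[k]] # v_b = l_ab * v_a
      ra <- find_root(a); rb <- find_root(b)
      if (ra$root == rb$root) {
        # implied v_b = (lam_b)^-1 ... check consistency:
        implied <- lam_mul(rb$lam, lam_inv(ra$lam)) # v_b/v_a via tree
        if (!lam_equal(implied, l_ab)) {
          abort(sprintf(
            "inconsistent coupling coefficients on the cycle through %s and %s: %s vs %s",
            a, b, lam_format(implied), lam_format(l_ab)))
        }
      } else {
        # attach root(b) under root(a): v_b = rb$lam * v_rootB
        # => v_rootB = rb$lam^-1 * v_b = rb$lam^-1 * l_ab * v_a
        #            = rb$lam^-1 * l_ab * ra$lam * v_rootA
        parent[[rb$root]] <- match(ra$root, reactions)
        lam_to_parent[[rb$root]] <- lam_mul(lam_inv(rb$lam), lam_mul(l_ab, ra$lam))
      }
    }
  }

  class_rep <- character(length(reactions)); names(class_rep) <- reactions
  lam_vs_rep <- stats::setNames(vector("list", length(reactions)), reactions)
  roots <- map(reactions, find_root)
  root_ids <- map_chr(roots, "root")
  for (root in unique(root_ids)) {
    members <- reactions[root_ids == root]
    rep_id <- min(members) # deterministic representative
    rep_lam <- roots[[match(rep_id, reactions)]]$lam # v_rep = rep_lam * v_root
    for (mm in members) {
      class_rep[[mm]] <- rep_id
      # v_m = lam_m * v_root = lam_m * rep_lam^-1 * v_rep
      lam_vs_rep[[mm]] <- lam_mul(roots[[match(mm, reactions)]]$lam, lam_inv(rep_lam))
    }
  }

  structure(
    list(reactions = reactions,
         class_rep = class_rep,
         lam_vs_rep = lam_vs_rep,
         evidence = edges %||% tibble(a = character(0), b = character(0),
                                      lam = list(), provenance = character(0)),
         theta = theta),
    class = "coupling_relation"
  )
}

#' @export
print.coupling_relation <- function(x, ...) {
  sizes <- table(x$class_rep)
  cat(sprintf("<coupling_relation> %d reactions in %d classes (%d non-trivial)\n",
              length(x$reactions), length(sizes), sum(sizes > 1)))
  invisible(x)
}

#' Coupling classes of a relation
#'
#' @param cr A `coupling_relation`.
#' @return Named list of character vectors, one per class with two or more
#'   members, named by the class representative.
#' @export
coupling_classes <- function(cr) {
  cls <- split(names(cr$class_rep), cr$class_rep)
  cls[lengths(cls) > 1]
}

#' Coupling coefficient between two reactions
#'
#' Returns lambda with `v_to = lambda * v_from`, or `NULL` when the reactions
#' are not fully coupled.
#'
#' @param cr A `coupling_relation`.
#' @param from,to Reaction ids.
#' @param theta Optional named rate constants used to evaluate theta ratios.
#' @param numeric If `TRUE` return a number (`NA` when theta ratios cannot be
#'   evaluated); otherwise an internal symbolic coefficient record.
#' @export
coupling_coefficient <- function(cr, from, to, theta = cr$theta, numeric = TRUE) {
  if (cr$class_rep[[from]] != cr$class_rep[[to]]) return(NULL)
  l <- lam_mul(cr$lam_vs_rep[[to]], lam_inv(cr$lam_vs_rep[[from]]))
  if (numeric) lam_eval(l, theta) else l
}

mutually_coupled <- function(cr, ids) {
  length(unique(cr$class_rep[ids])) <= 1
}

#' @export
tidy.coupling_relation <- function(x, theta = x$theta, ...) {
  ev_key <- paste(pmin(x$evidence$a, x$evidence$b), pmax(x$evidence$a, x$evidence$b))
  rows <- list()
  for (cls in coupling_classes(x)) {
    cls <- sort(cls)
    for (i in seq_along(cls)) {
      for (j in seq_along(cls)) {
        if (i >= j) next
        a <- cls[i]; b <- cls[j]
        l <- coupling_coefficient(x, a, b, theta = theta, numeric = FALSE)
        key <- paste(a, b)
        prov <- if (key %in% ev_key) x$evidence$provenance[match(key, ev_key)] else "transitive"
        rows[[length(rows) + 1L]] <- tibble(
          reaction_a = a, reaction_b = b,
          lambda = lam_eval(l, theta),
          lambda_expr = lam_format(l),
          provenance = prov
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(reaction_a = character(0), reaction_b = character(0),
                  lambda = numeric(0), lambda_expr = character(0),
                  provenance = character(0)))
  }
  list_rbind(rows)
}

# ---- structural couplings ------------------------------------------------

# connected components of reactions sharing a metabolite (restricting the
# quadratic pair scan; reactions in different components are never coupled)
reaction_components <- function(net) {
  N <- stoich(net)
  n <- ncol(N)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      mets <- which(abs(N[, k]) > .tol_zero)
      if (length(mets) == 0L) next
      nbr <- which(colSums(abs(N[mets, , drop = FALSE]) > .tol_zero) > 0 & comp == 0L)
      comp[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  split(colnames(N), comp)
}

#' Structurally fully coupled reactions
#'
#' Two unblocked reactions are structurally fully coupled when their flux
#' ratio is the same constant `lambda > 0` in every feasible steady state,
#' which holds exactly when the Charnes-Cooper ratio program returns
#' coinciding minimum and maximum. Determined purely by the stoichiometry.
#'
#' @inheritParams find_blocked
#' @param tol Relative tolerance for ratio equality (default 1e-6).
#' @return A `coupling_relation` with provenance `"structural"`.
#' @export
structural_couplings <- function(net, fs = flux_space(net), tol = .tol_equal) {
  ids <- net$rxns$id
  edges <- list()
  done_class <- stats::setNames(seq_along(ids), ids) # incremental union-find shortcut
  same <- function(a, b) done_class[[a]] == done_class[[b]]
  unite <- function(a, b) {
    old <- done_class[[b]]
    done_class[done_class == old] <<- done_class[[a]]
  }
  for (comp in reaction_components(net)) {
    comp <- sort(comp)
    if (length(comp) < 2) next
    for (i in seq_along(comp)) {
      for (j in seq_along(comp)) {
        if (i >= j) next
        a <- comp[i]; b <- comp[j]
        if (same(a, b)) next # already coupled transitively
        rr <- ratio_range(net, b, a, fs = fs)
        if (is.finite(rr[["max"]]) && rr[["max"]] > 0 &&
            near(rr[["min"]], rr[["max"]], rel = tol)) {
          ratio <- (rr[["min"]] + rr[["max"]]) / 2 # v_b = ratio * v_a
          edges[[length(edges) + 1L]] <- tibble(
            a = a, b = b, lam = list(lam(ratio)), provenance = "structural")
          unite(a, b)
        }
      }
    }
  }
  new_coupling_relation(ids, if (length(edges)) list_rbind(edges) else NULL)
}

#' Mass-action (kinetic) couplings
#'
#' Under mass action kinetics two reactions with identical substrate columns
#' (same substrates with the same stoichiometry) have flux ratio
#' `v_l / v_k = theta_l / theta_k` at any state of the system, not only at
#' steady state. This expands the set of fully coupled reactions beyond the
#' structural ones.
#'
#' @param net A [metabolic_network()].
#' @param theta Optional named positive rate constants; when supplied the
#'   tidied coefficients are numeric, otherwise they remain symbolic
#'   theta ratios.
#' @return A `coupling_relation` with provenance `"kinetic"`.
#' @export
kinetic_couplings <- function(net, theta = NULL) {
  if (!is.null(theta) && any(theta <= 0)) abort("rate constants must be > 0")
  keys <- apply(net$N_minus, 2, col_key)
  groups <- split(net$rxns$id, keys)
  edges <- list()
  for (g in groups) {
    if (length(g) < 2) next
    g <- sort(g)
    for (i in seq_along(g)) {
      for (k in seq_along(g)) {
        if (i >= k) next
        # v_gk = (theta_gk / theta_gi) * v_gi, at any state of the system
        edges[[length(edges) + 1L]] <- tibble(
          a = g[i], b = g[k],
          lam = list(lam(1, list(c(g[k], g[i])))),
          provenance = "kinetic")
      }
    }
  }
  new_coupling_relation(net$rxns$id,
                        if (length(edges)) list_rbind(edges) else NULL,
                        theta = theta)
}

#' Merge coupling relations by transitive closure
#'
#' Full coupling is transitive, so structural and kinetic couplings combine
#' into larger classes. Coefficients compose multiplicatively along merge
#' paths; an inconsistent cycle (coefficients that do not multiply to one)
#' raises an error.
#'
#' @param a,b `coupling_relation`s over the same reaction set.
#' @return The merged `coupling_relation`.
#' @export
merge_couplings <- function(a, b) {
  if (!setequal(a$reactions, b$reactions)) {
    abort("coupling relations are over different reaction sets")
  }
  theta <- a$theta %||% b$theta
  new_coupling_relation(sort(a$reactions), bind_rows(a$evidence, b$evidence),
                        theta = theta)
}

#' Check that a flux space supports a strictly positive steady state
#'
#' Maximizes the uniform flux floor `t` subject to `Nv = 0`,
#' `v >= t`, `v <= ub`; the network admits a strictly positive steady-state
#' flux iff the optimum is positive.
#'
#' @inheritParams find_blocked
#' @return The optimal floor (a positive number iff a strictly positive flux
#'   exists).
#' @export
max_uniform_flux <- function(net, fs = flux_space(net)) {
  N <- stoich(net)
  n <- ncol(N)
  if (n == 0L) return(0)
  # variables (v, t); v_k - t >= 0; v <= ub; N v = 0; max t
  A2 <- cbind(diag(n), -1)
  A1 <- cbind(diag(n), 0)
  res <- simplex_call(c(numeric(n), 1),
                      A1 = A1, b1 = fs$ub,
                      A2 = A2, b2 = numeric(n),
                      A3 = cbind(N, 0), b3 = numeric(nrow(N)),
                      maximize = TRUE)
  if (res$status == -1) return(0)
  res$objective
}
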