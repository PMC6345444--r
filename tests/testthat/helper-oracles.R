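# Independent oracles used across the suite.

# Extreme rays of the flux cone {v : Nv = 0, v >= 0}, by exhaustive support
# enumeration (feasible for n <= ~12 reactions): a support set S carries an
# extreme ray iff the null space of N restricted to S is one-dimensional
# with a sign-definite generator supported on all of S.
extreme_rays <- function(N, tol = 1e-9) {
  n <- ncol(N)
  rays <- list()
  for (code in seq_len(2^n - 1)) {
    S <- which(bitwAnd(code, bitwShiftL(1, seq_len(n) - 1)) != 0)
    sub <- N[, S, drop = FALSE]
    sv <- svd(sub, nu = 0, nv = length(S))
    d <- c(sv$d, rep(0, length(S) - length(sv$d)))
    null_dim <- sum(d < tol * max(1, max(d)))
    if (null_dim != 1L) next
    w <- sv$v[, length(S)]
    if (max(abs(sub %*% w)) > 1e-8) next
    if (all(w >= -tol)) w <- w else if (all(w <= tol)) w <- -w else next
    if (any(abs(w) <= tol)) next # support smaller than S: found elsewhere
    ray <- numeric(n)
    ray[S] <- w / max(w)
    rays[[length(rays) + 1L]] <- ray
  }
  rays <- unique(lapply(rays, function(r) round(r / max(r), 9)))
  do.call(rbind, rays)
}

# Full-coupling classes from the extreme rays: i and j coupled iff active on
# the same rays with a constant ratio.
oracle_coupled_pairs <- function(N, tol = 1e-7) {
  rays <- extreme_rays(N)
  n <- ncol(N)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ai <- rays[, i] > tol
      aj <- rays[, j] > tol
      if (!any(ai) || !any(aj)) next # blocked reactions are out of scope
      if (!identical(ai, aj)) next
      ratios <- rays[ai, i] / rays[ai, j]
      if (max(ratios) - min(ratios) <= tol * max(1, max(abs(ratios)))) {
        pairs[[length(pairs) + 1L]] <- c(colnames(N)[i], colnames(N)[j])
      }
    }
  }
  pairs
}

# Literal brute-force SCC test: conditions (i)-(iii) checked over every
# (target, witness, case) triple with plain set algebra, no witness scan.
brute_scc <- function(net, cr) {
  ids <- net$rxns$id
  mets <- net$mets$id
  Nm <- n_minus(net); Np <- n_plus(net)
  lackers <- function(l, i) {
    # all k with Nm[i, l] - Nm[i, k] = 1 and other rows equal
    ids[vapply(ids, function(k) {
      if (k == l) return(FALSE)
      d <- Nm[, l] - Nm[, k]
      abs(d[[i]] - 1) < 1e-9 && all(abs(d[setdiff(mets, i)]) < 1e-9)
    }, logical(1))]
  }
  found <- character(0)
  for (i in mets) {
    for (j in mets) {
      P_j <- ids[Np[j, ] > 1e-9]
      S_j <- ids[Nm[j, ] > 1e-9]
      if (length(P_j) == 0L || length(S_j) == 0L) next
      for (cs in c("I", "II")) {
        lack_side <- if (cs == "I") P_j else S_j
        intact <- if (cs == "I") S_j else P_j
        if (length(unique(cr$class_rep[intact])) > 1) next
        Qs <- lapply(lack_side, lackers, i = i)
        if (any(lengths(Qs) == 0L)) next
        cls <- Reduce(intersect, lapply(Qs, function(q) unique(cr$class_rep[q])))
        if (length(cls) > 0L) found <- c(found, i)
      }
    }
  }
  sort(unique(found))
}

# Small fixture networks used by several test files.
diamond_network <- function() {
  # 0 -> A; A -> B (two parallel branches); B -> 0
  metabolic_network(tibble::tibble(
    id = c("Rin", "Rb1", "Rb2", "Rout"),
    substrates = c("", "A", "A", "B"),
    products = c("A", "B", "B", "")
  ), tibble::tibble(id = c("A", "B")))
}

merged_couplings <- function(net, theta = NULL) {
  merge_couplings(structural_couplings(net), kinetic_couplings(net, theta))
}

chain_theta <- function() stats::setNames(c(2, 1, 4), c("R1", "R2", "R3"))
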