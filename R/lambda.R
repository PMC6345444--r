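# Coupling coefficients lambda with v_l = lambda * v_k are numbers times a
# product of rate-constant ratios theta_num/theta_den. Structural couplings
# contribute plain numbers; mass-action (shared-substrate) couplings
# contribute a theta ratio. Keeping the ratio pairs explicit (rather than a
# bare exponent vector) lets the missing-rate-constant substitution schemes
# operate on individual ratios, as the method prescribes.

lam <- function(coef = 1, pairs = list()) {
  list(coef = as.numeric(coef), pairs = pairs)
}

lam_mul <- function(a, b) lam(a$coef * b$coef, c(a$pairs, b$pairs))

lam_inv <- function(a) {
  lam(1 / a$coef, lapply(a$pairs, function(p) c(p[2], p[1])))
}

# canonical exponent vector over theta ids (for equality checks)
lam_expo <- function(a) {
  e <- numeric(0)
  for (p in a$pairs) {
    e[p[1]] <- (if (p[1] %in% names(e)) e[[p[1]]] else 0) + 1
    e[p[2]] <- (if (p[2] %in% names(e)) e[[p[2]]] else 0) - 1
  }
  e[e != 0]
}

# minimal ratio-pair decomposition after exponent cancellation: theta ids
# with positive exponent are matched against those with negative exponent
# (sorted, repeated by multiplicity). Path compositions through a class
# representative cancel exactly here, so only genuinely needed ratios remain.
lam_pairs_canonical <- function(a) {
  e <- lam_expo(a)
  if (length(e) == 0L) return(list())
  pos <- rep(names(e)[e > 0], times = e[e > 0])
  neg <- rep(names(e)[e < 0], times = -e[e < 0])
  stopifnot(length(pos) == length(neg)) # coupling ratios are balanced
  pos <- sort(pos); neg <- sort(neg)
  lapply(seq_along(pos), function(k) c(pos[k], neg[k]))
}

# numeric value given rate constants; NA when a needed theta is absent
lam_eval <- function(a, theta = NULL) {
  e <- lam_expo(a)
  if (length(e) == 0L) return(a$coef)
  if (is.null(theta) || !all(names(e) %in% names(theta))) return(NA_real_)
  a$coef * prod(theta[names(e)]^e)
}

lam_equal <- function(a, b, tol = .tol_equal) {
  ea <- lam_expo(a); eb <- lam_expo(b)
  ids <- union(names(ea), names(eb))
  get <- function(e, id) if (id %in% names(e)) e[[id]] else 0
  expo_ok <- all(vapply(ids, function(id) get(ea, id) == get(eb, id), logical(1)))
  expo_ok && near(a$coef, b$coef, rel = tol)
}

lam_format <- function(a) {
  e <- lam_expo(a)
  if (length(e) == 0L) return(format(a$coef, digits = 8))
  pow <- function(id, k) {
    if (k == 1) sprintf("theta[%s]", id) else sprintf("theta[%s]^%g", id, k)
  }
  num <- c(if (!near(a$coef, 1)) format(a$coef, digits = 8),
           unlist(imap(e[e > 0], function(k, id) pow(id, k))))
  den <- unlist(imap(e[e < 0], function(k, id) pow(id, -k)))
  out <- if (length(num)) paste(num, collapse = "*") else "1"
  if (length(den)) out <- paste0(out, "/", paste(den, collapse = "/"))
  out
}
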