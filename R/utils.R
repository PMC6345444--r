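# shared numeric tolerances
.tol_equal <- 1e-6   # relative equality of flux ratios / lambdas
.tol_zero  <- 1e-9   # absolute floor below which a flux counts as zero

# relative closeness with absolute floor
near <- function(a, b, rel = .tol_equal, abs_floor = .tol_zero) {
  abs(a - b) <= pmax(abs_floor, rel * pmax(abs(a), abs(b)))
}

# stable stringified key for a stoichiometry column, used to group identical
# substrate columns; tolerance-insensitive via rounding at 1e-9
col_key <- function(col) {
  nz <- which(abs(col) > .tol_zero)
  if (length(nz) == 0L) return("")
  paste(names(col)[nz], signif(col[nz], 12), sep = ":", collapse = "|")
}

# parse a reaction side like "2 A + B" into a named coefficient vector;
# "" or NA means no participants (boundary side)
parse_side <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) {
    return(stats::setNames(numeric(0), character(0)))
  }
  parts <- strsplit(txt, "\\+")[[1]]
  coefs <- numeric(0)
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    m <- regmatches(p, regexec("^([0-9]*\\.?[0-9]+)?\\s*(\\S+)$", p))[[1]]
    if (length(m) == 0L) {
      abort(sprintf("cannot parse reaction side term '%s'", p))
    }
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    id <- m[3]
    prev <- if (id %in% names(coefs)) coefs[[id]] else 0
    coefs[id] <- prev + coef
  }
  coefs
}

# inverse of parse_side
format_side <- function(coefs) {
  if (length(coefs) == 0L) return("")
  paste(ifelse(near(coefs, 1), names(coefs),
               paste(format(coefs, trim = TRUE), names(coefs))),
        collapse = " + ")
}
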