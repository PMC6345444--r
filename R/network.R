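#' Construct a stoichiometric metabolic network
#'
#' A metabolic network couples an ordered set of metabolites to an ordered set
#' of reactions through the split stoichiometric matrices `N+` (products) and
#' `N-` (substrates); the net stoichiometric matrix is `N = N+ - N-`. Under
#' mass action kinetics the rate of reaction i is
#' `v_i = theta_i * prod_j x_j^(Nminus[j, i])`, so the substrate matrix also
#' fixes the kinetic orders.
#'
#' @param reactions A data frame with one row per reaction and columns `id`,
#'   `substrates`, `products` (either strings like `"2 A + B"` or list-columns
#'   of named coefficient vectors), and optionally `lb`, `ub` (flux bounds,
#'   mmol/gDW/hr; defaults 0 and 1000).
#' @param metabolites Optional data frame with columns `id` and optionally
#'   `name`, `compartment`. Defaults to the metabolites referenced by the
#'   reactions.
#' @return An object of class `metabolic_network` with components `mets`,
#'   `rxns` (tibbles), `N_plus`, `N_minus` (non-negative m x n matrices with
#'   dimnames), and `split_map` (empty until [split_reversible()] is applied).
#' @examples
#' net <- metabolic_network(tibble::tibble(
#'   id = c("R1", "R2", "R3"),
#'   substrates = c("", "A", "B"),
#'   products = c("A", "B", "")
#' ))
#' stoich(net)
#' @export
metabolic_network <- function(reactions, metabolites = NULL) {
  reactions <- as_tibble(reactions)
  stopifnot(all(c("id", "substrates", "products") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) {
    abort("duplicated reaction ids")
  }
  subs <- side_list(reactions$substrates)
  prods <- side_list(reactions$products)
  used <- unique(c(unlist(lapply(subs, names)), unlist(lapply(prods, names))))

  if (is.null(metabolites)) {
    metabolites <- tibble(id = used)
  }
  metabolites <- as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- NA_character_
  if (anyDuplicated(metabolites$id)) abort("duplicated metabolite ids")
  missing <- setdiff(used, metabolites$id)
  if (length(missing) > 0L) {
    abort(sprintf("reaction references undeclared metabolite(s): %s",
                  paste(missing, collapse = ", ")))
  }

  m <- nrow(metabolites); n <- nrow(reactions)
  N_minus <- matrix(0, m, n, dimnames = list(metabolites$id, reactions$id))
  N_plus <- N_minus
  for (k in seq_len(n)) {
    s <- subs[[k]]; p <- prods[[k]]
    if (any(s < 0) || any(p < 0)) abort("stoichiometric coefficients must be >= 0")
    N_minus[names(s), k] <- s
    N_plus[names(p), k] <- p
  }

  rxns <- tibble(
    id = reactions$id,
    lb = if ("lb" %in% names(reactions)) as.numeric(reactions$lb) else 0,
    ub = if ("ub" %in% names(reactions)) as.numeric(reactions$ub) else 1000,
    exchange = if ("exchange" %in% names(reactions)) as.logical(reactions$exchange)
               else colSums(N_minus) == 0 | colSums(N_plus) == 0
  )
  if (any(rxns$lb > rxns$ub)) abort("reaction with lb > ub")

  structure(
    list(
      mets = select(metabolites, "id", "name", "compartment"),
      rxns = rxns,
      N_plus = N_plus,
      N_minus = N_minus,
      split_map = tibble(id = character(0), original = character(0),
                         direction = character(0))
    ),
    class = "metabolic_network"
  )
}

# normalize a substrates/products column (strings or list of named vectors)
side_list <- function(x) {
  if (is.list(x)) {
    lapply(x, function(s) {
      s <- unlist(s) %||% stats::setNames(numeric(0), character(0))
      if (length(s) && is.null(names(s))) abort("side coefficients must be named")
      s[s != 0]
    })
  } else {
    lapply(as.character(x), parse_side)
  }
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites x %d reactions\n",
              nrow(x$mets), nrow(x$rxns)))
  rev <- sum(x$rxns$lb < 0)
  if (rev > 0) cat(sprintf("  %d reversible reaction(s) (lb < 0), not yet split\n", rev))
  if (nrow(x$split_map) > 0) cat(sprintf("  %d split half-reaction(s)\n", nrow(x$split_map)))
  invisible(x)
}

#' Stoichiometric matrices of a network
#'
#' @param net A [metabolic_network()].
#' @return `stoich()` returns the net matrix `N = N+ - N-`; `n_plus()` and
#'   `n_minus()` return the product and substrate matrices.
#' @export
stoich <- function(net) net$N_plus - net$N_minus

#' @rdname stoich
#' @export
n_plus <- function(net) net$N_plus

#' @rdname stoich
#' @export
n_minus <- function(net) net$N_minus

#' @export
as_tibble.metabolic_network <- function(x, ...) {
  tibble(
    id = x$rxns$id,
    substrates = map_chr(seq_len(nrow(x$rxns)), function(k) {
      col <- x$N_minus[, k]
      format_side(col[col != 0])
    }),
    products = map_chr(seq_len(nrow(x$rxns)), function(k) {
      col <- x$N_plus[, k]
      format_side(col[col != 0])
    }),
    lb = x$rxns$lb,
    ub = x$rxns$ub,
    exchange = x$rxns$exchange
  )
}

#' Flux space of a network
#'
#' The feasible steady-state flux set `F = {v : Nv = 0, lb <= v <= ub}`.
#'
#' @param net A [metabolic_network()].
#' @param lb,ub Optional named overrides of the per-reaction bounds.
#' @return A `flux_space` object (named `lb`/`ub` vectors).
#' @export
flux_space <- function(net, lb = NULL, ub = NULL) {
  l <- stats::setNames(net$rxns$lb, net$rxns$id)
  u <- stats::setNames(net$rxns$ub, net$rxns$id)
  if (!is.null(lb)) l[names(lb)] <- lb
  if (!is.null(ub)) u[names(ub)] <- ub
  if (any(l > u)) abort("flux space with lb > ub")
  structure(list(lb = l, ub = u), class = "flux_space")
}

#' Read a metabolic network from file
#'
#' Supported formats: the package's TSV dialect (one reaction per row with
#' columns id, substrates, products, lb, ub; sides written like `"2 A + B"`),
#' BiGG JSON, and SBML Level 3 (optionally with FBC bounds).
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"bigg-json"`, `"sbml"`; guessed from the
#'   file extension by default.
#' @return A [metabolic_network()]. Reversible reactions keep their signed
#'   bounds until [split_reversible()] is applied.
#' @export
read_network <- function(path, format = c("auto", "tsv", "bigg-json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv",
                     json = "bigg-json",
                     xml = "sbml", sbml = "sbml",
                     abort(sprintf("cannot guess format of '%s'", path)))
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
         "tsv" = read_network_tsv(path),
         "bigg-json" = read_network_bigg(path),
         "sbml" = read_network_sbml(path))
}

read_network_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL,
                          colClasses = "character")
  need <- c("id", "substrates", "products")
  if (!all(need %in% names(df))) {
    abort(sprintf("TSV network file must have columns %s; got: %s",
                  paste(need, collapse = ", "), paste(names(df), collapse = ", ")))
  }
  if ("lb" %in% names(df)) df$lb <- as.numeric(df$lb)
  if ("ub" %in% names(df)) df$ub <- as.numeric(df$ub)
  metabolic_network(df)
}

read_network_bigg <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$reactions) || is.null(j$metabolites)) {
    abort(sprintf("'%s' does not look like a BiGG model (missing reactions/metabolites)", path))
  }
  mets <- tibble(
    id = map_chr(j$metabolites, "id"),
    name = map_chr(j$metabolites, function(m) m$name %||% m$id),
    compartment = map_chr(j$metabolites, function(m) as.character(m$compartment %||% NA))
  )
  rxns <- tibble(
    id = map_chr(j$reactions, "id"),
    substrates = map(j$reactions, function(r) {
      s <- unlist(r$metabolites)
      -s[s < 0]
    }),
    products = map(j$reactions, function(r) {
      s <- unlist(r$metabolites)
      s[s > 0]
    }),
    lb = map_dbl(j$reactions, function(r) r$lower_bound %||% 0),
    ub = map_dbl(j$reactions, function(r) r$upper_bound %||% 1000)
  )
  metabolic_network(rxns, mets)
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(species) == 0L) abort(sprintf("no species found in SBML file '%s'", path))
  mets <- tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"), xml2::xml_attr(species, "id")),
    compartment = xml2::xml_attr(species, "compartment")
  )
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  bnd_ids <- mets$id[boundary]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) abort(sprintf("no reactions found in SBML file '%s'", path))
  get_side <- function(node, tag) {
    refs <- xml2::xml_find_all(node, sprintf("./%s/speciesReference", tag))
    ids <- xml2::xml_attr(refs, "species")
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    keep <- !(ids %in% bnd_ids)
    stats::setNames(st[keep], ids[keep])
  }
  rxns <- tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    substrates = map(rx_nodes, get_side, tag = "listOfReactants"),
    products = map(rx_nodes, get_side, tag = "listOfProducts"),
    lb = map_dbl(rx_nodes, function(nd) {
      fb <- xml2::xml_attr(nd, "lowerFluxBound")
      if (!is.na(fb) && fb %in% names(pvals)) return(pvals[[fb]])
      rev <- xml2::xml_attr(nd, "reversible") %in% c("true", "1", NA)
      if (isTRUE(rev)) -1000 else 0
    }),
    ub = map_dbl(rx_nodes, function(nd) {
      fb <- xml2::xml_attr(nd, "upperFluxBound")
      if (!is.na(fb) && fb %in% names(pvals)) return(pvals[[fb]])
      1000
    })
  )
  metabolic_network(rxns, filter(mets, !boundary))
}

#' Write a network in the TSV dialect
#'
#' @param net A [metabolic_network()].
#' @param path Output path.
#' @return `path`, invisibly. Round-trips bit-for-bit with [read_network()]
#'   for the TSV dialect.
#' @export
write_network <- function(net, path) {
  utils::write.table(as_tibble(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with `lb < 0` is replaced by a forward copy (`_f`) and a
#' backward copy (`_b`) with substrates and products swapped, so that all
#' resulting bounds satisfy `lb >= 0`. The mapping back to original reaction
#' ids is kept in `split_map`, which downstream knockout handling uses to
#' remove both halves jointly.
#'
#' @param net A [metabolic_network()].
#' @return A [metabolic_network()] with only irreversible reactions.
#' @export
split_reversible <- function(net) {
  rev_idx <- which(net$rxns$lb < 0)
  if (length(rev_idx) == 0L) return(net)

  ids <- net$rxns$id
  keep <- setdiff(seq_along(ids), rev_idx)
  new_cols_minus <- list(); new_cols_plus <- list()
  new_rxns <- list(); map_rows <- list()

  for (k in seq_along(ids)) {
    if (k %in% rev_idx) {
      fid <- paste0(ids[k], "_f"); bid <- paste0(ids[k], "_b")
      new_cols_minus[[fid]] <- net$N_minus[, k]
      new_cols_plus[[fid]] <- net$N_plus[, k]
      new_cols_minus[[bid]] <- net$N_plus[, k]
      new_cols_plus[[bid]] <- net$N_minus[, k]
      new_rxns[[fid]] <- tibble(id = fid, lb = 0, ub = max(net$rxns$ub[k], 0),
                                exchange = net$rxns$exchange[k])
      new_rxns[[bid]] <- tibble(id = bid, lb = 0, ub = max(-net$rxns$lb[k], 0),
                                exchange = net$rxns$exchange[k])
      map_rows[[fid]] <- tibble(id = fid, original = ids[k], direction = "forward")
      map_rows[[bid]] <- tibble(id = bid, original = ids[k], direction = "backward")
    } else {
      new_cols_minus[[ids[k]]] <- net$N_minus[, k]
      new_cols_plus[[ids[k]]] <- net$N_plus[, k]
      new_rxns[[ids[k]]] <- net$rxns[k, ]
    }
  }

  out <- net
  out$N_minus <- do.call(cbind, new_cols_minus)
  out$N_plus <- do.call(cbind, new_cols_plus)
  rownames(out$N_minus) <- rownames(out$N_plus) <- net$mets$id
  out$rxns <- list_rbind(new_rxns)
  out$split_map <- bind_rows(net$split_map, list_rbind(map_rows))
  out
}

#' Remove blocked reactions (and orphaned metabolites)
#'
#' Blocked reactions carry zero flux in every feasible steady state and must
#' be removed before SCC analysis: a network with blocked reactions cannot
#' have a strictly positive steady-state flux. Metabolites left without any
#' reaction are dropped and reported via a message.
#'
#' @param net A split, irreversible [metabolic_network()].
#' @param blocked Character vector of blocked reaction ids, as returned by
#'   [find_blocked()]; computed from `fs` when missing.
#' @param fs Flux space used when `blocked` must be computed.
#' @return The reduced [metabolic_network()].
#' @export
remove_blocked <- function(net, blocked = NULL, fs = flux_space(net)) {
  if (is.null(blocked)) blocked <- find_blocked(net, fs)
  if (length(blocked) == 0L) return(net)
  keep <- !(net$rxns$id %in% blocked)
  if (!any(keep)) {
    warn("all reactions are blocked; returning an empty network")
  }
  out <- net
  out$N_minus <- net$N_minus[, keep, drop = FALSE]
  out$N_plus <- net$N_plus[, keep, drop = FALSE]
  out$rxns <- net$rxns[keep, ]
  orphan <- rowSums(abs(out$N_minus)) + rowSums(abs(out$N_plus)) == 0
  if (any(orphan)) {
    inform(sprintf("dropping %d metabolite(s) orphaned by blocked-reaction removal: %s",
                   sum(orphan), paste(out$mets$id[orphan], collapse = ", ")))
    out$N_minus <- out$N_minus[!orphan, , drop = FALSE]
    out$N_plus <- out$N_plus[!orphan, , drop = FALSE]
    out$mets <- out$mets[!orphan, ]
  }
  out$split_map <- filter(net$split_map, .data$id %in% net$rxns$id[keep])
  out
}

#' Preprocess a network for SCC analysis
#'
#' Convenience wrapper: split reversible reactions, then remove blocked
#' reactions.
#'
#' @inheritParams split_reversible
#' @return A split, blocked-free [metabolic_network()].
#' @export
preprocess_network <- function(net) {
  net <- split_reversible(net)
  remove_blocked(net)
}
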