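#' Build and validate a Boolean metabolic network
#'
#' A metabolic network is a bipartite directed graph with compound nodes
#' (OR semantics: a compound is producible if at least one producing
#' reaction is active) and reaction nodes (AND semantics: a reaction is
#' active only if all its substrates are producible).  The host network is
#' the subgraph induced by `host_nodes`; reactions of the reference network
#' outside the host are the candidates for insertion.
#'
#' @param compounds character vector of compound node ids.
#' @param reactions character vector of reaction node ids.
#' @param edges two-column `data.frame` (or matrix) of directed edges
#'   `from` -> `to`.  Every edge must join a compound to a reaction or a
#'   reaction to a compound.
#' @param sources character vector of source (seed) compound ids.  Sources
#'   are producible at any time and must have no incoming edges.
#' @param target single compound id to be made producible; must not be a
#'   source.
#' @param host_nodes character vector of node ids (compounds and reactions)
#'   forming the host network.
#' @param reversible_pairs optional list of character pairs recording the
#'   forward/backward halves of decomposed reversible reactions.
#' @param source_policy what to do when a declared source has incoming
#'   edges (frequent in real pathway maps): `"strip"` removes the offending
#'   edges with a warning, `"strict"` raises an error.
#' @return An object of class `metnet`.
#' @seealso [decompose_reversible()], [additional_reactions()],
#'   [read_network_json()]
#' @examples
#' net <- build_network(
#'   compounds = c("s", "c", "t"),
#'   reactions = c("r1", "r2"),
#'   edges = data.frame(from = c("s", "r1", "c", "r2"),
#'                      to   = c("r1", "c", "r2", "t")),
#'   sources = "s", target = "t",
#'   host_nodes = c("s", "c", "r1")
#' )
#' additional_reactions(net)
#' @export
build_network <- function(compounds, reactions, edges, sources, target,
                          host_nodes = character(),
                          reversible_pairs = list(),
                          source_policy = c("strip", "strict")) {
  source_policy <- match.arg(source_policy)
  compounds <- as.character(compounds)
  reactions <- as.character(reactions)
  sources <- as.character(sources)
  target <- as.character(target)
  host_nodes <- as.character(host_nodes)
  edges <- normalize_edges(edges)

  ids <- c(compounds, reactions)
  if (anyDuplicated(ids)) {
    stop("duplicate node ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- setdiff(c(edges$from, edges$to), ids)
  if (length(bad)) {
    stop("edges reference undeclared ids: ", paste(unique(bad), collapse = ", "))
  }

  is_cpd <- c(edges$from %in% compounds)
  to_cpd <- c(edges$to %in% compounds)
  mixed <- is_cpd == to_cpd
  if (any(mixed)) {
    i <- which(mixed)[1L]
    stop(sprintf("bipartiteness violated by edge (%s -> %s)",
                 edges$from[i], edges$to[i]))
  }

  if (length(target) != 1L || !(target %in% compounds)) {
    stop("target must be a single declared compound id")
  }
  if (!all(sources %in% compounds)) {
    stop("sources must be declared compounds; missing: ",
         paste(setdiff(sources, compounds), collapse = ", "))
  }
  if (target %in% sources) stop("target must not be a source")

  into_src <- edges$to %in% sources
  if (any(into_src)) {
    if (source_policy == "strict") {
      stop("source nodes must have no incoming edges: ",
           paste(unique(edges$to[into_src]), collapse = ", "))
    }
    warning("removed ", sum(into_src), " edge(s) into source node(s): ",
            paste(unique(edges$to[into_src]), collapse = ", "))
    edges <- edges[!into_src, , drop = FALSE]
  }

  if (!all(host_nodes %in% ids)) {
    stop("host_nodes contains undeclared ids: ",
         paste(setdiff(host_nodes, ids), collapse = ", "))
  }

  reversible_pairs <- lapply(reversible_pairs, function(p) sort(as.character(p)))
  for (p in reversible_pairs) {
    if (length(p) != 2L || !all(p %in% reactions)) {
      stop("reversible pairs must name two declared reactions")
    }
  }

  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(
    list(
      compounds = sort(unique(compounds)),
      reactions = sort(unique(reactions)),
      edges = edges,
      sources = sort(unique(sources)),
      target = target,
      host_nodes = sort(unique(host_nodes)),
      reversible_pairs = reversible_pairs[order(vapply(reversible_pairs, `[`, "", 1L))]
    ),
    class = "metnet"
  )
  net <- index_network(net)

  # Mirrored up to source compounds: the backward half of a reversible
  # reaction that consumes a source would "produce" it, and such edges
  # are removed by the source policy above.
  for (p in net$reversible_pairs) {
    mod_src <- function(x) setdiff(x, net$sources)
    if (!setequal(mod_src(net$subs[[p[1L]]]), mod_src(net$prods[[p[2L]]])) ||
        !setequal(mod_src(net$prods[[p[1L]]]), mod_src(net$subs[[p[2L]]]))) {
      stop("reversible pair {", p[1L], ", ", p[2L],
           "} does not have mirrored substrate/product sets")
    }
  }
  net
}

normalize_edges <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(c("from", "to") %in% names(edges))) names(edges)[1:2] <- c("from", "to")
  data.frame(from = as.character(edges$from), to = as.character(edges$to),
             stringsAsFactors = FALSE)
}

# Precompute adjacency lists; rebuilt whenever edges change.
index_network <- function(net) {
  e <- net$edges
  from_r <- e$from %in% net$reactions
  net$subs <- split_adj(e$to[!from_r], e$from[!from_r], net$reactions)
  net$prods <- split_adj(e$from[from_r], e$to[from_r], net$reactions)
  net$producers <- split_adj(e$to[from_r], e$from[from_r], net$compounds)
  net$consumers <- split_adj(e$from[!from_r], e$to[!from_r], net$compounds)
  net
}

split_adj <- function(key, value, universe) {
  out <- rep(list(character()), length(universe))
  names(out) <- universe
  if (length(key)) {
    got <- split(value, factor(key, levels = universe))
    got <- got[!vapply(got, is.null, TRUE)]
    out[names(got)] <- lapply(got, function(x) sort(unique(x)))
  }
  out
}

#' @export
print.metnet <- function(x, ...) {
  cat(sprintf(
    "<metnet> %d compounds, %d reactions, %d edges\n",
    length(x$compounds), length(x$reactions), nrow(x$edges)
  ))
  cat(sprintf("  sources: %s   target: %s\n",
              paste(x$sources, collapse = ", "), x$target))
  cat(sprintf("  host nodes: %d   additional reactions: %d\n",
              length(x$host_nodes), length(additional_reactions(x))))
  if (length(x$reversible_pairs)) {
    cat(sprintf("  reversible pairs: %d\n", length(x$reversible_pairs)))
  }
  invisible(x)
}

#' Reactions of the reference network not present in the host
#'
#' These are the candidate reactions for insertion (the additional
#' reaction nodes).
#'
#' @param net a `metnet` object.
#' @return sorted character vector of reaction ids.
#' @export
additional_reactions <- function(net) {
  stopifnot(inherits(net, "metnet"))
  setdiff(net$reactions, net$host_nodes)
}

host_reactions <- function(net) intersect(net$reactions, net$host_nodes)

#' Decompose reversible reactions into forward/backward halves
#'
#' Takes a network description with per-reaction reversibility flags and
#' returns a validated network in which every reversible reaction `R#####`
#' is replaced by an irreversible forward half `P#####` and a backward half
#' `Q#####` with swapped substrates and products.  The two halves are
#' recorded as a reversible pair; irreversible reactions are kept
#' unchanged.  Applying the decomposition to an already-decomposed
#' description (all flags `FALSE`) is a no-op.
#'
#' @param spec a network description: a list with elements `compounds`
#'   (character), `reactions` (list of `list(id, substrates, products,
#'   reversible, host)`), `sources`, `target`, and optionally
#'   `host_compounds` and `reversible_pairs`.  This is the structure
#'   produced by [as_network_spec()] and by the JSON reader.
#' @param source_policy forwarded to [build_network()].
#' @return a `metnet` object.
#' @examples
#' sp <- list(
#'   compounds = c("A", "B"),
#'   reactions = list(list(id = "R00001", substrates = "A", products = "B",
#'                         reversible = TRUE, host = TRUE)),
#'   sources = "A", target = "B"
#' )
#' net <- decompose_reversible(sp)
#' net$reversible_pairs
#' @export
decompose_reversible <- function(spec, source_policy = c("strip", "strict")) {
  source_policy <- match.arg(source_policy)
  stopifnot(is.list(spec), !is.null(spec$reactions))
  rxns <- list()
  pairs <- if (is.null(spec$reversible_pairs)) list() else spec$reversible_pairs
  for (r in spec$reactions) {
    rev <- isTRUE(r$reversible)
    if (!rev) {
      rxns[[length(rxns) + 1L]] <- r
      next
    }
    pq <- pq_ids(r$id)
    fwd <- list(id = pq[1L], substrates = r$substrates, products = r$products,
                reversible = FALSE, host = isTRUE(r$host))
    bwd <- list(id = pq[2L], substrates = r$products, products = r$substrates,
                reversible = FALSE, host = isTRUE(r$host))
    rxns <- c(rxns, list(fwd, bwd))
    pairs[[length(pairs) + 1L]] <- pq
  }
  ids <- vapply(rxns, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate derived reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  spec$reactions <- rxns
  spec$reversible_pairs <- pairs
  network_from_spec(spec, source_policy = source_policy)
}

# P/Q ids for a reversible reaction: R00001 -> P00001 / Q00001.
pq_ids <- function(id) {
  if (grepl("^R", id)) c(sub("^R", "P", id), sub("^R", "Q", id))
  else paste0(c("P", "Q"), id)
}

# Base id for reporting: P00001/Q00001 -> R00001.
base_reaction_id <- function(id) sub("^[PQ](?=[0-9])", "R", id, perl = TRUE)

network_from_spec <- function(spec, source_policy = c("strip", "strict")) {
  source_policy <- match.arg(source_policy)
  rxn_ids <- vapply(spec$reactions, function(r) r$id, "")
  edges_from <- character()
  edges_to <- character()
  for (r in spec$reactions) {
    edges_from <- c(edges_from, as.character(r$substrates), rep(r$id, length(r$products)))
    edges_to <- c(edges_to, rep(r$id, length(r$substrates)), as.character(r$products))
  }
  host_rxn <- rxn_ids[vapply(spec$reactions, function(r) isTRUE(r$host), TRUE)]
  host_cpd <- if (!is.null(spec$host_compounds)) {
    as.character(spec$host_compounds)
  } else {
    # Host compounds default to the sources plus compounds touching a host
    # reaction: the subgraph a host reaction set induces.
    touching <- unique(unlist(lapply(spec$reactions[vapply(spec$reactions, function(r) isTRUE(r$host), TRUE)],
                                     function(r) c(r$substrates, r$products))))
    union(spec$sources, touching)
  }
  build_network(
    compounds = spec$compounds,
    reactions = rxn_ids,
    edges = data.frame(from = edges_from, to = edges_to, stringsAsFactors = FALSE),
    sources = spec$sources,
    target = spec$target,
    host_nodes = c(intersect(host_cpd, spec$compounds), host_rxn),
    reversible_pairs = if (is.null(spec$reversible_pairs)) list() else spec$reversible_pairs,
    source_policy = source_policy
  )
}

#' Convert a network back into a plain description
#'
#' The inverse of [network_from_spec()]/[decompose_reversible()] on
#' decomposed networks: reactions keep their (already irreversible) ids,
#' host membership and the recorded reversible pairs are carried along.
#'
#' @param net a `metnet` object.
#' @return a network-description list (see [decompose_reversible()]).
#' @export
as_network_spec <- function(net) {
  stopifnot(inherits(net, "metnet"))
  list(
    compounds = net$compounds,
    reactions = lapply(net$reactions, function(r) {
      list(id = r, substrates = net$subs[[r]], products = net$prods[[r]],
           reversible = FALSE, host = r %in% net$host_nodes)
    }),
    sources = net$sources,
    target = net$target,
    host_compounds = intersect(net$host_nodes, net$compounds),
    reversible_pairs = net$reversible_pairs
  )
}

#' Read / write the JSON network interchange format
#'
#' The schema mirrors the network description used throughout the package:
#' `{"compounds": [...], "reactions": [{"id", "substrates", "products",
#' "reversible", "host"}], "sources": [...], "target": "...",
#' "host_compounds": [...], "reversible_pairs": [[..]]}`.  Serialization is
#' deterministic (sorted ids), so equal networks produce byte-identical
#' files.  Reading a file whose reactions carry `reversible: true` flags
#' decomposes them into P/Q halves.
#'
#' @param path file path.
#' @param net a `metnet` object.
#' @param source_policy forwarded to [build_network()].
#' @return `read_network_json()` returns a `metnet`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
read_network_json <- function(path, source_policy = c("strip", "strict")) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec$compounds <- as.character(unlist(spec$compounds))
  spec$sources <- as.character(unlist(spec$sources))
  spec$target <- as.character(spec$target)
  if (!is.null(spec$host_compounds)) {
    spec$host_compounds <- as.character(unlist(spec$host_compounds))
  }
  if (!is.null(spec$reversible_pairs)) {
    spec$reversible_pairs <- lapply(spec$reversible_pairs, function(p) as.character(unlist(p)))
  }
  spec$reactions <- lapply(spec$reactions, function(r) {
    list(id = as.character(r$id),
         substrates = as.character(unlist(r$substrates)),
         products = as.character(unlist(r$products)),
         reversible = isTRUE(r$reversible),
         host = isTRUE(r$host))
  })
  decompose_reversible(spec, source_policy = match.arg(source_policy))
}

#' @rdname read_network_json
#' @export
write_network_json <- function(net, path) {
  spec <- as_network_spec(net)
  out <- list(
    compounds = spec$compounds,
    reactions = lapply(spec$reactions, function(r) {
      list(id = r$id,
           substrates = as.list(r$substrates),
           products = as.list(r$products),
           reversible = r$reversible,
           host = r$host)
    }),
    sources = spec$sources,
    target = spec$target,
    host_compounds = spec$host_compounds,
    reversible_pairs = lapply(spec$reversible_pairs, as.list)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Host-induced subnetwork
#'
#' Returns the metabolic network induced by the host nodes (same sources
#' and target; the target may be unproducible there).
#'
#' @param net a `metnet` object.
#' @return a `metnet` object.
#' @export
host_network <- function(net) {
  stopifnot(inherits(net, "metnet"))
  keep <- union(net$host_nodes, c(net$sources, net$target))
  e <- net$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  pairs <- Filter(function(p) all(p %in% keep), net$reversible_pairs)
  build_network(
    compounds = intersect(net$compounds, keep),
    reactions = intersect(net$reactions, keep),
    edges = e,
    sources = net$sources,
    target = net$target,
    host_nodes = net$host_nodes,
    reversible_pairs = pairs
  )
}
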