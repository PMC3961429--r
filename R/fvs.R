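# Directed-graph helpers on plain id vectors / edge data.frames.

# Kahn's algorithm; TRUE when the directed graph is acyclic.
graph_is_acyclic <- function(nodes, edges) {
  if (!length(nodes) || !nrow(edges)) return(TRUE)
  indeg <- structure(integer(length(nodes)), names = nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out_adj <- split(edges$to, factor(edges$from, levels = nodes))
  queue <- nodes[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    removed <- removed + 1L
    for (w in out_adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed == length(nodes)
}

#' Greedy reaction-node feedback vertex set
#'
#' A feedback vertex set (FVS) is a node set whose removal makes the
#' directed graph acyclic.  Every directed cycle of a bipartite
#' compound/reaction graph alternates between the two node types, so a
#' reaction-only FVS always exists.  The greedy procedure repeatedly trims
#' nodes of in-degree or out-degree 0 (such nodes lie on no cycle); while
#' cycles remain it removes the reaction node of maximum total degree in
#' the residual graph, breaking ties by lexicographically smallest id.
#' The result is not necessarily minimum, which is harmless: the optimal
#' objective of the FVS-based insertion encoding does not depend on which
#' FVS is used.
#'
#' @param net a `metnet` object.
#' @return an object of class `fvs_result`: list with `members` (ordered
#'   reaction ids) and `size`.
#' @examples
#' find_greedy_fvs(fixture("CYCTRAP"))$members
#' @export
find_greedy_fvs <- function(net) {
  stopifnot(inherits(net, "metnet"))
  nodes <- c(net$compounds, net$reactions)
  edges <- net$edges
  members <- character()
  repeat {
    # trim: nodes with no in- or no out-edges are never on a cycle
    repeat {
      if (!length(nodes)) break
      indeg <- structure(integer(length(nodes)), names = nodes)
      outdeg <- indeg
      if (nrow(edges)) {
        ti <- table(edges$to); indeg[names(ti)] <- as.integer(ti)
        to <- table(edges$from); outdeg[names(to)] <- as.integer(to)
      }
      drop <- nodes[indeg == 0L | outdeg == 0L]
      if (!length(drop)) break
      nodes <- setdiff(nodes, drop)
      edges <- edges[!(edges$from %in% drop | edges$to %in% drop), , drop = FALSE]
    }
    if (!length(nodes)) break
    # all residual nodes lie on cycles; pick a reaction node
    rxn <- intersect(nodes, net$reactions)
    deg <- structure(integer(length(rxn)), names = rxn)
    if (nrow(edges)) {
      ti <- table(edges$to[edges$to %in% rxn])
      to <- table(edges$from[edges$from %in% rxn])
      deg[names(ti)] <- deg[names(ti)] + as.integer(ti)
      deg[names(to)] <- deg[names(to)] + as.integer(to)
    }
    pick <- sort(names(deg)[deg == max(deg)])[1L]
    members <- c(members, pick)
    nodes <- setdiff(nodes, pick)
    edges <- edges[edges$from != pick & edges$to != pick, , drop = FALSE]
  }
  structure(list(members = members, size = length(members)),
            class = "fvs_result")
}

#' @export
print.fvs_result <- function(x, ...) {
  cat(sprintf("<fvs_result> size %d: %s\n", x$size,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Exact minimum reaction-node feedback vertex set (oracle)
#'
#' Enumerates reaction subsets in increasing cardinality and returns the
#' first whose removal leaves the graph acyclic.  Exponential; intended as
#' a cross-check for [find_greedy_fvs()] on small networks.
#'
#' @param net a `metnet` object.
#' @param max_reactions refuse networks with more reactions than this.
#' @return an `fvs_result`.
#' @export
brute_force_fvs <- function(net, max_reactions = 12L) {
  stopifnot(inherits(net, "metnet"))
  rxns <- net$reactions
  if (length(rxns) > max_reactions) {
    stop("brute_force_fvs: more than ", max_reactions, " reactions")
  }
  nodes <- c(net$compounds, net$reactions)
  for (k in 0:length(rxns)) {
    for (comb in combn_list(rxns, k)) {
      rest <- setdiff(nodes, comb)
      e <- net$edges
      e <- e[e$from %in% rest & e$to %in% rest, , drop = FALSE]
      if (graph_is_acyclic(rest, e)) {
        return(structure(list(members = comb, size = k), class = "fvs_result"))
      }
    }
  }
  stop("unreachable: full reaction set is always an FVS of a bipartite graph")
}

combn_list <- function(x, k) {
  if (k == 0L) return(list(character()))
  if (length(x) < k) return(list())
  utils::combn(x, k, simplify = FALSE)
}

#' Border reactions: insertable reactions fed directly by the host
#'
#' Additional reactions having at least one substrate compound inside the
#' host network.  In the FVS-based encoding these are split like feedback
#' vertices so that host-computed values and downstream values live in
#' different time steps.
#'
#' @param net a `metnet` object.
#' @return sorted character vector of reaction ids.
#' @export
border_reactions <- function(net) {
  stopifnot(inherits(net, "metnet"))
  add <- additional_reactions(net)
  add[vapply(add, function(r) any(net$subs[[r]] %in% net$host_nodes), TRUE)]
}

#' Split reaction nodes into in/out halves
#'
#' Each listed reaction `r` is replaced by an in-half (receiving all of
#' `r`'s former in-edges and nothing else) and an out-half (emitting all
#' former out-edges).  When the listed set contains a feedback vertex set
#' the split graph is acyclic; `require_acyclic = TRUE` asserts this.
#'
#' @param net a `metnet` object.
#' @param to_split character vector of reaction ids.
#' @param require_acyclic error if the split graph still has a cycle.
#' @return an object of class `split_network`: list with `nodes`
#'   (data.frame `id`, `type` in compound/reaction/in/out, `base`),
#'   `edges`, and `split_pairs` (named list reaction -> c(in, out)).
#' @export
split_nodes <- function(net, to_split, require_acyclic = FALSE) {
  stopifnot(inherits(net, "metnet"))
  to_split <- sort(unique(as.character(to_split)))
  if (!all(to_split %in% net$reactions)) {
    stop("to_split must name reaction nodes; offending: ",
         paste(setdiff(to_split, net$reactions), collapse = ", "))
  }
  in_id <- function(r) paste0(r, "#in")
  out_id <- function(r) paste0(r, "#out")
  e <- net$edges
  from <- ifelse(e$from %in% to_split, out_id(e$from), e$from)
  to <- ifelse(e$to %in% to_split, in_id(e$to), e$to)
  keep_rxn <- setdiff(net$reactions, to_split)
  node_block <- function(ids, type, base) {
    if (!length(base)) {
      return(data.frame(id = character(), type = character(),
                        base = character(), stringsAsFactors = FALSE))
    }
    data.frame(id = ids, type = rep_len(type, length(ids)),
               base = base, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_block(net$compounds, "compound", net$compounds),
    node_block(keep_rxn, "reaction", keep_rxn),
    node_block(in_id(to_split), "in", to_split),
    node_block(out_id(to_split), "out", to_split)
  )
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  acyclic <- graph_is_acyclic(nodes$id, edges)
  if (require_acyclic && !acyclic) {
    stop("split graph still contains a directed cycle; ",
         "to_split does not cover a feedback vertex set")
  }
  split_pairs <- stats::setNames(
    lapply(to_split, function(r) c(in_id(r), out_id(r))), to_split)
  structure(list(base = net, nodes = nodes, edges = edges,
                 split_pairs = split_pairs, acyclic = acyclic),
            class = "split_network")
}

#' Contract split halves back into their original reactions
#'
#' Inverse of [split_nodes()]: merging each in/out pair recovers the
#' original node and edge sets.
#'
#' @param sn a `split_network`.
#' @return list with `nodes` (character) and `edges` (data.frame).
#' @export
merge_split <- function(sn) {
  stopifnot(inherits(sn, "split_network"))
  unsplit_id <- function(x) sub("#(in|out)$", "", x)
  e <- data.frame(from = unsplit_id(sn$edges$from), to = unsplit_id(sn$edges$to),
                  stringsAsFactors = FALSE)
  e <- unique(e)
  list(nodes = sort(unique(unsplit_id(sn$nodes$id))),
       edges = e[order(e$from, e$to), , drop = FALSE])
}
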