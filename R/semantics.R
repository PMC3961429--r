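#' Minimal valid assignment (least fixpoint) of a Boolean metabolic network
#'
#' A 0/1 assignment over the subgraph induced by the host nodes, the
#' inserted additional reactions `va` and their adjacent compounds is
#' *valid* when (i) every source is 1, (ii) a compound is 1 exactly when
#' some producing reaction in the induced graph is 1, and (iii) a reaction
#' is 1 exactly when all its substrates in the induced graph are 1.  With
#' cycles several valid assignments can exist; the *minimal* valid
#' assignment is the unique one whose set of 1-nodes is inclusion-minimal.
#' It equals the least fixpoint of the synchronous Boolean update started
#' from "only sources are 1", which is how it is computed here (Kleene
#' iteration; any worklist order gives the same result because the update
#' operator is monotone).
#'
#' @param net a `metnet` object.
#' @param va character vector of inserted additional reaction ids (may be
#'   empty).
#' @return named integer vector of 0/1 values over the induced node set,
#'   sorted by node id.
#' @examples
#' net <- fixture("CHAIN")
#' minimal_valid_assignment(net, "rm")
#' @export
minimal_valid_assignment <- function(net, va = character()) {
  dom <- induced_domain(net, va)
  vals <- integer(length(dom$nodes))
  names(vals) <- dom$nodes
  vals[net$sources] <- 1L

  rxns <- dom$reactions
  cpds_free <- setdiff(dom$compounds, net$sources)
  repeat {
    changed <- FALSE
    for (r in rxns) {
      if (vals[[r]] == 1L) next
      ss <- dom$subs[[r]]
      if (length(ss) == 0L || all(vals[ss] == 1L)) {
        vals[[r]] <- 1L
        changed <- TRUE
      }
    }
    for (cc in cpds_free) {
      if (vals[[cc]] == 1L) next
      pp <- dom$producers[[cc]]
      if (length(pp) && any(vals[pp] == 1L)) {
        vals[[cc]] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vals
}

# Node set and adjacency of the subgraph induced by host + va + the
# compounds adjacent to va.  Compounds of the reference network outside
# this set are absent (treated as 0 when queried).
induced_domain <- function(net, va = character()) {
  va <- as.character(va)
  extra <- setdiff(va, additional_reactions(net))
  if (length(extra)) {
    stop("not additional reactions of this network: ",
         paste(extra, collapse = ", "))
  }
  rxns <- sort(union(host_reactions(net), va))
  va_cpds <- unlist(c(net$subs[va], net$prods[va]), use.names = FALSE)
  cpds <- sort(union(intersect(net$host_nodes, net$compounds),
                     union(net$sources, va_cpds)))
  subs <- lapply(net$subs[rxns], intersect, cpds)
  producers <- lapply(net$producers[cpds], intersect, rxns)
  list(nodes = c(cpds, rxns), compounds = cpds, reactions = rxns,
       subs = subs, producers = producers)
}

#' Check whether an assignment is valid
#'
#' Tests the three validity conditions of the Boolean model on the
#' subgraph induced by host + `va` (see
#' [minimal_valid_assignment()]).  The assignment's domain must be exactly
#' that induced node set.
#'
#' @inheritParams minimal_valid_assignment
#' @param a named 0/1 vector as returned by [minimal_valid_assignment()].
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_assignment <- function(net, va = character(), a) {
  dom <- induced_domain(net, va)
  if (!setequal(names(a), dom$nodes)) {
    stop("assignment domain does not match the induced node set")
  }
  a <- a[dom$nodes]
  if (any(a[net$sources] != 1L)) return(FALSE)
  for (cc in setdiff(dom$compounds, net$sources)) {
    pp <- dom$producers[[cc]]
    produced <- length(pp) > 0L && any(a[pp] == 1L)
    if ((a[[cc]] == 1L) != produced) return(FALSE)
  }
  for (r in dom$reactions) {
    ss <- dom$subs[[r]]
    ready <- length(ss) == 0L || all(a[ss] == 1L)
    if ((a[[r]] == 1L) != ready) return(FALSE)
  }
  TRUE
}

#' Is a compound producible under a given insertion set?
#'
#' Evaluates the minimal valid assignment of host + `va` and reads off the
#' compound's value; compounds absent from the induced subgraph are not
#' producible.
#'
#' @inheritParams minimal_valid_assignment
#' @param compound a compound id of the reference network.
#' @return `TRUE` or `FALSE`.
#' @export
is_producible <- function(net, va = character(), compound = net$target) {
  if (!(compound %in% net$compounds)) {
    stop("unknown compound id: ", compound)
  }
  a <- minimal_valid_assignment(net, va)
  !is.na(a[compound]) && a[[compound]] == 1L
}

#' Source-connected nodes of an assignment
#'
#' Nodes reachable from some source along a directed path whose nodes are
#' all assigned 1.  For a minimal valid assignment this set equals exactly
#' the 1-nodes; zeroing all non-source-connected nodes of *any* valid
#' assignment yields the minimal valid assignment (which is why it is
#' unique).
#'
#' @param net a `metnet` object.
#' @param a named 0/1 assignment vector.
#' @return sorted character vector of node ids.
#' @export
source_connected_nodes <- function(net, a) {
  nodes <- names(a)
  ones <- nodes[a == 1L]
  start <- intersect(net$sources, ones)
  if (!length(start)) return(character())
  e <- net$edges
  keep <- e$from %in% ones & e$to %in% ones
  adj <- split(e$to[keep], e$from[keep])
  seen <- structure(logical(length(ones)), names = ones)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[[w]]) {
        seen[[w]] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  sort(names(seen)[seen])
}
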