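# Minimum vertex cover machinery: the reduction that proves Minimum
# Reaction Insertion NP-complete, the degree-bounding gadget, and a small
# exhaustive vertex-cover solver used as a cross-check.

#' Simple undirected graphs for the vertex-cover reduction
#'
#' @param vertices character vector of vertex ids.
#' @param edges two-column data.frame (or matrix) of unordered vertex
#'   pairs; self-loops and duplicates are rejected.
#' @return an object of class `mvc_graph`.
#' @export
mvc_graph <- function(vertices, edges) {
  vertices <- as.character(vertices)
  edges <- normalize_edges(edges)
  if (anyDuplicated(vertices)) stop("duplicate vertex ids")
  bad <- setdiff(c(edges$from, edges$to), vertices)
  if (length(bad)) stop("edges reference unknown vertices: ",
                        paste(unique(bad), collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b)
  if (anyDuplicated(key)) stop("duplicate edges")
  o <- order(a, b)
  structure(list(vertices = sort(vertices),
                 edges = data.frame(from = a[o], to = b[o],
                                    stringsAsFactors = FALSE)),
            class = "mvc_graph")
}

#' Read an undirected graph from an edge-list text file
#'
#' One `u v` pair per line, whitespace separated; vertices are the union
#' of the endpoints.
#'
#' @param path file path.
#' @return an `mvc_graph`.
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("from", "to"),
                           colClasses = "character")
  mvc_graph(unique(c(tab$from, tab$to)), tab)
}

#' Seeded Erdos-Renyi-style random simple graph
#'
#' Draws exactly `n_edges` distinct edges uniformly from all vertex pairs.
#'
#' @param n_vertices number of vertices.
#' @param n_edges number of edges (at most `choose(n_vertices, 2)`).
#' @param seed integer seed.
#' @return an `mvc_graph`.
#' @export
random_mvc_graph <- function(n_vertices, n_edges, seed = 1L) {
  stopifnot(n_vertices >= 2L, n_edges >= 1L,
            n_edges <= choose(n_vertices, 2L))
  with_seed(seed, {
    verts <- sprintf("v%d", seq_len(n_vertices))
    all_pairs <- utils::combn(verts, 2L, simplify = FALSE)
    chosen <- sample(all_pairs, n_edges)
    mvc_graph(verts, data.frame(from = vapply(chosen, `[`, "", 1L),
                                to = vapply(chosen, `[`, "", 2L),
                                stringsAsFactors = FALSE))
  })
}

#' Reduce minimum vertex cover to Minimum Reaction Insertion
#'
#' Builds the MRI instance whose minimum insertion count equals the
#' minimum vertex-cover size of `g`: one host source compound feeds one
#' insertable reaction per vertex; the reaction for vertex `v` produces
#' the edge compound `c_e` of every edge incident to `v`; a host target
#' reaction consumes all edge compounds and produces the host target.
#' The target becomes producible exactly when every edge compound has at
#' least one inserted producer, i.e. when the chosen vertices cover every
#' edge, so a size-k cover corresponds to a size-k insertion set.
#'
#' @param g an `mvc_graph` with at least one edge.
#' @return a `metnet` object.
#' @examples
#' g <- mvc_graph(c("u", "v"), data.frame(from = "u", to = "v"))
#' solve_mri(mvc_to_mri(g), method = "brute")$objective  # MVC of one edge: 1
#' @export
mvc_to_mri <- function(g) {
  stopifnot(inherits(g, "mvc_graph"))
  if (nrow(g$edges) == 0L) stop("the graph must have at least one edge")
  edge_cpd <- sprintf("ce_%s_%s", g$edges$from, g$edges$to)
  vx_rxn <- stats::setNames(sprintf("rv_%s", g$vertices), g$vertices)
  ef <- character(); et <- character()
  for (i in seq_along(g$vertices)) {
    v <- g$vertices[i]
    incident <- edge_cpd[g$edges$from == v | g$edges$to == v]
    ef <- c(ef, "src", rep(vx_rxn[[v]], length(incident)))
    et <- c(et, vx_rxn[[v]], incident)
  }
  ef <- c(ef, edge_cpd, "rt")
  et <- c(et, rep("rt", length(edge_cpd)), "tgt")
  build_network(
    compounds = c("src", edge_cpd, "tgt"),
    reactions = c(unname(vx_rxn), "rt"),
    edges = data.frame(from = ef, to = et, stringsAsFactors = FALSE),
    sources = "src", target = "tgt",
    host_nodes = c("src", edge_cpd, "tgt", "rt")
  )
}

#' Exact minimum vertex cover size (oracle)
#'
#' Subset enumeration in increasing cardinality; refuses graphs with more
#' than `max_vertices` vertices.
#'
#' @param g an `mvc_graph`.
#' @param max_vertices refusal bound (default 16).
#' @return integer: the minimum cover size.
#' @export
brute_force_mvc <- function(g, max_vertices = 16L) {
  stopifnot(inherits(g, "mvc_graph"))
  if (length(g$vertices) > max_vertices) {
    stop("brute_force_mvc: more than ", max_vertices, " vertices")
  }
  if (nrow(g$edges) == 0L) return(0L)
  for (k in 0:length(g$vertices)) {
    for (comb in combn_list(g$vertices, k)) {
      if (all(g$edges$from %in% comb | g$edges$to %in% comb)) return(k)
    }
  }
  length(g$vertices)
}

#' Bound all node degrees by 2 with pass-through gadgets
#'
#' Rewrites the network so that every node has indegree and outdegree at
#' most 2, the degree condition of the NP-completeness reduction.  Fan-in
#' and fan-out above 2 are routed through trees of intermediate
#' pass-through nodes (single-input AND / single-producer OR act as plain
#' copies), which preserves the Boolean semantics.  Intermediates are
#' host nodes, so the insertion candidates — and hence the MRI optimum —
#' are exactly those of the input network.
#'
#' @param net a `metnet` object.
#' @return a `metnet` object with `max(indegree, outdegree) <= 2` for
#'   every node.
#' @export
bound_degrees <- function(net) {
  stopifnot(inherits(net, "metnet"))
  compounds <- net$compounds
  reactions <- net$reactions
  host <- net$host_nodes
  edges <- net$edges
  fresh <- 0L
  new_id <- function(prefix) {
    fresh <<- fresh + 1L
    sprintf("%s%03d", prefix, fresh)
  }
  in_of <- function(v) which(edges$to == v)
  out_of <- function(v) which(edges$from == v)

  repeat {
    indeg <- table(factor(edges$to, levels = c(compounds, reactions)))
    outdeg <- table(factor(edges$from, levels = c(compounds, reactions)))
    over_in <- names(indeg)[indeg > 2L]
    over_out <- names(outdeg)[outdeg > 2L]
    if (!length(over_in) && !length(over_out)) break
    v <- c(over_in, over_out)[1L]
    if (v %in% over_in) {
      rows <- in_of(v)[1:2]
      feeders <- edges$from[rows]
      if (v %in% compounds) {
        # two producing reactions collected by an intermediate compound,
        # passed on through a single-substrate (copy) reaction
        xc <- new_id("xc"); xr <- new_id("xr")
        compounds <- c(compounds, xc); reactions <- c(reactions, xr)
        host <- c(host, xc, xr)
        edges <- rbind(edges[-rows, , drop = FALSE],
                       data.frame(from = c(feeders, xc, xr),
                                  to = c(xc, xc, xr, v),
                                  stringsAsFactors = FALSE))
      } else {
        # two substrates pre-combined by an intermediate (copy-out) AND
        xr <- new_id("xr"); xc <- new_id("xc")
        reactions <- c(reactions, xr); compounds <- c(compounds, xc)
        host <- c(host, xc, xr)
        edges <- rbind(edges[-rows, , drop = FALSE],
                       data.frame(from = c(feeders, xr, xc),
                                  to = c(xr, xr, xc, v),
                                  stringsAsFactors = FALSE))
      }
    } else {
      rows <- out_of(v)[1:2]
      sinks <- edges$to[rows]
      if (v %in% compounds) {
        # fan-out through a copy reaction and an intermediate compound
        xr <- new_id("xr"); xc <- new_id("xc")
        reactions <- c(reactions, xr); compounds <- c(compounds, xc)
        host <- c(host, xc, xr)
        edges <- rbind(edges[-rows, , drop = FALSE],
                       data.frame(from = c(v, xr, xc, xc),
                                  to = c(xr, xc, sinks),
                                  stringsAsFactors = FALSE))
      } else {
        xc <- new_id("xc"); xr <- new_id("xr")
        compounds <- c(compounds, xc); reactions <- c(reactions, xr)
        host <- c(host, xc, xr)
        edges <- rbind(edges[-rows, , drop = FALSE],
                       data.frame(from = c(v, xc, xr, xr),
                                  to = c(xc, xr, sinks),
                                  stringsAsFactors = FALSE))
      }
    }
  }
  # A rerouted half may no longer mirror its twin edge-for-edge; keep only
  # pairs whose recorded structure survived the rewrite.
  still_mirrored <- function(p) {
    subs <- function(r) edges$from[edges$to == r]
    prods <- function(r) edges$to[edges$from == r]
    setequal(subs(p[1L]), prods(p[2L])) && setequal(prods(p[1L]), subs(p[2L]))
  }
  pairs <- Filter(still_mirrored, net$reversible_pairs)
  build_network(compounds = compounds, reactions = reactions, edges = edges,
                sources = net$sources, target = net$target,
                host_nodes = intersect(host, c(compounds, reactions)),
                reversible_pairs = pairs)
}
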