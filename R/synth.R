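# Deterministic fixtures and a seeded random-instance generator, so every
# module is testable without external pathway downloads.

fixture_catalog <- c("CHAIN", "CYCTRAP", "BORDER", "INFEASIBLE")

#' Named deterministic test networks
#'
#' * `CHAIN` — a host path with one missing bridge reaction; optimum 1.
#' * `CYCTRAP` — host `rh: s1 -> c1`; an insertable 3-reaction path
#'   `ra1: c1 -> c4`, `ra2: c4 -> c5`, `ra3: c5 -> target`; and an
#'   insertable 2-reaction cycle `rb: target -> c2`, `rc: c2 -> target`.
#'   The cycle looks like a 2-insertion solution but is not source
#'   connected, so the true optimum is 3; timeless encodings fall into
#'   the trap and report 2.
#' * `BORDER` — no cycles; the first insertable reaction consumes a host
#'   compound (a border reaction), exercising the border-node splitting
#'   of the FVS-based encoding; optimum 2.
#' * `INFEASIBLE` — the target has no producing reaction anywhere.
#'
#' @param name one of the catalog names above.
#' @return a `metnet` object.
#' @examples
#' fixture("CYCTRAP")
#' @export
fixture <- function(name) {
  if (!name %in% fixture_catalog) {
    stop("unknown fixture '", name, "'; catalog: ",
         paste(fixture_catalog, collapse = ", "))
  }
  switch(name,
    CHAIN = build_network(
      compounds = c("s", "c1", "t"),
      reactions = c("rh", "rm"),
      edges = data.frame(from = c("s", "rh", "c1", "rm"),
                         to   = c("rh", "c1", "rm", "t")),
      sources = "s", target = "t",
      host_nodes = c("s", "c1", "rh")
    ),
    CYCTRAP = build_network(
      compounds = c("s1", "c1", "c2", "c4", "c5", "target"),
      reactions = c("rh", "ra1", "ra2", "ra3", "rb", "rc"),
      edges = data.frame(
        from = c("s1", "rh", "c1", "ra1", "c4", "ra2", "c5", "ra3",
                 "target", "rb", "c2", "rc"),
        to   = c("rh", "c1", "ra1", "c4", "ra2", "c5", "ra3", "target",
                 "rb", "c2", "rc", "target")),
      sources = "s1", target = "target",
      host_nodes = c("s1", "c1", "rh")
    ),
    BORDER = build_network(
      compounds = c("s", "h1", "c2", "t"),
      reactions = c("rh", "rb1", "rb2"),
      edges = data.frame(from = c("s", "rh", "h1", "rb1", "c2", "rb2"),
                         to   = c("rh", "h1", "rb1", "c2", "rb2", "t")),
      sources = "s", target = "t",
      host_nodes = c("s", "h1", "rh")
    ),
    INFEASIBLE = build_network(
      compounds = c("s", "c1", "t"),
      reactions = c("r1"),
      edges = data.frame(from = c("s", "r1"), to = c("r1", "c1")),
      sources = "s", target = "t",
      host_nodes = c("s", "c1", "r1")
    )
  )
}

#' Seeded random bipartite compound/reaction networks
#'
#' Generates a reproducible instance consisting of a directed
#' source-to-target reaction path (guaranteeing solvability when
#' `ensure_feasible`), additional randomly wired reactions, and
#' `cycle_count` injected compound-reaction-compound-reaction loops
#' attached off the main path — the topology that makes minimal valid
#' assignment semantics non-trivial.  Host membership is drawn per
#' reaction with probability `host_fraction` (the first path reaction is
#' always host, so the host is anchored at the sources); host compounds
#' are the sources plus all compounds touching a host reaction.  The same
#' seed always yields a byte-identical serialization.
#'
#' @param n_compounds total number of compounds including one source and
#'   one target (>= 3).
#' @param n_reactions total number of reactions (>= 2 + 2 * cycle_count).
#' @param host_fraction probability that a reaction belongs to the host.
#' @param cycle_count number of injected 2-reaction directed cycles.
#' @param seed integer seed.
#' @param ensure_feasible keep the generated source-to-target path intact
#'   so that inserting all additional reactions always produces the
#'   target.
#' @return a `metnet` object.
#' @examples
#' net <- random_network(n_compounds = 6, n_reactions = 6, seed = 1)
#' additional_reactions(net)
#' @export
random_network <- function(n_compounds = 8L, n_reactions = 8L,
                           host_fraction = 0.4, cycle_count = 1L,
                           seed = 1L, ensure_feasible = TRUE) {
  stopifnot(n_compounds >= 3L, n_reactions >= 2L,
            host_fraction >= 0, host_fraction <= 1, cycle_count >= 0L)
  if (n_reactions < 2L + 2L * cycle_count) {
    stop("n_reactions too small for ", cycle_count, " cycle(s): need >= ",
         2L + 2L * cycle_count)
  }
  with_seed(seed, {
    src <- "s1"
    tgt <- "t1"
    mids <- sprintf("c%02d", seq_len(n_compounds - 2L))
    rxn_pool <- sprintf("r%02d", seq_len(n_reactions))

    path_len <- min(2L + (stats::runif(1) < 0.5), length(mids) + 1L,
                    n_reactions - 2L * cycle_count)
    inner <- if (path_len > 1L) sample(mids, path_len - 1L) else character()
    path_cpds <- c(src, inner, tgt)
    path_rxns <- rxn_pool[seq_len(path_len)]
    ef <- character(); et <- character()
    for (i in seq_len(path_len)) {
      ef <- c(ef, path_cpds[i], path_rxns[i])
      et <- c(et, path_rxns[i], path_cpds[i + 1L])
    }

    used <- path_len
    # injected cycles: x -> ra -> y -> rb -> x, attached off the path
    for (k in seq_len(cycle_count)) {
      ra <- rxn_pool[used + 1L]; rb <- rxn_pool[used + 2L]; used <- used + 2L
      anchors <- setdiff(c(mids, tgt), src)
      x <- sample(anchors, 1L)
      y <- sample(setdiff(anchors, x), 1L)
      ef <- c(ef, x, ra, y, rb)
      et <- c(et, ra, y, rb, x)
    }

    # remaining reactions: random wiring (never into a source)
    producible_side <- c(mids, tgt)
    for (r in rxn_pool[seq_len(n_reactions - used) + used]) {
      ns <- 1L + (stats::runif(1) < 0.4)
      np <- 1L + (stats::runif(1) < 0.3)
      ss <- sample(c(src, mids, tgt), min(ns, n_compounds))
      rest <- setdiff(producible_side, ss)
      pp <- sample(rest, min(np, length(rest)))
      ef <- c(ef, ss, rep(r, length(pp)))
      et <- c(et, rep(r, length(ss)), pp)
    }

    host_rxn <- rxn_pool[stats::runif(n_reactions) < host_fraction]
    host_rxn <- union(host_rxn, path_rxns[1L])
    if (!ensure_feasible) {
      # allow the path to be broken by dropping its last reaction
      if (stats::runif(1) < 0.5) {
        drop <- path_rxns[path_len]
        keep <- !(ef == drop | et == drop)
        ef <- ef[keep]; et <- et[keep]
        host_rxn <- setdiff(host_rxn, drop)
        rxn_pool <- setdiff(rxn_pool, drop)
      }
    }
    edges <- data.frame(from = ef, to = et, stringsAsFactors = FALSE)
    edges <- unique(edges)
    host_cpd <- union(src, unique(c(edges$from[edges$to %in% host_rxn],
                                    edges$to[edges$from %in% host_rxn])))
    build_network(
      compounds = c(src, mids, tgt),
      reactions = rxn_pool,
      edges = edges,
      sources = src, target = tgt,
      host_nodes = c(host_cpd, host_rxn)
    )
  })
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
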