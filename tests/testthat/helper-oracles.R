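# Independent oracles and small builders used across the test files.
# Everything here is deliberately brute-force / order-naive so that it
# cannot share a bug with the implementation paths it checks.

# All valid assignments of host + va found by exhaustive enumeration over
# {0,1}^nodes of the induced domain.
enumerate_valid_assignments <- function(net, va = character()) {
  a0 <- minimal_valid_assignment(net, va)   # only used for the domain
  nodes <- names(a0)
  n <- length(nodes)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    a <- as.integer(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    names(a) <- nodes
    if (is_valid_assignment(net, va, a)) out[[length(out) + 1L]] <- a
  }
  out
}

# Inclusion-minimal members of a list of assignments (by their 1-sets).
minimal_members <- function(assignments) {
  one_sets <- lapply(assignments, function(a) names(a)[a == 1L])
  keep <- vapply(seq_along(one_sets), function(i) {
    !any(vapply(seq_along(one_sets), function(j) {
      j != i && all(one_sets[[j]] %in% one_sets[[i]]) &&
        !setequal(one_sets[[j]], one_sets[[i]])
    }, TRUE))
  }, TRUE)
  assignments[keep]
}

# Chaotic-order (worklist) least fixpoint, independent of the synchronous
# sweep order used by minimal_valid_assignment().
worklist_fixpoint <- function(net, va = character()) {
  a0 <- minimal_valid_assignment(net, va)
  nodes <- names(a0)
  vals <- stats::setNames(integer(length(nodes)), nodes)
  vals[net$sources] <- 1L
  rxns <- intersect(nodes, net$reactions)
  cpds <- setdiff(intersect(nodes, net$compounds), net$sources)
  queue <- sample(nodes)   # deliberate arbitrary order
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    new_val <- if (v %in% rxns) {
      ss <- intersect(net$subs[[v]], nodes)
      as.integer(length(ss) == 0L || all(vals[ss] == 1L))
    } else if (v %in% cpds) {
      pp <- intersect(net$producers[[v]], rxns)
      as.integer(length(pp) > 0L && any(vals[pp] == 1L))
    } else {
      1L
    }
    if (new_val > vals[[v]]) {
      vals[[v]] <- new_val
      nb <- unique(c(net$edges$to[net$edges$from == v]))
      queue <- c(queue, intersect(nb, nodes))
    }
  }
  vals
}

# Count elementary directed cycles by DFS with a canonical-rotation
# signature; fine for the small graphs used in tests.
count_elementary_cycles <- function(net) {
  nodes <- c(net$compounds, net$reactions)
  adj <- split(net$edges$to, factor(net$edges$from, levels = nodes))
  sigs <- character()
  walk <- function(start, v, path) {
    for (w in adj[[v]]) {
      if (w == start) {
        rot <- which(path == min(path))[1L]
        cyc <- c(path[rot:length(path)], path[seq_len(rot - 1L)])
        sigs[[paste(cyc, collapse = ">")]] <<- ""
      } else if (!(w %in% path) && w > start) {
        walk(start, w, c(path, w))
      }
    }
  }
  for (v in nodes) walk(v, v, v)
  length(sigs)
}

# Evaluate an ip_instance constraint set at a full 0/1 point.
ip_point_feasible <- function(constraints, point) {
  for (co in constraints) {
    lhs <- sum(co$coef * point[names(co$coef)])
    ok <- switch(co$rel,
                 "<=" = lhs <= co$rhs + 1e-9,
                 ">=" = lhs >= co$rhs - 1e-9,
                 "=" = abs(lhs - co$rhs) <= 1e-9)
    if (!ok) return(FALSE)
  }
  TRUE
}

# Distinct time-step indices appearing in an encoding's variable names.
encoding_time_indices <- function(ip) {
  hit <- grepl("\\([0-9]+\\)$", ip$variables)
  sort(unique(as.integer(sub(".*\\(([0-9]+)\\)$", "\\1", ip$variables[hit]))))
}

# The random-instance suite shared by the equivalence tests: small enough
# for the exhaustive oracle, varied enough to hit cycles, borders,
# trivial and infeasible cases.
suite_instance <- function(seed) {
  random_network(
    n_compounds = 4L + (seed %% 5L),
    n_reactions = 6L + (seed %% 5L),
    host_fraction = 0.3 + 0.1 * (seed %% 4L),
    cycle_count = seed %% 3L,
    seed = seed,
    ensure_feasible = seed %% 3L != 0L
  )
}

make_two_bridge_net <- function() {
  # two disjoint single-reaction bridges from host to the target
  build_network(
    compounds = c("s", "t"),
    reactions = c("r1", "r2"),
    edges = data.frame(from = c("s", "r1", "s", "r2"),
                       to = c("r1", "t", "r2", "t")),
    sources = "s", target = "t",
    host_nodes = "s"
  )
}

reset_rows <- function(d) {
  rownames(d) <- NULL
  d
}
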