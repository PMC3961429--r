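#' Solve Minimum Reaction Insertion
#'
#' Finds a minimum-cardinality set of additional (non-host) reactions
#' whose insertion makes the target compound producible under minimal
#' valid assignment semantics.  Producibility is always decided by the
#' Boolean least fixpoint, never by solver status alone: the trivial case
#' (host alone suffices) and the infeasible case (even the full reference
#' cannot produce the target) are detected by one fixpoint evaluation
#' before any integer program is built.
#'
#' Methods: `"C"` (default) is the FVS-based encoding
#' [build_ip_mri_c()] solved over `|split set| + 1` time steps, which is
#' always a sufficient horizon; `"A"` is the fully time-expanded encoding
#' [build_ip_mri_a()]; `"brute"` is the exhaustive oracle
#' [brute_force_mri()]; `"B"` is the timeless encoding, which is unsound
#' on cyclic networks and therefore refused unless `allow_unsafe = TRUE`.
#'
#' @param net a `metnet` object.
#' @param method one of `"C"`, `"A"`, `"brute"`, `"B"`.
#' @param reversible_cost `"pair"` (default) charges a decomposed
#'   reversible pair once; `"direction"` charges each half separately.
#' @param allow_unsafe must be `TRUE` to run the diagnostic `"B"` method.
#' @param node_limit forwarded to [solve_ip()].
#' @return an object of class `mri_solution`: list with `status`
#'   (`"optimal"`, `"trivial"`, `"infeasible"`, or `"limit"`), `inserted`
#'   (reaction ids), `objective` (number of insertion decisions),
#'   `witness` (the minimal valid assignment under the insertion),
#'   `encoding`, and `solver_meta`.
#' @examples
#' solve_mri(fixture("CYCTRAP"), method = "C")
#' @export
solve_mri <- function(net, method = c("C", "A", "brute", "B"),
                      reversible_cost = c("pair", "direction"),
                      allow_unsafe = FALSE, node_limit = 5e6) {
  stopifnot(inherits(net, "metnet"))
  method <- match.arg(method)
  reversible_cost <- match.arg(reversible_cost)

  if (verify_solution(net, character())) {
    return(new_mri_solution("trivial", character(), 0L,
                            minimal_valid_assignment(net, character()),
                            encoding = "none", solver_meta = list()))
  }
  all_add <- additional_reactions(net)
  if (!verify_solution(net, all_add)) {
    return(new_mri_solution("infeasible", character(), NA_integer_,
                            minimal_valid_assignment(net, all_add),
                            encoding = "none", solver_meta = list()))
  }

  if (method == "brute") return(brute_force_mri(net, reversible_cost = reversible_cost))
  if (method == "B" && !allow_unsafe) {
    stop("IP-MRI-B is unsound on cyclic networks; pass allow_unsafe = TRUE ",
         "to use it for diagnostics")
  }

  ip <- switch(method,
    A = build_ip_mri_a(net, reversible_cost),
    B = build_ip_mri_b(net, reversible_cost),
    C = {
      fvs <- find_greedy_fvs(net)
      S <- union(fvs$members, border_reactions(net))
      build_ip_mri_c(net, fvs, reversible_cost, split_border = TRUE,
                     n_steps = length(S) + 1L)
    })
  res <- solve_ip(ip, node_limit = node_limit)
  if (res$status %in% c("limit", "limit_feasible")) {
    return(new_mri_solution("limit", extract_insertion(ip, res), res$objective,
                            NULL, encoding = ip$meta$encoding,
                            solver_meta = res[c("status", "nodes")]))
  }
  if (res$status == "infeasible") {
    # Reachable only for the unsound B on pathological instances; A and C
    # are exact, and true infeasibility was excluded by the fixpoint above.
    stop("encoding ", ip$meta$encoding,
         " reported infeasible although the full reference suffices")
  }
  inserted <- extract_insertion(ip, res)
  if (method %in% c("A", "C") && !verify_solution(net, inserted)) {
    stop("internal error: IP solution failed fixpoint verification")
  }
  new_mri_solution("optimal", inserted, as.integer(round(res$objective)),
                   minimal_valid_assignment(net, inserted),
                   encoding = ip$meta$encoding,
                   solver_meta = list(nodes = res$nodes,
                                      n_variables = length(ip$variables),
                                      n_constraints = length(ip$constraints),
                                      time_steps = ip$meta$time_steps))
}

extract_insertion <- function(ip, res) {
  units <- ip$meta$units
  on <- vapply(names(units), function(u) {
    v <- res$values[[v_ter(u)]]
    !is.na(v) && v == 1L
  }, TRUE)
  sort(unlist(units[on], use.names = FALSE))
}

new_mri_solution <- function(status, inserted, objective, witness,
                             encoding, solver_meta) {
  structure(list(status = status, inserted = inserted, objective = objective,
                 witness = witness, encoding = encoding,
                 solver_meta = solver_meta),
            class = "mri_solution")
}

#' @export
print.mri_solution <- function(x, ...) {
  cat(sprintf("<mri_solution> status: %s", x$status))
  if (!is.na(x$objective)) cat(sprintf("   objective: %d", x$objective))
  cat("\n")
  if (length(x$inserted)) {
    cat("  inserted:", paste(x$inserted, collapse = ", "), "\n")
  }
  if (!is.null(x$encoding) && x$encoding != "none") {
    cat("  encoding:", x$encoding, "\n")
  }
  invisible(x)
}

#' Exhaustive-search oracle for Minimum Reaction Insertion
#'
#' Scans insertion-decision subsets in increasing cardinality (then
#' lexicographically) and returns the first subset under which the target
#' is producible in the minimal valid assignment.  Exact but exponential:
#' refuses instances with more candidate decisions than `max_candidates`.
#'
#' @inheritParams solve_mri
#' @param max_candidates refusal bound on the number of insertion
#'   decisions (default 20).
#' @return an `mri_solution` (encoding `"brute"`).
#' @export
brute_force_mri <- function(net, max_candidates = 20L,
                            reversible_cost = c("pair", "direction")) {
  stopifnot(inherits(net, "metnet"))
  du <- decision_units(net, match.arg(reversible_cost))
  unit_ids <- names(du$units)
  if (length(unit_ids) > max_candidates) {
    stop("brute_force_mri: ", length(unit_ids),
         " candidate decisions exceed the bound of ", max_candidates)
  }
  for (k in 0:length(unit_ids)) {
    for (comb in combn_list(unit_ids, k)) {
      va <- sort(unlist(du$units[comb], use.names = FALSE))
      if (is_producible(net, va, net$target)) {
        status <- if (k == 0L) "trivial" else "optimal"
        return(new_mri_solution(status, va, k,
                                minimal_valid_assignment(net, va),
                                encoding = "brute", solver_meta = list()))
      }
    }
  }
  new_mri_solution("infeasible", character(), NA_integer_,
                   minimal_valid_assignment(net, character()),
                   encoding = "brute", solver_meta = list())
}

#' Verify an insertion set by the fixpoint semantics
#'
#' `TRUE` iff the target is producible under `va` in the minimal valid
#' assignment — independent of any integer-programming artifacts.
#'
#' @inheritParams solve_mri
#' @param va character vector of additional reaction ids.
#' @return `TRUE` or `FALSE`.
#' @export
verify_solution <- function(net, va = character()) {
  is_producible(net, va, net$target)
}

#' Enumerate alternate optimal insertion sets
#'
#' Repeatedly solves the FVS-based encoding, adding after each optimum `V`
#' the no-good cut `sum(x_r, r in V) <= |V| - 1`, until the objective
#' degrades or `limit` solutions are found.  All returned sets are
#' distinct and of equal (optimal) cardinality.
#'
#' @inheritParams solve_mri
#' @param limit maximum number of optima to return.
#' @return list of character vectors (insertion sets).  Empty when the
#'   instance is trivial or infeasible.
#' @export
enumerate_optima <- function(net, limit = 10L,
                             reversible_cost = c("pair", "direction"),
                             node_limit = 5e6) {
  stopifnot(inherits(net, "metnet"))
  reversible_cost <- match.arg(reversible_cost)
  first <- solve_mri(net, method = "C", reversible_cost = reversible_cost,
                     node_limit = node_limit)
  if (first$status != "optimal") return(list())

  fvs <- find_greedy_fvs(net)
  S <- union(fvs$members, border_reactions(net))
  ip <- build_ip_mri_c(net, fvs, reversible_cost, split_border = TRUE,
                       n_steps = length(S) + 1L)
  units <- ip$meta$units

  optima <- list(first$inserted)
  cuts <- list(no_good_cut(units, first$inserted))
  while (length(optima) < limit) {
    res <- solve_ip(ip, extra_constraints = cuts, node_limit = node_limit)
    if (res$status != "optimal") break
    if (round(res$objective) > first$objective) break
    inserted <- extract_insertion(ip, res)
    optima[[length(optima) + 1L]] <- inserted
    cuts[[length(cuts) + 1L]] <- no_good_cut(units, inserted)
  }
  optima
}

no_good_cut <- function(units, inserted) {
  on <- names(units)[vapply(units, function(rs) all(rs %in% inserted), TRUE)]
  lincon(stats::setNames(rep(1, length(on)), v_ter(on)), "<=", length(on) - 1)
}

#' JSON report for an MRI solution
#'
#' Machine-readable summary: status, objective, inserted reactions (with
#' base ids and P/Q direction annotation for decomposed reversible
#' halves), and the producible compounds of the witnessing assignment.
#'
#' @param net a `metnet` object.
#' @param sol an `mri_solution` for `net`.
#' @param path optional output file; when `NULL` the JSON text is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
solution_report <- function(net, sol, path = NULL) {
  stopifnot(inherits(sol, "mri_solution"))
  inserted <- lapply(sol$inserted, function(r) {
    dir <- if (grepl("^P[0-9]", r)) "forward"
           else if (grepl("^Q[0-9]", r)) "backward"
           else "irreversible"
    list(id = base_reaction_id(r), node = r, direction = dir)
  })
  producible <- if (is.null(sol$witness)) character() else {
    sort(intersect(names(sol$witness)[sol$witness == 1L], net$compounds))
  }
  out <- list(status = sol$status,
              objective = if (is.na(sol$objective)) NULL else sol$objective,
              target = net$target,
              inserted = inserted,
              producible_compounds = producible,
              encoding = sol$encoding)
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
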