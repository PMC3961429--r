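# Binary integer-program instances for Minimum Reaction Insertion.
#
# Variables follow the TC/TR/TER/TSR naming convention: TC<id>(t) is the
# value of compound <id> at time step t, TR<id>(t) that of reaction <id>,
# TER<id> is the (time-constant) insertion decision for an additional
# reaction, and TSR<id>(t) is the out-half copy of a split reaction.  The
# complementary F-variables (FR = 1 - TR, ...) are eliminated by the
# 1 - T substitution, halving the variable count.

v_tc <- function(id, t = NULL) if (is.null(t)) paste0("TC", id) else sprintf("TC%s(%d)", id, t)
v_tr <- function(id, t = NULL) if (is.null(t)) paste0("TR", id) else sprintf("TR%s(%d)", id, t)
v_ter <- function(id) paste0("TER", id)
v_tsr <- function(id, t) sprintf("TSR%s(%d)", id, t)

new_ip_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$cons <- vector("list", 256L)
  env$n <- 0L
  env
}

push_cons <- function(env, cons_list) {
  k <- length(cons_list)
  if (env$n + k > length(env$cons)) {
    length(env$cons) <- max(2L * length(env$cons), env$n + k)
  }
  env$cons[env$n + seq_len(k)] <- cons_list
  env$n <- env$n + k
  invisible(env)
}

lincon <- function(coef, rel, rhs) list(coef = coef, rel = rel, rhs = rhs)

fix_var <- function(name, value) lincon(stats::setNames(1, name), "=", value)

#' Exact linearization of Boolean AND / OR over binary variables
#'
#' `linearize_and()` returns constraints whose binary solution set is
#' exactly `output = min(inputs)`: `output <= x_i` for each input and
#' `output >= sum(x_i) - (k - 1)`.  `linearize_or()` encodes
#' `output = max(inputs)`: `output >= x_i` and `output <= sum(x_i)`.  With
#' a single input both reduce to a copy.  Both directions are emitted so
#' that the output value is uniquely forced, which the minimality argument
#' of the time-expanded encodings requires.
#'
#' @param output_var variable name of the AND/OR output.
#' @param input_vars character vector of input variable names (length >= 1).
#' @return list of constraints `list(coef, rel, rhs)`.
#' @examples
#' linearize_and("y", c("x1", "x2"))
#' @export
linearize_and <- function(output_var, input_vars) {
  k <- length(input_vars)
  if (k == 0L) stop("AND with no inputs")
  cons <- lapply(input_vars, function(x) {
    lincon(stats::setNames(c(1, -1), c(output_var, x)), "<=", 0)
  })
  c(cons, list(lincon(
    stats::setNames(c(1, rep(-1, k)), c(output_var, input_vars)), ">=", 1 - k)))
}

#' @rdname linearize_and
#' @export
linearize_or <- function(output_var, input_vars) {
  k <- length(input_vars)
  if (k == 0L) stop("OR with no inputs")
  cons <- lapply(input_vars, function(x) {
    lincon(stats::setNames(c(1, -1), c(output_var, x)), ">=", 0)
  })
  c(cons, list(lincon(
    stats::setNames(c(1, rep(-1, k)), c(output_var, input_vars)), "<=", 0)))
}

# Insertion-decision units.  Under "pair" costing a reversible pair whose
# two halves are both insertable shares one decision variable (one
# insertion covers both directions); under "direction" each half is
# charged separately.
decision_units <- function(net, reversible_cost = c("pair", "direction")) {
  reversible_cost <- match.arg(reversible_cost)
  add <- additional_reactions(net)
  units <- stats::setNames(lapply(add, identity), add)
  if (reversible_cost == "pair") {
    for (p in net$reversible_pairs) {
      if (all(p %in% add)) {
        unit_id <- base_reaction_id(p[1L])
        units[p] <- NULL
        units[[unit_id]] <- p
      }
    }
  }
  units <- units[order(names(units))]
  gate <- character()
  for (u in names(units)) {
    gate[units[[u]]] <- v_ter(u)
  }
  list(units = units, gate = gate)
}

finish_ip <- function(builder, objective, meta) {
  cons <- builder$cons[seq_len(builder$n)]
  vars <- unique(c(names(objective),
                   unlist(lapply(cons, function(co) names(co$coef)), use.names = FALSE)))
  structure(list(variables = vars, objective = objective,
                 constraints = cons, meta = meta),
            class = "ip_instance")
}

#' @export
print.ip_instance <- function(x, ...) {
  cat(sprintf("<ip_instance> %s: %d binary variables, %d constraints\n",
              x$meta$encoding, length(x$variables), length(x$constraints)))
  if (!is.null(x$meta$time_steps)) {
    cat(sprintf("  time steps: %d   insertion decisions: %d\n",
                x$meta$time_steps, x$meta$n_decisions))
  }
  invisible(x)
}

#' Time-expanded insertion encoding (IP-MRI-A)
#'
#' The reference state is unrolled over time steps `t = 0..T` with
#' `T = #compounds + #reactions`, a safe upper bound on the number of
#' synchronous sweeps the least fixpoint needs.  The state at `t + 1` is
#' the exact synchronous Boolean update of the state at `t`: each reaction
#' is the AND of its substrates (plus, for an additional reaction, its
#' insertion decision variable acting as a virtual predecessor), each
#' non-source compound the OR of its producing reactions.  All non-source
#' nodes start at 0, sources are fixed to 1 at every step, the target must
#' be 1 at `t = T`, and the objective counts insertion decisions.  Because
#' the trajectory is forced by the zero initial state and the two-sided
#' AND/OR constraints, the feasible state assignment for a fixed insertion
#' choice is unique and equals the minimal valid assignment.
#'
#' @param net a `metnet` object.
#' @param reversible_cost `"pair"` charges a decomposed reversible pair
#'   once for both directions; `"direction"` charges each half.
#' @return an `ip_instance`.
#' @export
build_ip_mri_a <- function(net, reversible_cost = c("pair", "direction")) {
  stopifnot(inherits(net, "metnet"))
  du <- decision_units(net, reversible_cost)
  n_nodes <- length(net$compounds) + length(net$reactions)
  T_hor <- n_nodes
  b <- new_ip_builder()

  free_cpds <- setdiff(net$compounds, net$sources)
  for (t in 0:(T_hor - 1L)) {
    for (r in net$reactions) {
      inputs <- v_tc(net$subs[[r]], t)
      if (!is.na(du$gate[r])) inputs <- c(inputs, du$gate[[r]])
      out <- v_tr(r, t + 1L)
      if (length(inputs) == 0L) {
        push_cons(b, list(fix_var(out, 1)))
      } else {
        push_cons(b, linearize_and(out, inputs))
      }
    }
    for (cc in free_cpds) {
      prods <- net$producers[[cc]]
      out <- v_tc(cc, t + 1L)
      if (length(prods) == 0L) {
        push_cons(b, list(fix_var(out, 0)))
      } else {
        push_cons(b, linearize_or(out, v_tr(prods, t)))
      }
    }
  }
  for (s in net$sources) {
    push_cons(b, lapply(0:T_hor, function(t) fix_var(v_tc(s, t), 1)))
  }
  push_cons(b, lapply(free_cpds, function(cc) fix_var(v_tc(cc, 0L), 0)))
  push_cons(b, lapply(net$reactions, function(r) fix_var(v_tr(r, 0L), 0)))
  push_cons(b, list(fix_var(v_tc(net$target, T_hor), 1)))

  objective <- stats::setNames(rep(1, length(du$units)), v_ter(names(du$units)))
  finish_ip(b, objective, meta = list(
    encoding = "IP-MRI-A", time_steps = T_hor + 1L,
    n_decisions = length(du$units),
    n_state_vars = n_nodes * (T_hor + 1L),
    units = du$units, gate = du$gate,
    reversible_cost = match.arg(reversible_cost)
  ))
}

#' Timeless insertion encoding (IP-MRI-B; diagnostic only)
#'
#' One variable per node, exact AND/OR equalities, no initialization.  On
#' acyclic induced graphs this is equivalent to [build_ip_mri_a()] with
#' far fewer variables, but on cyclic networks it is *unsound*: a directed
#' cycle may be assigned all-1 without any source support, so the optimum
#' can undercut the true minimum insertion count.  Kept as the documented
#' stepping stone towards the FVS-based encoding and for diagnostics.
#'
#' @inheritParams build_ip_mri_a
#' @return an `ip_instance` (meta carries `sound_on_cycles = FALSE`).
#' @export
build_ip_mri_b <- function(net, reversible_cost = c("pair", "direction")) {
  stopifnot(inherits(net, "metnet"))
  du <- decision_units(net, reversible_cost)
  b <- new_ip_builder()
  for (r in net$reactions) {
    inputs <- v_tc(net$subs[[r]])
    if (!is.na(du$gate[r])) inputs <- c(inputs, du$gate[[r]])
    out <- v_tr(r)
    if (length(inputs) == 0L) {
      push_cons(b, list(fix_var(out, 1)))
    } else {
      push_cons(b, linearize_and(out, inputs))
    }
  }
  for (cc in setdiff(net$compounds, net$sources)) {
    prods <- net$producers[[cc]]
    if (length(prods) == 0L) {
      push_cons(b, list(fix_var(v_tc(cc), 0)))
    } else {
      push_cons(b, linearize_or(v_tc(cc), v_tr(prods)))
    }
  }
  push_cons(b, lapply(net$sources, function(s) fix_var(v_tc(s), 1)))
  push_cons(b, list(fix_var(v_tc(net$target), 1)))
  objective <- stats::setNames(rep(1, length(du$units)), v_ter(names(du$units)))
  finish_ip(b, objective, meta = list(
    encoding = "IP-MRI-B", time_steps = 1L,
    n_decisions = length(du$units),
    n_state_vars = length(net$compounds) + length(net$reactions),
    units = du$units, gate = du$gate, sound_on_cycles = FALSE,
    reversible_cost = match.arg(reversible_cost)
  ))
}

#' FVS-based insertion encoding (IP-MRI-C)
#'
#' The feedback vertex set `fvs` (plus, by default, the border reactions,
#' i.e. insertable reactions with a host substrate) is split into in/out
#' halves, leaving an acyclic graph that is encoded timelessly *within*
#' each time step: reactions (and in-halves) are the AND of their
#' substrates at the same step, compounds the OR of their producers'
#' out-values at the same step.  Time advances only through the split
#' nodes: out-halves start at 0 and copy the in-half of the previous step
#' (`TSR<id>(t+1) = TR<id>(t)`); at the final step in- and out-half must
#' agree, which pins the trajectory to the (unique) minimal valid
#' assignment.  The default horizon is `|fvs| + 1` time steps
#' (`t = 0..|fvs|`), the published step count of the method; it is exact
#' whenever only feedback vertices are split.  Each split border reaction
#' delays propagation by one extra copy, so [solve_mri()] passes
#' `n_steps = |split set| + 1`, which is always sufficient (each step
#' before the fixpoint switches at least one out-half to 1).
#'
#' @inheritParams build_ip_mri_a
#' @param fvs an `fvs_result` (default: [find_greedy_fvs()]).
#' @param split_border also split the border reactions (default `TRUE`).
#' @param n_steps number of time-step indices to unroll; default
#'   `fvs$size + 1`.
#' @return an `ip_instance`.
#' @export
build_ip_mri_c <- function(net, fvs = find_greedy_fvs(net),
                           reversible_cost = c("pair", "direction"),
                           split_border = TRUE, n_steps = NULL) {
  stopifnot(inherits(net, "metnet"))
  du <- decision_units(net, reversible_cost)
  S <- union(fvs$members, if (split_border) border_reactions(net) else character())
  S <- sort(S)
  sn <- split_nodes(net, S, require_acyclic = TRUE)
  if (is.null(n_steps)) n_steps <- fvs$size + 1L
  stopifnot(n_steps >= 1L)
  b <- new_ip_builder()

  free_cpds <- setdiff(net$compounds, net$sources)
  for (t in 0:(n_steps - 1L)) {
    for (r in net$reactions) {
      inputs <- v_tc(net$subs[[r]], t)
      if (!is.na(du$gate[r])) inputs <- c(inputs, du$gate[[r]])
      out <- v_tr(r, t)   # for split reactions this is the in-half
      if (length(inputs) == 0L) {
        push_cons(b, list(fix_var(out, 1)))
      } else {
        push_cons(b, linearize_and(out, inputs))
      }
    }
    for (cc in free_cpds) {
      prods <- net$producers[[cc]]
      if (length(prods) == 0L) {
        push_cons(b, list(fix_var(v_tc(cc, t), 0)))
        next
      }
      # producers that were split contribute through their out-half copy
      inputs <- ifelse(prods %in% S, v_tsr(prods, t), v_tr(prods, t))
      push_cons(b, linearize_or(v_tc(cc, t), inputs))
    }
    for (s in net$sources) push_cons(b, list(fix_var(v_tc(s, t), 1)))
  }
  push_cons(b, lapply(S, function(r) fix_var(v_tsr(r, 0L), 0)))
  if (n_steps >= 2L) {
    for (t in 0:(n_steps - 2L)) {
      push_cons(b, lapply(S, function(r) {
        lincon(stats::setNames(c(1, -1), c(v_tsr(r, t + 1L), v_tr(r, t))), "=", 0)
      }))
    }
  }
  # final-step agreement between in- and out-half: the trajectory has
  # stabilized, i.e. the final step carries the minimal valid assignment
  push_cons(b, lapply(S, function(r) {
    lincon(stats::setNames(c(1, -1), c(v_tr(r, n_steps - 1L), v_tsr(r, n_steps - 1L))), "=", 0)
  }))
  push_cons(b, list(fix_var(v_tc(net$target, n_steps - 1L), 1)))

  objective <- stats::setNames(rep(1, length(du$units)), v_ter(names(du$units)))
  finish_ip(b, objective, meta = list(
    encoding = "IP-MRI-C", time_steps = n_steps,
    n_decisions = length(du$units),
    n_state_vars = (length(net$compounds) + length(net$reactions) + length(S)) * n_steps,
    fvs = fvs$members, split = S,
    units = du$units, gate = du$gate,
    reversible_cost = match.arg(reversible_cost)
  ))
}

#' Export an IP instance in CPLEX-LP format
#'
#' @param ip an `ip_instance`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(ip, path) {
  stopifnot(inherits(ip, "ip_instance"))
  sanitize <- function(x) gsub("[()]", "_", x)
  term_str <- function(coef) {
    nm <- sanitize(names(coef))
    paste(sprintf("%+g %s", unname(coef), nm), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term_str(ip$objective)), "Subject To")
  rel_lp <- c("<=" = "<=", "=" = "=", ">=" = ">=")
  cons <- vapply(seq_along(ip$constraints), function(i) {
    co <- ip$constraints[[i]]
    sprintf(" c%d: %s %s %g", i, term_str(co$coef), rel_lp[[co$rel]], co$rhs)
  }, "")
  lines <- c(lines, cons, "Binary",
             paste("", sanitize(ip$variables)), "End")
  writeLines(lines, path)
  invisible(path)
}
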