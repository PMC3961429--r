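#' Solve a binary integer program exactly
#'
#' Exact minimization over binary variables by depth-first branch and
#' bound with bounds-consistency propagation, branching on the objective
#' (insertion-decision) variables first and trying 0 before 1.  All
#' objective coefficients must be non-negative.  Deterministic: the same
#' instance always yields the same optimal objective, and ties between
#' optimal solutions are broken towards the lexicographically earliest
#' 0/1 pattern in branch order.
#'
#' @param ip an `ip_instance` (see [build_ip_mri_a()] and friends).
#' @param fixed optional named 0/1 vector pre-assigning variables (used
#'   for diagnostics such as trajectory checks).
#' @param extra_constraints optional list of additional constraints
#'   `list(coef, rel, rhs)` (used for no-good cuts when enumerating
#'   alternate optima).
#' @param node_limit abort after this many search nodes; the returned
#'   status then reports `"limit"`/`"limit_feasible"` rather than an
#'   unproved answer.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"limit"`,
#'   `"limit_feasible"`), `objective`, `values` (named 0/1 vector) and
#'   `nodes` searched.
#' @export
solve_ip <- function(ip, fixed = NULL, extra_constraints = NULL,
                     node_limit = 5e6) {
  stopifnot(inherits(ip, "ip_instance"))
  cons <- ip$constraints
  if (length(extra_constraints)) cons <- c(cons, extra_constraints)
  vars <- unique(c(ip$variables,
                   unlist(lapply(extra_constraints, function(co) names(co$coef)),
                          use.names = FALSE)))
  n <- length(vars)
  vidx <- stats::setNames(seq_len(n), vars)

  idx_list <- vector("list", 2L * length(cons))
  coef_list <- vector("list", 2L * length(cons))
  rhs <- numeric(2L * length(cons))
  m <- 0L
  for (co in cons) {
    ii <- unname(vidx[names(co$coef)]) - 1L
    cf <- unname(co$coef)
    if (co$rel %in% c("<=", "=")) {
      m <- m + 1L
      idx_list[[m]] <- ii; coef_list[[m]] <- cf; rhs[m] <- co$rhs
    }
    if (co$rel %in% c(">=", "=")) {
      m <- m + 1L
      idx_list[[m]] <- ii; coef_list[[m]] <- -cf; rhs[m] <- -co$rhs
    }
  }
  idx_list <- idx_list[seq_len(m)]
  coef_list <- coef_list[seq_len(m)]
  rhs <- rhs[seq_len(m)]

  obj <- numeric(n)
  obj[vidx[names(ip$objective)]] <- unname(ip$objective)
  if (any(obj < 0)) stop("solve_ip requires non-negative objective coefficients")
  branch_order <- c(sort(unname(vidx[names(ip$objective)])),
                    setdiff(seq_len(n), unname(vidx[names(ip$objective)]))) - 1L

  init <- rep(-1L, n)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), vars)
    if (length(unknown)) stop("fixed refers to unknown variables: ",
                              paste(unknown, collapse = ", "))
    init[vidx[names(fixed)]] <- as.integer(fixed)
  }

  res <- .solve_ip_cpp(n, idx_list, coef_list, rhs, obj,
                       as.integer(branch_order), init, node_limit)
  values <- res$values
  names(values) <- vars
  list(status = res$status, objective = res$objective,
       values = values, nodes = res$nodes)
}
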