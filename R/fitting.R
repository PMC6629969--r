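# The inverse model: pairwise-stability linear constraints from an
# observed attributed network, and coefficient estimation by linear
# programming.

#' Build pairwise-stability constraints from an observed network
#'
#' Assuming the observed network is pairwise stable, every unordered node
#' pair yields two linear constraints on the six utility coefficients (one
#' per endpoint). For each pair the link is toggled and the endpoint's
#' six-feature vector is evaluated in the linked and unlinked states (all
#' other edges fixed); the constraint row is the difference
#' `linked - unlinked`, in which the distance and birth-time columns appear
#' un-differenced because they exist only in the linked state.
#'
#' Under `convention = "as_printed"` linked pairs receive sense `<= 0` and
#' unlinked pairs `>= 0` (the sign pattern that reproduces an all-negative
#' coefficient signature); `convention = "standard"` flips both senses to
#' match the stability definition literally (a stable network's true
#' coefficients satisfy every linked-pair constraint under this reading).
#'
#' @param graph a neural graph.
#' @param attrs attribute table covering all nodes.
#' @param convention `"as_printed"` or `"standard"` (see Details).
#' @return an object of class `constraint_set`: list with `records` (data
#'   frame: pair ids, endpoint, linked flag, the six feature deltas `d_D`,
#'   `d_B`, `d_S`, `d_P`, `d_C`, `d_Be`, and `sense`), `objective` (the
#'   six-vector of summed linked-state features over linked pairs, whose
#'   inner product with the coefficients is the total utility of the
#'   network), `n`, and `convention`. Exactly `n * (n - 1)` records are
#'   produced for an `n`-node network.
#' @export
build_constraints <- function(graph, attrs,
                              convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  validate_neural_graph(graph)
  A <- adj_from_graph(graph)
  ids <- rownames(A)
  n <- nrow(A)
  am <- attr_matrices(attrs, ids)
  need <- c(S = TRUE, P = TRUE, C = TRUE, Be = TRUE)
  prs <- upper_pairs(n)
  np <- nrow(prs)
  recs <- vector("list", np)
  objective <- setNames(numeric(6), FEATURE_NAMES)
  # observed-state structural features, computed once for the objective
  obs <- state_features(A, seq_len(n), need)
  for (r in seq_len(np)) {
    i <- prs[r, 1]; j <- prs[r, 2]
    ps <- pair_state_features(A, i, j, am$D, am$B, need, "low_to_high")
    sense <- if (ps$linked) {
      if (convention == "as_printed") "le0" else "ge0"
    } else {
      if (convention == "as_printed") "ge0" else "le0"
    }
    recs[[r]] <- data.frame(
      i = ids[c(i, i)], j = ids[c(j, j)], endpoint = ids[c(i, j)],
      linked = ps$linked,
      d_D = ps$delta[, "D"], d_B = ps$delta[, "B"], d_S = ps$delta[, "S"],
      d_P = ps$delta[, "P"], d_C = ps$delta[, "C"], d_Be = ps$delta[, "Be"],
      sense = sense, row.names = NULL)
    if (ps$linked) {
      objective <- objective +
        c(2 * am$D[i, j], 2 * am$B[i, j],
          sum(obs[c(i, j), "S"]), sum(obs[c(i, j), "P"]),
          sum(obs[c(i, j), "C"]), sum(obs[c(i, j), "Be"]))
    }
  }
  structure(list(records = do.call(rbind, recs), objective = objective,
                 n = n, convention = convention),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set: ", nrow(x$records), " records over ", x$n,
      " nodes (convention: ", x$convention, ")\n", sep = "")
  invisible(x)
}

#' @noRd
constraint_matrix <- function(cs) {
  M <- as.matrix(cs$records[, paste0("d_", FEATURE_NAMES)])
  colnames(M) <- FEATURE_NAMES
  M
}

#' Count satisfied constraints for given coefficients
#'
#' Recomputes the residual of every constraint record independently of the
#' solver and counts how many are satisfied at tolerance `tol`.
#'
#' @param cs a [build_constraints()] constraint set.
#' @param coeffs a [utility_coefficients()] vector.
#' @param tol residual tolerance.
#' @return list with `n_satisfied`, `n_violated`, `residuals`.
#' @export
check_constraints <- function(cs, coeffs, tol = 1e-8) {
  co <- as_coeffs(coeffs)
  M <- constraint_matrix(cs)
  res <- as.vector(M %*% co)
  le <- cs$records$sense == "le0"
  ok <- ifelse(le, res <= tol, res >= -tol)
  list(n_satisfied = sum(ok), n_violated = sum(!ok), residuals = res)
}

#' Estimate utility coefficients by linear programming
#'
#' Minimizes the total network utility (the constraint set's `objective`
#' vector dotted with the coefficients — the sum of both endpoints'
#' linked-state utilities over all linked pairs) subject to every
#' constraint record and box bounds on the coefficients. The constraint
#' system is homogeneous, so the zero vector is always feasible; the
#' objective together with the bounds selects a non-trivial vertex. The
#' solve runs through an internal two-phase simplex after shifting the box
#' to the positive orthant. Global optimality is not required of the model — any
#' feasible bounded optimum is acceptable — and coefficients that appear in
#' no constraint and carry no objective weight are reported as 0.
#'
#' In the optional soft mode every record gains a non-negative slack
#' penalized in the objective, so a small number of constraints may be left
#' violated; the satisfied/violated counts in the result are recomputed
#' from the residuals either way. Soft mode is intended for small networks
#' (it adds one LP variable per record).
#'
#' @param cs a [build_constraints()] constraint set.
#' @param bounds length-2 numeric, box bounds for every coefficient.
#' @param mode `"hard"` (default) or `"soft"`.
#' @param penalty slack penalty weight (soft mode).
#' @param objective optional override of the six objective weights.
#' @return an object of class `fit_result`: list with `coefficients` (a
#'   [utility_coefficients()] vector), `objective_value`, `n_satisfied`,
#'   `n_violated`, `solver_status`.
#' @export
fit_coefficients <- function(cs, bounds = c(-1, 1),
                             mode = c("hard", "soft"), penalty = 10,
                             objective = NULL) {
  mode <- match.arg(mode)
  if (!inherits(cs, "constraint_set")) stop("`cs` must be a constraint_set")
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("`bounds` must be c(lower, upper) with lower < upper")
  }
  a <- if (is.null(objective)) unname(cs$objective) else as.numeric(objective)
  if (length(a) != 6L) stop("objective must have six entries")
  M <- constraint_matrix(cs)
  le <- cs$records$sense == "le0"
  if (all(a == 0) && mode == "hard") {
    # no linked pair contributes to the total utility: the homogeneous
    # system admits the zero vector and nothing selects another vertex
    coeffs <- utility_coefficients()
    chk <- check_constraints(cs, coeffs)
    return(structure(list(coefficients = coeffs, objective_value = 0,
                          n_satisfied = chk$n_satisfied,
                          n_violated = chk$n_violated,
                          solver_status = "degenerate: zero objective"),
                     class = "fit_result"))
  }
  lo <- bounds[1]; hi <- bounds[2]
  nv <- 6L
  m <- nrow(M)
  # shift: c = y + lo, y in [0, hi - lo] (boot::simplex needs x >= 0)
  shift_rhs <- -as.vector(M %*% rep(lo, nv))
  if (mode == "hard") {
    rows <- rbind(M, diag(nv))
    rhs <- c(shift_rhs, rep(hi - lo, nv))
    row_le <- c(le, rep(TRUE, nv))
    obj <- a
  } else {
    slack <- matrix(0, m, m)
    slack[cbind(seq_len(m), seq_len(m))] <- ifelse(le, -1, 1)
    rows <- rbind(cbind(M, slack), cbind(diag(nv), matrix(0, nv, m)))
    rhs <- c(shift_rhs, rep(hi - lo, nv))
    row_le <- c(le, rep(TRUE, nv))
    obj <- c(a, rep(penalty, m))
  }
  # the solver expects non-negative rhs; flip offending rows' sense
  neg <- rhs < 0
  rows[neg, ] <- -rows[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  row_le[neg] <- !row_le[neg]
  sol <- tryCatch(
    lp_solve(obj, rows, rhs, ifelse(row_le, "le", "ge")),
    error = function(e) list(status = conditionMessage(e)))
  if (sol$status != "optimal") {
    return(structure(list(coefficients = NULL, objective_value = NA_real_,
                          n_satisfied = NA_integer_, n_violated = NA_integer_,
                          solver_status = paste("failed:", sol$status)),
                     class = "fit_result"))
  }
  y <- sol$x[seq_len(nv)]
  co <- y + lo
  # a coefficient absent from all constraints with zero objective weight is
  # undetermined; report it as 0
  free <- colSums(abs(M)) == 0 & a == 0
  co[free] <- 0
  names(co) <- COEF_NAMES
  coeffs <- do.call(utility_coefficients, as.list(co))
  chk <- check_constraints(cs, coeffs)
  structure(list(coefficients = coeffs,
                 objective_value = sum(a * co),
                 n_satisfied = chk$n_satisfied,
                 n_violated = chk$n_violated,
                 solver_status = "optimal"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Coefficient fit:", x$solver_status, "\n")
  if (!is.null(x$coefficients)) {
    print(round(unclass(x$coefficients), 6))
    cat("objective:", format(x$objective_value, digits = 6),
        " constraints satisfied:", x$n_satisfied, "/",
        x$n_satisfied + x$n_violated, "\n")
  }
  invisible(x)
}
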