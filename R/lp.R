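# Internal dense two-phase simplex used by fit_coefficients.
#
# The coefficient LP is small in variables (six, plus per-record slacks in
# soft mode) but carries hundreds of highly degenerate homogeneous
# constraint rows.  The solver below is a standard tableau simplex with a
# largest-reduced-cost entering rule, switching to Bland's rule after a
# pivot budget to rule out cycling, and an explicit phase 1 with
# artificial variables for the >= rows.

#' @noRd
lp_solve <- function(obj, A, b, sense, tol = 1e-9) {
  m <- nrow(A)
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == m, all(b >= -tol))
  b[b < 0] <- 0
  ge <- sense == "ge"
  n_art <- sum(ge)
  ncols <- n + m + n_art
  Tb <- cbind(A, matrix(0, m, m + n_art))
  basis <- integer(m)
  ai <- 0L
  for (r in seq_len(m)) {
    Tb[r, n + r] <- if (ge[r]) -1 else 1
    if (ge[r]) {
      ai <- ai + 1L
      Tb[r, n + m + ai] <- 1
      basis[r] <- n + m + ai
    } else {
      basis[r] <- n + r
    }
  }
  rhs <- b
  max_iter <- 200L * (m + n) + 5000L

  pivot <- function(state, pr, j) {
    piv <- state$Tb[pr, j]
    prow <- state$Tb[pr, ] / piv
    prhs <- state$rhs[pr] / piv
    f <- state$Tb[, j]
    state$Tb <- state$Tb - outer(f, prow)
    state$rhs <- state$rhs - f * prhs
    state$Tb[pr, ] <- prow
    state$rhs[pr] <- prhs
    state$rhs[state$rhs < 0 & state$rhs > -1e-9] <- 0
    state$basis[pr] <- j
    state
  }

  run_phase <- function(state, cost, allowed) {
    bland_after <- 10L * (m + n)
    for (it in seq_len(max_iter)) {
      red <- cost - as.vector(cost[state$basis] %*% state$Tb)
      red[!allowed] <- 0
      cand <- which(red < -tol)
      if (length(cand) == 0L) {
        state$status <- "optimal"
        return(state)
      }
      j <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
      col <- state$Tb[, j]
      rows <- which(col > tol)
      if (length(rows) == 0L) {
        state$status <- "unbounded"
        return(state)
      }
      ratios <- state$rhs[rows] / col[rows]
      rmin <- min(ratios)
      tie <- rows[ratios <= rmin + tol]
      pr <- tie[which.min(state$basis[tie])]
      state <- pivot(state, pr, j)
    }
    state$status <- "iteration_limit"
    state
  }

  state <- list(Tb = Tb, rhs = rhs, basis = basis, status = "init")
  allowed <- rep(TRUE, ncols)
  if (n_art > 0L) {
    c1 <- c(rep(0, n + m), rep(1, n_art))
    state <- run_phase(state, c1, allowed)
    if (state$status != "optimal") {
      return(list(status = paste0("phase1_", state$status)))
    }
    if (sum(c1[state$basis] * state$rhs) > 1e-6) {
      return(list(status = "infeasible"))
    }
    allowed[(n + m + 1L):ncols] <- FALSE
    # remove artificials still basic at level zero: pivot them out where a
    # structural/slack column is available, else the row is redundant
    keep <- rep(TRUE, length(state$rhs))
    for (r in which(state$basis > n + m)) {
      j <- which(abs(state$Tb[r, seq_len(n + m)]) > tol)[1]
      if (is.na(j)) keep[r] <- FALSE else state <- pivot(state, r, j)
    }
    if (!all(keep)) {
      state$Tb <- state$Tb[keep, , drop = FALSE]
      state$rhs <- state$rhs[keep]
      state$basis <- state$basis[keep]
    }
  }
  c2 <- c(obj, rep(0, ncols - n))
  state <- run_phase(state, c2, allowed)
  if (state$status != "optimal") return(list(status = state$status))
  x <- numeric(ncols)
  x[state$basis] <- state$rhs
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(obj * x[seq_len(n)]))
}
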