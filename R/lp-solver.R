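#' Solve a bounded-variable linear program
#'
#' Self-contained dense two-phase simplex for problems of the form
#' optimize \eqn{c'x} subject to \eqn{A x = b} and \eqn{l \le x \le u}.
#' This is the workhorse behind every flux balance computation in the
#' package; metabolic LPs are small (hundreds of rows/columns) and dense
#' tableau pivoting is entirely adequate at that scale.
#'
#' Upper bounds may be infinite; lower bounds must be finite (metabolic
#' models use the COBRA convention of bounds in \[-1000, 1000\], so this is
#' never restrictive in practice). Entering variables are chosen by the
#' largest reduced cost with smallest-index tie-breaking; after a run of
#' degenerate pivots the rule switches to Bland's rule, which guarantees
#' termination. All pivoting is deterministic, so repeated solves of the
#' same program return identical vertices.
#'
#' @param obj numeric objective coefficients, length n.
#' @param mat constraint matrix (m x n), equality constraints only.
#' @param rhs right-hand side, length m.
#' @param lb,ub variable bounds, length n. `lb` finite, `ub` may be `Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/pivot tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (optimal value, `NA` unless optimal) and `solution`
#'   (numeric vector, `NULL` unless optimal).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 1 written with a slack variable
#' solve_lp(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1, c(0, 0, 0), c(Inf, Inf, Inf))
#' @export
solve_lp <- function(obj, mat, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  mat <- as.matrix(mat)
  m <- nrow(mat)
  n <- ncol(mat)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(ub < lb - tol)) return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  obj <- as.numeric(obj)
  if (!maximize) obj <- -obj

  # shift to y = x - lb with 0 <= y <= span
  span <- ub - lb
  span[span < 0] <- 0
  b0 <- as.numeric(rhs - mat %*% lb)
  A <- mat
  neg <- b0 < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b0[neg] <- -b0[neg]
  }

  if (m == 0L) {
    # no constraints: each variable goes to whichever bound helps
    if (any(obj > tol & !is.finite(span))) {
      return(list(status = "unbounded", objective = NA_real_, solution = NULL))
    }
    x <- lb + ifelse(obj > 0, span, 0)
    val <- sum(obj * x)
    return(list(status = "optimal", objective = if (maximize) val else -val, solution = x))
  }

  ncols <- n + m                       # real + artificial
  Trow <- cbind(A, diag(m))
  span_ext <- c(span, rep(Inf, m))
  basis <- (n + 1L):(n + m)
  xB <- b0
  at_upper <- rep(FALSE, ncols)        # status of nonbasic variables
  is_basic <- rep(FALSE, ncols)
  is_basic[basis] <- TRUE

  run_simplex <- function(cost, allow, Trow, basis, xB, at_upper, is_basic, span_ext) {
    m_cur <- length(basis)
    degenerate_run <- 0L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > 50000L) stop("simplex iteration limit exceeded")
      cB <- cost[basis]
      d <- cost - as.numeric(crossprod(Trow, cB))
      d[basis] <- 0
      elig_lo <- !is_basic & !at_upper & allow & d > 1e-7
      elig_up <- !is_basic & at_upper & allow & d < -1e-7
      elig <- which(elig_lo | elig_up)
      if (length(elig) == 0L) {
        return(list(Trow = Trow, basis = basis, xB = xB, at_upper = at_upper,
                    is_basic = is_basic, status = "optimal"))
      }
      if (degenerate_run > 60L) {
        j <- elig[1L]                  # Bland: smallest index
      } else {
        j <- elig[which.max(abs(d[elig]))]
      }
      delta <- if (at_upper[j]) -1 else 1
      w <- Trow[, j]
      dw <- delta * w
      # ratio test
      t_best <- span_ext[j]            # bound flip
      r_best <- 0L                     # 0 = bound flip
      pos <- which(dw > 1e-9)
      if (length(pos)) {
        tt <- pmax(xB[pos], 0) / dw[pos]
        k <- which.min(tt)
        if (tt[k] < t_best) { t_best <- tt[k]; r_best <- pos[k] }
      }
      neg2 <- which(dw < -1e-9 & is.finite(span_ext[basis]))
      if (length(neg2)) {
        tt <- (span_ext[basis][neg2] - xB[neg2]) / (-dw[neg2])
        k <- which.min(tt)
        if (tt[k] < t_best) { t_best <- tt[k]; r_best <- neg2[k] }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded"))
      }
      t_best <- max(t_best, 0)
      if (t_best < 1e-11) degenerate_run <- degenerate_run + 1L else degenerate_run <- 0L
      xB <- xB - dw * t_best
      if (r_best == 0L) {
        at_upper[j] <- !at_upper[j]    # bound flip, basis unchanged
        next
      }
      leave <- basis[r_best]
      # leaving variable settles at lower (0) or upper bound
      hit_upper <- dw[r_best] < 0
      piv <- Trow[r_best, j]
      if (abs(piv) < 1e-11) stop("numerically singular pivot in simplex")
      Trow[r_best, ] <- Trow[r_best, ] / piv
      other <- seq_len(m_cur)[-r_best]
      colj <- Trow[other, j]
      nz <- which(abs(colj) > 1e-13)
      if (length(nz)) {
        rows <- other[nz]
        Trow[rows, ] <- Trow[rows, , drop = FALSE] -
          outer(colj[nz], Trow[r_best, ])
      }
      enter_val <- if (at_upper[j]) span_ext[j] - t_best else t_best
      basis[r_best] <- j
      xB[r_best] <- enter_val
      is_basic[j] <- TRUE
      is_basic[leave] <- FALSE
      at_upper[leave] <- hit_upper
      xB[xB < 0 & xB > -1e-9] <- 0
    }
  }

  # ---- phase 1: drive artificials to zero ----
  cost1 <- c(rep(0, n), rep(-1, m))
  allow1 <- rep(TRUE, ncols)
  p1 <- run_simplex(cost1, allow1, Trow, basis, xB, at_upper, is_basic, span_ext)
  if (identical(p1$status, "unbounded")) stop("phase-1 LP unbounded (internal error)")
  art_val <- sum(p1$xB[p1$basis > n])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  }
  Trow <- p1$Trow; basis <- p1$basis; xB <- p1$xB
  at_upper <- p1$at_upper; is_basic <- p1$is_basic

  # pivot residual artificials out of the basis; drop redundant rows
  keep <- rep(TRUE, length(basis))
  for (r in seq_along(basis)) {
    if (basis[r] <= n) next
    cand <- which(abs(Trow[r, seq_len(n)]) > 1e-8 & !is_basic[seq_len(n)])
    if (length(cand) == 0L) { keep[r] <- FALSE; next }
    j <- cand[1L]
    piv <- Trow[r, j]
    Trow[r, ] <- Trow[r, ] / piv
    other <- seq_along(basis)[-r]
    colj <- Trow[other, j]
    nz <- which(abs(colj) > 1e-13)
    if (length(nz)) {
      rows <- other[nz]
      Trow[rows, ] <- Trow[rows, , drop = FALSE] - outer(colj[nz], Trow[r, ])
    }
    is_basic[basis[r]] <- FALSE
    is_basic[j] <- TRUE
    xB[r] <- if (at_upper[j]) span_ext[j] else 0
    at_upper[j] <- FALSE
    basis[r] <- j
  }
  if (!all(keep)) {
    Trow <- Trow[keep, , drop = FALSE]
    xB <- xB[keep]
    basis <- basis[keep]
  }

  # ---- phase 2: real objective, artificials barred ----
  cost2 <- c(obj, rep(0, m))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  p2 <- run_simplex(cost2, allow2, Trow, basis, xB, at_upper, is_basic, span_ext)
  if (identical(p2$status, "unbounded")) {
    return(list(status = "unbounded", objective = NA_real_, solution = NULL))
  }
  y <- ifelse(p2$at_upper[seq_len(n)], span, 0)
  y[p2$basis[p2$basis <= n]] <- p2$xB[p2$basis <= n]
  x <- lb + y
  val <- sum(obj * x)
  list(status = "optimal",
       objective = if (maximize) val else -val,
       solution = x)
}
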