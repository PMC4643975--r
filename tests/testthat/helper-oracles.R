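# Independent oracles used across the suite. None of these share code with
# the package's LP path: the LP oracle enumerates basic solutions (vertices)
# directly, and the GPR oracle evaluates rules through R's own parser.

# Brute-force LP by vertex enumeration: optimize obj over {S v = 0 (rows
# given), lb <= v <= ub}. Every vertex has n - m variables at a bound with
# the rest solved from the equality system; all such candidates are checked
# against the bounds. Returns list(feasible, max) (max over vertices).
oracle_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- ncol(S)
  m <- nrow(S)
  best <- -Inf
  feasible <- FALSE
  sgn <- if (maximize) 1 else -1
  consider <- function(v) {
    if (all(v >= lb - 1e-7 & v <= ub + 1e-7)) {
      feasible <<- TRUE
      best <<- max(best, sgn * sum(obj * v))
    }
  }
  if (m == 0L) {
    consider(ifelse(sgn * obj > 0, ub, lb))
    return(list(feasible = feasible, opt = sgn * best))
  }
  fixed_sets <- utils::combn(n, n - m, simplify = FALSE)
  for (fx in fixed_sets) {
    free <- setdiff(seq_len(n), fx)
    Sf <- S[, free, drop = FALSE]
    if (abs(det(Sf)) < 1e-10) next
    grid <- expand.grid(rep(list(1:2), length(fx)))
    for (g in seq_len(nrow(grid))) {
      vfx <- ifelse(unlist(grid[g, ]) == 1, lb[fx], ub[fx])
      if (any(!is.finite(vfx))) next
      vfree <- solve(Sf, -S[, fx, drop = FALSE] %*% vfx)
      v <- numeric(n)
      v[fx] <- vfx
      v[free] <- vfree
      consider(v)
    }
  }
  list(feasible = feasible, opt = sgn * best)
}

oracle_fba <- function(model, objective = NULL) {
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == (objective %||% model$objective))
  oracle_lp(obj, S, model$reactions$lb, model$reactions$ub)
}

oracle_fva_range <- function(model, rid) {
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == rid)
  lo <- oracle_lp(obj, S, model$reactions$lb, model$reactions$ub, maximize = FALSE)
  hi <- oracle_lp(obj, S, model$reactions$lb, model$reactions$ub, maximize = TRUE)
  c(lo$opt, hi$opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GPR oracle: rewrite the rule as an R logical expression and let R's parser
# and evaluator decide. Independent of the package's tokenizer/evaluator.
oracle_gpr <- function(text, deleted) {
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  genes <- unique(unlist(regmatches(expr, gregexpr("[A-Za-z0-9_.-]+", expr))))
  genes <- setdiff(genes, c("TRUE", "FALSE"))
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  eval(parse(text = expr), envir = env)
}

# Dead-end oracle: direct sign-pattern scan over the dense S matrix.
oracle_dead_ends <- function(model) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  out <- character()
  for (i in seq_len(nrow(S))) {
    touch <- which(S[i, ] != 0)
    if (length(touch) == 0L) next
    prod <- any((S[i, touch] > 0 & ub[touch] > 0) | (S[i, touch] < 0 & lb[touch] < 0))
    cons <- any((S[i, touch] < 0 & ub[touch] > 0) | (S[i, touch] > 0 & lb[touch] < 0))
    if (length(touch) == 1L || !(prod && cons)) out <- c(out, rownames(S)[i])
  }
  out
}

# MCC straight from the formula, used as arithmetic cross-check.
oracle_mcc <- function(tp, tn, fp, fn) {
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}
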