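# Dense two-phase primal simplex. The flux networks this package solves
# are small (toy validation models and genome-scale stoichiometries of a
# few hundred reactions), so a plain tableau method with Bland's
# anti-cycling rule is adequate and fully deterministic.

# min c'x  s.t.  A x = b, x >= 0.
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
lp_solve_eq <- function(cvec, A, b, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  pivot <- function(tab, i, j) {
    piv <- tab[i, ] / tab[i, j]
    tab <- tab - outer(tab[, j], piv)
    tab[i, ] <- piv
    tab
  }
  iterate <- function(tab, basis, cost, allowed) {
    rhs <- ncol(tab)
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% tab[, -rhs, drop = FALSE])
      enter <- which(allowed & red < -tol)
      if (!length(enter))
        return(list(tab = tab, basis = basis, status = "optimal"))
      j <- min(enter)                      # Bland's rule
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(tab = tab, basis = basis, status = "unbounded"))
      ratio <- tab[pos, rhs] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]    # Bland's tie-break
      tab <- pivot(tab, i, j)
      basis[i] <- j
    }
    stop("simplex iteration limit reached")
  }

  # phase 1: drive the artificial variables out
  cost1 <- c(rep(0, n), rep(1, m))
  allowed1 <- rep(TRUE, n + m)
  ph1 <- iterate(tab, basis, cost1, allowed1)
  tab <- ph1$tab; basis <- ph1$basis
  if (sum(cost1[basis] * tab[, ncol(tab)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  # pivot any residual zero-level artificials out; drop redundant rows
  keep <- rep(TRUE, nrow(tab))
  for (i in which(basis > n)) {
    j <- which(abs(tab[i, seq_len(n)]) > tol)
    if (length(j)) {
      tab <- pivot(tab, i, j[1])
      basis[i] <- j[1]
    } else {
      keep[i] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  basis <- basis[keep]

  # phase 2 on the real objective, artificial columns barred
  cost2 <- c(cvec, rep(0, m))
  allowed2 <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- iterate(tab, basis, cost2, allowed2)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  tab <- ph2$tab; basis <- ph2$basis
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- tab[inb, ncol(tab)]
  list(status = "optimal", x = x, value = sum(cvec * x))
}

# max/min of v[objective]  s.t.  S v = 0, lb <= v <= ub.
# Shifted to y = v - lb >= 0 with explicit slack rows for y <= ub - lb.
solve_lp <- function(S, lb, ub, objective, maximize = TRUE) {
  n <- ncol(S); m <- nrow(S)
  u <- ub - lb
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(as.numeric(-S %*% lb), u)
  cvec <- numeric(2 * n)
  k <- match(objective, colnames(S))
  if (is.na(k)) stop("unknown objective reaction: ", objective)
  cvec[k] <- if (maximize) -1 else 1
  sol <- lp_solve_eq(cvec, A, b)
  if (sol$status != "optimal") {
    return(list(growth = 0, status = "infeasible",
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S))))
  }
  v <- sol$x[seq_len(n)] + lb
  list(growth = unname(v[k]), status = "optimal",
       fluxes = stats::setNames(v, colnames(S)))
}
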