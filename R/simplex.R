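# Internal LP solver ---------------------------------------------------------
#
# Dense two-phase primal simplex with Bland's anti-cycling rule, written for
# the small, heavily degenerate LPs that flux balance problems produce
# (many all-zero right-hand sides). Standard form: minimize c'z subject to
# A z = b, z >= 0. Phase 1 drives a full set of artificial variables to
# zero; artificial columns are barred from re-entering, and artificials
# left basic at zero level are harmless because the ratio test expels them
# before they could turn positive. Bland's rule (smallest eligible index
# enters; smallest basis index leaves on ties) guarantees termination.
# Tolerances: 1e-9 on reduced costs and pivots, 1e-7 on phase-1 residual.

lp_standard_form <- function(cc, A, b) {
  neg <- b < -0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  list(A = A, b = b, cc = cc)
}

simplex_phase <- function(tab, basis, cost, n_eligible, eps = 1e-9,
                          max_iter = NULL) {
  m <- nrow(tab)
  n <- ncol(tab) - 1L
  if (is.null(max_iter)) max_iter <- 2000L + 200L * n
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    # reduced costs over eligible (original) columns only
    red <- cost[seq_len(n_eligible)] -
      as.vector(crossprod(tab[, seq_len(n_eligible), drop = FALSE], cb))
    red[basis[basis <= n_eligible]] <- 0
    enter <- which(red < -eps)
    if (length(enter) == 0L)
      return(list(tab = tab, basis = basis, status = "optimal"))
    j <- enter[1L]                       # Bland: smallest index enters
    col <- tab[, j]
    pos <- which(col > eps)
    if (length(pos) == 0L)
      return(list(tab = tab, basis = basis, status = "unbounded"))
    ratios <- tab[pos, n + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + eps]
    i <- cand[order(basis[cand])][1L]    # Bland: smallest basis index leaves
    # pivot on (i, j)
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    others <- setdiff(seq_len(m), i)
    tab[others, ] <- tab[others, ] - outer(tab[others, j], tab[i, ])
    basis[i] <- j
  }
  stop("internal simplex exceeded its iteration budget")
}

# minimize cc' z  s.t.  A z = b, z >= 0
lp_solve_standard <- function(cc, A, b) {
  sf <- lp_standard_form(cc, A, b)
  A <- sf$A; b <- sf$b; cc <- sf$cc
  m <- nrow(A); n <- ncol(A)
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_phase(tab, basis, cost1, n_eligible = n)
  resid <- sum(ph1$tab[, ncol(ph1$tab)][ph1$basis > n])
  if (ph1$status != "optimal" || resid > 1e-7)
    return(list(status = "infeasible", z = NULL, value = NA_real_))
  tab <- ph1$tab
  basis <- ph1$basis
  # Drive artificials left basic at zero level out of the basis: pivot on
  # any nonzero original-column entry in their row, or drop the row as
  # redundant when none exists.
  art_rows <- which(basis > n)
  drop_rows <- integer(0)
  for (i in art_rows) {
    j <- which(abs(tab[i, seq_len(n)]) > 1e-9 &
                 !(seq_len(n) %in% basis))
    if (length(j) == 0L) {
      drop_rows <- c(drop_rows, i)
      next
    }
    j <- j[1L]
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    others <- setdiff(seq_len(nrow(tab)), i)
    tab[others, ] <- tab[others, ] - outer(tab[others, j], tab[i, ])
    basis[i] <- j
  }
  if (length(drop_rows) > 0L) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  cost2 <- c(cc, rep(0, m))
  ph2 <- simplex_phase(tab, basis, cost2, n_eligible = n)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", z = NULL, value = NA_real_))
  z <- numeric(n)
  keep <- ph2$basis <= n
  z[ph2$basis[keep]] <- ph2$tab[keep, ncol(ph2$tab)]
  list(status = "optimal", z = z, value = sum(cc * z))
}
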