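# Deterministic dense two-phase simplex with Bland's rule.
# minimize c'x  subject to  A x <= b,  x >= 0.
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
lp_solve_simplex <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # standard form: A x + s = b with slack sign flip for negative b
  Afull <- cbind(A, diag(m))
  for (i in seq_len(m)) if (b[i] < 0) { Afull[i, ] <- -Afull[i, ]; b[i] <- -b[i] }
  nv <- n + m
  # artificials where the slack entered with -1 (flipped rows)
  need_art <- vapply(seq_len(m), function(i) Afull[i, n + i] < 0, TRUE)
  n_art <- sum(need_art)
  art_cols <- integer(0)
  if (n_art > 0) {
    Aart <- matrix(0, m, n_art)
    k <- 0
    for (i in seq_len(m)) if (need_art[i]) { k <- k + 1; Aart[i, k] <- 1 }
    Afull <- cbind(Afull, Aart)
    art_cols <- nv + seq_len(n_art)
  }
  ntot <- ncol(Afull)
  basis <- integer(m); k <- 0
  for (i in seq_len(m)) {
    if (need_art[i]) { k <- k + 1; basis[i] <- nv + k } else basis[i] <- n + i
  }
  Tb <- cbind(Afull, b)  # tableau rows; objective handled via pricing

  pivot <- function(Tb, basis, pr, pc) {
    Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
    for (i in seq_len(nrow(Tb))) if (i != pr && abs(Tb[i, pc]) > 0) {
      Tb[i, ] <- Tb[i, ] - Tb[i, pc] * Tb[pr, ]
    }
    basis[pr] <- pc
    list(Tb = Tb, basis = basis)
  }
  run_phase <- function(Tb, basis, obj) {
    repeat {
      cb <- obj[basis]
      # reduced costs: c_j - cb' B^-1 a_j ; tableau already has B^-1 A
      red <- obj[seq_len(ntot)] - as.numeric(crossprod(cb, Tb[, seq_len(ntot), drop = FALSE]))
      enter <- 0
      for (j in seq_len(ntot)) if (red[j] < -tol) { enter <- j; break }  # Bland
      if (enter == 0) return(list(Tb = Tb, basis = basis, status = "optimal"))
      col <- Tb[, enter]; rhs <- Tb[, ntot + 1]
      leave <- 0; best <- Inf
      for (i in seq_len(m)) if (col[i] > tol) {
        ratio <- rhs[i] / col[i]
        if (ratio < best - tol ||
            (ratio < best + tol && (leave == 0 || basis[i] < basis[leave]))) {
          best <- ratio; leave <- i
        }
      }
      if (leave == 0) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      p <- pivot(Tb, basis, leave, enter)
      Tb <- p$Tb; basis <- p$basis
    }
  }

  if (n_art > 0) {
    obj1 <- numeric(ntot); obj1[art_cols] <- 1
    r <- run_phase(Tb, basis, obj1)
    Tb <- r$Tb; basis <- r$basis
    phase1 <- sum(obj1[basis] * Tb[, ntot + 1])
    if (phase1 > 1e-7) return(list(status = "infeasible", x = NULL, value = Inf))
    # drive remaining artificials out of the basis if possible
    for (i in seq_len(m)) if (basis[i] %in% art_cols) {
      pc <- 0
      for (j in seq_len(nv)) if (abs(Tb[i, j]) > tol) { pc <- j; break }
      if (pc > 0) { p <- pivot(Tb, basis, i, pc); Tb <- p$Tb; basis <- p$basis }
    }
  }
  obj2 <- numeric(ntot); obj2[seq_len(n)] <- cc
  obj2[art_cols] <- 1e9  # keep any stuck artificial at zero
  r <- run_phase(Tb, basis, obj2)
  if (r$status != "optimal") return(list(status = r$status, x = NULL, value = NA))
  Tb <- r$Tb; basis <- r$basis
  x <- numeric(ntot); x[basis] <- Tb[, ntot + 1]
  list(status = "optimal", x = x[seq_len(n)], value = sum(cc * x[seq_len(n)]))
}
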