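# Independent dip oracle: minimal sup-distance between the ECDF and the class
# of unimodal CDFs (convex-then-concave, atom allowed at the mode), solved as
# one small LP per candidate mode position. For tiny n only.


dip_oracle <- function(x) {
  n <- length(x)
  tb <- table(x)
  t <- as.numeric(names(tb))
  K <- length(t)
  if (K == 1L) return(1 / (2 * n))
  Fc <- cumsum(as.numeric(tb)) / n       # F_i at t_i
  Fp <- c(0, Fc[-K])                      # left limits

  best <- Inf
  for (k in seq_len(K)) {
    # variables: g_i (i != k), a, b, d  (all >= 0)
    nv <- (K - 1) + 3
    idx_g <- function(i) if (i < k) i else i - 1  # position of g_i among first K-1
    ia <- K; ib <- K + 1; id <- K + 2
    A <- NULL; rhs <- NULL
    addc <- function(coefs, r) {
      row <- numeric(nv); row[coefs[, 1]] <- coefs[, 2]
      A <<- rbind(A, row); rhs <<- c(rhs, r)
    }
    # bands
    for (i in seq_len(K)) {
      if (i == k) next
      gi <- idx_g(i)
      addc(cbind(c(gi, id), c(1, -1)), Fp[i])    # g_i - d <= Fprev_i
      addc(cbind(c(gi, id), c(-1, -1)), -Fc[i])  # -g_i - d <= -F_i
    }
    addc(cbind(c(ia, id), c(1, -1)), Fp[k])
    addc(cbind(c(ia, id), c(-1, -1)), -Fp[k])
    addc(cbind(c(ib, id), c(1, -1)), Fc[k])
    addc(cbind(c(ib, id), c(-1, -1)), -Fc[k])
    addc(cbind(c(ia, ib), c(1, -1)), 0)          # a <= b
    # left nodes: (t_1,g_1)..(t_{k-1},g_{k-1}),(t_k,a) convex, slopes >= 0
    lx <- c(t[seq_len(k - 1)], t[k])
    lv <- c(vapply(seq_len(k - 1), function(i) as.integer(idx_g(i)), 1L), ia)
    m <- length(lx)
    if (m >= 2) addc(cbind(c(lv[1], lv[2]), c(1, -1)), 0)  # first slope >= 0
    if (m >= 3) for (q in 2:(m - 1)) {
      d1 <- lx[q] - lx[q - 1]; d2 <- lx[q + 1] - lx[q]
      # (y_q-y_{q-1})/d1 <= (y_{q+1}-y_q)/d2
      addc(cbind(c(lv[q - 1], lv[q], lv[q + 1]), c(-d2, d1 + d2, -d1)), 0)
    }
    # right nodes: (t_k,b),(t_{k+1},g_{k+1})..(t_K,g_K) concave, slopes >= 0
    rx <- c(t[k], t[seq(k + 1, K)[seq_len(K - k)]])
    rv <- c(ib, vapply(seq(k + 1, length.out = K - k), function(i) as.integer(idx_g(i)), 1L))
    m <- length(rx)
    if (m >= 2) addc(cbind(c(rv[m - 1], rv[m]), c(1, -1)), 0)  # last slope >= 0
    if (m >= 3) for (q in 2:(m - 1)) {
      d1 <- rx[q] - rx[q - 1]; d2 <- rx[q + 1] - rx[q]
      # slopes nonincreasing: (y_{q+1}-y_q)/d2 <= (y_q-y_{q-1})/d1
      addc(cbind(c(rv[q - 1], rv[q], rv[q + 1]), c(d2, -(d1 + d2), d1)), 0)
    }
    cc <- numeric(nv); cc[id] <- 1
    sol <- lp_solve_simplex(cc, A, rhs)
    if (sol$status == "optimal") best <- min(best, sol$value)
  }
  max(best, 1 / (2 * n))
}
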