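# Independent oracles: derivative-free likelihood maximization, central
# finite-difference Hessians, and direct assembly of the scaled score
# statistics from the printed formulas. Nothing here calls the package's
# Newton fitter or block algebra.

# 12-row fixture (3 missing genotypes) used throughout the oracle tests.
fixture12 <- function() {
  list(
    y = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1),
    E = c(0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0),
    G = c(0, 1, 2, NA, 1, 0, 2, NA, 1, 0, NA, 1)
  )
}

fixture12_dataset <- function() {
  f <- fixture12()
  case_control_dataset(f$y, E = matrix(f$E, ncol = 1,
                                       dimnames = list(NULL, "E")))
}

fixture12_genotype <- function() genotype_vector(fixture12()$G)

oracle_loglik <- function(y, X, theta) {
  p <- plogis(drop(as.matrix(X) %*% theta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Derivative-free MLE via Nelder-Mead with a tight stopping rule.
oracle_mle <- function(y, X, init = NULL) {
  X <- as.matrix(X)
  if (is.null(init)) init <- rep(0, ncol(X))
  opt <- optim(init, function(th) -oracle_loglik(y, X, th),
               method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 50000))
  # one restart from the optimum sharpens Nelder-Mead's final simplex
  opt <- optim(opt$par, function(th) -oracle_loglik(y, X, th),
               method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 50000))
  list(theta = opt$par, loglik = -opt$value)
}

num_hessian <- function(fn, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xpp <- x; xpp[i] <- xpp[i] + eps; xpp[j] <- xpp[j] + eps
      xpm <- x; xpm[i] <- xpm[i] + eps; xpm[j] <- xpm[j] - eps
      xmp <- x; xmp[i] <- xmp[i] - eps; xmp[j] <- xmp[j] + eps
      xmm <- x; xmm[i] <- xmm[i] - eps; xmm[j] <- xmm[j] - eps
      H[i, j] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * eps^2)
    }
  }
  (H + t(H)) / 2
}

# Missing-weighted log-likelihood of the full design at (theta1, theta2),
# the generating function whose negative scaled Hessian is the J-block
# matrix; mask = observation indicators.
oracle_loglik_masked <- function(y, X1, X2, theta, mask) {
  Xf <- cbind(as.matrix(X1), as.matrix(X2))
  p <- plogis(drop(Xf %*% theta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(mask * (y * log(p) + (1 - y) * log(1 - p)))
}

# Numerical J blocks at the null point (theta1, 0): -(1/n) Hessian,
# partitioned into the four blocks; also returns the score by central
# differences.
oracle_blocks <- function(y, X1, X2, theta1, mask, eps = 1e-4) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- length(y)
  p1 <- ncol(X1); p2 <- ncol(X2)
  th0 <- c(theta1, rep(0, p2))
  fn <- function(th) oracle_loglik_masked(y, X1, X2, th, mask)
  H <- num_hessian(fn, th0, eps)
  gr <- sapply(seq_along(th0), function(i) {
    xp <- th0; xp[i] <- xp[i] + eps
    xm <- th0; xm[i] <- xm[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  })
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  list(u1 = gr[i1], u2 = gr[i2],
       J11 = -H[i1, i1, drop = FALSE] / n,
       J12 = -H[i1, i2, drop = FALSE] / n,
       J22 = -H[i2, i2, drop = FALSE] / n,
       n = n)
}

# Scaled assembly of the three score statistics exactly as printed:
# S = {(1/n) sum u2}' V^{-1} {(1/n) sum u2}, V = {-J21 Jmid^{-1} J12 + J22}/n.
oracle_score_stat <- function(U2_scaled_sum, Jmid, J12, J22, n) {
  V <- (-t(J12) %*% solve(Jmid) %*% J12 + J22) / n
  drop(t(U2_scaled_sum) %*% solve(V) %*% U2_scaled_sum)
}

oracle_x2 <- function(E, G, model) {
  G0 <- ifelse(is.na(G), 0, G)
  if (model == "g") matrix(G0, ncol = 1) else cbind(G0, G0 * E)
}

oracle_cst <- function(y, E, G, model = "g") {
  mask <- as.numeric(!is.na(G))
  X1 <- cbind(1, E)
  X2 <- oracle_x2(E, G, model)
  sub <- which(mask == 1)
  th_m <- oracle_mle(y[sub], X1[sub, , drop = FALSE])$theta
  ob <- oracle_blocks(y, X1, X2, th_m, mask)
  oracle_score_stat(ob$u2 / ob$n, ob$J11, ob$J12, ob$J22, ob$n)
}

oracle_pm1 <- function(y, E, G, model = "g") {
  mask <- as.numeric(!is.na(G))
  X1 <- cbind(1, E)
  X2 <- oracle_x2(E, G, model)
  th_f <- oracle_mle(y, X1)$theta
  obm <- oracle_blocks(y, X1, X2, th_f, mask)
  obf <- oracle_blocks(y, X1, X2, th_f, rep(1, length(y)))
  oracle_score_stat(obm$u2 / obm$n, obf$J11, obm$J12, obm$J22, obm$n)
}

oracle_pm2 <- function(y, E, G, model = "g") {
  mask <- as.numeric(!is.na(G))
  X1 <- cbind(1, E)
  X2 <- oracle_x2(E, G, model)
  n <- length(y)
  th_f <- oracle_mle(y, X1)$theta
  obm <- oracle_blocks(y, X1, X2, th_f, mask)
  # efficient score: per-individual assembly of the modified contributions
  p <- plogis(drop(X1 %*% th_f))
  r <- y - p
  B <- solve(obm$J11) %*% obm$J12   # p1 x p2; u2i* = u2i - u1i' (J11^-1 J12)
  u2i <- X2 * (r * mask)
  u1i <- X1 * (r * mask)
  u2star <- u2i - u1i %*% B
  U <- colSums(u2star) / n
  oracle_score_stat(matrix(U, ncol = 1), obm$J11, obm$J12, obm$J22, n)
}

oracle_median <- function(y, E, G, model = "g") {
  obs <- G[!is.na(G)]
  med <- median(obs)
  fill <- floor(med + 0.5 - .Machine$double.eps^0.5)
  Gi <- ifelse(is.na(G), fill, G)
  X1 <- cbind(1, E)
  X2 <- oracle_x2(E, Gi, model)
  th_f <- oracle_mle(y, X1)$theta
  ob <- oracle_blocks(y, X1, X2, th_f, rep(1, length(y)))
  oracle_score_stat(ob$u2 / ob$n, ob$J11, ob$J12, ob$J22, ob$n)
}

oracle_wald <- function(y, E, G, model = "g", eps = 1e-4) {
  mask <- !is.na(G)
  X2 <- oracle_x2(E, G, model)
  X <- cbind(1, E, X2)[mask, , drop = FALSE]
  ys <- y[mask]
  mle <- oracle_mle(ys, X)
  H <- num_hessian(function(th) oracle_loglik(ys, X, th), mle$theta, eps)
  V <- solve(-H)
  i2 <- 2 + seq_len(ncol(X2))
  drop(t(mle$theta[i2]) %*% solve(V[i2, i2, drop = FALSE]) %*% mle$theta[i2])
}

oracle_lrt <- function(y, E, G, model = "g") {
  mask <- !is.na(G)
  X1 <- cbind(1, E)[mask, , drop = FALSE]
  Xf <- cbind(1, E, oracle_x2(E, G, model))[mask, , drop = FALSE]
  ys <- y[mask]
  2 * (oracle_mle(ys, Xf)$loglik - oracle_mle(ys, X1)$loglik)
}
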