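# Independent oracles used to cross-check the package's own algorithms.
# These deliberately share no code with R/.

# SIMPLS (de Jong 1993): an algorithmically distinct PLS formulation whose
# fitted values must agree with the NIPALS engine.
simpls_fit <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  ctr <- colMeans(x)
  yc <- colMeans(y)
  X0 <- sweep(x, 2, ctr)
  Y0 <- sweep(y, 2, yc)
  S <- crossprod(X0, Y0)
  R <- matrix(0, ncol(x), ncomp)
  V <- matrix(0, ncol(x), ncomp)
  Q <- matrix(0, ncol(y), ncomp)
  for (a in seq_len(ncomp)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% q
    t_ <- X0 %*% r
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt
    r <- r / nt
    p_ <- crossprod(X0, t_)
    q_full <- crossprod(Y0, t_)
    v <- p_
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    Q[, a] <- q_full
  }
  B <- R %*% t(Q)
  list(B = B, fitted = sweep(X0 %*% B, 2, yc, "+"))
}

# dense direct solve of the asymmetric-least-squares system, same iteration
# semantics as the sparse implementation
whittaker_dense <- function(y, lambda, p, max_iter = 10L) {
  m <- length(y)
  D <- diff(diag(m), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# small deterministic feature matrix for IO / subset tests: 2 groups x 5
# days x 3 replicates plus QC rows, arbitrary smooth values
toy_fm <- function(n_bins = 4L, qc = 2L) {
  days <- c(1L, 4L, 8L, 12L, 16L)
  meta <- expand.grid(replicate = 1:3, day = days, group = c("B", "F"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_D%d_R%d", meta$group, meta$day,
                            meta$replicate)
  meta <- meta[c("sample_id", "group", "day", "replicate")]
  if (qc > 0) {
    meta <- rbind(meta,
                  data.frame(sample_id = paste0("QC_", seq_len(qc)),
                             group = "QC", day = NA_integer_,
                             replicate = seq_len(qc)))
  }
  vals <- outer(seq_len(nrow(meta)), seq_len(n_bins),
                function(i, j) 100 + 10 * i + j^2)
  feature_matrix(vals, meta,
                 data.frame(bin_id = seq_len(n_bins),
                            rt_min = seq(12, 30, length.out = n_bins)))
}
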