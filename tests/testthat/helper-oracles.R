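# Independent oracles used by the unit and acceptance tests.  These are
# deliberately literal (loops, enumeration) and share no code with the
# package implementations they check.

# Bray-Curtis by the formula, one pair at a time
brute_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

brute_bray_matrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- brute_bray(m[i, ], m[j, ])
  D
}

# Benjamini-Hochberg by the literal step-up definition: walk the sorted
# p-values from the largest down, carrying the running minimum of m*p/rank
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(1, running)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration over all
# C(n1+n2, n1) assignments of the observed values to the in-set group
mwu_enumerate <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  N <- length(vals)
  u_of <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    u <- 0
    for (v in a) u <- u + sum(b < v) + 0.5 * sum(b == v)
    u
  }
  u_obs <- u_of(seq_len(n1))
  all_idx <- utils::combn(N, n1)
  us <- apply(all_idx, 2, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# One-term PERMANOVA pseudo-F by explicit loops: Gower centering and
# hat-matrix traces written out elementwise
permanova_literal_F <- function(D, term) {
  n <- nrow(D)
  A <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) A[i, j] <- -0.5 * D[i, j]^2
  rm_ <- rowMeans(A); cm <- colMeans(A); gm <- mean(A)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) G[i, j] <- A[i, j] - rm_[i] - cm[j] + gm
  X <- cbind(1, term)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  H0 <- matrix(1 / n, n, n)
  tr <- function(M1, M2) {
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + M1[i, j] * M2[j, i]
    s
  }
  trG <- sum(diag(G))
  ss_term <- tr(H, G) - tr(H0, G)
  ss_res <- trG - tr(H, G)
  df_term <- qr(X)$rank - 1
  df_res <- n - qr(X)$rank
  (ss_term / df_term) / (ss_res / df_res)
}

# small null species table: log-normal intensities, TSS-normalized
null_species_matrix <- function(n_samples, n_species) {
  m <- matrix(stats::rlnorm(n_samples * n_species, sdlog = 1.5), n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("sp", seq_len(n_species))))
  m / rowSums(m)
}
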