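# Shared fixtures and independent oracles used across the test files.

# Small designs for fast simulations: same heading sets as the full blocks,
# fewer trials per heading.
small_wide <- function(per = 5L) {
  heading_distribution(c(-33, -27, -21, -15, -9, -3, 3, 9, 15, 21, 27, 33),
                       rep(per, 12L), "wide_small")
}
small_narrow <- function(per = 5L) {
  heading_distribution(seq(3, 33, by = 6), rep(per, 6L), "narrow_small")
}

# Independent matrix-algebra oracle for a balanced two-way fully
# within-subject ANOVA. Y is an n x (A*B) matrix of per-subject cell means
# with columns ordered A-major (B varying fastest). Returns F, dfs and
# GG epsilon per effect, computed from textbook sums of squares and the
# contrast-covariance definition of epsilon - no model-fitting machinery.
rm2way_oracle <- function(Y, A, B) {
  n <- nrow(Y)
  stopifnot(ncol(Y) == A * B)
  arr <- array(t(Y), dim = c(B, A, n)) # [b, a, s]
  m <- mean(arr)
  m_ab <- apply(arr, c(2, 1), mean)      # A x B
  m_a <- rowMeans(m_ab)
  m_b <- colMeans(m_ab)
  m_s <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(2, 3), mean)      # A x n
  m_sb <- apply(arr, c(1, 3), mean)      # B x n

  ss_a <- n * B * sum((m_a - m)^2)
  dev_as <- m_sa - outer(m_a, rep(1, n)) - outer(rep(1, A), m_s) + m
  ss_as <- B * sum(dev_as^2)
  ss_b <- n * A * sum((m_b - m)^2)
  dev_bs <- m_sb - outer(m_b, rep(1, n)) - outer(rep(1, B), m_s) + m
  ss_bs <- A * sum(dev_bs^2)
  dev_ab <- m_ab - outer(m_a, rep(1, B)) - outer(rep(1, A), m_b) + m
  ss_ab <- n * sum(dev_ab^2)
  ss_abs <- 0
  for (s in seq_len(n)) {
    for (a in seq_len(A)) {
      for (b in seq_len(B)) {
        ss_abs <- ss_abs +
          (arr[b, a, s] - m_ab[a, b] - m_sa[a, s] - m_sb[b, s] +
             m_a[a] + m_b[b] + m_s[s] - m)^2
      }
    }
  }
  f_a <- (ss_a / (A - 1)) / (ss_as / ((A - 1) * (n - 1)))
  f_b <- (ss_b / (B - 1)) / (ss_bs / ((B - 1) * (n - 1)))
  f_ab <- (ss_ab / ((A - 1) * (B - 1))) /
    (ss_abs / ((A - 1) * (B - 1) * (n - 1)))

  orth <- function(k) qr.Q(qr(stats::contr.helmert(k)))
  eps_from <- function(M) {
    E <- t(M) %*% stats::cov(Y) %*% M
    sum(diag(E))^2 / (ncol(M) * sum(E * E))
  }
  # columns are A-major with B fastest, so effect transforms are kronecker
  # products with A first
  one_a <- rep(1, A) / A
  one_b <- rep(1, B) / B
  eps_a <- if (A > 2) eps_from(kronecker(orth(A), one_b)) else NA_real_
  eps_b <- if (B > 2) eps_from(kronecker(one_a, orth(B))) else NA_real_
  eps_ab <- eps_from(kronecker(orth(A), orth(B)))

  list(
    F = c(A = f_a, B = f_b, AB = f_ab),
    df1 = c(A = A - 1, B = B - 1, AB = (A - 1) * (B - 1)),
    df2 = c(A = (A - 1) * (n - 1), B = (B - 1) * (n - 1),
            AB = (A - 1) * (B - 1) * (n - 1)),
    pes = c(A = ss_a / (ss_a + ss_as), B = ss_b / (ss_b + ss_bs),
            AB = ss_ab / (ss_ab + ss_abs)),
    gg_eps = c(A = eps_a, B = eps_b, AB = eps_ab)
  )
}

# Long-format table from a subjects x cells matrix, for feeding rm_anova.
# Cell order: A-major, B fastest.
rm2way_long <- function(Y, A, B) {
  n <- nrow(Y)
  grid <- expand.grid(b = seq_len(B), a = seq_len(A))
  do.call(rbind, lapply(seq_len(n), function(s) {
    data.frame(
      participant = sprintf("s%02d", s),
      condition = paste0("a", grid$a),
      ah_deg = grid$b, # reuse the heading column as the second factor
      trial = seq_len(A * B),
      ph_deg = Y[s, ],
      stringsAsFactors = FALSE
    )
  }))
}
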