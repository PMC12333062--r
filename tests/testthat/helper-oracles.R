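# Independent brute-force oracles for the exact tests and the BH step-up.
# These enumerate margin-preserving tables directly and never call the
# package's (or stats::fisher.test's) code paths.

# Two-sided Fisher p for a 2x2 matrix by full hypergeometric enumeration:
# sum the point probabilities of every table with the observed margins that
# do not exceed the observed table's probability (small relative tolerance
# for floating-point ties).
oracle_fisher_2x2 <- function(m, tie_tol = 1e-7) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- exp(lchoose(c1, support) + lchoose(n - c1, r1 - support) -
                 lchoose(n, r1))
  p_obs <- probs[support == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

# All first rows (x_1..x_k) with sum r1 and 0 <= x_j <= colsum_j.
enumerate_first_rows <- function(col_sums, r1) {
  if (length(col_sums) == 1) {
    if (r1 >= 0 && r1 <= col_sums) return(matrix(r1, 1, 1))
    return(matrix(integer(0), 0, 1))
  }
  out <- list()
  for (x in 0:min(col_sums[1], r1)) {
    rest <- enumerate_first_rows(col_sums[-1], r1 - x)
    if (nrow(rest) > 0) {
      out[[length(out) + 1]] <- cbind(x, rest, deparse.level = 0)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, length(col_sums)))
  do.call(rbind, out)
}

# Freeman-Halton exact p for a 2xK matrix by complete enumeration under the
# margin-fixed multivariate hypergeometric null.
oracle_fisher_2xk <- function(m, tie_tol = 1e-7) {
  r1 <- sum(m[1, ]); col_sums <- colSums(m); n <- sum(m)
  if (any(rowSums(m) == 0)) return(1)
  rows <- enumerate_first_rows(col_sums, r1)
  log_p <- vapply(seq_len(nrow(rows)), function(i) {
    sum(lchoose(col_sums, rows[i, ])) - lchoose(n, r1)
  }, numeric(1))
  probs <- exp(log_p)
  obs <- which(apply(rows, 1, function(x) all(x == m[1, ])))
  sum(probs[probs <= probs[obs] * (1 + tie_tol)])
}

# Hand application of the BH step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj_sorted, 1)[order(o)]
}

# Random nonnegative 2x2 table with grand total <= max_n.
random_2x2 <- function(max_n = 30) {
  n <- sample(4:max_n, 1)
  r1 <- sample(1:(n - 1), 1)
  c1 <- sample(1:(n - 1), 1)
  a <- sample(max(0, r1 + c1 - n):min(r1, c1), 1)
  matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), nrow = 2)
}
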