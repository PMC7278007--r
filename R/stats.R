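#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided test of symmetry about zero. Zeros are handled by the
#' Pratt method: all differences (including zeros) are ranked by
#' absolute value with midranks, then the zeros are discarded. For up
#' to `exact_max_n` non-zero differences the null distribution of W+
#' is built exactly by enumerating the sign-flip generating function
#' over the observed (mid)rank multiset, which is valid under ties;
#' above that a normal approximation with Pratt zero correction and
#' tie correction is used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_max_n switchover from exact to approximate (default 25).
#' @return List with `statistic` (W+), `p_value`, `n_nonzero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max_n = 25) {
  d <- differences[is.finite(differences)]
  if (length(d) == 0) stop("no finite differences")
  if (all(d == 0)) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, exact = TRUE))
  }
  r_all <- rank(abs(d))  # Pratt: zeros ranked, then dropped
  nz <- d != 0
  r <- r_all[nz]
  s <- d[nz] > 0
  w <- sum(r[s])
  n <- sum(nz)
  if (n <= exact_max_n) {
    # generating function over 2*rank (integers even with .5 midranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- c(1, numeric(total))  # cnt[w2 + 1] = #sign patterns
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(total + 1 - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, n_nonzero = n, exact = TRUE))
  }
  N <- length(d)
  n0 <- N - n
  mu <- (N * (N + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r_all)
  sigma2 <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = w, p_value = p, n_nonzero = n, exact = FALSE)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided test. For pooled sample sizes up to `exact_max_n` the
#' p-value is exact by enumerating all assignments of the pooled values
#' to the two groups (valid under ties); above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @param exact_max_n switchover from exact to approximate (default 12).
#' @return List with `statistic` (U of group_a), `p_value`, `exact`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max_n = 12) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) {
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  u <- u_of(seq_len(na))
  mu <- na * nb / 2
  if (na + nb <= exact_max_n) {
    combos <- combn(na + nb, na)
    us <- apply(combos, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p_value = p, exact = TRUE))
  }
  n <- na + nb
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {  # all values tied
    return(list(statistic = u, p_value = 1, exact = FALSE))
  }
  z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = u, p_value = p, exact = FALSE)
}
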