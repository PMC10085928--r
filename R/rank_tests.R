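#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetry of the paired differences `x - y` about zero.
#' Zero differences are dropped before ranking (classic Wilcoxon handling).
#' With 25 or fewer remaining pairs the null distribution of the
#' positive-rank sum is computed exactly by convolution over the (mid)ranks,
#' so ties are handled exactly; with more pairs a tie-corrected normal
#' approximation is used.
#'
#' @param x,y numeric vectors of equal length (paired observations).
#' @param exact_max largest number of nonzero pairs for which the exact null
#'   distribution is enumerated.
#' @return Object of class `rank_test`: list with `statistic` (positive-rank
#'   sum W+), `z` (`NA` for exact), `p_value`, `n` (pairs after dropping
#'   zeros), `method` (`"exact"`, `"normal approximation"` or
#'   `"degenerate"`) and `degenerate` flag.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))  # exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(rank_test(statistic = 0, z = NA_real_, p_value = 1, n = 0,
                     method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: W+ sums a uniformly random subset of the (mid)ranks;
    # doubling makes midranks integral for the convolution
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * w))
    cdf_le <- sum(f[seq_len(w2 + 1L)])
    cdf_ge <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    return(rank_test(statistic = w, z = NA_real_, p_value = p, n = n,
                     method = "exact", degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) {
    return(rank_test(statistic = w, z = NA_real_, p_value = 1, n = n,
                     method = "degenerate", degenerate = TRUE))
  }
  z <- (w - mu) / sqrt(v)
  rank_test(statistic = w, z = z, p_value = 2 * stats::pnorm(-abs(z)),
            n = n, method = "normal approximation", degenerate = FALSE)
}

# probability mass of W+ on the support 0..sum(r2), in units of r2 (= 2*ranks)
signed_rank_null <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
      f[seq_len(total + 1L - r)]
    f <- g
  }
  f / 2^length(r2)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided test comparing the distributions of two independent samples.
#' The statistic is `U = #{(i, j): a_i > b_j}` (ties counted 1/2), so
#' swapping the samples maps `U` to `n_a * n_b - U`. The exact null
#' distribution is used when `n_a * n_b <= 400` and the pooled sample is
#' tie-free; otherwise a tie-corrected normal approximation.
#'
#' @param a,b numeric samples (e.g. chronological ages at one stage in two
#'   populations).
#' @param exact_max largest `n_a * n_b` for which the exact distribution is
#'   used (tie-free data only).
#' @return Object of class `rank_test`: list with `statistic` (U for sample
#'   `a`), `z`, `p_value`, `n` (`c(n_a, n_b)`), `method`, `degenerate`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max = 400) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  ra <- sum(r[seq_len(na)])
  u <- ra - na * (na + 1) / 2  # = #{a > b} + 0.5 * #ties
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && na * nb <= exact_max) {
    p <- min(1, 2 * min(stats::pwilcox(u, na, nb),
                        1 - stats::pwilcox(u - 1, na, nb)))
    return(rank_test(statistic = u, z = NA_real_, p_value = p,
                     n = c(na, nb), method = "exact", degenerate = FALSE))
  }
  nn <- na + nb
  mu <- na * nb / 2
  ties <- table(pooled)
  v <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (v <= 0) {
    return(rank_test(statistic = u, z = NA_real_, p_value = 1,
                     n = c(na, nb), method = "degenerate", degenerate = TRUE))
  }
  z <- (u - mu) / sqrt(v)
  rank_test(statistic = u, z = z, p_value = 2 * stats::pnorm(-abs(z)),
            n = c(na, nb), method = "normal approximation", degenerate = FALSE)
}

rank_test <- function(statistic, z, p_value, n, method, degenerate) {
  out <- list(statistic = statistic, z = z, p_value = p_value, n = n,
              method = method, degenerate = degenerate)
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat("Rank test (", x$method, "): statistic = ", format(x$statistic),
      if (!is.na(x$z)) paste0(", z = ", round(x$z, 3)) else "",
      ", p = ", format.pval(x$p_value, digits = 4),
      ", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}
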