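# Independent brute-force / closed-form oracles used to verify the
# package's statistics and the selfing Markov chain. These deliberately
# avoid the code paths (and, for the statistics, the stats:: wrappers)
# they are used to check.

# Exact k-step selfing distribution by gamete enumeration with integer
# weights: each selfing draws one allele from each of two independent
# meioses of the parent, so a heterozygote splits into 4 equally likely
# ordered gamete pairs. Weights are multiples of 4^k, i.e. exact.
enum_selfing_exact <- function(genotype, k) {
  w <- c(0, 0, 0)          # integer weights for genotypes 0,1,2
  w[genotype + 1] <- 1
  for (step in seq_len(k)) {
    w_new <- c(4 * w[1] + w[2],  # 0 stays; het -> aa in 1 of 4 pairings
               2 * w[2],         # het -> Aa or aA
               w[2] + 4 * w[3])  # het -> AA in 1 of 4; hom stays
    w <- w_new
  }
  w / 4^k
}

# Closed-form pooled-variance two-sample t-test (one- or two-tailed)
pooled_t_oracle <- function(x, y, tails = 1) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- if (tails == 1) {
    pt(t_stat, df, lower.tail = FALSE)
  } else {
    2 * pt(abs(t_stat), df, lower.tail = FALSE)
  }
  list(t = t_stat, df = df, p = p)
}

# Simple linear regression by normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  df_res <- length(y) - 2
  r2 <- 1 - ss_res / ss_tot
  f_stat <- (ss_tot - ss_res) / (ss_res / df_res)
  list(intercept = beta[1], slope = beta[2], r_squared = r2,
       f_statistic = f_stat,
       p = pf(f_stat, 1, df_res, lower.tail = FALSE))
}

# Sequential (type I) sums of squares for a nested sequence of design
# matrices, via explicit least squares; returns per-term F and p
seq_anova_oracle <- function(y, X_list) {
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  rss_seq <- c(sum((y - mean(y))^2), vapply(X_list, rss, 0))
  df_terms <- vapply(X_list, ncol, 0L) - c(1L, vapply(
    X_list[-length(X_list)], ncol, 0L))
  ss_terms <- -diff(rss_seq)
  df_res <- length(y) - ncol(X_list[[length(X_list)]])
  ms_res <- rss_seq[length(rss_seq)] / df_res
  f_vals <- (ss_terms / df_terms) / ms_res
  list(sum_sq = ss_terms, df = df_terms, f = f_vals,
       p = pf(f_vals, df_terms, df_res, lower.tail = FALSE))
}
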