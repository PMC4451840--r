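#' Number of distinct two-group arrangements
#'
#' Exact binomial coefficient `C(n, n1)`: the number of ways to reassign
#' `n` pooled observations to a group of size `n1`, i.e. the size of the
#' exhaustive randomisation distribution (8,568 for n = 18, n1 = 13;
#' 225,792,840 for n = 32, n1 = 20).
#'
#' @param n pooled sample size.
#' @param n1 size of group 1.
#' @return exact count (numeric; exact for all values below 2^53).
#' @export
count_arrangements <- function(n, n1) {
  if (n < 0 || n1 < 0) stop("n and n1 must be non-negative")
  if (n1 > n) stop("n1 must not exceed n")
  n <- as.numeric(n); n1 <- as.numeric(min(n1, n - n1))
  if (n1 == 0) return(1)
  ## multiplicative formula; every intermediate product C(n, k) is integral
  out <- 1
  for (k in seq_len(n1)) out <- out * (n - n1 + k) / k
  round(out)
}

#' Two-group randomisation test
#'
#' Permutation test without replacement on the difference of group means.
#' When the number of distinct reassignments `C(n, n1)` does not exceed
#' `exhaustive_limit`, every arrangement is enumerated and the p-value is
#' exact (a rational with that denominator); otherwise `n_iterations` random
#' reassignments are drawn and the Monte-Carlo p-value uses the add-one
#' convention `(b + 1)/(m + 1)`, which counts the observed arrangement and
#' never reports zero.
#'
#' @param x,y numeric vectors: the two groups.
#' @param tail `"two_sided"` (default, for undirected group comparisons),
#'   `"greater"` or `"less"` on `mean(x) - mean(y)`.
#' @param exhaustive_limit switch point between exhaustive enumeration and
#'   Monte-Carlo sampling (default 200,000: a sample of 18 with group size
#'   13 enumerates, 32 with 20 samples).
#' @param n_iterations Monte-Carlo iterations.
#' @param seed integer RNG seed (Monte-Carlo branch only).
#' @return list of class `permutation_test` with `statistic`, `p_value`,
#'   `method`, `n_arrangements` or `n_iterations`, and `tail`.
#' @export
randomisation_test <- function(x, y, tail = c("two_sided", "greater", "less"),
                               exhaustive_limit = 200000,
                               n_iterations = 9999, seed = 1L) {
  tail <- match.arg(tail)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  obs <- mean(x) - mean(y)
  if (max(pooled) == min(pooled)) {
    warning("pooled data are constant; p = 1")
    return(structure(list(statistic = 0, p_value = 1, method = "exhaustive",
                          n_arrangements = count_arrangements(n, n1),
                          n_iterations = NA_integer_, tail = tail),
                     class = "permutation_test"))
  }
  tot <- sum(pooled)
  ## mean(x*) - mean(y*) is an affine function of sum(x*)
  stat_from_sum1 <- function(s1) s1 / n1 - (tot - s1) / (n - n1)
  eps <- 1e-9 * max(1, abs(obs))
  exceeds <- switch(tail,
    two_sided = function(s) abs(s) >= abs(obs) - eps,
    greater = function(s) s >= obs - eps,
    less = function(s) s <= obs + eps)
  n_arr <- count_arrangements(n, n1)
  if (n_arr <= exhaustive_limit) {
    sums <- utils::combn(pooled, n1, sum)
    b <- sum(exceeds(stat_from_sum1(sums)))
    structure(list(statistic = obs, p_value = b / n_arr,
                   method = "exhaustive", n_arrangements = n_arr,
                   n_iterations = NA_integer_, tail = tail),
              class = "permutation_test")
  } else {
    b <- with_seed(seed, {
      sums <- replicate(n_iterations, sum(pooled[sample.int(n, n1)]))
      sum(exceeds(stat_from_sum1(sums)))
    })
    structure(list(statistic = obs, p_value = (b + 1) / (n_iterations + 1),
                   method = "monte_carlo", n_arrangements = n_arr,
                   n_iterations = n_iterations, tail = tail),
              class = "permutation_test")
  }
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Randomisation test (%s, %s): diff of means = %.4g, p = %.4g\n",
              x$method, x$tail, x$statistic, x$p_value))
  if (x$method == "exhaustive")
    cat(sprintf("  %s arrangements enumerated\n",
                format(x$n_arrangements, big.mark = ",")))
  else
    cat(sprintf("  %d Monte-Carlo iterations (of %s arrangements)\n",
                x$n_iterations, format(x$n_arrangements, big.mark = ",")))
  invisible(x)
}

#' Monte-Carlo Spearman rank correlation test
#'
#' Spearman's rho on average ranks, with a one-tailed p-value approximated
#' by Monte-Carlo permutation of `v` (default 9,999 replications), using
#' the add-one convention `(b + 1)/(m + 1)`.
#'
#' @param u,v numeric vectors of equal length (>= 3).
#' @param tail `"greater"` (rho larger than null) or `"less"`.
#' @param n_iterations permutation replications.
#' @param seed integer RNG seed.
#' @return list of class `correlation_test` with `rho`, `p_value`, `n`,
#'   `n_iterations`, `tail`.
#' @export
spearman_mc_test <- function(u, v, tail = c("greater", "less"),
                             n_iterations = 9999, seed = 1L) {
  tail <- match.arg(tail)
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (length(u) < 3) stop("need at least 3 pairs")
  if (max(u) == min(u) || max(v) == min(v))
    stop("constant vector: rank correlation undefined")
  ru <- rank(u); rv <- rank(v)
  rho_of <- function(rv_perm) stats::cor(ru, rv_perm)
  rho <- rho_of(rv)
  eps <- 1e-12
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_iterations), function(i) {
      r <- rho_of(rv[sample.int(length(rv))])
      if (tail == "greater") r >= rho - eps else r <= rho + eps
    }, logical(1)))
  })
  structure(list(rho = rho, p_value = (b + 1) / (n_iterations + 1),
                 n = length(u), n_iterations = n_iterations, tail = tail),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo Spearman test (%s): rho = %.3f, n = %d, p = %.4g (%d replications)\n",
              x$tail, x$rho, x$n, x$p_value, x$n_iterations))
  invisible(x)
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected statistic `sum((|O - E| - 0.5)^2 / E)` with the
#' correction clamped at `|O - E|` so near-proportional tables cannot yield
#' a negative correction; p-value from the chi-square distribution with one
#' degree of freedom.
#'
#' @param a,b,c,d cell counts, row-wise: `a` and `b` are the first row
#'   (e.g. recovered / not recovered among tagged birds), `c` and `d` the
#'   second (untagged birds).
#' @return list with `chi2`, `p_value`, `df`.
#' @export
yates_chi2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  if (any(o < 0)) stop("counts must be non-negative")
  rs <- c(a + b, c + d); cs <- c(a + c, b + d); n <- sum(o)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  e <- c(rs[1] * cs[1], rs[1] * cs[2], rs[2] * cs[1], rs[2] * cs[2]) / n
  dev <- pmax(abs(o - e) - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}
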