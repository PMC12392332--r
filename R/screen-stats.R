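#' Average-tie rank transform
#'
#' 1-based ranks with ties receiving the average of the tied positions, as
#' used by the Spearman correlation.  A thin validating wrapper around
#' [base::rank()].
#'
#' @param values numeric vector, finite, non-empty.
#' @return Numeric vector of midranks.
#' @examples
#' rank_transform(c(5, 5, 1))  # 2.5 2.5 1
#' @export
rank_transform <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite value at index ", paste(bad, collapse = ", "),
         call. = FALSE)
  rank(values, ties.method = "average")
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the midrank transforms; without ties this equals
#' the classical `1 - 6 * sum(d^2) / (n * (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return rho in \[-1, 1\].
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  cor(rx, ry)
}

#' Two-sided p-value for a Spearman correlation
#'
#' `method = "t_approx"` (default) refers
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` to a Student-t distribution with
#' `n - 2` degrees of freedom.  `method = "exact_perm"` (n <= 9) enumerates
#' all `n!` permutations of the ranks of one margin and returns
#' `P(|rho_perm| >= |rho|)`; at `|rho| = 1` this is `2 / n!`.
#'
#' @param rho observed correlation in \[-1, 1\].
#' @param n sample size, `n >= 4`.
#' @param method `"t_approx"` or `"exact_perm"`.
#' @return p-value in (0, 1\].
#' @examples
#' spearman_pvalue(0.8, 5)            # ~0.104
#' spearman_pvalue(1, 5, "exact_perm")  # 2/120
#' @export
spearman_pvalue <- function(rho, n, method = c("t_approx", "exact_perm")) {
  method <- match.arg(method)
  if (!is.finite(rho) || abs(rho) > 1 + 1e-12)
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  rho <- max(-1, min(1, rho))
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (method == "t_approx") {
    if (abs(rho) >= 1) return(.Machine$double.xmin)
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    return(min(1, 2 * pt(-abs(t), df = n - 2)))
  }
  if (n > 9) stop("exact_perm supported only for n <= 9", call. = FALSE)
  rhos <- perm_rho_distribution(n)
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

# All n! Spearman correlations between 1..n and its permutations
# (tie-free case); cached per n.
perm_rho_distribution <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perms <- permutations_of(n)
    r <- seq_len(n)
    # rho = 1 - 6 * sum((r - perm)^2) / (n (n^2 - 1))
    d2 <- colSums((r - t(perms))^2)
    rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
    cache[[key]] <<- rhos
    rhos
  }
})

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Estimate the null proportion pi0 (Storey)
#'
#' `mode = "smoother"`: compute `pi0(lambda) = #\{p > lambda\} / (m (1 -
#' lambda))` on a grid of lambda values, fit a cubic smoothing spline
#' (3 df) and evaluate it at the largest lambda; the estimate is clamped to
#' `[pi0_floor, 1]`.  `mode = "fixed"` returns `pi0_fixed` (so q-values
#' reduce to Benjamini-Hochberg when `pi0_fixed = 1`).  Fewer than 10
#' p-values in smoother mode falls back to the fixed value with a warning.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param mode `"smoother"` or `"fixed"`.
#' @param lambda_grid grid for the smoother, strictly increasing in \[0, 1).
#' @param pi0_fixed value returned in fixed mode (default 1).
#' @param pi0_floor lower clamp; defaults to `1 / length(p_values)`.
#' @return pi0 estimate in (0, 1\].
#' @export
estimate_pi0 <- function(p_values,
                         mode = c("smoother", "fixed"),
                         lambda_grid = seq(0.05, 0.95, by = 0.05),
                         pi0_fixed = 1.0,
                         pi0_floor = 1 / length(p_values)) {
  mode <- match.arg(mode)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (mode == "fixed") return(pi0_fixed)
  m <- length(p_values)
  if (m < 10L) {
    warning("fewer than 10 p-values; falling back to fixed pi0 = ",
            pi0_fixed)
    return(pi0_fixed)
  }
  if (is.unsorted(lambda_grid, strictly = TRUE) ||
      any(lambda_grid < 0) || any(lambda_grid >= 1))
    stop("`lambda_grid` must be strictly increasing within [0, 1)",
         call. = FALSE)
  pi0_lambda <- vapply(lambda_grid,
                       function(l) mean(p_values > l) / (1 - l), 0.0)
  fit <- smooth.spline(lambda_grid, pi0_lambda, df = 3)
  pi0 <- predict(fit, x = max(lambda_grid))$y
  max(pi0_floor, min(1, pi0))
}

#' Storey q-values
#'
#' With p-values sorted ascending, `q(i) = min_{j >= i} pi0 * m * p(j) / j`,
#' capped at 1 and returned in the input order.  With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjusted p-value.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param pi0 estimated null proportion in (0, 1\], e.g. from
#'   [estimate_pi0()].
#' @return q-values, same length and order as `p_values`.
#' @examples
#' storey_qvalues(c(0.001, 0.5, 0.9), pi0 = 1)  # 0.003 0.75 0.90
#' @export
storey_qvalues <- function(p_values, pi0) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1)
    stop("`pi0` must lie in (0, 1]", call. = FALSE)
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, pi0 * m * p_values[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
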