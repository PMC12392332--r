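#' Steel-Dwass pairwise rank statistic
#'
#' For one pair of groups, pools the observations, assigns midranks, and
#' computes the rank sum `W` of the second group, its null expectation
#' `E_W = n_b (N + 1) / 2`, the ties-corrected variance
#' `Var_W = n_a n_b / (N (N - 1)) * (sum(r^2) - N (N + 1)^2 / 4)`, and the
#' standardized statistic `t = (W - E_W) / sqrt(Var_W)` (defined as 0 when
#' every pooled value is tied).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A list (class `"steel_dwass_pair"`) with `n_a`, `n_b`, `W`,
#'   `E_W`, `Var_W`, `t_stat`.
#' @export
steel_dwass_pair_stat <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite observations", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b), ties.method = "average")
  W <- sum(r[(na + 1L):N])
  E_W <- nb * (N + 1) / 2
  Var_W <- na * nb / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  t_stat <- if (Var_W > 0) (W - E_W) / sqrt(Var_W) else 0
  structure(list(n_a = na, n_b = nb, W = W, E_W = E_W,
                 Var_W = Var_W, t_stat = t_stat),
            class = "steel_dwass_pair")
}

#' Upper tail of the studentized range distribution (infinite df)
#'
#' `P(Q_{k, Inf} >= q)`, the reference law of the Steel-Dwass procedure.
#' For `k = 2` this reduces to the two-sided normal tail at `q / sqrt(2)`.
#'
#' @param q nonnegative quantile.
#' @param k number of groups, `k >= 2`.
#' @return Survival probability in (0, 1\].
#' @examples
#' studentized_range_sf(sqrt(2) * 1.96, k = 2)  # ~0.05
#' @export
studentized_range_sf <- function(q, k) {
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every unordered pair of groups, computes the pairwise rank statistic
#' ([steel_dwass_pair_stat()]) and refers `sqrt(2) * |t|` to the
#' studentized range distribution with `k` groups and infinite degrees of
#' freedom.  Family-wise error control is internal to the procedure; no
#' further multiplicity adjustment is applied.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each of
#'   length >= 2), or a data frame plus `value_col`/`group_col` names.
#' @param value_col,group_col column names when `groups` is a data frame.
#' @return A data frame of class `"steel_dwass"`, one row per pair:
#'   `group_a`, `group_b`, `W`, `E_W`, `Var_W`, `t_stat`, `p_value`.
#' @examples
#' steel_dwass_test(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
steel_dwass_test <- function(groups, value_col = NULL, group_col = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(value_col), !is.null(group_col))
    groups <- split(groups[[value_col]], groups[[group_col]])
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_len(k))
  small <- names(groups)[vapply(groups, length, 0L) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)

  pairs <- combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1L, j]; gb <- pairs[2L, j]
    s <- steel_dwass_pair_stat(groups[[ga]], groups[[gb]])
    data.frame(group_a = ga, group_b = gb,
               W = s$W, E_W = s$E_W, Var_W = s$Var_W, t_stat = s$t_stat,
               p_value = studentized_range_sf(sqrt(2) * abs(s$t_stat), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("steel_dwass", "data.frame")
  attr(out, "k") <- k
  out
}

#' @export
print.steel_dwass <- function(x, digits = 4, ...) {
  cat(sprintf("Steel-Dwass all-pairs comparison (%d groups)\n", attr(x, "k")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Pairs with zero difference are dropped (with a message).  The exact
#' signed-rank distribution is used for n <= 25 untied differences; with
#' ties or larger n, the normal approximation with ties-corrected variance
#' and continuity correction is used.  If every difference is zero,
#' returns p = 1 with a warning.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))  # 0.25
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  zero <- d == 0
  if (any(zero)) message("dropping ", sum(zero), " zero difference(s)")
  d <- d[!zero]
  if (length(d) == 0L) {
    warning("all differences are zero; p = 1")
    return(1.0)
  }
  n <- length(d)
  exact <- n <= 25L && !anyDuplicated(abs(d))
  suppressWarnings(
    wilcox.test(d, mu = 0, exact = exact, correct = !exact)$p.value
  )
}
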