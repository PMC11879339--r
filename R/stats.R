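#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution for small samples without ties (<= 25 per group),
#' normal approximation with continuity correction otherwise; midranks for
#' ties.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list of class `test_result`: `statistic` (W), `p`, `n`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 25 && length(y) <= 25
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value, c(length(x), length(y)),
              if (exact) "wilcoxon-exact" else "wilcoxon-normal")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; p from the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return `test_result` with `statistic` = rho; `flag = "zero_variance"`
#'   and `statistic = NA` when either rank vector is constant.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need n >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    out <- test_result(NA_real_, NA_real_, length(x), "spearman")
    out$flag <- "zero_variance"
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  test_result(unname(ct$estimate), ct$p.value, length(x), "spearman")
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) over the lower triangles; permutation p
#' by joint row/column permutation of one matrix, observed statistic
#' included in the count, so p >= 1/(n_permutations + 1).
#'
#' @param d1,d2 [stats::dist] objects or symmetric matrices over the same
#'   samples.
#' @param n_permutations permutations.
#' @param seed integer seed.
#' @param method correlation method ("spearman" or "pearson").
#' @return `test_result` with `statistic` = Mantel r.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1,
                        method = "spearman") {
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size")) {
    stop("distance matrices differ in size", call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = method,
                       permutations = n_permutations)
  test_result(unname(fit$statistic), fit$signif, attr(d1, "Size"),
              paste0("mantel-", method))
}

#' Bonferroni correction
#'
#' @param p numeric p-values in (0, 1].
#' @return `min(1, p * m)` with `m = length(p)`.
#' @export
bonferroni <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni")
}

test_result <- function(statistic, p, n, method) {
  structure(list(statistic = statistic, p = p, n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}
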