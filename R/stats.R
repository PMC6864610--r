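# Group summaries and Wilcoxon rank-sum comparisons.

mann_whitney_u <- function(ranks_x, n_x, n_y) {
  sum(ranks_x) - n_x * (n_x + 1) / 2
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of identical distributions against a location shift.  For
#' combined samples of at most 12 values without ties the null distribution
#' of U is enumerated exactly; with ties at that size a seeded permutation
#' test (10^4 draws) is used; larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param n_perm permutation draws for the tied small-sample path.
#' @param perm_seed seed for the permutation path (recorded in the result).
#' @param method `"auto"` (size- and tie-based dispatch as described) or one
#'   of `"exact"`, `"permutation"`, `"normal"` to force a path.
#' @return list with `U` (statistic for `x`), `p` (two-sided), `method`, and
#'   `perm_seed` when the permutation path was taken.
#' @export
rank_sum_test <- function(x, y, n_perm = 10000L, perm_seed = 20191025L,
                          method = c("auto", "exact", "permutation",
                                     "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty sample")
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- mann_whitney_u(r[seq_len(n_x)], n_x, n_y)
  ties <- anyDuplicated(pooled) > 0
  if (method == "exact" || (method == "auto" && n <= 12 && !ties)) {
    if (ties) stop("exact enumeration requires untied data")
    combs <- utils::combn(n, n_x)
    ustats <- apply(combs, 2, function(idx)
      mann_whitney_u(r[idx], n_x, n_y))
    u_low <- min(U, n_x * n_y - U)
    p <- min(1, 2 * mean(ustats <= u_low + 1e-9))
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  if (method == "permutation" || (method == "auto" && n <= 12)) {
    mu <- n_x * n_y / 2
    obs <- abs(U - mu)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(perm_seed)
    stat <- replicate(n_perm, {
      idx <- sample.int(n, n_x)
      abs(mann_whitney_u(r[idx], n_x, n_y) - mu)
    })
    p <- mean(stat >= obs - 1e-9)
    return(list(U = U, p = p, method = "permutation",
                perm_seed = perm_seed))
  }
  mu <- n_x * n_y / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(n_x * n_y / 12 * ((n + 1) - tie_corr))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal approximation"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Group summary statistics
#'
#' @param values numeric vector (non-empty).
#' @param kind `"median_iqr"` (IQR = Q3 - Q1, linear-interpolation quantiles)
#'   or `"mean_sd"` (sample SD, n-1).
#' @return named numeric `c(location, spread)`.
#' @export
group_summary <- function(values, kind = c("median_iqr", "mean_sd")) {
  kind <- match.arg(kind)
  if (!length(values)) stop("empty sample")
  if (kind == "median_iqr") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], iqr = q[3] - q[1])
  } else {
    c(mean = mean(values),
      sd = if (length(values) > 1) stats::sd(values) else 0)
  }
}

#' Compare two groups variable by variable
#'
#' One rank-sum comparison per variable with per-variable significance at
#' `alpha` (no multiplicity adjustment by default, `"holm"` available).
#'
#' @param data data.frame of per-subject results; one row per subject.
#' @param variables character vector of numeric column names to compare.
#' @param group_col name of the two-level grouping column.
#' @param alpha significance level (default 0.05).
#' @param kind summary kind passed to [group_summary()].
#' @param adjust `"none"` or `"holm"`.
#' @return data.frame with one row per variable: group summaries, `U`, `p`
#'   and `significant`.
#' @export
compare_groups <- function(data, variables, group_col = "group",
                           alpha = 0.05, kind = "median_iqr",
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop("grouping column must have exactly 2 levels")
  if (any(table(g) == 0)) stop("a group has zero subjects")
  lv <- levels(g)
  rows <- lapply(variables, function(v) {
    xa <- data[[v]][g == lv[1]]; xb <- data[[v]][g == lv[2]]
    ts <- rank_sum_test(xa, xb)
    sa <- group_summary(xa, kind); sb <- group_summary(xb, kind)
    data.frame(variable = v,
               loc_a = sa[1], spread_a = sa[2],
               loc_b = sb[1], spread_b = sb[2],
               U = ts$U, p = ts$p, method = ts$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (adjust == "holm") res$p <- stats::p.adjust(res$p, "holm")
  res$significant <- res$p < alpha
  attr(res, "groups") <- lv
  attr(res, "alpha") <- alpha
  res
}
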