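#' Exact paired Wilcoxon signed-rank test
#'
#' Paired test of `x` vs `y` by the signed-rank procedure: differences
#' `d = x - y`, zero differences discarded (Wilcoxon's original convention;
#' Pratt's zero-rank method available via `zero_method = "pratt"`), absolute
#' differences ranked with midranks for ties, statistic `W` = sum of ranks of
#' positive differences. For `n_effective <= exact_limit` the two-sided
#' p-value is exact, by full enumeration of all `2^n` equiprobable sign
#' assignments: `p = min(1, 2 * min(P(W* <= W), P(W* >= W)))` (doubled
#' smaller tail, capped at 1). Beyond the limit, a normal approximation with
#' tie and continuity correction is used. Enumeration handles ties, so exact
#' p-values remain valid with midranks.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest `n_effective` enumerated exactly (default 12,
#'   i.e. at most 4096 sign vectors).
#' @param zero_method `"wilcox"` (discard zero differences before ranking)
#'   or `"pratt"` (rank with zeros included, then drop their ranks).
#' @param comparison optional label carried into the result.
#' @return Object of class `wsr_test`: `comparison`, `n_total`,
#'   `n_effective`, `statistic` (W), `p_value`, `method`
#'   (`"exact_enumeration"` or `"normal_approximation"`), `degenerate`
#'   (TRUE when all differences are zero, in which case `p_value = 1`).
#' @export
wilcoxon_signed_rank_exact <- function(x, y, exact_limit = 12,
                                       zero_method = c("wilcox", "pratt"),
                                       comparison = NULL) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("need at least one pair")
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  if (!all(is.finite(d))) stop("values must be finite")
  n_total <- length(d)

  res <- list(comparison = comparison %||% "x vs y", n_total = n_total)

  if (zero_method == "wilcox") {
    dnz <- d[d != 0]
    r_all <- rank(abs(dnz))
    ranks_pos <- r_all[dnz > 0]
    ranks_used <- r_all
  } else {
    r_all <- rank(abs(d))       # zeros share the lowest midranks
    ranks_pos <- r_all[d > 0]
    ranks_used <- r_all[d != 0] # zeros never flip sign in the null
    dnz <- d[d != 0]
  }
  n_eff <- length(dnz)
  res$n_effective <- n_eff
  res$statistic <- sum(ranks_pos)

  if (n_eff == 0) {
    res$p_value <- 1
    res$method <- "exact_enumeration"
    res$degenerate <- TRUE
    class(res) <- "wsr_test"
    return(res)
  }
  res$degenerate <- FALSE

  if (n_eff <= exact_limit) {
    # all 2^n sign assignments: W* = sum of ranks given a positive sign
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n_eff)))
    w_star <- as.vector(signs %*% ranks_used)
    eps <- 1e-9
    p_le <- mean(w_star <= res$statistic + eps)
    p_ge <- mean(w_star >= res$statistic - eps)
    res$p_value <- min(1, 2 * min(p_le, p_ge))
    res$method <- "exact_enumeration"
  } else {
    mu <- sum(ranks_used) / 2
    sigma2 <- sum(ranks_used^2) / 4  # midranks make this tie-corrected
    z_num <- res$statistic - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    res$p_value <- min(1, 2 * stats::pnorm(-abs(z)))
    res$method <- "normal_approximation"
  }
  class(res) <- "wsr_test"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wsr_test <- function(x, ...) {
  cat("Exact paired Wilcoxon signed-rank test:", x$comparison, "\n")
  cat(sprintf("  n = %d (%d nonzero differences), W = %g\n",
              x$n_total, x$n_effective, x$statistic))
  cat(sprintf("  two-sided p = %.6g  [%s]%s\n", x$p_value, x$method,
              if (x$degenerate) "  (all differences zero)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, returned in input order. Input
#' validation plus a delegation to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order and length as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Friedman test with Kendall's W effect size
#'
#' Rank-based global test across k matched treatment conditions observed in
#' n blocks (cultures). Values are midranked within each block; the
#' chi-square statistic uses the standard tie correction,
#' `chi2 = 12 * sum_j (R_j - n(k+1)/2)^2 / (n k (k+1) - sum(t^3 - t)/(k-1))`,
#' with `R_j` the rank sum of treatment j and t the tie-group sizes. The
#' p-value comes from the chi-square distribution with k - 1 degrees of
#' freedom, and the effect size is Kendall's coefficient of concordance
#' `W = chi2 / (n (k - 1))`, which is 1 exactly when every block ranks the
#' treatments identically (no ties) and 0 when all within-block values tie.
#' Blocks with missing cells are dropped with a message.
#'
#' @param m numeric matrix, blocks (cultures) in rows, treatments
#'   (conditions) in columns.
#' @return Object of class `friedman_w`: `n_blocks`, `k_treatments`,
#'   `statistic` (chi2), `df`, `p_value`, `kendalls_w`, `n_dropped`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("dropping %d incomplete block(s)", n_dropped))
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 complete blocks")
  if (k < 2) stop("need at least 2 treatments")

  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  # tie-group sizes from the midranks, so correction and rank sums agree
  tie_term <- sum(apply(r, 1, function(rr) {
    t <- table(rr)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  chi2 <- if (denom <= 0) 0 else
    12 * sum((rj - n * (k + 1) / 2)^2) / denom
  res <- list(
    n_blocks = n, k_treatments = k,
    statistic = chi2, df = k - 1,
    p_value = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
    kendalls_w = chi2 / (n * (k - 1)),
    n_dropped = n_dropped
  )
  class(res) <- "friedman_w"
  res
}

#' @export
print.friedman_w <- function(x, ...) {
  cat("Friedman rank test across matched conditions\n")
  cat(sprintf("  n = %d blocks, k = %d treatments\n", x$n_blocks, x$k_treatments))
  cat(sprintf("  chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  Kendall's W = %.3f\n", x$kendalls_w))
  invisible(x)
}

#' Paired comparisons of treatments against a control condition
#'
#' Runs one exact paired Wilcoxon signed-rank test per treatment column of a
#' culture x condition matrix against the control column, using the cultures
#' observed in both (pairwise-complete), and applies Benjamini-Hochberg
#' adjustment across the declared comparison family.
#'
#' @param m culture x condition matrix (e.g. `cohort_matrix()$matrix`).
#' @param control control condition column name.
#' @param family treatment columns forming the adjustment family; defaults
#'   to every non-control column.
#' @inheritParams wilcoxon_signed_rank_exact
#' @return data.frame with one row per comparison: `comparison`, `n_total`,
#'   `n_effective`, `statistic`, `p_value`, `p_adjusted`, `method`,
#'   `degenerate`.
#' @export
compare_conditions <- function(m, control,
                               family = setdiff(colnames(m), control),
                               exact_limit = 12,
                               zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  m <- as.matrix(m)
  if (!control %in% colnames(m)) stop("control column not found: ", control)
  missing_trt <- setdiff(family, colnames(m))
  if (length(missing_trt) > 0)
    stop("treatment column(s) not found: ", paste(missing_trt, collapse = ", "))
  if (length(family) < 1) stop("need at least one treatment comparison")

  tests <- lapply(family, function(trt) {
    ok <- stats::complete.cases(m[, control], m[, trt])
    wilcoxon_signed_rank_exact(m[ok, control], m[ok, trt],
                               exact_limit = exact_limit,
                               zero_method = zero_method,
                               comparison = paste(control, "vs", trt))
  })
  out <- do.call(rbind, lapply(tests, function(t) data.frame(
    comparison = t$comparison, n_total = t$n_total,
    n_effective = t$n_effective, statistic = t$statistic,
    p_value = t$p_value, method = t$method, degenerate = t$degenerate,
    stringsAsFactors = FALSE
  )))
  out$p_adjusted <- bh_adjust(out$p_value)
  out[, c("comparison", "n_total", "n_effective", "statistic",
          "p_value", "p_adjusted", "method", "degenerate")]
}

#' Descriptive normality screen for a readout matrix
#'
#' Shapiro-Wilk applied to the pooled values of a culture x condition
#' matrix, reported descriptively (it motivates the nonparametric tests,
#' nothing downstream branches on it).
#'
#' @param m numeric matrix of readout values.
#' @return List with `statistic` and `p_value`, or NULL when fewer than 3
#'   distinct finite values are available.
#' @export
normality_screen <- function(m) {
  v <- as.vector(m)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(NULL)
  s <- stats::shapiro.test(v)
  list(statistic = unname(s$statistic), p_value = s$p.value)
}
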