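# Test-result container shared by every primitive. `statistic_name` labels the
# reported statistic (t, W, chi-squared, r, z); `df` is NA when not applicable.
epimyo_test <- function(statistic, p, statistic_name, df = NA_real_,
                        estimate = NULL, two_sided = TRUE, note = NULL) {
  stopifnot(is.finite(p) || is.na(p))
  out <- list(statistic = unname(statistic), df = unname(df), p = unname(p),
              statistic_name = statistic_name, estimate = estimate,
              two_sided = two_sided, note = note)
  class(out) <- "epimyo_test"
  out
}

#' @export
print.epimyo_test <- function(x, ...) {
  cat(sprintf("%s = %.6g", x$statistic_name, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.6g", x$df))
  cat(sprintf(", p = %.4g (%s)\n", x$p,
              if (isTRUE(x$two_sided)) "two-sided" else "one-sided"))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: with the p-values sorted increasingly,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1, then mapped back to the
#' original input order.
#'
#' @param p Numeric vector of p-values, all in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("bh_fdr: p-values must all lie in [0, 1] with no missing values")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default, Welch-Satterthwaite df) or `"pooled"`.
#' @return An `epimyo_test` with the t statistic (sign of `mean(x) - mean(y)`),
#'   degrees of freedom and two-sided p.
#' @export
two_sample_ttest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L, all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(epimyo_test(0, 1, "t", df = if (variant == "pooled") n1 + n2 - 2 else NA_real_,
                         estimate = 0, note = "zero variance in both groups, equal means"))
    }
    warning("two_sample_ttest: zero variance with unequal means; p -> 0")
    return(epimyo_test(sign(m1 - m2) * Inf, 0, "t", df = n1 + n2 - 2,
                       estimate = m1 - m2, note = "degenerate: zero variance"))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  epimyo_test(tval, 2 * stats::pt(-abs(tval), df), "t", df = df, estimate = m1 - m2)
}

#' Covariate-adjusted group comparison by ordinary least squares
#'
#' Fits `y ~ intercept + group + covariates` by OLS and tests the group
#' coefficient with `t = coef / SE` on `n - rank` residual df (two-sided).
#' This is the per-feature model used to compare array data between groups
#' while adjusting for age, BMI and sex.
#'
#' @param y Numeric response vector.
#' @param group Binary indicator (0/1, or a two-level factor/logical).
#' @param covariates Optional numeric matrix or data.frame with named columns.
#' @return An `epimyo_test` with the t statistic; `estimate` carries the group
#'   coefficient (difference on the scale of `y`).
#' @export
linear_model_group_test <- function(y, group, covariates = NULL) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.numeric(group)
  stopifnot(length(y) == length(group), all(group %in% c(0, 1)))
  X <- cbind(`(Intercept)` = 1, group = group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(covariates) == length(y))
    X <- cbind(X, covariates)
  }
  n <- length(y)
  if (n <= ncol(X)) stop("linear_model_group_test: n must exceed the number of fitted parameters")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("linear_model_group_test: design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  df <- n - qx$rank
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tval <- if (se == 0) 0 else coefs[["group"]] / se
  epimyo_test(tval, 2 * stats::pt(-abs(tval), df), "t", df = df,
              estimate = coefs[["group"]])
}

# cache of exact signed-rank-sum distributions for untied ranks (keyed by n)
.signedrank_cache <- new.env(parent = emptyenv())

# Distribution of 2*W over sign assignments for (doubled, integer) ranks r2.
# Returns counts over sums 0..sum(r2); total mass 2^n.
signed_rank_counts <- function(r2) {
  maxs <- sum(r2)
  counts <- numeric(maxs + 1L)
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(maxs + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original treatment); ties in the
#' absolute differences receive midranks. `W` is the sum of ranks of the
#' positive differences. Exact two-sided p-values come from a dynamic-programming
#' enumeration of the signed-rank-sum distribution (run on doubled ranks so
#' midranks stay integral); the normal approximation applies a tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"auto"` (exact when the number of non-zero differences is <= 25
#'   and there are no ties, else normal), `"exact"`, or `"normal"`.
#' @return An `epimyo_test` with statistic `W`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  d <- as.numeric(x) - as.numeric(y)
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("wilcoxon_signed_rank: all paired differences are zero; p = 1")
    return(epimyo_test(0, 1, "W", note = "all differences zero"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = n <= 25L && !has_ties)
  if (use_exact) {
    r2 <- as.integer(round(2 * r))
    if (!has_ties && n <= 64L) {
      key <- as.character(n)
      counts <- .signedrank_cache[[key]]
      if (is.null(counts)) {
        counts <- signed_rank_counts(2L * seq_len(n))
        .signedrank_cache[[key]] <- counts
      }
    } else {
      counts <- signed_rank_counts(r2)
    }
    total <- 2^n
    w2 <- round(2 * W)
    grid <- seq_along(counts) - 1L
    p_le <- sum(counts[grid <= w2 + 1e-9]) / total
    p_ge <- sum(counts[grid >= w2 - 1e-9]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(epimyo_test(W, p, "W"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    warning("wilcoxon_signed_rank: degenerate variance; p = 1")
    return(epimyo_test(W, 1, "W", note = "degenerate variance"))
  }
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  epimyo_test(W, min(1, 2 * stats::pnorm(-abs(z))), "W")
}

#' Chi-squared test (independence or goodness of fit)
#'
#' `chi2 = sum (O - E)^2 / E` with no continuity correction. For an r x c table
#' with `expected = "independence"` the expectations come from the margins and
#' `df = (r-1)(c-1)`; for a count vector with a matching `expected` vector
#' (counts or proportions, rescaled to the observed total) `df = K - 1`.
#'
#' @param observed Non-negative count table (matrix) or vector.
#' @param expected `"independence"`, `"uniform"`, or a numeric vector/matrix of
#'   expectations matching `observed`.
#' @return An `epimyo_test`; `note` flags expected cells below 1 (warning, not
#'   fatal).
#' @export
chi2_test <- function(observed, expected = "independence") {
  stopifnot(is.numeric(observed), all(observed >= 0))
  if (sum(observed) == 0) stop("chi2_test: zero-total table")
  if (is.matrix(observed) && identical(expected, "independence")) {
    E <- outer(rowSums(observed), colSums(observed)) / sum(observed)
    df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  } else {
    O <- as.numeric(observed)
    E <- if (identical(expected, "uniform")) {
      rep(sum(O) / length(O), length(O))
    } else {
      stopifnot(is.numeric(expected), length(expected) == length(O))
      as.numeric(expected) / sum(expected) * sum(O)
    }
    observed <- O
    df <- length(O) - 1
  }
  if (any(E <= 0)) stop("chi2_test: expected counts must be positive in every cell")
  note <- NULL
  if (any(E < 1)) {
    warning("chi2_test: expected count below 1 in at least one cell")
    note <- "expected cell < 1"
  }
  stat <- sum((observed - E)^2 / E)
  epimyo_test(stat, stats::pchisq(stat, df, lower.tail = FALSE), "chi2",
              df = df, note = note)
}

#' Correlation test (Spearman or Pearson)
#'
#' Pearson r from the product-moment formula; Spearman replaces both vectors by
#' midranks first. The p-value uses the t approximation
#' `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` df (two-sided).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An `epimyo_test` with statistic `r` (also in `estimate`), or with
#'   `r = NA` and a warning when either vector has zero variance.
#' @export
correlation_test <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3L) stop("correlation_test: need n >= 3")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("correlation_test: zero variance; correlation undefined")
    return(epimyo_test(NA_real_, NA_real_, "r", note = "zero variance"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (1 - r^2 < 1e-15) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  epimyo_test(r, p, "r", df = n - 2, estimate = r,
              note = paste0("method=", method))
}

#' Principal component analysis of a feature-by-sample matrix
#'
#' Features (rows) are centered across samples, then the sample-space SVD gives
#' orthogonal sample scores and explained-variance fractions.
#'
#' @param X Numeric matrix, features x samples.
#' @param k Number of components to return, `k <= min(dim(X))`.
#' @return List with `scores` (samples x k), `explained` (length k fractions),
#'   and `explained_all` (all singular-value fractions).
#' @export
pca_top_components <- function(X, k) {
  X <- as.matrix(X)
  stopifnot(k >= 1L, k <= min(dim(X)))
  Xc <- X - rowMeans(X)
  sv <- svd(t(Xc))
  if (max(sv$d) < 1e-12) stop("pca_top_components: constant matrix has no principal components")
  frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(X)
  list(scores = scores[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)],
       explained_all = frac)
}
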