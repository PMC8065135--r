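# Group differential-expression screen (T2D vs NGT within one state) and the
# t-statistic gene ranking that feeds preranked enrichment.

#' Collapse probe-level expression to gene level
#'
#' @param expr Probe-by-sample expression matrix.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene` (a probe may
#'   map to several genes, a gene to several probes).
#' @param rule `"highest_mean"` keeps, per gene, the probe with the highest
#'   mean intensity across samples (default); `"most_detected"` keeps the probe
#'   with the fewest missing values, breaking ties by mean intensity. Both are
#'   readings of the usual "highest occurrence" collapse for multi-probe genes.
#' @return Gene-by-sample matrix, one row per mapped gene.
#' @export
collapse_probes_to_genes <- function(expr, probe_to_gene,
                                     rule = c("highest_mean", "most_detected")) {
  rule <- match.arg(rule)
  if (nrow(probe_to_gene) == 0L) stop("collapse_probes_to_genes: empty mapping")
  stopifnot(all(c("probe_id", "gene") %in% names(probe_to_gene)))
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(expr), , drop = FALSE]
  if (nrow(map) == 0L) stop("collapse_probes_to_genes: mapping covers no probe in the matrix")
  mean_int <- rowMeans(expr, na.rm = TRUE)
  n_det <- rowSums(!is.na(expr))
  pick <- vapply(split(map$probe_id, map$gene), function(pr) {
    if (rule == "most_detected") {
      best_det <- pr[n_det[pr] == max(n_det[pr])]
      best_det[which.max(mean_int[best_det])]
    } else {
      pr[which.max(mean_int[pr])]
    }
  }, "")
  out <- expr[pick, , drop = FALSE]
  rownames(out) <- names(pick)
  out[order(rownames(out)), , drop = FALSE]
}

#' Covariate-adjusted differential expression, one state at a time
#'
#' Per gene, ordinary least squares of expression on
#' `group + age + bmi + sex` (sex coded female = 0, male = 1) over the samples
#' of the requested state; the group coefficient (log2 units, T2D - NGT) is
#' tested with [linear_model_group_test()]'s t, and q-values come from
#' [bh_fdr()] across all tested genes. Genes constant across samples are
#' skipped with a warning.
#'
#' @param expr Gene-by-sample log2 expression matrix.
#' @param samples Sample sheet covering the matrix columns.
#' @param state `"myoblast"` or `"myotube"`.
#' @return data.frame with columns `gene`, `coefficient`, `fold_change`
#'   (`2^coefficient`), `t`, `p`, `q`, `direction` (`up`/`down`), ordered by
#'   increasing q; attributes `state` and `n` record the design.
#' @export
differential_expression <- function(expr, samples,
                                    state = c("myoblast", "myotube")) {
  state <- match.arg(state)
  ss <- samples[samples$state == state & samples$sample_id %in% colnames(expr), ,
                drop = FALSE]
  if (length(unique(ss$group)) < 2L) {
    stop("differential_expression: both groups must be represented in state ", state)
  }
  Y <- expr[, ss$sample_id, drop = FALSE]
  grp <- as.numeric(ss$group == "T2D")
  X <- cbind(`(Intercept)` = 1, group = grp, age = ss$age, bmi = ss$bmi,
             sex = as.numeric(ss$sex == "male"))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("differential_expression: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  keep <- apply(Y, 1L, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    warning(sprintf("differential_expression: skipped %d gene(s) constant across samples",
                    sum(!keep)))
    Y <- Y[keep, , drop = FALSE]
  }
  if (nrow(Y) == 0L) stop("differential_expression: no testable genes")
  n <- ncol(Y)
  df <- n - qx$rank
  B <- qr.coef(qx, t(Y))                      # parameters x genes
  res <- t(Y) - X %*% B
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  coef_g <- B["group", ]
  tval <- coef_g / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(gene = rownames(Y), coefficient = unname(coef_g),
                    fold_change = unname(2^coef_g), t = unname(tval),
                    p = unname(p), q = bh_fdr(unname(p)),
                    direction = ifelse(coef_g >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "state") <- state
  attr(out, "n") <- n
  out
}

#' Rank genes by t statistic for preranked enrichment
#'
#' @param de Differential-expression table from [differential_expression()].
#' @return data.frame `(gene, t)` in descending t order, ties broken
#'   alphabetically by gene symbol; same length as the input.
#' @export
rank_genes <- function(de) {
  if (nrow(de) == 0L) stop("rank_genes: empty input")
  o <- order(-de$t, de$gene)
  out <- de[o, c("gene", "t")]
  rownames(out) <- NULL
  out
}

#' Cross-state overlap of differential-expression calls
#'
#' Partitions the genes significant in either state into shared-concordant
#' (same direction), shared-discordant, and state-unique sets.
#'
#' @param de_myoblast,de_myotube Differential-expression tables over the same
#'   gene universe.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return List with the four gene-id vectors and a `counts` summary.
#' @export
cross_state_overlap <- function(de_myoblast, de_myotube, q_threshold = 0.05) {
  sig_b <- de_myoblast[de_myoblast$q < q_threshold, ]
  sig_t <- de_myotube[de_myotube$q < q_threshold, ]
  shared <- intersect(sig_b$gene, sig_t$gene)
  dir_b <- sig_b$direction[match(shared, sig_b$gene)]
  dir_t <- sig_t$direction[match(shared, sig_t$gene)]
  res <- list(shared_concordant = shared[dir_b == dir_t],
              shared_discordant = shared[dir_b != dir_t],
              myoblast_only = setdiff(sig_b$gene, shared),
              myotube_only = setdiff(sig_t$gene, shared))
  res$counts <- lengths(res)
  res
}
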