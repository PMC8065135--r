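# Paired myoblast-vs-myotube methylation dynamics per group, cross-group
# overlap, opposite-direction site detection, genomic-region averages and
# PCA-group association. Signed-rank tests run on beta fractions (rank tests
# are scale invariant); means, SDs and differences are reported on the percent
# scale used by printed tables.

#' Paired differentiation dynamics of DNA methylation, one group at a time
#'
#' Per probe, a subject-paired Wilcoxon signed-rank test of myotube versus
#' myoblast beta values across the subjects of the requested group, with BH
#' q-values across all probes within the group. Subjects lacking either state
#' are excluded with a warning.
#'
#' @param beta Probe-by-sample beta matrix (fractions).
#' @param samples Sample sheet covering the matrix columns.
#' @param group `"NGT"` or `"T2D"`.
#' @param mode Passed to [wilcoxon_signed_rank()] (default `"auto"`).
#' @return data.frame with one row per probe: percent-scale
#'   `mean_myoblast`/`sd_myoblast`/`mean_myotube`/`sd_myotube`, signed
#'   `difference` (myotube - myoblast, percent points), `W`, `p`, `q`;
#'   attribute `n_pairs` records the subject count.
#' @export
paired_dynamics <- function(beta, samples, group = c("NGT", "T2D"),
                            mode = "auto") {
  group <- match.arg(group)
  ss <- samples[samples$group == group & samples$sample_id %in% colnames(beta), ,
                drop = FALSE]
  tab <- table(ss$subject_id)
  paired_subj <- names(tab)[tab == 2L]
  unpaired <- setdiff(unique(ss$subject_id), paired_subj)
  if (length(unpaired)) {
    warning("paired_dynamics: excluding unpaired subject(s): ",
            paste(unpaired, collapse = ", "))
  }
  if (length(paired_subj) < 3L) {
    stop("paired_dynamics: need >= 3 subjects of group ", group,
         " with both states")
  }
  mb_ids <- ss$sample_id[match(paste0(paired_subj, ".myoblast"),
                               paste(ss$subject_id, ss$state, sep = "."))]
  mt_ids <- ss$sample_id[match(paste0(paired_subj, ".myotube"),
                               paste(ss$subject_id, ss$state, sep = "."))]
  mb <- beta[, mb_ids, drop = FALSE]
  mt <- beta[, mt_ids, drop = FALSE]
  np <- nrow(beta)
  W <- p <- numeric(np)
  for (i in seq_len(np)) {
    res <- suppressWarnings(wilcoxon_signed_rank(mt[i, ], mb[i, ], mode = mode))
    W[i] <- res$statistic
    p[i] <- res$p
  }
  out <- data.frame(probe_id = rownames(beta), group = group,
                    mean_myoblast = 100 * rowMeans(mb),
                    sd_myoblast = 100 * apply(mb, 1L, stats::sd),
                    mean_myotube = 100 * rowMeans(mt),
                    sd_myotube = 100 * apply(mt, 1L, stats::sd),
                    difference = 100 * (rowMeans(mt) - rowMeans(mb)),
                    W = W, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_pairs") <- length(paired_subj)
  out
}

#' Overlap of significant methylation dynamics between groups
#'
#' @param ngt,t2d Per-group dynamics tables over the same probe universe.
#' @param q_threshold Significance threshold on q.
#' @return List with the four significant sets (`up`/`down` per group), their
#'   pairwise same-direction intersections, and a `counts` summary.
#' @export
dynamics_overlap <- function(ngt, t2d, q_threshold = 0.05) {
  pick <- function(d, dir) {
    if (dir == "up") d$probe_id[d$q < q_threshold & d$difference > 0]
    else d$probe_id[d$q < q_threshold & d$difference < 0]
  }
  up_ngt <- pick(ngt, "up"); down_ngt <- pick(ngt, "down")
  up_t2d <- pick(t2d, "up"); down_t2d <- pick(t2d, "down")
  res <- list(up_ngt = up_ngt, down_ngt = down_ngt,
              up_t2d = up_t2d, down_t2d = down_t2d,
              up_shared = intersect(up_ngt, up_t2d),
              down_shared = intersect(down_ngt, down_t2d))
  res$counts <- lengths(res)
  res
}

#' Opposite-direction differentiation sites
#'
#' Probes whose methylation change during differentiation is significant
#' (q below threshold) in BOTH groups with strictly opposite signs. The output
#' is the printed-report shape: annotation columns plus per-group percent
#' means +/- SD, signed difference, p and q.
#'
#' @param ngt,t2d Per-group dynamics tables (joined on `probe_id`).
#' @param q_threshold Significance threshold (default 0.05).
#' @param manifest Optional probe manifest supplying annotation columns.
#' @return data.frame of flagged sites (0 rows when none).
#' @export
opposite_direction_sites <- function(ngt, t2d, q_threshold = 0.05,
                                     manifest = NULL) {
  merged <- merge(ngt, t2d, by = "probe_id", suffixes = c("_ngt", "_t2d"))
  flag <- merged$q_ngt < q_threshold & merged$q_t2d < q_threshold &
    merged$difference_ngt * merged$difference_t2d < 0
  hits <- merged[flag, , drop = FALSE]
  ann <- if (!is.null(manifest)) {
    annotate_probes(hits$probe_id, manifest)
  } else {
    data.frame(probe_id = hits$probe_id, chromosome = "", nearest_gene = "",
               gene_region = "", island_region = "", stringsAsFactors = FALSE)
  }
  out <- data.frame(
    probe_id = hits$probe_id,
    chromosome = ann$chromosome, nearest_gene = ann$nearest_gene,
    gene_region = ann$gene_region, island_region = ann$island_region,
    ngt_myoblast_mean = hits$mean_myoblast_ngt, ngt_myoblast_sd = hits$sd_myoblast_ngt,
    ngt_myotube_mean = hits$mean_myotube_ngt, ngt_myotube_sd = hits$sd_myotube_ngt,
    ngt_difference = hits$difference_ngt, ngt_p = hits$p_ngt, ngt_q = hits$q_ngt,
    t2d_myoblast_mean = hits$mean_myoblast_t2d, t2d_myoblast_sd = hits$sd_myoblast_t2d,
    t2d_myotube_mean = hits$mean_myotube_t2d, t2d_myotube_sd = hits$sd_myotube_t2d,
    t2d_difference = hits$difference_t2d, t2d_p = hits$p_t2d, t2d_q = hits$q_t2d,
    stringsAsFactors = FALSE)
  out[order(out$probe_id), ]
}

#' Average methylation per genomic-context class, with contrasts
#'
#' Per sample, the mean beta over the (unique) probes of each gene-region
#' class and each island-context class. Group contrasts (T2D vs NGT within
#' each state) reuse the covariate-adjusted linear model; state contrasts
#' (myotube vs myoblast within each group) use the paired signed-rank test.
#' q-values are computed across classes within each scheme and contrast
#' family. Empty classes are omitted with a warning.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param samples Sample sheet.
#' @param manifest Probe manifest.
#' @return List with `averages` (long data.frame: scheme, class, sample_id,
#'   mean_beta), `group_contrasts` and `state_contrasts` data.frames.
#' @export
region_average_methylation <- function(beta, samples, manifest) {
  mf <- manifest[manifest$probe_id %in% rownames(beta), , drop = FALSE]
  schemes <- list(gene_region = GENE_REGIONS, island_region = ISLAND_REGIONS)
  averages <- list(); group_rows <- list(); state_rows <- list()
  for (scheme in names(schemes)) {
    pairs <- unique(mf[, c("probe_id", scheme)])
    for (cls in schemes[[scheme]]) {
      pr <- pairs$probe_id[pairs[[scheme]] == cls]
      if (length(pr) == 0L) {
        warning(sprintf("region_average_methylation: no probes in class %s/%s; omitted",
                        scheme, cls))
        next
      }
      avg <- colMeans(beta[pr, , drop = FALSE])
      averages[[paste(scheme, cls)]] <- data.frame(
        scheme = scheme, class = cls, sample_id = names(avg),
        mean_beta = unname(avg), stringsAsFactors = FALSE)
      for (st in c("myoblast", "myotube")) {
        ss <- samples[samples$state == st & samples$sample_id %in% names(avg), ]
        tst <- linear_model_group_test(
          avg[ss$sample_id], as.numeric(ss$group == "T2D"),
          cbind(age = ss$age, bmi = ss$bmi, sex = as.numeric(ss$sex == "male")))
        group_rows[[paste(scheme, cls, st)]] <- data.frame(
          scheme = scheme, class = cls, state = st,
          estimate = tst$estimate, t = tst$statistic, p = tst$p,
          stringsAsFactors = FALSE)
      }
      for (g in c("NGT", "T2D")) {
        ss <- samples[samples$group == g & samples$sample_id %in% names(avg), ]
        tab <- table(ss$subject_id)
        subj <- names(tab)[tab == 2L]
        key <- paste(ss$subject_id, ss$state, sep = ".")
        mb <- avg[ss$sample_id[match(paste0(subj, ".myoblast"), key)]]
        mt <- avg[ss$sample_id[match(paste0(subj, ".myotube"), key)]]
        tst <- suppressWarnings(wilcoxon_signed_rank(mt, mb))
        state_rows[[paste(scheme, cls, g)]] <- data.frame(
          scheme = scheme, class = cls, group = g,
          difference = mean(mt) - mean(mb), W = tst$statistic, p = tst$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  group_contrasts <- do.call(rbind, group_rows)
  state_contrasts <- do.call(rbind, state_rows)
  rownames(group_contrasts) <- rownames(state_contrasts) <- NULL
  for (scheme in names(schemes)) {
    for (st in c("myoblast", "myotube")) {
      sel <- group_contrasts$scheme == scheme & group_contrasts$state == st
      group_contrasts$q[sel] <- bh_fdr(group_contrasts$p[sel])
    }
    for (g in c("NGT", "T2D")) {
      sel <- state_contrasts$scheme == scheme & state_contrasts$group == g
      state_contrasts$q[sel] <- bh_fdr(state_contrasts$p[sel])
    }
  }
  avg_df <- do.call(rbind, averages)
  rownames(avg_df) <- NULL
  list(averages = avg_df, group_contrasts = group_contrasts,
       state_contrasts = state_contrasts)
}

#' Association of top methylome principal components with disease group
#'
#' PCA of the beta matrix over the samples of one state, then a point-biserial
#' (Pearson) correlation of each of the top k sample scores with the group
#' indicator.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param samples Sample sheet.
#' @param state `"myoblast"` or `"myotube"`.
#' @param k Number of components (default 10, capped at n - 1).
#' @return data.frame with `component`, `explained` (variance fraction), `r`,
#'   `p`.
#' @export
pc_group_association <- function(beta, samples,
                                 state = c("myoblast", "myotube"), k = 10L) {
  state <- match.arg(state)
  ss <- samples[samples$state == state & samples$sample_id %in% colnames(beta), ]
  if (k > nrow(ss) - 1L) stop("pc_group_association: k must be <= n_samples - 1")
  pca <- pca_top_components(beta[, ss$sample_id, drop = FALSE], k)
  grp <- as.numeric(ss$group == "T2D")
  rows <- lapply(seq_len(k), function(i) {
    tst <- correlation_test(pca$scores[, i], grp, method = "pearson")
    data.frame(component = i, explained = pca$explained[i],
               r = tst$statistic, p = tst$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
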