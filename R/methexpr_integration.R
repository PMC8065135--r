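# Methylation-expression correlation screen over CpGs annotated to the DE
# genes, genomic-context enrichment of the negatively correlated sites, and
# the candidate-gene prioritization filter (reduced expression in both states
# plus an inverse methylation-expression correlation).

#' Map manifest probes to a set of differentially expressed genes
#'
#' All manifest rows whose annotated gene belongs to `de_genes`; a probe
#' annotated to several matching genes contributes one pair per gene.
#'
#' @param manifest Probe manifest.
#' @param de_genes Character vector of gene symbols (may be empty).
#' @return data.frame `(probe_id, gene)`, unique pairs.
#' @export
map_probes_to_de_genes <- function(manifest, de_genes) {
  hit <- manifest$nearest_gene %in% setdiff(de_genes, "")
  out <- unique(data.frame(probe_id = manifest$probe_id[hit],
                           gene = manifest$nearest_gene[hit],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Methylation-expression correlation screen
#'
#' Per (probe, gene) pair, the correlation of the probe's beta values with the
#' gene's expression across the subjects of one state, both disease groups
#' pooled. Samples present in only one matrix are dropped pairwise and the
#' per-record n reported. No multiple-testing correction is applied: the
#' screen's filter is the nominal p < 0.05, and the column is named
#' `p_nominal` accordingly.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param expr Gene-by-sample expression matrix.
#' @param pairs data.frame `(probe_id, gene)` from [map_probes_to_de_genes()].
#' @param samples Sample sheet.
#' @param state `"myoblast"` or `"myotube"`.
#' @param method Correlation method (default `"spearman"`).
#' @param manifest Optional manifest to attach `gene_region`/`island_region`.
#' @return data.frame with `probe_id`, `gene`, `n`, `r`, `p_nominal`,
#'   `sign_class` (`negative`/`positive`), annotation columns when a manifest
#'   is supplied; attribute `n_skipped` counts pairs dropped for missing rows
#'   or zero variance.
#' @export
correlation_screen <- function(beta, expr, pairs, samples,
                               state = c("myoblast", "myotube"),
                               method = c("spearman", "pearson"),
                               manifest = NULL) {
  state <- match.arg(state)
  method <- match.arg(method)
  ids <- samples$sample_id[samples$state == state]
  ids <- intersect(ids, intersect(colnames(beta), colnames(expr)))
  if (length(ids) < 3L) stop("correlation_screen: fewer than 3 shared samples")
  skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs$probe_id[i]; g <- pairs$gene[i]
    if (!(pr %in% rownames(beta)) || !(g %in% rownames(expr))) {
      skipped <- skipped + 1L
      next
    }
    tst <- withCallingHandlers(
      correlation_test(beta[pr, ids], expr[g, ids], method = method),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(tst$statistic)) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(probe_id = pr, gene = g, n = length(ids),
                            r = tst$statistic, p_nominal = tst$p,
                            sign_class = if (tst$statistic < 0) "negative" else "positive",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(probe_id = character(0), gene = character(0),
                      n = integer(0), r = numeric(0), p_nominal = numeric(0),
                      sign_class = character(0), stringsAsFactors = FALSE)
  }
  if (skipped) warning(sprintf("correlation_screen: skipped %d pair(s)", skipped))
  if (!is.null(manifest) && nrow(out)) {
    key <- paste(manifest$probe_id, manifest$nearest_gene)
    idx <- match(paste(out$probe_id, out$gene), key)
    idx2 <- match(out$probe_id, manifest$probe_id)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    out$gene_region <- manifest$gene_region[idx]
    out$island_region <- manifest$island_region[idx]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  attr(out, "method") <- method
  out
}

#' Genomic-context enrichment of a probe set against a screened background
#'
#' Percent frequency of the foreground probes per gene-region category and per
#' island-context category, with a goodness-of-fit chi-squared test of the
#' foreground counts against the background proportions. Typical foreground:
#' the negatively correlated, nominally significant CpGs of a
#' [correlation_screen()].
#'
#' @param foreground_probes,background_probes Character vectors of probe ids
#'   (foreground need not be a subset, but its categories must exist in the
#'   background).
#' @param manifest Probe manifest.
#' @return List with one element per scheme (`gene_region`, `island_region`),
#'   each holding `table` (category, fg/bg counts and percentages) and `test`
#'   (the chi-squared `epimyo_test`).
#' @export
context_enrichment <- function(foreground_probes, background_probes, manifest) {
  foreground_probes <- unique(foreground_probes)
  background_probes <- unique(background_probes)
  if (length(foreground_probes) == 0L || length(background_probes) == 0L) {
    stop("context_enrichment: empty foreground or background")
  }
  out <- list()
  for (scheme in c("gene_region", "island_region")) {
    pairs <- unique(manifest[, c("probe_id", scheme)])
    cls_of <- split(pairs[[scheme]], pairs$probe_id)
    count_classes <- function(ids) {
      tab <- table(unlist(cls_of[ids], use.names = FALSE))
      tab
    }
    bg <- count_classes(background_probes)
    fg <- count_classes(foreground_probes)
    if (length(setdiff(names(fg), names(bg)))) {
      stop("context_enrichment: foreground category absent from background (",
           scheme, ")")
    }
    cats <- names(bg)
    fg_full <- setNames(rep(0, length(cats)), cats)
    fg_full[names(fg)] <- as.numeric(fg)
    bg_full <- as.numeric(bg)
    tab <- data.frame(category = cats,
                      fg_count = unname(fg_full),
                      fg_pct = 100 * unname(fg_full) / sum(fg_full),
                      bg_count = bg_full,
                      bg_pct = 100 * bg_full / sum(bg_full),
                      stringsAsFactors = FALSE)
    test <- suppressWarnings(chi2_test(fg_full, expected = bg_full))
    out[[scheme]] <- list(table = tab, test = test)
  }
  out
}

#' Prioritize candidate genes: down in both states, inversely correlated
#'
#' Genes with q below threshold and direction `down` in BOTH states and at
#' least one negative correlation record with nominal p below
#' `corr_p_threshold`. Literature-based novelty triage is explicitly not
#' automated.
#'
#' @param de_myoblast,de_myotube Differential-expression tables.
#' @param corr Correlation records from [correlation_screen()].
#' @param q_threshold DE significance threshold (default 0.05).
#' @param corr_p_threshold Nominal correlation threshold (default 0.05).
#' @return data.frame `(gene, de_q_myoblast, de_q_myotube, direction,
#'   n_negative_cpgs)`, sorted by myoblast q.
#' @export
prioritize_candidates <- function(de_myoblast, de_myotube, corr,
                                  q_threshold = 0.05, corr_p_threshold = 0.05) {
  down_b <- de_myoblast[de_myoblast$q < q_threshold &
                          de_myoblast$direction == "down", ]
  down_t <- de_myotube[de_myotube$q < q_threshold &
                         de_myotube$direction == "down", ]
  both <- intersect(down_b$gene, down_t$gene)
  neg <- corr[corr$sign_class == "negative" & corr$p_nominal < corr_p_threshold, ]
  n_neg <- table(neg$gene)
  keep <- both[both %in% names(n_neg)]
  out <- data.frame(gene = keep,
                    de_q_myoblast = down_b$q[match(keep, down_b$gene)],
                    de_q_myotube = down_t$q[match(keep, down_t$gene)],
                    direction = "down",
                    n_negative_cpgs = as.integer(n_neg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$de_q_myoblast, out$gene), ]
  rownames(out) <- NULL
  out
}
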