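# End-to-end workflow: DE per state -> cross-state overlap -> correlation
# screen -> context enrichment -> candidates; paired dynamics per group ->
# overlap -> opposite-direction sites -> region averages -> PC association;
# preranked GSEA, GO search-term and promoter motif enrichment on the ranked
# myoblast list. Every stage writes a TSV and contributes counts to the run
# manifest.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' @param config A [simulation_config()] used when `bundle` is NULL (its seed
#'   drives all randomness, including GSEA permutations).
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @param bundle Optional pre-built `cohort_bundle`; when NULL a cohort is
#'   simulated from `config`.
#' @param q_threshold Significance threshold used by the call-set stages.
#' @param n_perm GSEA permutation count.
#' @return The run manifest (list of stage counts and output paths), invisibly
#'   written as JSON to `out_dir/run_manifest.json`.
#' @export
run_full_pipeline <- function(config = simulation_config(), out_dir,
                              bundle = NULL, q_threshold = 0.05,
                              n_perm = 1000L) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (is.null(bundle)) {
    bundle <- stage("simulate", simulate_cohort(config))
    stage("simulate", write_cohort(bundle, file.path(out_dir, "bundle"),
                                   seed = seed))
  }
  counts <- list(seed = seed, n_genes = nrow(bundle$expr),
                 n_probes = nrow(bundle$beta),
                 n_samples = nrow(bundle$samples))

  de_mb <- stage("de_myoblast",
                 differential_expression(bundle$expr, bundle$samples, "myoblast"))
  de_mt <- stage("de_myotube",
                 differential_expression(bundle$expr, bundle$samples, "myotube"))
  write_tsv(de_mb, file.path(out_dir, "de_myoblast.tsv"), seed = seed)
  write_tsv(de_mt, file.path(out_dir, "de_myotube.tsv"), seed = seed)
  counts$de_genes_tested <- nrow(de_mb)
  counts$de_sig_myoblast <- sum(de_mb$q < q_threshold)
  counts$de_sig_myotube <- sum(de_mt$q < q_threshold)

  overlap <- stage("cross_state_overlap",
                   cross_state_overlap(de_mb, de_mt, q_threshold))
  counts$de_shared_concordant <- length(overlap$shared_concordant)

  sig_genes <- de_mb$gene[de_mb$q < q_threshold]
  pairs <- stage("map_probes", map_probes_to_de_genes(bundle$manifest, sig_genes))
  corr <- stage("correlation_screen",
                suppressWarnings(correlation_screen(
                  bundle$beta, bundle$expr, pairs, bundle$samples,
                  "myoblast", manifest = bundle$manifest)))
  write_tsv(corr, file.path(out_dir, "correlation_screen.tsv"), seed = seed)
  counts$correlation_pairs <- nrow(corr)
  counts$correlation_nominal <- sum(corr$p_nominal < 0.05)
  counts$correlated_genes <- length(unique(corr$gene[corr$p_nominal < 0.05]))

  fg <- corr$probe_id[corr$sign_class == "negative" & corr$p_nominal < 0.05]
  ctx <- if (length(fg)) {
    stage("context_enrichment",
          context_enrichment(fg, corr$probe_id, bundle$manifest))
  } else NULL
  if (!is.null(ctx)) {
    write_tsv(rbind(cbind(scheme = "gene_region", ctx$gene_region$table),
                    cbind(scheme = "island_region", ctx$island_region$table)),
              file.path(out_dir, "context_enrichment.tsv"), seed = seed)
    counts$context_chi2_p_gene_region <- ctx$gene_region$test$p
    counts$context_chi2_p_island <- ctx$island_region$test$p
  }

  cand <- stage("candidates",
                prioritize_candidates(de_mb, de_mt, corr, q_threshold))
  write_tsv(cand, file.path(out_dir, "candidates.tsv"), seed = seed)
  counts$candidates <- nrow(cand)

  dyn_ngt <- stage("dynamics_NGT", paired_dynamics(bundle$beta, bundle$samples, "NGT"))
  dyn_t2d <- stage("dynamics_T2D", paired_dynamics(bundle$beta, bundle$samples, "T2D"))
  counts$dynamic_sig_ngt <- sum(dyn_ngt$q < q_threshold)
  counts$dynamic_sig_t2d <- sum(dyn_t2d$q < q_threshold)
  dov <- stage("dynamics_overlap", dynamics_overlap(dyn_ngt, dyn_t2d, q_threshold))
  counts$dynamic_up_shared <- length(dov$up_shared)
  counts$dynamic_down_shared <- length(dov$down_shared)
  opp <- stage("opposite_sites",
               opposite_direction_sites(dyn_ngt, dyn_t2d, q_threshold,
                                        bundle$manifest))
  write_tsv(opp, file.path(out_dir, "opposite_sites.tsv"), seed = seed)
  stage("dynamics_report",
        write_dynamics_report(dyn_ngt, dyn_t2d, bundle$manifest,
                              file.path(out_dir, "dynamics_report.tsv"),
                              seed = seed))
  counts$opposite_sites <- nrow(opp)

  reg <- stage("region_averages",
               suppressWarnings(region_average_methylation(
                 bundle$beta, bundle$samples, bundle$manifest)))
  write_tsv(reg$group_contrasts, file.path(out_dir, "region_group_contrasts.tsv"),
            seed = seed)
  write_tsv(reg$state_contrasts, file.path(out_dir, "region_state_contrasts.tsv"),
            seed = seed)

  pc <- stage("pc_association",
              pc_group_association(bundle$beta, bundle$samples, "myoblast",
                                   k = min(10L, sum(bundle$samples$state == "myoblast") - 1L)))
  write_tsv(pc, file.path(out_dir, "pc_group_association.tsv"), seed = seed)
  counts$pc_min_p <- min(pc$p)

  ranked <- stage("rank_genes", rank_genes(de_mb))
  if (!is.null(bundle$gene_sets)) {
    gsea <- stage("gsea", gsea_preranked(ranked, bundle$gene_sets,
                                         n_perm = n_perm, seed = seed))
    write_tsv(gsea[, setdiff(names(gsea), "leading_edge")],
              file.path(out_dir, "gsea.tsv"), seed = seed)
    counts$gsea_sets_tested <- nrow(gsea)
    counts$gsea_sig <- sum(gsea$fdr < 0.05, na.rm = TRUE)
  }
  if (!is.null(bundle$annotation)) {
    go <- stage("goterms",
                suppressWarnings(go_searchterm_enrichment(
                  sig_genes, rownames(bundle$expr), bundle$annotation)))
    write_tsv(go, file.path(out_dir, "go_searchterms.tsv"), seed = seed)
    counts$go_queries <- nrow(go)
  }
  if (!is.null(bundle$promoters) && !is.null(bundle$motif)) {
    down_genes <- de_mb$gene[de_mb$q < q_threshold & de_mb$direction == "down"]
    fg_prom <- bundle$promoters[intersect(down_genes, names(bundle$promoters))]
    bg_prom <- bundle$promoters
    if (length(fg_prom) >= 1L) {
      mot <- stage("motif", motif_enrichment(bundle$motif, fg_prom, bg_prom))
      write_tsv(data.frame(motif = mot$motif_name, z = mot$z, p = mot$p,
                           mean_best_fg = mot$mean_best_fg,
                           mean_best_bg = mot$mean_best_bg,
                           frac_with_motif_fg = mot$frac_with_motif_fg,
                           frac_with_motif_bg = mot$frac_with_motif_bg),
                file.path(out_dir, "motif_enrichment.tsv"), seed = seed)
      counts$motif_z <- mot$z
    }
  }

  counts$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- list(package = "epimyo",
                   version = as.character(utils::packageVersion("epimyo")),
                   seed = seed, timestamp = format(t0, tz = "UTC"),
                   out_dir = normalizePath(out_dir), counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("epimyo run (seed %s) -> %s\n", x$seed, x$out_dir))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %s\n", nm,
                format(x$counts[[nm]], digits = 4)))
  }
  invisible(x)
}
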