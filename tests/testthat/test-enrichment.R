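test_that("GSEA edge behavior: singleton at rank 1, size filter, reversal", {
  ranked <- data.frame(gene = paste0("g", 1:50), t = seq(5, -5, length.out = 50),
                       stringsAsFactors = FALSE)
  sets <- list(TOP1 = "g1", ALL = ranked$gene)
  res <- gsea_preranked(ranked, sets, n_perm = 50, seed = 1,
                        size_range = c(1, 20))
  expect_equal(res$ES[res$set_name == "TOP1"], 1)
  expect_true("ALL" %in% attr(res, "dropped"))
  # reversing the ranked list negates every ES
  set.seed(2)
  sets_r <- lapply(1:10, function(i) sample(ranked$gene, 8))
  names(sets_r) <- paste0("S", 1:10)
  fwd <- gsea_preranked(ranked, sets_r, n_perm = 5, seed = 3)
  rev_ranked <- ranked[nrow(ranked):1, ]
  rev_ranked$t <- -rev_ranked$t
  bwd <- gsea_preranked(rev_ranked, sets_r, n_perm = 5, seed = 3)
  expect_equal(bwd$ES[match(fwd$set_name, bwd$set_name)], -fwd$ES,
               tolerance = 1e-12)
})

test_that("GSEA flags the planted coherent set on a synthetic cohort", {
  b <- simulate_cohort(small_config(seed = 101, n_per_group = 14L))
  de <- differential_expression(b$expr, b$samples, "myoblast")
  res <- gsea_preranked(rank_genes(de), b$gene_sets, n_perm = 500, seed = 101)
  planted <- res[res$set_name == b$truth$planted_set, ]
  expect_gt(planted$ES, 0)
  expect_lt(planted$p_nominal, 0.05)
  expect_equal(res$set_name[1], b$truth$planted_set)
  expect_true(all(planted$leading_edge[[1]] %in%
                    b$gene_sets$sets[[b$truth$planted_set]]))
})

test_that("GO search-term counts: identity, oracle, order invariance", {
  ann <- data.frame(
    gene = rep(paste0("g", 1:20), each = 3),
    term = rep(c("regulation of autophagy", "cardiac muscle contraction",
                 "muscle cell differentiation"), 20),
    stringsAsFactors = FALSE)
  universe <- paste0("g", 1:20)
  res_same <- suppressWarnings(go_searchterm_enrichment(universe, universe, ann))
  matched <- !is.na(res_same$chi2)
  expect_true(any(matched))
  expect_true(all(res_same$chi2[matched] < 1e-9))
  feature <- paste0("g", 1:5)
  res <- suppressWarnings(go_searchterm_enrichment(feature, universe, ann))
  # brute-force oracle for the muscle query with exclusions
  fg_rows <- ann[ann$gene %in% feature, ]
  brute <- sum(vapply(fg_rows$term, function(tm) {
    tm2 <- gsub("cardiac muscle", "", gsub("smooth muscle", "", tolower(tm)))
    grepl("muscle", tm2, fixed = TRUE)
  }, TRUE))
  expect_equal(res$fg_count[res$query == "muscle"], brute)
  expect_equal(res$fg_count[res$query == "muscle"], 5L) # exclusion works
  # row order invariance
  res_shuf <- suppressWarnings(
    go_searchterm_enrichment(feature, universe, ann[sample(nrow(ann)), ]))
  expect_equal(res_shuf$fg_count, res$fg_count)
  expect_equal(res_shuf$bg_count, res$bg_count)
  # query matching nothing -> NA with warning
  expect_warning(
    res_none <- go_searchterm_enrichment(feature, universe, ann,
                                         list(nil = list(include = "zzz"))),
    "matches no")
  expect_true(is.na(res_none$p))
})

test_that("doubled term density is detected by the chi-squared query test", {
  # feature genes carry 2 of 4 autophagy terms (50% density) vs 1 of 4 (25%)
  # in the rest of the universe; >= 500 total occurrences
  universe <- paste0("g", 1:300)
  feature <- paste0("g", 1:60)
  mk <- function(g, n_auto) {
    data.frame(gene = g,
               term = c(rep("regulation of autophagy", n_auto),
                        rep("protein folding", 4 - n_auto)),
               stringsAsFactors = FALSE)
  }
  ann <- rbind(do.call(rbind, lapply(feature, mk, n_auto = 2)),
               do.call(rbind, lapply(setdiff(universe, feature), mk, n_auto = 1)))
  res <- suppressWarnings(go_searchterm_enrichment(feature, universe, ann))
  expect_lt(res$p[res$query == "autophagy"], 0.05)
  expect_equal(res$fg_pct[res$query == "autophagy"], 50)
})

test_that("PWM scoring: consensus hit, reverse strand, fg = bg null", {
  counts <- matrix(1, 4, 8)
  cons <- "ACGTACGT"
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(idx, 1:8)] <- 20
  m <- motif_model("M", counts)
  set.seed(9)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  planted <- bgseq
  substr(planted, 100, 107) <- cons
  sc <- pwm_best_scores(c(a = planted, b = bgseq), m)
  expect_equal(sc$relative[1], 1.0)
  # reverse complement scores identically
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", planted), "")[[1]]),
              collapse = "")
  sc_rc <- pwm_best_scores(c(x = rc), m)
  expect_equal(sc_rc$score, sc$score[1])
  # fg = bg gives z = 0, p = 0.5
  proms <- setNames(vapply(1:8, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  }, ""), paste0("p", 1:8))
  res <- motif_enrichment(m, proms, proms)
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  # promoter shorter than the motif is excluded and counted
  res2 <- motif_enrichment(m, c(proms, short = "ACG"), proms)
  expect_equal(res2$n_excluded, 1L)
  expect_equal(res2$n_fg, 8L)
})
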