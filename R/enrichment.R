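# Preranked gene-set enrichment (weighted running-sum ES with gene-set
# randomization null), GO search-term frequency enrichment (keyword queries
# with exclusions, chi-squared on term-occurrence totals), and promoter motif
# enrichment (PWM log-odds best-score z statistic with presence fractions).

## ---- preranked GSEA ---------------------------------------------------------

# ES of a hit-position set on a ranked list: hit steps are |t|^weight
# normalized by the set total, miss steps 1/(N - Nh); the ES is the running
# sum's maximum deviation from zero. O(|S|) given sorted hit positions.
gsea_es <- function(pos, absw, N) {
  Nh <- length(pos)
  hw <- absw[pos]
  tot <- sum(hw)
  if (tot == 0) {
    hw <- rep(1, Nh)
    tot <- Nh
  }
  cum <- cumsum(hw) / tot
  missfrac <- (pos - seq_len(Nh)) / (N - Nh)
  after <- cum - missfrac
  before <- c(0, cum[-Nh]) - missfrac
  max_dev <- max(after)
  min_dev <- min(before)
  if (max_dev >= -min_dev) {
    list(es = max_dev, peak = which.max(after), positive = TRUE)
  } else {
    list(es = min_dev, peak = which.min(before), positive = FALSE)
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum enrichment on a t-ranked gene list. Hits
#' increment by `|t|^weight` (normalized by the set total), misses decrement
#' by `1/(N - Nh)`; ES is the maximum deviation. The null distribution comes
#' from `n_perm` random same-size gene draws from the ranked list (gene-set
#' randomization, the standard for preranked mode); NES divides ES by the mean
#' same-sign |null ES|, nominal p is the same-sign null tail fraction, and FDR
#' follows the pooled-NES procedure.
#'
#' @param ranked data.frame `(gene, t)` in descending t order (see
#'   [rank_genes()]).
#' @param sets A `gene_set_collection` (or bare named list of member vectors).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param size_range Sets kept after intersecting with the universe must have
#'   sizes within this range (default `c(1, 500)`).
#' @param weight Hit-weight exponent: 1 (classic weighted, default) or 0
#'   (Kolmogorov-Smirnov).
#' @return data.frame with `set_name`, `set_size`, `ES`, `NES`, `p_nominal`,
#'   `fdr` and a `leading_edge` list-column; attribute `dropped` names sets
#'   removed by the size filter.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           size_range = c(1L, 500L), weight = 1) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- ranked$gene
  N <- length(genes)
  absw <- abs(ranked$t)^weight
  members <- lapply(sets, function(s) sort(match(unique(s), genes)))
  members <- lapply(members, function(m) m[!is.na(m)])
  sizes <- lengths(members)
  keep <- sizes >= size_range[1L] & sizes <= size_range[2L] & sizes < N
  dropped <- names(sets)[!keep]
  members <- members[keep]
  sizes <- sizes[keep]
  if (length(members) == 0L) {
    out <- data.frame(set_name = character(0), set_size = integer(0),
                      ES = numeric(0), NES = numeric(0),
                      p_nominal = numeric(0), fdr = numeric(0))
    attr(out, "dropped") <- dropped
    return(out)
  }
  set.seed(seed)
  null_by_size <- list()
  for (sz in sort(unique(sizes))) {
    null_by_size[[as.character(sz)]] <- vapply(seq_len(n_perm), function(b) {
      gsea_es(sort(sample.int(N, sz)), absw, N)$es
    }, 0)
  }
  norm_null <- function(nulls) {
    mp <- mean(nulls[nulls >= 0])
    mn <- mean(abs(nulls[nulls < 0]))
    out <- nulls
    out[nulls >= 0] <- if (is.nan(mp) || mp == 0) NA_real_ else nulls[nulls >= 0] / mp
    out[nulls < 0] <- if (is.nan(mn) || mn == 0) NA_real_ else nulls[nulls < 0] / mn
    out
  }
  pooled_null_nes <- unlist(lapply(names(null_by_size), function(k) {
    reps <- sum(sizes == as.integer(k))
    rep(norm_null(null_by_size[[k]]), reps)
  }), use.names = FALSE)
  pooled_null_nes <- pooled_null_nes[!is.na(pooled_null_nes)]

  rows <- lapply(seq_along(members), function(i) {
    pos <- members[[i]]
    r <- gsea_es(pos, absw, N)
    nulls <- null_by_size[[as.character(length(pos))]]
    same <- if (r$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    p <- if (length(same)) mean(abs(same) >= abs(r$es)) else 0
    denom <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (is.na(denom) || denom == 0) NA_real_ else r$es / denom
    le <- if (r$positive) genes[pos[seq_len(r$peak)]] else genes[pos[r$peak:length(pos)]]
    data.frame(set_name = names(members)[i], set_size = length(pos),
               ES = r$es, NES = nes, p_nominal = p,
               leading_edge = I(list(le)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # pooled-NES FDR, per sign
  obs <- out$NES
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    nes <- obs[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_pos <- pooled_null_nes[pooled_null_nes >= 0]
      obs_pos <- obs[!is.na(obs) & obs >= 0]
      num <- if (length(null_pos)) mean(null_pos >= nes) else 0
      den <- mean(obs_pos >= nes)
    } else {
      null_neg <- pooled_null_nes[pooled_null_nes < 0]
      obs_neg <- obs[!is.na(obs) & obs < 0]
      num <- if (length(null_neg)) mean(null_neg <= nes) else 0
      den <- mean(obs_neg <= nes)
    }
    max(0, min(1, num / max(den, .Machine$double.eps)))
  }, 0)
  out <- out[order(out$p_nominal, -abs(out$ES)), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

## ---- GO search-term enrichment ---------------------------------------------

#' Default GO search-term queries
#'
#' The four keyword families used for search-term frequency enrichment:
#' autophagy; muscle (excluding terms that only concern cardiac or smooth
#' muscle); epigenetics and histones; oxidative phosphorylation and
#' respiratory chain.
#' @return Named list of `list(include=, exclude=)` queries.
#' @export
default_term_queries <- function() {
  list(autophagy = list(include = "autophagy", exclude = character(0)),
       muscle = list(include = "muscle",
                     exclude = c("cardiac muscle", "smooth muscle")),
       epigenetics_histones = list(include = c("epigenet", "histone"),
                                   exclude = character(0)),
       oxidative_phosphorylation = list(
         include = c("oxidative phosphorylation", "respiratory chain"),
         exclude = character(0)))
}

match_query_terms <- function(terms, include, exclude = character(0)) {
  stripped <- tolower(terms)
  for (ex in exclude) stripped <- gsub(tolower(ex), "", stripped, fixed = TRUE)
  hit <- rep(FALSE, length(terms))
  for (inc in include) hit <- hit | grepl(tolower(inc), stripped, fixed = TRUE)
  hit
}

#' GO search-term frequency enrichment
#'
#' For each keyword query, counts matching term occurrences among the feature
#' genes and among the universe (a gene annotated to several matching terms is
#' counted once per term; frequencies are fractions of the total term count),
#' then tests over-representation with a 2x2 chi-squared on
#' matching/non-matching occurrence totals.
#'
#' @param feature_genes Character vector (e.g. differentially expressed genes).
#' @param universe Character vector of all analyzed genes.
#' @param annotation data.frame `(gene, term)`, one row per annotation.
#' @param term_queries Named list of `list(include=, exclude=)`; default
#'   [default_term_queries()].
#' @return data.frame per query: observed/expected feature counts, totals,
#'   frequencies (%), chi-squared statistic and p (NA with a warning for a
#'   query matching no universe term).
#' @export
go_searchterm_enrichment <- function(feature_genes, universe, annotation,
                                     term_queries = default_term_queries()) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  ann_u <- annotation[annotation$gene %in% universe, , drop = FALSE]
  ann_f <- annotation[annotation$gene %in% feature_genes, , drop = FALSE]
  total_u <- nrow(ann_u)
  total_f <- nrow(ann_f)
  if (total_u == 0L) stop("go_searchterm_enrichment: annotation covers no universe gene")
  rows <- lapply(names(term_queries), function(qn) {
    q <- term_queries[[qn]]
    mu <- sum(match_query_terms(ann_u$term, q$include, q$exclude))
    mf <- sum(match_query_terms(ann_f$term, q$include, q$exclude))
    if (mu == 0L) {
      warning("go_searchterm_enrichment: query '", qn, "' matches no universe term")
      chi <- NA_real_; p <- NA_real_
    } else {
      tab <- matrix(c(mf, total_f - mf, mu, total_u - mu), 2L, 2L, byrow = TRUE)
      tst <- suppressWarnings(chi2_test(tab))
      chi <- tst$statistic; p <- tst$p
    }
    data.frame(query = qn,
               fg_count = mf, fg_total = total_f,
               fg_pct = if (total_f) 100 * mf / total_f else NA_real_,
               bg_count = mu, bg_total = total_u, bg_pct = 100 * mu / total_u,
               expected_fg = total_f * mu / total_u,
               chi2 = chi, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- promoter motif enrichment ---------------------------------------------

#' Log-odds scoring matrix of a motif model
#'
#' `log2((c_ij + pc * b_i) / (n_j + pc) / b_i)` per column, the usual PWM
#' construction with a background-proportional pseudocount.
#'
#' @param motif A `motif_model`.
#' @return 4 x L numeric matrix (rows A, C, G, T), log2 odds.
#' @export
pwm_log_odds <- function(motif) {
  counts <- motif$counts
  bg <- motif$background
  pc <- motif$pseudocount
  probs <- sweep(counts + pc * bg, 2L, colSums(counts) + pc, `/`)
  log2(probs / bg)
}

revcomp_pwm <- function(lo) lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]

seq_to_int <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
}

# all window scores of one integer-coded sequence under one strand's matrix
pwm_window_scores <- function(idx, lo) {
  L <- ncol(lo)
  nw <- length(idx) - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(L)) {
    s <- s + lo[cbind(idx[j:(j + nw - 1L)], j)]
  }
  s
}

#' Best PWM score of each sequence over all offsets and both strands
#'
#' The reverse strand is scored by the reverse-complemented matrix. Relative
#' scores rescale the best log-odds to `[0, 1]` between the motif's minimum
#' and maximum attainable scores. Windows containing non-ACGT characters are
#' ignored; sequences shorter than the motif get NA.
#'
#' @param seqs Named character vector of sequences.
#' @param motif A `motif_model`.
#' @return data.frame `(name, score, relative)`.
#' @export
pwm_best_scores <- function(seqs, motif) {
  lo <- pwm_log_odds(motif)
  lo_rc <- revcomp_pwm(lo)
  min_s <- sum(apply(lo, 2L, min))
  max_s <- sum(apply(lo, 2L, max))
  best <- vapply(seqs, function(s) {
    idx <- seq_to_int(s)
    sc <- c(pwm_window_scores(idx, lo), pwm_window_scores(idx, lo_rc))
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) NA_real_ else max(sc)
  }, 0)
  nms <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  data.frame(name = nms, score = unname(best),
             relative = (unname(best) - min_s) / (max_s - min_s),
             stringsAsFactors = FALSE)
}

#' Promoter motif enrichment (best-score z statistic)
#'
#' Scores every promoter by its best PWM log-odds over all windows and both
#' strands, then tests whether the foreground mean best score exceeds the
#' background mean: `z = (mean_fg - mean_bg) / (sd_bg / sqrt(n_fg))`, one-sided
#' p. Presence fractions at the relative-score threshold are reported
#' descriptively.
#'
#' @param motif A `motif_model`.
#' @param fg_promoters,bg_promoters Named character vectors of promoter
#'   sequences (background is typically all promoters).
#' @param presence_threshold Relative score above which a promoter "has" the
#'   motif (default 0.8, the conventional PWM cutoff).
#' @return List with `motif_name`, `z`, `p`, `mean_best_fg`, `mean_best_bg`,
#'   `frac_with_motif_fg`, `frac_with_motif_bg`, counts, and the per-promoter
#'   score tables.
#' @export
motif_enrichment <- function(motif, fg_promoters, bg_promoters,
                             presence_threshold = 0.8) {
  fg <- pwm_best_scores(fg_promoters, motif)
  bg <- pwm_best_scores(bg_promoters, motif)
  n_excluded <- sum(is.na(fg$score)) + sum(is.na(bg$score))
  fg <- fg[!is.na(fg$score), ]
  bg <- bg[!is.na(bg$score), ]
  if (nrow(fg) == 0L || nrow(bg) < 2L) {
    stop("motif_enrichment: need scored foreground and >= 2 background promoters")
  }
  m_fg <- mean(fg$score); m_bg <- mean(bg$score)
  sd_bg <- stats::sd(bg$score)
  z <- if (sd_bg == 0) {
    if (m_fg == m_bg) 0 else sign(m_fg - m_bg) * Inf
  } else {
    (m_fg - m_bg) / (sd_bg / sqrt(nrow(fg)))
  }
  list(motif_name = motif$name, z = z,
       p = stats::pnorm(z, lower.tail = FALSE),
       mean_best_fg = m_fg, mean_best_bg = m_bg,
       frac_with_motif_fg = mean(fg$relative >= presence_threshold),
       frac_with_motif_bg = mean(bg$relative >= presence_threshold),
       n_fg = nrow(fg), n_bg = nrow(bg), n_excluded = n_excluded,
       fg_scores = fg, bg_scores = bg)
}
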