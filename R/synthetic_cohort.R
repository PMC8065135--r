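# Synthetic paired two-state cohort generator. The generator plants every
# structure the downstream analyses assume -- group effects on expression,
# TSS-concentrated negative methylation-expression couplings, asymmetric
# per-group differentiation dynamics, opposite-direction CpG sites,
# motif-bearing promoters, an enriched gene set and a term-annotation table --
# and returns the ground truth alongside the bundle for evaluation.

#' Simulation configuration
#'
#' Defaults state the emulated cohort: 14 subjects per group sampled in both
#' the myoblast and myotube state, covariates age ~ N(56, 7) years and
#' BMI ~ N(25.7, 3.1) kg/m2 with balanced sex, a 450K-style methylome scaled
#' down to 10,000 probes, 2,000 genes with 5% differentially expressed at 1
#' log2 unit, 60% of DE genes negatively coupled to a TSS-proximal CpG at
#' expected correlation -0.8, 5% of probes shifting during differentiation in
#' controls with a 2x larger set in T2D, and 39 opposite-direction sites.
#'
#' @param seed Integer seed; fully determines the bundle.
#' @param n_per_group Subjects per group (each contributes both states).
#' @param n_genes,n_probes Feature counts.
#' @param frac_de_genes Fraction of genes with a planted group effect.
#' @param de_effect_log2 Planted |log2 effect| (T2D - NGT) in myoblasts.
#' @param frac_de_both_states Fraction of DE genes whose effect persists in
#'   myotubes.
#' @param expr_sd Residual SD of log2 expression.
#' @param coupling_frac Fraction of DE genes given a coupled TSS-proximal probe.
#' @param coupling_strength Expected |negative correlation| of coupled pairs,
#'   in (0, 1].
#' @param dynamics_frac_ngt Fraction of probes shifting between states in NGT.
#' @param dynamics_ratio_t2d Multiplier for the T2D dynamic-probe count.
#' @param dynamics_overlap_frac Fraction of the NGT dynamic set also dynamic
#'   (same direction) in T2D.
#' @param n_opposite_sites Probes shifted in strictly opposite directions
#'   between the groups.
#' @param motif_frac_fg,motif_frac_bg Fractions of down-truth / remaining
#'   promoters carrying the planted motif.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions.
#' @param opensea_offset_t2d Additive beta offset (fraction) applied to
#'   open-sea probes in T2D myoblast samples; 0 by default.
#' @param n_candidate_genes Optional: force exactly this many genes to be
#'   down-in-both-states AND coupled (the candidate-gene truth); when NULL the
#'   strata follow `frac_de_both_states` and `coupling_frac`.
#' @param promoter_length Promoter length in bp.
#' @param motif_consensus Planted motif consensus (a 12-bp E-box-containing
#'   myogenic-like site by default; long enough that random 1 kb promoters
#'   rarely reach the 0.8 relative-score presence cutoff by chance).
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_per_group = 14L, n_genes = 2000L,
                              n_probes = 10000L, frac_de_genes = 0.05,
                              de_effect_log2 = 1.0, frac_de_both_states = 0.5,
                              expr_sd = 0.5, coupling_frac = 0.6,
                              coupling_strength = 0.8,
                              dynamics_frac_ngt = 0.05,
                              dynamics_ratio_t2d = 2.0,
                              dynamics_overlap_frac = 0.3,
                              n_opposite_sites = 39L,
                              motif_frac_fg = 0.9, motif_frac_bg = 0.05,
                              age_mean = 56, age_sd = 7,
                              bmi_mean = 25.7, bmi_sd = 3.1,
                              opensea_offset_t2d = 0,
                              n_candidate_genes = NULL,
                              promoter_length = 1000L,
                              motif_consensus = "GCAACAGCTGTT") {
  cfg <- as.list(environment())
  fracs <- c(frac_de_genes, frac_de_both_states, coupling_frac,
             dynamics_frac_ngt, dynamics_overlap_frac, motif_frac_fg,
             motif_frac_bg)
  if (any(fracs < 0 | fracs > 1)) stop("simulation_config: fractions must lie in [0, 1]")
  if (coupling_strength <= 0 || coupling_strength > 1) {
    stop("simulation_config: coupling_strength must be in (0, 1]")
  }
  if (n_opposite_sites > n_probes) stop("simulation_config: n_opposite_sites > n_probes")
  if (round(frac_de_genes * n_genes) < 1) {
    stop("simulation_config: infeasible, frac_de_genes * n_genes < 1")
  }
  class(cfg) <- "simulation_config"
  cfg
}

GENE_REGION_BG_PROBS <- c(TSS200 = 0.10, TSS1500 = 0.12, `5'UTR` = 0.10,
                          `1stExon` = 0.08, Body = 0.45, `3'UTR` = 0.15)
GENE_REGION_TSS_PROBS <- c(TSS200 = 0.45, TSS1500 = 0.35, `5'UTR` = 0.10,
                           `1stExon` = 0.05, Body = 0.04, `3'UTR` = 0.01)
ISLAND_TSS_PROBS <- c(Island = 0.45, N_Shore = 0.18, S_Shore = 0.18,
                      N_Shelf = 0.05, S_Shelf = 0.05, OpenSea = 0.09)
ISLAND_BODY_PROBS <- c(Island = 0.12, N_Shore = 0.10, S_Shore = 0.10,
                       N_Shelf = 0.10, S_Shelf = 0.10, OpenSea = 0.48)

GO_TERM_VOCAB <- list(
  autophagy = c("autophagosome assembly", "regulation of autophagy",
                "macroautophagy", "autophagosome maturation"),
  muscle = c("muscle cell differentiation", "skeletal muscle tissue development",
             "muscle fiber development", "myotube fusion"),
  muscle_excluded = c("cardiac muscle contraction",
                      "smooth muscle cell proliferation"),
  epigenetics = c("histone acetylation", "histone H3 deacetylation",
                  "chromatin remodeling", "DNA methylation maintenance"),
  oxphos = c("oxidative phosphorylation", "respiratory chain complex assembly"),
  generic = c("cell cycle arrest", "DNA replication", "apoptotic process",
              "glycolytic process", "lipid metabolic process", "protein folding",
              "ribosome biogenesis", "RNA splicing", "signal transduction",
              "ion transport", "cell adhesion", "immune response",
              "translation", "proteolysis", "vesicle-mediated transport"))

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""), ""))
}

#' Simulate a paired two-state cohort with ground truth
#'
#' @param config A [simulation_config()].
#' @return A `cohort_bundle` carrying `expr`, `beta`, `manifest`, `samples`,
#'   plus `gene_sets` (GMT-style collection with one planted set), `promoters`
#'   (named sequences), `motif` (the planted `motif_model`), `annotation`
#'   (gene/term table) and `truth` (planted ground-truth tables).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_per_group

  ## ---- samples ------------------------------------------------------------
  subjects <- c(sprintf("NGT%02d", seq_len(n)), sprintf("T2D%02d", seq_len(n)))
  group <- rep(c("NGT", "T2D"), each = n)
  sex <- rep(rep_len(c("male", "female"), n), 2L)
  # cases were selected to match controls on sex, age and BMI, so covariates
  # are drawn pair-matched: a shared base per subject pair plus a small
  # within-pair jitter; marginals keep the configured mean/SD while group
  # imbalance stays far below that of independent sampling
  matched_pairs <- function(mu, sdev, jitter_frac = 0.3) {
    sd_j <- jitter_frac * sdev
    sd_b <- sqrt(max(sdev^2 - sd_j^2, 1e-8))
    base <- stats::rnorm(n, mu, sd_b)
    c(base + stats::rnorm(n, 0, sd_j), base + stats::rnorm(n, 0, sd_j))
  }
  age <- matched_pairs(config$age_mean, config$age_sd)
  bmi <- matched_pairs(config$bmi_mean, config$bmi_sd)
  samples <- data.frame(
    sample_id = c(paste0(subjects, "_mb"), paste0(subjects, "_mt")),
    subject_id = rep(subjects, 2L),
    group = rep(group, 2L),
    state = rep(c("myoblast", "myotube"), each = 2L * n),
    age = rep(round(age, 1), 2L),
    bmi = rep(round(bmi, 1), 2L),
    sex = rep(sex, 2L),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  is_t2d <- samples$group == "T2D"
  is_mb <- samples$state == "myoblast"

  ## ---- differential expression truth --------------------------------------
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  n_de <- round(config$frac_de_genes * config$n_genes)
  de_genes <- sample(genes, n_de)
  n_down <- floor(n_de / 2)
  down_genes <- de_genes[seq_len(n_down)]
  up_genes <- de_genes[-seq_len(n_down)]
  # frac_de_both_states governs the OVERALL fraction of DE genes whose effect
  # persists into myotubes; by default it is split evenly over the two
  # directions. When n_candidate_genes pins the down-and-both stratum (the
  # candidate truth, all coupled), the remainder of the both-state quota goes
  # to up-regulated genes so the myotube signal density stays as configured.
  n_both_total <- round(config$frac_de_both_states * n_de)
  if (!is.null(config$n_candidate_genes)) {
    k <- config$n_candidate_genes
    if (k > n_down) stop("simulate_cohort: n_candidate_genes exceeds down-gene stratum")
    down_both <- down_genes[seq_len(k)]
    up_both <- up_genes[seq_len(min(length(up_genes), max(0L, n_both_total - k)))]
  } else {
    down_both <- down_genes[seq_len(round(config$frac_de_both_states * n_down))]
    up_both <- up_genes[seq_len(round(config$frac_de_both_states * length(up_genes)))]
  }
  both_genes <- c(down_both, up_both)
  n_coupled <- round(config$coupling_frac * n_de)
  if (!is.null(config$n_candidate_genes)) {
    pool <- setdiff(de_genes, down_both)
    coupled_genes <- c(down_both, sample(pool, max(0L, n_coupled - length(down_both))))
  } else {
    coupled_genes <- sample(de_genes, n_coupled)
  }
  effect <- ifelse(de_genes %in% down_genes, -config$de_effect_log2,
                   config$de_effect_log2)
  names(effect) <- de_genes

  ## ---- expression matrix ---------------------------------------------------
  baseline <- stats::rnorm(config$n_genes, 8, 2)
  age_slope <- stats::rnorm(config$n_genes, 0, 0.01)
  sex_eff <- stats::rnorm(config$n_genes, 0, 0.05)
  expr <- matrix(stats::rnorm(config$n_genes * ns, 0, config$expr_sd),
                 config$n_genes, ns, dimnames = list(genes, samples$sample_id))
  expr <- expr + baseline +
    outer(age_slope, samples$age - config$age_mean) +
    outer(sex_eff, as.numeric(samples$sex == "male"))
  de_rows <- match(de_genes, genes)
  # effect in T2D myoblasts always; in T2D myotubes only for both-state genes
  state_ok <- matrix(is_mb, length(de_genes), ns, byrow = TRUE) |
    matrix(de_genes %in% both_genes, length(de_genes), ns)
  mask <- state_ok & matrix(is_t2d, length(de_genes), ns, byrow = TRUE)
  expr[de_rows, ] <- expr[de_rows, ] + matrix(effect, length(de_genes), ns) * mask

  ## ---- probe manifest -------------------------------------------------------
  np <- config$n_probes
  probes <- sprintf("cg%08d", seq_len(np))
  n_coupled_probes <- length(coupled_genes)
  coupled_probes <- probes[seq_len(n_coupled_probes)]
  rest <- if (n_coupled_probes) probes[-seq_len(n_coupled_probes)] else probes
  n_annot <- round(0.85 * length(rest))
  annot_rest <- sample(rest, n_annot)
  nearest <- setNames(rep("", np), probes)
  nearest[coupled_probes] <- coupled_genes
  nearest[annot_rest] <- sample(genes, n_annot, replace = TRUE)
  gene_region <- setNames(rep("intergenic", np), probes)
  gene_region[coupled_probes] <- sample(names(GENE_REGION_TSS_PROBS),
                                        n_coupled_probes, replace = TRUE,
                                        prob = GENE_REGION_TSS_PROBS)
  gene_region[annot_rest] <- sample(names(GENE_REGION_BG_PROBS), n_annot,
                                    replace = TRUE, prob = GENE_REGION_BG_PROBS)
  tss_like <- gene_region %in% c("TSS200", "TSS1500", "5'UTR", "1stExon")
  island_region <- setNames(rep(NA_character_, np), probes)
  island_region[tss_like] <- sample(names(ISLAND_TSS_PROBS), sum(tss_like),
                                    replace = TRUE, prob = ISLAND_TSS_PROBS)
  island_region[!tss_like] <- sample(names(ISLAND_BODY_PROBS), sum(!tss_like),
                                     replace = TRUE, prob = ISLAND_BODY_PROBS)
  manifest <- data.frame(probe_id = probes,
                         chromosome = as.character(sample.int(22L, np, replace = TRUE)),
                         nearest_gene = unname(nearest),
                         gene_region = unname(gene_region),
                         island_region = unname(island_region),
                         stringsAsFactors = FALSE)

  ## ---- dynamics truth -------------------------------------------------------
  n_dyn_ngt <- round(config$dynamics_frac_ngt * np)
  n_dyn_t2d <- round(config$dynamics_ratio_t2d * n_dyn_ngt)
  n_shared <- round(config$dynamics_overlap_frac * n_dyn_ngt)
  n_opp <- config$n_opposite_sites
  n_ngt_only <- n_dyn_ngt - n_shared - n_opp
  n_t2d_only <- n_dyn_t2d - n_shared - n_opp
  if (n_ngt_only < 0 || n_t2d_only < 0) {
    stop("simulate_cohort: infeasible dynamics configuration")
  }
  need <- n_ngt_only + n_t2d_only + n_shared + n_opp
  if (need > length(rest)) stop("simulate_cohort: not enough probes for dynamics plan")
  dyn_pool <- sample(rest, need)
  idx <- cumsum(c(n_ngt_only, n_t2d_only, n_shared, n_opp))
  ngt_only <- dyn_pool[seq_len(idx[1L])]
  t2d_only <- dyn_pool[(idx[1L] + 1L):idx[2L]]
  shared <- if (n_shared) dyn_pool[(idx[2L] + 1L):idx[3L]] else character(0)
  opp <- if (n_opp) dyn_pool[(idx[3L] + 1L):idx[4L]] else character(0)

  shift_mag <- function(k, lo = 0.05, hi = 0.15) {
    stats::runif(k, lo, hi) * sample(c(-1, 1), k, replace = TRUE)
  }
  sh_ngt_only <- shift_mag(length(ngt_only))
  sh_t2d_only <- shift_mag(length(t2d_only))
  sh_shared <- shift_mag(length(shared))
  # opposite sites: detectable magnitude, mixed directions in equal halves
  opp_sign <- rep(c(1, -1), length.out = length(opp))
  sh_opp_ngt <- stats::runif(length(opp), 0.08, 0.15) * opp_sign
  sh_opp_t2d <- -sh_opp_ngt

  dyn_block <- function(probes, group, shift) {
    if (length(probes) == 0L) return(NULL)
    data.frame(probe_id = probes, group = rep(group, length(probes)),
               shift = shift, stringsAsFactors = FALSE)
  }
  dyn_truth <- do.call(rbind, Filter(Negate(is.null), list(
    dyn_block(ngt_only, "NGT", sh_ngt_only),
    dyn_block(shared, "NGT", sh_shared),
    dyn_block(opp, "NGT", sh_opp_ngt),
    dyn_block(t2d_only, "T2D", sh_t2d_only),
    dyn_block(shared, "T2D", sh_shared),
    dyn_block(opp, "T2D", sh_opp_t2d))))
  if (is.null(dyn_truth)) {
    dyn_truth <- data.frame(probe_id = character(0), group = character(0),
                            shift = numeric(0), stringsAsFactors = FALSE)
  }

  ## ---- beta matrix ----------------------------------------------------------
  # bimodal baseline on the logit scale (hypo ~0.1 / hyper ~0.9 modes)
  mode_hi <- stats::runif(np) < 0.5
  mu_logit <- stats::rnorm(np, ifelse(mode_hi, stats::qlogis(0.9),
                                      stats::qlogis(0.1)), 0.5)
  beta <- stats::plogis(matrix(stats::rnorm(np * ns, 0, 0.15), np, ns) + mu_logit)
  dimnames(beta) <- list(probes, samples$sample_id)

  # dynamic probes: mid-range baseline, paired myotube = myoblast + shift
  dyn_probes <- unique(dyn_truth$probe_id)
  base_dyn <- stats::runif(length(dyn_probes), 0.25, 0.65)
  names(base_dyn) <- dyn_probes
  shift_tab <- list(
    NGT = setNames(rep(0, length(dyn_probes)), dyn_probes),
    T2D = setNames(rep(0, length(dyn_probes)), dyn_probes))
  for (g in c("NGT", "T2D")) {
    sub <- dyn_truth[dyn_truth$group == g, ]
    shift_tab[[g]][sub$probe_id] <- sub$shift
  }
  for (g in c("NGT", "T2D")) {
    subj <- subjects[group == g]
    mb_ids <- paste0(subj, "_mb")
    mt_ids <- paste0(subj, "_mt")
    mb_vals <- base_dyn +
      matrix(stats::rnorm(length(dyn_probes) * length(subj), 0, 0.02),
             length(dyn_probes), length(subj))
    mt_vals <- mb_vals + shift_tab[[g]] +
      matrix(stats::rnorm(length(dyn_probes) * length(subj), 0, 0.01),
             length(dyn_probes), length(subj))
    beta[dyn_probes, mb_ids] <- mb_vals
    beta[dyn_probes, mt_ids] <- mt_vals
  }

  # coupled probes: beta is a monotone decreasing function of the paired
  # gene's expression (logit-linear), noise set so the expected correlation
  # magnitude equals coupling_strength
  if (n_coupled_probes) {
    k_slope <- 1.0
    rho <- config$coupling_strength
    noise_sd <- if (rho >= 1) 0 else k_slope * sqrt(1 / rho^2 - 1)
    alpha <- stats::rnorm(n_coupled_probes, 0, 0.5)
    zexpr <- t(scale(t(expr[coupled_genes, , drop = FALSE])))
    beta[coupled_probes, ] <- stats::plogis(
      alpha - k_slope * zexpr +
        matrix(stats::rnorm(n_coupled_probes * ns, 0, noise_sd),
               n_coupled_probes, ns))
  }

  if (config$opensea_offset_t2d != 0) {
    os_probes <- probes[island_region == "OpenSea"]
    cols <- samples$sample_id[is_t2d & is_mb]
    beta[os_probes, cols] <- beta[os_probes, cols] + config$opensea_offset_t2d
  }
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

  ## ---- promoters + motif ----------------------------------------------------
  promoters <- vapply(genes, function(g) random_dna(config$promoter_length), "")
  motif_seq <- config$motif_consensus
  L <- nchar(motif_seq)
  fg_motif <- sample(down_genes, round(config$motif_frac_fg * length(down_genes)))
  others <- setdiff(genes, down_genes)
  bg_motif <- sample(others, round(config$motif_frac_bg * length(others)))
  for (g in c(fg_motif, bg_motif)) {
    pos <- sample.int(config$promoter_length - L + 1L, 1L)
    ins <- if (stats::runif(1) < 0.5) motif_seq else reverse_complement(motif_seq)
    substr(promoters[[g]], pos, pos + L - 1L) <- ins
  }
  base_idx <- match(strsplit(motif_seq, "")[[1L]], c("A", "C", "G", "T"))
  counts <- matrix(1, 4L, L)
  counts[cbind(base_idx, seq_len(L))] <- 10
  motif <- motif_model("Ebox_myogenic_synthetic", counts)

  ## ---- gene sets ------------------------------------------------------------
  # planted set: 70% DE genes drawn from one direction (up) so the set's
  # t-statistics are coherent and its running-sum ES does not self-cancel
  set_size <- min(50L, max(10L, round(n_de / 2)))
  n_from_de <- min(round(0.7 * set_size), length(up_genes))
  planted_set <- c(sample(up_genes, n_from_de),
                   sample(setdiff(genes, de_genes), set_size - n_from_de))
  sets <- list(PLANTED_DE_SET = unique(planted_set))
  sz_hi <- min(80L, config$n_genes)
  sz_lo <- min(15L, sz_hi)
  for (i in seq_len(20L)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(genes, sample(seq(sz_lo, sz_hi), 1L))
  }
  gene_sets <- structure(list(sets = sets,
                              description = setNames(rep("synthetic", length(sets)),
                                                     names(sets))),
                         class = "gene_set_collection")

  ## ---- GO-style annotation --------------------------------------------------
  special <- unlist(GO_TERM_VOCAB[c("autophagy", "muscle", "epigenetics")],
                    use.names = FALSE)
  vocab <- unlist(GO_TERM_VOCAB, use.names = FALSE)
  w_plain <- rep(1, length(vocab))
  w_de <- ifelse(vocab %in% special, 3, 1)
  ann <- lapply(genes, function(g) {
    k <- sample(2:6, 1L)
    w <- if (g %in% de_genes) w_de else w_plain
    data.frame(gene = g, term = sample(vocab, k, prob = w), stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, ann)

  truth <- list(
    de = data.frame(gene = de_genes, effect = unname(effect),
                    both_states = de_genes %in% both_genes,
                    coupled = de_genes %in% coupled_genes,
                    stringsAsFactors = FALSE),
    coupled_pairs = data.frame(probe_id = coupled_probes, gene = coupled_genes,
                               stringsAsFactors = FALSE),
    dynamics = dyn_truth,
    shared_same_direction = shared,
    opposite_probes = opp,
    candidate_genes = intersect(down_both, coupled_genes),
    motif_genes = fg_motif,
    motif_background_genes = bg_motif,
    planted_set = "PLANTED_DE_SET",
    config = config)

  cohort_bundle(expr = expr, beta = beta, manifest = manifest,
                samples = samples, gene_sets = gene_sets,
                promoters = promoters, motif = motif,
                annotation = annotation, truth = truth)
}

#' Evaluate a call set against planted truth
#'
#' @param calls Character vector of called ids.
#' @param truth_ids Character vector of planted-truth ids.
#' @return List with `sensitivity` (`|calls & truth| / |truth|`), `fdr`
#'   (`|calls \ truth| / max(|calls|, 1)`), and the underlying counts.
#' @export
evaluate_calls <- function(calls, truth_ids) {
  calls <- unique(calls)
  truth_ids <- unique(truth_ids)
  tp <- length(intersect(calls, truth_ids))
  list(sensitivity = if (length(truth_ids)) tp / length(truth_ids) else NA_real_,
       fdr = (length(calls) - tp) / max(length(calls), 1L),
       n_calls = length(calls), n_truth = length(truth_ids), tp = tp)
}
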