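# Shared fixtures, built in code at test time.

table2_path <- function() {
  system.file("extdata", "table2_opposite_sites.tsv", package = "epimyo",
              mustWork = TRUE)
}

# a small, fast cohort for unit tests (the acceptance suite uses defaults)
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_per_group = 10L, n_genes = 400L,
               n_probes = 1500L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# hand-built 4-sample toy bundle (2 subjects x 2 states) with short decimals
toy_bundle <- function() {
  samples <- data.frame(
    sample_id = c("S1_mb", "S2_mb", "S1_mt", "S2_mt"),
    subject_id = c("S1", "S2", "S1", "S2"),
    group = c("NGT", "T2D", "NGT", "T2D"),
    state = c("myoblast", "myoblast", "myotube", "myotube"),
    age = c(55, 60, 55, 60), bmi = c(24.5, 27.1, 24.5, 27.1),
    sex = c("male", "female", "male", "female"),
    stringsAsFactors = FALSE)
  expr <- matrix(c(8.1, 7.9, 8.3, 8.0,
                   5.5, 6.1, 5.2, 6.4), 2, 4, byrow = TRUE,
                 dimnames = list(c("GENEA", "GENEB"), samples$sample_id))
  beta <- matrix(c(0.10, 0.12, 0.15, 0.11,
                   0.90, 0.88, 0.85, 0.92,
                   0.50, 0.55, 0.45, 0.52), 3, 4, byrow = TRUE,
                 dimnames = list(c("cg001", "cg002", "cg003"), samples$sample_id))
  manifest <- data.frame(
    probe_id = c("cg001", "cg002", "cg003"),
    chromosome = c("1", "2", "3"),
    nearest_gene = c("GENEA", "GENEB", ""),
    gene_region = c("TSS200", "Body", "intergenic"),
    island_region = c("Island", "OpenSea", "OpenSea"),
    stringsAsFactors = FALSE)
  cohort_bundle(expr = expr, beta = beta, manifest = manifest,
                samples = samples)
}

# empirical Kolmogorov-Smirnov distance to Uniform(0, 1)
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p))
}

# permute group labels at the subject level, keeping pairs intact
permute_groups <- function(samples, seed) {
  set.seed(seed)
  subj <- unique(samples$subject_id)
  new_grp <- setNames(sample(samples$group[match(subj, samples$subject_id)]),
                      subj)
  samples$group <- unname(new_grp[samples$subject_id])
  samples
}
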