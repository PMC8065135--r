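# Readers/writers for every plain-text format the pipeline touches. All
# downstream modules consume only the in-memory shapes defined here:
#   sample sheet  data.frame(sample_id, subject_id, group, state, age, bmi, sex)
#   matrices      numeric matrix, features x samples, rownames/colnames set
#   manifest      data.frame(probe_id, chromosome, nearest_gene, gene_region,
#                            island_region); one row per (probe, gene)
# Betas are stored as fractions in [0, 1]; percent only at the report boundary.

GENE_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
                  "intergenic")
ISLAND_REGIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                    "OpenSea")

comment_header <- function(params = NULL, seed = NULL) {
  lines <- sprintf("# epimyo %s",
                   as.character(utils::packageVersion("epimyo")))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (length(params)) {
    lines <- c(lines, sprintf("# %s: %s", names(params),
                              vapply(params, function(v) paste(v, collapse = ","), "")))
  }
  lines
}

write_tsv <- function(df, path, params = NULL, seed = NULL) {
  # %.17g guarantees doubles survive the write -> read round trip bit-exactly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read/write a feature-by-sample matrix TSV
#'
#' Dialect: `#`-prefixed comment header, then a header row whose first column
#' is `feature_id` followed by sample ids, one feature per row.
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("matrix TSV needs a feature id column plus samples: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m))) stop("non-finite values in matrix file ", path)
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with rownames and colnames.
#' @param ... Passed to the comment header (`params`, `seed`).
#' @export
write_matrix_tsv <- function(m, path, ...) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path, ...)
}

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `subject_id`, `group` (NGT/T2D), `state`
#' (myoblast/myotube), `age`, `bmi`, `sex` (male/female). Sample ids must be
#' unique and each (subject, state) pair may occur at most once.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read_tsv(path))
}

validate_sample_sheet <- function(ss) {
  need <- c("sample_id", "subject_id", "group", "state", "age", "bmi", "sex")
  missing <- setdiff(need, names(ss))
  if (length(missing)) stop("sample sheet missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("sample sheet: duplicate sample_id")
  if (!all(ss$group %in% c("NGT", "T2D"))) stop("sample sheet: group must be NGT or T2D")
  if (!all(ss$state %in% c("myoblast", "myotube"))) {
    stop("sample sheet: state must be myoblast or myotube")
  }
  if (!all(ss$sex %in% c("male", "female"))) stop("sample sheet: sex must be male or female")
  if (anyDuplicated(ss[, c("subject_id", "state")])) {
    stop("sample sheet: each (subject_id, state) pair may appear at most once")
  }
  stopifnot(is.numeric(ss$age), is.numeric(ss$bmi))
  ss
}

#' Read and validate a probe manifest
#'
#' One row per (probe, annotated gene); probes annotated to several genes keep
#' several rows. Empty `nearest_gene` marks unannotated probes; empty region
#' fields are normalized to `intergenic` / `OpenSea`.
#'
#' @param path TSV path with columns `probe_id`, `chromosome`, `nearest_gene`,
#'   `gene_region`, `island_region`.
#' @return Validated data.frame.
#' @export
read_manifest <- function(path) {
  validate_manifest(read_tsv(path))
}

validate_manifest <- function(mf) {
  need <- c("probe_id", "chromosome", "nearest_gene", "gene_region", "island_region")
  missing <- setdiff(need, names(mf))
  if (length(missing)) stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("chromosome", "nearest_gene", "gene_region", "island_region")) {
    mf[[col]] <- as.character(mf[[col]])
    mf[[col]][is.na(mf[[col]])] <- ""
  }
  mf$gene_region[mf$gene_region == ""] <- "intergenic"
  mf$island_region[mf$island_region == ""] <- "OpenSea"
  bad <- setdiff(unique(mf$gene_region), GENE_REGIONS)
  if (length(bad)) stop("manifest: unknown gene_region value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(mf$island_region), ISLAND_REGIONS)
  if (length(bad)) stop("manifest: unknown island_region value(s): ", paste(bad, collapse = ", "))
  mf
}

check_beta_range <- function(beta, tol = 1e-9) {
  bad <- which(beta < -tol | beta > 1 + tol, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0, 1]: probe %s, sample %s (value %g)",
                 rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]],
                 beta[bad[1L, , drop = FALSE]]))
  }
  invisible(beta)
}

align_matrix_to_sheet <- function(m, ss, what) {
  unknown <- setdiff(colnames(m), ss$sample_id)
  if (length(unknown)) {
    stop(sprintf("%s matrix has sample(s) absent from the sample sheet: %s",
                 what, paste(unknown, collapse = ", ")))
  }
  keep <- ss$sample_id[ss$sample_id %in% colnames(m)]
  m[, keep, drop = FALSE]
}

#' Assemble a cohort bundle from its four TSV files
#'
#' Matrices are column-aligned to the sample sheet order (matrices may cover a
#' subset of the sheet, e.g. expression assayed on fewer subjects than
#' methylation). Probes present in the beta matrix but absent from the manifest
#' are retained and classed `intergenic` / `OpenSea`.
#'
#' @param expr_path,beta_path,manifest_path,samples_path TSV file paths.
#' @return A list of class `cohort_bundle` with elements `expr`, `beta`,
#'   `manifest`, `samples`.
#' @export
read_cohort <- function(expr_path, beta_path, manifest_path, samples_path) {
  ss <- read_sample_sheet(samples_path)
  expr <- tryCatch(read_matrix_tsv(expr_path),
                   error = function(e) stop("expression file ", expr_path, ": ",
                                            conditionMessage(e)))
  beta <- tryCatch(read_matrix_tsv(beta_path),
                   error = function(e) stop("beta file ", beta_path, ": ",
                                            conditionMessage(e)))
  check_beta_range(beta)
  beta <- pmin(pmax(beta, 0), 1)
  mf <- read_manifest(manifest_path)
  expr <- align_matrix_to_sheet(expr, ss, "expression")
  beta <- align_matrix_to_sheet(beta, ss, "beta")
  orphan <- setdiff(rownames(beta), mf$probe_id)
  if (length(orphan)) {
    mf <- rbind(mf, data.frame(probe_id = orphan, chromosome = "",
                               nearest_gene = "", gene_region = "intergenic",
                               island_region = "OpenSea",
                               stringsAsFactors = FALSE))
  }
  cohort_bundle(expr = expr, beta = beta, manifest = mf, samples = ss)
}

#' Construct a cohort bundle in memory
#'
#' @param expr,beta Feature-by-sample matrices (columns aligned to `samples`).
#' @param manifest Probe manifest data.frame.
#' @param samples Sample sheet data.frame.
#' @param ... Optional extras kept alongside (e.g. `gene_sets`, `promoters`,
#'   `motif`, `annotation`, `truth`).
#' @return Object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(expr, beta, manifest, samples, ...) {
  samples <- validate_sample_sheet(samples)
  manifest <- validate_manifest(manifest)
  check_beta_range(beta)
  out <- c(list(expr = expr, beta = beta, manifest = manifest,
                samples = samples), list(...))
  class(out) <- "cohort_bundle"
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d genes x %d samples (expression), %d probes x %d samples (beta), %d subjects\n",
              nrow(x$expr), ncol(x$expr), nrow(x$beta), ncol(x$beta),
              length(unique(x$samples$subject_id))))
  invisible(x)
}

#' Write a cohort bundle to a directory as TSV files
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if absent).
#' @param seed Optional seed recorded in the file headers.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(bundle, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(bundle$expr, file.path(dir, "expression.tsv"), seed = seed)
  write_matrix_tsv(bundle$beta, file.path(dir, "beta.tsv"), seed = seed)
  write_tsv(bundle$manifest, file.path(dir, "manifest.tsv"), seed = seed)
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"), seed = seed)
  invisible(dir)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: tab-delimited `name`, `description`, then members.
#'
#' @param path GMT file path.
#' @return List of class `gene_set_collection`: `sets` (named list of unique
#'   member vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_)) stop("GMT: duplicate set name(s): ",
                                  paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L)) stop("GMT: empty member set")
  names(sets) <- names_
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- names_
  structure(list(sets = sets, description = desc),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param gsc A `gene_set_collection`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a position frequency motif model
#'
#' @param name Motif name.
#' @param counts 4 x L non-negative matrix with rows A, C, G, T.
#' @param background Base frequencies (length 4, positive, summing to 1).
#' @param pseudocount Positive pseudocount used when forming log-odds.
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(name, counts, background = rep(0.25, 4),
                        pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("motif counts must have 4 rows (A, C, G, T), got ",
                               nrow(counts))
  if (ncol(counts) < 1L) stop("motif must have length >= 1")
  if (any(counts < 0)) stop("motif counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("motif has an all-zero column")
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts,
                 background = as.numeric(background),
                 pseudocount = pseudocount),
            class = "motif_model")
}

#' Read a JASPAR-style PFM file
#'
#' Dialect: a `>name` header line, then 4 count rows, either labeled
#' (`A [ 1 2 ... ]`) or bare numbers, in A, C, G, T order.
#'
#' @param path PFM file path.
#' @inheritParams motif_model
#' @return A `motif_model`.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1L], ">")) stop("PFM: expected '>' header line")
  name <- trimws(sub("^>", "", lines[1L]))
  rows <- lines[-1L]
  if (length(rows) != 4L) stop("PFM: expected 4 count rows, got ", length(rows))
  parse_row <- function(line) {
    nums <- regmatches(line, gregexpr("[0-9.]+", line))[[1L]]
    as.numeric(nums)
  }
  vals <- lapply(rows, parse_row)
  if (length(unique(lengths(vals))) != 1L) stop("PFM: count rows have unequal lengths")
  counts <- do.call(rbind, vals)
  labels <- toupper(substr(rows, 1L, 1L))
  if (all(labels %in% c("A", "C", "G", "T"))) {
    counts <- counts[match(c("A", "C", "G", "T"), labels), , drop = FALSE]
  }
  motif_model(name, counts, background = background, pseudocount = pseudocount)
}

#' Consensus sequence of a motif (column argmax)
#' @param motif A `motif_model`.
#' @return Character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$counts)[apply(motif$counts, 2L, which.max)],
        collapse = "")
}

#' Read promoter sequences from FASTA
#'
#' The first whitespace token of each header is taken as the gene symbol;
#' duplicates are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_promoters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("FASTA: duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nms
  out
}

#' @rdname read_fasta_promoters
#' @param promoters Named character vector of sequences.
#' @export
write_fasta_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

DYNAMICS_REPORT_COLS <- c(
  "probe_id", "chromosome", "nearest_gene", "gene_region", "island_region",
  "ngt_myoblast_mean", "ngt_myoblast_sd", "ngt_myotube_mean", "ngt_myotube_sd",
  "ngt_difference", "ngt_p", "ngt_q",
  "t2d_myoblast_mean", "t2d_myoblast_sd", "t2d_myotube_mean", "t2d_myotube_sd",
  "t2d_difference", "t2d_p", "t2d_q")

#' Parse a two-group dynamics report (percent scale)
#'
#' Ingests a report with per-probe annotation plus, for each group, the
#' myoblast and myotube mean +/- SD, the signed myotube-minus-myoblast
#' difference, and paired signed-rank p and q values, all on the percent scale
#' used for printed tables.
#'
#' @param path TSV path with columns `probe_id`, `chromosome`, `nearest_gene`,
#'   `gene_region`, `island_region`, then `ngt_*` / `t2d_*` numeric columns.
#' @return data.frame, one row per probe; empty (0-row) for a header-only file.
#' @export
parse_dynamics_report <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(DYNAMICS_REPORT_COLS, names(df))
  if (length(missing)) stop("dynamics report missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- df[, DYNAMICS_REPORT_COLS]
  if (nrow(df) == 0L) return(df)
  num_cols <- DYNAMICS_REPORT_COLS[6:19]
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("dynamics report: non-numeric or missing value for probe %s, column %s",
                   df$probe_id[bad[1L]], col))
    }
    df[[col]] <- v
  }
  for (col in c("nearest_gene", "gene_region", "island_region", "chromosome")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

#' Split a parsed dynamics report into per-group dynamics tables
#'
#' @param report data.frame from [parse_dynamics_report()].
#' @return Named list with `NGT` and `T2D` data.frames in the shape produced by
#'   [paired_dynamics()] (percent-scale means, signed difference, p, q).
#' @export
dynamics_report_groups <- function(report) {
  pick <- function(prefix, group) {
    data.frame(probe_id = report$probe_id,
               group = group,
               mean_myoblast = report[[paste0(prefix, "_myoblast_mean")]],
               sd_myoblast = report[[paste0(prefix, "_myoblast_sd")]],
               mean_myotube = report[[paste0(prefix, "_myotube_mean")]],
               sd_myotube = report[[paste0(prefix, "_myotube_sd")]],
               difference = report[[paste0(prefix, "_difference")]],
               p = report[[paste0(prefix, "_p")]],
               q = report[[paste0(prefix, "_q")]],
               stringsAsFactors = FALSE)
  }
  list(NGT = pick("ngt", "NGT"), T2D = pick("t2d", "T2D"))
}

#' Write a two-group dynamics report in the dialect read by
#' [parse_dynamics_report()]
#'
#' Percent values are rounded to 1 decimal and p/q to 4 decimals at this report
#' boundary only; the input tables keep full precision.
#'
#' @param ngt,t2d Per-group dynamics data.frames (from [paired_dynamics()]).
#' @param manifest Probe manifest used for the annotation columns.
#' @param path Output TSV path.
#' @param ... Header parameters passed through (`seed`, `params`).
#' @export
write_dynamics_report <- function(ngt, t2d, manifest, path, ...) {
  merged <- merge(ngt, t2d, by = "probe_id", suffixes = c("_ngt", "_t2d"))
  ann <- annotate_probes(merged$probe_id, manifest)
  out <- data.frame(
    probe_id = merged$probe_id,
    chromosome = ann$chromosome,
    nearest_gene = ann$nearest_gene,
    gene_region = ann$gene_region,
    island_region = ann$island_region,
    ngt_myoblast_mean = round(merged$mean_myoblast_ngt, 1),
    ngt_myoblast_sd = round(merged$sd_myoblast_ngt, 1),
    ngt_myotube_mean = round(merged$mean_myotube_ngt, 1),
    ngt_myotube_sd = round(merged$sd_myotube_ngt, 1),
    ngt_difference = round(merged$difference_ngt, 1),
    ngt_p = round(merged$p_ngt, 4),
    ngt_q = round(merged$q_ngt, 4),
    t2d_myoblast_mean = round(merged$mean_myoblast_t2d, 1),
    t2d_myoblast_sd = round(merged$sd_myoblast_t2d, 1),
    t2d_myotube_mean = round(merged$mean_myotube_t2d, 1),
    t2d_myotube_sd = round(merged$sd_myotube_t2d, 1),
    t2d_difference = round(merged$difference_t2d, 1),
    t2d_p = round(merged$p_t2d, 4),
    t2d_q = round(merged$q_t2d, 4),
    stringsAsFactors = FALSE)
  write_tsv(out, path, ...)
}

# Collapse the (possibly multi-row) manifest annotation of each probe to one
# row, joining multiple genes/regions with "; " as printed reports do.
annotate_probes <- function(probe_ids, manifest) {
  mf <- manifest[manifest$probe_id %in% probe_ids, , drop = FALSE]
  join <- function(x) paste(unique(x), collapse = "; ")
  agg <- function(col) {
    v <- tapply(mf[[col]], mf$probe_id, join)
    out <- as.character(v[probe_ids])
    out[is.na(out)] <- ""
    out
  }
  data.frame(probe_id = probe_ids,
             chromosome = agg("chromosome"),
             nearest_gene = agg("nearest_gene"),
             gene_region = agg("gene_region"),
             island_region = agg("island_region"),
             stringsAsFactors = FALSE)
}

#' Parse a flat key/value configuration file
#'
#' Lines of the form `key: value`; `#` starts a comment; values are coerced to
#' numeric or logical where possible. Used by the command-line front-end so
#' every flag can also come from a config file.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("config: cannot parse line: ", ln)
    key <- m[2L]; val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else val
  }
  out
}
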