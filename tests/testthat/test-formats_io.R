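test_that("cohort bundle round-trips through TSV files bit-identically", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  write_cohort(b, dir, seed = 42)
  b2 <- read_cohort(file.path(dir, "expression.tsv"), file.path(dir, "beta.tsv"),
                    file.path(dir, "manifest.tsv"), file.path(dir, "samples.tsv"))
  expect_identical(b2$expr, b$expr)
  expect_identical(b2$beta, b$beta)
  expect_equal(b2$manifest, b$manifest)
  expect_equal(b2$samples, b$samples)
  # loader never reorders samples relative to the sheet
  expect_identical(colnames(b2$beta), b2$samples$sample_id)
})

test_that("matrix round trip is the identity on randomized fixtures", {
  dir <- withr::local_tempdir()
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
    path <- file.path(dir, sprintf("m%d.tsv", i))
    write_matrix_tsv(m, path)
    expect_identical(read_matrix_tsv(path), m)
  }
})

test_that("out-of-range beta raises an error naming probe and sample", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  b$beta["cg002", "S2_mt"] <- 1.2
  write_matrix_tsv(b$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(b$expr, file.path(dir, "expression.tsv"))
  write_tsv(b$manifest, file.path(dir, "manifest.tsv"))
  write_tsv(b$samples, file.path(dir, "samples.tsv"))
  expect_error(
    read_cohort(file.path(dir, "expression.tsv"), file.path(dir, "beta.tsv"),
                file.path(dir, "manifest.tsv"), file.path(dir, "samples.tsv")),
    "cg002.*S2_mt")
})

test_that("probes missing from the manifest are classed intergenic/OpenSea", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  mf <- b$manifest[b$manifest$probe_id != "cg003", ]
  write_tsv(mf, file.path(dir, "manifest.tsv"))
  b2 <- read_cohort(file.path(dir, "expression.tsv"), file.path(dir, "beta.tsv"),
                    file.path(dir, "manifest.tsv"), file.path(dir, "samples.tsv"))
  row <- b2$manifest[b2$manifest$probe_id == "cg003", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$gene_region, "intergenic")
  expect_equal(row$island_region, "OpenSea")
})

test_that("GMT parsing follows the standard dialect", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "S2\tother\tG3\tG1\tG4"), path)
  gsc <- read_gmt(path)
  expect_setequal(gsc$sets$S1, c("G1", "G2"))
  expect_setequal(gsc$sets$S2, c("G3", "G1", "G4"))
  expect_equal(unname(gsc$description["S1"]), "desc")
  # duplicate names and empty member lists are rejected
  writeLines(c("S1\td\tG1", "S1\td\tG2"), path)
  expect_error(read_gmt(path), "duplicate")
  # round trip
  writeLines(c("S1\tdesc\tG1\tG2"), path)
  gsc <- read_gmt(path)
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, path2)
  expect_equal(read_gmt(path2), gsc)
})

test_that("JASPAR PFM parsing and consensus", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 testmotif", "A [ 1 0 ]", "C [ 0 1 ]", "G [ 0 0 ]",
               "T [ 0 0 ]"), path)
  m <- read_jaspar_pfm(path)
  expect_s3_class(m, "motif_model")
  expect_equal(ncol(m$counts), 2L)
  expect_equal(motif_consensus(m), "AC")
  # malformed: wrong number of rows
  writeLines(c(">M2", "A [ 1 ]", "C [ 0 ]", "G [ 0 ]"), path)
  expect_error(read_jaspar_pfm(path), "4 count rows")
  # all-zero column rejected by the model constructor
  expect_error(motif_model("bad", matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 4, 2)),
               "all-zero")
})

test_that("FASTA promoter reading enforces unique gene symbols", {
  path <- withr::local_tempfile(fileext = ".fa")
  set.seed(5)
  seqs <- setNames(vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  }, ""), c("G1", "G2", "G3"))
  write_fasta_promoters(seqs, path)
  got <- read_fasta_promoters(path)
  expect_equal(length(got), 3L)
  expect_true(all(nchar(got) == 1000L))
  expect_identical(got, seqs)
  writeLines(c(">G1 descr", "ACGT", ">G1 again", "TTTT"), path)
  expect_error(read_fasta_promoters(path), "G1")
})

test_that("dynamics report parsing: values, empty file, missing cells", {
  rep <- parse_dynamics_report(table2_path())
  expect_equal(nrow(rep), 39L)
  row <- rep[rep$probe_id == "cg05133314", ]
  expect_equal(row$ngt_myoblast_mean, 11.0)
  expect_equal(row$ngt_myotube_mean, 10.0)
  expect_equal(row$ngt_difference, -1.0)

  # header-only file parses to an empty table
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(epimyo:::DYNAMICS_REPORT_COLS, collapse = "\t"), path)
  expect_equal(nrow(parse_dynamics_report(path)), 0L)

  # a missing q-value is an error naming the probe
  lines <- readLines(table2_path())
  lines[grep("^cg09158487", lines)] <-
    sub("0\\.0267$", "", lines[grep("^cg09158487", lines)])
  writeLines(lines, path)
  expect_error(parse_dynamics_report(path), "cg09158487")
})

test_that("flat config parsing coerces types", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("n_genes: 100", "frac_de_genes: 0.1", "# comment",
               "motif_consensus: ACGTACGT", "flag: TRUE"), path)
  cfg <- read_flat_config(path)
  expect_identical(cfg$n_genes, 100)
  expect_identical(cfg$frac_de_genes, 0.1)
  expect_identical(cfg$motif_consensus, "ACGTACGT")
  expect_identical(cfg$flag, TRUE)
})
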