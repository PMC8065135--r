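test_that("paired dynamics: identity, symmetry and unrounded difference", {
  b <- simulate_cohort(small_config(seed = 31, n_probes = 300L, n_genes = 50L,
                                    n_opposite_sites = 5L))
  # a probe identical in both states for every subject has p = 1
  subj <- unique(b$samples$subject_id[b$samples$group == "NGT"])
  b$beta[1, paste0(subj, "_mt")] <- b$beta[1, paste0(subj, "_mb")]
  dyn <- suppressWarnings(paired_dynamics(b$beta, b$samples, "NGT"))
  expect_equal(dyn$p[1], 1)
  # unrounded identity holds exactly for every record
  expect_equal(dyn$difference, dyn$mean_myotube - dyn$mean_myoblast)
  # inverting state labels negates differences, p unchanged
  ss_flip <- b$samples
  ss_flip$state <- ifelse(ss_flip$state == "myoblast", "myotube", "myoblast")
  dyn_flip <- suppressWarnings(paired_dynamics(b$beta, ss_flip, "NGT"))
  expect_equal(dyn_flip$difference, -dyn$difference)
  expect_equal(dyn_flip$p, dyn$p)
})

test_that("unpaired subjects are dropped with warning; n >= 3 enforced", {
  b <- simulate_cohort(small_config(seed = 32, n_probes = 60L, n_genes = 30L,
                                    n_opposite_sites = 2L))
  ss <- b$samples[!(b$samples$subject_id == "NGT01" &
                      b$samples$state == "myotube"), ]
  expect_warning(paired_dynamics(b$beta, ss, "NGT"), "NGT01")
  ss3 <- b$samples[b$samples$subject_id %in% c("NGT01", "NGT02", "T2D01", "T2D02"), ]
  expect_error(paired_dynamics(b$beta, ss3, "NGT"), ">= 3 subjects")
})

test_that("significant-probe counts are monotone in the q threshold", {
  b <- simulate_cohort(small_config(seed = 33))
  dyn <- paired_dynamics(b$beta, b$samples, "NGT")
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2), function(thr) sum(dyn$q < thr), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("dynamics overlap reports per-direction intersections", {
  mk <- function(probes, q, d) data.frame(probe_id = probes, q = q,
                                          difference = d, stringsAsFactors = FALSE)
  a <- mk(c("p1", "p2", "p3"), c(0.01, 0.01, 0.5), c(1, -1, 1))
  ov_same <- dynamics_overlap(a, a)
  expect_equal(ov_same$up_shared, "p1")
  expect_equal(ov_same$down_shared, "p2")
  bdf <- mk(c("p1", "p2", "p3"), c(0.5, 0.5, 0.01), c(1, -1, 1))
  ov_disj <- dynamics_overlap(a, bdf)
  expect_equal(length(ov_disj$up_shared), 0L)
  expect_equal(length(ov_disj$down_shared), 0L)
})

test_that("shared planted dynamics are recovered in the overlap (3 seeds)", {
  rel_err <- vapply(1:3, function(s) {
    b <- simulate_cohort(small_config(seed = 40 + s))
    ngt <- paired_dynamics(b$beta, b$samples, "NGT")
    t2d <- paired_dynamics(b$beta, b$samples, "T2D")
    ov <- dynamics_overlap(ngt, t2d)
    found <- length(ov$up_shared) + length(ov$down_shared)
    planted <- length(b$truth$shared_same_direction)
    abs(found - planted) / planted
  }, 0)
  expect_lte(mean(rel_err), 0.10)
})

test_that("opposite-direction detection is exact on rule and symmetric", {
  mk <- function(q1, d1, q2, d2) {
    list(ngt = data.frame(probe_id = c("p1", "p2", "p3"), group = "NGT",
                          mean_myoblast = 10, sd_myoblast = 1,
                          mean_myotube = 10 + d1, sd_myotube = 1,
                          difference = d1, W = 0, p = q1 / 2, q = q1),
         t2d = data.frame(probe_id = c("p1", "p2", "p3"), group = "T2D",
                          mean_myoblast = 10, sd_myoblast = 1,
                          mean_myotube = 10 + d2, sd_myotube = 1,
                          difference = d2, W = 0, p = q2 / 2, q = q2))
  }
  # p1 opposite+significant, p2 same-sign, p3 not significant in T2D
  x <- mk(q1 = c(0.01, 0.01, 0.01), d1 = c(2, 2, 2),
          q2 = c(0.01, 0.01, 0.5), d2 = c(-2, 2, -2))
  opp <- opposite_direction_sites(x$ngt, x$t2d)
  expect_equal(opp$probe_id, "p1")
  # swapping the group arguments flags the same probes (columns relabel)
  opp_swap <- opposite_direction_sites(x$t2d, x$ngt)
  expect_equal(opp_swap$probe_id, opp$probe_id)
})

test_that("region averages: constants, bounds, planted open-sea offset", {
  b <- simulate_cohort(small_config(seed = 51, n_probes = 300L, n_genes = 60L,
                                    n_opposite_sites = 5L))
  flat <- b$beta
  flat[] <- 0.5
  res <- suppressWarnings(region_average_methylation(flat, b$samples, b$manifest))
  expect_true(all(abs(res$averages$mean_beta - 0.5) < 1e-12))
  expect_true(all(res$state_contrasts$p == 1))
  # class averages are convex combinations of betas
  res2 <- suppressWarnings(region_average_methylation(b$beta, b$samples, b$manifest))
  expect_true(all(res2$averages$mean_beta >= min(b$beta) - 1e-12))
  expect_true(all(res2$averages$mean_beta <= max(b$beta) + 1e-12))
  # planted +5pp open-sea offset in T2D myoblasts: open sea significant,
  # island not (aggregate over 3 seeds). Couplings are disabled in this
  # scenario: a coupled probe's beta tracks its gene's group effect, which
  # would put a genuine group signal into the island classes too.
  ps_open <- ps_island <- numeric(3)
  for (s in 1:3) {
    bo <- simulate_cohort(small_config(seed = 60 + s, opensea_offset_t2d = 0.05,
                                       coupling_frac = 0))
    r <- suppressWarnings(region_average_methylation(bo$beta, bo$samples, bo$manifest))
    gc <- r$group_contrasts
    ps_open[s] <- gc$q[gc$class == "OpenSea" & gc$state == "myoblast"]
    ps_island[s] <- gc$q[gc$class == "Island" & gc$state == "myoblast"]
  }
  expect_true(all(ps_open < 0.05))
  expect_gte(mean(ps_island >= 0.05), 2 / 3)
})

test_that("PC-group association finds a planted group-aligned direction", {
  set.seed(71)
  n <- 20
  samples <- data.frame(
    sample_id = paste0("s", 1:n), subject_id = paste0("s", 1:n),
    group = rep(c("NGT", "T2D"), each = n / 2), state = "myoblast",
    age = rnorm(n, 56, 7), bmi = rnorm(n, 25.7, 3.1),
    sex = rep_len(c("male", "female"), n), stringsAsFactors = FALSE)
  X <- matrix(rnorm(500 * n), 500, n,
              dimnames = list(paste0("f", 1:500), samples$sample_id))
  grp <- as.numeric(samples$group == "T2D")
  X[1:50, ] <- X[1:50, ] + 10 * outer(rnorm(50), grp - mean(grp))
  res <- pc_group_association(X, samples, "myoblast", k = 5)
  expect_equal(sum(abs(res$r) > 0.8), 1L)
  # permuted labels: no strong component association (seeded null)
  hits <- vapply(1:50, function(i) {
    ss_p <- permute_groups(samples, seed = 100 + i)
    grp_p <- as.numeric(ss_p$group == "T2D")
    pca <- pca_top_components(matrix(rnorm(500 * n), 500, n,
                                     dimnames = dimnames(X)), 5)
    min(vapply(1:5, function(k) {
      correlation_test(pca$scores[, k], grp_p, "pearson")$p
    }, 0))
  }, 0)
  expect_gte(mean(hits > 0.005), 0.9)
})
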