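test_that("the correlation gene filter requires the threshold in both panels", {
  mk <- function(means) matrix(rep(means, 2), length(means), 2,
                               dimnames = list(paste0("g", seq_along(means)),
                                               c("a", "b")))
  gb <- mk(c(1, 0.6, 0.1, 0.6, 0.5))
  nogb <- mk(c(1, 0.6, 2, 0.4, 0.5))
  kept <- correlation_gene_filter(gb, nogb)
  expect_setequal(kept, c("g1", "g2"))  # g4 fails noGB, g3 fails GB
  expect_false("g5" %in% kept)          # exactly 0.5 excluded (strict >)
  expect_error(correlation_gene_filter(mk(0.1), mk(0.1)), "lowering")
  expect_error(correlation_gene_filter(gb, nogb[c(2, 1, 3, 4, 5), ][1:4, ]),
               "universe")
})

test_that("the Spearman matrix uses average ranks and names bad samples", {
  mk <- function(...) {
    v <- list(...)
    matrix(unlist(v), ncol = length(v),
           dimnames = list(paste0("g", seq_along(v[[1]])),
                           paste0("s", seq_along(v))))
  }
  x <- mk(c(1, 2, 3, 4))
  expect_equal(unname(spearman_matrix(x, x, rownames(x))$raw[1, 1]), 1)
  expect_equal(unname(spearman_matrix(x, mk(c(2, 4, 6, 8)),
                                      rownames(x))$raw[1, 1]), 1)
  y5 <- mk(c(1, 2, 3, 4, 5))
  expect_equal(unname(spearman_matrix(y5, mk(c(5, 4, 3, 2, 1)),
                                      rownames(y5))$raw[1, 1]), -1)

  # tie handling against an explicit rank-then-Pearson oracle
  a <- c(1, 2, 2, 4); b <- c(3, 1, 4, 2)
  oracle <- stats::cor(rank(a), rank(b))
  got <- spearman_matrix(mk(a), mk(b), paste0("g", 1:4))$raw[1, 1]
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  expect_error(spearman_matrix(mk(c(2, 2, 2, 2)), mk(b), paste0("g", 1:4)),
               "constant.*s1")
  expect_error(spearman_matrix(mk(c(1, 2)), mk(c(1, 2)), c("g1", "g2")),
               "at least 3")
})

test_that("scaling divides by column means then row maxima", {
  raw <- rbind(c(0.90, 0.80), c(0.70, 0.95))
  scaled <- scale_correlation_matrix(raw)
  expect_equal(scaled, rbind(c(1, 0.8126984), c(0.8059211, 1)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(scale_correlation_matrix(matrix(0.9)), matrix(1))
  expect_error(scale_correlation_matrix(rbind(c(-1, 0.5), c(0.5, 0.5))),
               "column mean")
})

test_that("every row maximum of the scaled matrix is exactly one", {
  set.seed(7)
  for (i in 1:25) {
    raw <- matrix(runif(30, 0.2, 1), 5, 6)
    scaled <- scale_correlation_matrix(raw)
    expect_identical(unname(apply(scaled, 1, max)), rep(1, 5))
    expect_true(all(scaled <= 1))
  }
})

test_that("scaling agrees with the brute-force double loop", {
  set.seed(11)
  for (i in 1:100) {
    raw <- matrix(runif(36, 0.1, 1), 6, 6)
    expect_equal(scale_correlation_matrix(raw), scale_matrix_bruteforce(raw),
                 tolerance = 1e-12)
  }
})

test_that("scaling is invariant to positive column rescaling", {
  set.seed(3)
  for (i in 1:20) {
    raw <- matrix(runif(30, 0.2, 1), 6, 5)
    scales <- runif(5, 0.1, 10)
    expect_equal(scale_correlation_matrix(sweep(raw, 2, scales, "*")),
                 scale_correlation_matrix(raw), tolerance = 1e-12)
  }
})

test_that("assignment picks the unit score and honours ground truth", {
  scaled <- rbind(c(1, 0.81), c(0.81, 1))
  dimnames(scaled) <- list(c("n1", "n2"), c("g1", "g2"))
  truth <- data.frame(gb_sample = c("g1", "g2"), nogb_sample = c("n1", "n2"))
  rep <- assign_pairs(scaled, truth)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$assignments$gb_assigned, c("g1", "g2"))

  # ties break to the lowest column index with a warning
  tied <- matrix(1, 1, 2, dimnames = list("n1", c("g1", "g2")))
  expect_warning(rep2 <- assign_pairs(tied), "tied")
  expect_equal(rep2$assignments$gb_assigned, "g1")

  # many-to-one assignment is allowed (that is how mismatches look)
  lop <- rbind(c(1, 0.5), c(1, 0.4))
  dimnames(lop) <- dimnames(scaled)
  rep3 <- assign_pairs(lop, truth)
  expect_equal(rep3$assignments$gb_assigned, c("g1", "g1"))
  expect_equal(rep3$accuracy, 0.5)
})

test_that("assignment is equivariant under matched permutations", {
  set.seed(19)
  raw <- matrix(runif(25, 0.3, 1), 5, 5,
                dimnames = list(paste0("n", 1:5), paste0("g", 1:5)))
  truth <- data.frame(gb_sample = paste0("g", 1:5),
                      nogb_sample = paste0("n", 1:5))
  base <- assign_pairs(scale_correlation_matrix(raw), truth)
  pr <- sample(5); pc <- sample(5)
  perm <- assign_pairs(scale_correlation_matrix(raw[pr, pc]), truth)
  expect_equal(perm$accuracy, base$accuracy)
  m <- merge(base$assignments, perm$assignments, by = "nogb_sample")
  expect_equal(m$gb_assigned.x, m$gb_assigned.y)
})

test_that("outlier detection flags samples that correlate far less", {
  # per-row mean correlations (0.90, 0.91, 0.89, 0.90, 0.30): the robust
  # z-score of the last row is (0.30 - 0.90) / (1.4826 * 0.01), far below -2.5
  raw <- matrix(rep(c(0.90, 0.91, 0.89, 0.90, 0.30), 5), 5, 5,
                dimnames = list(paste0("n", 1:5), paste0("g", 1:5)))
  expect_equal(detect_outliers(raw), "n5")

  flat <- matrix(0.9, 4, 4, dimnames = list(paste0("n", 1:4), paste0("g", 1:4)))
  expect_equal(length(detect_outliers(flat)), 0)
  expect_equal(length(detect_outliers(raw, z_threshold = -Inf)), 0)
  expect_error(detect_outliers(raw[1:2, ]), "at least 3")
})

test_that("iterative matching excludes constructed outlier pairs and recovers", {
  co <- simulate_paired_cohort(desk_config(n_individuals = 10, n_genes = 600,
                                           libsize = 3e4, seed = 31),
                               "dataset2")
  panels <- split_panels(co)
  # destroy one noGB sample by shuffling its gene labels
  set.seed(1)
  panels$nogb[, "iso004_noGB"] <- sample(panels$nogb[, "iso004_noGB"])
  rep <- iterative_matching(panels$nogb, panels$gb, co$genes, co$truth,
                            max_rounds = 2)
  expect_true("iso004_noGB" %in% unlist(rep$excluded_outliers))
  expect_false("iso004_noGB" %in% rep$assignments$nogb_sample)
  expect_false("iso004_GB" %in% rep$assignments$gb_assigned)
  # surviving pairs all match; the excluded pair counts as a failure
  expect_equal(rep$accuracy_post_exclusion, 1)
  expect_lte(rep$accuracy, 9 / 10)

  # single-pass mode reports but does not apply the detection
  rep1 <- iterative_matching(panels$nogb, panels$gb, co$genes, co$truth,
                             max_rounds = 1)
  expect_equal(nrow(rep1$assignments), 10)
  expect_equal(rep1$rounds, 1)
})

test_that("clean shared-lane cohorts match perfectly in a single pass", {
  accs <- vapply(1:5, function(seed) {
    co <- simulate_paired_cohort(desk_config(n_individuals = 10,
                                             n_genes = 800, libsize = 3e4,
                                             seed = 300 + seed), "dataset2")
    panels <- split_panels(co)
    iterative_matching(panels$nogb, panels$gb, co$genes, co$truth,
                       max_rounds = 1)$accuracy
  }, numeric(1))
  expect_equal(accs, rep(1, 5))
})
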