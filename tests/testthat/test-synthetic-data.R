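test_that("globin-block rescaling preserves within-set proportions", {
  p <- c(g = 0.43, a = 0.27, b = 0.30)
  out <- apply_globin_block(p, c(TRUE, FALSE, FALSE), 0.08)
  # non-globin genes rescaled by (1 - 0.08) / (1 - 0.43)
  expect_equal(unname(out),
               c(0.08, 0.27 * 0.92 / 0.57, 0.30 * 0.92 / 0.57),
               tolerance = 1e-12)
  expect_equal(sum(out), 1)

  # identity when target equals current globin mass
  expect_equal(apply_globin_block(p, c(TRUE, FALSE, FALSE), 0.43), p)

  # two globin genes at 0.3/0.1 keep their 3:1 ratio at target 0.2
  p2 <- c(g1 = 0.3, g2 = 0.1, a = 0.6)
  out2 <- apply_globin_block(p2, c(TRUE, TRUE, FALSE), 0.2)
  expect_equal(unname(out2[1:2]), c(0.15, 0.05))

  # complete depletion as explicit limiting case
  out0 <- apply_globin_block(p, c(TRUE, FALSE, FALSE), 0)
  expect_equal(unname(out0[1]), 0)
  expect_equal(sum(out0), 1)
})

test_that("globin-block rescaling rejects degenerate masks and targets", {
  p <- c(0.5, 0.5)
  expect_error(apply_globin_block(p, c(TRUE, TRUE), 0.1), "non-globin")
  expect_error(apply_globin_block(p, c(FALSE, FALSE), 0.1), "globin")
  expect_error(apply_globin_block(p, c(TRUE, FALSE), 1), "\\[0, 1\\)")
  expect_error(apply_globin_block(c(0.6, 0.6), c(TRUE, FALSE), 0.1), "sum to 1")
})

test_that("batch perturbation is shared within a batch and null at sd 0", {
  p <- rep(1 / 4, 4)
  expect_identical(apply_batch_effect(p, 0, seed = 3), p)
  s <- batch_seed(99, "run:run2")
  expect_identical(apply_batch_effect(p, 0.5, s), apply_batch_effect(p, 0.5, s))
  expect_false(identical(apply_batch_effect(p, 0.5, s),
                         apply_batch_effect(p, 0.5, batch_seed(99, "run:run1"))))
  expect_error(apply_batch_effect(p, -1, 1), ">= 0")
})

test_that("batch perturbation matches its configured log-variance", {
  # mean squared log-ratio (before renormalization) estimates batch_sd^2;
  # with z ~ N(0, 0.25), Var(z^2) = 2 * 0.25^2, so the Monte Carlo s.e.
  # of the mean over 1000 genes is sqrt(0.125 / 1000)
  p <- rep(1 / 1000, 1000)
  out <- apply_batch_effect(p, 0.5, seed = 11)
  # out = p * exp(z) / c, so log(out / p) = z - log(c); centering
  # removes the common renormalization constant (E[z] = 0)
  lr <- log(out / p)
  msq <- mean((lr - mean(lr))^2)
  expect_lt(abs(msq - 0.25), 3 * sqrt(0.125 / 1000) + 0.25 / 1000)
})

test_that("simulated cohorts are deterministic and respect library sizes", {
  cfg <- desk_config(n_individuals = 3, seed = 21)
  a <- simulate_paired_cohort(cfg)
  b <- simulate_paired_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)

  # library size drawn per sample is hit exactly by the multinomial
  cfg0 <- desk_config(n_individuals = 4, seed = 8)
  cfg0$libsize_noGB_sd <- 0; cfg0$libsize_GB_sd <- 0
  co <- simulate_paired_cohort(cfg0)
  expect_true(all(colSums(co$counts) == 2e4))
})

test_that("ground truth is a bijection with full batch assignment", {
  co <- simulate_paired_cohort(desk_config(n_individuals = 6, seed = 2))
  expect_setequal(co$truth$gb_sample,
                  co$samples$sample_id[co$samples$protocol == "GB"])
  expect_setequal(co$truth$nogb_sample,
                  co$samples$sample_id[co$samples$protocol == "noGB"])
  expect_false(anyDuplicated(co$truth$gb_sample) > 0)
  expect_true(all(!is.na(co$samples$run) & !is.na(co$samples$machine) &
                    !is.na(co$samples$lane)))
})

test_that("scenarios lay out batches as designed", {
  co1 <- simulate_paired_cohort(desk_config(n_individuals = 3), "dataset1")
  s1 <- co1$samples
  expect_equal(unique(s1$run[s1$protocol == "noGB"]), "run1")
  expect_equal(unique(s1$run[s1$protocol == "GB"]), "run2")
  expect_equal(unique(s1$machine), "HiSeq2500")

  co2 <- simulate_paired_cohort(desk_config(n_individuals = 3), "dataset2")
  expect_equal(unique(co2$samples$run), "run1")
  expect_equal(unique(co2$samples$lane), 1L)

  co3 <- simulate_paired_cohort(desk_config(n_individuals = 3), "cross_machine")
  expect_equal(sort(unique(co3$samples$machine)), c("HiSeq2500", "HiSeq4000"))
})

test_that("no-effect configuration collapses to exchangeable samples", {
  cfg <- desk_config(n_individuals = 6, n_genes = 300, bio_effect_sd = 0,
                     libsize = 5e4, seed = 13)
  cfg$globin_fraction_GB_mean <- cfg$globin_fraction_noGB_mean
  cfg$globin_fraction_GB_sd <- 0
  cfg$globin_fraction_noGB_sd <- 0
  co <- simulate_paired_cohort(cfg, "dataset2")
  # expected proportions identical across samples: per-gene count
  # proportions deviate only by multinomial noise around a common value
  props <- sweep(co$counts, 2, colSums(co$counts), "/")
  spread <- apply(props, 1, sd)
  binom_se <- sqrt(rowMeans(props) * (1 - rowMeans(props)) / 5e4)
  expect_lt(median(spread[binom_se > 0] / binom_se[binom_se > 0]), 2)
})

test_that("realized globin fractions recover configured depletion", {
  cfg <- desk_config(n_individuals = 30, libsize = 5e4, seed = 17)
  co <- simulate_paired_cohort(cfg)
  gf <- globin_fraction(co$counts, co$genes)
  proto <- co$samples$protocol[match(names(gf), co$samples$sample_id)]
  se_nogb <- 0.14 / sqrt(30)
  se_gb <- 0.043 / sqrt(30)
  expect_lt(abs(mean(gf[proto == "noGB"]) - 0.43), 3 * se_nogb)
  expect_lt(abs(mean(gf[proto == "GB"]) - 0.080), 3 * se_gb)
})

test_that("paired samples correlate more than cross-isolate pairs", {
  # with no batch layers and bio_effect_sd > 0, the shared isolate
  # signal must dominate: check over 20 independent cohorts
  wins <- vapply(1:20, function(seed) {
    co <- simulate_paired_cohort(
      desk_config(n_individuals = 4, n_genes = 300, libsize = 2e4,
                  seed = 100 + seed), "dataset2")
    panels <- split_panels(co)
    raw <- stats::cor(panels$nogb, panels$gb, method = "spearman")
    paired_idx <- cbind(match(co$truth$nogb_sample, rownames(raw)),
                        match(co$truth$gb_sample, colnames(raw)))
    mean(raw[paired_idx]) > mean(raw[-(paired_idx[, 1] +
                                        (paired_idx[, 2] - 1) * nrow(raw))])
  }, logical(1))
  expect_true(all(wins))
})

test_that("config validation rejects impossible settings", {
  expect_error(desk_config(n_genes = 1), "n_genes")
  expect_error(suppressMessages(simulation_config(globin_fraction_GB_mean = 1.4)),
               "\\[0, 1\\]")
  expect_error(suppressMessages(simulation_config(bio_effect_sd = -0.1)), ">= 0")
  expect_error(suppressMessages(simulation_config(libsize_GB_mean = 0)), "> 0")
  # defaults announce truncation (GB mean - 3 s.d. < 0)
  expect_message(simulation_config(), "truncated")
})
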