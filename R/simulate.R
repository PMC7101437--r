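#' Configuration for a paired GB/noGB cohort simulation
#'
#' Collects every knob of the synthetic-data generator. The defaults
#' encode the depletion observed in a real blocked/unblocked blood
#' cohort: unblocked (noGB) libraries carry a globin fraction of about
#' 0.43 (s.d. 0.14), blocking (GB) reduces it to about 0.080
#' (s.d. 0.043), and blocked libraries are somewhat shallower
#' (11.3M reads, s.d. 2.8M) than unblocked ones (13.8M, s.d. 2.1M).
#' Baseline expression is log-normal per gene; each isolate adds a
#' shared log-deviation so both libraries of one donor carry the same
#' biological signal.
#'
#' Globin-fraction draws are truncated to `[0.001, 0.999]`; a message is
#' emitted at construction when the configured mean +/- 3 s.d. leaves
#' `[0, 1]`, i.e. when truncation is expected to bite (the defaults do,
#' on the GB side).
#'
#' @param n_individuals Number of RNA isolates; each contributes one GB
#'   and one noGB library.
#' @param n_genes Total number of genes, globin genes included.
#' @param n_globin_genes Number of globin genes (at most 10 receive the
#'   canonical hemoglobin symbols).
#' @param baseline_log_mean,baseline_log_sd Location and spread of the
#'   per-gene log-expression baseline (natural log scale).
#' @param bio_effect_sd Per-isolate, per-gene log-fold deviation shared
#'   by both libraries of one isolate; 0 removes all biology.
#' @param globin_fraction_noGB_mean,globin_fraction_noGB_sd Normal
#'   parameters of the unblocked globin fraction.
#' @param globin_fraction_GB_mean,globin_fraction_GB_sd Normal
#'   parameters of the blocked globin fraction.
#' @param globin_fraction_correlation Within-isolate correlation between
#'   the noGB and GB globin-fraction draws (a high-globin donor stays
#'   high-globin when blocked). Default 0: independent draws.
#' @param libsize_noGB_mean,libsize_noGB_sd,libsize_GB_mean,libsize_GB_sd
#'   Normal parameters of the per-library sequencing depth (reads).
#' @param run_batch_sd Gene-wise s.d. of the log perturbation applied
#'   per sequencing run.
#' @param machine_batch_sd Gene-wise s.d. of the log perturbation
#'   applied per sequencing machine.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `simulation_config`.
#' @seealso [simulate_paired_cohort()]
#' @export
simulation_config <- function(n_individuals = 91L,
                              n_genes = 2000L,
                              n_globin_genes = 10L,
                              baseline_log_mean = 0,
                              baseline_log_sd = 1.5,
                              bio_effect_sd = 0.5,
                              globin_fraction_noGB_mean = 0.43,
                              globin_fraction_noGB_sd = 0.14,
                              globin_fraction_GB_mean = 0.080,
                              globin_fraction_GB_sd = 0.043,
                              globin_fraction_correlation = 0,
                              libsize_noGB_mean = 13.8e6,
                              libsize_noGB_sd = 2.1e6,
                              libsize_GB_mean = 11.3e6,
                              libsize_GB_sd = 2.8e6,
                              run_batch_sd = 0.1,
                              machine_batch_sd = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    n_globin_genes = as.integer(n_globin_genes),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    bio_effect_sd = bio_effect_sd,
    globin_fraction_noGB_mean = globin_fraction_noGB_mean,
    globin_fraction_noGB_sd = globin_fraction_noGB_sd,
    globin_fraction_GB_mean = globin_fraction_GB_mean,
    globin_fraction_GB_sd = globin_fraction_GB_sd,
    globin_fraction_correlation = globin_fraction_correlation,
    libsize_noGB_mean = libsize_noGB_mean,
    libsize_noGB_sd = libsize_noGB_sd,
    libsize_GB_mean = libsize_GB_mean,
    libsize_GB_sd = libsize_GB_sd,
    run_batch_sd = run_batch_sd,
    machine_batch_sd = machine_batch_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_individuals < 1L) stop("n_individuals must be >= 1")
  if (cfg$n_genes < 2L) stop("n_genes must be >= 2")
  if (cfg$n_globin_genes < 1L || cfg$n_globin_genes >= cfg$n_genes) {
    stop("need at least one globin and one non-globin gene")
  }
  props <- c(cfg$globin_fraction_noGB_mean, cfg$globin_fraction_GB_mean)
  if (any(props < 0 | props > 1)) stop("globin fraction means must lie in [0, 1]")
  sds <- c(cfg$baseline_log_sd, cfg$bio_effect_sd,
           cfg$globin_fraction_noGB_sd, cfg$globin_fraction_GB_sd,
           cfg$run_batch_sd, cfg$machine_batch_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$baseline_log_sd <= 0) stop("baseline_log_sd must be > 0")
  if (abs(cfg$globin_fraction_correlation) > 1) {
    stop("globin_fraction_correlation must lie in [-1, 1]")
  }
  if (cfg$libsize_noGB_mean <= 0 || cfg$libsize_GB_mean <= 0) {
    stop("library-size means must be > 0")
  }
  if (cfg$libsize_noGB_sd < 0 || cfg$libsize_GB_sd < 0) {
    stop("library-size sds must be >= 0")
  }
  truncating <-
    cfg$globin_fraction_noGB_mean + 3 * cfg$globin_fraction_noGB_sd > 1 ||
    cfg$globin_fraction_noGB_mean - 3 * cfg$globin_fraction_noGB_sd < 0 ||
    cfg$globin_fraction_GB_mean + 3 * cfg$globin_fraction_GB_sd > 1 ||
    cfg$globin_fraction_GB_mean - 3 * cfg$globin_fraction_GB_sd < 0
  if (truncating) {
    message("globin-fraction mean +/- 3 s.d. leaves [0, 1]; ",
            "draws will be truncated to [0.001, 0.999]")
  }
  invisible(cfg)
}

#' Rescale the globin mass of an expression profile
#'
#' Models cDNA blocking at the level of expected read proportions: the
#' total mass of the globin genes is set to `target_globin_fraction`
#' while relative proportions within the globin set and within the
#' non-globin set are preserved.
#'
#' @param expected_proportions Numeric vector over genes, summing to 1.
#' @param globin_mask Logical vector marking globin genes; at least one
#'   gene on each side of the mask is required.
#' @param target_globin_fraction Target total globin mass in `[0, 1)`;
#'   0 is the limiting case of complete depletion.
#' @return Proportion vector summing to 1 with globin mass equal to the
#'   target.
#' @examples
#' p <- c(HBB = 0.43, a = 0.27, b = 0.30)
#' apply_globin_block(p, c(TRUE, FALSE, FALSE), 0.08)
#' @export
apply_globin_block <- function(expected_proportions, globin_mask,
                               target_globin_fraction) {
  p <- expected_proportions
  if (abs(sum(p) - 1) > 1e-8) stop("expected_proportions must sum to 1")
  if (any(p < 0)) stop("expected_proportions must be non-negative")
  globin_mask <- as.logical(globin_mask)
  if (length(globin_mask) != length(p)) {
    stop("globin_mask length must match expected_proportions")
  }
  if (!any(globin_mask) || all(globin_mask)) {
    stop("need at least one globin and one non-globin gene")
  }
  t <- target_globin_fraction
  if (t < 0 || t >= 1) stop("target_globin_fraction must lie in [0, 1)")
  g <- sum(p[globin_mask])
  if (g == 0 && t > 0) stop("cannot raise globin mass from zero")
  if (g == 1) stop("profile has no non-globin mass to rescale")
  out <- p
  out[globin_mask] <- if (g > 0) p[globin_mask] * (t / g) else 0
  out[!globin_mask] <- p[!globin_mask] * ((1 - t) / (1 - g))
  out
}

#' Perturb an expression profile with a gene-wise batch effect
#'
#' Multiplies each gene's expected proportion by `exp(z_g)` with
#' `z_g ~ Normal(0, batch_sd)` drawn once per (batch, gene), then
#' renormalizes. Passing the same `seed` (derive it from the batch id,
#' e.g. via [batch_seed()]) reproduces the same perturbation vector for
#' every member sample of that batch.
#'
#' @param expected_proportions Numeric vector over genes, summing to 1.
#' @param batch_sd Non-negative gene-wise s.d. on the log scale.
#' @param seed Integer seed identifying the batch draw.
#' @return Perturbed proportion vector summing to 1.
#' @export
apply_batch_effect <- function(expected_proportions, batch_sd, seed) {
  p <- expected_proportions
  if (abs(sum(p) - 1) > 1e-8) stop("expected_proportions must sum to 1")
  if (batch_sd < 0) stop("batch_sd must be >= 0")
  if (batch_sd == 0) return(p)
  z <- withr::with_seed(as.integer(seed), rnorm(length(p), 0, batch_sd))
  q <- p * exp(z)
  q / sum(q)
}

#' Derive a reproducible sub-seed for a batch
#'
#' Hashes a batch identifier together with the cohort seed so that the
#' perturbation of a batch depends on its identity, not on sample
#' order. Plain polynomial string hash reduced modulo 2^31 - 1.
#'
#' @param seed Integer cohort seed.
#' @param batch_id Character batch identifier (e.g. `"run:run2"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
batch_seed <- function(seed, batch_id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(as.character(batch_id))) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

#' @keywords internal
#' @noRd
simulated_gene_ids <- function(n_genes, n_globin_genes) {
  n_named <- min(n_globin_genes, length(default_globin_genes))
  globin <- default_globin_genes[seq_len(n_named)]
  if (n_globin_genes > n_named) {
    globin <- c(globin, sprintf("HBSIM%02d", seq_len(n_globin_genes - n_named)))
  }
  other <- sprintf("GENE%05d", seq_len(n_genes - n_globin_genes))
  c(globin, other)
}

#' @keywords internal
#' @noRd
truncated_normal_pair <- function(mean1, sd1, mean2, sd2, rho,
                                  lower = 0.001, upper = 0.999) {
  z1 <- rnorm(1)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
  f1 <- min(max(mean1 + sd1 * z1, lower), upper)
  f2 <- min(max(mean2 + sd2 * z2, lower), upper)
  c(f1, f2)
}

#' Batch layout for a simulation scenario
#'
#' `dataset1` places the two protocols on two separate sequencing runs
#' of the same machine, four lanes each (the discovery-cohort layout);
#' `dataset2` places every library on one lane of one run of one
#' machine (the technical-validation layout, where no batch layer
#' separates the protocols); `cross_machine` additionally puts the two
#' protocols on different machine models, the layout under which
#' machine-level batch noise degrades sample matching.
#'
#' @keywords internal
#' @noRd
scenario_batches <- function(scenario, protocol, index) {
  switch(scenario,
    dataset1 = list(
      run = ifelse(protocol == "noGB", "run1", "run2"),
      machine = rep("HiSeq2500", length(protocol)),
      lane = ((index - 1L) %% 4L) + 1L
    ),
    dataset2 = list(
      run = rep("run1", length(protocol)),
      machine = rep("HiSeq4000", length(protocol)),
      lane = rep(1L, length(protocol))
    ),
    cross_machine = list(
      run = ifelse(protocol == "noGB", "run1", "run2"),
      machine = ifelse(protocol == "noGB", "HiSeq2500", "HiSeq4000"),
      lane = ((index - 1L) %% 4L) + 1L
    ),
    stop("unknown scenario: ", scenario)
  )
}

#' Simulate a paired GB/noGB whole-blood cohort
#'
#' Generates gene-level counts for `n_individuals` RNA isolates, each
#' sequenced once unblocked (noGB) and once globin-blocked (GB). Per
#' isolate, a latent log-normal expression profile (baseline plus
#' isolate deviation, shared by both libraries) is rescaled to a drawn
#' globin fraction per protocol via [apply_globin_block()], perturbed by
#' gene-wise run- and machine-level batch effects, and sampled
#' multinomially at a drawn library size. The full cohort is
#' reproducible from `config$seed`; batch perturbations are keyed to
#' batch identity via [batch_seed()], so two samples on the same run
#' share the same run perturbation.
#'
#' @param config A [simulation_config()].
#' @param scenario Batch layout: `"dataset1"` (protocols on distinct
#'   runs, one machine), `"dataset2"` (everything on one lane of one
#'   machine), or `"cross_machine"` (protocols on distinct runs and
#'   distinct machines).
#' @return A list of class `gb_cohort` with elements
#'   \describe{
#'     \item{counts}{genes x samples integer matrix}
#'     \item{genes}{[gene_table()] of simulated genes}
#'     \item{samples}{sample sheet: `sample_id`, `isolate_id`,
#'       `protocol` (GB/noGB), `run`, `machine`, `lane`}
#'     \item{truth}{ground-truth pairing: `gb_sample`, `nogb_sample`,
#'       `isolate_id`}
#'   }
#' @examples
#' cfg <- simulation_config(n_individuals = 4, n_genes = 200,
#'                          libsize_noGB_mean = 2e4, libsize_noGB_sd = 0,
#'                          libsize_GB_mean = 2e4, libsize_GB_sd = 0,
#'                          seed = 7)
#' cohort <- simulate_paired_cohort(cfg)
#' colSums(cohort$counts)
#' @export
simulate_paired_cohort <- function(config,
                                   scenario = c("dataset1", "dataset2",
                                                "cross_machine")) {
  stopifnot(inherits(config, "simulation_config"))
  scenario <- match.arg(scenario)
  n <- config$n_individuals
  n_genes <- config$n_genes

  gene_ids <- simulated_gene_ids(n_genes, config$n_globin_genes)
  globin_mask <- seq_len(n_genes) <= config$n_globin_genes

  isolate_id <- sprintf("iso%03d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0(isolate_id, "_noGB"), paste0(isolate_id, "_GB")),
    isolate_id = rep(isolate_id, 2L),
    protocol = rep(c("noGB", "GB"), each = n),
    stringsAsFactors = FALSE
  )
  b <- scenario_batches(scenario, samples$protocol, rep(seq_len(n), 2L))
  samples$run <- b$run
  samples$machine <- b$machine
  samples$lane <- b$lane

  # batch perturbation vectors keyed to batch identity, outside the
  # cohort stream so batch membership, not sample order, fixes them
  run_logz <- lapply(unique(samples$run), function(r) {
    if (config$run_batch_sd == 0) return(numeric(n_genes))
    withr::with_seed(batch_seed(config$seed, paste0("run:", r)),
                     rnorm(n_genes, 0, config$run_batch_sd))
  })
  names(run_logz) <- unique(samples$run)
  machine_logz <- lapply(unique(samples$machine), function(m) {
    if (config$machine_batch_sd == 0) return(numeric(n_genes))
    withr::with_seed(batch_seed(config$seed, paste0("machine:", m)),
                     rnorm(n_genes, 0, config$machine_batch_sd))
  })
  names(machine_logz) <- unique(samples$machine)

  counts <- matrix(0L, nrow = n_genes, ncol = 2L * n,
                   dimnames = list(gene_ids, samples$sample_id))

  withr::with_seed(config$seed, {
    gene_log_mu <- config$baseline_log_mean +
      config$baseline_log_sd * rnorm(n_genes)
    gene_length <- round(exp(stats::runif(n_genes, log(200), log(10000))))

    for (i in seq_len(n)) {
      delta <- if (config$bio_effect_sd > 0) {
        rnorm(n_genes, 0, config$bio_effect_sd)
      } else numeric(n_genes)
      latent <- exp(gene_log_mu + delta)
      base_p <- latent / sum(latent)

      f <- truncated_normal_pair(
        config$globin_fraction_noGB_mean, config$globin_fraction_noGB_sd,
        config$globin_fraction_GB_mean, config$globin_fraction_GB_sd,
        config$globin_fraction_correlation
      )
      prof <- list(
        noGB = apply_globin_block(base_p, globin_mask, f[1L]),
        GB   = apply_globin_block(base_p, globin_mask, f[2L])
      )
      size <- c(
        noGB = max(1, round(rnorm(1, config$libsize_noGB_mean,
                                  config$libsize_noGB_sd))),
        GB   = max(1, round(rnorm(1, config$libsize_GB_mean,
                                  config$libsize_GB_sd)))
      )
      for (proto in c("noGB", "GB")) {
        sid <- paste0(isolate_id[i], "_", proto)
        row <- samples[samples$sample_id == sid, ]
        p <- prof[[proto]] *
          exp(run_logz[[row$run]] + machine_logz[[row$machine]])
        p <- p / sum(p)
        counts[, sid] <- as.integer(rmultinom(1L, size[[proto]], p))
      }
    }
  })

  genes <- gene_table(gene_ids, length = gene_length,
                      is_globin = globin_mask)
  truth <- data.frame(
    gb_sample = paste0(isolate_id, "_GB"),
    nogb_sample = paste0(isolate_id, "_noGB"),
    isolate_id = isolate_id,
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = counts, genes = genes, samples = samples, truth = truth,
         config = config, scenario = scenario),
    class = "gb_cohort"
  )
}

#' @export
print.gb_cohort <- function(x, ...) {
  cat("gb_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "samples",
      sprintf("(%d isolates, scenario %s, seed %d)\n",
              x$config$n_individuals, x$scenario, x$config$seed))
  invisible(x)
}
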