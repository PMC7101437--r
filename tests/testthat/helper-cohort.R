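# shared fixtures: small simulated cohorts built in code

desk_config <- function(n_individuals = 10, n_genes = 500,
                        libsize = 2e4, bio_effect_sd = 0.5,
                        run_batch_sd = 0, machine_batch_sd = 0,
                        seed = 1, ...) {
  suppressMessages(simulation_config(
    n_individuals = n_individuals, n_genes = n_genes,
    bio_effect_sd = bio_effect_sd,
    libsize_noGB_mean = libsize, libsize_noGB_sd = libsize / 10,
    libsize_GB_mean = libsize, libsize_GB_sd = libsize / 10,
    run_batch_sd = run_batch_sd, machine_batch_sd = machine_batch_sd,
    seed = seed, ...
  ))
}

split_panels <- function(cohort) {
  gb <- cohort$samples$sample_id[cohort$samples$protocol == "GB"]
  nogb <- cohort$samples$sample_id[cohort$samples$protocol == "noGB"]
  list(gb = cohort$counts[, gb, drop = FALSE],
       nogb = cohort$counts[, nogb, drop = FALSE])
}

# independent oracle for the scaled correlation score: plain double loop
scale_matrix_bruteforce <- function(raw) {
  n <- nrow(raw); m <- ncol(raw)
  col_mean <- numeric(m)
  for (j in seq_len(m)) col_mean[j] <- sum(raw[, j]) / n
  a <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) a[i, j] <- raw[i, j] / col_mean[j]
  out <- matrix(0, n, m, dimnames = dimnames(raw))
  for (i in seq_len(n)) {
    rmax <- max(a[i, ])
    for (j in seq_len(m)) out[i, j] <- a[i, j] / rmax
  }
  out
}

# independent oracle for the upper-tail hypergeometric probability:
# enumerate every subset draw outcome explicitly (feasible for N <= 12)
hypergeom_upper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "successes"
  mean(hits >= k)
}
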