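# Shared fixtures and independent oracles. Oracles are deliberately
# written as the most naive possible computations so they stay
# independent of the implementation under test.

# one random cell: component count and lengths drawn uniformly
random_cell <- function(id, max_components = 40, len_range = c(0.2, 8),
                        population = "pop") {
  n <- sample.int(max_components, 1L)
  mito_cell(id, runif(n, len_range[1], len_range[2]),
            population = population)
}

random_cells <- function(n, prefix = "rc", ...) {
  lapply(seq_len(n), function(i) random_cell(sprintf("%s%05d", prefix, i), ...))
}

# brute-force metric oracles
oracle_fission <- function(lengths) length(lengths) / sum(lengths)

oracle_fusion_k <- function(lengths, k) {
  s <- sort(lengths, decreasing = TRUE)
  100 * sum(s[seq_len(min(k, length(s)))]) / sum(s)
}

# Pearson chi-square by direct sum over the contingency table
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# sort-based median and unscaled MAD, avoiding stats::median/mad
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad_threshold <- function(x) {
  m <- oracle_median(x)
  m + 1.5 * oracle_median(abs(x - m))
}

# simulator archetypes used across tests: a fusion-dominant archetype
# whose cells are reliably hyperfused, and a fragmentation archetype
# landing in the intermediate gate (100 um cell, 0.5 um resolution floor)
arch_hf <- function(n_events = 1000) {
  sim_params(total_length = 100, k_fis = 0.05, k_fus = 1, min_len = 0.5,
             n_events = n_events)
}

arch_int <- function(n_events = 1000) {
  sim_params(total_length = 100, k_fis = 3, k_fus = 1, min_len = 0.5,
             n_events = n_events)
}

# synthesize a metric table realizing prescribed HF/Int/Other gate counts
metrics_from_gate_counts <- function(counts) {
  stopifnot(identical(rownames(counts), c("HF", "Int", "Other")))
  anchor <- list(HF = c(0.05, 95), Int = c(0.3, 60), Other = c(0.05, 20))
  rows <- list()
  for (p in colnames(counts)) {
    for (g in rownames(counts)) {
      k <- counts[g, p]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, fission = rep(anchor[[g]][1], k),
          fusion5 = rep(anchor[[g]][2], k), fusion1 = 50)
      }
    }
  }
  do.call(rbind, rows)
}
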