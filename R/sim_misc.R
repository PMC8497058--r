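#' Simulate limiting-dilution well outcomes
#'
#' Under the single-hit Poisson model a well seeded with `d` cells stays
#' negative with probability `exp(-f * d)`, where `f` is the frequency of
#' assay-active (sphere-initiating) cells. Positive-well counts per dose
#' are binomial draws under that probability. The default design seeds
#' 1, 10, 100 and 1000 cells per well with 24 wells per dose.
#'
#' @param frequency Active-cell frequency per plated cell, in `(0, 1]`.
#' @param doses Integer vector of cells seeded per well.
#' @param wells_per_dose Wells per dose (recycled across doses).
#' @param group Optional group label column.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `group` (if given), `dose`,
#'   `wells`, `positive`.
#' @examples
#' simulate_lda_wells(1 / 150, seed = 1)
#' @export
simulate_lda_wells <- function(frequency, doses = c(1, 10, 100, 1000),
                               wells_per_dose = 24, group = NULL,
                               seed = 1L) {
  if (length(frequency) != 1L || !is.finite(frequency) ||
      frequency <= 0 || frequency > 1) {
    stop("`frequency` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(doses) >= 1L, all(doses >= 1), all(doses == floor(doses)))
  wells <- as.integer(rep_len(wells_per_dose, length(doses)))
  out <- with_seed(seed, data.frame(
    dose = as.integer(doses),
    wells = wells,
    positive = rbinom(length(doses), wells, 1 - exp(-frequency * doses))
  ))
  if (!is.null(group)) out <- cbind(group = group, out)
  out
}

#' Simulate per-cell cluster and cell-cycle phase assignments
#'
#' Draws multinomial phase counts for each (population, cluster) group
#' from planted phase probabilities and expands them to a per-cell table,
#' emulating the phase-labelled output of an upstream cell-cycle scoring
#' step.
#'
#' @param design A `data.frame` with one row per (population, cluster)
#'   group and columns `population`, `cluster`, `n` (cells in the group)
#'   and `p_g1`, `p_s`, `p_g2m` (phase probabilities; rescaled to sum
#'   to 1 within each row).
#' @param seed Integer seed.
#' @param phases Phase labels to emit, in the order (G1, S, G2M).
#' @return A `data.frame` with columns `cell_id`, `population`,
#'   `cluster`, `phase`.
#' @examples
#' d <- data.frame(population = "TF1", cluster = c(3, 5), n = 100,
#'                 p_g1 = c(0.6, 0.2), p_s = c(0.2, 0.4),
#'                 p_g2m = c(0.2, 0.4))
#' head(simulate_phases(d, seed = 1))
#' @export
simulate_phases <- function(design, seed = 1L,
                            phases = c("G0/G1", "S", "G2M")) {
  stopifnot(is.data.frame(design),
            all(c("population", "cluster", "n", "p_g1", "p_s", "p_g2m")
                %in% names(design)),
            length(phases) == 3L)
  if (any(design$n < 1)) stop("`n` must be >= 1 per group", call. = FALSE)
  pm <- as.matrix(design[, c("p_g1", "p_s", "p_g2m")])
  if (any(pm < 0) || any(rowSums(pm) <= 0)) {
    stop("phase probabilities must be nonnegative with positive sums",
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      counts <- as.vector(rmultinom(1, design$n[i], pm[i, ]))
      data.frame(
        population = design$population[i],
        cluster = design$cluster[i],
        phase = rep(phases, counts)
      )
    })
    out <- do.call(rbind, rows)
    out <- cbind(cell_id = sprintf("ph%06d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
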