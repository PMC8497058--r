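#' Specification of a two-channel intensity mixture
#'
#' Models per-cell two-channel immunofluorescence as a mixture of "lo"
#' and "hi" expression states per channel, log-normal within each state
#' (fluorescence intensities are positive and right-skewed). The two
#' channels' hi-states may be correlated: a correlation of 1 makes every
#' hi cell hi in both channels, emulating a single latent marker-high
#' state driving both stains; 0 makes the channels independent.
#'
#' @param lo_meanlog,hi_meanlog Length-2 numeric: log-mean intensity of
#'   the lo and hi state in channels 1 and 2 (a.u.).
#' @param lo_sdlog,hi_sdlog Length-2 numeric, log-sd per channel (>= 0;
#'   0 gives the degenerate point-mass limit).
#' @param hi_fraction Length-2 numeric in `[0, 1]`: marginal fraction of
#'   hi cells per channel.
#' @param correlation Correlation of the binary hi-states between
#'   channels, in `[-1, 1]`; must be feasible for the given marginals.
#' @return An object of class `intensity_spec`.
#' @examples
#' intensity_spec(hi_fraction = c(0.26, 0.26), correlation = 1)
#' @export
intensity_spec <- function(lo_meanlog = log(c(100, 100)),
                           lo_sdlog = c(0.2, 0.2),
                           hi_meanlog = log(c(600, 600)),
                           hi_sdlog = c(0.2, 0.2),
                           hi_fraction = c(0.26, 0.26),
                           correlation = 1) {
  fix2 <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  lo_meanlog <- fix2(lo_meanlog); hi_meanlog <- fix2(hi_meanlog)
  lo_sdlog <- fix2(lo_sdlog); hi_sdlog <- fix2(hi_sdlog)
  hi_fraction <- fix2(hi_fraction)
  stopifnot(length(lo_meanlog) == 2L, length(hi_meanlog) == 2L,
            length(lo_sdlog) == 2L, length(hi_sdlog) == 2L,
            length(hi_fraction) == 2L, length(correlation) == 1L)
  if (any(c(lo_sdlog, hi_sdlog) < 0)) stop("log-sd must be >= 0", call. = FALSE)
  if (any(hi_fraction < 0 | hi_fraction > 1)) {
    stop("`hi_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(correlation) > 1) stop("|correlation| must be <= 1", call. = FALSE)
  joint <- joint_hi_probs(hi_fraction[1], hi_fraction[2], correlation)
  structure(
    list(lo_meanlog = lo_meanlog, lo_sdlog = lo_sdlog,
         hi_meanlog = hi_meanlog, hi_sdlog = hi_sdlog,
         hi_fraction = hi_fraction, correlation = correlation,
         joint = joint),
    class = "intensity_spec"
  )
}

# joint distribution of the (hi1, hi2) binary pair with given marginals
# and correlation; order: (1,1), (1,0), (0,1), (0,0)
joint_hi_probs <- function(p1, p2, rho) {
  p11 <- p1 * p2 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop("infeasible hi-state correlation for these marginals", call. = FALSE)
  }
  p11 <- min(max(p11, lo), hi)
  c(hh = p11, hl = p1 - p11, lh = p2 - p11, ll = 1 - p1 - p2 + p11)
}

#' Simulate a two-channel intensity table
#'
#' Draws `n_cells` cells: the joint (hi, lo) state pair first, then
#' log-normal intensities per channel conditional on state. As with
#' [simulate_population()], `"stratified"` assignment plants the joint
#' state fractions as exact counts (shuffled order), so the planted
#' double-hi fraction is realized exactly in each sample;
#' `"multinomial"` samples states i.i.d.
#'
#' @param spec An [intensity_spec()].
#' @param n_cells Number of cells.
#' @param population Population label for the output table.
#' @param seed Integer seed.
#' @param method `"stratified"` (default) or `"multinomial"`.
#' @return A `data.frame` with columns `cell_id`, `population`, `ch1`,
#'   `ch2` (a.u.) and the planted ground truth `truth_ch1`, `truth_ch2`
#'   (1 = hi state, 0 = lo).
#' @examples
#' head(simulate_intensities(intensity_spec(), 5, "TF1", seed = 1))
#' @export
simulate_intensities <- function(spec, n_cells, population = "sample",
                                 seed = 1L,
                                 method = c("stratified", "multinomial")) {
  stopifnot(inherits(spec, "intensity_spec"), n_cells >= 1)
  method <- match.arg(method)
  with_seed(seed, {
    state <- if (method == "multinomial") {
      sample.int(4L, n_cells, replace = TRUE, prob = spec$joint)
    } else {
      sample(rep.int(1:4, largest_remainder(spec$joint, n_cells)))
    }
    hi1 <- state %in% c(1L, 2L)
    hi2 <- state %in% c(1L, 3L)
    draw <- function(hi, ch) {
      rlnorm(length(hi),
             meanlog = ifelse(hi, spec$hi_meanlog[ch], spec$lo_meanlog[ch]),
             sdlog = ifelse(hi, spec$hi_sdlog[ch], spec$lo_sdlog[ch]))
    }
    data.frame(
      cell_id = sprintf("%s_i%05d", population, seq_len(n_cells)),
      population = population,
      ch1 = draw(hi1, 1L),
      ch2 = draw(hi2, 2L),
      truth_ch1 = as.integer(hi1),
      truth_ch2 = as.integer(hi2)
    )
  })
}
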