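#' Robust MAD-based signal threshold
#'
#' The signal threshold for an intensity channel is
#' `median + 1.5 * MAD`, where MAD is the median of absolute deviations
#' from the median, left *unscaled* (no normal-consistency factor). This
#' is the robust cut used to draw quadrant lines on immunofluorescence
#' dot plots: it tracks the bulk (lo) population and is insensitive to a
#' minority of strongly stained cells.
#'
#' The threshold is affine-equivariant: for `a > 0`,
#' `mad_threshold(a * x + b) == a * mad_threshold(x) + b`. Because the
#' threshold is at least the median, no more than half of the sample it
#' was computed from can exceed it.
#'
#' @param values Numeric vector of intensities (at least one finite
#'   value; all values must be finite).
#' @return Numeric scalar threshold, same units as `values`.
#' @examples
#' mad_threshold(c(1, 2, 3, 4, 100))  # median 3, MAD 1 -> 4.5
#' @export
mad_threshold <- function(values) {
  if (length(values) < 1L) stop("empty intensity vector", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("intensities must be finite", call. = FALSE)
  }
  median(values) + 1.5 * mad(values, constant = 1)
}

#' Two-channel quadrant gating with a common robust threshold
#'
#' Splits each population's cells into the four quadrants of a
#' two-channel dot plot - hi-hi, hi-lo, lo-hi, lo-lo - using one
#' [mad_threshold()] per channel. "hi" means strictly greater than the
#' threshold, so at a degenerate (MAD = 0) cut ties stay "lo". With
#' `mode = "reference"` (default) both thresholds are computed on the
#' reference (control) population and applied uniformly, which is what
#' makes quadrant percentages comparable across populations; with
#' `mode = "per_population"` each population is cut at its own
#' thresholds. When at least two populations are present, quadrant
#' composition is compared with a Pearson chi-square test (no continuity
#' correction) on the quadrants x populations table, dropping quadrant
#' rows that are empty everywhere.
#'
#' @param intensities A `data.frame` with columns `population`, `ch1`,
#'   `ch2` (e.g. from [simulate_intensities()]).
#' @param reference Label of the reference population used for
#'   thresholds in `"reference"` mode; must be present.
#' @param mode `"reference"` (default) or `"per_population"`.
#' @return An object of class `quadrant_table`: list with `thresholds`
#'   (per population in `"per_population"` mode, otherwise one row),
#'   `counts`, `percent` (quadrants x populations, summing to 100 per
#'   population), and `chisq` (`htest`, or `NULL` with one population).
#' @examples
#' tf <- simulate_intensities(intensity_spec(hi_fraction = 0.26), 200,
#'                            "TF1", seed = 1)
#' par <- simulate_intensities(intensity_spec(hi_fraction = 0.06), 200,
#'                             "Parental", seed = 2)
#' quadrant_table(rbind(tf, par), reference = "Parental")
#' @export
quadrant_table <- function(intensities, reference = NULL,
                           mode = c("reference", "per_population")) {
  stopifnot(is.data.frame(intensities),
            all(c("population", "ch1", "ch2") %in% names(intensities)))
  mode <- match.arg(mode)
  pops <- unique(intensities$population)
  if (mode == "reference") {
    if (is.null(reference) && length(pops) == 1L) reference <- pops
    if (is.null(reference) || !reference %in% pops) {
      stop("reference population ",
           if (is.null(reference)) "(none given)" else shQuote(reference),
           " not present in the data", call. = FALSE)
    }
    ref <- intensities[intensities$population == reference, , drop = FALSE]
    thr <- data.frame(population = "(reference)",
                      thr_ch1 = mad_threshold(ref$ch1),
                      thr_ch2 = mad_threshold(ref$ch2))
    cut1 <- rep(thr$thr_ch1, nrow(intensities))
    cut2 <- rep(thr$thr_ch2, nrow(intensities))
  } else {
    thr <- do.call(rbind, lapply(pops, function(p) {
      sub <- intensities[intensities$population == p, , drop = FALSE]
      data.frame(population = p,
                 thr_ch1 = mad_threshold(sub$ch1),
                 thr_ch2 = mad_threshold(sub$ch2))
    }))
    i <- match(intensities$population, thr$population)
    cut1 <- thr$thr_ch1[i]
    cut2 <- thr$thr_ch2[i]
  }
  hi1 <- intensities$ch1 > cut1
  hi2 <- intensities$ch2 > cut2
  quad <- factor(ifelse(hi1, ifelse(hi2, "hi-hi", "hi-lo"),
                        ifelse(hi2, "lo-hi", "lo-lo")),
                 levels = c("hi-hi", "hi-lo", "lo-hi", "lo-lo"))
  counts <- unclass(table(
    quadrant = quad,
    population = factor(intensities$population, levels = pops)))
  percent <- sweep(counts, 2L, colSums(counts), "/") * 100
  chisq <- NULL
  if (length(pops) >= 2L) {
    test_tab <- counts[rowSums(counts) > 0, , drop = FALSE]
    chisq <- chisq.test(test_tab, correct = FALSE)
  }
  structure(
    list(thresholds = thr, counts = counts, percent = percent,
         chisq = chisq, mode = mode, reference = reference),
    class = "quadrant_table"
  )
}

#' @export
print.quadrant_table <- function(x, digits = 1, ...) {
  cat("Quadrant composition (% of cells), thresholds: median + 1.5 MAD")
  cat(if (x$mode == "reference")
        sprintf(" on reference %s\n", shQuote(x$reference))
      else " per population\n")
  print(round(x$percent, digits))
  if (!is.null(x$chisq)) {
    cat(sprintf("\nChi-square = %.4g, df = %d, p = %.3g\n",
                unname(x$chisq$statistic), unname(x$chisq$parameter),
                x$chisq$p.value))
  }
  invisible(x)
}
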