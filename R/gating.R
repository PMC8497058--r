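#' Gate bounds for bivariate fission/fusion subpopulations
#'
#' Encodes the standard gates of the bivariate fission x fusion5 dot
#' plot: the hyperfused gate (HF, `fusion5 > 80`: nearly all
#' mitochondrial mass in at most five networks) and the intermediate
#' gate (Int, `fission` in 0.15-0.4 per um and `fusion5` in 40-80:
#' smaller fused networks coexisting with fragments). The HF bound is
#' strict and the Int ranges are closed intervals, so a cell at
#' `fusion5 = 80` exactly is Int, never HF, and the gates cannot
#' overlap. Cells in neither box are reported as a single Other class.
#' `fusion1_hi_min` is the (strict) bound for the fusion1-high fraction,
#' the share of cells whose longest element carries more than 80% of
#' total mitochondrial length.
#'
#' @param hf_fusion5_min Exclusive lower fusion5 bound of the HF gate
#'   (percent).
#' @param int_fission_range Closed fission interval of the Int gate
#'   (1/um).
#' @param int_fusion5_range Closed fusion5 interval of the Int gate
#'   (percent); its upper end must not exceed `hf_fusion5_min`.
#' @param fusion1_hi_min Exclusive fusion1 bound for
#'   [fusion1_hi_fraction()] (percent).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(hf_fusion5_min = 80,
                        int_fission_range = c(0.15, 0.4),
                        int_fusion5_range = c(40, 80),
                        fusion1_hi_min = 80) {
  stopifnot(length(hf_fusion5_min) == 1L, length(int_fission_range) == 2L,
            length(int_fusion5_range) == 2L, length(fusion1_hi_min) == 1L)
  if (hf_fusion5_min < 0 || hf_fusion5_min > 100 ||
      any(int_fusion5_range < 0 | int_fusion5_range > 100) ||
      fusion1_hi_min < 0 || fusion1_hi_min > 100) {
    stop("percent bounds must lie in [0, 100]", call. = FALSE)
  }
  if (diff(int_fission_range) < 0 || diff(int_fusion5_range) < 0) {
    stop("gate ranges must be ordered [min, max]", call. = FALSE)
  }
  if (int_fusion5_range[2] > hf_fusion5_min) {
    stop("Int fusion5 range must not extend past the HF bound",
         call. = FALSE)
  }
  structure(
    list(hf_fusion5_min = hf_fusion5_min,
         int_fission_range = int_fission_range,
         int_fusion5_range = int_fusion5_range,
         fusion1_hi_min = fusion1_hi_min),
    class = "gate_config"
  )
}

#' Classify cells into HF / Int / Other fission-fusion gates
#'
#' @param metrics A metric table from [metrics_table()] (needs columns
#'   `fission` and `fusion5`).
#' @param config A [gate_config()].
#' @return A factor with levels `HF`, `Int`, `Other`, one per row of
#'   `metrics`.
#' @examples
#' m <- data.frame(fission = c(0.10, 0.30, 0.05), fusion5 = c(90, 60, 30))
#' classify_cells(m)
#' @export
classify_cells <- function(metrics, config = gate_config()) {
  stopifnot(is.data.frame(metrics), inherits(config, "gate_config"),
            all(c("fission", "fusion5") %in% names(metrics)))
  hf <- metrics$fusion5 > config$hf_fusion5_min
  int <- !hf &
    metrics$fission >= config$int_fission_range[1] &
    metrics$fission <= config$int_fission_range[2] &
    metrics$fusion5 >= config$int_fusion5_range[1] &
    metrics$fusion5 <= config$int_fusion5_range[2]
  factor(ifelse(hf, "HF", ifelse(int, "Int", "Other")),
         levels = c("HF", "Int", "Other"))
}

#' Gate abundances across populations with chi-square comparison
#'
#' Tabulates HF / Int / Other gate membership per population, tests
#' whether gate composition differs across populations with a Pearson
#' chi-square test (no continuity correction) on the gates x populations
#' contingency table, and attaches two per-population summaries of the
#' fission-fusion relationship: the fusion1-high cell fraction and the
#' inverse-correlation scatter of [correlation_scatter()]. Gate rows
#' empty in every population are dropped before the chi-square test.
#' A warning is issued when any expected count falls below 5.
#'
#' @param metrics Metric table covering at least two populations.
#' @param config A [gate_config()].
#' @return An object of class `gate_table`: list with elements `counts`
#'   (gates x populations matrix), `fractions`, `chisq` (the `htest`),
#'   `fusion1_hi` (named vector), `scatter` (data.frame of per-population
#'   `r` and `residual_sd`, `NA` where fewer than 3 cells or degenerate
#'   variance), and `config`.
#' @export
gate_table <- function(metrics, config = gate_config()) {
  stopifnot(is.data.frame(metrics), "population" %in% names(metrics))
  pops <- unique(metrics$population)
  if (length(pops) < 2L) {
    stop("gate_table() needs at least two populations to compare",
         call. = FALSE)
  }
  gate <- classify_cells(metrics, config)
  counts <- table(gate = gate,
                  population = factor(metrics$population, levels = pops))
  counts <- unclass(counts)
  fractions <- sweep(counts, 2L, colSums(counts), "/")
  test_tab <- counts[rowSums(counts) > 0, , drop = FALSE]
  chisq <- chisq.test(test_tab, correct = FALSE)
  f1 <- vapply(pops, function(p) {
    fusion1_hi_fraction(metrics[metrics$population == p, , drop = FALSE],
                        config)
  }, numeric(1))
  scatter <- do.call(rbind, lapply(pops, function(p) {
    sub <- metrics[metrics$population == p, , drop = FALSE]
    cs <- tryCatch(correlation_scatter(sub), error = function(e) {
      warning("scatter not computed for population ", p, ": ",
              conditionMessage(e), call. = FALSE)
      list(r = NA_real_, residual_sd = NA_real_)
    })
    data.frame(population = p, r = cs$r, residual_sd = cs$residual_sd)
  }))
  structure(
    list(counts = counts, fractions = fractions, chisq = chisq,
         fusion1_hi = setNames(f1, pops), scatter = scatter,
         config = config),
    class = "gate_table"
  )
}

#' @export
print.gate_table <- function(x, digits = 3, ...) {
  cat("Fission/fusion gate composition (fraction of cells)\n")
  print(round(x$fractions, digits))
  cat(sprintf("\nChi-square = %.4g, df = %d, p = %.3g\n",
              unname(x$chisq$statistic), unname(x$chisq$parameter),
              x$chisq$p.value))
  cat("\nfusion1 > ", x$config$fusion1_hi_min, " fraction:\n", sep = "")
  print(round(x$fusion1_hi, digits))
  cat("\nFission-fusion5 regression scatter:\n")
  print(x$scatter, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Inverse-correlation scatter of the fission/fusion5 relationship
#'
#' Quantifies how tightly a population follows the inverse
#' fission-fusion5 relationship: the Pearson correlation `r` between the
#' two metrics, and the residual standard deviation about the ordinary
#' least-squares line of `fusion5` on `fission` (`sqrt(RSS / (n - 2))`,
#' the regression standard error). Populations whose cells scatter off
#' the line - heterogeneous mixtures of shape states - show larger
#' residual SD and weaker `|r|`.
#'
#' @param metrics Metric table for a single population (>= 3 cells,
#'   nonzero variance in both metrics).
#' @return List with elements `r` and `residual_sd` (percent units, the
#'   scale of fusion5).
#' @examples
#' m <- data.frame(fission = c(0, 1, 2), fusion5 = c(0, 1, 0))
#' correlation_scatter(m)
#' @export
correlation_scatter <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("fission", "fusion5") %in% names(metrics)))
  x <- metrics$fission
  y <- metrics$fusion5
  if (length(x) < 3L) {
    stop("need at least 3 cells for a regression scatter", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate (zero-variance) metric; scatter undefined",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  list(r = cor(x, y),
       residual_sd = sqrt(sum(residuals(fit)^2) / (length(x) - 2L)))
}

#' Fraction of fusion1-high cells
#'
#' Share of cells whose longest mitochondrial element holds more than
#' `fusion1_hi_min` percent of the total mitochondrial length.
#'
#' @param metrics Metric table (needs column `fusion1`).
#' @param config A [gate_config()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
fusion1_hi_fraction <- function(metrics, config = gate_config()) {
  stopifnot(is.data.frame(metrics), "fusion1" %in% names(metrics),
            inherits(config, "gate_config"))
  mean(metrics$fusion1 > config$fusion1_hi_min)
}
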