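#' Cell-cycle phase composition per population and cluster
#'
#' Tabulates phase percentages within each (population, cluster) group.
#' Accepts either a per-cell table (columns `population`, `cluster`,
#' `phase`, one row per cell) or a pre-counted table with an `n` column.
#' Groups with zero total cells are excluded with a warning.
#'
#' @param x A `data.frame`, per-cell or counted (see above).
#' @return A `data.frame` with columns `population`, `cluster`, `phase`,
#'   `n`, `pct`; `pct` sums to 100 within each (population, cluster).
#' @examples
#' d <- data.frame(population = "P", cluster = 3,
#'                 phase = rep(c("G0/G1", "S", "G2M"), c(10, 10, 10)))
#' phase_fractions(d)
#' @export
phase_fractions <- function(x) {
  counts <- phase_counts(x)
  totals <- aggregate(n ~ population + cluster, counts, sum)
  empty <- totals[totals$n == 0, , drop = FALSE]
  if (nrow(empty)) {
    warning("excluding empty group(s): ",
            paste(empty$population, empty$cluster, sep = "/",
                  collapse = ", "), call. = FALSE)
    keep <- !paste(counts$population, counts$cluster) %in%
      paste(empty$population, empty$cluster)
    counts <- counts[keep, , drop = FALSE]
    totals <- totals[totals$n > 0, , drop = FALSE]
  }
  i <- match(paste(counts$population, counts$cluster),
             paste(totals$population, totals$cluster))
  counts$pct <- 100 * counts$n / totals$n[i]
  rownames(counts) <- NULL
  counts
}

# normalize per-cell or counted input to a (population, cluster, phase, n)
# table covering every phase level in every group
phase_counts <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("population", "cluster", "phase") %in% names(x)))
  if ("n" %in% names(x)) {
    if (any(x$n < 0) || any(x$n != floor(x$n))) {
      stop("phase counts must be nonnegative integers", call. = FALSE)
    }
    tab <- x[, c("population", "cluster", "phase", "n")]
    tab <- aggregate(n ~ population + cluster + phase, tab, sum)
  } else {
    tab <- aggregate(list(n = rep(1L, nrow(x))),
                     x[, c("population", "cluster", "phase")], sum)
  }
  # complete missing (group, phase) combinations with zero counts
  grid <- expand.grid(
    phase = unique(tab$phase),
    key = unique(paste(tab$population, tab$cluster, sep = "\r")),
    stringsAsFactors = FALSE)
  key <- do.call(rbind, strsplit(grid$key, "\r", fixed = TRUE))
  full <- data.frame(population = key[, 1], cluster = key[, 2],
                     phase = grid$phase)
  i <- match(paste(full$population, full$cluster, full$phase),
             paste(tab$population, tab$cluster, tab$phase))
  full$n <- ifelse(is.na(i), 0L, tab$n[i])
  full[order(full$population, full$cluster, full$phase), , drop = FALSE]
}

#' G1-to-S reciprocity between two cell clusters
#'
#' For each population, computes the G1%/S% ratio within cluster
#' `cluster_a` and within cluster `cluster_b`, and their quotient - the
#' reciprocity. A reciprocity of 1 means the two clusters have the same
#' G1-vs-S residency balance; large values mean cluster A is shifted
#' toward G1 exactly where cluster B is shifted toward S. The statistic
#' is invariant to each population's total cell count and inverts
#' exactly when the two clusters are swapped. When a `reference`
#' population is given, each population's fold-change in reciprocity
#' relative to the reference is reported alongside.
#'
#' A group with zero S-phase cells makes the ratio undefined; this is an
#' error naming the offending group unless `pseudocount = TRUE`, which
#' adds 0.5 to every phase count in every group before forming
#' percentages (an explicitly flagged regularization, never silent).
#'
#' @param x Per-cell or counted phase table (see [phase_fractions()]).
#' @param cluster_a,cluster_b Cluster labels to contrast.
#' @param reference Optional reference population label.
#' @param pseudocount Add 0.5 to every phase count first (default
#'   `FALSE`).
#' @param g1_label,s_label Phase labels counted as G1 and S.
#' @return An object of class `reciprocity_result`: a `data.frame` with
#'   columns `population`, `ratio_a`, `ratio_b`, `reciprocity` and, when
#'   `reference` is given, `fold_vs_ref`.
#' @examples
#' d <- data.frame(population = "TF1", cluster = rep(c(3, 5), each = 3),
#'                 phase = rep(c("G0/G1", "S", "G2M"), 2),
#'                 n = c(60, 20, 20, 20, 40, 40))
#' reciprocity(d, cluster_a = 3, cluster_b = 5)  # (60/20)/(20/40) = 6
#' @export
reciprocity <- function(x, cluster_a, cluster_b, reference = NULL,
                        pseudocount = FALSE,
                        g1_label = "G0/G1", s_label = "S") {
  counts <- phase_counts(x)
  if (pseudocount) counts$n <- counts$n + 0.5
  pops <- unique(counts$population)
  if (!is.null(reference) && !reference %in% pops) {
    stop("reference population ", shQuote(reference), " not in the data",
         call. = FALSE)
  }
  ratio_in <- function(pop, cl) {
    sub <- counts[counts$population == pop & counts$cluster == cl, ,
                  drop = FALSE]
    if (!nrow(sub) || sum(sub$n) == 0) {
      stop("cluster ", cl, " absent (or empty) in population ", pop,
           call. = FALSE)
    }
    g1 <- sum(sub$n[sub$phase == g1_label])
    s <- sum(sub$n[sub$phase == s_label])
    if (s == 0) {
      stop("S-phase count is zero in population ", pop, ", cluster ", cl,
           "; reciprocity undefined (see `pseudocount`)", call. = FALSE)
    }
    # shared denominator cancels in g1% / s%
    g1 / s
  }
  out <- do.call(rbind, lapply(pops, function(p) {
    ra <- ratio_in(p, cluster_a)
    rb <- ratio_in(p, cluster_b)
    data.frame(population = p, ratio_a = ra, ratio_b = rb,
               reciprocity = ra / rb)
  }))
  if (!is.null(reference)) {
    out$fold_vs_ref <-
      out$reciprocity / out$reciprocity[out$population == reference]
  }
  rownames(out) <- NULL
  structure(out, class = c("reciprocity_result", "data.frame"),
            cluster_a = cluster_a, cluster_b = cluster_b,
            reference = reference)
}

#' @export
print.reciprocity_result <- function(x, digits = 3, ...) {
  cat(sprintf("G1-to-S reciprocity: cluster %s vs cluster %s\n",
              attr(x, "cluster_a"), attr(x, "cluster_b")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
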