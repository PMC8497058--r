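#' Parameters of the stochastic fission-fusion simulator
#'
#' The simulator represents one cell's mitochondria as a partition of a
#' conserved total length into linear components and evolves it by a
#' fragmentation-coagulation jump process: each component of length `L`
#' undergoes fission at rate `k_fis * L` with a breakpoint drawn uniformly
#' along the component, and each unordered pair of components fuses at
#' rate `k_fus` (mass action). A fission whose daughter would fall below
#' `min_len` is rejected, mimicking the optical resolution floor of
#' confocal skeletonization without breaking mass conservation. The chain
#' is run for `n_events` accepted events from a single fused component,
#' which is ample burn-in to reach the stationary regime for the defaults.
#'
#' The rates set only the stationary shape statistics through their ratio;
#' they are simulation knobs, not measured biological rate constants.
#'
#' @param total_length Conserved total mitochondrial length, um (> 0).
#' @param k_fis Fission rate per um per unit time (>= 0).
#' @param k_fus Fusion rate per unordered component pair per unit time
#'   (>= 0). `k_fis` and `k_fus` must not both be zero.
#' @param min_len Minimum resolvable fragment length, um
#'   (0 < `min_len` < `total_length`).
#' @param n_events Number of accepted events to simulate (burn-in).
#' @param seed Optional integer seed for a reproducible cell.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(total_length = 100, k_fis = 3, k_fus = 1)
#' @export
sim_params <- function(total_length = 100, k_fis = 1, k_fus = 1,
                       min_len = 0.5, n_events = 5000, seed = NULL) {
  stopifnot(is.numeric(total_length), length(total_length) == 1L,
            is.numeric(k_fis), length(k_fis) == 1L,
            is.numeric(k_fus), length(k_fus) == 1L,
            is.numeric(min_len), length(min_len) == 1L,
            is.numeric(n_events), length(n_events) == 1L)
  if (!is.finite(total_length) || total_length <= 0) {
    stop("`total_length` must be > 0", call. = FALSE)
  }
  if (k_fis < 0 || k_fus < 0) stop("rates must be >= 0", call. = FALSE)
  if (k_fis == 0 && k_fus == 0) {
    stop("`k_fis` and `k_fus` must not both be zero", call. = FALSE)
  }
  if (min_len <= 0 || min_len >= total_length) {
    stop("`min_len` must lie in (0, total_length)", call. = FALSE)
  }
  if (n_events < 0 || n_events != floor(n_events)) {
    stop("`n_events` must be a nonnegative integer", call. = FALSE)
  }
  structure(
    list(total_length = total_length, k_fis = k_fis, k_fus = k_fus,
         min_len = min_len, n_events = as.integer(n_events), seed = seed),
    class = "sim_params"
  )
}

#' Simulate one cell's steady-state mitochondrial length partition
#'
#' Runs the fission-fusion jump process of [sim_params()] and returns the
#' cell state after `n_events` accepted events. Event types are selected
#' with probability proportional to their total rates (fission:
#' `k_fis * total_length`, constant by mass conservation; fusion:
#' `k_fus * n(n-1)/2`); the fissioning component is chosen with
#' probability proportional to its length. If the process reaches a state
#' from which no event can ever be accepted (for example `k_fus = 0` with
#' every component at or below `2 * min_len`, or pure fusion collapsed to
#' one component), the current state is returned early.
#'
#' @param params A [sim_params()] object.
#' @param cell_id,population,archetype Labels attached to the returned
#'   cell.
#' @return A [mito_cell()]; its component lengths sum to
#'   `params$total_length` exactly up to floating-point error and are all
#'   `>= min_len` (the initial single component aside, which is
#'   `total_length` itself).
#' @examples
#' simulate_cell(sim_params(k_fis = 3, k_fus = 1, seed = 1))
#' @export
simulate_cell <- function(params, cell_id = "cell", population = NA_character_,
                          archetype = NA_character_) {
  stopifnot(inherits(params, "sim_params"))
  lengths <- with_seed(params$seed, run_fission_fusion(params))
  mito_cell(cell_id, lengths, population = population, archetype = archetype)
}

run_fission_fusion <- function(p) {
  len <- p$total_length
  accepted <- 0L
  r_fis <- p$k_fis * p$total_length  # constant: total length is conserved
  while (accepted < p$n_events) {
    n <- length(len)
    r_fus <- if (n >= 2L) p$k_fus * n * (n - 1) / 2 else 0
    splittable <- p$k_fis > 0 && any(len > 2 * p$min_len)
    if (r_fus == 0 && !splittable) break  # absorbed: no acceptable event
    take_fission <- if (r_fus == 0) TRUE else runif(1) < r_fis / (r_fis + r_fus)
    if (take_fission) {
      i <- if (n == 1L) 1L else sample.int(n, 1L, prob = len)
      b <- runif(1, 0, len[i])
      if (b >= p$min_len && len[i] - b >= p$min_len) {
        len <- c(len[-i], b, len[i] - b)
        accepted <- accepted + 1L
      }
    } else {
      ij <- sample.int(n, 2L)
      len <- c(len[-ij], len[ij[1L]] + len[ij[2L]])
      accepted <- accepted + 1L
    }
  }
  len
}

#' Specification of a simulated cell population
#'
#' A population is a mixture of simulator archetypes: each cell is
#' generated from one `sim_params` setting, drawn according to mixture
#' weights. This emulates the subpopulation structure seen in bivariate
#' fission/fusion dot plots, where hyperfused cells coexist with cells
#' carrying many smaller fused networks.
#'
#' @param name Population label.
#' @param n_cells Number of cells (>= 1).
#' @param archetypes Named list of [sim_params()] objects.
#' @param weights Numeric mixture weights, same length as `archetypes`;
#'   nonnegative, summing to 1 (rescaled if they sum to something else
#'   positive).
#' @return An object of class `population_spec`.
#' @examples
#' population_spec("kd", 50,
#'   archetypes = list(hf = sim_params(k_fis = 0.05),
#'                     int = sim_params(k_fis = 3)),
#'   weights = c(0.6, 0.4))
#' @export
population_spec <- function(name, n_cells, archetypes, weights = NULL) {
  stopifnot(length(name) == 1L, is.list(archetypes), length(archetypes) >= 1L)
  if (!all(vapply(archetypes, inherits, logical(1), "sim_params"))) {
    stop("`archetypes` must be a list of sim_params objects", call. = FALSE)
  }
  if (n_cells < 1 || n_cells != floor(n_cells)) {
    stop("`n_cells` must be a positive integer", call. = FALSE)
  }
  if (is.null(names(archetypes)) || any(!nzchar(names(archetypes)))) {
    names(archetypes) <- paste0("archetype", seq_along(archetypes))
  }
  if (is.null(weights)) weights <- rep(1, length(archetypes))
  stopifnot(length(weights) == length(archetypes))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be nonnegative with a positive sum", call. = FALSE)
  }
  structure(
    list(name = as.character(name), n_cells = as.integer(n_cells),
         archetypes = archetypes, weights = weights / sum(weights)),
    class = "population_spec"
  )
}

#' Simulate a population of cells from an archetype mixture
#'
#' Cells draw their generating archetype from the mixture in
#' `spec$weights` and are then simulated independently, each on its own
#' random stream derived from the master `seed` by counter offset, so the
#' output is reproducible and independent of evaluation order. The
#' default `"stratified"` assignment realizes the mixture weights as
#' exact per-archetype cell counts (largest-remainder rounding, order
#' shuffled), so the planted mixture fraction in each simulated sample is
#' the weight itself; `"multinomial"` draws archetypes i.i.d. instead.
#'
#' @param spec A [population_spec()].
#' @param seed Integer master seed.
#' @param method `"stratified"` (default) or `"multinomial"` archetype
#'   assignment.
#' @return A list of [mito_cell()] objects, each carrying its archetype
#'   label.
#' @examples
#' spec <- population_spec("kd", 10,
#'   archetypes = list(hf = sim_params(k_fis = 0.05, n_events = 200)))
#' cells <- simulate_population(spec, seed = 1)
#' @export
simulate_population <- function(spec, seed = 1L,
                                method = c("stratified", "multinomial")) {
  stopifnot(inherits(spec, "population_spec"))
  method <- match.arg(method)
  k <- length(spec$archetypes)
  assignment <- with_seed(seed, {
    if (method == "multinomial" || k == 1L) {
      sample.int(k, spec$n_cells, replace = TRUE, prob = spec$weights)
    } else {
      counts <- largest_remainder(spec$weights, spec$n_cells)
      sample(rep.int(seq_len(k), counts))
    }
  })
  lapply(seq_len(spec$n_cells), function(i) {
    a <- assignment[i]
    p <- spec$archetypes[[a]]
    p$seed <- derive_seed(seed, i)
    simulate_cell(p,
                  cell_id = sprintf("%s_c%04d", spec$name, i),
                  population = spec$name,
                  archetype = names(spec$archetypes)[a])
  })
}

# integer apportionment of n among weights, largest remainder method
largest_remainder <- function(w, n) {
  exact <- w / sum(w) * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    top <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}
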