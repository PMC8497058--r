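test_that("simulated cells conserve mass and respect the resolution floor", {
  set.seed(501)
  for (i in 1:40) {
    L <- runif(1, 5, 200)
    ml <- runif(1, 0.05, 0.1) * L
    p <- sim_params(total_length = L, k_fis = runif(1, 0, 5),
                    k_fus = runif(1, 0.1, 2), min_len = ml,
                    n_events = 300, seed = 9000 + i)
    cell <- simulate_cell(p)
    expect_equal(sum(cell$lengths), L, tolerance = 1e-9)
    expect_true(all(cell$lengths >= ml - 1e-12))
  }
})

test_that("pure coagulation is absorbed into a single fused component", {
  cell <- simulate_cell(sim_params(total_length = 50, k_fis = 0, k_fus = 1,
                                   min_len = 0.5, n_events = 5000,
                                   seed = 1))
  expect_length(cell$lengths, 1L)
  expect_equal(fusion_k_metric(cell, 1), 100)
})

test_that("fission is never accepted when min_len exceeds half the mass", {
  # every breakpoint would leave a daughter under the floor
  cell <- simulate_cell(sim_params(total_length = 10, k_fis = 5, k_fus = 0,
                                   min_len = 6, n_events = 1000, seed = 2))
  expect_equal(cell$lengths, 10)
})

test_that("identical seeds reproduce cells and populations exactly", {
  p <- sim_params(k_fis = 2, k_fus = 1, n_events = 500, seed = 77)
  expect_identical(simulate_cell(p)$lengths, simulate_cell(p)$lengths)
  spec <- population_spec("rep", 8,
                          archetypes = list(hf = arch_hf(300),
                                            int = arch_int(300)),
                          weights = c(0.5, 0.5))
  a <- simulate_population(spec, seed = 5)
  b <- simulate_population(spec, seed = 5)
  expect_identical(cells_to_table(a), cells_to_table(b))
  # a different seed gives a different draw
  expect_false(identical(cells_to_table(a),
                         cells_to_table(simulate_population(spec, seed = 6))))
})

test_that("higher fission/fusion rate ratio yields more fragmented cells", {
  lo <- sim_params(total_length = 100, k_fis = 0.1, k_fus = 1,
                   min_len = 0.5, n_events = 500)
  hi <- sim_params(total_length = 100, k_fis = 10, k_fus = 1,
                   min_len = 0.5, n_events = 500)
  n_of <- function(p, seeds) {
    vapply(seeds, function(s) {
      p$seed <- s
      length(simulate_cell(p)$lengths)
    }, numeric(1))
  }
  n_lo <- n_of(lo, 1:200)
  n_hi <- n_of(hi, 201:400)
  expect_gt(mean(n_hi), mean(n_lo))
  expect_lt(suppressWarnings(wilcox.test(n_hi, n_lo,
                                         alternative = "greater"))$p.value,
            0.01)
})

test_that("archetype mixtures are assigned as specified", {
  quick <- list(a = arch_hf(5), b = arch_int(5))
  spec <- population_spec("mix", 1000, archetypes = quick,
                          weights = c(0.5, 0.5))
  strat <- simulate_population(spec, seed = 11)
  labs <- vapply(strat, `[[`, character(1), "archetype")
  expect_equal(sum(labs == "a"), 500L)  # stratified: exact split
  multi <- simulate_population(spec, seed = 11, method = "multinomial")
  labs_m <- vapply(multi, `[[`, character(1), "archetype")
  # i.i.d. split within 4 binomial standard errors of 50/50
  expect_lt(abs(mean(labs_m == "a") - 0.5), 4 * sqrt(0.25 / 1000))
  # single archetype: identical params, distinct random streams
  one <- population_spec("one", 10, archetypes = list(a = arch_int(300)))
  cells <- simulate_population(one, seed = 3)
  expect_length(unique(vapply(cells, function(c) sum(c$lengths^2),
                              numeric(1))), 10L)
})

test_that("intensity simulation plants hi/lo states as specified", {
  # no hi cells at hi_fraction 0
  lo_only <- simulate_intensities(intensity_spec(hi_fraction = c(0, 0)),
                                  200, seed = 1)
  expect_true(all(lo_only$truth_ch1 == 0 & lo_only$truth_ch2 == 0))
  # fully correlated hi-states: double-hi truth fraction matches planting
  sp <- intensity_spec(hi_fraction = c(0.26, 0.26), correlation = 1)
  strat <- simulate_intensities(sp, 5000, seed = 2)
  expect_equal(mean(strat$truth_ch1 == 1 & strat$truth_ch2 == 1), 0.26)
  expect_equal(strat$truth_ch1, strat$truth_ch2)
  multi <- simulate_intensities(sp, 5000, seed = 3, method = "multinomial")
  dh <- mean(multi$truth_ch1 == 1 & multi$truth_ch2 == 1)
  expect_lt(abs(dh - 0.26), 4 * sqrt(0.26 * 0.74 / 5000))
  # degenerate log-sd: intensities collapse to two point masses
  pt <- simulate_intensities(
    intensity_spec(lo_sdlog = 0, hi_sdlog = 0, hi_fraction = 0.3),
    100, seed = 4)
  expect_setequal(round(unique(pt$ch1), 9), round(c(100, 600), 9))
  # infeasible correlation is rejected
  expect_error(intensity_spec(hi_fraction = c(0.9, 0.9), correlation = -1),
               "infeasible")
})

test_that("well outcomes follow the single-hit binomial model", {
  # frequency 1: success probability 1 - exp(-dose) >= 0.63 at dose >= 1
  w <- simulate_lda_wells(1, doses = rep(1, 500), wells_per_dose = 1,
                          seed = 5)
  expect_lt(abs(mean(w$positive) - (1 - exp(-1))), 0.06)
  # near-zero frequency: essentially all wells negative
  w0 <- simulate_lda_wells(1e-9, seed = 6)
  expect_equal(sum(w0$positive), 0L)
  # closed-form mean positive fraction at the top dose of the standard
  # design: 1 - exp(-1000/150)
  set.seed(7)
  frac <- vapply(1:500, function(i) {
    simulate_lda_wells(1 / 150, seed = NULL)$positive[4] / 24
  }, numeric(1))
  expect_equal(mean(frac), 1 - exp(-1000 / 150), tolerance = 0.005)
})

test_that("simulator parameters are validated", {
  expect_error(sim_params(total_length = -1), "total_length")
  expect_error(sim_params(k_fis = 0, k_fus = 0), "both")
  expect_error(sim_params(min_len = 200), "min_len")
  expect_error(sim_params(n_events = -5), "n_events")
  expect_error(simulate_lda_wells(0), "frequency")
  expect_error(simulate_lda_wells(1.5), "frequency")
})
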