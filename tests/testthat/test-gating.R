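test_that("cells are classified into the HF / Int / Other gates", {
  cfg <- gate_config()
  m <- data.frame(fission = c(0.10, 0.30, 0.05),
                  fusion5 = c(90, 60, 30))
  expect_equal(as.character(classify_cells(m, cfg)),
               c("HF", "Int", "Other"))
  # closed Int box, strict HF bound: fusion5 = 80 exactly is never HF
  edge <- data.frame(fission = c(0.15, 0.4, 0.15, 0.1, 0.3),
                     fusion5 = c(80, 40, 39.999, 80, 80.0001))
  expect_equal(as.character(classify_cells(edge, cfg)),
               c("Int", "Int", "Other", "Other", "HF"))
})

test_that("every cell lands in exactly one gate and fractions sum to 1", {
  set.seed(601)
  m <- data.frame(population = rep(c("A", "B"), each = 200),
                  fission = runif(400, 0, 1),
                  fusion5 = runif(400, 0, 100),
                  fusion1 = runif(400, 0, 100))
  g <- classify_cells(m)
  expect_false(anyNA(g))
  tab <- suppressWarnings(gate_table(m))
  expect_equal(colSums(tab$fractions), c(A = 1, B = 1), tolerance = 1e-12)
  expect_equal(colSums(tab$counts), c(A = 200, B = 200), ignore_attr = TRUE)
})

test_that("gate chi-square equals the brute-force expected-count oracle", {
  # hand-checkable 2 x 2 case (empty Other row is dropped): 6.6667
  counts <- matrix(c(10, 20, 0, 20, 10, 0), ncol = 2,
                   dimnames = list(c("HF", "Int", "Other"), c("A", "B")))
  m <- metrics_from_gate_counts(counts)
  tab <- gate_table(m)
  expect_equal(unname(tab$chisq$statistic), 20 / 3, tolerance = 1e-12)
  expect_equal(unname(tab$chisq$parameter), 1)
  # random tables up to 3 populations x 3 gates, cell counts <= 30
  set.seed(602)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    counts <- matrix(sample(1:30, 3 * k, replace = TRUE), nrow = 3,
                     dimnames = list(c("HF", "Int", "Other"),
                                     LETTERS[seq_len(k)]))
    tab <- suppressWarnings(gate_table(metrics_from_gate_counts(counts)))
    expect_equal(unname(tab$chisq$statistic), oracle_chisq(counts),
                 tolerance = 1e-10)
    expect_equal(unname(tab$chisq$parameter), 2 * (k - 1))
  }
  # identical compositions: statistic 0, p = 1
  same <- matrix(c(30, 20, 10, 30, 20, 10), ncol = 2,
                 dimnames = list(c("HF", "Int", "Other"), c("A", "B")))
  tab <- gate_table(metrics_from_gate_counts(same))
  expect_equal(unname(tab$chisq$statistic), 0)
  expect_equal(tab$chisq$p.value, 1)
})

test_that("an expected gate count below 5 triggers a warning", {
  counts <- matrix(c(50, 3, 1, 50, 2, 1), ncol = 2,
                   dimnames = list(c("HF", "Int", "Other"), c("A", "B")))
  expect_warning(gate_table(metrics_from_gate_counts(counts)),
                 "approximation")
})

test_that("regression scatter matches closed forms and detects noise", {
  col <- data.frame(fission = c(0.1, 0.2, 0.3, 0.4),
                    fusion5 = c(90, 80, 70, 60))
  cs <- correlation_scatter(col)
  expect_equal(cs$r, -1)
  expect_equal(cs$residual_sd, 0, tolerance = 1e-10)
  # 3-point toy: slope 0, residuals (-1/3, 2/3, -1/3)
  toy <- data.frame(fission = c(0, 1, 2), fusion5 = c(0, 1, 0))
  cs <- correlation_scatter(toy)
  expect_equal(cs$r, 0)
  expect_equal(cs$residual_sd, sqrt((2 / 3) / 1))
  # isotropic noise strictly inflates the residual SD
  set.seed(603)
  x <- runif(100, 0, 0.5)
  clean <- data.frame(fission = x, fusion5 = 100 - 100 * x)
  noisy <- clean
  noisy$fusion5 <- noisy$fusion5 + rnorm(100, sd = 8)
  expect_gt(correlation_scatter(noisy)$residual_sd,
            correlation_scatter(clean)$residual_sd)
  expect_error(correlation_scatter(clean[1:2, ]), "at least 3")
  flat <- data.frame(fission = rep(0.2, 5), fusion5 = 1:5)
  expect_error(correlation_scatter(flat), "degenerate")
})

test_that("fusion1-high fractions follow the planted mixture", {
  single <- metrics_table(lapply(1:20, function(i) {
    mito_cell(paste0("s", i), 7)
  }))
  expect_equal(fusion1_hi_fraction(single), 1)
  frag <- metrics_table(lapply(1:20, function(i) {
    mito_cell(paste0("f", i), rep(1, 10))
  }))
  expect_equal(fusion1_hi_fraction(frag), 0)
  # planted 30% single-component cells among fragmented cells
  set.seed(604)
  hi <- rbinom(1000, 1, 0.3)
  cells <- lapply(seq_len(1000), function(i) {
    if (hi[i]) mito_cell(paste0("m", i), runif(1, 5, 20))
    else mito_cell(paste0("m", i), runif(10, 0.5, 3))
  })
  frac <- fusion1_hi_fraction(metrics_table(cells))
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / 1000))
})

test_that("gate configuration and inputs are validated", {
  expect_error(gate_config(hf_fusion5_min = 70,
                           int_fusion5_range = c(40, 80)),
               "HF bound")
  expect_error(gate_config(int_fission_range = c(0.4, 0.15)), "ordered")
  one_pop <- data.frame(population = "A", fission = runif(5),
                        fusion5 = runif(5, 0, 100))
  expect_error(gate_table(one_pop), "at least two populations")
})
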