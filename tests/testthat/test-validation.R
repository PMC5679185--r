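test_that("differences pair measured minus estimated GFR by patient", {
  co <- data.frame(id = c("a", "b"), age = 50, sex = "F",
                   scr = 1, mgfr = c(50, 60))
  d <- gfr_differences(co, c(45, 65))
  expect_equal(unname(d), c(5, -5))
  expect_equal(names(d), c("a", "b"))
  expect_equal(unname(gfr_differences(co, c(45, 65),
                                      direction = "egfr_minus_mgfr")),
               c(-5, 5))
  expect_equal(unname(gfr_differences(co, co$mgfr)), c(0, 0))
  expect_error(gfr_differences(co, 1), "one entry per")
  co$mgfr <- NULL
  expect_error(gfr_differences(co, c(45, 65)), "measured GFR")
})

test_that("point metrics match their definitions on small cases", {
  expect_equal(median_bias(c(-1, 0, 1)), 0)
  expect_equal(median_bias(c(1, 2, 3, 10)), 2.5)
  expect_equal(median_bias(7), 7)
  expect_equal(iqr_precision(rep(3.3, 4)), 0)
  expect_equal(iqr_precision(1:8), 3.5)  # frozen from the interpolation rule
  d <- c(-4, 1, 2.5, 9, 20)
  expect_equal(iqr_precision(d + 10), iqr_precision(d))
  expect_equal(p30_accuracy(100, 130), 1)    # boundary inclusive
  expect_equal(p30_accuracy(100, 130.01), 0)
  expect_equal(p30_accuracy(c(50, 60), c(50, 60)), 1)
  expect_error(median_bias(numeric(0)), "non-empty")
  expect_error(iqr_precision(5), "at least two")
  expect_error(p30_hits(c(0, 50), c(10, 50)), "positive")
})

test_that("metrics agree with brute-force oracles on random inputs", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(2:40, 1)
    d <- rnorm(n, sd = runif(1, 0.5, 20))
    expect_equal(median_bias(d), oracle_median(d))
    expect_equal(iqr_precision(d), oracle_iqr(d))
    mgfr <- runif(n, 10, 150)
    egfr <- mgfr * exp(rnorm(n, sd = 0.3))
    expect_equal(p30_accuracy(mgfr, egfr), oracle_p30(mgfr, egfr))
  }
})

test_that("metrics are invariant under consistent patient reordering", {
  set.seed(7)
  n <- 60
  co <- data.frame(id = paste0("p", 1:n), age = runif(n, 20, 80),
                   sex = sample(c("F", "M"), n, TRUE),
                   scr = runif(n, 0.5, 6), mgfr = runif(n, 10, 150))
  egfr <- co$mgfr * exp(rnorm(n, sd = 0.2))
  perm <- sample(n)
  d1 <- gfr_differences(co, egfr)
  d2 <- gfr_differences(co[perm, ], egfr[perm])
  expect_equal(median_bias(d1), median_bias(d2))
  expect_equal(iqr_precision(d1), iqr_precision(d2))
  expect_equal(p30_accuracy(co$mgfr, egfr),
               p30_accuracy(co$mgfr[perm], egfr[perm]))
})

test_that("bootstrap intervals are seeded, ordered and degenerate-safe", {
  x <- rnorm(80)
  ci1 <- bootstrap_ci(x, median, B = 500, seed = 11)
  ci2 <- bootstrap_ci(x, median, B = 500, seed = 11)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  const <- rep(4.2, 30)
  expect_equal(bootstrap_ci(const, median, B = 200, seed = 1), c(4.2, 4.2))
  expect_error(bootstrap_ci(x, median, B = 50), "at least 100")
  expect_error(bootstrap_ci(1, median), "at least two")
})

test_that("the Wilcoxon bias comparison matches exact enumeration", {
  expect_equal(compare_bias_wilcoxon(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(202)
  for (rep in 1:300) {
    n <- sample(4:12, 1)
    z <- rnorm(n, mean = runif(1, -1, 1))
    p_pkg <- compare_bias_wilcoxon(z, rep(0, n))
    expect_equal(p_pkg, oracle_wilcoxon_exact(z), tolerance = 1e-12)
  }
  # constant shift at n = 50 is overwhelming evidence
  set.seed(3)
  dB <- rnorm(50)
  expect_lt(compare_bias_wilcoxon(dB + 2, dB), 0.01)
})

test_that("the precision bootstrap comparison behaves under null and alternative", {
  set.seed(55)
  d <- rnorm(200)
  expect_equal(compare_precision_bootstrap(d, d, B = 500, seed = 1), 1)
  dB0 <- rnorm(200)
  p1 <- compare_precision_bootstrap(d, dB0, B = 500, seed = 9)
  expect_identical(p1, compare_precision_bootstrap(d, dB0, B = 500,
                                                   seed = 9))
  expect_true(p1 >= 0 && p1 <= 1)
  # known unequal spreads are detected in the vast majority of runs
  hits <- vapply(1:20, function(k) {
    set.seed(500 + k)
    dA <- rnorm(400, sd = 1)
    dB <- rnorm(400, sd = 3)
    compare_precision_bootstrap(dA, dB, B = 400, seed = 600 + k) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the McNemar accuracy comparison matches the binomial oracle", {
  expect_equal(compare_accuracy_mcnemar(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(compare_accuracy_mcnemar(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # b = 10, c = 0: two-sided exact tail 2 * 0.5^10
  A <- c(rep(1, 10), rep(1, 5)); B <- c(rep(0, 10), rep(1, 5))
  expect_equal(compare_accuracy_mcnemar(A, B), 0.001953125)
  set.seed(303)
  for (rep in 1:500) {
    b <- sample(0:12, 1); cc <- sample(0:(24 - 2 * b %/% 2), 1)
    if (b + cc >= 25) next
    conc1 <- sample(0:10, 1); conc0 <- sample(0:10, 1)
    hitsA <- c(rep(1, b), rep(0, cc), rep(1, conc1), rep(0, conc0))
    hitsB <- c(rep(0, b), rep(1, cc), rep(1, conc1), rep(0, conc0))
    expect_equal(compare_accuracy_mcnemar(hitsA, hitsB),
                 oracle_mcnemar_exact(b, cc), tolerance = 1e-12)
  }
  expect_error(compare_accuracy_mcnemar(c(1, 2), c(0, 1)), "0 and 1")
})

test_that("McNemar depends only on the discordant counts", {
  hitsA <- c(1, 1, 1, 0, 0)
  hitsB <- c(0, 0, 1, 1, 1)
  p0 <- compare_accuracy_mcnemar(hitsA, hitsB)
  # append concordant pairs: p must not move
  p1 <- compare_accuracy_mcnemar(c(hitsA, 1, 1, 0, 0),
                                 c(hitsB, 1, 1, 0, 0))
  expect_identical(p0, p1)
})

test_that("stratified summaries bin on measured GFR with half-open bins", {
  n <- 90
  set.seed(9)
  co <- data.frame(id = paste0("p", 1:n), age = 50, sex = "M", scr = 2,
                   mgfr = c(30, 60, runif(n - 2, 12, 140)))
  egfr <- co$mgfr * exp(rnorm(n, sd = 0.15))
  out <- stratified_summary(co, list(model = egfr), B = 200, seed = 5)
  expect_setequal(out$subgroup, c("Overall", "<30", "30-60", ">=60"))
  bins <- gfrens:::assign_subgroup(co$mgfr, c(30, 60))
  expect_equal(as.character(bins[1]), "30-60")  # mgfr = 30
  expect_equal(as.character(bins[2]), ">=60")   # mgfr = 60
  # Overall row equals direct computation on the full cohort
  ov <- out[out$subgroup == "Overall", ]
  d <- co$mgfr - egfr
  expect_equal(ov$bias, median_bias(d))
  expect_equal(ov$precision, iqr_precision(d))
  expect_equal(ov$accuracy, p30_accuracy(co$mgfr, egfr))
  expect_equal(ov$n, n)
  # a cohort confined to one stratum leaves the others empty, not errored
  co2 <- co[co$mgfr >= 30 & co$mgfr < 60, ]
  out2 <- stratified_summary(co2, list(model = co2$mgfr), B = 200, seed = 5)
  expect_equal(out2$n[out2$subgroup == "<30"], 0L)
  expect_true(is.na(out2$bias[out2$subgroup == "<30"]))
  expect_equal(out2$n[out2$subgroup == "30-60"], nrow(co2))
})

test_that("evaluate_models produces the full benchmark-comparison report", {
  set.seed(12)
  n <- 120
  co <- data.frame(id = paste0("p", 1:n), age = runif(n, 25, 80),
                   sex = sample(c("F", "M"), n, TRUE),
                   scr = runif(n, 0.6, 5), mgfr = runif(n, 12, 140))
  bench <- co$mgfr + rnorm(n, sd = 12)
  tight <- co$mgfr + rnorm(n, sd = 6)
  rep1 <- evaluate_models(co, list(regression = bench, tight = tight),
                          B = 300, seed = 21)
  expect_s3_class(rep1, "gfr_report")
  expect_equal(nrow(rep1$summaries), 2 * 4)
  expect_equal(nrow(rep1$comparisons), 4)
  ovr <- rep1$comparisons[rep1$comparisons$subgroup == "Overall", ]
  expect_lt(ovr$p_precision, 0.05)  # half the spread must register
  # candidate identical to the benchmark: all p-values 1
  rep2 <- evaluate_models(co, list(regression = bench, same = bench),
                          B = 300, seed = 21)
  cmp <- rep2$comparisons
  expect_true(all(cmp$p_bias == 1 & cmp$p_precision == 1 &
                    cmp$p_accuracy == 1))
  # benchmark-only map: summaries, no comparisons
  rep3 <- evaluate_models(co, list(regression = bench), B = 300, seed = 2)
  expect_equal(nrow(rep3$comparisons), 0L)
  expect_error(evaluate_models(co, list(a = bench), benchmark = "reg"),
               "not found")
})

test_that("a noiseless equation-consistent cohort scores perfectly", {
  co <- simulate_cohort(branch_spec("female_high", n = 150,
                                    noise_sigma = 0, seed = 31))
  egfr <- estimate_gfr_regression(co$age, co$sex, co$scr, warn_age = FALSE)
  rep <- evaluate_models(co, list(regression = egfr), B = 200, seed = 1)
  ov <- rep$summaries[rep$summaries$subgroup == "Overall", ]
  expect_equal(ov$bias, 0, tolerance = 1e-9)
  expect_equal(ov$precision, 0, tolerance = 1e-9)
  expect_equal(ov$accuracy, 1)
})
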