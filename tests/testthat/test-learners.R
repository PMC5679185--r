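test_that("feature construction encodes age, sex and log creatinine", {
  co <- data.frame(age = c(60, 40), sex = c("male", "female"),
                   scr = c(1.0, exp(1)))
  X <- build_features(co)
  expect_equal(X$age, c(60, 40))
  expect_equal(X$sex_male, c(1, 0))
  expect_equal(X$log_scr, c(0, 1))
  empty <- build_features(data.frame(age = numeric(0),
                                     sex = character(0),
                                     scr = numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("the regression member reproduces the equation inside the API", {
  m <- regression_member()
  co <- data.frame(age = 0, sex = "female", scr = 1.2)
  expect_identical(predict(m, co), 92)
  expect_identical(predict(m, co[0, ]), numeric(0))
})

test_that("training requires measured GFR and a minimum cohort size", {
  dev <- simulate_cohort(cohort_preset("development", n = 80, seed = 1))
  no_mgfr <- dev; no_mgfr$mgfr <- NULL
  expect_error(train_member("ann", no_mgfr, seed = 1), "measured GFR")
  expect_error(train_member("svm", dev[1:20, ], seed = 1), "at least")
})

test_that("members learn an almost-noiseless generator to low error", {
  spec <- branch_spec("male_high", n = 300, noise_sigma = 0.01, seed = 21)
  dev <- simulate_cohort(spec)
  spec2 <- spec; spec2$seed <- 22L
  held <- simulate_cohort(spec2)
  for (kind in c("ann", "svm")) {
    m <- train_member(kind, dev, seed = 7)
    rmse <- sqrt(mean((predict(m, held) - held$mgfr)^2))
    expect_lt(rmse, 3)  # ml/min/1.73 m2, against a ~12-52 range target
  }
})

test_that("training and prediction are bit-reproducible for a fixed seed", {
  dev <- simulate_cohort(cohort_preset("development", n = 150, seed = 4))
  new <- simulate_cohort(cohort_preset("validation", n = 60, seed = 5))
  for (kind in c("ann", "svm")) {
    m1 <- train_member(kind, dev, seed = 99)
    m2 <- train_member(kind, dev, seed = 99)
    expect_identical(predict(m1, new), predict(m2, new))
  }
})

test_that("serialized members reproduce predictions bit-exactly", {
  dev <- simulate_cohort(cohort_preset("development", n = 150, seed = 4))
  new <- simulate_cohort(cohort_preset("validation", n = 60, seed = 5))
  for (kind in c("ann", "svm")) {
    m <- train_member(kind, dev, seed = 31)
    path <- withr::local_tempfile(fileext = ".json")
    write_member(m, path)
    m2 <- read_member(path)
    expect_identical(predict(m2, new), predict(m, new))
  }
})

test_that("captured state agrees with the fitting libraries' own predict", {
  # dual route: our forward passes vs nnet/e1071 predictions
  set.seed(42)
  n <- 120
  Xs <- matrix(rnorm(n * 3), ncol = 3)
  ys <- rnorm(n)
  fit_n <- nnet::nnet(x = Xs, y = ys, size = 4, linout = TRUE,
                      maxit = 200, trace = FALSE)
  ours <- gfrens:::ann_forward(fit_n$wts, 4L, Xs)
  expect_equal(ours, drop(predict(fit_n, Xs)), tolerance = 1e-10)
  fit_s <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                      kernel = "radial", gamma = 0.3, cost = 5,
                      epsilon = 0.1, scale = FALSE)
  state <- list(sv = unname(as.matrix(fit_s$SV)),
                sv_coefs = drop(fit_s$coefs), rho = fit_s$rho, gamma = 0.3)
  expect_equal(gfrens:::svm_forward(state, Xs),
               unname(drop(predict(fit_s, Xs))), tolerance = 1e-10)
})

test_that("predictions are floored so downstream ratios stay defined", {
  dev <- simulate_cohort(cohort_preset("development", n = 150, seed = 4))
  m <- train_member("ann", dev, seed = 2)
  # absurd inputs can push the net below zero; the floor catches them
  wild <- data.frame(age = rep(c(20, 95), 10),
                     sex = "male", scr = seq(20, 60, length.out = 20))
  expect_true(all(predict(m, wild) >= 1))
  expect_true(all(predict(m, wild, floor = 5) >= 5))
})

test_that("ensemble averaging is the element-wise member mean", {
  co <- tiny_cohort()
  reg <- regression_member()
  ens3 <- gfr_ensemble(reg, reg, reg)
  expect_equal(predict(ens3, co), predict(reg, co))
  # permutation invariance and member-wise bounds on distinct members
  dev <- simulate_cohort(cohort_preset("development", n = 150, seed = 4))
  ann <- train_member("ann", dev, seed = 1)
  svm <- train_member("svm", dev, seed = 1)
  pa <- predict(ann, co); ps <- predict(svm, co); pr <- predict(reg, co)
  e1 <- predict(gfr_ensemble(reg, ann, svm), co)
  e2 <- predict(gfr_ensemble(svm, reg, ann), co)
  expect_equal(e1, (pa + ps + pr) / 3)
  expect_equal(e1, e2)
  expect_true(all(e1 >= pmin(pa, ps, pr) - 1e-12))
  expect_true(all(e1 <= pmax(pa, ps, pr) + 1e-12))
  expect_error(gfr_ensemble(), "at least one")
  expect_identical(predict(gfr_ensemble(reg), co[0, ]), numeric(0))
})

test_that("averaging unbiased independent members shrinks the error IQR", {
  set.seed(77)
  wins <- replicate(40, {
    mgfr <- runif(400, 15, 120)
    errs <- matrix(rnorm(400 * 3, sd = 10), ncol = 3)
    member_iqr <- apply(errs, 2, iqr_precision)
    ens_iqr <- iqr_precision(rowMeans(errs))
    all(ens_iqr < member_iqr)
  })
  expect_gt(mean(wins), 0.95)
})
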