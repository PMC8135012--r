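test_that("noiseless data yield a near-perfect training fit", {
  d <- simulate_methylation(sim_config(
    n_probes = 200L, n_blood = 40L, n_oocyte = 0L,
    classes = c(blood_up = 25L, blood_down = 25L), noise_sd = 0, seed = 4L))
  cl <- train_clock(d$betas, d$samples, seed = 1)
  ev <- evaluate_clock(cl$fitted)
  expect_gte(ev$pearson_r, 0.999)
  expect_lte(ev$mae, 0.1)
})

test_that("permuted ages destroy out-of-sample accuracy", {
  d <- simulate_methylation(sim_config(
    n_probes = 100L, n_blood = 20L, n_oocyte = 0L,
    classes = c(blood_up = 15L), seed = 14L))
  s <- d$samples
  set.seed(99)
  s$age_years <- sample(s$age_years)
  est <- loo_estimates(d$betas, s, seed = 1)
  r <- cor(est$age_years, est$dnam_age_years)
  # no spurious positive accuracy; r may be pushed negative by the LOO-mean
  # artifact (held-out estimates shrink toward the training mean, which
  # anti-correlates with the held-out age by construction)
  expect_lt(r, 2 / sqrt(nrow(est)))
  # and the errors are those of an uninformative predictor
  ev <- evaluate_clock(est)
  expect_gt(ev$mae, 1.5)
})

test_that("all-null probes give a near-empty clock predicting near the mean age", {
  d <- simulate_methylation(sim_config(
    n_probes = 300L, n_blood = 40L, n_oocyte = 0L,
    classes = c(blood_up = 0L), seed = 15L))
  cl <- train_clock(d$betas, d$samples, seed = 1)
  expect_lte(length(cl$coefficients), 25L)
  pred <- predict(cl, d$betas, warn_range = FALSE)
  expect_lt(abs(mean(pred) - mean(d$samples$age_years)), 1)
  expect_lt(sd(pred), sd(d$samples$age_years))
})

test_that("training rejects degenerate inputs", {
  d <- small_sim()
  expect_error(train_clock(d$betas[, 1:5], d$samples[1:5, ]), "at least 10")
  s <- d$samples
  s$age_years <- 5
  s$donor_id <- NA_character_
  expect_error(train_clock(d$betas, s), "constant")
  expect_error(train_clock(d$betas[, 1:12], d$samples[1:12, ], nfolds = 20L),
               "folds")
})

test_that("LOO holds out exactly one sample each time and is order-invariant", {
  d <- simulate_methylation(sim_config(
    n_probes = 80L, n_blood = 14L, n_oocyte = 0L,
    classes = c(blood_up = 10L), seed = 16L))
  est <- loo_estimates(d$betas, d$samples, seed = 2)
  expect_identical(sort(est$fold_id), seq_len(14L))
  expect_identical(est$sample_id, d$samples$sample_id)

  perm <- sample(ncol(d$betas))
  est_p <- loo_estimates(d$betas[, perm], d$samples, seed = 2)
  est_p <- est_p[match(est$sample_id, est_p$sample_id), ]
  expect_equal(est_p$dnam_age_years, est$dnam_age_years, tolerance = 1e-6)
})

test_that("folds are balanced, donor-coherent and seed-deterministic", {
  s <- tiny_samples(100)
  f <- make_folds(s, k = 10L, seed = 3)
  expect_true(max(table(f)) - min(table(f)) <= 1L)
  expect_identical(f, make_folds(s, k = 10L, seed = 3))
  expect_false(identical(f, make_folds(s, k = 10L, seed = 4)))

  sd_ <- tiny_samples(40, donor = rep(sprintf("d%02d", 1:20), each = 2),
                      ages = rep(seq(1, 12, length.out = 20), each = 2))
  sd_$tissue <- rep(c("blood", "oocyte"), 20)
  fd <- make_folds(sd_, k = 5L, group_by_donor = TRUE, seed = 1)
  expect_true(all(tapply(fd, sd_$donor_id, function(x) length(unique(x))) == 1L))
  expect_error(make_folds(s[1:4, ], k = 10L), "more folds")
})

test_that("prediction applies the stored linear model and back-transform", {
  probes <- sprintf("cg%05d", 1:4)
  b <- tiny_betas(4, c("a", "b", "c"))
  # zero-coefficient clock: everyone gets the intercept age
  cl0 <- epiclock:::new_meth_clock(age_transform("identity"), 5,
                                   setNames(numeric(0), character(0)),
                                   0.5, 0.1, list())
  expect_equal(unname(predict(cl0, b)), rep(5, 3))
  # relative clock: relative prediction 0.5 at cattle lifespan 38 -> 19 y
  clr <- epiclock:::new_meth_clock(age_transform("relative"), 0.5,
                                   setNames(numeric(0), character(0)),
                                   0.5, 0.1, list())
  expect_equal(unname(predict(clr, b, max_lifespan = 38)), rep(19, 3))
  expect_error(predict(clr, b), "samples")
  # missing probes are an error naming them, never imputed
  cl1 <- epiclock:::new_meth_clock(age_transform("identity"), 0,
                                   c(cgZZ = 1), 0.5, 0.1, list())
  expect_error(predict(cl1, b), "cgZZ")
})

test_that("evaluation reports Pearson r and median absolute error", {
  est <- data.frame(sample_id = letters[1:4], age_years = 1:4,
                    dnam_age_years = 1:4, tissue = "blood",
                    species = "cattle")
  ev <- evaluate_clock(est)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mae, 0)
  est$dnam_age_years <- est$age_years + 2
  ev <- evaluate_clock(est)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mae, 2)
  est$dnam_age_years <- c(2, 1, 4, 3)
  ev <- evaluate_clock(est)
  expect_equal(ev$pearson_r, 0.6)
  expect_equal(ev$mae, 1)
  est$age_years <- rep(3, 4)  # constant ages: r undefined, reported as NA
  expect_true(is.na(evaluate_clock(est)$pearson_r))
})

test_that("age acceleration is the within-tissue OLS residual", {
  est <- data.frame(sample_id = sprintf("s%d", 1:20),
                    age_years = rep(seq(1, 12, length.out = 10), 2),
                    tissue = rep(c("blood", "oocyte"), each = 10),
                    species = "cattle")
  est$dnam_age_years <- est$age_years
  expect_equal(age_acceleration(est)$acceleration, rep(0, 20))
  est$dnam_age_years <- est$age_years + 5  # offset absorbed by intercept
  expect_equal(age_acceleration(est)$acceleration, rep(0, 20))
  set.seed(8)
  est$dnam_age_years <- est$age_years + rnorm(20)
  acc <- age_acceleration(est)
  for (tis in c("blood", "oocyte")) {
    i <- acc$tissue == tis
    expect_lt(abs(cor(acc$acceleration[i], acc$age_years[i])), 1e-8)
  }
  expect_error(age_acceleration(est[1:2, ]), "<3")
})

test_that("acceleration correlation pairs donors and detects identity", {
  mk <- function(tissue, accel) {
    age <- seq(1, 12, length.out = 12)
    data.frame(sample_id = paste0(tissue, 1:12), age_years = age,
               dnam_age_years = age + accel, tissue = tissue,
               species = "cattle", donor_id = sprintf("d%02d", 1:12))
  }
  set.seed(3)
  a <- rnorm(12)
  res <- acceleration_correlation(mk("blood", a), mk("oocyte", a))
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_identical(res$n_pairs, 12L)
  expect_identical(rownames(res$summaries), c("blood", "oocyte"))
  no_donor <- mk("blood", a); no_donor$donor_id <- NA_character_
  expect_error(acceleration_correlation(no_donor, mk("oocyte", a)),
               "donor_id")
})

test_that("training is deterministic given the seed", {
  d <- small_sim()
  c1 <- train_clock(d$betas, d$samples, seed = 7)
  c2 <- train_clock(d$betas, d$samples, seed = 7)
  expect_identical(c1$coefficients, c2$coefficients)
  expect_identical(c1$lambda, c2$lambda)
})
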