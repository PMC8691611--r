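test_that("epoching floors to whole epochs and rejects short series", {
  ep <- epoch_params(60, fs = 10)
  e <- epochs(rnorm(1250), ep)
  expect_equal(dim(e), c(600, 2))          # 50 samples dropped
  expect_equal(ncol(epochs(rnorm(600), ep)), 1)
  expect_error(epochs(rnorm(599), ep), class = "actimetr_size_error")
})

test_that("PIM integrates the epoch by Riemann sum", {
  expect_equal(pim(c(1, 2, 3), 0.1, "riemann"), 0.6)
  expect_equal(pim(rep(2.5, 600), 0.1, "riemann"), 2.5 * 600 * 0.1)
})

test_that("Simpson 3/8 integrates a cubic exactly", {
  # 31 samples = 30 intervals, divisible by 3: pure 3/8 rule, no tail
  ts <- 0.1
  x <- (0:30) * ts
  f <- 2 * x^3 - 3 * x^2 + x + 0.5
  exact <- function(t) t^4 / 2 - t^3 + t^2 / 2 + 0.5 * t
  expect_equal(pim(f, ts, "simpson38"), exact(3) - exact(0),
               tolerance = 1e-10)
})

test_that("ZCM counts threshold crossings with on-threshold samples inheriting their side", {
  expect_equal(zcm(c(0.2, 0.8, 0.3, 0.9), 0.5), 3)
  expect_equal(zcm(rep(0.4, 100), 0.5), 0)
  # flat touch of the level is not a pair of crossings
  expect_equal(zcm(c(0.2, 0.5, 0.2), 0.5), 0)
  expect_equal(zcm(c(0.2, 0.5, 0.9), 0.5), 1)
  expect_equal(zcm(c(0.5, 0.5, 0.9, 0.1), 0.5), 1)   # leading on-threshold ignored
})

test_that("a 1 Hz sinusoid crosses zero 120 times per minute epoch", {
  t <- (0:599) / 10
  x <- sin(2 * pi * t - 0.05)
  expect_equal(zcm(x, 0), 120)
  expect_equal(zcm(x, 0), oracle_zcm(x, 0))
})

test_that("TAT measures time strictly above the threshold", {
  expect_equal(tat(c(0.2, 0.8, 0.9, 0.1), 0.5, 0.1), 0.2)
  x <- rep(0.9, 600)
  expect_equal(tat(x, 0.5, 0.1), 60)       # all samples above: full epoch
  # square wave with duty cycle d
  d <- 0.3
  sq <- rep(c(rep(1, 30), rep(0, 70)), 6)  # 10 s period, duty 0.3, 60 s
  expect_equal(tat(sq, 0.5, 0.1), d * 60, tolerance = 0.1)
  expect_equal(tat(sq, 0.5, 0.1), oracle_tat(sq, 0.5, 0.1))
})

test_that("MAD is the mean absolute deviation and is offset invariant", {
  expect_equal(mad_epoch(c(1, 2, 3)), 2 / 3)
  expect_equal(mad_epoch(rep(0.7, 50)), 0)
  set.seed(7)
  x <- rnorm(600)
  expect_equal(mad_epoch(x + 0.37), mad_epoch(x), tolerance = 1e-12)
})

test_that("ENMO keeps only the part of the magnitude above 1 g", {
  expect_equal(enmo(c(1.2, 0.8, 1.0)), 0.2 / 3)
  expect_equal(enmo(rep(1, 600)), 0)
  expect_equal(enmo(c(0.2, 0.5, 0.99)), 0)
})

test_that("HFEN is the epoch mean of its input and scales linearly", {
  x <- abs(rnorm(600, 0, 0.1))
  expect_equal(hfen(x), mean(x))
  expect_equal(hfen(3 * x), 3 * hfen(x), tolerance = 1e-12)
})

test_that("AI subtracts the systematic noise variance per axis, floored at zero", {
  nm <- noise_model(0)
  expect_equal(activity_index(rep(1, 60), rep(2, 60), rep(3, 60), nm), 0)
  set.seed(8)
  ex <- rnorm(600); ey <- rnorm(600); ez <- rnorm(600)
  matched <- noise_model((var(ex) + var(ey) + var(ez)) / 3)
  expect_equal(activity_index(ex, ey, ez, matched), 0)
  nm2 <- noise_model(1e-4)
  expect_equal(activity_index(ex, ey, ez, nm2),
               oracle_ai(ex, ey, ez, 1e-4), tolerance = 1e-12)
  expect_equal(activity_index(ex, ey, ez, nm2, variant = "sqrt"),
               sqrt(oracle_ai(ex, ey, ez, 1e-4)), tolerance = 1e-12)
})

test_that("every metric matches its naive loop oracle on random epochs", {
  set.seed(9)
  ep <- epoch_params(6, fs = 10)   # 60-sample epochs, many of them
  ts <- 0.1
  for (rep_i in 1:40) {
    x <- abs(rnorm(60, 0.5, 0.4))
    thr <- runif(1, 0.1, 0.9)
    expect_equal(pim(x, ts, "riemann"), oracle_pim_riemann(x, ts),
                 tolerance = 1e-13)
    expect_equal(zcm(x, thr), oracle_zcm(x, thr))
    expect_equal(tat(x, thr, ts), oracle_tat(x, thr, ts), tolerance = 1e-13)
    expect_equal(mad_epoch(x), oracle_mad(x), tolerance = 1e-13)
    expect_equal(enmo(x), oracle_enmo(x), tolerance = 1e-13)
  }
})

test_that("PIM is positively homogeneous and ZCM/TAT decrease with the threshold", {
  set.seed(10)
  x <- abs(rnorm(600, 0.3, 0.3))
  expect_equal(pim(3.1 * x, 0.1), 3.1 * pim(x, 0.1), tolerance = 1e-12)
  thrs <- seq(0.05, 0.9, by = 0.05)
  tats <- vapply(thrs, function(t) tat(x, t, 0.1), numeric(1))
  expect_true(all(diff(tats) <= 0))
})

test_that("the applicability matrix gates metric/dataset combinations", {
  ds <- build_datasets(gravity_recording(6000))
  ep <- epoch_params(60, fs = 10)
  # PIM, ZCM, TAT are inapplicable to raw axial data
  expect_error(compute_activity(ds$UFX, "PIMr", ep),
               class = "actimetr_applicability_error")
  expect_error(compute_activity(ds$UFY, "ZCM", ep, threshold = 0.1),
               class = "actimetr_applicability_error")
  # ENMO needs the gravity-bearing magnitude
  expect_error(compute_activity(ds$FMpost, "ENMO", ep),
               class = "actimetr_applicability_error")
  expect_error(compute_activity(ds$FMpre, "ENMO", ep),
               class = "actimetr_applicability_error")
  # MAD is applicable per axis, even unfiltered
  a <- compute_activity(ds$UFY, "MAD", ep)
  expect_s3_class(a, "activity_series")
  expect_equal(a$dataset_kind, "UFY")
  # HFEN only on its conditioned magnitude
  expect_error(compute_activity(ds$UFM, "HFEN", ep),
               class = "actimetr_applicability_error")
  # level-crossing metrics demand a threshold
  expect_error(compute_activity(ds$UFNM, "ZCM", ep),
               class = "actimetr_parameter_error")
  # error message names the rule
  err <- tryCatch(compute_activity(ds$UFX, "PIMr", ep), error = identity)
  expect_match(conditionMessage(err), "allowed datasets")
})

test_that("PIM input is rectified on zero-centred datasets", {
  ds <- medium_datasets()
  ep <- epoch_params(60, fs = 10)
  a <- compute_activity(ds$FMpost, "PIMr", ep)
  expect_true(all(a$values >= 0))
  manual <- apply(epochs(abs(ds$FMpost$values), ep), 2, pim, t_s = 0.1)
  expect_equal(a$values, manual, tolerance = 1e-12)
})

test_that("PIM on UFM can subtract the gravity baseline", {
  ds <- build_datasets(gravity_recording(1200))
  ep <- epoch_params(60, fs = 10)
  plain <- compute_activity(ds$UFM, "PIMr", ep)
  expect_equal(plain$values, rep(60, 2), tolerance = 1e-9)  # 1 g * 60 s
  sub <- compute_activity(ds$UFM, "PIMr", ep, baseline_subtract = TRUE)
  expect_equal(sub$values, rep(0, 2), tolerance = 1e-9)
})

test_that("the noise floor estimate recovers the generator's sensor noise", {
  set.seed(11)
  n <- 12000
  sd_true <- 0.05
  rec <- raw_recording(rnorm(n, 0, sd_true), rnorm(n, 0, sd_true),
                       1 + rnorm(n, 0, sd_true), fs = 10)
  nm <- estimate_noise_variance(rec, epoch_params(60, fs = 10))
  expect_equal(nm$variance, sd_true^2, tolerance = 0.1)

  const <- gravity_recording(12000)
  nm0 <- estimate_noise_variance(const, epoch_params(60, fs = 10))
  expect_equal(nm0$variance, 0)
  expect_error(estimate_noise_variance(gravity_recording(1200),
                                       epoch_params(60, fs = 10)),
               class = "actimetr_size_error")
})

test_that("movement bursts barely move the low-quantile noise floor", {
  out <- medium_synth()
  rec <- out$recording
  nm <- estimate_noise_variance(rec, epoch_params(60, fs = 10))
  p <- out$params
  # burst-free variance: sensor noise plus a drift contribution; compare
  # against the same generator with movement disabled
  p0 <- p; p0$burst_sd_g <- 0
  rec0 <- generate_recording(p0)$recording
  nm0 <- estimate_noise_variance(rec0, epoch_params(60, fs = 10))
  expect_equal(nm$variance, nm0$variance, tolerance = 0.15)
})

test_that("AI runs on axial triples and rejects mixed ones", {
  ds <- medium_datasets()
  ep <- epoch_params(60, fs = 10)
  nm <- noise_model(1e-4)
  a <- compute_activity(list(ds$UFX, ds$UFY, ds$UFZ), "AI", ep, noise = nm)
  expect_equal(a$dataset_kind, "UFXYZ")
  expect_true(all(a$values >= 0))
  af <- compute_activity(list(ds$FX, ds$FY, ds$FZ), "AI", ep, noise = nm)
  expect_equal(af$dataset_kind, "FXYZ")
  expect_error(compute_activity(list(ds$UFX, ds$FY, ds$FZ), "AI", ep, noise = nm),
               class = "actimetr_applicability_error")
  expect_error(compute_activity(list(ds$UFX, ds$UFY, ds$UFZ), "AI", ep),
               class = "actimetr_parameter_error")
})
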