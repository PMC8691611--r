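test_that("pearson matches the two-pass covariance formula and handles edge cases", {
  set.seed(41)
  a <- activity_series(rnorm(100), "MAD", "UFM")
  expect_equal(pearson(a, a), 1)
  neg <- activity_series(-a$values + 5, "MAD", "UFM")
  expect_equal(pearson(a, neg), -1)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson(activity_series(x, "MAD", "UFM"),
                         activity_series(y, "MAD", "UFM")),
                 oracle, tolerance = 1e-12)
  }
  const <- activity_series(rep(1, 100), "MAD", "UFM")
  expect_error(pearson(a, const), class = "actimetr_correlation_error")
  shorter <- activity_series(rnorm(99), "MAD", "UFM")
  expect_error(pearson(a, shorter), class = "actimetr_alignment_error")
})

test_that("spectral correlation is 1 for identical signals and phase-blind for shifts", {
  set.seed(42)
  n <- 512
  t <- seq_len(n)
  x <- sin(2 * pi * t / 16) + 0.5 * sin(2 * pi * t / 5) + rnorm(n, 0, 0.2)
  pp <- list(segment = 64, overlap = 0.5)
  expect_equal(spectral_correlation(x, x, pp), 1)
  shifted <- c(x[11:n], x[1:10])
  expect_lt(abs(spectral_correlation(x, x, pp) -
                spectral_correlation(x, shifted, pp)), 0.05)
  expect_error(spectral_correlation(x[1:100], x[1:100], pp),
               class = "actimetr_size_error")
})

test_that("independent white-noise series fall inside the permutation null band", {
  set.seed(43)
  n <- 512
  pp <- list(segment = 64, overlap = 0.5)
  a <- rnorm(n); b <- rnorm(n)
  obs <- spectral_correlation(a, b, pp)
  # permutation oracle: null distribution from phase-destroying reshuffles
  null_r <- replicate(60, spectral_correlation(a, sample(b), pp))
  lo <- quantile(null_r, 0.005); hi <- quantile(null_r, 0.995)
  expect_gte(obs, lo - 0.15)
  expect_lte(obs, hi + 0.15)
  expect_lt(abs(obs), 0.6)
})

test_that("the Welch PSD concentrates power at the right frequency", {
  t <- seq_len(2048)
  x <- sin(2 * pi * 0.125 * t)
  ps <- welch_psd(x, fs = 1, segment = 256)
  expect_equal(ps$freq[which.max(ps$psd)], 0.125, tolerance = 0.01)
})

test_that("the default catalog covers the applicability matrix deterministically", {
  cat1 <- default_catalog()
  cat2 <- default_catalog()
  expect_identical(cat1, cat2)
  expect_false(anyDuplicated(cat1$id) > 0)
  for (d in c("UFM", "UFNM", "FMpre", "FMpost")) {
    expect_true(sprintf("PIMr(%s)", d) %in% cat1$id)
    expect_true(sprintf("PIMs(%s)", d) %in% cat1$id)
  }
  expect_false("ENMO(FMpre)" %in% cat1$id)
  expect_false("ENMO(FMpost)" %in% cat1$id)
  expect_true("AI(UFXYZ)" %in% cat1$id)
  expect_true("MAD(UFY)" %in% cat1$id)
  expect_true("ZCM_vm3(FXYZ)" %in% cat1$id)
  # every non-combined entry passes the applicability matrix
  app <- applicability()
  plain <- cat1[cat1$combination == "none" & cat1$metric != "AI", ]
  for (i in seq_len(nrow(plain)))
    expect_true(any(app$metric == plain$metric[i] &
                    app$dataset == plain$dataset[i]))
})

test_that("catalog manifests round-trip through CSV", {
  cat1 <- default_catalog(sweep_steps = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat1, f)
  back <- read_catalog(f)
  expect_equal(as.data.frame(back), as.data.frame(cat1))
})

test_that("one subject with two identical definitions gives a unit matrix with zero SD", {
  set.seed(44)
  v <- rnorm(100)
  sig <- list(a = activity_series(v, "MAD", "UFM"),
              b = activity_series(v, "MAD", "UFM"))
  cm <- correlation_matrix(list(sig), "time")
  expect_equal(unname(cm$mean), matrix(1, 2, 2))
  expect_equal(unname(cm$sd), matrix(0, 2, 2))
  expect_equal(cm$n_subjects, 1)
})

test_that("correlation matrices are symmetric with unit diagonal and correct cell means", {
  set.seed(45)
  subjects <- lapply(1:3, function(i) {
    x <- rnorm(200); y <- 0.5 * x + rnorm(200); z <- rnorm(200)
    list(A = activity_series(x, "MAD", "UFM"),
         B = activity_series(y, "MAD", "UFM"),
         C = activity_series(z, "MAD", "UFM"))
  })
  cm <- correlation_matrix(subjects, "time")
  expect_equal(cm$mean, t(cm$mean))
  expect_equal(unname(diag(cm$mean)), rep(1, 3))
  # cell mean equals the arithmetic mean of per-subject coefficients
  per <- vapply(subjects, function(s) pearson(s$A, s$B), numeric(1))
  expect_equal(cm$mean["A", "B"], mean(per), tolerance = 1e-12)
  expect_equal(cm$sd["A", "B"], sd(per), tolerance = 1e-12)
})

test_that("missing catalog entries raise a coverage error naming the gaps", {
  v <- rnorm(50)
  s1 <- list(A = activity_series(v, "MAD", "UFM"),
             B = activity_series(v + rnorm(50), "MAD", "UFM"))
  s2 <- list(A = activity_series(v, "MAD", "UFM"))
  err <- tryCatch(correlation_matrix(list(s1, s2), "time"), error = identity)
  expect_s3_class(err, "actimetr_coverage_error")
  expect_match(conditionMessage(err), "B")
})

test_that("constant signals become missing cells, never zero", {
  set.seed(46)
  sig <- list(A = activity_series(rnorm(64), "MAD", "UFM"),
              B = activity_series(rep(2, 64), "MAD", "UFM"))
  cm <- correlation_matrix(list(sig), "time")
  expect_true(is.na(cm$mean["A", "B"]))
  expect_equal(cm$n_effective["A", "B"], 0)
})

test_that("correlation summaries export in long and square layouts", {
  set.seed(47)
  sig <- lapply(1:2, function(i)
    list(A = activity_series(rnorm(64), "MAD", "UFM"),
         B = activity_series(rnorm(64), "MAD", "UFM")))
  cm <- correlation_matrix(sig, "time")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_correlation(cm, fl, "long")
  long <- read.csv(fl)
  expect_named(long, c("entry_a", "entry_b", "domain", "mean_r", "sd_r", "n"))
  expect_equal(nrow(long), 3)   # upper triangle incl. diagonal of a 2x2
  fs <- withr::local_tempfile(fileext = ".csv")
  write_correlation(cm, fs, "square")
  sq <- read.csv(fs, row.names = 1)
  expect_equal(dim(sq), c(2, 2))
})

test_that("frequency-domain matrices run on epoch signals", {
  set.seed(48)
  sig <- lapply(1:2, function(i) {
    x <- sin(2 * pi * seq_len(512) / 32) + rnorm(512, 0, 0.5)
    list(A = activity_series(x, "MAD", "UFM"),
         B = activity_series(x + rnorm(512, 0, 0.1), "MAD", "UFM"))
  })
  cm <- correlation_matrix(sig, "frequency",
                           psd_params = list(segment = 64, overlap = 0.5))
  expect_equal(cm$domain, "frequency")
  expect_gt(cm$mean["A", "B"], 0.9)
})
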