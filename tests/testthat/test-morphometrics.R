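test_that("generator-default morphometrics are classified as dimorphic", {
  m <- simulate_morphometrics(n1 = 34, n2 = 62, seed = 61)
  cls <- classify_morphs(m)
  expect_true(cls$dimorphic)

  st <- cls$class_stats
  mac <- st[st$class == "macropterous", ]
  mic <- st[st$class == "micropterous", ]
  expect_lt(abs(mac$mean - 1.06), 3 * 0.15 / sqrt(mac$n))
  expect_lt(abs(mic$mean - 0.26), 3 * 0.28 / sqrt(mic$n))
  # threshold sits between the class means
  expect_true(cls$threshold > mic$mean && cls$threshold < mac$mean)
  # classification mostly recovers the generating classes; the wide
  # micropterous ratio spread (sd 0.28) leaves a few percent beyond the
  # class boundary by construction
  expect_gt(mean(cls$class_label == m$true_class), 0.9)
})

test_that("degenerate and outlier-driven splits are not called dimorphic", {
  m <- data.frame(body_mm = rep(10, 12), forewing_mm = rep(5, 12))
  expect_false(classify_morphs(m)$dimorphic)

  # unimodal ratios with one extreme outlier: the outlier forms a
  # singleton cluster, which cannot establish a second morph
  set.seed(62)
  body <- rnorm(40, 10, 0.5)
  ratio <- c(rnorm(39, 1.0, 0.05), 3.0)
  m2 <- data.frame(body_mm = body, forewing_mm = ratio * body)
  expect_false(classify_morphs(m2)$dimorphic)

  expect_error(classify_morphs(data.frame(body_mm = 1, forewing_mm = 1)))
  expect_error(
    classify_morphs(data.frame(body_mm = c(0, 1), forewing_mm = c(1, 1))),
    "positive"
  )
})

test_that("classification is scale invariant", {
  m <- simulate_morphometrics(n1 = 20, n2 = 30, seed = 63)
  cls <- classify_morphs(m)
  m_scaled <- m
  m_scaled$body_mm <- m$body_mm * 17.3
  m_scaled$forewing_mm <- m$forewing_mm * 17.3
  cls_scaled <- classify_morphs(m_scaled)
  expect_identical(cls$class_label, cls_scaled$class_label)
  expect_identical(cls$dimorphic, cls_scaled$dimorphic)
})

test_that("the wing model recovers noise-free coefficients exactly", {
  set.seed(64)
  n <- 60
  dat <- data.frame(
    body_mm = runif(n, 8, 12),
    sex = sample(c("F", "M"), n, replace = TRUE),
    altitude_m = sample(c(90, 130, 200), n, replace = TRUE),
    true_class = sample(c("macropterous", "micropterous"), n, replace = TRUE)
  )
  dat$forewing_mm <- 2 + 0.2 * dat$body_mm + 0.5 * (dat$sex == "M") -
    6 * (dat$true_class == "micropterous") + 0 * dat$altitude_m
  fit <- suppressWarnings(wing_model(dat)) # "essentially perfect fit" is the point
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["body_mm"]], 0.2, tolerance = 1e-9)
  expect_equal(est[["sexM"]], 0.5, tolerance = 1e-9)
  expect_equal(est[["class_labelmicropterous"]], -6, tolerance = 1e-9)
  expect_equal(est[["altitude_m"]], 0, tolerance = 1e-9)

  # residuals orthogonal to every regressor
  mm <- stats::model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(mm, stats::resid(fit$fit)))), 1e-8)
})

test_that("constant terms are dropped without disturbing the rest", {
  set.seed(65)
  n <- 50
  dat <- data.frame(
    body_mm = runif(n, 8, 12),
    sex = sample(c("F", "M"), n, replace = TRUE),
    altitude_m = rep(130, n),
    true_class = rep(c("macropterous", "micropterous"), n / 2)
  )
  dat$forewing_mm <- 0.9 * dat$body_mm - 5 * (dat$true_class == "micropterous") +
    rnorm(n, 0, 0.1)
  expect_warning(fit <- wing_model(dat), "altitude_m")
  expect_false("altitude_m" %in% fit$coefficients$term)

  dat2 <- dat[, setdiff(names(dat), "altitude_m")]
  dat2$altitude_m <- sample(c(90, 200), n, replace = TRUE) # non-constant
  fit2 <- wing_model(dat2)
  expect_true("altitude_m" %in% fit2$coefficients$term)

  # estimates of the shared terms agree with a model never offered altitude
  keep <- c("(Intercept)", "body_mm", "sexM", "class_labelmicropterous")
  est1 <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)[keep]
  ref <- stats::lm(forewing_mm ~ body_mm + sex + true_class, data = dat)
  expect_equal(unname(est1), unname(stats::coef(ref)), tolerance = 1e-10)
})

test_that("confidence intervals have nominal coverage", {
  set.seed(66)
  hits <- matrix(FALSE, 1000, 4)
  truth <- c(body_mm = 0.2, sexM = 0.5, altitude_m = 0,
             class_labelmicropterous = -6)
  n <- 80
  for (r in 1:1000) {
    dat <- data.frame(
      body_mm = runif(n, 8, 12),
      sex = sample(c("F", "M"), n, replace = TRUE),
      altitude_m = sample(c(90, 130, 200), n, replace = TRUE),
      true_class = sample(c("macropterous", "micropterous"), n, replace = TRUE)
    )
    dat$forewing_mm <- 2 + 0.2 * dat$body_mm + 0.5 * (dat$sex == "M") -
      6 * (dat$true_class == "micropterous") + rnorm(n, 0, 0.4)
    fit <- wing_model(dat)
    co <- fit$coefficients
    half <- stats::qt(0.975, df = n - 5) * co$std_error
    lo <- co$estimate - half
    hi <- co$estimate + half
    idx <- match(names(truth), co$term)
    hits[r, ] <- truth >= lo[idx] & truth <= hi[idx]
  }
  expect_true(all(colMeans(hits) >= 0.93))
})

test_that("the morph term dominates on generator-default data", {
  m <- simulate_morphometrics(n1 = 34, n2 = 62, seed = 67)
  fit <- wing_model(m)
  co <- fit$coefficients
  t_class <- abs(co$t[co$term == "class_labelmicropterous"])
  others <- abs(co$t[!co$term %in% c("class_labelmicropterous", "(Intercept)")])
  expect_true(all(t_class > others))
})
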