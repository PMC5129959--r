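test_that("CoxModelFit invariants: HR = exp(coef), CI(HR) = exp(CI(coef))", {
  m <- trainingSpreadModel()
  expect_equal(hazardRatios(m), exp(coef(m)))
  expect_equal(exp(confint(m)), exp(confint(m, level = 0.95)))
  ## published training model round-trips its printed hazard ratios
  expect_equal(round(unname(hazardRatios(m)), 2),
               c(1.46, 2.77, 2.01, 1.72, 1.75), tolerance = 1e-12)
  expect_equal(m@n, 165)
  expect_equal(nEvents(m), 78)
})

test_that("a covariate with identical event patterns has HR near 1", {
  set.seed(40)
  d <- data.frame(time_months = rep(c(5, 10, 15, 20, 25), 2),
                  event = rep(c(1, 1, 0, 1, 0), 2),
                  x = rep(0:1, each = 5))
  fit <- fitCoxModel(d, covariates = "x")
  expect_equal(unname(coef(fit)["x"]), 0, tolerance = 1e-6)
  expect_equal(unname(hazardRatios(fit)["x"]), 1, tolerance = 1e-6)
})

test_that("fitCoxModel matches brute-force Breslow partial-likelihood maxima", {
  set.seed(41)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    d <- data.frame(time_months = round(rexp(n, 0.1), i %% 2) + 1,
                    event = rbinom(n, 1, 0.8),
                    x = rnorm(n))
    if (sum(d$event) < 2) d$event[1:2] <- 1
    fit <- try(fitCoxModel(d, covariates = "x"), silent = TRUE)
    if (inherits(fit, "try-error")) next   # separation draws are rejected
    opt <- stats::optimize(function(b)
      breslowLogLik(b, d$time_months, d$event, d$x),
      interval = c(-10, 10), maximum = TRUE, tol = 1e-9)
    expect_equal(unname(coef(fit)["x"]), opt$maximum, tolerance = 1e-4)
  }
})

test_that("the Breslow score vanishes at the reported optimum", {
  d <- generateSurvival(80, seed = 42)
  fit <- fitCoxModel(d)
  X <- as.matrix(d[, names(coef(fit))])
  g <- breslowScore(coef(fit), d$time_months, d$event, X)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("large-sample estimates are consistent", {
  d <- generateSurvival(2000, coefficients = c(x = log(2)), censorRate = 0.3,
                        seed = 43)
  fit <- fitCoxModel(d, covariates = "x")
  expect_lt(abs(coef(fit)[["x"]] - log(2)) / log(2), 0.10)
})

test_that("linearPredictor is the exact coefficient-weighted sum", {
  m <- trainingSpreadModel()
  zero <- data.frame(age_decades = 0, figo = 0, residual = 0, grade = 0,
                     predictor = 0)
  expect_equal(unname(linearPredictor(m, zero)), 0)
  a <- data.frame(age_decades = 2, figo = 1, residual = 0, grade = 1,
                  predictor = 0)
  b <- data.frame(age_decades = 4, figo = 1, residual = 1, grade = 0,
                  predictor = 1)
  ab <- a + b
  expect_equal(linearPredictor(m, ab),
               linearPredictor(m, a) + linearPredictor(m, b))
  ## worked example: 60-year-old, FIGO III, residual tumor, grade 3, high risk
  pt <- data.frame(age_decades = 6, figo = 1, residual = 1, grade = 1,
                   predictor = 1)
  expect_equal(unname(linearPredictor(m, pt)), 5.10, tolerance = 1e-12)
  expect_error(linearPredictor(m, a[, 1:3]), "lacks")
})

test_that("transfer validation fails for scrambled risk and halves for doubled effects", {
  set.seed(44)
  train <- trainingSpreadModel()
  val <- generateSurvival(2000, coefficients = coef(train), censorRate = 0.3)
  ## permuted risk scores carry no information: slope near 0, no pass
  perm <- val
  perm[, names(coef(train))] <- perm[sample(nrow(perm)),
                                     names(coef(train))]
  rv <- validateTransfer(train, perm)
  expect_lt(abs(rv$slope), 0.15)
  expect_false(rv$pass)
  ## doubling the training coefficients halves the calibration slope
  double <- coxModelFromSummary(2 * coef(train),
                                exp(2 * confint(train)), 165, 78)
  rv2 <- validateTransfer(double, val)
  expect_equal(rv2$slope, 0.5, tolerance = 0.1)
})

test_that("hrWithinCI reproduces the published validation decision", {
  train <- trainingSpreadModel()
  mkval <- function(hr) coxModelFromSummary(
    c(predictor = log(hr)),
    matrix(c(hr / 2, hr * 2), 1, dimnames = list("predictor", NULL)),
    32, 15)
  ## validation HR 2.54 lies inside the training CI 1.06-2.86
  expect_true(hrWithinCI(mkval(2.54), train, "predictor"))
  expect_false(hrWithinCI(mkval(3.0), train, "predictor"))
  expect_true(hrWithinCI(train, train, "grade"))
  expect_error(hrWithinCI(mkval(2), train, "figo"), "absent")
})

test_that("perfect separation triggers a monotone-likelihood diagnostic", {
  d <- data.frame(time_months = 1:20, event = 1,
                  x = as.integer(1:20 <= 10))
  expect_error(fitCoxModel(d, covariates = "x"), "monotone")
  expect_error(fitCoxModel(d[0, ], covariates = "x"), "event")
  d$y <- d$x * 2
  expect_error(fitCoxModel(d, covariates = c("x", "y")), "collinear")
})
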