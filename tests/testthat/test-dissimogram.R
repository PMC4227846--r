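test_that("curve evaluations match their closed forms", {
  # Gompertz at d = 0: a * exp(-b)
  expect_equal(gompertz_eval(0, 0.8, 0.5, 1e-4), 0.8 * exp(-0.5))
  expect_equal(0.8 * exp(-0.5), 0.4852245, tolerance = 1e-6)
  # b = 0: constant a
  expect_equal(gompertz_eval(c(0, 1e4, 1e6), 0.7, 0, 1e-4), rep(0.7, 3))
  # asymptote as d grows
  expect_equal(gompertz_eval(1e9, 0.85, 0.6, 1e-4), 0.85)
  # monotone non-decreasing in d for positive parameters
  d <- seq(0, 5e4, length.out = 100)
  expect_true(all(diff(gompertz_eval(d, 0.9, 1.2, 2e-4)) >= 0))

  expect_equal(negexp_eval(0, 0.9, 0.3, 1e-4), 0.6)
  expect_equal(negexp_eval(c(0, 1e5), 0.7, 0, 1e-4), rep(0.7, 2))
  expect_equal(negexp_eval(c(0, 1e5), 0.7, 0.2, 0), rep(0.5, 2))
})

test_that("noiseless model data are recovered to high precision", {
  set.seed(21)
  for (fam in c("gompertz", "negexp")) {
    evalf <- if (fam == "gompertz") gompertz_eval else negexp_eval
    for (i in 1:10) {
      a <- runif(1, 0.3, 0.95)
      b <- if (fam == "gompertz") runif(1, 0.1, 2) else runif(1, 0.05, a)
      cc <- runif(1, 1e-5, 1e-3)
      d <- sort(runif(200, 250, 45000))
      y <- evalf(d, a, b, cc)
      fit <- dissimogram(dissimilarity ~ distance,
                         data.frame(distance = d, dissimilarity = y),
                         family = fam)
      expect_true(fit$converged)
      expect_lt(max(abs(coef(fit) - c(a, b, cc))), 1e-6)
      expect_equal(fit$pseudo_r2, 1, tolerance = 1e-8)
      # nugget/asymptote consistency with the model value at d = 0
      expect_equal(nugget(fit), evalf(0, a, b, cc), tolerance = 1e-6)
      expect_equal(asymptote(fit), a, tolerance = 1e-6)
    }
  }
})

test_that("fit errors on degenerate inputs and flags flat data", {
  d <- c(100, 200, 300)
  expect_error(dissimogram(dissimilarity ~ distance,
                           data.frame(distance = d[1:2],
                                      dissimilarity = c(0.2, 0.4))),
               "at least 3")
  expect_error(dissimogram(dissimilarity ~ distance,
                           data.frame(distance = rep(500, 5),
                                      dissimilarity = runif(5))),
               "zero spread")
  flat <- dissimogram(dissimilarity ~ distance,
                      data.frame(distance = seq(250, 45000, length.out = 50),
                                 dissimilarity = rep(0.5, 50)))
  expect_true(flat$converged)
  expect_true(flat$degenerate)
  expect_equal(flat$nugget, 0.5)
  expect_equal(flat$asymptote, 0.5)
  expect_true(is.na(flat$pseudo_r2))
})

test_that("nugget and asymptote follow the family bookkeeping", {
  d <- seq(250, 45000, length.out = 100)
  g <- dissimogram(dissimilarity ~ distance,
                   data.frame(distance = d,
                              dissimilarity = gompertz_eval(d, 1, 1e-9, 1e-4)))
  expect_equal(nugget(g), 1, tolerance = 1e-4)

  ne <- dissimogram(dissimilarity ~ distance,
                    data.frame(distance = d,
                               dissimilarity = negexp_eval(d, 0.7, 0.7, 1e-4)),
                    family = "negexp")
  expect_equal(nugget(ne), 0, tolerance = 1e-6)
  expect_equal(asymptote(ne), 0.7, tolerance = 1e-6)

  bad <- g
  bad$converged <- FALSE
  expect_error(nugget(bad), "did not converge")
})

test_that("gompertz nugget < asymptote whenever b > 0", {
  set.seed(33)
  for (i in 1:20) {
    a <- runif(1, 0.3, 0.95); b <- runif(1, 0.05, 2); cc <- runif(1, 1e-5, 1e-3)
    d <- sort(runif(150, 250, 45000))
    y <- gompertz_eval(d, a, b, cc) + rnorm(150, 0, 0.02)
    fit <- dissimogram(dissimilarity ~ distance,
                       data.frame(distance = d, dissimilarity = y))
    if (fit$converged && coef(fit)[["b"]] > 0) {
      expect_lt(nugget(fit), asymptote(fit))
    }
  }
})

test_that("fit is invariant to row order", {
  set.seed(12)
  d <- runif(300, 250, 45000)
  y <- gompertz_eval(d, 0.8, 0.7, 1.5e-4) + rnorm(300, 0, 0.1)
  dat <- data.frame(distance = d, dissimilarity = y)
  f1 <- dissimogram(dissimilarity ~ distance, dat)
  f2 <- dissimogram(dissimilarity ~ distance, dat[sample(300), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(nugget(f1), nugget(f2), tolerance = 1e-9)
})

test_that("pseudo-R2 equals an independent correlation computation", {
  set.seed(99)
  d <- runif(1225, 250, 45000)
  y <- gompertz_eval(d, 0.8, 0.6, 1e-4) + rnorm(1225, 0, 0.3)
  fit <- dissimogram(dissimilarity ~ distance,
                     data.frame(distance = d, dissimilarity = y))
  # two-pass oracle: standardize both series explicitly, average products
  f <- fitted(fit)
  zf <- (f - mean(f)) / sd(f)
  zy <- (y - mean(y)) / sd(y)
  oracle <- (sum(zf * zy) / (length(y) - 1))^2
  expect_equal(pseudo_r2(fit), oracle, tolerance = 1e-12)
  expect_gte(pseudo_r2(fit), 0)
  expect_lte(pseudo_r2(fit), 1)
})

test_that("validity flag applies the nugget range rule", {
  d <- seq(250, 45000, length.out = 100)
  fit <- dissimogram(dissimilarity ~ distance,
                     data.frame(distance = d,
                                dissimilarity = gompertz_eval(d, 0.8, 0.2, 1e-4)))
  expect_true(validate_fit(fit)$valid)

  # force an out-of-range nugget
  fit$nugget <- 1.2
  expect_false(validate_fit(fit)$valid)
  fit$nugget <- -0.1
  expect_false(validate_fit(fit)$valid)
  fit$nugget <- 0.66
  fit$converged <- FALSE
  expect_false(validate_fit(fit)$valid)
})

test_that("gauss-newton matches minpack.lm on noisy data", {
  skip_if_not_installed("minpack.lm")
  set.seed(4)
  d <- runif(400, 250, 45000)
  y <- gompertz_eval(d, 0.75, 0.8, 2e-4) + rnorm(400, 0, 0.15)
  fit <- dissimogram(dissimilarity ~ distance,
                     data.frame(distance = d, dissimilarity = y))
  ref <- minpack.lm::nlsLM(y ~ a * exp(-b * exp(-cc * dk)),
                           data = data.frame(dk = d / 1000, y = y),
                           start = list(a = 0.7, b = 0.5, cc = 0.2))
  rss_ref <- sum(residuals(ref)^2)
  expect_lte(fit$rss, rss_ref + 1e-8)
})

test_that("predict, residuals and simulate behave like a model object", {
  set.seed(8)
  d <- runif(100, 250, 45000)
  y <- gompertz_eval(d, 0.8, 0.6, 1e-4) + rnorm(100, 0, 0.05)
  fit <- dissimogram(dissimilarity ~ distance,
                     data.frame(distance = d, dissimilarity = y))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, data.frame(distance = 0)), nugget(fit),
               tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), y)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(100L, 3L))
  expect_output(print(fit), "Dissimogram fit")
  expect_output(print(summary(fit)), "residual sd")
})
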