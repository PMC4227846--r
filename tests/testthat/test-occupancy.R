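# exhaustive enumeration of P(history) over all 0/1 histories of length T
enumerate_single <- function(T_, psi, p) {
  hist_grid <- as.matrix(expand.grid(rep(list(0:1), T_)))
  vapply(seq_len(nrow(hist_grid)), function(i) {
    exp(single_season_loglik(matrix(hist_grid[i, ], 1), psi, p))
  }, numeric(1L))
}

test_that("single-season likelihood matches its closed form", {
  # all-zero history, T = 2: psi (1-p)^2 + (1-psi)
  expect_equal(exp(single_season_loglik(matrix(c(0, 0), 1), 0.5, 0.5)),
               0.5 * 0.25 + 0.5)
  # psi = 1, T = 1, one detection: just p
  expect_equal(exp(single_season_loglik(matrix(1, 1), 1, 0.3)), 0.3)
  # impossible event handled as a floor, not -Inf
  ll <- single_season_loglik(matrix(c(1, 0), 1), 0.5, 1)
  expect_true(is.finite(ll))
  expect_lt(ll, -600)
  expect_error(single_season_loglik(matrix(1, 1), 1.2, 0.5), "\\[0, 1\\]")
})

test_that("likelihood sums to 1 over all possible histories (T <= 4)", {
  for (T_ in 2:4) {
    for (par in list(c(0.3, 0.7), c(0.57, 0.5), c(0.9, 0.2))) {
      expect_equal(sum(enumerate_single(T_, par[1], par[2])), 1,
                   tolerance = 1e-12)
    }
  }
  # multi-season: sum over all season-1 x season-2 histories
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (i in seq_len(nrow(grid))) {
    h <- array(grid[i, ], dim = c(1, 2, 2))
    total <- total + exp(multi_season_loglik(h, 0.6, 0.3, 0.2, 0.45))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("one-season dynamic likelihood equals the single-season form", {
  set.seed(31)
  h <- matrix(rbinom(40, 1, 0.4), nrow = 10)
  h3 <- array(h, dim = c(10, 1, 4))
  for (par in list(c(0.5, 0.5), c(0.2, 0.8), c(0.9, 0.1))) {
    expect_identical(multi_season_loglik(h3, par[1], 0.3, 0.6, par[2]),
                     single_season_loglik(h, par[1], par[2]))
  }
})

test_that("static dynamic model matches latent-state enumeration", {
  # epsilon = gamma = 0: occupancy fixed over seasons; brute-force sum over
  # the latent state z in {0, 1} per plot
  set.seed(5)
  h <- array(rbinom(18, 1, 0.5), dim = c(3, 3, 2))
  psi <- 0.6; p <- 0.4
  oracle <- 0
  for (i in 1:3) {
    lik_z1 <- prod(p^h[i, , ] * (1 - p)^(1 - h[i, , ]))
    lik_z0 <- as.numeric(all(h[i, , ] == 0))
    oracle <- oracle + log(psi * lik_z1 + (1 - psi) * lik_z0)
  }
  expect_equal(multi_season_loglik(h, psi, 0, 0, p), oracle,
               tolerance = 1e-12)
})

test_that("p = 0 makes the likelihood independent of the data", {
  h1 <- array(0L, dim = c(4, 2, 3))
  h2 <- h1; h2[1, 1, 1] <- 1L
  # with p = 0, detections are impossible: all-zero data get the same value
  # regardless of psi-path, and any detection hits the floor
  expect_equal(multi_season_loglik(h1, 0.5, 0.3, 0.2, 0), 0,
               tolerance = 1e-12)
  expect_lt(multi_season_loglik(h2, 0.5, 0.3, 0.2, 0), -600)
})

test_that("missing occasions are skipped in the likelihood", {
  h_full <- matrix(c(1, 0, 1), 1)
  h_miss <- matrix(c(1, NA, 0, 1), 1)
  expect_equal(single_season_loglik(h_miss, 0.6, 0.4),
               single_season_loglik(h_full, 0.6, 0.4))
})

test_that("single-season MLE matches a dense grid-search oracle", {
  set.seed(17)
  h <- matrix(rbinom(8, 1, 0.6), nrow = 2)  # tiny instance: 2 plots x 4 occ.
  fit <- fit_occupancy(h, model = "single")
  grid <- seq(0.0025, 0.9975, length.out = 200)
  best <- -Inf; best_par <- c(NA, NA)
  for (psi in grid) for (p in grid) {
    ll <- single_season_loglik(h, psi, p)
    if (ll > best) { best <- ll; best_par <- c(psi, p) }
  }
  res <- diff(grid)[1]
  expect_gte(fit$loglik, best - 1e-8)  # MLE at least as good as the grid
  if (!fit$boundary) {
    expect_lt(abs(fit$psi - best_par[1]), res)
    expect_lt(abs(fit$p - best_par[2]), res)
  }
})

test_that("occupancy parameters are recovered from simulated histories", {
  set.seed(23)
  psi <- 0.6; p <- 0.5
  z <- rbinom(150, 1, psi)
  h <- matrix(rbinom(150 * 5, 1, p), nrow = 150) * z
  fit <- fit_occupancy(h, model = "single")
  expect_true(fit$converged)
  expect_lt(abs(fit$psi - psi), 0.07)
  expect_lt(abs(fit$p - p), 0.07)
  # log-likelihood at the MLE dominates the truth
  expect_gte(fit$loglik, single_season_loglik(h, psi, p) - 1e-8)
})

test_that("multi-season fit recovers dynamic occupancy parameters", {
  set.seed(61)
  n <- 60; seasons <- 4; occ <- 3
  psi1 <- 0.6; gamma <- 0.2; epsilon <- 0.3; p <- 0.6
  z <- matrix(0L, n, seasons)
  z[, 1] <- rbinom(n, 1, psi1)
  for (t in 2:seasons) {
    z[, t] <- ifelse(z[, t - 1] == 1, rbinom(n, 1, 1 - epsilon),
                     rbinom(n, 1, gamma))
  }
  h <- array(0L, dim = c(n, seasons, occ))
  for (t in seq_len(seasons)) {
    h[, t, ] <- matrix(rbinom(n * occ, 1, p), n) * z[, t]
  }
  fit <- fit_occupancy(h, model = "multi")
  expect_true(fit$converged)
  # loose recovery bounds: 60 plots give limited information
  expect_lt(abs(fit$psi - psi1), 0.15)
  expect_lt(abs(fit$p - p), 0.1)
  expect_lt(abs(fit$gamma - gamma), 0.15)
  expect_lt(abs(fit$epsilon - epsilon), 0.2)
  # MLE dominates the generating parameters
  expect_gte(fit$loglik,
             multi_season_loglik(h, psi1, gamma, epsilon, p) - 1e-8)
})

test_that("boundary data give flagged boundary estimates, not errors", {
  h <- matrix(1L, nrow = 5, ncol = 4)
  fit <- fit_occupancy(h, model = "single")
  expect_true(fit$boundary)
  expect_gt(fit$psi, 0.99)
  expect_gt(fit$p, 0.99)

  h0 <- matrix(0L, nrow = 5, ncol = 4)
  fit0 <- fit_occupancy(h0, model = "single")
  expect_true(fit0$boundary)
})

test_that("MLE is invariant to plot order", {
  set.seed(41)
  h <- matrix(rbinom(60, 1, 0.4), nrow = 15)
  f1 <- fit_occupancy(h, model = "single")
  f2 <- fit_occupancy(h[sample(15), ], model = "single")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("detection histories are built from survey records", {
  tab <- tiny_surveys()
  h <- build_histories(tab, "s1", n_rounds = 3)
  # s1 detected at A in 2008 rounds 1 and 2, not round 3
  expect_equal(unname(h["A", "2008", ]), c(1L, 1L, 0L))
  expect_equal(unname(h["B", "2008", ]), c(1L, 0L, 0L))
  # species never recorded -> all zero
  expect_true(all(build_histories(tab, "ghost", n_rounds = 3) == 0L))
  # unsurveyed occasions marked missing
  sv <- expand.grid(plot_id = c("A", "B"), year = c(2008L, 2009L),
                    round = 1:2, stringsAsFactors = FALSE)
  hm <- build_histories(tab, "s1", n_rounds = 3, surveyed = sv)
  expect_true(all(is.na(hm[, , 3])))
  expect_equal(unname(hm["A", "2008", 1:2]), c(1L, 1L))
})

test_that("detectability summary averages psi over converged fits", {
  f <- function(psi) {
    structure(list(psi = psi, p = 0.5, gamma = NA_real_,
                   epsilon = NA_real_, loglik = -10, converged = TRUE,
                   boundary = FALSE, model = "single", n_histories = 10L),
              class = "occupancy_fit")
  }
  sm <- summarize_detectability(list(a = f(0.5), b = f(0.6), c = f(0.64)))
  expect_equal(sm$mean_psi, 0.58)
  expect_equal(sm$n_converged, 3L)
  sm1 <- summarize_detectability(list(only = f(0.4)))
  expect_equal(sm1$mean_psi, 0.4)
  bad <- f(0.5); bad$converged <- FALSE
  expect_error(summarize_detectability(list(bad)), "no converged")
})
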