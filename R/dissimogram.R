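#' Dissimogram model curves
#'
#' Evaluate the two distance-decay curve families used to model pairwise
#' community dissimilarity as a function of geographic distance.
#'
#' The Gompertz curve is \eqn{a e^{-b e^{-c d}}}: its value at d = 0 (the
#' nugget) is \eqn{a e^{-b}} and its limit as d grows (the asymptote) is a.
#' The negative-exponential curve is \eqn{a - b e^{-c d}}, with nugget
#' \eqn{a - b} and asymptote a.
#'
#' @param d distance (meters); vectorized.
#' @param a asymptotic dissimilarity.
#' @param b shape parameter (dimensionless).
#' @param c decay rate per meter.
#' @return fitted dissimilarity, same length as \code{d}.
#' @export
gompertz_eval <- function(d, a, b, c) {
  a * exp(-b * exp(-c * d))
}

#' @rdname gompertz_eval
#' @export
negexp_eval <- function(d, a, b, c) {
  a - b * exp(-c * d)
}

## Residuals and analytic Jacobian for one family; distances in km
## internally so that c is O(0.01..1) and the normal equations are
## well conditioned.
.model_fn <- function(family) {
  switch(family,
    gompertz = list(
      f = function(d, th) {
        e <- exp(pmax(pmin(-th[3L] * d, 700), -700))
        th[1L] * exp(pmax(pmin(-th[2L] * e, 700), -700))
      },
      jac = function(d, th) {
        e <- exp(pmax(pmin(-th[3L] * d, 700), -700))
        g <- exp(pmax(pmin(-th[2L] * e, 700), -700))
        cbind(g, -th[1L] * e * g, th[1L] * th[2L] * d * e * g)
      }
    ),
    negexp = list(
      f = function(d, th) {
        th[1L] - th[2L] * exp(pmax(pmin(-th[3L] * d, 700), -700))
      },
      jac = function(d, th) {
        e <- exp(pmax(pmin(-th[3L] * d, 700), -700))
        cbind(rep(1, length(d)), -e, th[2L] * d * e)
      }
    ),
    stop("unknown family: ", family)
  )
}

## Gauss-Newton least squares with Levenberg-style damping when a step
## fails to reduce the residual sum of squares. Converged when the
## relative RSS reduction or the parameter step falls below `tol`.
gauss_newton <- function(d, y, family, start, max_iter = 200L, tol = 1e-10) {
  mf <- .model_fn(family)
  th <- as.numeric(start)
  r <- y - mf$f(d, th)
  rss <- sum(r * r)
  lambda <- 0
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    J <- mf$jac(d, th)
    if (any(!is.finite(J)) || any(!is.finite(r))) break
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:30) {
      A <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), 3L)
      step <- tryCatch(drop(solve(A, Jtr)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        lambda <- max(lambda * 10, 1e-8)
        next
      }
      th_new <- th + step
      r_new <- y - mf$f(d, th_new)
      rss_new <- sum(r_new * r_new)
      if (is.finite(rss_new) && rss_new <= rss) {
        step_size <- max(abs(step))
        rel_red <- (rss - rss_new) / max(rss_new, 1e-300)
        th <- th_new; r <- r_new; rss <- rss_new
        lambda <- lambda / 10
        if (lambda < 1e-12) lambda <- 0
        improved <- TRUE
        if (rel_red < tol || step_size < tol) converged <- TRUE
        break
      }
      lambda <- max(lambda * 10, 1e-8)
    }
    if (!improved) {
      ## damping exhausted: we are at a (local) least-squares solution
      converged <- TRUE
      break
    }
    if (converged) break
  }
  list(par = th, rss = rss, iterations = it, converged = converged)
}

## Multi-start initial values (distances in km)
.dissimogram_starts <- function(d, y, family) {
  a0 <- as.numeric(stats::quantile(y, 0.95, names = FALSE))
  if (a0 <= 0) a0 <- max(y, 0.1)
  c0 <- unique(c(1 / stats::median(d), 1 / max(d), 10 / max(d)))
  if (family == "gompertz") {
    ## the negative start makes decreasing/flat curves reachable, so fits
    ## to spatially unstructured data are not biased toward increasing ones
    b0 <- c(-0.5, 0.1, 0.5, 1, 2)
  } else {
    b0 <- c(-1, 1) * max(a0 - min(y), 1e-3)
  }
  starts <- expand.grid(a = a0, b = b0, c = c0, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(starts)), function(i) as.numeric(starts[i, ]))
}

#' Fit a dissimogram: community dissimilarity against geographic distance
#'
#' Fits a non-linear least-squares curve through the pairwise dissimilarity
#' versus distance scatter by the Gauss-Newton algorithm (with
#' Levenberg-style damping when a step fails to reduce the residual sum of
#' squares, and multiple starting values). The fitted y-intercept -- the
#' \emph{nugget} -- is the compositional dissimilarity remaining at zero
#' geographic distance and is interpreted as the fraction of community
#' composition driven by spatially unpredictable (random) processes; the
#' fitted maximum -- the \emph{asymptote} -- is the dissimilarity at
#' infinite distance.
#'
#' Distances are rescaled to kilometers internally for numerical
#' conditioning; the decay rate \code{c} is reported back in per-meter
#' units. No box constraints are imposed during optimization; fits whose
#' nugget falls outside [0, 1] are flagged invalid (\code{valid = FALSE})
#' rather than constrained, mirroring post-hoc exclusion of poorly fitting
#' models.
#'
#' @param formula model formula of the form \code{dissimilarity ~ distance}
#'   with distance in meters.
#' @param data a \code{pair_table} from [build_pair_table()] or any data
#'   frame containing the formula variables.
#' @param family curve family: \code{"gompertz"} (\eqn{a e^{-b e^{-c d}}})
#'   or \code{"negexp"} (\eqn{a - b e^{-c d}}).
#' @param max_iter maximum Gauss-Newton iterations per start (default 200).
#' @param tol convergence tolerance on the relative RSS reduction and the
#'   parameter step (default 1e-10).
#' @return an object of class \code{dissimogram}: a list with components
#'   \code{coefficients} (a, b, c; c per meter), \code{nugget},
#'   \code{asymptote}, \code{pseudo_r2}, \code{converged}, \code{valid},
#'   \code{n_pairs}, \code{iterations}, \code{fitted.values},
#'   \code{residuals}, \code{family}, \code{data}.
#' @seealso [nugget()], [asymptote()], [pseudo_r2()], [validate_fit()]
#' @examples
#' d <- seq(250, 45000, length.out = 200)
#' y <- gompertz_eval(d, a = 0.85, b = 0.6, c = 1e-4)
#' fit <- dissimogram(dissimilarity ~ distance,
#'                    data = data.frame(distance = d, dissimilarity = y))
#' nugget(fit)
#' @export
dissimogram <- function(formula = dissimilarity ~ distance, data,
                        family = c("gompertz", "negexp"),
                        max_iter = 200L, tol = 1e-10) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(mf[[1L]])
  d_m <- as.numeric(mf[[2L]])
  keep <- is.finite(y) & is.finite(d_m)
  y <- y[keep]; d_m <- d_m[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 pairs to fit a dissimogram")
  if (diff(range(d_m)) <= 0) {
    stop("zero spread in distances: decay rate is unidentifiable")
  }
  d <- d_m / 1000  # km internally

  if (stats::sd(y) == 0) {
    ## constant dissimilarity: b = 0 gives the exact flat curve; c is
    ## unidentifiable and reported as 0
    fitted_v <- rep(y[1L], n)
    return(structure(list(
      coefficients = c(a = y[1L], b = 0, c = 0),
      family = family, nugget = y[1L], asymptote = y[1L],
      pseudo_r2 = NA_real_, converged = TRUE, valid = y[1L] >= 0 && y[1L] <= 1,
      degenerate = TRUE, n_pairs = n, iterations = 0L, rss = 0,
      fitted.values = fitted_v, residuals = y - fitted_v,
      data = data.frame(distance = d_m, dissimilarity = y),
      call = match.call()
    ), class = "dissimogram"))
  }

  starts <- .dissimogram_starts(d, y, family)
  fits <- lapply(starts, function(s) {
    gauss_newton(d, y, family, s, max_iter = max_iter, tol = tol)
  })
  conv <- vapply(fits, `[[`, logical(1L), "converged")
  pool <- if (any(conv)) fits[conv] else fits
  rank <- order(vapply(pool, `[[`, numeric(1L), "rss"),
                vapply(pool, `[[`, integer(1L), "iterations"))
  best <- pool[[rank[1L]]]

  th <- unname(best$par)
  fitted_v <- .model_fn(family)$f(d, th)
  nug <- if (family == "gompertz") th[1L] * exp(-th[2L]) else th[1L] - th[2L]
  asym <- th[1L]
  pr2 <- if (stats::sd(fitted_v) > 0 && stats::sd(y) > 0) {
    as.numeric(stats::cor(fitted_v, y)^2)
  } else {
    NA_real_
  }
  degenerate <- stats::sd(y) == 0
  converged <- best$converged
  valid <- isTRUE(converged) && is.finite(nug) && nug >= 0 && nug <= 1

  structure(list(
    coefficients = c(a = th[1L], b = th[2L], c = th[3L] / 1000),
    family = family,
    nugget = as.numeric(nug),
    asymptote = as.numeric(asym),
    pseudo_r2 = pr2,
    converged = converged,
    valid = valid,
    degenerate = degenerate,
    n_pairs = n,
    iterations = best$iterations,
    rss = best$rss,
    fitted.values = fitted_v,
    residuals = y - fitted_v,
    data = data.frame(distance = d_m, dissimilarity = y),
    call = match.call()
  ), class = "dissimogram")
}

#' Fit a dissimogram from a pair table
#'
#' Convenience wrapper around [dissimogram()] for the standard pair-table
#' columns \code{distance_m} and \code{dissimilarity}.
#'
#' @param pairs a \code{pair_table} from [build_pair_table()].
#' @param ... further arguments passed to [dissimogram()].
#' @inheritParams dissimogram
#' @return a \code{dissimogram} fit object.
#' @export
fit_dissimogram <- function(pairs, family = c("gompertz", "negexp"), ...) {
  stopifnot(is.data.frame(pairs))
  dat <- data.frame(distance = pairs$distance_m,
                    dissimilarity = pairs$dissimilarity)
  dissimogram(dissimilarity ~ distance, data = dat,
              family = match.arg(family), ...)
}

#' Nugget of a fitted dissimogram
#'
#' The model value at zero distance: \eqn{a e^{-b}} for the Gompertz family
#' and \eqn{a - b} for the negative exponential.
#'
#' @param object a fitted model.
#' @param ... further arguments (unused).
#' @return the nugget (dissimilarity at d = 0).
#' @export
nugget <- function(object, ...) UseMethod("nugget")

#' @rdname nugget
#' @export
nugget.dissimogram <- function(object, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge: nugget undefined")
  object$nugget
}

#' Asymptote of a fitted dissimogram
#'
#' @inheritParams nugget
#' @return the fitted maximum dissimilarity (parameter a).
#' @export
asymptote <- function(object, ...) UseMethod("asymptote")

#' @rdname asymptote
#' @export
asymptote.dissimogram <- function(object, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge: asymptote undefined")
  object$asymptote
}

#' Pseudo-R-squared of a non-linear fit
#'
#' The squared Pearson correlation between the model fitted values and the
#' observed dissimilarities; a goodness-of-fit proxy for non-linear models.
#' Undefined (NA) when the fitted values are constant.
#'
#' @param object a fitted \code{dissimogram}.
#' @param pairs optional data to evaluate against; defaults to the data the
#'   model was fitted to.
#' @return squared correlation in [0, 1], or NA.
#' @export
pseudo_r2 <- function(object, pairs = NULL) {
  stopifnot(inherits(object, "dissimogram"))
  if (!isTRUE(object$converged)) stop("fit did not converge")
  if (is.null(pairs)) return(object$pseudo_r2)
  d <- if (!is.null(pairs$distance_m)) pairs$distance_m else pairs$distance
  y <- pairs$dissimilarity
  f <- predict(object, data.frame(distance = d))
  if (stats::sd(f) == 0 || stats::sd(y) == 0) return(NA_real_)
  as.numeric(stats::cor(f, y)^2)
}

#' Re-apply the nugget validity rule to a fit
#'
#' A fit is valid when it converged and its nugget lies in [0, 1]; nuggets
#' outside that range indicate a poorly fitting model and are excluded from
#' downstream summaries (reported as "n/a").
#'
#' @param fit a \code{dissimogram} object.
#' @return the fit with its \code{valid} flag recomputed.
#' @export
validate_fit <- function(fit) {
  stopifnot(inherits(fit, "dissimogram"))
  fit$valid <- isTRUE(fit$converged) && is.finite(fit$nugget) &&
    fit$nugget >= 0 && fit$nugget <= 1
  fit
}

#' @export
coef.dissimogram <- function(object, ...) object$coefficients

#' @export
fitted.dissimogram <- function(object, ...) object$fitted.values

#' @export
residuals.dissimogram <- function(object, ...) object$residuals

#' @export
logLik.dissimogram <- function(object, ...) {
  n <- object$n_pairs
  val <- -n / 2 * (log(2 * pi) + log(object$rss / n) + 1)
  structure(val, df = 4L, nobs = n, class = "logLik")
}

#' @export
predict.dissimogram <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  d <- if (!is.null(newdata$distance)) newdata$distance else newdata$distance_m
  th <- object$coefficients
  if (object$family == "gompertz") {
    gompertz_eval(d, th[["a"]], th[["b"]], th[["c"]])
  } else {
    negexp_eval(d, th[["a"]], th[["b"]], th[["c"]])
  }
}

#' @export
print.dissimogram <- function(x, digits = 4L, ...) {
  cat("Dissimogram fit (", x$family, " family), ", x$n_pairs, " pairs\n",
      sep = "")
  print(round(x$coefficients, 8L))
  cat("nugget:", format(round(x$nugget, digits), nsmall = digits),
      " asymptote:", format(round(x$asymptote, digits), nsmall = digits),
      " pseudo-R2:",
      if (is.na(x$pseudo_r2)) "n/a" else format(round(x$pseudo_r2, 3L)), "\n")
  cat("converged:", x$converged, " valid:", x$valid, "\n")
  invisible(x)
}

#' @export
summary.dissimogram <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(object$rss / max(object$n_pairs - 3L, 1L)),
                 dist_range = range(object$data$distance)),
            class = "summary.dissimogram")
}

#' @export
print.summary.dissimogram <- function(x, ...) {
  print(x$fit)
  cat("residual sd:", format(round(x$sigma, 4L)),
      " distance range (m):", paste(round(x$dist_range), collapse = " - "),
      "\n")
  invisible(x)
}

#' @export
plot.dissimogram <- function(x, ...) {
  graphics::plot(x$data$distance, x$data$dissimilarity,
                 xlab = "distance (m)", ylab = "Jaccard dissimilarity (1 - D')",
                 pch = 16, cex = 0.4, col = "grey40", ...)
  dd <- seq(min(x$data$distance), max(x$data$distance), length.out = 200)
  graphics::lines(dd, predict(x, data.frame(distance = dd)), lwd = 2)
  graphics::abline(h = x$nugget, lty = 3)
  invisible(x)
}

#' @export
simulate.dissimogram <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$rss / max(object$n_pairs - 3L, 1L))
  n <- object$n_pairs
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
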