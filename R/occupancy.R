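#' Build detection histories for one species
#'
#' Converts survey records into per-plot binary detection histories (1 if
#' the species was recorded with count > 0 at that plot, year and round).
#' Occasions not surveyed can be marked via \code{surveyed}; they enter the
#' histories as NA and contribute no emission term to the likelihoods.
#'
#' @param tab survey table (see [read_surveys()]).
#' @param species species identifier; a species never recorded yields
#'   all-zero histories.
#' @param plots,years plot and year universes (default: all in \code{tab}).
#' @param n_rounds occasions per season (default 5).
#' @param surveyed optional \code{data.frame} with columns \code{plot_id},
#'   \code{year}, \code{round} listing the occasions actually surveyed;
#'   when supplied, unlisted occasions are NA.
#' @return a 3-d array [plots x years x rounds] of 0/1/NA.
#' @export
build_histories <- function(tab, species, plots = NULL, years = NULL,
                            n_rounds = 5L, surveyed = NULL) {
  if (is.null(plots)) plots <- sort(unique(tab$plot_id))
  if (is.null(years)) years <- sort(unique(tab$year))
  h <- array(0L, dim = c(length(plots), length(years), n_rounds),
             dimnames = list(plots, years, seq_len(n_rounds)))
  if (!is.null(surveyed)) {
    h[] <- NA_integer_
    idx <- cbind(match(surveyed$plot_id, plots),
                 match(surveyed$year, years),
                 surveyed$round)
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    h[idx] <- 0L
  }
  det <- tab[tab$species == species & tab$count > 0, , drop = FALSE]
  if (nrow(det) > 0L) {
    idx <- cbind(match(det$plot_id, plots), match(det$year, years), det$round)
    keep <- stats::complete.cases(idx)
    h[idx[keep, , drop = FALSE]] <- 1L
  }
  h
}

.check_prob <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
}

#' Single-season occupancy log-likelihood
#'
#' The MacKenzie closed form with constant occupancy (psi) and detection
#' (p): histories with at least one detection contribute
#' \eqn{\psi p^y (1-p)^{T-y}}; all-zero histories contribute
#' \eqn{\psi (1-p)^T + (1-\psi)} (either occupied-but-missed or truly
#' absent). Zero-probability histories are floored rather than returning
#' -Inf.
#'
#' @param histories matrix of 0/1/NA detections, plots x occasions.
#' @param psi occupancy probability in [0, 1].
#' @param p per-occasion detection probability in [0, 1].
#' @return total log-likelihood over plots.
#' @export
single_season_loglik <- function(histories, psi, p) {
  .check_prob(psi, p)
  if (is.null(dim(histories))) histories <- matrix(histories, nrow = 1L)
  obs <- !is.na(histories)
  T_ <- rowSums(obs)
  y <- rowSums(histories == 1L & obs, na.rm = TRUE)
  e1 <- p^y * (1 - p)^(T_ - y)
  e0 <- as.numeric(y == 0L)
  sum(log(pmax(psi * e1 + (1 - psi) * e0, 1e-300)))
}

#' Dynamic (multi-season) occupancy log-likelihood
#'
#' Forward recursion over the latent occupancy state: first-season
#' occupancy \code{psi1}, between-season colonization \code{gamma} and
#' extinction \code{epsilon}, and constant per-occasion detection \code{p}.
#' With a single season this reduces exactly to [single_season_loglik()].
#'
#' @param histories 3-d array [plots x seasons x occasions] of 0/1/NA.
#' @param psi1 first-season occupancy probability.
#' @param gamma colonization probability between consecutive seasons.
#' @param epsilon extinction probability between consecutive seasons.
#' @param p per-occasion detection probability.
#' @return total log-likelihood over plots.
#' @export
multi_season_loglik <- function(histories, psi1, gamma, epsilon, p) {
  .check_prob(psi1, gamma, epsilon, p)
  if (length(dim(histories)) == 2L) {
    histories <- array(histories, dim = c(dim(histories)[1L], 1L,
                                          dim(histories)[2L]))
  }
  stopifnot(length(dim(histories)) == 3L)
  n <- dim(histories)[1L]
  n_seasons <- dim(histories)[2L]
  trans <- rbind(c(1 - gamma, gamma), c(epsilon, 1 - epsilon))
  obs <- !is.na(histories)
  T_ <- apply(obs, c(1L, 2L), sum)
  y <- apply(histories == 1L & obs, c(1L, 2L), sum)
  alpha <- cbind(rep(1 - psi1, n), rep(psi1, n))
  for (t in seq_len(n_seasons)) {
    e1 <- p^y[, t] * (1 - p)^(T_[, t] - y[, t])
    e0 <- as.numeric(y[, t] == 0L)
    alpha <- alpha * cbind(e0, e1)
    if (t < n_seasons) alpha <- alpha %*% trans
  }
  sum(log(pmax(rowSums(alpha), 1e-300)))
}

#' Fit an occupancy-detection model
#'
#' Maximum-likelihood estimation of constant occupancy and detection
#' parameters (plus colonization and extinction for the dynamic model)
#' from repeated-survey detection histories. Optimization runs on the
#' logit scale (BFGS) from a grid of starting values (each probability
#' started at 0.2, 0.5 and 0.8); the best converged start wins. Data with
#' no detections anywhere drive the estimates to the boundary, which is
#' flagged rather than raised as an error.
#'
#' @param histories detection histories: a plots x occasions matrix for
#'   the single-season model, or a [plots x seasons x occasions] array for
#'   the multi-season model.
#' @param model \code{"single"} or \code{"multi"}.
#' @param tol convergence tolerance passed to \code{optim} (reltol).
#' @return an object of class \code{occupancy_fit} with components
#'   \code{psi}, \code{p}, \code{gamma}, \code{epsilon} (NA for the
#'   single-season model), \code{loglik}, \code{converged},
#'   \code{boundary}, \code{model}.
#' @export
fit_occupancy <- function(histories, model = c("single", "multi"),
                          tol = 1e-8) {
  model <- match.arg(model)
  if (model == "single") {
    if (length(dim(histories)) == 3L) {
      ## collapse seasons x occasions into one occasion axis
      histories <- matrix(histories, nrow = dim(histories)[1L])
    }
    obj <- function(par) {
      -single_season_loglik(histories, stats::plogis(par[1L]),
                            stats::plogis(par[2L]))
    }
    grid <- stats::qlogis(as.matrix(expand.grid(psi = c(0.2, 0.5, 0.8),
                                                p = c(0.2, 0.5, 0.8))))
  } else {
    if (length(dim(histories)) == 2L) {
      histories <- array(histories, dim = c(dim(histories)[1L], 1L,
                                            dim(histories)[2L]))
    }
    obj <- function(par) {
      -multi_season_loglik(histories, stats::plogis(par[1L]),
                           stats::plogis(par[2L]), stats::plogis(par[3L]),
                           stats::plogis(par[4L]))
    }
    grid <- stats::qlogis(as.matrix(expand.grid(psi = c(0.2, 0.5, 0.8),
                                                gamma = c(0.2, 0.5, 0.8),
                                                epsilon = c(0.2, 0.5, 0.8),
                                                p = c(0.2, 0.5, 0.8))))
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      stats::optim(grid[i, ], obj, method = "BFGS",
                   control = list(reltol = tol, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best)) stop("occupancy optimization failed from every start")
  est <- stats::plogis(best$par)
  boundary <- any(est < 1e-4 | est > 1 - 1e-4)
  out <- list(
    psi = unname(est[1L]),
    p = unname(est[length(est)]),
    gamma = if (model == "multi") unname(est[2L]) else NA_real_,
    epsilon = if (model == "multi") unname(est[3L]) else NA_real_,
    loglik = -best$value,
    converged = best$convergence == 0L || boundary,
    boundary = boundary,
    model = model,
    n_histories = dim(histories)[1L]
  )
  class(out) <- "occupancy_fit"
  out
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Occupancy-detection fit (", x$model, "-season), ",
      x$n_histories, " histories\n", sep = "")
  cat(sprintf("  psi = %.4f  p = %.4f", x$psi, x$p))
  if (x$model == "multi") {
    cat(sprintf("  gamma = %.4f  epsilon = %.4f", x$gamma, x$epsilon))
  }
  cat(sprintf("\n  logLik = %.4f  converged: %s%s\n", x$loglik, x$converged,
              if (x$boundary) "  (boundary estimate)" else ""))
  invisible(x)
}

#' @export
logLik.occupancy_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$model == "multi") 4L else 2L,
            nobs = object$n_histories, class = "logLik")
}

#' @export
coef.occupancy_fit <- function(object, ...) {
  if (object$model == "multi") {
    c(psi = object$psi, gamma = object$gamma, epsilon = object$epsilon,
      p = object$p)
  } else {
    c(psi = object$psi, p = object$p)
  }
}

#' Summarize per-species detectability
#'
#' Arithmetic mean and quantiles of the occupancy estimates (psi-hat) over
#' converged per-species fits. Note the single reported "detectability"
#' conflates occupancy and detection; both psi-hat and p-hat are carried in
#' the per-species table, and the summary mean is computed on psi-hat.
#'
#' @param fits list of \code{occupancy_fit} objects (named by species).
#' @return list with \code{mean_psi}, \code{quantiles} (5 number summary of
#'   psi-hat), \code{n_converged}, and a per-species \code{table}.
#' @export
summarize_detectability <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1L))
  if (!any(conv)) stop("no converged occupancy fits to summarize")
  tab <- data.frame(
    species = if (!is.null(names(fits))) names(fits) else seq_along(fits),
    model = vapply(fits, `[[`, character(1L), "model"),
    psi = vapply(fits, `[[`, numeric(1L), "psi"),
    p = vapply(fits, `[[`, numeric(1L), "p"),
    gamma = vapply(fits, `[[`, numeric(1L), "gamma"),
    epsilon = vapply(fits, `[[`, numeric(1L), "epsilon"),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    converged = conv,
    stringsAsFactors = FALSE
  )
  psis <- tab$psi[conv]
  list(mean_psi = mean(psis),
       quantiles = stats::quantile(psis, c(0, 0.25, 0.5, 0.75, 1)),
       n_converged = sum(conv),
       table = tab)
}
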