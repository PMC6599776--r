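#' Prediction scenario for a fitted response model
#'
#' Fixes the non-exposure covariates at which dose-response curves and
#' thresholds are evaluated: the piling-order value (raw cumulative count),
#' ADD use, the vessel count (0 by default, matching the partial-
#' contribution convention) and the random-intercept value (0 = typical
#' site).
#'
#' @param order raw cumulative piling-order value.
#' @param add_used 0/1 ADD-use indicator (ignored by models without the
#'   ADD term).
#' @param vessel_count raw vessel count (default 0).
#' @param random_effect probit-scale random-intercept value (default 0).
#' @return an object of class `dr_scenario`.
#' @export
scenario <- function(order, add_used = 1, vessel_count = 0,
                     random_effect = 0) {
  structure(list(order = order, add_used = add_used,
                 vessel_count = vessel_count,
                 random_effect = random_effect),
            class = "dr_scenario")
}

# one-row raw-covariate data frame for a scenario at exposure value(s) x
scenario_newdata <- function(model, sc, exposure_raw) {
  nd <- tibble::tibble(order = sc$order, add_used = sc$add_used)
  nd <- nd[rep(1, length(exposure_raw)), ]
  nd[[model$exposure]] <- exposure_raw
  if (model$spec$vessel != "none") nd[[model$spec$vessel]] <- sc$vessel_count
  nd
}

# draws from the asymptotic fixed-effects distribution N(beta, fixed_cov)
draw_fixed_effects <- function(model, n, seed = NULL) {
  with_seed(seed, {
    S <- (model$fixed_cov + t(model$fixed_cov)) / 2
    # eigen factorization tolerates semi-definite (including zero)
    # covariances; tiny negative eigenvalues from numerical Hessians are
    # clamped to zero
    E <- eigen(S, symmetric = TRUE)
    L <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), nrow(S))
    p <- length(model$coefficients)
    z <- matrix(rnorm(n * p), n, p)
    sweep(z %*% t(L), 2, model$coefficients, "+")
  })
}

# exposure extrapolation guard: observed raw range widened by `frac` of
# its width on each side
exposure_guard <- function(model, frac = 0.2) {
  r <- model$exposure_range
  r + c(-1, 1) * frac * diff(r)
}

#' Dose-response curve with fixed-effects confidence band
#'
#' Evaluates the fitted response probability along an exposure grid for a
#' fixed scenario, `p = Phi(eta(x) + u)`, with the random intercept held
#' at `scenario$random_effect`. The pointwise confidence band propagates
#' uncertainty in the fixed effects only: coefficients are drawn from a
#' multivariate normal with the fitted mean and covariance, and the 2.5
#' and 97.5 percentiles of the drawn curves are reported.
#'
#' @param model a fitted [fit_probit_glmm()] model.
#' @param sc a [scenario()].
#' @param grid exposure grid: distances in km for distance models, SEL in
#'   dB for SEL models.
#' @param draws number of fixed-effects draws for the band (0 disables).
#' @param seed optional seed for the draws.
#' @param level confidence level (default 0.95).
#' @param allow_extrapolation permit grid points outside the observed
#'   exposure range widened by 20%.
#' @param population if `TRUE`, return the population-averaged curve
#'   `Phi(eta / sqrt(1 + sigma_u^2))` (integrating over the random-
#'   intercept distribution) instead of the typical-site curve.
#' @return a tibble with columns `exposure`, `p`, `ci_low`, `ci_high`.
#' @export
predict_curve <- function(model, sc, grid, draws = 10000, seed = NULL,
                          level = 0.95, allow_extrapolation = FALSE,
                          population = FALSE) {
  stopifnot(inherits(sc, "dr_scenario"))
  raw <- if (model$exposure == "log_distance") log(grid) else grid
  g <- exposure_guard(model)
  if (!allow_extrapolation && (any(raw < g[1]) || any(raw > g[2]))) {
    stop_input("grid outside the observed exposure range +/- 20%; ",
               "set allow_extrapolation = TRUE to override")
  }
  nd <- scenario_newdata(model, sc, raw)
  shrink <- if (population) 1 / sqrt(1 + model$re_variance) else 1
  eta <- linpred(model, nd) + sc$random_effect
  out <- tibble::tibble(exposure = grid, p = pnorm(eta * shrink))
  if (draws > 0) {
    B <- draw_fixed_effects(model, draws, seed)
    etas <- vapply(seq_len(draws), function(i)
      linpred(model, nd, beta = setNames(B[i, ],
                                         names(model$coefficients))),
      numeric(nrow(nd)))
    ps <- pnorm((etas + sc$random_effect) * shrink)
    a <- (1 - level) / 2
    qs <- apply(ps, 1, quantile7, probs = c(a, 1 - a))
    out$ci_low <- qs[1, ]; out$ci_high <- qs[2, ]
  }
  out
}

#' 50%-response threshold in distance or SEL
#'
#' Solves `eta(x) + u = 0` in closed form for the exposure value at which
#' the predicted response probability is 0.5 (the linear predictor is
#' linear in the standardized exposure once the scenario fixes the other
#' covariates). The confidence interval re-solves the threshold on each
#' multivariate-normal draw of the fixed effects; draws whose root falls
#' outside the extrapolation guard, or whose exposure slope has the wrong
#' sign, are discarded and counted.
#'
#' @param model a fitted [fit_probit_glmm()] model.
#' @param sc a [scenario()].
#' @param draws fixed-effects draws for the CI (default 10000).
#' @param seed optional seed.
#' @param level confidence level.
#' @param guard_frac extrapolation-guard widening fraction (default 0.2,
#'   i.e. observed range +/- 20%); `Inf` disables the guard.
#' @return an object of class `threshold_estimate`: list with `estimate`
#'   (km or dB), `ci_low`, `ci_high`, `axis`, `scenario`, `n_discarded`,
#'   `draws`.
#' @export
threshold_50 <- function(model, sc, draws = 10000, seed = NULL,
                         level = 0.95, guard_frac = 0.2) {
  stopifnot(inherits(sc, "dr_scenario"))
  solve_one <- function(beta) {
    parts <- threshold_parts(model, sc, beta)
    if (parts$B == 0) return(NA_real_)
    ze <- -parts$A / parts$B
    sc_row <- model$scaling[model$scaling$term == model$exposure, ]
    ze * sc_row$scale + sc_row$center  # raw exposure (ln km or dB)
  }
  b0 <- model$coefficients
  raw0 <- solve_one(b0)
  B0 <- threshold_parts(model, sc, b0)$B
  if (!is.finite(raw0)) stop_input("exposure slope is zero for this scenario")
  g <- exposure_guard(model, if (is.finite(guard_frac)) guard_frac else 1e6)
  est <- if (model$exposure == "log_distance") exp(raw0) else raw0

  ci <- c(NA_real_, NA_real_); n_disc <- 0L
  if (draws > 0) {
    Bm <- draw_fixed_effects(model, draws, seed)
    roots <- numeric(draws); keep <- logical(draws)
    flipped <- 0L
    for (i in seq_len(draws)) {
      beta <- setNames(Bm[i, ], names(b0))
      Bi <- threshold_parts(model, sc, beta)$B
      if (!is.finite(Bi) || sign(Bi) != sign(B0)) { flipped <- flipped + 1L; next }
      r <- solve_one(beta)
      if (is.finite(r) && r >= g[1] && r <= g[2]) {
        roots[i] <- r; keep[i] <- TRUE
      }
    }
    if (flipped > draws / 2) {
      stop_input("exposure slope sign unstable across draws; ",
                 "threshold not identified")
    }
    n_disc <- draws - sum(keep)
    a <- (1 - level) / 2
    qs <- quantile7(roots[keep], c(a, 1 - a))
    ci <- if (model$exposure == "log_distance") exp(qs) else qs
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 axis = if (model$exposure == "log_distance") "distance_km"
                        else model$exposure,
                 scenario = sc, n_discarded = n_disc, draws = draws),
            class = "threshold_estimate")
}

# decompose eta = A + B * z_exposure for a fixed scenario
threshold_parts <- function(model, sc, beta = model$coefficients) {
  scl <- model$scaling
  zval <- function(term, x) (x - scl$center[scl$term == term]) /
    scl$scale[scl$term == term]
  zo <- zval("order", sc$order)
  A <- beta[["(Intercept)"]] + beta[["order"]] * zo + sc$random_effect
  if ("add_used" %in% names(beta)) A <- A + beta[["add_used"]] * sc$add_used
  vt <- model$spec$vessel
  if (vt != "none") A <- A + beta[[vt]] * zval(vt, sc$vessel_count)
  B <- beta[[model$exposure]]
  int_name <- paste0(model$exposure, ":order")
  if (int_name %in% names(beta)) B <- B + beta[[int_name]] * zo
  list(A = unname(A), B = unname(B))
}

#' @export
print.threshold_estimate <- function(x, ...) {
  unit <- if (x$axis == "distance_km") "km" else "dB re 1 uPa^2 s"
  cat(sprintf("50%%-response threshold: %.2f %s (95%% CI %.2f-%.2f)\n",
              x$estimate, unit, x$ci_low, x$ci_high))
  cat(sprintf("  order = %s, ADD = %d, vessels = %s; %d of %d draws discarded\n",
              format(x$scenario$order), x$scenario$add_used,
              format(x$scenario$vessel_count), x$n_discarded, x$draws))
  invisible(x)
}

#' Threshold contrast with and without prior ADD use
#'
#' Compares 50%-response distances for piling preceded by ADD use and
#' piling without it, at the piling-order values of the paired events
#' (by convention consecutive locations, one of which was unmitigated).
#'
#' @param model a fitted model including the ADD term.
#' @param order_with,order_without raw piling-order values for the
#'   ADD-used and no-ADD scenarios.
#' @param vessel_count raw vessel count for both scenarios (default 0).
#' @param draws,seed,level passed to [threshold_50()].
#' @return a tibble with one row per scenario: `add_used`, `order`,
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
add_contrast <- function(model, order_with, order_without, vessel_count = 0,
                         draws = 10000, seed = NULL, level = 0.95) {
  if (!"add_used" %in% names(model$coefficients)) {
    stop_input("model has no ADD term; refit with model_spec(add = TRUE)")
  }
  scs <- list(
    with_add = scenario(order_with, add_used = 1, vessel_count = vessel_count),
    without_add = scenario(order_without, add_used = 0,
                           vessel_count = vessel_count))
  rows <- lapply(names(scs), function(nm) {
    th <- threshold_50(model, scs[[nm]], draws = draws,
                       seed = if (is.null(seed)) NULL else
                         child_seed(seed, nm), level = level)
    tibble::tibble(add_used = scs[[nm]]$add_used, order = scs[[nm]]$order,
                   estimate = th$estimate, ci_low = th$ci_low,
                   ci_high = th$ci_high)
  })
  dplyr::bind_rows(rows)
}
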