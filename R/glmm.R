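#' Specify a probit response model
#'
#' Defines the fixed-effect structure of a binomial probit mixed model of
#' behavioural response. Exactly one exposure metric enters a model
#' (distance and received levels are highly collinear and are never
#' combined). Continuous covariates are centred and scaled to unit SD by
#' default; the fitted object records the scaling so results can be mapped
#' back to the raw scale.
#'
#' @param exposure exposure term: `"log_distance"` (natural log of km) or
#'   one of the single-pulse SEL metrics `"sel_audiogram"`, `"sel_noaa"`,
#'   `"sel_m"`, `"sel_unweighted"`.
#' @param interaction include the exposure x piling-order interaction.
#' @param add include the ADD-use factor.
#' @param vessel vessel covariate: `"vessels_1km"`, `"vessels_500m"` or
#'   `"none"`.
#' @param standardize centre/scale continuous covariates (default TRUE).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(exposure = c("log_distance", "sel_audiogram",
                                    "sel_noaa", "sel_m", "sel_unweighted"),
                       interaction = TRUE, add = FALSE,
                       vessel = c("vessels_1km", "vessels_500m", "none"),
                       standardize = TRUE) {
  structure(list(exposure = match.arg(exposure),
                 interaction = isTRUE(interaction), add = isTRUE(add),
                 vessel = match.arg(vessel),
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

# design matrix + response + grouping from a response-record table
build_design <- function(records, spec) {
  need <- c(spec$exposure, "order", "response", "site_id", "device_id")
  if (spec$add) need <- c(need, "add_used")
  if (spec$vessel != "none") need <- c(need, spec$vessel)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_input("records lack columns: ",
                               paste(miss, collapse = ", "))
  cont <- c(spec$exposure, "order",
            if (spec$vessel != "none") spec$vessel)
  scaling <- tibble::tibble(term = cont,
                            center = vapply(cont, function(v)
                              mean(records[[v]]), numeric(1)),
                            scale = vapply(cont, function(v)
                              sd(records[[v]]), numeric(1)))
  if (any(scaling$scale == 0)) {
    stop_input("covariate constant across records: ",
               paste(scaling$term[scaling$scale == 0], collapse = ", "))
  }
  # optimization always runs on the standardized scale for conditioning;
  # raw-scale reporting is recovered by an exact affine transform
  z <- function(v) (records[[v]] - scaling$center[scaling$term == v]) /
    scaling$scale[scaling$term == v]
  X <- cbind(`(Intercept)` = 1, z(spec$exposure), z("order"))
  colnames(X)[2:3] <- c(spec$exposure, "order")
  if (spec$interaction) {
    X <- cbind(X, X[, spec$exposure] * X[, "order"])
    colnames(X)[ncol(X)] <- paste0(spec$exposure, ":order")
  }
  if (spec$add) {
    if (length(unique(records$add_used)) < 2) {
      stop_input("covariate constant across records: add_used")
    }
    X <- cbind(X, add_used = records$add_used)
  }
  if (spec$vessel != "none") {
    X <- cbind(X, z(spec$vessel))
    colnames(X)[ncol(X)] <- spec$vessel
  }
  list(X = X, y = as.integer(records$response),
       group = factor(paste(records$site_id, records$device_id, sep = ":")),
       scaling = scaling,
       exposure_range = range(records[[spec$exposure]]))
}

# lambda(z) = phi(z)/Phi(z), numerically stable in the lower tail
inv_mills <- function(z) exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))

# per-observation probit log-likelihood pieces at linear predictor lp:
# ll = log Phi(s lp), d1 = dll/dlp, d2 = -d2ll/dlp2 (> 0)
probit_pieces <- function(lp, s) {
  slp <- s * lp
  lam <- inv_mills(slp)
  list(ll = pnorm(slp, log.p = TRUE), d1 = s * lam, d2 = lam * (lam + slp))
}

# plain probit GLM by Newton-Raphson with step halving (sigma_u = 0 path
# and initializer for the mixed fit)
probit_glm_newton <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-10) {
  s <- 2 * y - 1
  beta <- rep(0, ncol(X))
  ll_at <- function(b) sum(pnorm(s * drop(X %*% b), log.p = TRUE)) -
    0.5 * ridge * sum(b^2)
  ll <- ll_at(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- probit_pieces(drop(X %*% beta), s)
    grad <- drop(crossprod(X, p$d1)) - ridge * beta
    H <- crossprod(X * p$d2, X) + diag(ridge, ncol(X))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    fac <- 1
    repeat {
      ll_new <- ll_at(beta + fac * step)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) break
    }
    beta <- beta + fac * step
    if (max(abs(fac * step)) < tol) { converged <- TRUE; ll <- ll_at(beta); break }
    ll <- ll_new
  }
  list(beta = beta, loglik = ll_at(beta), converged = converged)
}

# Laplace-approximated marginal negative log-likelihood for a probit model
# with one scalar random intercept per group. `uenv` carries warm-started
# conditional modes between calls.
laplace_nll <- function(beta, log_sigma, X, y, gidx, ngrp, uenv,
                        ridge = 0) {
  s <- 2 * y - 1
  eta <- drop(X %*% beta)
  sigma2 <- exp(2 * log_sigma)
  u <- uenv$u
  pen_ll <- function(u) {
    lp <- eta + u[gidx]
    sum(pnorm(s * lp, log.p = TRUE)) - sum(u^2) / (2 * sigma2)
  }
  f <- pen_ll(u)
  for (it in 1:60) {
    p <- probit_pieces(eta + u[gidx], s)
    g1 <- rowsum(p$d1, gidx, reorder = TRUE)[, 1] - u / sigma2
    g2 <- rowsum(p$d2, gidx, reorder = TRUE)[, 1] + 1 / sigma2
    step <- g1 / g2
    fac <- 1
    repeat {
      f_new <- pen_ll(u + fac * step)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) break
    }
    u <- u + fac * step
    if (max(abs(fac * step)) < 1e-9) break
    f <- f_new
  }
  uenv$u <- u
  p <- probit_pieces(eta + u[gidx], s)
  H <- rowsum(p$d2, gidx, reorder = TRUE)[, 1]
  ll <- sum(p$ll) - sum(u^2) / (2 * sigma2) -
    0.5 * sum(log1p(sigma2 * H))
  -(ll - 0.5 * ridge * sum(beta^2))
}

#' Fit a probit random-intercept mixed model of behavioural response
#'
#' Maximum-likelihood fit of a binomial probit regression with a single
#' Gaussian random intercept for the combined site x device grouping
#' factor. The marginal likelihood integrates the random intercept out by
#' a Laplace approximation: for fixed parameters, per-group conditional
#' modes are found by damped Newton iterations on the concave penalized
#' log-likelihood, and the outer optimization runs over
#' `(beta, log sigma_u)`. With `sigma_fixed = 0` the model reduces to a
#' plain probit GLM fitted by Newton-Raphson.
#'
#' The covariance of the fixed effects is the inverse of the observed
#' information for `beta` at the optimum (conditional on the estimated
#' variance parameter). If the fit diverges (separation), it is retried
#' with a mild ridge (`1e-6` on the probit scale) and flagged.
#'
#' @param records response-record table from [assemble_records()].
#' @param spec a [model_spec()].
#' @param sigma_fixed optionally fix the random-intercept SD (0 gives the
#'   plain GLM); `NULL` (default) estimates it.
#' @return an object of class `probit_glmm` with elements `coefficients`
#'   (on the standardized scale), `fixed_cov`, `re_variance`, `re_sd`,
#'   `loglik`, `aic`, `n_obs`, `n_groups`, `n_par`, `scaling`,
#'   `ranef` (conditional modes), `residual_acf1`, `converged`,
#'   `ridge_used`, plus the spec and exposure range used.
#' @export
fit_probit_glmm <- function(records, spec = model_spec(),
                            sigma_fixed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  d <- build_design(records, spec)
  X <- d$X; y <- d$y
  gidx <- as.integer(d$group)
  ngrp <- nlevels(d$group)
  if (is.null(sigma_fixed) && ngrp < 2) {
    stop_input("need >= 2 groups to estimate a random intercept")
  }
  p <- ncol(X)

  fit_once <- function(ridge) {
    init <- probit_glm_newton(X, y, ridge = ridge)
    if (!is.null(sigma_fixed) && sigma_fixed == 0) {
      H <- {
        pc <- probit_pieces(drop(X %*% init$beta), 2 * y - 1)
        crossprod(X * pc$d2, X)
      }
      return(list(beta = init$beta, log_sigma = -Inf, sigma = 0,
                  loglik = init$loglik, hess_beta = H,
                  converged = init$converged, n_par = p))
    }
    uenv <- new.env(); uenv$u <- rep(0, ngrp)
    if (!is.null(sigma_fixed)) {
      obj <- function(par) laplace_nll(par, log(sigma_fixed), X, y, gidx,
                                       ngrp, uenv, ridge)
      opt <- nlminb(init$beta, obj,
                    control = list(iter.max = 500, eval.max = 1200))
      beta <- opt$par; ls <- log(sigma_fixed); kpar <- p
    } else {
      obj <- function(par) laplace_nll(par[1:p], par[p + 1], X, y, gidx,
                                       ngrp, uenv, ridge)
      start <- c(init$beta, log(0.3))
      opt <- nlminb(start, obj,
                    lower = c(rep(-Inf, p), log(1e-4)),
                    upper = c(rep(Inf, p), log(25)),
                    control = list(iter.max = 500, eval.max = 1200))
      beta <- opt$par[1:p]; ls <- opt$par[p + 1]; kpar <- p + 1
    }
    hb <- optimHess(beta, function(b) laplace_nll(b, ls, X, y, gidx, ngrp,
                                                  uenv, ridge))
    conv <- opt$convergence == 0 ||
      grepl("relative convergence|X-convergence|singular convergence",
            opt$message %||% "")
    if (!conv) {
      # nlminb's "false convergence" is frequently a flat-likelihood
      # artefact; accept the solution when the gradient is numerically flat
      gr <- vapply(seq_along(opt$par), function(j) {
        h <- 1e-5 * max(1, abs(opt$par[j]))
        pp <- opt$par; pm <- opt$par
        pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
        (obj(pp) - obj(pm)) / (2 * h)
      }, numeric(1))
      conv <- max(abs(gr)) < 0.05
    }
    if (!conv && is.null(sigma_fixed) && exp(ls) < 0.05) {
      # the variance profile is crawling into the boundary: the MLE is a
      # singular fit with sigma_u = 0, whose exact profile is the plain
      # probit GLM
      bfit <- probit_glm_newton(X, y, ridge = ridge)
      if (bfit$loglik >= -obj_value(opt) - 0.05) {
        pc <- probit_pieces(drop(X %*% bfit$beta), 2 * y - 1)
        return(list(beta = bfit$beta, log_sigma = -Inf, sigma = 0,
                    loglik = bfit$loglik,
                    hess_beta = crossprod(X * pc$d2, X),
                    converged = bfit$converged, n_par = p + 1,
                    uenv = NULL))
      }
    }
    list(beta = beta, log_sigma = ls, sigma = exp(ls),
         loglik = -obj_value(opt), hess_beta = hb,
         converged = conv, n_par = kpar, uenv = uenv)
  }

  ridge_used <- 0
  res <- fit_once(0)
  bad <- !res$converged || any(!is.finite(res$beta)) ||
    max(abs(res$beta)) > 50
  if (bad) {
    warning("possible separation or non-convergence; refitting with ",
            "ridge 1e-6 on the probit scale")
    ridge_used <- 1e-6
    res <- fit_once(ridge_used)
    if (!res$converged) {
      stop_input("probit mixed model failed to converge (max |coef| = ",
                 signif(max(abs(res$beta)), 3), ")")
    }
  }

  beta <- setNames(res$beta, colnames(X))
  fixed_cov <- tryCatch(solve(res$hess_beta),
                        error = function(e) solve(res$hess_beta +
                                                    diag(1e-8, p)))
  fixed_cov <- (fixed_cov + t(fixed_cov)) / 2
  dimnames(fixed_cov) <- list(names(beta), names(beta))

  scaling <- d$scaling
  if (!spec$standardize) {
    # map estimates and covariance to the raw covariate scale
    Tm <- unscale_matrix(scaling, names(beta), spec)
    beta <- setNames(drop(Tm %*% beta), names(beta))
    fixed_cov <- Tm %*% fixed_cov %*% t(Tm)
    dimnames(fixed_cov) <- list(names(beta), names(beta))
    scaling$center <- 0; scaling$scale <- 1
  }

  u <- if (!is.null(res$uenv)) res$uenv$u else rep(0, ngrp)
  eta <- drop(X %*% res$beta) + u[gidx]
  resid <- y - pnorm(eta)
  acf1 <- if (length(resid) > 2) {
    stats::cor(resid[-1], resid[-length(resid)])
  } else NA_real_

  structure(list(
    coefficients = beta, fixed_cov = fixed_cov,
    re_variance = res$sigma^2, re_sd = res$sigma,
    loglik = res$loglik,
    aic = -2 * res$loglik + 2 * res$n_par,
    n_obs = length(y), n_groups = ngrp, n_par = res$n_par,
    scaling = scaling, spec = spec, exposure = spec$exposure,
    exposure_range = d$exposure_range,
    ranef = setNames(u, levels(d$group)),
    residual_acf1 = acf1,
    converged = res$converged, ridge_used = ridge_used
  ), class = "probit_glmm")
}

obj_value <- function(opt) opt$objective %||% opt$value

#' @export
print.probit_glmm <- function(x, ...) {
  cat("Probit mixed model (Laplace), ", x$n_obs, " obs, ", x$n_groups,
      " site:device groups\n", sep = "")
  cat("  exposure: ", x$exposure,
      if (x$spec$interaction) " (x order interaction)", "\n", sep = "")
  se <- sqrt(diag(x$fixed_cov))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(se, 4),
                    z = round(x$coefficients / se, 3))
  print(tab)
  cat(sprintf("  random intercept: variance = %.3f, s.d. = %.3f\n",
              x$re_variance, x$re_sd))
  cat(sprintf("  logLik = %.3f, AIC = %.1f\n", x$loglik, x$aic))
  if (x$ridge_used > 0) cat("  NOTE: fitted with ridge", x$ridge_used, "\n")
  invisible(x)
}

#' @export
logLik.probit_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' Akaike information criterion of a fitted response model
#'
#' `-2 logLik + 2 k`, where `k` counts fixed effects plus estimated
#' variance parameters.
#'
#' @param object a fitted [fit_probit_glmm()] model.
#' @param ... unused.
#' @param k penalty per parameter (2 for AIC).
#' @return AIC value.
#' @export
AIC.probit_glmm <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$n_par
}

#' Coefficients mapped back to the raw covariate scale
#'
#' Undoes the centring/scaling recorded in the fit, including the
#' redistribution of the interaction term, so that the linear predictor in
#' raw covariates (natural-log km, dB, raw order, raw counts) is
#' identical to the fitted one.
#'
#' @param model a fitted [fit_probit_glmm()] model.
#' @return named vector of raw-scale coefficients.
#' @export
coef_raw <- function(model) {
  Tm <- unscale_matrix(model$scaling, names(model$coefficients),
                       model$spec)
  setNames(drop(Tm %*% model$coefficients), names(model$coefficients))
}

# affine map from standardized-scale to raw-scale coefficients:
# b_raw = Tm %*% b_std reproduces the identical linear predictor
unscale_matrix <- function(scaling, coef_names, spec) {
  cs <- function(term) c(scaling$center[scaling$term == term],
                         scaling$scale[scaling$term == term])
  ex <- spec$exposure
  e <- cs(ex); o <- cs("order")
  p <- length(coef_names)
  Tm <- diag(p); dimnames(Tm) <- list(coef_names, coef_names)
  int_name <- paste0(ex, ":order")
  Tm[ex, ex] <- 1 / e[2]
  Tm["order", "order"] <- 1 / o[2]
  Tm["(Intercept)", ex] <- -e[1] / e[2]
  Tm["(Intercept)", "order"] <- -o[1] / o[2]
  if (int_name %in% coef_names) {
    Tm[int_name, int_name] <- 1 / (e[2] * o[2])
    Tm[ex, int_name] <- -o[1] / (e[2] * o[2])
    Tm["order", int_name] <- -e[1] / (e[2] * o[2])
    Tm["(Intercept)", int_name] <- e[1] * o[1] / (e[2] * o[2])
  }
  if (spec$vessel != "none" && spec$vessel %in% coef_names) {
    v <- cs(spec$vessel)
    Tm[spec$vessel, spec$vessel] <- 1 / v[2]
    Tm["(Intercept)", spec$vessel] <- -v[1] / v[2]
  }
  Tm
}

#' Predicted response probabilities
#'
#' @param object a fitted [fit_probit_glmm()] model.
#' @param newdata data frame with the raw covariate columns the model uses
#'   (exposure, `order`, and `add_used` / vessel counts where present).
#' @param re random-intercept value on the probit scale (default 0, the
#'   conditional-mode prediction for a typical site).
#' @param type `"response"` (probability) or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.probit_glmm <- function(object, newdata, re = 0,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- linpred(object, newdata) + re
  if (type == "link") eta else pnorm(eta)
}

# linear predictor (fixed effects only) for raw-scale newdata
linpred <- function(model, newdata, beta = model$coefficients) {
  sc <- model$scaling
  z <- function(term) (newdata[[term]] - sc$center[sc$term == term]) /
    sc$scale[sc$term == term]
  ex <- model$exposure
  eta <- beta[["(Intercept)"]] + beta[[ex]] * z(ex) +
    beta[["order"]] * z("order")
  int_name <- paste0(ex, ":order")
  if (int_name %in% names(beta)) eta <- eta + beta[[int_name]] * z(ex) * z("order")
  if ("add_used" %in% names(beta)) eta <- eta + beta[["add_used"]] * newdata$add_used
  vt <- model$spec$vessel
  if (vt != "none") eta <- eta + beta[[vt]] * z(vt)
  eta
}

#' Likelihood-ratio test of nested response models
#'
#' @param null_model,full_model fitted [fit_probit_glmm()] models on the
#'   identical record set, with the null's fixed-effect terms a strict
#'   subset of the full's.
#' @return a list with `deviance` (`2 (logLik_full - logLik_null)`), `df`
#'   and `p_value` (upper chi-squared tail).
#' @export
lrt <- function(null_model, full_model) {
  if (null_model$n_obs != full_model$n_obs) {
    stop_input("models fitted on different record sets")
  }
  if (!all(names(null_model$coefficients) %in%
           names(full_model$coefficients)) ||
      full_model$n_par <= null_model$n_par) {
    stop_input("null model must be nested in the full model")
  }
  dev <- 2 * (full_model$loglik - null_model$loglik)
  df <- full_model$n_par - null_model$n_par
  list(deviance = dev, df = df,
       p_value = pchisq(max(dev, 0), df, lower.tail = FALSE))
}

#' Fit and rank candidate response models by AIC
#'
#' Fits every candidate specification on the identical record table and
#' returns them ranked by AIC with a `delta_aic` column. Candidates that
#' fail to converge are listed with `converged = FALSE` and excluded from
#' the ranking.
#'
#' @param records response-record table.
#' @param specs named list of [model_spec()] objects (>= 2).
#' @return a tibble with one row per candidate (`model`, `exposure`,
#'   `interaction`, `k`, `loglik`, `aic`, `delta_aic`, `converged`),
#'   sorted by AIC, with the fitted models in attribute `fits`.
#' @export
model_table <- function(records, specs) {
  if (length(specs) < 2) stop_input("need >= 2 candidate specs")
  nms <- names(specs) %||% paste0("m", seq_along(specs))
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_probit_glmm(records, sp), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  pull <- function(field) vapply(fits, function(f)
    if (inherits(f, "error")) NA_real_ else as.numeric(f[[field]]),
    numeric(1))
  tab <- tibble::tibble(
    model = nms,
    exposure = vapply(specs, function(s) s$exposure, character(1)),
    interaction = vapply(specs, function(s) s$interaction, logical(1)),
    k = pull("n_par"), loglik = pull("loglik"), aic = pull("aic"),
    converged = ok & vapply(fits, function(f)
      !inherits(f, "error") && f$converged, logical(1)))
  tab$aic[!tab$converged] <- NA
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- round(tab$aic - min(tab$aic, na.rm = TRUE), 1)
  attr(tab, "fits") <- setNames(fits, nms)
  tab
}
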