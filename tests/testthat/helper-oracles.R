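# Independent oracles and small data builders shared across tests.

# Adaptive Gauss-Hermite quadrature log-likelihood for the probit
# random-intercept model: per group, nodes are centred at the conditional
# mode and scaled by the mode's curvature. Independent of the package's
# Laplace implementation.
agq_loglik <- function(beta, sigma, X, y, grp, nq = 50) {
  i <- sqrt(seq_len(nq - 1) / 2)
  J <- rbind(cbind(0, diag(i, nq - 1)), 0)
  E <- eigen(J + t(J), symmetric = TRUE)
  qx <- rev(E$values)
  qw <- rev(E$vectors[1, ]^2) * sqrt(pi)
  s <- 2 * y - 1
  eta <- drop(X %*% beta)
  total <- 0
  for (g in unique(grp)) {
    idx <- grp == g
    nfun <- function(u) -(sum(pnorm(s[idx] * (eta[idx] + u), log.p = TRUE)) +
                            dnorm(u, 0, sigma, log = TRUE))
    mu <- optimize(nfun, c(-15, 15))$minimum
    sc <- 1 / sqrt(optimHess(mu, nfun)[1, 1])
    u <- mu + sqrt(2) * sc * qx
    lg <- vapply(u, function(ui)
      sum(pnorm(s[idx] * (eta[idx] + ui), log.p = TRUE)) +
        dnorm(ui, 0, sigma, log = TRUE), numeric(1))
    m <- max(lg + qx^2)
    total <- total + m + log(sum(qw * exp(lg + qx^2 - m) * sqrt(2) * sc))
  }
  total
}

# toy response-record table with known mixed-probit structure
toy_records <- function(n = 60, g = 3, beta = c(0.3, 0.8, -0.2),
                        sigma = 0.4, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n); o <- rnorm(n)
    grp <- rep(seq_len(g), length.out = n)
    u <- rnorm(g, 0, sigma)
    y <- rbinom(n, 1, pnorm(beta[1] + beta[2] * x + beta[3] * o + u[grp]))
    tibble::tibble(site_id = paste0("s", grp), device_id = "d",
                   response = y, log_distance = x, order = o)
  })
}

# hand-built fitted-model object for the closed-form threshold /
# prediction algebra, bypassing the fitting machinery
fake_model <- function(coefs, center_exposure = 0, scale_exposure = 1,
                       center_order = 0, scale_order = 1,
                       fixed_cov = NULL, exposure = "log_distance",
                       exposure_range = c(-2, 4), re_variance = 0) {
  spec <- model_spec(exposure,
                     interaction = paste0(exposure, ":order") %in% names(coefs),
                     add = "add_used" %in% names(coefs), vessel = "none")
  p <- length(coefs)
  structure(list(
    coefficients = coefs,
    fixed_cov = fixed_cov %||% matrix(0, p, p,
                                      dimnames = list(names(coefs),
                                                      names(coefs))),
    re_variance = re_variance, re_sd = sqrt(re_variance),
    loglik = NA_real_, aic = NA_real_, n_obs = NA_integer_,
    n_groups = NA_integer_, n_par = p,
    scaling = tibble::tibble(term = c(exposure, "order"),
                             center = c(center_exposure, center_order),
                             scale = c(scale_exposure, scale_order)),
    spec = spec, exposure = exposure, exposure_range = exposure_range,
    converged = TRUE, ridge_used = 0
  ), class = "probit_glmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hourly series builder
hourly_series <- function(detected, start = "2017-03-01", site = "s1",
                          device = "d1") {
  tibble::tibble(
    site_id = site, device_id = device,
    hour_start = seq(as.POSIXct(start, tz = "UTC"), by = 3600,
                     length.out = length(detected)),
    detected = as.integer(detected))
}
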