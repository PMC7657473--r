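#' Piecewise mean functions for the speed and accuracy differences
#'
#' The speed difference between frame-wise and progressive tracking
#' declines linearly with point velocity `V` up to a critical velocity
#' and is constant above it:
#' `delta_S(V) = b + c * (V - v_crit) * [V <= v_crit]`.
#' The accuracy difference is constant below the critical velocity and
#' grows linearly above it:
#' `delta_A(V) = b + c * (V - v_crit) * [V >= v_crit]`.
#' Both forms are continuous at `V = v_crit` (value `b`). Whether the
#' boundary point itself belongs to the sloped regime is a measure-zero
#' convention, exposed via `boundary`.
#'
#' @param V Point velocity, px/frame (vectorized).
#' @param b Plateau level (intercept at the breakpoint).
#' @param c Slope of the sloped regime.
#' @param v_crit Critical point velocity (breakpoint), px/frame.
#' @param boundary `"closed"` (default, the breakpoint belongs to the
#'   sloped regime as written above) or `"open"` (strict inequality).
#' @return Mean `delta_S` or `delta_A` at `V`.
#' @export
predict_delta_S <- function(V, b, c, v_crit,
                            boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  active <- if (boundary == "closed") V <= v_crit else V < v_crit
  b + c * (V - v_crit) * active
}

#' @rdname predict_delta_S
#' @export
predict_delta_A <- function(V, b, c, v_crit,
                            boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  active <- if (boundary == "closed") V >= v_crit else V > v_crit
  b + c * (V - v_crit) * active
}

model_variants <- c("full", "no_vcrit", "no_user", "no_device")

# Group labels per model variant.
variant_groups <- function(data, variant) {
  switch(variant,
    full = paste(data$user, data$device, sep = ":"),
    no_vcrit = paste(data$user, data$device, sep = ":"),
    no_user = as.character(data$device),
    no_device = as.character(data$user)
  )
}

# JAGS model code. `kink_sign` selects which side of the breakpoint is
# sloped: +1 -> sloped for V <= v_crit (delta_S), -1 -> V >= v_crit.
jags_code_piecewise <- "
model {
  for (i in 1:n) {
    on[i] <- step(kink_sign * (vc[g[i]] - V[i]))
    mu[i] <- b[g[i]] + c[g[i]] * (V[i] - vc[g[i]]) * on[i]
    y[i] ~ dnorm(mu[i], tau)
  }
  for (j in 1:ng) {
    b[j] ~ dnorm(0, prec_b)
    c[j] ~ dnorm(0, prec_c)
    vc[j] ~ dunif(v_lo, v_hi)
  }
  sigma ~ dnorm(0, prec_s) T(0,)
  tau <- pow(sigma, -2)
}"

jags_code_linear <- "
model {
  for (i in 1:n) {
    mu[i] <- b[g[i]] + c[g[i]] * V[i]
    y[i] ~ dnorm(mu[i], tau)
  }
  for (j in 1:ng) {
    b[j] ~ dnorm(0, prec_b)
    c[j] ~ dnorm(0, prec_c)
  }
  sigma ~ dnorm(0, prec_s) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit the piecewise Bayesian changepoint model by MCMC
#'
#' Models a per-frame paired difference (`delta_S` or `delta_A`) as a
#' piecewise-linear function of point velocity `V` with a breakpoint
#' `v_crit`, a plateau `b` and a slope `c`, each estimated per group
#' (user x device in the full model), plus a shared residual standard
#' deviation `epsilon` under a Gaussian likelihood. Priors are weakly
#' informative: `b, c ~ Normal(0, scaled to the outcome)`, `v_crit ~
#' Uniform` over the observed velocity range, half-Normal on `epsilon`.
#' Sampling runs in JAGS (Gibbs/slice), which handles the discontinuous
#' dependence of the likelihood on `v_crit` without gradient-based
#' samplers.
#'
#' Model variants for comparison: `"full"` (b, c, v_crit per user x
#' device), `"no_vcrit"` (a plain linear fit per user x device),
#' `"no_user"` (groups collapse to device only) and `"no_device"`
#' (user only).
#'
#' @param data Tibble of paired per-frame differences (see
#'   [paired_deltas()]) with columns `V`, `user`, `device` and the
#'   outcome column. Apply [filter_valid()] to both modes beforehand.
#' @param outcome `"delta_S"` or `"delta_A"`; selects the outcome column
#'   and which side of the breakpoint carries the slope.
#' @param variant One of `"full"`, `"no_vcrit"`, `"no_user"`,
#'   `"no_device"`.
#' @param chains,iter,warmup MCMC settings (defaults 4 chains, 1000
#'   draws each after 1000 warmup; adaptation uses half the warmup).
#' @param seed Integer seed; fixes both initial values and the JAGS RNG
#'   streams, making results exactly reproducible.
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `piecewise_fit` with posterior `draws`
#'   (a draws x parameters matrix), per-parameter `diagnostics`
#'   (split-chain R-hat and effective sample size), the data, and
#'   metadata. Use [tidy()], [glance()], [autoplot()], [waic()] and
#'   [psis_loo()] on it.
#' @export
fit_piecewise <- function(data, outcome = c("delta_S", "delta_A"),
                          variant = c("full", "no_vcrit", "no_user",
                                      "no_device"),
                          chains = 4L, iter = 1000L, warmup = 1000L,
                          seed = 1L, quiet = TRUE) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  needed <- c("V", "user", "device", outcome)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "protrack_data_error")
  }
  y <- data[[outcome]]
  V <- data$V
  ok <- is.finite(y) & is.finite(V)
  y <- y[ok]; V <- V[ok]
  glab <- variant_groups(data[ok, ], variant)
  glev <- sort(unique(glab))
  g <- match(glab, glev)
  if (variant == "full" &&
      (length(unique(data$user[ok])) < 2L ||
       length(unique(data$device[ok])) < 2L)) {
    warn("Full model requested but users or devices are not both varied.")
  }
  n <- length(y)
  sd_y <- sd(y)
  sd_V <- max(sd(V), 1e-6)
  prior_sd_b <- 5 * max(sd_y, 1e-6)
  prior_sd_c <- 5 * max(sd_y, 1e-6) / sd_V
  prior_sd_s <- 3 * max(sd_y, 1e-6)
  v_lo <- min(V); v_hi <- max(V)

  jdata <- list(y = y, V = V, g = g, n = n, ng = length(glev),
                prec_b = prior_sd_b^-2, prec_c = prior_sd_c^-2,
                prec_s = prior_sd_s^-2)
  monitors <- c("b", "c", "sigma")
  if (variant == "no_vcrit") {
    code <- jags_code_linear
  } else {
    code <- jags_code_piecewise
    jdata$v_lo <- v_lo
    jdata$v_hi <- v_hi
    jdata$kink_sign <- if (outcome == "delta_S") 1 else -1
    monitors <- c(monitors, "vc")
  }

  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  adapt <- max(100L, warmup %/% 2L)
  jm <- rjags::jags.model(textConnection(code), data = jdata, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  stats::update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter,
                              progress.bar = "none")

  draws_by_chain <- lapply(samp, as.matrix)
  draws <- do.call(rbind, draws_by_chain)
  chain_id <- rep(seq_len(chains), each = iter)
  diagnostics <- mcmc_diagnostics(draws_by_chain)

  fit <- structure(
    list(draws = draws, chain_id = chain_id, diagnostics = diagnostics,
         data = tibble(y = y, V = V, group = glab),
         outcome = outcome, variant = variant, groups = glev,
         chains = chains, iter = iter, warmup = warmup, seed = seed,
         priors = list(sd_b = prior_sd_b, sd_c = prior_sd_c,
                       sd_sigma = prior_sd_s, v_range = c(v_lo, v_hi)),
         accuracy_form = "inverse_one_plus"),
    class = "piecewise_fit"
  )
  if (!all(fit$diagnostics$converged)) {
    warn(paste0(
      "Convergence flagged: R-hat > 1.05 or ESS < 100 for ",
      paste(fit$diagnostics$parameter[!fit$diagnostics$converged],
            collapse = ", ")),
      class = "protrack_convergence_warning")
  }
  fit
}

# Split-chain R-hat and effective sample size per parameter.
mcmc_diagnostics <- function(draws_by_chain) {
  split_halves <- function(m) {
    h <- nrow(m) %/% 2L
    list(m[seq_len(h), , drop = FALSE],
         m[(h + 1L):(2L * h), , drop = FALSE])
  }
  halves <- unlist(lapply(draws_by_chain, split_halves), recursive = FALSE)
  params <- colnames(draws_by_chain[[1]])
  rhat <- vapply(params, function(p) {
    chains <- vapply(halves, function(m) m[, p], numeric(nrow(halves[[1]])))
    n <- nrow(chains)
    W <- mean(apply(chains, 2, var))
    B <- n * var(colMeans(chains))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  ess <- tryCatch(
    coda::effectiveSize(coda::as.mcmc.list(
      lapply(draws_by_chain, coda::as.mcmc))),
    error = function(e) rep(NA_real_, length(params))
  )
  tibble(parameter = params, rhat = unname(rhat),
         ess = unname(ess[params]),
         converged = is.finite(rhat) & rhat < 1.05 &
           (!is.finite(ess[params]) | ess[params] >= 100))
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> outcome %s, variant %s\n  %d obs, groups: %s\n  %d chains x %d draws (warmup %d), seed %d\n",
    x$outcome, x$variant, nrow(x$data), paste(x$groups, collapse = ", "),
    x$chains, x$iter, x$warmup, x$seed))
  print(tidy(x), n = Inf)
  invisible(x)
}

# Map a JAGS parameter name like "vc[2]" to (term, group).
split_param <- function(p, groups) {
  base <- sub("\\[.*", "", p)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\].*", "\\1", p)))
  term <- c(b = "b", c = "c", vc = "v_crit", sigma = "epsilon")[base]
  group <- if (!is.na(idx) && grepl("\\[", p)) groups[idx] else NA_character_
  list(term = term, group = group)
}

#' Tidy posterior summaries of a piecewise fit
#'
#' @param x A `piecewise_fit`.
#' @param conf_level Credible-interval mass (default 0.89, i.e. the
#'   5.5% and 94.5% posterior quantiles).
#' @param ... Unused.
#' @return A tibble with `term, group, estimate` (posterior mean),
#'   `std.error` (posterior SD), `conf.low, conf.high`, `rhat, ess`.
#' @export
tidy.piecewise_fit <- function(x, conf_level = 0.89, ...) {
  a <- (1 - conf_level) / 2
  params <- colnames(x$draws)
  purrr::map_dfr(params, function(p) {
    z <- x$draws[, p]
    tg <- split_param(p, x$groups)
    dg <- x$diagnostics[x$diagnostics$parameter == p, ]
    tibble(term = tg$term, group = tg$group,
           estimate = mean(z), std.error = sd(z),
           conf.low = quantile(z, a, names = FALSE),
           conf.high = quantile(z, 1 - a, names = FALSE),
           rhat = dg$rhat, ess = dg$ess)
  })
}

#' One-row model summary of a piecewise fit
#'
#' @param x A `piecewise_fit`.
#' @param ... Unused.
#' @return A tibble with `outcome, variant, nobs, n_groups, epsilon,
#'   waic, se_waic, p_waic, elpd_loo, se_elpd_loo, max_rhat, min_ess,
#'   converged`.
#' @export
glance.piecewise_fit <- function(x, ...) {
  w <- waic(x)
  l <- psis_loo(x)
  tibble(
    outcome = x$outcome, variant = x$variant,
    nobs = nrow(x$data), n_groups = length(x$groups),
    epsilon = mean(x$draws[, "sigma"]),
    waic = w$waic, se_waic = w$se_waic, p_waic = w$p_waic,
    elpd_loo = l$elpd_loo, se_elpd_loo = l$se_elpd_loo,
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = all(x$diagnostics$converged)
  )
}

# Posterior mean curve per draw subset; returns draws x length(V) matrix
# of mu for one group.
posterior_mu <- function(fit, V, group, draws_idx = NULL) {
  j <- match(group, fit$groups)
  d <- fit$draws
  if (!is.null(draws_idx)) d <- d[draws_idx, , drop = FALSE]
  # JAGS drops the index on scalar parameter arrays (single group)
  col_of <- function(base) {
    nm <- paste0(base, "[", j, "]")
    if (!nm %in% colnames(d)) nm <- base
    d[, nm, drop = TRUE]
  }
  b <- col_of("b")
  cc <- col_of("c")
  if (fit$variant == "no_vcrit") {
    outer(b, rep(1, length(V))) + outer(cc, V)
  } else {
    vc <- col_of("vc")
    pred <- if (fit$outcome == "delta_S") predict_delta_S else predict_delta_A
    t(vapply(seq_along(b),
             function(s) pred(V, b[s], cc[s], vc[s]),
             numeric(length(V))))
  }
}

# Pointwise log-likelihood matrix (draws x observations), thinned to at
# most `max_draws` posterior draws to bound memory.
pointwise_loglik <- function(fit, max_draws = 1000L) {
  nd <- nrow(fit$draws)
  idx <- if (nd > max_draws) {
    round(seq(1L, nd, length.out = max_draws))
  } else {
    seq_len(nd)
  }
  sigma <- fit$draws[idx, "sigma"]
  ll <- matrix(NA_real_, length(idx), nrow(fit$data))
  for (grp in fit$groups) {
    sel <- fit$data$group == grp
    mu <- posterior_mu(fit, fit$data$V[sel], grp, draws_idx = idx)
    ll[, sel] <- dnorm(rep(fit$data$y[sel], each = length(idx)),
                       mean = mu, sd = sigma, log = TRUE)
  }
  ll
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion (WAIC)
#'
#' Computed from the pointwise posterior log-likelihood:
#' `lppd_i = log mean_s p(y_i | theta_s)`, `p_waic_i = var_s log p(y_i |
#' theta_s)`, `WAIC = -2 * sum(lppd_i - p_waic_i)`, with the standard
#' error from the pointwise contributions.
#'
#' @param fit A `piecewise_fit`.
#' @param max_draws Posterior draws used (thinned if more are stored).
#' @return A list with `waic, se_waic, elpd_waic, p_waic` and the
#'   `pointwise` tibble.
#' @export
waic <- function(fit, max_draws = 1000L) {
  ll <- pointwise_loglik(fit, max_draws)
  s <- nrow(ll)
  lppd <- apply(ll, 2, function(z) log_sum_exp(z) - log(s))
  p <- apply(ll, 2, var)
  elpd_i <- lppd - p
  n <- length(elpd_i)
  list(waic = -2 * sum(elpd_i), se_waic = 2 * sqrt(n * var(elpd_i)),
       elpd_waic = sum(elpd_i), p_waic = sum(p),
       pointwise = tibble(lppd = lppd, p_waic = p, elpd = elpd_i))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out predictive density using importance
#' sampling with the full-posterior draws, stabilizing each
#' observation's importance weights by fitting a generalized Pareto
#' distribution to their upper tail (PSIS). The tail-shape diagnostic
#' `k_hat` is returned per observation; values above 0.7 flag unreliable
#' contributions.
#'
#' @inheritParams waic
#' @return A list with `elpd_loo, se_elpd_loo, looic, se_looic`, and the
#'   `pointwise` tibble including `k_hat`.
#' @export
psis_loo <- function(fit, max_draws = 1000L) {
  ll <- pointwise_loglik(fit, max_draws)
  s <- nrow(ll)
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_hat <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    sm <- psis_smooth_tail(lw)
    lw <- sm$lw - log_sum_exp(sm$lw)
    k_hat[i] <- sm$k
    elpd_i[i] <- log_sum_exp(lw + ll[, i])
  }
  list(elpd_loo = sum(elpd_i), se_elpd_loo = sqrt(n * var(elpd_i)),
       looic = -2 * sum(elpd_i), se_looic = 2 * sqrt(n * var(elpd_i)),
       pointwise = tibble(elpd_loo = elpd_i, k_hat = k_hat))
}

# Smooth the upper tail of log-weights with a generalized Pareto fit
# (Zhang & Stephens 2009 profile-posterior estimator).
psis_smooth_tail <- function(lw) {
  s <- length(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (m < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(s - m + 1):s]
  cutoff <- exp(lw[ord[s - m]])
  exc <- exp(lw[tail_ids]) - cutoff
  if (all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  gp <- gpd_fit(exc)
  if (!is.finite(gp$k)) return(list(lw = lw, k = gp$k))
  # Replace tail weights by expected order statistics of the fitted GPD.
  p <- (seq_len(m) - 0.5) / m
  q <- gpd_quantile(p, gp$k, gp$sigma) + cutoff
  smoothed <- lw
  smoothed[tail_ids[order(exp(lw[tail_ids]))]] <- log(q)
  smoothed <- pmin(smoothed, 0)  # cap at the (normalized) max weight
  list(lw = smoothed, k = gp$k)
}

# Generalized Pareto fit on exceedances (k is the shape xi).
gpd_fit <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  m_grid <- 30 + floor(sqrt(n))
  jj <- seq_len(m_grid)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m_grid / (jj - 0.5))) / prior_bs / xstar
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  sigma <- k / th_hat
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * ((1 - p)^(-k) - 1) / k
}

#' Fit and rank model variants by WAIC and PSIS-LOO
#'
#' Fits each requested variant on the same data and outcome, then ranks
#' by WAIC (lower is better). Differences relative to the best model and
#' their standard errors (from the paired pointwise contributions) are
#' included.
#'
#' @param data Paired-differences tibble (see [fit_piecewise()]).
#' @param outcome `"delta_S"` or `"delta_A"`.
#' @param variants Variants to fit (default all four).
#' @param ... Passed to [fit_piecewise()] (chains, iter, warmup, seed).
#' @return A list with `table` (ranked tibble: variant, waic, se_waic,
#'   d_waic, se_d_waic, elpd_loo, se_elpd_loo, d_elpd_loo) and `fits`
#'   (named list of `piecewise_fit` objects).
#' @export
compare_piecewise <- function(data, outcome = c("delta_S", "delta_A"),
                              variants = model_variants, ...) {
  outcome <- match.arg(outcome)
  variants <- match.arg(variants, model_variants, several.ok = TRUE)
  if (length(variants) < 2L) {
    abort("Need >= 2 variants to compare.", class = "protrack_config_error")
  }
  fits <- lapply(variants, function(v) {
    fit_piecewise(data, outcome = outcome, variant = v, ...)
  })
  names(fits) <- variants
  compare_fits(fits)
}

#' Rank already-fitted model variants
#'
#' @param fits Named list of `piecewise_fit` objects on identical data.
#' @return See [compare_piecewise()].
#' @export
compare_fits <- function(fits) {
  ys <- lapply(fits, function(f) f$data$y)
  if (length(unique(vapply(ys, length, integer(1)))) != 1L ||
      !all(vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])),
                  logical(1)))) {
    abort("Model variants were fitted on different data.",
          class = "protrack_comparison_error")
  }
  ws <- lapply(fits, waic)
  ls <- lapply(fits, psis_loo)
  tab <- purrr::map_dfr(seq_along(fits), function(i) {
    tibble(variant = names(fits)[i],
           waic = ws[[i]]$waic, se_waic = ws[[i]]$se_waic,
           p_waic = ws[[i]]$p_waic,
           elpd_loo = ls[[i]]$elpd_loo,
           se_elpd_loo = ls[[i]]$se_elpd_loo)
  }) %>%
    arrange(.data$waic)
  best <- which.min(vapply(ws, function(w) w$waic, numeric(1)))
  tab$d_waic <- tab$waic - min(tab$waic)
  tab$se_d_waic <- vapply(tab$variant, function(v) {
    i <- match(v, names(fits))
    if (i == best) return(0)
    diff_i <- -2 * (ws[[i]]$pointwise$elpd - ws[[best]]$pointwise$elpd)
    sqrt(length(diff_i) * var(diff_i))
  }, numeric(1), USE.NAMES = FALSE)
  tab$d_elpd_loo <- tab$elpd_loo - max(tab$elpd_loo)
  list(table = tab, fits = fits)
}
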