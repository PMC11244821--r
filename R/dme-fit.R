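# Parameter packing: each model kind has a fixed set of free DME
# parameters, optimized on log (positive) or logit (proportion) scale.

dme_par_info <- function(kind) {
  base <- data.frame(
    name = c("m", "k", "q", "p0"),
    trans = c("log", "log", "logit", "logit"),
    stringsAsFactors = FALSE)
  switch(kind,
    snm_only = base,
    single_dme = {
      base$name[4] <- "U_free"; base$trans[4] <- "log"; base
    },
    two_gamma = rbind(base, data.frame(
      name = c("m_unid", "k_unid", "q_unid", "U_unid"),
      trans = c("log", "log", "logit", "log"))),
    gaussian_unid = rbind(base, data.frame(
      name = c("mu_unid", "sigma_unid"),
      trans = c("identity", "log"))),
    stop_domain("unknown model kind: ", kind))
}

trans_fwd <- function(x, trans) {
  switch(trans, log = log(x), logit = logit(pmin(pmax(x, 1e-9), 1 - 1e-9)),
         identity = x)
}
trans_inv <- function(x, trans) {
  switch(trans, log = exp(x), logit = inv_logit(x), identity = x)
}

pars_to_model <- function(kind, pars, M_diploid) {
  args <- as.list(pars)
  args$kind <- kind
  args$M_diploid <- M_diploid
  do.call(dme_model, args)
}

model_to_pars <- function(model) {
  info <- dme_par_info(model$kind)
  stats::setNames(vapply(info$name, function(nm) model[[nm]], 0),
                  info$name)
}

default_dme_start <- function(kind) {
  s <- c(m = 5e-3, k = 0.2, q = 0.1, p0 = 0.1)
  switch(kind,
         snm_only = s,
         single_dme = c(s[1:3], U_free = 2),
         two_gamma = c(s, m_unid = 3e-3, k_unid = 0.3, q_unid = 0.1,
                       U_unid = 1),
         gaussian_unid = c(s, mu_unid = -1e-3, sigma_unid = 5e-3))
}

#' Fit a DME model to strain-level summaries or full colony data
#'
#' Two fitting modes share the Fourier-domain density machinery:
#'
#' * **summary** (`x` = data frame with `strain_id`, `s_est`, `se`):
#'   each strain's estimated mutational effect is modeled as the true
#'   combined effect plus Gaussian estimation error; the likelihood of
#'   the DME parameters is the product over strains of the convolved
#'   density at `s_est` (see [strain_summary_loglik()]).
#' * **full** (`x` = [pair_colonies()] result): for each strain, the
#'   likelihood integrates the DME density of the strain's true effect
#'   `s` against the product of paired-difference mixture densities at
#'   that `s`, with the strain's petite proportion profiled out; the
#'   petite-control likelihood is added. The integral is a trapezoid
#'   rule over the region of the FFT grid carrying the DME mass,
#'   evaluated in log space with max-subtraction.
#'
#' Free parameters (positive parameters on log scale, proportions on
#' logit scale) are maximized with a quasi-Newton optimizer from
#' `n_starts` starting points. AIC is `2 k - 2 lnL`, where `k` counts
#' only DME parameters in summary mode and DME + 7 general + per-strain
#' petite-proportion parameters in full mode.
#'
#' @param x summaries data frame or `paired_diffs` object.
#' @param kind model variant (see [dme_model()]).
#' @param mode `"summary"` or `"full"` (defaults to match `x`).
#' @param petite_controls colony table rows of petite-control colonies
#'   (full mode).
#' @param general a [general_params()] with the measurement parameters
#'   (full mode), e.g. from [fit_colony_model()].
#' @param optimize_general logical: re-optimize the general parameters
#'   jointly with the DME parameters (full mode; slower).
#' @param M_diploid mean SNMs per diploid parent (fixed, not fitted).
#' @param kernel_sd smoothing-kernel sd (default `2^-16`).
#' @param n,s_max density-grid controls (default `2^12` points on
#'   ±0.5 for fitting).
#' @param n_starts optimizer starts.
#' @param seed seed for start-point jitter.
#' @param start optional named vector of natural-scale starting values.
#' @param maxit outer iteration cap.
#' @return An object of class `dme_fit`: fitted [dme_model()], `par`
#'   (named natural-scale estimates), `logLik`, `n_free_params`, `AIC`,
#'   convergence info, and a data fingerprint used by
#'   [compare_models()].
#' @export
fit_dme <- function(x, kind = c("snm_only", "single_dme", "two_gamma",
                                "gaussian_unid"),
                    mode = NULL, petite_controls = NULL, general = NULL,
                    optimize_general = FALSE, M_diploid = 8,
                    kernel_sd = 2^-16, n = 2^12, s_max = 0.5,
                    n_starts = 2L, seed = 1L, start = NULL,
                    maxit = 400L) {
  kind <- match.arg(kind)
  mode <- mode %||% if (inherits(x, "paired_diffs")) "full" else "summary"
  info <- dme_par_info(kind)
  start_nat <- default_dme_start(kind)
  if (!is.null(start)) start_nat[names(start)] <- start
  th0 <- mapply(trans_fwd, start_nat[info$name], info$trans)

  if (mode == "summary") {
    stopifnot(is.data.frame(x), all(c("s_est", "se") %in% names(x)),
              nrow(x) >= 1)
    if (any(x$se <= 0)) stop_domain("all `se` must be > 0")
    negll <- summary_negll_factory(x, kind, M_diploid, kernel_sd, n,
                                   s_max)
    n_free <- n_dme_params(kind)
    n_extra <- 0
    fingerprint <- c(nrow(x), sum(x$s_est), sum(x$se))
  } else {
    stopifnot(inherits(x, "paired_diffs"))
    if (is.null(general)) {
      stop_domain("full mode needs `general` measurement parameters ",
                  "(fit them with fit_colony_model, or set ",
                  "optimize_general = TRUE and supply starting values)")
    }
    ctrl_by_well <- if (!is.null(petite_controls)) {
      split(petite_controls$growth_rate, petite_controls$well)
    } else list()
    negll <- full_negll_factory(x, ctrl_by_well, kind, M_diploid,
                                kernel_sd, n, s_max, general,
                                optimize_general)
    n_strains <- length(unique(x$strain_id))
    n_free <- n_dme_params(kind) + 7L + n_strains
    n_extra <- if (optimize_general) 7L else 0L
    if (optimize_general) th0 <- c(th0, general_to_theta(general))
    fingerprint <- c(nrow(x), sum(x$d), length(ctrl_by_well))
  }

  starts <- list(th0)
  if (n_starts > 1) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      th0 + stats::rnorm(length(th0), 0, 0.4)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, negll,
                         control = list(iter.max = maxit,
                                        rel.tol = 1e-8))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (!is.finite(best$objective)) {
    stop_domain("DME fit failed to converge from any start ",
                "(best objective not finite)")
  }
  th_dme <- best$par[seq_len(nrow(info))]
  pars <- stats::setNames(mapply(trans_inv, th_dme, info$trans),
                          info$name)
  model <- pars_to_model(kind, pars, M_diploid)
  gen_hat <- if (mode == "full" && optimize_general) {
    structure(theta_to_general(best$par[-seq_len(nrow(info))]),
              class = "general_params")
  } else general
  structure(list(model = model, par = pars, logLik = -best$objective,
                 n_free_params = n_free,
                 AIC = 2 * n_free - 2 * (-best$objective),
                 mode = mode, general = gen_hat,
                 M_diploid = M_diploid,
                 grid = list(n = n, s_max = s_max,
                             kernel_sd = kernel_sd),
                 data = x, petite_controls = petite_controls,
                 optimize_general = optimize_general,
                 negll = negll, par_info = info,
                 reliable = kind != "two_gamma",
                 fingerprint = fingerprint,
                 convergence = list(code = best$convergence,
                                    message = best$message,
                                    n_starts = length(starts)),
                 seed = seed),
            class = "dme_fit")
}

# Summary-mode negative log-likelihood closure. The frequency grid,
# phase factor and per-strain error factors are precomputed; each
# evaluation costs one model-CF evaluation plus one FFT per distinct
# standard error.
summary_negll_factory <- function(summaries, kind, M_diploid, kernel_sd,
                                  n, s_max) {
  ds <- 2 * s_max / n
  s0 <- -s_max
  s_grid <- s0 + (0:(n - 1)) * ds
  jw <- c(0:(n / 2 - 1), -(n / 2):-1)
  omega <- 2 * pi * jw / (n * ds)
  phase <- exp(complex(imaginary = -omega * s0))
  se_u <- sort(unique(summaries$se))
  err_fac <- lapply(se_u, function(se) {
    exp(-omega^2 * max(kernel_sd^2 + se^2, ds^2) / 2)
  })
  s_by_se <- lapply(se_u, function(se) summaries$s_est[summaries$se == se])
  if (any(abs(summaries$s_est) > s_max * 0.95)) {
    stop_domain("observations near or beyond the grid edge; ",
                "increase `s_max`")
  }
  edge <- max(n %/% 128L, 1L)
  info <- dme_par_info(kind)
  function(th) {
    pars <- stats::setNames(mapply(trans_inv, th, info$trans), info$name)
    model <- try(pars_to_model(kind, pars, M_diploid), silent = TRUE)
    if (inherits(model, "try-error")) return(1e10)
    phi <- model_cf(model, omega)
    ll <- 0
    for (i in seq_along(se_u)) {
      dens <- Re(stats::fft(phi * err_fac[[i]] * phase)) / (n * ds)
      dens[dens < 0] <- 0
      tot <- sum(dens) * ds
      edge_mass <- (sum(dens[seq_len(edge)]) +
                      sum(dens[(n - edge + 1L):n])) * ds
      if (!is.finite(tot) || tot < 0.5 || edge_mass > 1e-3) return(1e10)
      dens <- dens / tot
      d_at <- stats::approx(s_grid, dens, xout = s_by_se[[i]])$y
      ll <- ll + sum(log(pmax(d_at, 1e-300)))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# Full-mode negative log-likelihood closure (the per-strain integral of
# the DME density against the paired-difference likelihood). The point
# mass of the compound-Poisson distribution at zero mutations (weight
# exp(-U), shifted by mu_unid for a degenerate Gaussian component) is
# handled analytically; only the continuous remainder of the CF is
# inverted and integrated numerically.
full_negll_factory <- function(pairs, ctrl_by_well, kind, M_diploid,
                               kernel_sd, n, s_max, general,
                               optimize_general) {
  d_by_strain <- split(pairs$d, pairs$strain_id)
  n_dme <- nrow(dme_par_info(kind))
  info <- dme_par_info(kind)
  function(th) {
    pars <- stats::setNames(mapply(trans_inv, th[seq_len(n_dme)],
                                   info$trans), info$name)
    model <- try(pars_to_model(kind, pars, M_diploid), silent = TRUE)
    if (inherits(model, "try-error")) return(1e10)
    g <- if (optimize_general) {
      theta_to_general(th[-seq_len(n_dme)])
    } else unclass(general)
    dec <- try(decompose_dme_density(model, n, s_max, kernel_sd),
               silent = TRUE)
    if (inherits(dec, "try-error")) return(1e10)
    ll <- full_data_loglik(dec, d_by_strain, ctrl_by_well, g)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# Split the model distribution into its atom (no effective mutations)
# and a continuous density tabulated on the FFT grid.
decompose_dme_density <- function(model, n, s_max, kernel_sd) {
  atom <- exp(-(snm_poisson_mean(model) +
                  (if (model$kind == "two_gamma") model$U_unid else 0)))
  atom_loc <- 0
  if (model$kind == "gaussian_unid") {
    if (model$sigma_unid > 0) atom <- 0 else atom_loc <- model$mu_unid
  }
  mass_c <- 1 - atom
  if (mass_c < 1e-12) {
    return(list(atom = atom, atom_loc = atom_loc, grid = NULL))
  }
  phi_c <- function(w) {
    model_cf(model, w) - atom * exp(complex(imaginary = w * atom_loc))
  }
  grid <- invert_cf_grid(phi_c, n, s_max, kernel_sd)
  edge <- max(n %/% 128L, 1L)
  edge_mass <- (sum(grid$density[seq_len(edge)]) +
                  sum(grid$density[(n - edge + 1L):n])) * grid$ds
  if (edge_mass > 1e-3) stop_domain("density grid too narrow")
  tot <- sum(grid$density) * grid$ds
  if (!is.finite(tot) || tot < mass_c * 0.5) {
    stop_domain("continuous density lost mass on the grid")
  }
  grid$density <- grid$density * (mass_c / tot)
  list(atom = atom, atom_loc = atom_loc, grid = grid)
}

# Sum over strains of log( atom * P(D | atom_loc, rho_i) +
# integral f_c(s) P(D | s, rho_i) ds ), with rho_i profiled out, plus
# the petite-control likelihood.
full_data_loglik <- function(dec, d_by_strain, ctrl_by_well, g,
                             n_quad = 257L) {
  grid <- dec$grid
  if (!is.null(grid)) {
    dmax <- max(grid$density)
    keep <- which(grid$density > dmax * 1e-13)
    lo <- min(keep); hi <- max(keep)
    idx <- unique(sort(c(which.max(grid$density),
                         round(seq(lo, hi,
                                   length.out = min(n_quad,
                                                    hi - lo + 1L))))))
    s_sub <- grid$s[idx]
    f_sub <- pmax(grid$density[idx], 1e-300)
    w <- diff(s_sub)
    w_trap <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2,
                w[length(w)] / 2)
    # renormalize the thinned quadrature to the known continuous mass
    mass_c <- sum(grid$density) * grid$ds
    log_fw <- log(f_sub) + log(w_trap)
    log_fw <- log_fw + (log(mass_c) - logsumexp(log_fw))
  } else {
    s_sub <- numeric(0)
    log_fw <- numeric(0)
  }
  log_atom <- if (dec$atom > 0) log(dec$atom) else -Inf
  s_eval <- c(s_sub, dec$atom_loc)
  n_sub <- length(s_sub)

  v_np <- g$sigma_nonpetite^2
  v_p <- g$sigma_petite^2
  sds <- sqrt(c(2 * v_np, v_np + v_p, v_np + v_p, 2 * v_p))
  ll <- petite_control_loglik(ctrl_by_well, mu_petite = g$mu_petite,
                              sigma_petite = g$sigma_petite,
                              sigma_plate = g$sigma_plate,
                              sigma_well = g$sigma_well)
  rho_j <- g$rho_ancestor
  for (d in d_by_strain) {
    # component log-densities over (s grid x observed differences);
    # only the mixture weights depend on rho, so they are reused across
    # the rho profile
    m1 <- outer(g$mu_ancestor * s_eval, d, "-")         # both non-petite
    m2 <- outer(g$mu_ancestor * (1 + s_eval) - g$mu_petite, d, "-")
    m3 <- (g$mu_petite - g$mu_ancestor) - matrix(d, nrow = length(s_eval),
                                                 ncol = length(d),
                                                 byrow = TRUE)
    m4 <- -matrix(d, nrow = length(s_eval), ncol = length(d),
                  byrow = TRUE)
    L <- list(stats::dnorm(m1, 0, sds[1], log = TRUE),
              stats::dnorm(m2, 0, sds[2], log = TRUE),
              stats::dnorm(m3, 0, sds[3], log = TRUE),
              stats::dnorm(m4, 0, sds[4], log = TRUE))
    Lmax <- Reduce(pmax, L)
    P <- lapply(L, function(M) exp(M - Lmax))
    strain_ll <- function(rho) {
      wts <- c((1 - rho) * (1 - rho_j), (1 - rho) * rho_j,
               rho * (1 - rho_j), rho * rho_j)
      dens <- wts[1] * P[[1]] + wts[2] * P[[2]] + wts[3] * P[[3]] +
        wts[4] * P[[4]]
      gk <- rowSums(log(pmax(dens, 1e-300)) + Lmax)
      logsumexp(c(log_fw + gk[seq_len(n_sub)], log_atom + gk[n_sub + 1L]))
    }
    opt <- stats::optimize(strain_ll, interval = c(0, 1),
                           maximum = TRUE, tol = 1e-5)
    ll <- ll + opt$objective
  }
  ll
}

#' Profile-likelihood confidence interval for a DME parameter
#'
#' Scans the named parameter over an adaptive grid (multiplicative steps
#' for positive parameters, logit steps for proportions), re-maximizing
#' all other free parameters at each point, and returns the two
#' crossings of `lnL_max - drop` located by quadratic interpolation.
#' When the profile is still above the threshold at the search bound, a
#' one-sided interval is returned. A non-monotone profile (as arises for
#' the weakly identified two-gamma variant) is flagged `reliable =
#' FALSE` rather than raising an error.
#'
#' @param fit a [fit_dme()] result.
#' @param param parameter name (e.g. `"m"`, `"k"`, `"q"`, `"p0"`).
#' @param drop log-likelihood drop defining the interval (default 2.5).
#' @param maxit per-point refit iteration cap.
#' @return List with `low`, `high`, `se`, `reliable`, and the scanned
#'   profile points.
#' @export
profile_ci <- function(fit, param, drop = 2.5, maxit = 200L) {
  stopifnot(inherits(fit, "dme_fit"))
  info <- fit$par_info
  if (!param %in% info$name) {
    stop_domain("unknown parameter: ", param, " (available: ",
                paste(info$name, collapse = ", "), ")")
  }
  j <- match(param, info$name)
  trans <- info$trans[j]
  th_hat <- mapply(trans_fwd, fit$par[info$name], info$trans)
  if (fit$mode == "full" && fit$optimize_general) {
    th_hat <- c(th_hat, general_to_theta(fit$general))
  }
  negll <- fit$negll
  prof <- function(x_t) {
    fix <- th_hat[j]
    obj <- function(th_rest) {
      th <- th_hat
      th[-j] <- th_rest
      th[j] <- x_t
      negll(th)
    }
    if (length(th_hat) == 1) return(-negll(x_t))
    opt <- stats::nlminb(th_hat[-j], obj,
                         control = list(iter.max = maxit,
                                        rel.tol = 1e-8))
    -opt$objective
  }
  x_hat_t <- th_hat[j]
  fhat <- fit$logLik
  step <- switch(trans, log = 0.15, logit = 0.3, identity =
                   max(abs(fit$par[[param]]) * 0.2, 1e-3))
  pc <- profile_interval(prof, x_hat_t, fhat, step, drop = drop,
                         lower = switch(trans, logit = -12, -Inf),
                         upper = switch(trans, logit = 12, Inf))
  list(low = trans_inv(pc$low, trans), high = trans_inv(pc$high, trans),
       se = pc$se, reliable = pc$reliable && fit$reliable,
       x = trans_inv(pc$x, trans), logLik = pc$f)
}

#' Compare fitted DME models by AIC and likelihood-ratio tests
#'
#' Tabulates log-likelihood, free-parameter count, AIC and delta-AIC of
#' each fit relative to a baseline fit, and, for pairs nested in the
#' baseline (the SNM-only model is nested in both the two-gamma and
#' Gaussian variants), the likelihood-ratio statistic `2 delta lnL` and
#' its chi-square p-value with df equal to the difference in free
#' parameters. Fits of different data (mismatched fingerprints) are
#' refused.
#'
#' @param fits list of [fit_dme()] results on the same data.
#' @param baseline index or name of the reference fit (default 1).
#' @return Data frame with one row per fit.
#' @export
compare_models <- function(fits, baseline = 1L) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE,
                                          "dme_fit")))
  fp <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fp, function(f) isTRUE(all.equal(f, fp[[1]])), TRUE))) {
    stop_domain("fits were made on different data; refusing to compare")
  }
  if (is.character(baseline)) baseline <- match(baseline, names(fits))
  base <- fits[[baseline]]
  nested_in <- function(a, b) {
    (a == b) ||
      (a == "snm_only" && b %in% c("two_gamma", "gaussian_unid"))
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    d_aic <- f$AIC - base$AIC
    stat <- p <- df <- NA_real_
    if (i != baseline && nested_in(base$model$kind, f$model$kind)) {
      df <- f$n_free_params - base$n_free_params
      stat <- max(2 * (f$logLik - base$logLik), 0)
      p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    }
    data.frame(model = f$model$kind, logLik = f$logLik,
               n_free_params = f$n_free_params, AIC = f$AIC,
               delta_AIC = d_aic, LRT_stat = stat, LRT_df = df,
               LRT_p = p, reliable = f$reliable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base$model$kind
  out
}

# ---- dme_fit methods ---------------------------------------------------

#' @export
print.dme_fit <- function(x, ...) {
  cat("DME fit (", x$mode, " mode): ", x$model$kind, "\n", sep = "")
  cat("  parameters:\n")
  for (nm in names(x$par)) {
    cat(sprintf("    %-10s %s\n", nm, format(x$par[[nm]], digits = 4)))
  }
  cat(sprintf("  logLik %.3f, %d free parameters, AIC %.3f\n",
              x$logLik, x$n_free_params, x$AIC))
  if (!x$reliable) {
    cat("  note: this variant is weakly identified;",
        "parameter estimates may be uninterpretable\n")
  }
  invisible(x)
}

#' @export
summary.dme_fit <- function(object, ...) print(object)

#' @export
coef.dme_fit <- function(object, ...) object$par

#' @export
logLik.dme_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- object$n_free_params
  class(val) <- "logLik"
  val
}

#' @export
confint.dme_fit <- function(object, parm = NULL, level = 0.95,
                            drop = 2.5, ...) {
  parm <- parm %||% object$par_info$name
  out <- t(vapply(parm, function(p) {
    ci <- profile_ci(object, p, drop = drop)
    c(low = ci$low, high = ci$high)
  }, c(low = 0, high = 0)))
  out
}

#' @export
predict.dme_fit <- function(object, type = c("density", "tail"),
                            cutoff = 1e-6,
                            direction = "negative", ...) {
  type <- match.arg(type)
  if (type == "density") {
    cf_to_pdf(object$model, n = object$grid$n,
              s_max = object$grid$s_max,
              kernel_sd = object$grid$kernel_sd)
  } else {
    dme_tail_probability(object$model, cutoff, direction)
  }
}

#' @export
simulate.dme_fit <- function(object, nsim = 1, seed = 1L, ...) {
  simulate_strain_effects(object$model, nsim, seed = seed)
}

#' @export
plot.dme_fit <- function(x, ...) {
  plot(predict(x, "density"), ...)
}
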