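#' Pair MA and reference colonies within imaging fields
#'
#' Differences in growth rate between an MA colony and a reference
#' colony from the same plate, well, and imaging field are free of
#' additive plate/well batch effects. Within each field, both colony
#' lists are shuffled (deterministically from `seed`) and paired up to
#' the smaller count; surplus colonies are discarded so that pairs are
#' independent. Fields lacking either side contribute no pairs.
#'
#' @param table a colony table (see [simulate_colony_table()] /
#'   [validate_colony_table()]).
#' @param seed integer seed controlling the random pairing.
#' @return An object of class `paired_diffs`: a data frame with columns
#'   `strain_id`, `plate`, `well`, `field`, `ma_colony`, `ref_colony`,
#'   `d` (MA minus reference growth rate). Strains present in the table
#'   but yielding no pairs are reported with a warning.
#' @export
pair_colonies <- function(table, seed) {
  table <- validate_colony_table(table, quiet = TRUE)
  ma <- table[table$role == "ma", ]
  ref <- table[table$role == "reference", ]
  key <- function(df) paste(df$plate, df$well, df$field, sep = "\r")
  ref_split <- split(seq_len(nrow(ref)), key(ref))
  out <- with_seed(seed, {
    groups <- split(seq_len(nrow(ma)), paste(key(ma), ma$strain_id,
                                             sep = "\r"))
    res <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      idx_ma <- groups[[gi]]
      k <- key(ma[idx_ma[1], , drop = FALSE])
      idx_ref <- ref_split[[k]]
      n <- min(length(idx_ma), length(idx_ref))
      if (is.null(idx_ref) || n == 0) next
      ia <- sample(idx_ma)[seq_len(n)]
      ib <- sample(idx_ref)[seq_len(n)]
      res[[gi]] <- data.frame(
        strain_id = ma$strain_id[ia], plate = ma$plate[ia],
        well = ma$well[ia], field = ma$field[ia],
        ma_colony = ma$colony_id[ia], ref_colony = ref$colony_id[ib],
        d = ma$growth_rate[ia] - ref$growth_rate[ib],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  if (is.null(out)) {
    out <- data.frame(strain_id = character(), plate = integer(),
                      well = character(), field = integer(),
                      ma_colony = character(), ref_colony = character(),
                      d = numeric(), stringsAsFactors = FALSE)
  }
  unpaired <- setdiff(unique(ma$strain_id), unique(out$strain_id))
  if (length(unpaired)) {
    warning("strains with no MA/reference pairs (excluded downstream): ",
            paste(unpaired, collapse = ", "), call. = FALSE)
  }
  structure(out, class = c("paired_diffs", "data.frame"), seed = seed)
}

#' Log-density of a paired growth-rate difference
#'
#' The difference `D` between an MA colony (strain `i`) and a reference
#' colony (strain `j`) growth rate, with petite statuses unknown, follows
#' a four-component Gaussian mixture: both non-petite, MA petite only,
#' reference petite only, or both petite. Component weights come from the
#' two petite proportions; component variances combine the non-petite and
#' petite across-colony variances. Computed with log-sum-exp.
#'
#' @param d difference value(s) (numeric vector).
#' @param mu_i,mu_j non-petite mean growth rates of the two strains.
#' @param rho_i,rho_j petite proportions, in `[0, 1]`.
#' @param sigma_nonpetite,sigma_petite combined across-colony sds (> 0).
#' @param mu_petite mean petite growth rate.
#' @return Vector of log-densities.
#' @export
diff_loglik <- function(d, mu_i, mu_j, rho_i, rho_j, sigma_nonpetite,
                        sigma_petite, mu_petite) {
  if (any(c(rho_i, rho_j) < 0 | c(rho_i, rho_j) > 1)) {
    stop_domain("petite proportions must be in [0, 1]")
  }
  if (sigma_nonpetite <= 0 || sigma_petite <= 0) {
    stop_domain("sds must be > 0")
  }
  v_np <- sigma_nonpetite^2
  v_p <- sigma_petite^2
  lw <- log(pmax(c((1 - rho_i) * (1 - rho_j), (1 - rho_i) * rho_j,
                   rho_i * (1 - rho_j), rho_i * rho_j), 0))
  mus <- c(mu_i - mu_j, mu_i - mu_petite, mu_petite - mu_j, 0)
  sds <- sqrt(c(2 * v_np, v_np + v_p, v_np + v_p, 2 * v_p))
  comps <- lapply(1:4, function(c) {
    if (!is.finite(lw[c])) return(rep(-Inf, length(d)))
    lw[c] + stats::dnorm(d, mus[c], sds[c], log = TRUE)
  })
  logsumexp_mats(comps)
}

#' Marginal log-likelihood of petite-only control colonies
#'
#' Control colonies are all petite; their growth rates within a well
#' share a plate + well batch effect, inducing an exchangeable
#' correlation. The likelihood is the per-well Gaussian
#' random-intercept marginal: `y_w ~ N(mu_petite, sigma_petite^2 I +
#' (sigma_plate^2 + sigma_well^2) J)`, evaluated in closed form.
#'
#' @param rates numeric vector of control growth rates, or a list of
#'   per-well vectors.
#' @param well well identifiers (ignored when `rates` is a list).
#' @param mu_petite,sigma_petite petite mean and across-colony sd (> 0).
#' @param sigma_plate,sigma_well batch-effect sds (>= 0).
#' @return Total log-likelihood.
#' @export
petite_control_loglik <- function(rates, well = NULL, mu_petite,
                                  sigma_petite, sigma_plate = 0,
                                  sigma_well = 0) {
  if (sigma_petite <= 0) stop_domain("`sigma_petite` must be > 0")
  if (sigma_plate < 0 || sigma_well < 0) stop_domain("sds must be >= 0")
  if (!is.list(rates)) {
    rates <- if (is.null(well)) list(rates) else split(rates, well)
  }
  v <- sigma_petite^2
  tau2 <- sigma_plate^2 + sigma_well^2
  ll <- 0
  for (y in rates) {
    n <- length(y)
    if (n == 0) next
    ybar <- mean(y)
    ss <- sum((y - ybar)^2)
    ll <- ll - 0.5 * (n * log(2 * pi) + (n - 1) * log(v) +
                        log(v + n * tau2) + ss / v +
                        n * (ybar - mu_petite)^2 / (v + n * tau2))
  }
  ll
}

# ---- internal machinery for the nested maximization -------------------

# Transform general parameters to an unconstrained vector and back.
general_to_theta <- function(g) {
  c(g$mu_ancestor, g$mu_petite, logit(min(max(g$rho_ancestor, 1e-6),
                                          1 - 1e-6)),
    log(g$sigma_nonpetite), log(g$sigma_petite),
    log(max(g$sigma_plate, 1e-6)), log(max(g$sigma_well, 1e-6)))
}

theta_to_general <- function(th) {
  list(mu_ancestor = th[1], mu_petite = th[2],
       rho_ancestor = inv_logit(th[3]), sigma_nonpetite = exp(th[4]),
       sigma_petite = exp(th[5]), sigma_plate = exp(th[6]),
       sigma_well = exp(th[7]))
}

# Per-strain log-likelihood of its differences given general params.
# Natural-scale fast path (mixture densities are well within double
# range for plausible parameters); falls back to the log-sum-exp
# implementation when a density underflows.
strain_diff_ll <- function(d, s, rho, g) {
  v_np <- g$sigma_nonpetite^2
  v_p <- g$sigma_petite^2
  sd1 <- sqrt(2 * v_np); sd2 <- sqrt(v_np + v_p); sd3 <- sqrt(2 * v_p)
  rho_j <- g$rho_ancestor
  mu_a <- g$mu_ancestor
  dens <- (1 - rho) * (1 - rho_j) * stats::dnorm(d, mu_a * s, sd1) +
    (1 - rho) * rho_j * stats::dnorm(d, mu_a * (1 + s) - g$mu_petite,
                                     sd2) +
    rho * (1 - rho_j) * stats::dnorm(d, g$mu_petite - mu_a, sd2) +
    rho * rho_j * stats::dnorm(d, 0, sd3)
  if (any(dens <= 0)) {
    return(sum(diff_loglik(d, mu_i = mu_a * (1 + s), mu_j = mu_a,
                           rho_i = rho, rho_j = rho_j,
                           sigma_nonpetite = g$sigma_nonpetite,
                           sigma_petite = g$sigma_petite,
                           mu_petite = g$mu_petite)))
  }
  sum(log(dens))
}

# Maximize over (s, rho) for one strain; 2-D Nelder-Mead on
# (s, logit rho), warm-startable. With `rho_zero` the petite proportion
# is pinned at 0 and only s is optimized (1-D golden section).
inner_strain_max <- function(d, g, start = NULL, rho_zero = FALSE) {
  if (rho_zero) {
    f <- function(s) strain_diff_ll(d, s, 0, g)
    s0 <- start[1] %||% (mean(d) / g$mu_ancestor)
    opt <- stats::optimize(f, interval = s0 + c(-0.3, 0.3),
                           maximum = TRUE, tol = 1e-7)
    return(list(s = opt$maximum, rho = 0, ll = opt$objective))
  }
  cold <- is.null(start)
  par0 <- start %||% c(mean(d) / g$mu_ancestor, logit(0.05))
  nf <- function(p) -strain_diff_ll(d, p[1], inv_logit(p[2]), g)
  opt <- stats::optim(par0, nf, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-9))
  if (cold) {
    # petite-free data can drive rho to the boundary; try a near-zero
    # restart on the first (cold) solve
    opt2 <- stats::optim(c(par0[1], logit(1e-4)), nf,
                         method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-9))
    if (opt2$value < opt$value) opt <- opt2
  }
  list(s = opt$par[1], rho = inv_logit(opt$par[2]), ll = -opt$value,
       par = opt$par)
}

# Profile log-likelihood over rho for a fixed s.
profile_ll_at_s <- function(d, s, g) {
  stats::optimize(function(r) strain_diff_ll(d, s, r, g),
                  interval = c(0, 1), maximum = TRUE,
                  tol = 1e-6)$objective
}

# Full-data negative log-likelihood of the general parameters, with
# per-strain (s, rho) profiled out. `warm` is an environment caching
# per-strain solutions across evaluations.
general_negll <- function(th, d_by_strain, ctrl_by_well, warm,
                          rho_zero = FALSE) {
  g <- theta_to_general(th)
  ll <- petite_control_loglik(ctrl_by_well, mu_petite = g$mu_petite,
                              sigma_petite = g$sigma_petite,
                              sigma_plate = g$sigma_plate,
                              sigma_well = g$sigma_well)
  if (rho_zero) g$rho_ancestor <- 0
  for (sid in names(d_by_strain)) {
    fit <- inner_strain_max(d_by_strain[[sid]], g,
                            start = warm$starts[[sid]],
                            rho_zero = rho_zero)
    warm$starts[[sid]] <- if (rho_zero) fit$s else fit$par
    warm$fits[[sid]] <- fit
    ll <- ll + fit$ll
  }
  -ll
}

# Moment-based starting values for the general parameters. The raw
# reference colony rates pin the ancestral mean: when petite
# proportions are near zero the difference likelihood is flat along
# mu_ancestor (only mu_ancestor * s is identified), so the optimizer
# keeps whatever value it starts from — make that the data's own
# non-petite reference mean.
general_start_values <- function(pairs, controls, ref_rates = NULL) {
  if (nrow(controls)) {
    mu_pet <- mean(controls$growth_rate)
    well_means <- tapply(controls$growth_rate, controls$well, mean)
    nbar <- nrow(controls) / length(well_means)
    sig_pet <- sqrt(mean(tapply(controls$growth_rate, controls$well,
                                stats::var), na.rm = TRUE))
    if (!is.finite(sig_pet)) sig_pet <- stats::sd(controls$growth_rate)
    batch_var <- if (length(well_means) >= 2) {
      max(stats::var(well_means) - sig_pet^2 / nbar, 2e-6)
    } else 2e-5
  } else {
    mu_pet <- NA
    sig_pet <- 0.03
    batch_var <- 2e-5
  }
  sig_np <- stats::mad(pairs$d) / sqrt(2)
  mu_anc <- if (!is.null(ref_rates) && length(ref_rates)) {
    med <- stats::median(ref_rates)
    cutpt <- if (is.finite(mu_pet)) (mu_pet + med) / 2 else -Inf
    mean(ref_rates[ref_rates > cutpt])
  } else if (is.finite(mu_pet)) mu_pet * 1.6 else 0.35
  general_params(mu_ancestor = mu_anc,
                 mu_petite = if (is.finite(mu_pet)) mu_pet else
                   mu_anc * 0.65,
                 rho_ancestor = 0.05,
                 sigma_nonpetite = max(sig_np, 1e-4),
                 sigma_petite = max(sig_pet, 1e-4),
                 sigma_plate = sqrt(batch_var / 2),
                 sigma_well = sqrt(batch_var / 2))
}

#' Fit the paired-difference petite-mixture colony model
#'
#' Estimates, by maximum likelihood, the seven "general" measurement
#' parameters (reference and petite growth rates, reference petite
#' proportion, combined non-petite/petite sds, plate and well batch-effect
#' sds) together with each MA strain's selection coefficient `s` and
#' petite proportion `rho`. The likelihood combines the four-component
#' mixture density of same-field MA-vs-reference growth-rate differences
#' (which cancels batch effects) with the random-intercept likelihood of
#' the petite-only control colonies. Maximization is nested: per-strain
#' `(s, rho)` are profiled out inside a bounded quasi-Newton search over
#' the general parameters, run from multiple starting points.
#'
#' Per-strain 95% confidence intervals on `s` come from the profile
#' likelihood (all other strain parameters re-optimized), at a
#' log-likelihood drop of `ci_drop` (default 2.5) with quadratic
#' interpolation between scan points; the per-strain standard error is
#' the sd of a quadratic fit to the profile. Each strain's p-value is a
#' likelihood-ratio test of `s = 0` (or `s = s_baseline` when a baseline
#' strain is designated) against a chi-square with 1 df, and strains are
#' flagged at a Benjamini-Hochberg FDR of `fdr_level`.
#'
#' @param table colony table containing MA, reference, and
#'   petite-control rows.
#' @param baseline optional strain id; when given (e.g. the ancestor
#'   strain assayed alongside the MA strains), selection coefficients are
#'   reported relative to that strain's fitted growth rate rather than to
#'   the in-well reference.
#' @param seed integer seed (controls colony pairing).
#' @param pairs optionally, a precomputed [pair_colonies()] result.
#' @param general_start optional [general_params()] starting values.
#' @param n_starts number of optimizer starts over the general
#'   parameters.
#' @param ci_drop profile log-likelihood drop defining the 95% CI
#'   (default 2.5).
#' @param fdr_level FDR for significance calls (default 0.05).
#' @param maxit iteration cap for the outer optimization.
#' @param compute_ci set `FALSE` to skip profile CIs/p-values (used
#'   internally for model comparison).
#' @return An object of class `colony_fit` with components `estimates`
#'   (per-strain data frame), `general` (fitted [general_params()]),
#'   `logLik`, `pairs`, `convergence`, and metadata.
#' @export
fit_colony_model <- function(table, baseline = NULL, seed = 1L,
                             pairs = NULL, general_start = NULL,
                             n_starts = 2L, ci_drop = 2.5,
                             fdr_level = 0.05, maxit = 200L,
                             compute_ci = TRUE) {
  table <- validate_colony_table(table, quiet = TRUE)
  if (is.null(pairs)) pairs <- pair_colonies(table, seed)
  controls <- table[table$role == "petite_control", ]
  if (!nrow(controls)) {
    stop_domain("table contains no petite-control colonies")
  }
  if (!any(table$role == "reference")) {
    stop_domain("table contains no reference colonies")
  }
  d_by_strain <- split(pairs$d, pairs$strain_id)
  ctrl_by_well <- split(controls$growth_rate, controls$well)
  if (!is.null(baseline) && !baseline %in% names(d_by_strain)) {
    stop_domain("baseline strain '", baseline, "' has no colony pairs")
  }

  g0 <- general_start %||%
    general_start_values(pairs, controls,
                         table$growth_rate[table$role == "reference"])
  th0 <- general_to_theta(g0)
  starts <- list(th0)
  if (n_starts > 1) {
    jit <- with_seed(seed + 1L, lapply(seq_len(n_starts - 1L), function(i)
      th0 + stats::rnorm(7, 0, c(0.02, 0.02, 0.5, 0.2, 0.2, 0.3, 0.3))))
    starts <- c(starts, jit)
  }

  best <- NULL
  for (st in starts) {
    warm <- new.env(parent = emptyenv())
    warm$starts <- list(); warm$fits <- list()
    opt <- stats::nlminb(st, general_negll, d_by_strain = d_by_strain,
                         ctrl_by_well = ctrl_by_well, warm = warm,
                         control = list(iter.max = maxit,
                                        rel.tol = 1e-9))
    if (is.null(best) || opt$objective < best$opt$objective) {
      best <- list(opt = opt, warm = warm)
    }
  }
  opt <- best$opt
  g_hat <- theta_to_general(opt$par)
  # final inner solve at the optimum; a cold restart guards against
  # warm starts stranded by earlier parameter values
  warm <- best$warm
  fits <- lapply(names(d_by_strain), function(sid) {
    d <- d_by_strain[[sid]]
    f1 <- inner_strain_max(d, g_hat, start = warm$starts[[sid]])
    f2 <- inner_strain_max(d, g_hat, start = NULL)
    if (f2$ll > f1$ll) f2 else f1
  })
  names(fits) <- names(d_by_strain)
  lnL <- sum(vapply(fits, `[[`, 0, "ll")) +
    petite_control_loglik(ctrl_by_well, mu_petite = g_hat$mu_petite,
                          sigma_petite = g_hat$sigma_petite,
                          sigma_plate = g_hat$sigma_plate,
                          sigma_well = g_hat$sigma_well)

  s_hat <- vapply(fits, `[[`, 0, "s")
  rho_hat <- vapply(fits, `[[`, 0, "rho")
  strain_ll <- vapply(fits, `[[`, 0, "ll")

  null_s <- 0
  if (!is.null(baseline)) null_s <- s_hat[[baseline]]

  est <- data.frame(strain_id = names(d_by_strain), s = s_hat,
                    rho = rho_hat, se = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (compute_ci) {
    for (i in seq_len(nrow(est))) {
      d <- d_by_strain[[est$strain_id[i]]]
      prof <- function(s) profile_ll_at_s(d, s, g_hat)
      fhat <- strain_ll[i]
      step <- max(stats::mad(d) / sqrt(2) / g_hat$mu_ancestor /
                    sqrt(length(d)), 1e-4)
      pc <- profile_interval(prof, est$s[i], fhat, step, drop = ci_drop)
      est$ci_low[i] <- pc$low
      est$ci_high[i] <- pc$high
      est$se[i] <- pc$se
      if (est$strain_id[i] == (baseline %||% "")) {
        est$p_value[i] <- NA_real_
      } else {
        lrt <- 2 * (fhat - prof(null_s))
        est$p_value[i] <- stats::pchisq(max(lrt, 0), df = 1,
                                        lower.tail = FALSE)
      }
    }
  }

  if (!is.null(baseline)) {
    sb <- s_hat[[baseline]]
    resc <- function(x) (1 + x) / (1 + sb) - 1
    est$s <- resc(est$s)
    est$ci_low <- resc(est$ci_low)
    est$ci_high <- resc(est$ci_high)
    est$se <- est$se / (1 + sb)
  }
  est <- call_significance(est, fdr_level = fdr_level)

  structure(list(estimates = est,
                 general = structure(g_hat, class = "general_params"),
                 logLik = lnL, n_strains = length(d_by_strain),
                 n_pairs = nrow(pairs), pairs = pairs,
                 controls_wells = length(ctrl_by_well),
                 baseline = baseline, ci_drop = ci_drop,
                 fdr_level = fdr_level, seed = seed,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    n_starts = length(starts)),
                 d_by_strain = d_by_strain,
                 ctrl_by_well = ctrl_by_well),
            class = "colony_fit")
}

# Generic profile-likelihood interval scanner. `f` returns the profile
# log-likelihood; `xhat`/`fhat` its maximum. Returns the two crossings
# of fhat - drop (one-sided at bounds), the sd of a quadratic fit to the
# profile, and a reliability flag (FALSE when the profile is
# non-monotone away from the optimum).
profile_interval <- function(f, xhat, fhat, step, drop = 2.5,
                             lower = -Inf, upper = Inf,
                             max_steps = 40L) {
  scan_side <- function(dir) {
    xs <- xhat; fs <- fhat
    cur <- step
    bound_hit <- FALSE
    for (i in seq_len(max_steps)) {
      x_new <- xs[length(xs)] + dir * cur
      bnd <- if (dir > 0) upper else lower
      if ((dir > 0 && x_new >= bnd) || (dir < 0 && x_new <= bnd)) {
        x_new <- bnd
        bound_hit <- TRUE
      }
      f_new <- f(x_new)
      xs <- c(xs, x_new); fs <- c(fs, f_new)
      if (f_new < fhat - drop) break
      if (bound_hit) break
      if (fhat - f_new < drop / 4) cur <- cur * 2 else cur <- cur * 1.3
    }
    list(x = xs, f = fs, bound_hit = bound_hit)
  }
  right <- scan_side(1)
  left <- scan_side(-1)
  target <- fhat - drop
  cross <- function(side) {
    n <- length(side$x)
    if (side$f[n] >= target) return(NA_real_) # one-sided (bound hit)
    interp_crossing(side$x, side$f, target)
  }
  hi <- cross(right)
  lo <- cross(left)
  if (is.na(hi)) hi <- right$x[length(right$x)]
  if (is.na(lo)) lo <- left$x[length(left$x)]
  allx <- c(rev(left$x), right$x[-1])
  allf <- c(rev(left$f), right$f[-1])
  reliable <- !is.unsorted(allf[allx <= xhat], strictly = FALSE) &&
    !is.unsorted(rev(allf[allx >= xhat]), strictly = FALSE)
  keep <- allf > fhat - 2 * drop
  se <- NA_real_
  if (sum(keep) >= 3) {
    co <- unname(stats::lm.fit(cbind(1, allx[keep], allx[keep]^2),
                               allf[keep])$coefficients)
    if (is.finite(co[3]) && co[3] < 0) se <- sqrt(-1 / (2 * co[3]))
  }
  list(low = lo, high = hi, se = se, reliable = reliable,
       x = allx, f = allf)
}

#' Benjamini-Hochberg significance calls on strain estimates
#'
#' Adjusts the per-strain likelihood-ratio p-values with the
#' Benjamini-Hochberg procedure and flags strains whose selection
#' coefficient differs from the baseline at the given FDR.
#'
#' @param estimates data frame with a `p_value` column (NA p-values,
#'   e.g. the baseline strain itself, are left unflagged).
#' @param fdr_level false discovery rate (default 0.05).
#' @return `estimates` with columns `q_value` and `significant` added or
#'   updated.
#' @export
call_significance <- function(estimates, fdr_level = 0.05) {
  p <- estimates$p_value
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  estimates$q_value <- q
  estimates$significant <- !is.na(q) & q <= fdr_level
  estimates
}

#' Likelihood-ratio test for the necessity of the petite mixture
#'
#' Fits the full colony model and a constrained model in which every
#' petite proportion (each MA strain's and the reference's) is fixed at
#' zero, and compares them by a likelihood-ratio test with degrees of
#' freedom equal to the number of petite-proportion parameters removed.
#' Note the null pins parameters at the boundary of their space, so the
#' chi-square reference is conservative.
#'
#' @inheritParams fit_colony_model
#' @return List with `statistic` (2 * delta lnL), `df`, `p_value`, and
#'   the two fits (`full`, `no_petite`).
#' @export
compare_petite_vs_nopetite <- function(table, baseline = NULL, seed = 1L,
                                       general_start = NULL,
                                       n_starts = 1L, maxit = 200L) {
  table <- validate_colony_table(table, quiet = TRUE)
  pairs <- pair_colonies(table, seed)
  full <- fit_colony_model(table, baseline = baseline, seed = seed,
                           pairs = pairs, general_start = general_start,
                           n_starts = n_starts, maxit = maxit,
                           compute_ci = FALSE)
  controls <- table[table$role == "petite_control", ]
  d_by_strain <- split(pairs$d, pairs$strain_id)
  ctrl_by_well <- split(controls$growth_rate, controls$well)
  th0 <- general_to_theta(general_start %||%
                            general_start_values(
                              pairs, controls,
                              table$growth_rate[table$role ==
                                                  "reference"]))
  warm <- new.env(parent = emptyenv())
  warm$starts <- list(); warm$fits <- list()
  opt0 <- stats::nlminb(th0, general_negll, d_by_strain = d_by_strain,
                        ctrl_by_well = ctrl_by_well, warm = warm,
                        rho_zero = TRUE,
                        control = list(iter.max = maxit, rel.tol = 1e-9))
  lnL0 <- -opt0$objective
  df <- length(d_by_strain) + 1L
  stat <- max(2 * (full$logLik - lnL0), 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       full = full, logLik_no_petite = lnL0)
}

# ---- colony_fit methods ------------------------------------------------

#' @export
print.colony_fit <- function(x, ...) {
  cat("Paired-difference petite-mixture colony model\n")
  cat(sprintf("  %d strains, %d colony pairs, %d petite-control wells\n",
              x$n_strains, x$n_pairs, x$controls_wells))
  cat(sprintf("  log-likelihood: %.2f\n", x$logLik))
  if (!is.null(x$baseline)) {
    cat("  s reported relative to baseline strain:", x$baseline, "\n")
  }
  nsig <- sum(x$estimates$significant, na.rm = TRUE)
  cat(sprintf("  %d / %d strains significant at FDR %.2g\n", nsig,
              sum(!is.na(x$estimates$p_value)), x$fdr_level))
  invisible(x)
}

#' @export
summary.colony_fit <- function(object, ...) {
  print(object)
  cat("\nGeneral parameters:\n")
  g <- object$general
  for (f in names(unclass(g))) {
    cat(sprintf("  %-16s %.5f\n", f, g[[f]]))
  }
  cat("\nStrain estimates:\n")
  print(object$estimates, digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
coef.colony_fit <- function(object, ...) {
  stats::setNames(object$estimates$s, object$estimates$strain_id)
}

#' @export
logLik.colony_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- 7L + 2L * object$n_strains
  class(val) <- "logLik"
  val
}

#' @export
confint.colony_fit <- function(object, parm, level = 0.95, ...) {
  ci <- as.matrix(object$estimates[, c("ci_low", "ci_high")])
  rownames(ci) <- object$estimates$strain_id
  colnames(ci) <- c("low", "high")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.colony_fit <- function(x, ...) {
  est <- x$estimates
  ord <- order(est$s)
  est <- est[ord, ]
  graphics::plot(est$s, seq_len(nrow(est)),
                 xlim = range(c(est$ci_low, est$ci_high), finite = TRUE),
                 pch = 19, col = ifelse(est$significant, "goldenrod",
                                        "grey40"),
                 xlab = "selection coefficient s", ylab = "strain rank",
                 ...)
  graphics::segments(est$ci_low, seq_len(nrow(est)), est$ci_high,
                     seq_len(nrow(est)), col = "grey70")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
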