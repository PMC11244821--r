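# Summaries drawn from a known snm_only truth, with Gaussian estimation
# error added directly (the colony stage has its own tests).
make_summaries <- function(n = 70, se = 0.003, seed = 9,
                           model = dme_model("snm_only", m = 5e-3,
                                             k = 0.2, q = 0.1,
                                             p0 = 0.1)) {
  tr <- simulate_strain_effects(model, n, seed = seed)
  set.seed(seed + 1)
  data.frame(strain_id = tr$strain_id,
             s_est = tr$s_true + rnorm(n, 0, se), se = se)
}

test_that("summary fit recovers snm_only truth parameters", {
  sm <- make_summaries(n = 70, se = 0.003, seed = 9)
  fit <- fit_dme(sm, "snm_only", n = 2^12, n_starts = 2, seed = 2)
  expect_equal(fit$n_free_params, 4)
  expect_equal(fit$AIC, 2 * 4 - 2 * fit$logLik)
  # point estimates in the right ballpark (m within a factor of ~2.5)
  expect_lt(abs(log(fit$par[["m"]] / 5e-3)), log(2.5))
  # profile CI for m covers the truth
  ci <- profile_ci(fit, "m")
  expect_lt(ci$low, 5e-3)
  expect_gt(ci$high, 5e-3)
})

test_that("the fitter's internal likelihood equals strain_summary_loglik", {
  sm <- make_summaries(n = 12, se = c(0.003, 0.005), seed = 30)
  sm$se <- rep(c(0.003, 0.005), 6)
  fit <- fit_dme(sm, "snm_only", n = 2^12, n_starts = 1)
  ll_ref <- strain_summary_loglik(sm$s_est, sm$se, fit$model,
                                  n = 2^12)
  expect_equal(fit$logLik, ll_ref, tolerance = 1e-6)
})

test_that("nesting: richer models never fit worse on the same data", {
  sm <- make_summaries(n = 40, se = 0.004, seed = 12)
  f0 <- fit_dme(sm, "snm_only", n = 2^11, n_starts = 2, seed = 5)
  f1 <- fit_dme(sm, "gaussian_unid", n = 2^11, n_starts = 2, seed = 5,
                start = c(coef(f0), mu_unid = 0, sigma_unid = 1e-4))
  f2 <- fit_dme(sm, "two_gamma", n = 2^11, n_starts = 2, seed = 5,
                start = c(coef(f0), m_unid = 1e-3, k_unid = 0.3,
                          q_unid = 0.1, U_unid = 1e-3))
  expect_gte(f1$logLik, f0$logLik - 1e-4)
  expect_gte(f2$logLik, f0$logLik - 1e-4)
  expect_false(f2$reliable) # two-gamma flagged weakly identified
})

test_that("neutral data drive the fit to a degenerate but finite optimum", {
  sm <- data.frame(strain_id = sprintf("s%02d", 1:20), s_est = 0,
                   se = 1e-4)
  fit <- fit_dme(sm, "snm_only", n = 2^12, n_starts = 1)
  expect_true(is.finite(fit$logLik))
  # neutrality: either almost all mutations neutral or vanishing effects
  expect_true(fit$par[["p0"]] > 0.9 || fit$par[["m"]] < 1e-4)
})

test_that("AIC bookkeeping and delta-AIC arithmetic are exact", {
  # two fits with the headline bookkeeping of the full-data fits:
  # 81 = 4 DME + 7 general + 70 petite proportions, 83 = 81 + 2
  mk <- function(kind, lnL, k) {
    structure(list(model = list(kind = kind), logLik = lnL,
                   n_free_params = k, AIC = 2 * k - 2 * lnL,
                   reliable = TRUE, fingerprint = c(1, 2, 3)),
              class = "dme_fit")
  }
  f_snm <- mk("snm_only", 384760.6, 81)
  f_gau <- mk("gaussian_unid", 384768.1, 83)
  expect_equal(f_snm$AIC, -769359.2, tolerance = 1e-9)
  expect_equal(f_gau$AIC, -769370.2, tolerance = 1e-9)
  cmp <- compare_models(list(f_snm, f_gau), baseline = 1)
  expect_equal(cmp$delta_AIC, c(0, -11.0), tolerance = 1e-9)
  expect_equal(cmp$LRT_df[2], 2)
  expect_equal(cmp$LRT_stat[2], 2 * (384768.1 - 384760.6),
               tolerance = 1e-9)
  # identical model fitted twice: delta AIC exactly 0
  cmp2 <- compare_models(list(f_snm, f_snm))
  expect_equal(cmp2$delta_AIC, c(0, 0))
  # mismatched data fingerprints are refused
  f_other <- mk("snm_only", 100, 81)
  f_other$fingerprint <- c(9, 9, 9)
  expect_error(compare_models(list(f_snm, f_other)), "different data")
})

test_that("full-data fit with a point-mass DME matches the colony likelihood", {
  sim <- small_assay(n_strains = 3, plates = 1, colonies = 60,
                     s_true = 0, rho = 0.1, seed = 81)
  pd <- pair_colonies(sim$table, seed = 82)
  controls <- sim$table[sim$table$role == "petite_control", ]
  gen <- combine_noise(sim$noise, rho_ancestor = sim$general$rho_ancestor)
  # DME concentrated at 0 (all mutations neutral)
  degenerate <- dme_model("snm_only", m = 1e-4, k = 0.2, q = 0.1, p0 = 1)
  negll <- madfe:::full_negll_factory(pd, split(controls$growth_rate,
                                                controls$well),
                                      "snm_only", 8, 2^-16, 2^12, 0.25,
                                      gen, FALSE)
  th <- mapply(madfe:::trans_fwd, madfe:::model_to_pars(degenerate),
               madfe:::dme_par_info("snm_only")$trans)
  lnL_dme <- -negll(th)
  # oracle: colony mixture likelihood with every s fixed at 0, rho
  # profiled, plus the petite-control term
  ll <- petite_control_loglik(split(controls$growth_rate, controls$well),
                              mu_petite = gen$mu_petite,
                              sigma_petite = gen$sigma_petite,
                              sigma_plate = gen$sigma_plate,
                              sigma_well = gen$sigma_well)
  for (d in split(pd$d, pd$strain_id)) {
    ll <- ll + optimize(function(r)
      sum(diff_loglik(d, gen$mu_ancestor, gen$mu_ancestor, r,
                      gen$rho_ancestor, gen$sigma_nonpetite,
                      gen$sigma_petite, gen$mu_petite)),
      c(0, 1), maximum = TRUE, tol = 1e-6)$objective
  }
  expect_equal(lnL_dme, ll, tolerance = 1e-3)
})

test_that("full-data fit recovers the DME scale at small problem size", {
  truth <- dme_model("snm_only", m = 0.02, k = 0.5, q = 0.1, p0 = 0.1)
  sim <- small_assay(n_strains = 10, plates = 2, colonies = 80,
                     seed = 91)
  # rebuild truths from the same model so s_true has the right scale
  pd <- pair_colonies(sim$table, seed = 92)
  controls <- sim$table[sim$table$role == "petite_control", ]
  gen <- combine_noise(sim$noise, rho_ancestor = sim$general$rho_ancestor)
  fit <- fit_dme(pd, "snm_only", petite_controls = controls,
                 general = gen, n = 2^11, s_max = 0.5, n_starts = 1,
                 start = c(m = 0.01, k = 0.4, q = 0.1, p0 = 0.2))
  expect_equal(fit$n_free_params, 4 + 7 + 10)
  expect_true(is.finite(fit$logLik))
  # mean effect of the fitted compound distribution tracks the mean
  # realized effect of the 10 simulated strains (which itself scatters
  # around the analytic mean at this sample size)
  mean_fit <- with(as.list(fit$par),
                   -(8 / 2) * (1 - p0) * m * (1 - 2 * q))
  realized <- simulate_strain_effects(truth, 10, seed = 91)
  expect_lt(abs(mean_fit - mean(realized$s_true)), 0.025)
})

test_that("summary and full fits agree on simulated data", {
  sim <- small_assay(n_strains = 12, plates = 2, colonies = 100,
                     seed = 101)
  cfit <- fit_colony_model(sim$table, seed = 102, n_starts = 1)
  sm <- data.frame(strain_id = cfit$estimates$strain_id,
                   s_est = cfit$estimates$s, se = cfit$estimates$se)
  sm <- sm[is.finite(sm$se) & sm$se > 0, ]
  fs <- fit_dme(sm, "snm_only", n = 2^11, n_starts = 1,
                start = c(m = 0.02, k = 0.5, q = 0.1, p0 = 0.1))
  pd <- cfit$pairs
  controls <- sim$table[sim$table$role == "petite_control", ]
  ff <- fit_dme(pd, "snm_only", petite_controls = controls,
                general = cfit$general, n = 2^11, n_starts = 1,
                start = coef(fs))
  # the two routes see the same data; their fitted mean effects agree
  # within the scale of the summary fit's profile uncertainty
  mean_of <- function(p) -(8 / 2) * (1 - p[["p0"]]) * p[["m"]] *
    (1 - 2 * p[["q"]])
  expect_lt(abs(mean_of(coef(fs)) - mean_of(coef(ff))), 0.01)
})

test_that("fitted quantities are invariant to rescaling all growth rates", {
  sim <- small_assay(n_strains = 5, plates = 1, colonies = 60,
                     s_true = c(-0.05, -0.02, 0, 0.02, -0.08),
                     rho = 0.05, seed = 111)
  f1 <- fit_colony_model(sim$table, seed = 112, n_starts = 1,
                         compute_ci = FALSE)
  tab2 <- sim$table
  tab2$growth_rate <- tab2$growth_rate * 3
  f2 <- fit_colony_model(tab2, seed = 112, n_starts = 1,
                         compute_ci = FALSE)
  expect_equal(f2$estimates$s, f1$estimates$s, tolerance = 5e-3)
})

test_that("profile CIs flag one-sided intervals at parameter bounds", {
  # p0 truth near 0: its lower CI end typically hits the bound
  sm <- make_summaries(n = 25, se = 0.004, seed = 13,
                       model = dme_model("snm_only", m = 0.01, k = 0.5,
                                         q = 0.1, p0 = 0.01))
  fit <- fit_dme(sm, "snm_only", n = 2^11, n_starts = 1)
  ci <- profile_ci(fit, "p0")
  expect_gte(ci$low, 0)
  expect_lte(ci$low, fit$par[["p0"]] + 1e-9)
  expect_lte(ci$high, 1)
})
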