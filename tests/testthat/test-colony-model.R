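test_that("pairing uses the min count per field and is seed-deterministic", {
  tab <- data.frame(
    strain_id = c(rep("A", 3), rep("reference", 2)),
    role = c(rep("ma", 3), rep("reference", 2)),
    plate = 1, well = "w1", field = 1,
    colony_id = paste0("c", 1:5),
    growth_rate = c(0.30, 0.31, 0.32, 0.35, 0.36),
    stringsAsFactors = FALSE)
  pd <- pair_colonies(tab, seed = 1)
  expect_equal(nrow(pd), 2) # 3 MA vs 2 ref -> 2 pairs
  expect_identical(pd, pair_colonies(tab, seed = 1))
  # each colony used at most once
  expect_false(anyDuplicated(pd$ma_colony) > 0)
  expect_false(anyDuplicated(pd$ref_colony) > 0)
  # a strain without any reference in its field yields no pairs
  tab2 <- tab
  tab2$field <- c(1, 1, 1, 2, 2)
  expect_warning(pd2 <- pair_colonies(tab2, seed = 1), "no MA/reference")
  expect_equal(nrow(pd2), 0)
})

test_that("difference log-density matches the four-outcome enumeration", {
  pars <- list(mu_i = 0.33, mu_j = 0.35, rho_i = 0.3, rho_j = 0.1,
               sigma_nonpetite = 0.035, sigma_petite = 0.03,
               mu_petite = 0.22)
  d <- seq(-0.3, 0.3, length.out = 7)
  got <- do.call(diff_loglik, c(list(d = d), pars))
  # brute force: sum the density over the 2x2 petite-status outcomes
  oracle <- sapply(d, function(x) {
    tot <- 0
    for (pi in 0:1) for (pj in 0:1) {
      w <- ifelse(pi, pars$rho_i, 1 - pars$rho_i) *
        ifelse(pj, pars$rho_j, 1 - pars$rho_j)
      mi <- ifelse(pi, pars$mu_petite, pars$mu_i)
      mj <- ifelse(pj, pars$mu_petite, pars$mu_j)
      vi <- ifelse(pi, pars$sigma_petite, pars$sigma_nonpetite)^2
      vj <- ifelse(pj, pars$sigma_petite, pars$sigma_nonpetite)^2
      tot <- tot + w * dnorm(x, mi - mj, sqrt(vi + vj))
    }
    log(tot)
  })
  expect_equal(got, oracle, tolerance = 1e-12)
  # degenerate corners reduce to single Gaussians
  expect_equal(
    diff_loglik(0.01, 0.33, 0.35, 0, 0, 0.035, 0.03, 0.22),
    dnorm(0.01, -0.02, sqrt(2) * 0.035, log = TRUE))
  expect_equal(
    diff_loglik(0.01, 0.33, 0.35, 1, 1, 0.035, 0.03, 0.22),
    dnorm(0.01, 0, sqrt(2) * 0.03, log = TRUE))
})

test_that("petite-control likelihood handles batch correlation", {
  # no batch effects: iid normal
  y <- c(0.21, 0.22, 0.25, 0.19)
  expect_equal(
    petite_control_loglik(y, mu_petite = 0.22, sigma_petite = 0.03),
    sum(dnorm(y, 0.22, 0.03, log = TRUE)))
  # single colony at the mode
  expect_equal(
    petite_control_loglik(0.22, mu_petite = 0.22, sigma_petite = 0.03,
                          sigma_plate = 0.01, sigma_well = 0.01),
    dnorm(0.22, 0.22, sqrt(0.03^2 + 2 * 1e-4), log = TRUE))
  # exchangeable-covariance marginal equals the direct multivariate form
  set.seed(5)
  yw <- rnorm(6, 0.22, 0.04)
  tau2 <- 0.01^2 + 0.005^2
  Sigma <- diag(0.03^2, 6) + tau2
  mvn_ll <- -0.5 * (6 * log(2 * pi) + determinant(Sigma)$modulus +
                      t(yw - 0.22) %*% solve(Sigma) %*% (yw - 0.22))
  expect_equal(
    petite_control_loglik(list(yw), mu_petite = 0.22,
                          sigma_petite = 0.03, sigma_plate = 0.01,
                          sigma_well = 0.005),
    as.numeric(mvn_ll), tolerance = 1e-10)
})

test_that("control-data likelihood recovers the petite mean", {
  des <- design_2000gen(n_strains = 1, plates = 6,
                        petite_control_wells = 2,
                        colonies_per_control_well = 150)
  gen <- general_params()
  ctrl <- simulate_petite_controls(des, gen, noise_model(), seed = 21)
  byw <- split(ctrl$growth_rate, ctrl$well)
  prof <- sapply(seq(0.20, 0.24, by = 0.0005), function(mu) {
    petite_control_loglik(byw, mu_petite = mu, sigma_petite = 0.031,
                          sigma_plate = 0.01, sigma_well = 0.005)
  })
  mu_hat <- seq(0.20, 0.24, by = 0.0005)[which.max(prof)]
  expect_lt(abs(mu_hat - gen$mu_petite), 0.01)
})

test_that("Benjamini-Hochberg calls match hand-computed thresholds", {
  est <- data.frame(strain_id = letters[1:4],
                    p_value = c(0.001, 0.01, 0.02, 0.9))
  out <- call_significance(est, fdr_level = 0.05)
  # BH thresholds at ranks 1..4: 0.0125, 0.025, 0.0375, 0.05
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  # all p = 1: nothing significant
  est2 <- data.frame(p_value = rep(1, 5))
  expect_false(any(call_significance(est2)$significant))
  # single test: BH reduces to the raw level
  est3 <- data.frame(p_value = 0.04)
  expect_true(call_significance(est3)$significant)
  # NA p-values (baseline strain) stay unflagged
  est4 <- data.frame(p_value = c(NA, 0.01))
  out4 <- call_significance(est4)
  expect_false(out4$significant[1])
})

test_that("profile interval solves the quadratic closed form", {
  f <- function(x) -2 * (x - 2)^2 + 10
  pc <- madfe:::profile_interval(f, xhat = 2, fhat = 10, step = 0.2,
                                 drop = 2.5)
  expect_equal(pc$low, 2 - sqrt(2.5 / 2), tolerance = 1e-6)
  expect_equal(pc$high, 2 + sqrt(2.5 / 2), tolerance = 1e-6)
  expect_equal(pc$se, sqrt(1 / 4), tolerance = 1e-6)
  expect_true(pc$reliable)
  # flat profile at a bound gives a one-sided interval
  g <- function(x) if (x < 0) -100 else -0.001 * x
  pc2 <- madfe:::profile_interval(g, xhat = 0.5, fhat = g(0.5),
                                  step = 0.5, lower = 0, upper = 1)
  expect_equal(pc2$high, 1) # bound hit before the drop
})

test_that("degenerate noise-free data give the exact rate ratio", {
  des <- design_2000gen(n_strains = 2, plates = 1,
                        colonies_per_side = 20,
                        colonies_per_control_well = 20)
  truths <- data.frame(strain_id = des$strain_ids,
                       s_true = c(-0.05, 0.02), rho_true = 0,
                       n_mutations = 0)
  gen <- general_params(rho_ancestor = 0)
  noi <- noise_model(1e-4, 1e-4, 0, 0, 0) # nearly noise-free
  tab <- rbind(simulate_colony_table(des, truths, gen, noi, seed = 31),
               simulate_petite_controls(des, gen, noi, seed = 32))
  fit <- fit_colony_model(tab, seed = 33, n_starts = 1,
                          compute_ci = FALSE)
  expect_equal(fit$estimates$s, truths$s_true, tolerance = 1e-2)
})

test_that("estimates recover truth and CIs behave on simulated data", {
  sim <- small_assay(n_strains = 8, plates = 2, colonies = 120,
                     s_true = c(0, 0, -0.02, -0.02, -0.05, -0.05,
                                -0.1, 0.03),
                     rho = c(0.05, 0.3), seed = 51)
  fit <- fit_colony_model(sim$table, seed = 52, n_starts = 1)
  est <- fit$estimates
  expect_true(all(est$ci_low <= est$s & est$s <= est$ci_high))
  covered <- sim$truths$s_true >= est$ci_low &
    sim$truths$s_true <= est$ci_high
  expect_gte(sum(covered), 7) # ~95% coverage, binomial slack at n = 8
  # petite proportions recovered to first order
  expect_lt(mean(abs(est$rho - sim$truths$rho_true)), 0.08)
  # strains simulated at s = 0: CI overlaps 0
  expect_true(all(est$ci_low[1:2] < 0 & est$ci_high[1:2] > 0))
})

test_that("petite mixture LRT prefers the petite model when petites exist", {
  sim <- small_assay(n_strains = 4, plates = 2, colonies = 100,
                     s_true = c(0, -0.03, -0.05, 0.01), rho = 0.2,
                     seed = 61)
  cmp <- compare_petite_vs_nopetite(sim$table, seed = 62)
  expect_gte(cmp$statistic, 0) # nesting: constrained lnL <= full lnL
  expect_equal(cmp$df, 5)      # 4 strain rhos + the reference rho
  expect_lt(cmp$p_value, 1e-3)
})

test_that("selection coefficients are reported relative to the baseline strain", {
  # reference strain grows 3% faster than the designated baseline:
  # s must be relative to the baseline, not the in-well reference
  des <- experiment_design(c("anc", "mut1", "mut2"), plates = 2,
                           wells_per_strain_per_plate = 2,
                           strain_plate_assignment =
                             list(anc = 1:2, mut1 = 1:2, mut2 = 1:2),
                           colonies_per_well_ma = 120,
                           colonies_per_well_ref = 120,
                           baseline_strain_id = "anc")
  truths <- data.frame(strain_id = c("anc", "mut1", "mut2"),
                       s_true = c(0, -0.04, 0.02), rho_true = 0.08,
                       n_mutations = 0)
  gen <- general_params()
  noi <- noise_model()
  tab <- rbind(
    simulate_colony_table(des, truths, gen, noi, seed = 71,
                          s_reference = 0.03),
    simulate_petite_controls(des, gen, noi, seed = 72))
  fit <- fit_colony_model(tab, baseline = "anc", seed = 73, n_starts = 1)
  est <- fit$estimates
  expect_equal(est$s[est$strain_id == "anc"], 0)
  for (i in 2:3) {
    expect_lt(abs(est$s[est$strain_id == truths$strain_id[i]] -
                    truths$s_true[i]), 0.02)
  }
  expect_true(is.na(est$p_value[est$strain_id == "anc"]))
})
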