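test_that("strain-effect draws honor degenerate parameter settings", {
  z <- dme_model("snm_only", m = 0.01, k = 0.5, q = 0.5, p0 = 0,
                 M_diploid = 0)
  tr <- simulate_strain_effects(z, 20, seed = 1)
  expect_true(all(tr$s_true == 0))
  expect_true(all(tr$n_mutations == 0))

  pos <- dme_model("single_dme", m = 0.01, k = 0.5, q = 1, U_free = 5)
  tr2 <- simulate_strain_effects(pos, 50, seed = 2)
  expect_true(all(tr2$s_true[tr2$n_mutations > 0] > 0))
})

test_that("mean simulated effect matches the compound-Poisson expectation", {
  mod <- dme_model("snm_only", m = 0.004, k = 0.1, q = 0.1, p0 = 0.1,
                   M_diploid = 8) # U_total = 4
  tr <- simulate_strain_effects(mod, 1e5, seed = 3)
  expected <- -4 * 0.004 * (1 - 2 * 0.1) * (1 - 0.1)
  # MC standard error of the mean
  se <- sd(tr$s_true) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$s_true) - expected), 4 * se)
  # mutation counts are Poisson(M/2)
  expect_equal(mean(tr$n_mutations), 4, tolerance = 0.05)
})

test_that("colony table has the layout forced by the design", {
  sim <- small_assay(n_strains = 4, plates = 2, colonies = 30)
  tab <- sim$table
  assay <- tab[tab$role != "petite_control", ]
  expect_equal(nrow(assay), 4 * (30 + 30))
  expect_equal(sort(unique(assay$strain_id[assay$role == "ma"])),
               sort(sim$design$strain_ids))
  # every assay well holds one MA strain plus the reference
  for (w in unique(assay$well)) {
    roles <- assay$role[assay$well == w]
    expect_setequal(unique(roles), c("ma", "reference"))
  }
  # petite controls: one well per plate
  ctrl <- tab[tab$role == "petite_control", ]
  expect_equal(length(unique(ctrl$well)), 2)
})

test_that("zero noise and zero petites give exactly the ancestral rate", {
  des <- design_2000gen(n_strains = 2, plates = 1, colonies_per_side = 10)
  truths <- data.frame(strain_id = des$strain_ids, s_true = 0,
                       rho_true = 0, n_mutations = 0)
  gen <- general_params(rho_ancestor = 0)
  noi <- noise_model(0, 0, 0, 0, 0)
  tab <- simulate_colony_table(des, truths, gen, noi, seed = 5)
  expect_true(all(tab$growth_rate == gen$mu_ancestor))
})

test_that("empirical petite fraction matches the Bernoulli rate", {
  des <- design_2000gen(n_strains = 1, plates = 1,
                        colonies_per_side = 10000)
  truths <- data.frame(strain_id = des$strain_ids, s_true = 0,
                       rho_true = 0.3, n_mutations = 0)
  gen <- general_params(rho_ancestor = 0)
  noi <- noise_model(sigma_plate = 0, sigma_well = 0)
  tab <- simulate_colony_table(des, truths, gen, noi, seed = 6)
  ma <- tab[tab$role == "ma", ]
  mid <- (gen$mu_petite + gen$mu_ancestor) / 2
  frac <- mean(ma$growth_rate < mid)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / nrow(ma)) + 0.01)
})

test_that("petite controls have the petite mean and combined sd", {
  des <- design_2000gen(n_strains = 1, plates = 4,
                        colonies_per_side = 10,
                        petite_control_wells = 5,
                        colonies_per_control_well = 500)
  gen <- general_params()
  noi <- noise_model(sigma_plate = 0, sigma_well = 0)
  ctrl <- simulate_petite_controls(des, gen, noi, seed = 7)
  expect_true(all(ctrl$role == "petite_control"))
  expect_equal(mean(ctrl$growth_rate), gen$mu_petite, tolerance = 0.01)
  expect_equal(sd(ctrl$growth_rate),
               sqrt(noi$sigma_petite_bio^2 + noi$sigma_col^2),
               tolerance = 0.02)
  # no control wells -> empty table
  des0 <- design_2000gen(n_strains = 1, plates = 1,
                         petite_control_wells = 0)
  expect_equal(nrow(simulate_petite_controls(des0, gen, noi, seed = 1)),
               0)
  # degenerate noise -> all rates at mu_petite
  ctrl0 <- simulate_petite_controls(des, gen, noise_model(0, 0, 0, 0, 0),
                                    seed = 8)
  expect_true(all(ctrl0$growth_rate == gen$mu_petite))
})

test_that("well-mean variance decomposes into batch and within-well parts", {
  noi <- noise_model(sigma_plate = 0.02, sigma_well = 0.01)
  gen <- general_params(rho_ancestor = 0)
  nwell <- 200
  des <- design_2000gen(n_strains = nwell, plates = nwell,
                        colonies_per_side = 50)
  truths <- data.frame(strain_id = des$strain_ids, s_true = 0,
                       rho_true = 0, n_mutations = 0)
  tab <- simulate_colony_table(des, truths, gen, noi, seed = 9)
  ref <- tab[tab$role == "reference", ]
  wm <- tapply(ref$growth_rate, ref$well, mean)
  within_var <- noi$sigma_nonpetite_bio^2 + noi$sigma_col^2
  expected <- noi$sigma_plate^2 + noi$sigma_well^2 + within_var / 50
  # chi-square MC tolerance on a variance from `nwell` well means
  expect_lt(abs(var(wm) - expected), 4 * expected * sqrt(2 / nwell))
})

test_that("paired differences cancel batch effects", {
  # plate sd set 10x the colony sd: the paired-difference mean and
  # variance must not feel it
  noi <- noise_model(sigma_nonpetite_bio = 0.02, sigma_col = 0.01,
                     sigma_plate = 0.25, sigma_well = 0.05)
  gen <- general_params(rho_ancestor = 0)
  sim <- small_assay(n_strains = 10, plates = 5, colonies = 400,
                     s_true = -0.05, rho = 0, noise = noi,
                     general = gen)
  pd <- pair_colonies(sim$table, seed = 10)
  expect_lt(abs(mean(pd$d) - gen$mu_ancestor * -0.05),
            4 * sd(pd$d) / sqrt(nrow(pd)))
  v_expected <- 2 * (0.02^2 + 0.01^2)
  expect_lt(abs(var(pd$d) - v_expected),
            4 * v_expected * sqrt(2 / nrow(pd)))
})

test_that("identical seeds and configs give byte-identical tables", {
  a <- small_assay(seed = 42)
  b <- small_assay(seed = 42)
  expect_identical(a$table, b$table)
  c <- small_assay(seed = 43)
  expect_false(identical(a$table$growth_rate, c$table$growth_rate))
})

test_that("noise and parameter constructors enforce their domains", {
  expect_error(general_params(mu_petite = 0.4), "mu_petite")
  expect_error(general_params(rho_ancestor = 1.2), "rho_ancestor")
  expect_error(noise_model(sigma_col = -1), "deviation")
  g <- combine_noise(noise_model(0.03, 0.025, 0.018, 0.01, 0.005))
  expect_equal(g$sigma_nonpetite, sqrt(0.03^2 + 0.018^2))
  expect_equal(g$sigma_petite, sqrt(0.025^2 + 0.018^2))
})
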