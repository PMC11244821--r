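# Shared fixtures: small simulated assays built in code.

table1_gaussian <- function() {
  dme_model("gaussian_unid", m = 4.1e-3, k = 5.5e-2, q = 0.06,
            p0 = 0.059, mu_unid = -3.3e-3, sigma_unid = 5.5e-3,
            M_diploid = 8)
}

table1_snm_only <- function() {
  dme_model("snm_only", m = 5.0e-3, k = 0.14, q = 0.105, p0 = 0.001,
            M_diploid = 8)
}

# A small assay: n strains on a couple of plates with petite controls.
small_assay <- function(n_strains = 6, plates = 2, colonies = 80,
                        s_true = NULL, rho = 0.1, seed = 11,
                        noise = noise_model(),
                        general = general_params()) {
  des <- design_2000gen(n_strains = n_strains, plates = plates,
                        colonies_per_side = colonies)
  truths <- if (is.null(s_true)) {
    simulate_strain_effects(dme_model("snm_only", m = 0.02, k = 0.5,
                                      q = 0.1, p0 = 0.1),
                            n_strains, seed = seed, rho = rho)
  } else {
    data.frame(strain_id = des$strain_ids,
               s_true = rep_len(s_true, n_strains),
               rho_true = rep_len(rho, n_strains),
               n_mutations = NA_integer_)
  }
  truths$strain_id <- des$strain_ids
  tab <- rbind(
    simulate_colony_table(des, truths, general, noise, seed = seed + 1),
    simulate_petite_controls(des, general, noise, seed = seed + 2))
  list(design = des, truths = truths, table = tab, general = general,
       noise = noise)
}

# Monte-Carlo draws of the per-strain combined effect under a DME model
# (independent of the package's own simulate_strain_effects where
# needed, but reusing it is fine when it is itself the tested unit).
mc_compound_sums <- function(model, n, seed) {
  set.seed(seed)
  U <- (model$M_diploid / 2)
  if (model$kind == "single_dme") U <- model$U_free
  counts <- rpois(n, U)
  total <- sum(counts)
  keep <- runif(total) >= model$p0
  mag <- rgamma(total, shape = model$k, scale = model$m / model$k)
  sgn <- ifelse(runif(total) < model$q, 1, -1)
  z <- mag * sgn * keep
  idx <- rep.int(seq_len(n), counts)
  s <- numeric(n)
  agg <- rowsum(z, idx)
  s[as.integer(rownames(agg))] <- agg[, 1]
  s
}
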