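#' Describe the layout of a microcolony growth-rate assay
#'
#' An experiment design records how MA strains are distributed over
#' plates, wells, and imaging fields, how many MA and reference colonies
#' are measured per well, and how many petite-only control wells each
#' plate carries. Two ready-made constructors reproduce the layouts of
#' the assays the package models: [design_2000gen()] and [design_msh3()].
#'
#' @param strain_ids character vector of MA strain identifiers.
#' @param plates number of experimental plates (imaging days).
#' @param wells_per_strain_per_plate wells occupied by each strain on
#'   each plate it appears on.
#' @param strain_plate_assignment named list mapping each strain id to
#'   the integer plate(s) it is assayed on; `NULL` distributes strains
#'   round-robin across plates at simulation time.
#' @param colonies_per_well_ma,colonies_per_well_ref MA and reference
#'   colonies measured per well.
#' @param fields_per_well imaging fields per well (colonies are split
#'   evenly across fields).
#' @param petite_control_wells petite-only control wells per plate.
#' @param colonies_per_control_well colonies per petite-control well.
#' @param baseline_strain_id strain against which selection coefficients
#'   are reported; `NULL` means the in-well reference strain is the
#'   baseline (the 2,000-generation convention).
#' @return An object of class `ma_design`.
#' @export
experiment_design <- function(strain_ids, plates,
                              wells_per_strain_per_plate = 1L,
                              strain_plate_assignment = NULL,
                              colonies_per_well_ma = 500L,
                              colonies_per_well_ref = 500L,
                              fields_per_well = 4L,
                              petite_control_wells = 1L,
                              colonies_per_control_well = 200L,
                              baseline_strain_id = NULL) {
  stopifnot(length(strain_ids) >= 1, plates >= 1,
            wells_per_strain_per_plate >= 1, colonies_per_well_ma >= 1,
            colonies_per_well_ref >= 1, fields_per_well >= 1,
            petite_control_wells >= 0)
  strain_ids <- as.character(strain_ids)
  if (anyDuplicated(strain_ids)) stop_domain("duplicate strain ids")
  if (!is.null(strain_plate_assignment)) {
    missing <- setdiff(strain_ids, names(strain_plate_assignment))
    if (length(missing)) {
      stop_domain("strains without plate assignment: ",
                  paste(missing, collapse = ", "))
    }
  }
  if (!is.null(baseline_strain_id) &&
      !baseline_strain_id %in% strain_ids) {
    stop_domain("`baseline_strain_id` must be one of `strain_ids`")
  }
  structure(list(strain_ids = strain_ids, plates = as.integer(plates),
                 wells_per_strain_per_plate =
                   as.integer(wells_per_strain_per_plate),
                 strain_plate_assignment = strain_plate_assignment,
                 colonies_per_well_ma = as.integer(colonies_per_well_ma),
                 colonies_per_well_ref = as.integer(colonies_per_well_ref),
                 fields_per_well = as.integer(fields_per_well),
                 petite_control_wells = as.integer(petite_control_wells),
                 colonies_per_control_well =
                   as.integer(colonies_per_control_well),
                 baseline_strain_id = baseline_strain_id),
            class = "ma_design")
}

#' @rdname experiment_design
#' @param n_strains number of MA strains.
#' @param colonies_per_side MA (and reference) colonies per well.
#' @details `design_2000gen()` reproduces the 2,000-generation assay:
#'   each of 70 haploid MA strains in a single well, 14 plates, about
#'   500 MA and 500 reference colonies per well; selection coefficients
#'   are relative to the in-well reference (a derivative of the
#'   ancestor).
#' @export
design_2000gen <- function(n_strains = 70L, plates = 14L,
                           colonies_per_side = 500L, ...) {
  experiment_design(sprintf("MAH%03d", seq_len(n_strains)),
                    plates = plates,
                    wells_per_strain_per_plate = 1L,
                    colonies_per_well_ma = colonies_per_side,
                    colonies_per_well_ref = colonies_per_side, ...)
}

#' @rdname experiment_design
#' @param ... passed on to [experiment_design()].
#' @details `design_msh3()` reproduces the slippage-repair-deficient
#'   (msh3 deletion) assay: 18 MA strains, each in 3 wells per plate on
#'   each of 10 plates, with the msh3 ancestor itself assayed in 9 wells
#'   per plate and designated the baseline for `s`.
#' @export
design_msh3 <- function(n_strains = 18L, plates = 10L,
                        colonies_per_side = 500L, ...) {
  ids <- c(sprintf("msh3MA%02d", seq_len(n_strains)), "msh3anc")
  assign <- c(
    stats::setNames(rep(list(seq_len(plates)), n_strains),
                    ids[seq_len(n_strains)]),
    list(msh3anc = seq_len(plates)))
  wells <- stats::setNames(rep(3L, n_strains + 1L), ids)
  wells["msh3anc"] <- 9L
  d <- experiment_design(ids, plates = plates,
                         wells_per_strain_per_plate = 3L,
                         strain_plate_assignment = assign,
                         colonies_per_well_ma = colonies_per_side,
                         colonies_per_well_ref = colonies_per_side,
                         baseline_strain_id = "msh3anc", ...)
  d$wells_per_strain <- wells
  d
}

#' @export
print.ma_design <- function(x, ...) {
  cat("MA assay design:", length(x$strain_ids), "strains,", x$plates,
      "plates,", x$wells_per_strain_per_plate, "well(s)/strain/plate\n")
  cat("  colonies/well:", x$colonies_per_well_ma, "MA +",
      x$colonies_per_well_ref, "reference;", x$fields_per_well,
      "fields/well\n")
  cat("  petite-control wells/plate:", x$petite_control_wells, "\n")
  if (!is.null(x$baseline_strain_id)) {
    cat("  baseline strain:", x$baseline_strain_id, "\n")
  }
  invisible(x)
}

#' Shared measurement-model parameters of the colony assay
#'
#' `general_params()` bundles the "general" parameters common to all
#' strains: the non-petite reference growth rate `mu_ancestor`, the
#' petite growth rate `mu_petite`, the reference strain's petite
#' proportion `rho_ancestor`, the combined (biological + colony
#' measurement) growth-rate standard deviations of non-petite and petite
#' colonies, and the plate and well batch-effect standard deviations.
#' `noise_model()` holds the generative decomposition used by the
#' simulator, in which colony measurement noise `sigma_col` is kept
#' separate from biological variation; the fitter only ever sees the
#' combined `sigma_nonpetite^2 = sigma_col^2 + sigma_nonpetite_bio^2`
#' (and likewise for petites), since the two are not separately
#' identifiable from growth data.
#'
#' Defaults are in units of 1/hour for a yeast microcolony assay with an
#' ancestral growth rate of 0.35/h and petites growing at about
#' two-thirds of that rate.
#'
#' @param mu_ancestor non-petite growth rate of the ancestral/reference
#'   strain (1/h).
#' @param mu_petite mean petite growth rate (must be below
#'   `mu_ancestor`).
#' @param rho_ancestor petite proportion of the reference strain.
#' @param sigma_nonpetite,sigma_petite combined across-colony sds.
#' @param sigma_plate,sigma_well batch-effect sds.
#' @return An object of class `general_params`.
#' @export
general_params <- function(mu_ancestor = 0.35, mu_petite = 0.22,
                           rho_ancestor = 0.08,
                           sigma_nonpetite = 0.035, sigma_petite = 0.031,
                           sigma_plate = 0.010, sigma_well = 0.005) {
  if (mu_petite >= mu_ancestor) {
    stop_domain("`mu_petite` must be below `mu_ancestor`")
  }
  if (rho_ancestor < 0 || rho_ancestor > 1) {
    stop_domain("`rho_ancestor` must be in [0, 1]")
  }
  sds <- c(sigma_nonpetite, sigma_petite, sigma_plate, sigma_well)
  if (any(sds < 0)) stop_domain("standard deviations must be >= 0")
  structure(list(mu_ancestor = mu_ancestor, mu_petite = mu_petite,
                 rho_ancestor = rho_ancestor,
                 sigma_nonpetite = sigma_nonpetite,
                 sigma_petite = sigma_petite, sigma_plate = sigma_plate,
                 sigma_well = sigma_well),
            class = "general_params")
}

#' @rdname general_params
#' @param sigma_nonpetite_bio,sigma_petite_bio biological across-colony
#'   sds of non-petite and petite growth rates.
#' @param sigma_col colony-level measurement-noise sd.
#' @export
noise_model <- function(sigma_nonpetite_bio = 0.030,
                        sigma_petite_bio = 0.025, sigma_col = 0.018,
                        sigma_plate = 0.010, sigma_well = 0.005) {
  sds <- c(sigma_nonpetite_bio, sigma_petite_bio, sigma_col, sigma_plate,
           sigma_well)
  if (any(sds < 0)) stop_domain("standard deviations must be >= 0")
  structure(list(sigma_nonpetite_bio = sigma_nonpetite_bio,
                 sigma_petite_bio = sigma_petite_bio,
                 sigma_col = sigma_col, sigma_plate = sigma_plate,
                 sigma_well = sigma_well),
            class = "noise_model")
}

#' @rdname general_params
#' @param noise a [noise_model()].
#' @details `combine_noise()` applies the variance decomposition to turn
#'   a generative [noise_model()] into the combined [general_params()]
#'   sds the fitter works with.
#' @export
combine_noise <- function(noise, mu_ancestor = 0.35, mu_petite = 0.22,
                          rho_ancestor = 0.08) {
  stopifnot(inherits(noise, "noise_model"))
  general_params(
    mu_ancestor = mu_ancestor, mu_petite = mu_petite,
    rho_ancestor = rho_ancestor,
    sigma_nonpetite = sqrt(noise$sigma_col^2 +
                             noise$sigma_nonpetite_bio^2),
    sigma_petite = sqrt(noise$sigma_col^2 + noise$sigma_petite_bio^2),
    sigma_plate = noise$sigma_plate, sigma_well = noise$sigma_well)
}

#' Draw per-strain ground-truth mutational effects from a DME model
#'
#' For each strain, the number of mutations is Poisson-distributed
#' (mean `M_diploid / 2` for SNM-bearing variants, `U_free` for
#' `single_dme`); each mutation is exactly neutral with probability `p0`
#' and otherwise contributes a reflected-gamma draw. `two_gamma` adds an
#' independent compound-Poisson set of unidentified mutations;
#' `gaussian_unid` adds one `N(mu_unid, sigma_unid^2)` draw per strain.
#'
#' @param model a [dme_model()].
#' @param n_strains number of strains to draw.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param rho petite proportion(s) assigned to the strains (recycled);
#'   these are nuisance truth for the colony simulator, not part of the
#'   DME.
#' @return Data frame with columns `strain_id`, `s_true`, `rho_true`,
#'   `n_mutations` (SNM-class mutations only, neutral ones included).
#' @examples
#' simulate_strain_effects(dme_model("snm_only", m = 0.004, k = 0.1,
#'                                   q = 0.1), 5, seed = 1)
#' @export
simulate_strain_effects <- function(model, n_strains, seed, rho = 0.1) {
  stopifnot(inherits(model, "dme_model"), n_strains >= 1)
  if (any(rho < 0 | rho > 1)) stop_domain("`rho` must be in [0, 1]")
  with_seed(seed, {
    # total SNM-class mutations: Poisson(M/2); for single_dme the free
    # rate U_free plays that role directly (its p0 is 0)
    n_mut <- stats::rpois(n_strains,
                          if (model$kind == "single_dme") model$U_free
                          else model$M_diploid / 2)
    s <- vapply(n_mut, function(n) {
      if (n == 0) return(0)
      nonzero <- stats::rbinom(1, n, 1 - model$p0)
      sum(reflected_gamma_draws(nonzero, model$m, model$k, model$q))
    }, 0)
    if (model$kind == "two_gamma") {
      s <- s + vapply(stats::rpois(n_strains, model$U_unid), function(n) {
        sum(reflected_gamma_draws(n, model$m_unid, model$k_unid,
                                  model$q_unid))
      }, 0)
    }
    if (model$kind == "gaussian_unid") {
      s <- s + stats::rnorm(n_strains, model$mu_unid, model$sigma_unid)
    }
    data.frame(strain_id = sprintf("MAH%03d", seq_len(n_strains)),
               s_true = s, rho_true = rep_len(rho, n_strains),
               n_mutations = n_mut, stringsAsFactors = FALSE)
  })
}

reflected_gamma_draws <- function(n, m, k, q) {
  if (n == 0) return(numeric(0))
  mag <- stats::rgamma(n, shape = k, scale = m / k)
  sign <- ifelse(stats::runif(n) < q, 1, -1)
  mag * sign
}

#' Simulate a colony-level growth-rate table
#'
#' Generates one row per microcolony following the hierarchical
#' measurement model of the assay: each colony's growth rate is its
#' strain's non-petite rate `mu_ancestor * (1 + s_true)` (or the common
#' petite rate, with probability `rho_true`) plus biological colony
#' variation, colony measurement noise, and plate and well batch effects
#' shared by every colony in the same plate/well. Reference colonies in
#' every assay well use the ancestral truth (`s = s_reference`, petite
#' proportion `rho_ancestor`).
#'
#' @param design an [experiment_design()].
#' @param truths data frame as returned by [simulate_strain_effects()]
#'   (`strain_id`, `s_true`, `rho_true`); must cover every strain in the
#'   design.
#' @param general a [general_params()] (means and `rho_ancestor`;
#'   combined sds are ignored in favor of `noise`).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param s_reference selection coefficient of the in-well reference
#'   strain relative to `mu_ancestor` (default 0; nonzero values model a
#'   reference that grows at a different rate than the designated
#'   baseline strain).
#' @return A `data.frame` colony table with columns `strain_id`, `role`
#'   (`"ma"` or `"reference"`), `plate`, `well`, `field`, `colony_id`,
#'   `growth_rate`.
#' @export
simulate_colony_table <- function(design, truths, general, noise, seed,
                                  s_reference = 0) {
  stopifnot(inherits(design, "ma_design"),
            inherits(general, "general_params"),
            inherits(noise, "noise_model"))
  missing <- setdiff(design$strain_ids, truths$strain_id)
  if (length(missing)) {
    stop_domain("truths missing strains: ", paste(missing, collapse = ", "))
  }
  tr <- truths[match(design$strain_ids, truths$strain_id), ]
  with_seed(seed, {
    wells <- layout_wells(design)
    plate_eff <- stats::rnorm(design$plates, 0, noise$sigma_plate)
    well_eff <- stats::rnorm(nrow(wells), 0, noise$sigma_well)
    out <- vector("list", nrow(wells))
    for (w in seq_len(nrow(wells))) {
      i <- match(wells$strain_id[w], tr$strain_id)
      batch <- plate_eff[wells$plate[w]] + well_eff[w]
      ma <- colony_rates(design$colonies_per_well_ma,
                         general$mu_ancestor * (1 + tr$s_true[i]),
                         tr$rho_true[i], general, noise) + batch
      ref <- colony_rates(design$colonies_per_well_ref,
                          general$mu_ancestor * (1 + s_reference),
                          general$rho_ancestor, general, noise) + batch
      n_ma <- length(ma); n_ref <- length(ref)
      out[[w]] <- data.frame(
        strain_id = c(rep(wells$strain_id[w], n_ma),
                      rep("reference", n_ref)),
        role = c(rep("ma", n_ma), rep("reference", n_ref)),
        plate = wells$plate[w], well = wells$well[w],
        field = c(assign_fields(n_ma, design$fields_per_well),
                  assign_fields(n_ref, design$fields_per_well)),
        colony_id = sprintf("%s_c%04d", wells$well[w],
                            seq_len(n_ma + n_ref)),
        growth_rate = c(ma, ref), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# Draw the within-well (batch-free) part of colony growth rates.
colony_rates <- function(n, mu_nonpetite, rho, general, noise) {
  petite <- stats::runif(n) < rho
  bio <- ifelse(petite,
                stats::rnorm(n, general$mu_petite, noise$sigma_petite_bio),
                stats::rnorm(n, mu_nonpetite, noise$sigma_nonpetite_bio))
  bio + stats::rnorm(n, 0, noise$sigma_col)
}

assign_fields <- function(n, fields) {
  sort(rep_len(seq_len(fields), n))
}

# Expand a design into one row per assay well (plate, well id, strain).
# Wells are distributed round-robin over plates when no explicit
# assignment is given; randomization of strain order uses the RNG stream
# already seeded by the caller.
layout_wells <- function(design) {
  rows <- list()
  wells_per_strain <- design[["wells_per_strain"]] %||%
    stats::setNames(rep(design$wells_per_strain_per_plate,
                        length(design$strain_ids)), design$strain_ids)
  if (is.null(design$strain_plate_assignment)) {
    ord <- sample(design$strain_ids)
    plates <- rep_len(seq_len(design$plates), length(ord))
    assign <- stats::setNames(as.list(plates), ord)
  } else {
    assign <- design$strain_plate_assignment
  }
  for (sid in design$strain_ids) {
    for (pl in assign[[sid]]) {
      for (rep_i in seq_len(wells_per_strain[[sid]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          plate = pl, strain_id = sid,
          stringsAsFactors = FALSE)
      }
    }
  }
  wells <- do.call(rbind, rows)
  wells <- wells[order(wells$plate), ]
  wells$well <- stats::ave(seq_len(nrow(wells)), wells$plate,
                           FUN = seq_along)
  wells$well <- sprintf("p%02dw%02d", wells$plate, wells$well)
  rownames(wells) <- NULL
  wells
}

#' Simulate petite-only control wells
#'
#' Petite-only control strains are included on each experimental plate;
#' their colonies are all petite (`rho = 1`) and share the plate's batch
#' effect plus their own well effect.
#'
#' @inheritParams simulate_colony_table
#' @return A colony table with `role = "petite_control"` (empty if the
#'   design has no control wells).
#' @export
simulate_petite_controls <- function(design, general, noise, seed) {
  stopifnot(inherits(design, "ma_design"),
            inherits(general, "general_params"),
            inherits(noise, "noise_model"))
  empty <- data.frame(strain_id = character(), role = character(),
                      plate = integer(), well = character(),
                      field = integer(), colony_id = character(),
                      growth_rate = numeric(), stringsAsFactors = FALSE)
  if (design$petite_control_wells == 0) return(empty)
  with_seed(seed, {
    plate_eff <- stats::rnorm(design$plates, 0, noise$sigma_plate)
    out <- list()
    for (pl in seq_len(design$plates)) {
      for (wi in seq_len(design$petite_control_wells)) {
        batch <- plate_eff[pl] + stats::rnorm(1, 0, noise$sigma_well)
        n <- design$colonies_per_control_well
        rates <- colony_rates(n, general$mu_ancestor, 1, general,
                              noise) + batch
        wid <- sprintf("p%02dpet%02d", pl, wi)
        out[[length(out) + 1L]] <- data.frame(
          strain_id = "petite_control", role = "petite_control",
          plate = pl, well = wid,
          field = assign_fields(n, design$fields_per_well),
          colony_id = sprintf("%s_c%04d", wid, seq_len(n)),
          growth_rate = rates, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
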