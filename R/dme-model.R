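#' Specify a distribution-of-mutational-effects (DME) model
#'
#' Constructs one of four compound-Poisson models for the combined effect
#' `S` of the mutations carried by a mutation-accumulation (MA) strain on
#' its growth rate (expressed as a selection coefficient). Individual
#' single-nucleotide mutation (SNM) effects are drawn from a reflected
#' gamma distribution: two gamma densities mirrored about zero, with mass
#' `q` on the positive (beneficial) side and `1 - q` on the negative
#' side, parameterized by the mean magnitude `m` and shape `k`
#' (scale = `m / k`). A proportion `p0` of mutations is exactly neutral.
#' The number of SNMs per haploid strain is Poisson with mean
#' `M_diploid / 2`, half the mean mutation count of the diploid parent
#' lines, so the non-neutral SNM rate is `U = (M_diploid / 2) * (1 - p0)`.
#'
#' The four variants differ in how mutations missed by sequencing
#' ("unidentified" mutations, e.g. simple-sequence-repeat indels) are
#' handled:
#' \describe{
#'   \item{`snm_only`}{sequenced SNMs are the only source of effects.}
#'   \item{`single_dme`}{one reflected gamma for all mutations, with the
#'     Poisson mean `U_free` a free parameter (mutation count
#'     unconstrained by sequencing).}
#'   \item{`two_gamma`}{SNMs as in `snm_only` plus a second, independent
#'     compound-Poisson reflected gamma (`m_unid`, `k_unid`, `q_unid`,
#'     `U_unid`) for unidentified mutations.}
#'   \item{`gaussian_unid`}{SNMs as in `snm_only` plus a single Gaussian
#'     draw per strain, `N(mu_unid, sigma_unid^2)`, for the combined
#'     effect of all unidentified mutations.}
#' }
#'
#' @param kind model variant; one of `"snm_only"`, `"single_dme"`,
#'   `"two_gamma"`, `"gaussian_unid"`.
#' @param m mean magnitude of a single SNM effect (dimensionless `s`
#'   units, > 0).
#' @param k gamma shape parameter (> 0); values below 1 give densities
#'   sharply peaked at zero.
#' @param q proportion of non-neutral SNMs with positive effect, in
#'   `[0, 1]`.
#' @param p0 proportion of SNMs with exactly zero effect, in `[0, 1]`
#'   (ignored for `single_dme`, where neutral mutations are absorbed into
#'   `U_free`).
#' @param M_diploid mean number of SNMs per diploid MA parent line
#'   (default 8, i.e. about 4 per haploid strain).
#' @param U_free Poisson mean of non-neutral mutations per strain
#'   (`single_dme` only, >= 0).
#' @param m_unid,k_unid,q_unid,U_unid reflected-gamma and Poisson
#'   parameters of the unidentified-mutation component (`two_gamma`
#'   only).
#' @param mu_unid,sigma_unid mean and standard deviation of the combined
#'   per-strain unidentified effect (`gaussian_unid` only;
#'   `sigma_unid >= 0`).
#'
#' @return An object of class `dme_model`.
#' @examples
#' mod <- dme_model("gaussian_unid", m = 4.1e-3, k = 5.5e-2, q = 0.06,
#'                  p0 = 0.059, mu_unid = -3.3e-3, sigma_unid = 5.5e-3)
#' model_cf(mod, 0) # CF at 0 is always 1
#' @export
dme_model <- function(kind = c("snm_only", "single_dme", "two_gamma",
                               "gaussian_unid"),
                      m = 5e-3, k = 0.2, q = 0.1, p0 = 0,
                      M_diploid = 8, U_free = NULL,
                      m_unid = NULL, k_unid = NULL, q_unid = NULL,
                      U_unid = NULL, mu_unid = NULL, sigma_unid = NULL) {
  kind <- match.arg(kind)
  check_gamma_params(m, k, q)
  if (p0 < 0 || p0 > 1) stop_domain("`p0` must be in [0, 1]")
  if (M_diploid < 0) stop_domain("`M_diploid` must be >= 0")
  obj <- list(kind = kind, m = m, k = k, q = q, p0 = p0,
              M_diploid = M_diploid)
  if (kind == "single_dme") {
    obj$U_free <- U_free %||% 2
    if (obj$U_free < 0) stop_domain("`U_free` must be >= 0")
    obj$p0 <- 0 # neutral mutations are indistinguishable from a lower U
  }
  if (kind == "two_gamma") {
    obj$m_unid <- m_unid %||% m
    obj$k_unid <- k_unid %||% k
    obj$q_unid <- q_unid %||% q
    obj$U_unid <- U_unid %||% 1
    check_gamma_params(obj$m_unid, obj$k_unid, obj$q_unid)
    if (obj$U_unid < 0) stop_domain("`U_unid` must be >= 0")
  }
  if (kind == "gaussian_unid") {
    obj$mu_unid <- mu_unid %||% 0
    obj$sigma_unid <- sigma_unid %||% 0
    if (obj$sigma_unid < 0) stop_domain("`sigma_unid` must be >= 0")
  }
  structure(obj, class = "dme_model")
}

check_gamma_params <- function(m, k, q) {
  if (!is.numeric(m) || m <= 0) stop_domain("gamma mean `m` must be > 0")
  if (!is.numeric(k) || k <= 0) stop_domain("gamma shape `k` must be > 0")
  if (q < 0 || q > 1) stop_domain("`q` must be in [0, 1]")
  invisible(TRUE)
}

#' @export
print.dme_model <- function(x, ...) {
  cat("DME model:", x$kind, "\n")
  flds <- setdiff(names(x), "kind")
  vals <- vapply(flds, function(f) format(x[[f]], digits = 4), "")
  cat(paste0("  ", flds, " = ", vals, collapse = "\n"), "\n")
  if (x$kind != "single_dme") {
    cat("  U (non-neutral SNMs/strain) =",
        format(snm_poisson_mean(x), digits = 4), "\n")
  }
  invisible(x)
}

# Poisson mean of non-neutral SNMs per haploid strain.
snm_poisson_mean <- function(model) {
  if (model$kind == "single_dme") return(model$U_free)
  (model$M_diploid / 2) * (1 - model$p0)
}

#' Characteristic function of the reflected gamma distribution
#'
#' The single-mutation effect `Z` is gamma-distributed in magnitude
#' (mean `m`, shape `k`) and positive with probability `q`, negative with
#' probability `1 - q`. Its characteristic function is
#' `(1 - q) (1 + i w m / k)^(-k) + q (1 - i w m / k)^(-k)`.
#'
#' @param omega angular frequency (numeric vector).
#' @param m,k,q reflected-gamma parameters (see [dme_model()]).
#' @return Complex vector of the same length as `omega`.
#' @export
reflected_gamma_cf <- function(omega, m, k, q) {
  check_gamma_params(m, k, q)
  z <- complex(real = 0, imaginary = omega * m / k)
  (1 - q) * (1 + z)^(-k) + q * (1 - z)^(-k)
}

#' Characteristic function of a compound-Poisson sum
#'
#' For `S = Z_1 + ... + Z_N` with `N ~ Poisson(U)` and i.i.d. `Z` with
#' characteristic function `base_cf`, the CF of `S` is
#' `exp(U * (base_cf(omega) - 1))`.
#'
#' @param omega angular frequency (numeric vector).
#' @param U Poisson mean (>= 0).
#' @param base_cf function mapping `omega` to the complex CF of a single
#'   summand.
#' @return Complex vector.
#' @export
compound_poisson_cf <- function(omega, U, base_cf) {
  if (U < 0) stop_domain("`U` must be >= 0")
  exp(U * (base_cf(omega) - 1))
}

#' Characteristic function of the per-strain combined mutational effect
#'
#' Evaluates the CF of `S` under the model variant: the compound-Poisson
#' reflected gamma for SNMs (with `U = (M_diploid / 2) * (1 - p0)`, the
#' zero-effect atoms absorbed into the Poisson rate), times, depending on
#' `kind`, a second compound-Poisson gamma factor or a Gaussian factor
#' `exp(i w mu_unid - w^2 sigma_unid^2 / 2)`.
#'
#' @param model a [dme_model()].
#' @param omega angular frequency (numeric vector).
#' @return Complex vector.
#' @export
model_cf <- function(model, omega) {
  stopifnot(inherits(model, "dme_model"))
  snm <- compound_poisson_cf(
    omega, snm_poisson_mean(model),
    function(w) reflected_gamma_cf(w, model$m, model$k, model$q))
  switch(model$kind,
    snm_only = ,
    single_dme = snm,
    two_gamma = snm * compound_poisson_cf(
      omega, model$U_unid,
      function(w) reflected_gamma_cf(w, model$m_unid, model$k_unid,
                                     model$q_unid)),
    gaussian_unid = snm * exp(
      complex(real = -omega^2 * model$sigma_unid^2 / 2,
              imaginary = omega * model$mu_unid)),
    stop_domain("unknown model kind: ", model$kind))
}

#' Tail probability of the single-mutation effect distribution
#'
#' Proportion of *all* mutations (neutral ones included) whose individual
#' effect magnitude exceeds `cutoff` in the given direction, computed
#' analytically from the regularized incomplete gamma function:
#' `q (1 - p0) P(Gamma(k, m) > cutoff)` for positive effects and
#' `(1 - q)(1 - p0) P(Gamma(k, m) > cutoff)` for negative effects. This
#' concerns the SNM component of the model, not the per-strain sum.
#'
#' @param model a [dme_model()].
#' @param cutoff effect-magnitude threshold (> 0).
#' @param direction `"positive"`, `"negative"`, or `"both"` (sum).
#' @return Proportion in `[0, 1]`.
#' @examples
#' mod <- dme_model("gaussian_unid", m = 4.1e-3, k = 5.5e-2, q = 0.06,
#'                  p0 = 0.059, mu_unid = -3.3e-3, sigma_unid = 5.5e-3)
#' dme_tail_probability(mod, 1e-6, "positive") # ~0.025
#' @export
dme_tail_probability <- function(model, cutoff,
                                 direction = c("positive", "negative",
                                               "both")) {
  stopifnot(inherits(model, "dme_model"))
  direction <- match.arg(direction)
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop_domain("`cutoff` must be > 0")
  }
  surv <- stats::pgamma(cutoff, shape = model$k,
                        scale = model$m / model$k, lower.tail = FALSE)
  w <- switch(direction,
              positive = model$q,
              negative = 1 - model$q,
              both = 1)
  w * (1 - model$p0) * surv
}

#' Read and write DME model specifications as JSON
#'
#' @param model a [dme_model()].
#' @param path file path.
#' @return `read_dme_model()` returns a [dme_model()];
#'   `write_dme_model()` returns `path` invisibly.
#' @export
write_dme_model <- function(model, path) {
  stopifnot(inherits(model, "dme_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dme_model
#' @export
read_dme_model <- function(path) {
  do.call(dme_model, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Number of free DME parameters for each model variant (used for AIC).
n_dme_params <- function(kind) {
  switch(kind,
         snm_only = 4L,      # m, k, q, p0
         single_dme = 4L,    # m, k, q, U_free
         two_gamma = 8L,
         gaussian_unid = 6L,
         stop_domain("unknown model kind: ", kind))
}
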