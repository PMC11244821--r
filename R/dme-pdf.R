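#' Invert a DME characteristic function to a density grid
#'
#' Evaluates the model characteristic function on the conjugate frequency
#' grid, multiplies it by the CF of a narrow Gaussian smoothing kernel
#' (which regularizes the point mass at `S = 0` onto the grid) and by an
#' optional measurement-error Gaussian, and applies the discrete inverse
#' Fourier transform. The real part is clipped at zero and renormalized
#' to integrate to one.
#'
#' The grid has `n` points (a power of two) spanning
#' `[-s_max, s_max)` with spacing `ds = 2 s_max / n`. If more than
#' `1e-4` of the probability mass falls in the outermost 1/128 of the
#' grid on either side, the density is aliased (wrapped around); the grid
#' is then widened by doubling `s_max` up to `max_widen` times before an
#' error is raised.
#'
#' @param model a [dme_model()].
#' @param n number of grid points (power of two; default `2^14`).
#' @param s_max half-width of the selection-coefficient grid (default
#'   0.5; observed `s` values in the MA assays lie within about
#'   ±0.15).
#' @param kernel_sd standard deviation of the Gaussian smoothing kernel
#'   (default `2^-16`, about `1.5e-5`).
#' @param error_sd optional additional Gaussian measurement-error sd
#'   convolved into the density (default 0).
#' @param widen logical: widen automatically on aliasing (default TRUE).
#' @param max_widen maximum number of doublings of `s_max` (default 6).
#' @return An object of class `dme_pdf`: a list with `s` (grid points),
#'   `density`, and `ds`.
#' @examples
#' mod <- dme_model("snm_only", m = 5e-3, k = 0.14, q = 0.105, p0 = 1e-3)
#' g <- cf_to_pdf(mod)
#' sum(g$density) * g$ds # 1
#' @export
cf_to_pdf <- function(model, n = 2^14, s_max = 0.5, kernel_sd = 2^-16,
                      error_sd = 0, widen = TRUE, max_widen = 6L) {
  stopifnot(inherits(model, "dme_model"))
  if (n < 8 || bitwAnd(n, n - 1L) != 0) {
    stop_domain("`n` must be a power of two (>= 8)")
  }
  if (kernel_sd < 0) stop_domain("`kernel_sd` must be >= 0")
  phi <- function(w) model_cf(model, w)
  for (attempt in 0:max_widen) {
    grid <- invert_cf_grid(phi, n, s_max, kernel_sd, error_sd)
    edge <- n %/% 128L
    edge_mass <- (sum(grid$density[seq_len(edge)]) +
                  sum(grid$density[(n - edge + 1L):n])) * grid$ds
    if (edge_mass <= 1e-4) {
      grid$density <- grid$density / (sum(grid$density) * grid$ds)
      return(structure(grid, class = "dme_pdf"))
    }
    if (!widen || attempt == max_widen) {
      stop_domain("density grid too narrow: ", format(edge_mass),
                  " probability mass at the grid edges (s_max = ",
                  format(s_max), ")")
    }
    s_max <- s_max * 2
  }
}

# Core inverse-FFT step shared by cf_to_pdf and the summary likelihood.
# f(s_p) = (1 / (n ds)) * sum_j phi(w_j) exp(-i w_j s_p), with w_j on the
# wrapped DFT frequency grid; the phase factor exp(-i w_j s0) shifts the
# output so index p corresponds to s0 + p ds. The total Gaussian
# smoothing (kernel + measurement error) is floored at one grid spacing:
# a kernel narrower than the grid cannot suppress the ringing around the
# near-atom at S = 0 that it exists to regularize.
invert_cf_grid <- function(phi, n, s_max, kernel_sd, error_sd = 0) {
  ds <- 2 * s_max / n
  s0 <- -s_max
  smooth_var <- max(kernel_sd^2 + error_sd^2, ds^2)
  jw <- c(0:(n / 2 - 1), -(n / 2):-1)
  omega <- 2 * pi * jw / (n * ds)
  y <- phi(omega) *
    exp(-omega^2 * smooth_var / 2) *
    exp(complex(imaginary = -omega * s0))
  dens <- Re(stats::fft(y)) / (n * ds)
  dens[dens < 0] <- 0
  list(s = s0 + (0:(n - 1)) * ds, density = dens, ds = ds)
}

#' @export
print.dme_pdf <- function(x, ...) {
  cat("DME density grid:", length(x$s), "points on [",
      format(min(x$s)), ",", format(max(x$s) + x$ds), "), ds =",
      format(x$ds), "\n")
  mu <- sum(x$s * x$density) * x$ds
  cat("  mean =", format(mu, digits = 4),
      "; P(S < 0) =", format(sum(x$density[x$s < 0]) * x$ds, digits = 4),
      "\n")
  invisible(x)
}

#' @export
plot.dme_pdf <- function(x, xlim = NULL, log = "", ...) {
  if (is.null(xlim)) {
    cdf <- cumsum(x$density) * x$ds
    xlim <- range(x$s[cdf > 1e-4 & cdf < 1 - 1e-4])
  }
  plot(x$s, x$density, type = "l", xlab = "selection coefficient s",
       ylab = "density", xlim = xlim, log = log, ...)
  invisible(x)
}

#' Export a density grid as a two-column CSV
#'
#' @param grid a [cf_to_pdf()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pdf_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dme_pdf"))
  utils::write.csv(data.frame(s = grid$s, density = grid$density),
                   path, row.names = FALSE)
  invisible(path)
}

# Linear interpolation of a density grid at arbitrary points, floored so
# logs stay finite; points outside the grid raise an error (the grid
# does not cover the observation).
interp_density <- function(grid, s, floor = 1e-300) {
  rng <- range(grid$s)
  if (any(s < rng[1] | s > rng[2])) {
    stop_domain("observation outside density grid [", format(rng[1]),
                ", ", format(rng[2]), "]; widen `s_max`")
  }
  d <- stats::approx(grid$s, grid$density, xout = s)$y
  pmax(d, floor)
}

#' Log-likelihood of one strain's summary estimate under a DME model
#'
#' The per-strain estimated mutational effect `s_est` is modeled as the
#' true combined effect `S` (distributed according to `model`) plus
#' Gaussian estimation error with standard deviation `se`, plus the
#' narrow smoothing kernel. The convolution is performed in the Fourier
#' domain; the resulting density is linearly interpolated at `s_est` and
#' floored at `1e-300` before taking the log.
#'
#' @param s_est estimated selection coefficient(s) (numeric vector).
#' @param se standard error(s) of the estimate(s) (> 0; recycled).
#' @param model a [dme_model()].
#' @param kernel_sd smoothing-kernel sd (default `2^-16`).
#' @param n,s_max grid controls as in [cf_to_pdf()].
#' @return Summed log-likelihood over the supplied strains.
#' @export
strain_summary_loglik <- function(s_est, se, model, kernel_sd = 2^-16,
                                  n = 2^14, s_max = 0.5) {
  if (any(se <= 0)) stop_domain("`se` must be > 0")
  se <- rep_len(se, length(s_est))
  ll <- 0
  for (u in unique(se)) {
    idx <- se == u
    grid <- cf_to_pdf(model, n = n, s_max = s_max, kernel_sd = kernel_sd,
                      error_sd = u)
    ll <- ll + sum(log(interp_density(grid, s_est[idx])))
  }
  ll
}
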