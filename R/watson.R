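#' Sample axes from a Watson distribution
#'
#' Draws antipodally symmetric axes from the Watson distribution with density
#' proportional to \eqn{\exp(\kappa (\mu^T n)^2)} on the unit sphere. Used by
#' the phantom generator to disperse fibre orientations around a bundle axis.
#'
#' Sampling is by rejection: the cosine \eqn{t = \mu^T n \in [0,1]} is proposed
#' from a truncated exponential envelope (valid because \eqn{t^2 \le t} on
#' \eqn{[0,1]}, so \eqn{e^{\kappa t^2} \le e^{\kappa t}}), accepted with
#' probability \eqn{e^{\kappa(t^2 - t)}}. The envelope stays efficient for all
#' concentrations, including the near-delta limit. Azimuth is uniform and a
#' random sign gives the axial (antipodal) symmetry.
#'
#' @param mu unit 3-vector, mean axis.
#' @param kappa Watson concentration, `>= 0`. `kappa = 0` is the uniform
#'   distribution on the sphere.
#' @param n number of axes to draw.
#' @param seed optional integer seed for a self-contained stream.
#' @return `n x 3` matrix of unit axes.
#' @export
#' @examples
#' x <- sample_watson(c(0, 0, 1), kappa = 12.7, n = 500, seed = 1)
sample_watson <- function(mu, kappa, n, seed = NULL) {
  stopifnot_unit(mu, "mu")
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draw <- function() {
    t <- if (kappa == 0) stats::runif(n) else {
      out <- numeric(0)
      while (length(out) < n) {
        m <- 2L * (n - length(out)) + 16L
        r <- stats::runif(m)
        # inverse CDF of Exp(kappa) truncated to [0,1], in u = 1 - t
        u <- -log1p(-r * (1 - exp(-kappa))) / kappa
        tt <- 1 - u
        acc <- log(stats::runif(m)) < kappa * (tt^2 - tt)
        out <- c(out, tt[acc])
      }
      out[seq_len(n)]
    }
    t <- t * sample(c(-1, 1), n, replace = TRUE)   # antipodal symmetry
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - t^2))
    cbind(s * cos(phi), s * sin(phi), t)
  }
  xyz <- if (is.null(seed)) draw() else with_seed(seed, draw())
  xyz %*% t(rotation_z_to(mu))
}

#' Mean squared cosine of a Watson distribution
#'
#' \eqn{\tau_1(\kappa) = E[(\mu^T n)^2]}, the largest eigenvalue of the mean
#' dyadic \eqn{E[n n^T]}. Computed by numerical integration of the Watson
#' density; this is the independent oracle used to check the sampler and the
#' link between dispersion and tensor anisotropy.
#'
#' @param kappa concentration(s), `>= 0`.
#' @return value(s) in `[1/3, 1]`.
#' @export
watson_tau1 <- function(kappa) {
  vapply(kappa, function(k) {
    if (k == 0) return(1 / 3)
    # integrand scaled by exp(-k) for numerical stability at large k
    num <- stats::integrate(function(t) t^2 * exp(k * (t^2 - 1)), 0, 1,
                            rel.tol = 1e-12)$value
    den <- stats::integrate(function(t) exp(k * (t^2 - 1)), 0, 1,
                            rel.tol = 1e-12)$value
    num / den
  }, numeric(1))
}

# Invert tau1(kappa) numerically; used to estimate an empirical concentration
# (and hence ODI) from the dyadic of a sample of axes.
kappa_from_tau1 <- function(tau1) {
  vapply(tau1, function(t1) {
    if (t1 <= 1 / 3) return(0)
    if (t1 >= 1 - 1e-12) return(Inf)
    stats::uniroot(function(k) watson_tau1(k) - t1, c(1e-8, 1e4),
                   tol = 1e-10)$root
  }, numeric(1))
}

# Empirical ODI of a sample of axes via the dyadic tensor.
odi_from_axes <- function(axes) {
  Tm <- crossprod(axes) / nrow(axes)
  tau1 <- max(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
  odi_from_kappa(kappa_from_tau1(tau1))
}
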