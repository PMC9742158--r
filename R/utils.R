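#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: mix a base seed with small integer labels so
# every stage (per subject, per noise source) draws from its own stream while
# everything is reproducible from the single scenario seed. Result stays well
# below 2^31.
substream_seed <- function(seed, ...) {
  labels <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (x in labels) {
    v <- if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else as.double(x)
    h <- (h * 69069 + v * 12345 + 1) %% 2147483647
  }
  as.integer(h %% 2000000000)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_unit <- function(v, name = "vector", tol = 1e-6) {
  if (length(v) != 3L || any(!is.finite(v)))
    stop(name, " must be a finite 3-vector", call. = FALSE)
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > tol)
    stop(name, " must be a unit vector (|v| = ", format(n), ")", call. = FALSE)
  invisible(v)
}

# Rotation taking +z onto the unit vector mu (Rodrigues construction).
rotation_z_to <- function(mu) {
  z <- c(0, 0, 1)
  c_ <- sum(z * mu)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * mu[3] - z[3] * mu[2],
         z[3] * mu[1] - z[1] * mu[3],
         z[1] * mu[2] - z[2] * mu[1])
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Rician-distorted magnitude of a noise-free signal: |s + complex N(0, sigma)|.
add_rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  sqrt((s + stats::rnorm(length(s), sd = sigma))^2 +
         stats::rnorm(length(s), sd = sigma)^2)
}
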