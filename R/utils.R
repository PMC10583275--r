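# Internal helpers: reproducible RNG substreams and rotation algebra.

# Derive a 31-bit child seed from (seed, purpose[, index]) so that every
# stochastic stage of the pipeline draws from its own reproducible stream.
sub_seed <- function(seed, purpose, index = 0L) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  # exact in double precision: all intermediates < 2^53
  s <- (abs(as.numeric(seed)) %% 2147483647) * 69069 + h * 2654435 + index * 40503
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

# Rotation by `angle_deg` degrees about `axis` (Rodrigues formula).
rotation_about <- function(axis, angle_deg) {
  u <- unit(axis)
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Uniform random rotation (quaternion method); relies on the caller's RNG.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# ZYZ Euler angles: R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma), angles radians.
euler_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

matrix_to_euler <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(sin(beta)) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal lock: fold the whole in-plane rotation into alpha
    gamma <- 0
    alpha <- if (cb > 0) atan2(R[2, 1], R[1, 1]) else atan2(R[2, 1], R[1, 1]) + pi
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}
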