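# Internal angle and rigid-motion helpers. All public interfaces use degrees;
# everything in here is radians.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap to (-pi, pi]
.wrap_pi <- function(x) atan2(sin(x), cos(x))

# wrap to [0, 2*pi)
.wrap_2pi <- function(x) {
  y <- x %% (2 * pi)
  y[y < 0] <- y[y < 0] + 2 * pi
  y
}

# direction angle of a 2-D vector, standard math convention (radians from +x, CCW)
.dir <- function(v) atan2(v[2], v[1])

# clamp an arcsine/arccosine argument, erroring beyond `slack`
.clamp1 <- function(x, slack = 1e-12, what = "trigonometric argument") {
  bad <- abs(x) > 1 + slack
  if (any(bad)) {
    abort(sprintf("%s out of [-1, 1] (max |value| = %.6g)", what, max(abs(x))))
  }
  pmin(pmax(x, -1), 1)
}

# rotate rows of an n x 2 matrix by `theta` radians CCW about `center`
.rotate_about <- function(xy, theta, center) {
  ct <- cos(theta)
  st <- sin(theta)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  cbind(center[1] + ct * dx - st * dy, center[2] + st * dx + ct * dy)
}

# run `expr` under a temporary RNG seed, restoring caller RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
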