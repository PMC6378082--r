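#' Specify a synthetic patient by baseline alignment
#'
#' A synthetic patient is defined by the spinopelvic parameters the
#' constructed landmark set must realize (PI, PT, SVA), the lumbar lordosis
#' carried as a constant, and a handful of scale parameters: trunk height
#' (femoral head to T1), the polar position of the osteotomy fulcrum
#' relative to the femoral head, and the S1 endplate width.
#'
#' @param pi_deg Pelvic incidence (degrees), in `[20, 100]`.
#' @param pt_deg Pelvic tilt (degrees), in `[-10, 50]`.
#' @param sva_mm Sagittal vertical axis (mm), `|sva_mm| <= 400`.
#' @param ll_deg Lumbar lordosis (degrees).
#' @param trunk_height_mm Femoral-head-to-T1 vertical scale (default 420).
#' @param fulcrum_offset_mm,fulcrum_angle_deg Polar position of the fulcrum
#'   relative to the femoral head: distance (default 55 mm) and angle from
#'   vertical toward posterior (default 35 degrees).
#' @param endplate_width_mm S1 endplate width (default 35).
#' @param seed Optional integer carried into file metadata / cohort sampling.
#' @return A list of class `bpo_patient_spec`.
#' @export
patient_spec <- function(pi_deg = 55, pt_deg = 25, sva_mm = 150, ll_deg = 30,
                         trunk_height_mm = 420, fulcrum_offset_mm = 55,
                         fulcrum_angle_deg = 35, endplate_width_mm = 35,
                         seed = NULL) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
      abort(sprintf("%s = %s outside [%g, %g]", nm, format(x), lo, hi))
    }
    as.numeric(x)
  }
  out <- list(
    pi_deg = chk(pi_deg, 20, 100, "pi_deg"),
    pt_deg = chk(pt_deg, -10, 50, "pt_deg"),
    sva_mm = chk(sva_mm, -400, 400, "sva_mm"),
    ll_deg = chk(ll_deg, -20, 90, "ll_deg"),
    trunk_height_mm = chk(trunk_height_mm, 200, 700, "trunk_height_mm"),
    fulcrum_offset_mm = chk(fulcrum_offset_mm, 20, 120, "fulcrum_offset_mm"),
    fulcrum_angle_deg = chk(fulcrum_angle_deg, 0, 80, "fulcrum_angle_deg"),
    endplate_width_mm = chk(endplate_width_mm, 10, 70, "endplate_width_mm"),
    seed = seed
  )
  ss <- out$pi_deg - out$pt_deg
  if (abs(ss) >= 89) {
    abort(sprintf(
      "unconstructible spec: sacral slope PI - PT = %.1f deg must lie within (-89, 89)", ss
    ))
  }
  class(out) <- "bpo_patient_spec"
  out
}

#' Construct a landmark set realizing a prescribed baseline alignment
#'
#' Deterministic inverse of [measure_parameters()]: places the femoral head
#' at the origin, the S1 midpoint along the prescribed pelvic-tilt
#' direction, orients the endplate corners so the measured PI equals the
#' spec (hence SS = PI - PT, with the endplate descending anteriorly for
#' positive SS), puts the C7 centroid where the measured SVA equals the
#' spec, places T1 just below C7 on a smooth lordosis-dependent arc from the
#' S1 midpoint, and the fulcrum at its polar offset. Measuring the result
#' reproduces (PI, PT, SVA) to machine precision.
#'
#' @param spec A [patient_spec()] (or arguments passed to it via `...`).
#' @param ... If `spec` is missing, forwarded to [patient_spec()].
#' @return A `bpo_landmarks` tibble.
#' @examples
#' lm <- make_patient(patient_spec(pi_deg = 55, pt_deg = 25, sva_mm = 150))
#' measure_parameters(lm, ll_deg = 30)
#' @export
make_patient <- function(spec, ...) {
  if (missing(spec)) spec <- patient_spec(...)
  stopifnot(inherits(spec, "bpo_patient_spec"))

  pt <- .deg2rad(spec$pt_deg)
  ss <- .deg2rad(spec$pi_deg - spec$pt_deg)
  fa <- .deg2rad(spec$fulcrum_angle_deg)

  fh <- c(0, 0)
  s1_dist <- 0.22 * spec$trunk_height_mm
  mid <- fh + s1_dist * c(-sin(pt), cos(pt))
  half <- (spec$endplate_width_mm / 2) * c(cos(ss), -sin(ss))
  ant <- mid + half
  post <- mid - half
  fulcrum <- fh + spec$fulcrum_offset_mm * c(-sin(fa), cos(fa))

  c7 <- c(post[1] + spec$sva_mm, spec$trunk_height_mm + 18)

  # T1 near the top of a quadratic arc from the S1 midpoint to C7, bulged
  # anteriorly in proportion to the lordosis; the trunk is rigid, so the arc
  # is cosmetic and only the endpoint positions enter the model
  ctrl <- (mid + c7) / 2 + c(0.25 * spec$ll_deg, 0)
  t <- 0.93
  t1 <- (1 - t)^2 * mid + 2 * t * (1 - t) * ctrl + t^2 * c7

  landmark_set(
    femoral_head = fh, fulcrum = fulcrum,
    s1_anterior = ant, s1_posterior = post,
    t1_centroid = t1, c7_centroid = c7
  )
}

#' Default plausible parameter ranges for synthetic cohorts
#'
#' Deformity-like uniform sampling ranges: PI 45-85, PT 15-35, SVA 80-250
#' mm, LL 20-40 degrees. No claim of epidemiological realism is made.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
cohort_ranges <- function() {
  list(
    pi_deg = c(45, 85),
    pt_deg = c(15, 35),
    sva_mm = c(80, 250),
    ll_deg = c(20, 40)
  )
}

#' Generate a reproducible cohort of synthetic patients
#'
#' Draws `n` patients with parameters sampled uniformly from `ranges` under
#' the given seed and constructs their landmark sets with [make_patient()].
#'
#' @param n Number of patients (`>= 1`).
#' @param ranges Named list of sampling ranges as in [cohort_ranges()].
#' @param seed Integer RNG seed.
#' @return A tibble with columns `patient_id`, `pi_deg`, `pt_deg`, `sva_mm`,
#'   `ll_deg` and a list-column `landmarks` of `bpo_landmarks` tables.
#' @export
make_cohort <- function(n, ranges = cohort_ranges(), seed = 1) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  defaults <- cohort_ranges()
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad)) abort(sprintf("unknown range name(s): %s", paste(bad, collapse = ", ")))
  ranges <- utils::modifyList(defaults, ranges)
  draws <- .with_seed(seed, {
    tibble(
      patient_id = seq_len(n),
      pi_deg = runif(n, ranges$pi_deg[1], ranges$pi_deg[2]),
      pt_deg = runif(n, ranges$pt_deg[1], ranges$pt_deg[2]),
      sva_mm = runif(n, ranges$sva_mm[1], ranges$sva_mm[2]),
      ll_deg = runif(n, ranges$ll_deg[1], ranges$ll_deg[2])
    )
  })
  draws$landmarks <- purrr::pmap(
    draws[, c("pi_deg", "pt_deg", "sva_mm", "ll_deg")],
    function(pi_deg, pt_deg, sva_mm, ll_deg) {
      make_patient(patient_spec(
        pi_deg = pi_deg, pt_deg = pt_deg, sva_mm = sva_mm, ll_deg = ll_deg
      ))
    }
  )
  draws
}

#' Default fulcrum position of the synthetic frame
#'
#' The sagittal-plane fulcrum shared by [make_patient()] defaults and the
#' packaged synthetic muscle fixture: 55 mm from the femoral head (at the
#' origin) at 35 degrees posterior of vertical.
#'
#' @return Numeric `c(x, y)` in mm.
#' @export
default_fulcrum <- function() {
  55 * c(-sin(.deg2rad(35)), cos(.deg2rad(35)))
}

#' Packaged synthetic muscle attachment fixture
#'
#' Eight straight-line muscle segments crossing the osteotomy site (three
#' sections each of gluteus medius and maximus, tensor fasciae latae, and
#' piriformis) with synthetic 3-D attachment coordinates in the synthetic
#' patient frame (femoral head at the origin, fulcrum at
#' [default_fulcrum()]). The coordinates were constructed (see
#' `data-raw/muscle_fixture.R`) so that at a 20-degree opening the stretch
#' pattern matches the expected anatomy-driven behaviour: anterior segments
#' (TFL, anterior GMed) lengthen, the middle GMed stays isometric, and the
#' posterior segments (posterior GMed, all GMax sections, piriformis)
#' shorten.
#'
#' @return A `bpo_attachments` tibble with 8 rows.
#' @export
default_muscle_fixture <- function() {
  path <- system.file("extdata", "muscle_attachments_synthetic.json",
    package = "bposim"
  )
  if (path == "" || !file.exists(path)) {
    abort("packaged muscle fixture data file is missing")
  }
  read_attachments(path, complete = TRUE)
}
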