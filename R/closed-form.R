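#' Derive the patient-specific scalars of the closed-form equations
#'
#' Extracts from a baseline landmark set the distances and angles that make
#' the parameter-vs-opening-angle relationships closed-form: the segment
#' lengths `a` (fulcrum to femoral head), `b` (fulcrum to S1 midpoint), `L`
#' (fulcrum to T1 centroid) and `L'` (fulcrum to posterior S1 corner), their
#' ratios `k = b/a`, `k' = a/b`, `k'' = a/L`, and the baseline angles
#' `alpha1..alpha6` fixing the relative orientations of the fulcrum rays, the
#' endplate perpendicular and the vertical.
#'
#' The three arcsine kernels of the closed form are triangle angles (law of
#' sines): at the S1 midpoint in the fulcrum/femoral-head/S1-midpoint
#' triangle (drives PI), at the femoral head in the same triangle (the
#' auxiliary angle driving TPA), and at the femoral head in the
#' fulcrum/femoral-head/T1 triangle (drives T1 inclination). Their
#' orientation signs are frozen here by requiring agreement with the
#' rigid-rotation oracle at 0 and 10 degrees; the oracle is normative.
#'
#' @inheritParams measure_parameters
#' @return An object of class `bpo_geometry` (a list of scalars).
#' @export
derive_geometry <- function(landmarks, plumbline = c("c7", "t1")) {
  plumbline <- match.arg(plumbline)
  landmarks <- validate_landmarks(landmarks)

  fh <- .lm_point(landmarks, "femoral_head")
  fc <- .lm_point(landmarks, "fulcrum")
  ant <- .lm_point(landmarks, "s1_anterior")
  post <- .lm_point(landmarks, "s1_posterior")
  t1 <- .lm_point(landmarks, "t1_centroid")
  c7 <- .lm_point(landmarks, "c7_centroid")
  mid <- (ant + post) / 2

  len <- function(p, q, what) {
    d <- sqrt(sum((p - q)^2))
    if (d < 1e-9) abort(sprintf("zero-length segment: %s", what))
    d
  }
  a <- len(fc, fh, "fulcrum-femoral_head")
  b <- len(fc, mid, "fulcrum-S1 midpoint")
  L <- len(fc, t1, "fulcrum-t1_centroid")
  L_prime <- len(fc, post, "fulcrum-s1_posterior")
  L_c7 <- len(fc, c7, "fulcrum-c7_centroid")

  # signed CCW fulcrum angles from the (fixed) fulcrum->femoral-head ray;
  # the osteotomy adds +OA to each
  dir_fh <- .dir(fh - fc)
  alpha2 <- .wrap_2pi(.dir(mid - fc) - dir_fh)
  alpha6 <- .wrap_2pi(.dir(t1 - fc) - dir_fh)

  # anterior-from-vertical inclinations of the fulcrum rays to the trunk
  # landmarks and the posterior S1 corner; each becomes (phi - OA) after
  # rotation of the cranial fragment
  phi_t1 <- atan2(t1[1] - fc[1], t1[2] - fc[2])
  phi_c7 <- atan2(c7[1] - fc[1], c7[2] - fc[2])
  phi_post <- atan2(post[1] - fc[1], post[2] - fc[2])
  alpha4 <- phi_post + pi / 2

  base <- measure_parameters(landmarks, ll_deg = 0, plumbline = plumbline)
  pi0 <- .deg2rad(base$pi_deg)
  ss0 <- .deg2rad(base$ss_deg)
  t1spa0 <- .deg2rad(base$t1spi_deg)
  tpa0 <- .deg2rad(base$tpa_deg)

  k <- b / a
  k_prime <- a / b
  k_dprime <- a / L

  psi <- function(oa) asin(.clamp1(
    sin(alpha2 + oa) / sqrt(1 + k^2 - 2 * k * cos(alpha2 + oa)),
    what = "PI arcsine argument"
  ))
  beta <- function(oa) asin(.clamp1(
    sin(alpha2 + oa) / sqrt(1 + k_prime^2 - 2 * k_prime * cos(alpha2 + oa)),
    what = "beta arcsine argument"
  ))
  eta <- function(oa) asin(.clamp1(
    sin(alpha6 + oa) / sqrt(1 + k_dprime^2 - 2 * k_dprime * cos(alpha6 + oa)),
    what = "T1 inclination arcsine argument"
  ))

  # freeze orientation signs against the oracle at a reference opening angle
  oa_ref <- .deg2rad(10)
  ref <- measure_parameters(
    apply_osteotomy(landmarks, 10),
    ll_deg = 0, plumbline = plumbline
  )

  pick_sign <- function(err_plus, err_minus, what) {
    if (min(err_plus, err_minus) > .deg2rad(1e-6)) {
      warn(sprintf(
        "closed-form %s does not reproduce the oracle at the reference angle (residual %.3g deg); the oracle remains normative",
        what, .rad2deg(min(err_plus, err_minus))
      ))
    }
    if (err_plus <= err_minus) 1 else -1
  }

  err_pi <- function(s) abs((pi0 - s * psi(0) + s * psi(oa_ref)) - .deg2rad(ref$pi_deg))
  s_pi <- pick_sign(err_pi(1), err_pi(-1), "PI")
  alpha1 <- pi0 - s_pi * psi(0)
  alpha3 <- pi / 2 - alpha1 + ss0 # makes PT = PI - SS0 + OA exact

  err_t1 <- function(s) abs((t1spa0 - s * eta(0) + s * eta(oa_ref)) - .deg2rad(ref$t1spi_deg))
  s_t1 <- pick_sign(err_t1(1), err_t1(-1), "T1 inclination")
  alpha5 <- t1spa0 - s_t1 * eta(0) + pi / 2

  err_tpa <- function(s) {
    abs((s_t1 * eta(oa_ref) - s * beta(oa_ref)) +
      (tpa0 - s_t1 * eta(0) + s * beta(0)) - .deg2rad(ref$tpa_deg))
  }
  s_beta <- pick_sign(err_tpa(1), err_tpa(-1), "TPA")
  tpa_offset <- tpa0 - s_t1 * eta(0) + s_beta * beta(0) # 0 for consistent geometry

  out <- list(
    a = a, b = b, L = L, L_prime = L_prime, L_c7 = L_c7,
    k = k, k_prime = k_prime, k_dprime = k_dprime,
    alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
    alpha4 = alpha4, alpha5 = alpha5, alpha6 = alpha6,
    phi_t1 = phi_t1, phi_c7 = phi_c7, phi_post = phi_post,
    s_pi = s_pi, s_t1 = s_t1, s_beta = s_beta,
    tpa_offset = tpa_offset,
    pi0 = pi0, ss0 = ss0, pt0 = .deg2rad(base$pt_deg),
    plumbline = plumbline
  )
  class(out) <- "bpo_geometry"
  out
}

#' @export
print.bpo_geometry <- function(x, ...) {
  cat("Closed-form osteotomy geometry\n")
  cat(sprintf(
    "  a = %.2f mm, b = %.2f mm, L = %.2f mm, L' = %.2f mm\n",
    x$a, x$b, x$L, x$L_prime
  ))
  cat(sprintf(
    "  k = %.4f, k' = %.4f, k'' = %.4f\n", x$k, x$k_prime, x$k_dprime
  ))
  cat(sprintf(
    "  alpha1..alpha6 (deg): %s\n",
    paste(sprintf("%.2f", .rad2deg(c(
      x$alpha1, x$alpha2, x$alpha3, x$alpha4, x$alpha5, x$alpha6
    ))), collapse = ", ")
  ))
  cat(sprintf("  SVA plumbline: %s\n", x$plumbline))
  invisible(x)
}

#' Closed-form prediction of parameters at given opening angles
#'
#' Evaluates the closed-form predictive equations from a [derive_geometry()]
#' object: PI through the law-of-sines triangle with sides `a`, `b` and
#' fulcrum angle `alpha2 + OA`; PT through the exact linear relation
#' `PT = PI - SS(0) + OA` (equivalently `SS(OA) = SS(0) - OA`); the T1
#' inclination through the companion triangle with `k''`; TPA as the
#' difference of the two femoral-head triangle angles; and SVA by
#' decomposing the plumb offset through the fulcrum,
#' `SVA = L_pl sin(phi_pl - OA) + L' cos(alpha4 - OA)`, where `phi_pl` is the
#' baseline anterior inclination of the fulcrum ray to the plumb landmark.
#'
#' @param geom A `bpo_geometry` object.
#' @inheritParams measure_parameters
#' @param oa_deg Numeric vector of opening angles (degrees).
#' @return A tibble of class `bpo_prediction`, one row per opening angle,
#'   with the same columns as [oracle_predict()].
#' @export
closed_form_predict <- function(geom, ll_deg, oa_deg, plumbline = NULL) {
  stopifnot(inherits(geom, "bpo_geometry"))
  if (is.null(plumbline)) plumbline <- geom$plumbline
  plumbline <- match.arg(plumbline, c("c7", "t1"))
  stopifnot(is.numeric(oa_deg), all(is.finite(oa_deg)))
  oa <- .deg2rad(oa_deg)

  kernel <- function(gamma, kk, what) {
    arg <- sin(gamma) / sqrt(1 + kk^2 - 2 * kk * cos(gamma))
    bad <- abs(arg) > 1 + 1e-12
    if (any(bad)) {
      abort(sprintf(
        "%s out of [-1, 1] at OA = %.3f deg", what,
        .rad2deg(gamma[which(bad)[1]] - if (identical(kk, geom$k_dprime)) geom$alpha6 else geom$alpha2)
      ))
    }
    asin(pmin(pmax(arg, -1), 1))
  }

  g2 <- geom$alpha2 + oa
  g6 <- geom$alpha6 + oa
  psi <- kernel(g2, geom$k, "PI arcsine argument")
  beta <- kernel(g2, geom$k_prime, "beta arcsine argument")
  eta <- kernel(g6, geom$k_dprime, "T1 inclination arcsine argument")

  pi_r <- geom$alpha1 + geom$s_pi * psi
  pt_r <- pi_r + pi / 2 - geom$alpha1 - geom$alpha3 + oa
  ss_r <- geom$ss0 - oa
  t1spa_r <- geom$s_t1 * eta + geom$alpha5 - pi / 2
  tpa_r <- geom$s_t1 * eta - geom$s_beta * beta + geom$tpa_offset

  if (plumbline == "c7") {
    sva <- geom$L_c7 * sin(geom$phi_c7 - oa) + geom$L_prime * cos(geom$alpha4 - oa)
  } else {
    sva <- geom$L * sin(geom$phi_t1 - oa) + geom$L_prime * cos(geom$alpha4 - oa)
  }

  out <- tibble(
    oa_deg = oa_deg,
    pi_deg = .rad2deg(pi_r),
    pt_deg = .rad2deg(pt_r),
    ss_deg = .rad2deg(ss_r),
    sva_mm = sva,
    tpa_deg = .rad2deg(tpa_r),
    t1spi_deg = .rad2deg(t1spa_r),
    pi_minus_ll_deg = .rad2deg(pi_r) - ll_deg,
    ll_deg = ll_deg
  )
  class(out) <- c("bpo_prediction", class(out))
  out
}

#' Fit linear parameter-vs-opening-angle models
#'
#' Over the practical range of opening angles the nonlinear closed-form
#' relationships are very nearly linear; this fits one ordinary least-squares
#' line per parameter against the opening angle.
#'
#' @param table A `bpo_prediction` tibble (from [oracle_predict()] or
#'   [closed_form_predict()]) with at least 3 distinct opening angles.
#' @param parameters Character vector of parameter columns to fit.
#' @return A tibble of class `bpo_linear_fit` with columns `parameter`,
#'   `slope`, `intercept`, `r_squared`, `oa_min_deg`, `oa_max_deg`.
#' @export
fit_linear <- function(table,
                       parameters = c("sva_mm", "pi_deg", "pt_deg", "tpa_deg")) {
  df <- as_tibble(table)
  if (!"oa_deg" %in% names(df)) abort("table must have an oa_deg column")
  if (length(unique(df$oa_deg)) < 3) {
    abort("need at least 3 distinct opening angles to fit linear models")
  }
  missing <- setdiff(parameters, names(df))
  if (length(missing)) {
    abort(sprintf("parameter column(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  out <- purrr::map_dfr(parameters, function(p) {
    fit <- lm(df[[p]] ~ df$oa_deg)
    ssr <- sum(residuals(fit)^2)
    sst <- sum((df[[p]] - mean(df[[p]]))^2)
    tibble(
      parameter = p,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
      oa_min_deg = min(df$oa_deg),
      oa_max_deg = max(df$oa_deg)
    )
  })
  class(out) <- c("bpo_linear_fit", class(out))
  out
}

#' Evaluate fitted linear models at given opening angles
#'
#' @param models A `bpo_linear_fit` tibble (from [fit_linear()] or
#'   [example_linear_models()]).
#' @param oa_deg Numeric vector of opening angles (degrees).
#' @param parameter Optional single parameter name; if given, returns a
#'   numeric vector of `slope * oa + intercept` for that parameter, otherwise
#'   a wide tibble with one column per modelled parameter.
#' @export
evaluate_linear <- function(models, oa_deg, parameter = NULL) {
  df <- as_tibble(models)
  stopifnot(all(c("parameter", "slope", "intercept") %in% names(df)))
  stopifnot(is.numeric(oa_deg), all(is.finite(oa_deg)))
  if (!is.null(parameter)) {
    i <- match(parameter, df$parameter)
    if (is.na(i)) abort(sprintf("no linear model for parameter '%s'", parameter))
    return(df$slope[i] * oa_deg + df$intercept[i])
  }
  out <- tibble(oa_deg = oa_deg)
  for (i in seq_len(nrow(df))) {
    out[[df$parameter[i]]] <- df$slope[i] * oa_deg + df$intercept[i]
  }
  out
}

#' Linear models of the packaged reference deformity case
#'
#' Slope/intercept coefficients of the parameter-vs-opening-angle lines for
#' the package's reference example: a severe rigid sagittal deformity with
#' baseline SVA 223.8 mm, PI 54.4 deg, PT 10.4 deg and TPA 27.0 deg. SVA is
#' in mm; the opening angle and the other parameters are in degrees. These
#' are packaged constants (the underlying radiographic landmark coordinates
#' are not available), useful as a worked example and for exercising the
#' planner on a linear engine.
#'
#' @return A `bpo_linear_fit` tibble with models for `sva_mm`, `pi_deg`,
#'   `pt_deg`, `tpa_deg` over opening angles 0-40 degrees.
#' @export
example_linear_models <- function() {
  out <- tibble(
    parameter = c("sva_mm", "pi_deg", "pt_deg", "tpa_deg"),
    slope = c(-8.3, -0.7, 0.3, -0.6),
    intercept = c(223.8, 54.4, 10.4, 27.0),
    r_squared = NA_real_,
    oa_min_deg = 0,
    oa_max_deg = 40
  )
  class(out) <- c("bpo_linear_fit", class(out))
  out
}
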