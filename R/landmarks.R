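#' Sagittal-plane landmark sets
#'
#' A landmark set is the geometric state of the osteotomy model: six named
#' sagittal-plane points in a frame with x anterior-positive and y
#' cranial-positive, units mm. The fulcrum (posterior cortex at the sciatic
#' notch) is the hinge of the osteotomy; the femoral head belongs to the
#' caudal fragment, and the S1 endplate corners, T1 and C7 centroids to the
#' cranial fragment that rotates when the wedge is opened.
#'
#' @param femoral_head,fulcrum,s1_anterior,s1_posterior,t1_centroid,c7_centroid
#'   Numeric length-2 vectors `c(x, y)` in mm.
#'
#' @return A tibble of class `bpo_landmarks` with columns `landmark`, `x`,
#'   `y`, `fragment`.
#' @examples
#' lm <- landmark_set(
#'   femoral_head = c(0, 0), fulcrum = c(-31.5, 45),
#'   s1_anterior = c(-27, 75), s1_posterior = c(-54, 97),
#'   t1_centroid = c(-60, 420), c7_centroid = c(-55, 438)
#' )
#' measure_parameters(lm, ll_deg = 30)
#' @export
landmark_set <- function(femoral_head, fulcrum, s1_anterior, s1_posterior,
                         t1_centroid, c7_centroid) {
  pts <- list(
    femoral_head = femoral_head, fulcrum = fulcrum,
    s1_anterior = s1_anterior, s1_posterior = s1_posterior,
    t1_centroid = t1_centroid, c7_centroid = c7_centroid
  )
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2 || !all(is.finite(p))) {
      abort(sprintf("landmark '%s' must be a finite numeric vector c(x, y)", nm))
    }
  }
  out <- tibble(
    landmark = names(pts),
    x = unname(vapply(pts, `[`, numeric(1), 1)),
    y = unname(vapply(pts, `[`, numeric(1), 2)),
    fragment = .bpo_fragments[names(pts)]
  )
  class(out) <- c("bpo_landmarks", class(out))
  validate_landmarks(out)
}

.bpo_landmark_names <- c(
  "femoral_head", "fulcrum", "s1_anterior", "s1_posterior",
  "t1_centroid", "c7_centroid"
)

.bpo_fragments <- c(
  femoral_head = "caudal", fulcrum = "fulcrum",
  s1_anterior = "cranial", s1_posterior = "cranial",
  t1_centroid = "cranial", c7_centroid = "cranial"
)

#' Validate a landmark table
#'
#' Checks the structural invariants of a landmark set: all six landmarks
#' present with finite coordinates, correct fragment membership, fulcrum
#' distinct from the femoral head, distinct S1 corners with the anterior
#' corner anterior to (greater x than) the posterior corner, and an S1
#' midpoint distinct from the femoral head.
#'
#' @param landmarks A data frame as produced by [landmark_set()].
#' @return The validated landmark table, invisibly classed `bpo_landmarks`.
#' @export
validate_landmarks <- function(landmarks) {
  df <- as_tibble(landmarks)
  need <- c("landmark", "x", "y", "fragment")
  if (!all(need %in% names(df))) {
    abort("landmark table needs columns landmark, x, y, fragment")
  }
  missing <- setdiff(.bpo_landmark_names, df$landmark)
  if (length(missing)) {
    abort(sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$landmark)) abort("duplicated landmark names")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    abort("landmark coordinates must be finite")
  }
  bad_frag <- df$fragment != .bpo_fragments[df$landmark]
  if (any(bad_frag)) {
    abort(sprintf(
      "wrong fragment assignment for: %s",
      paste(df$landmark[bad_frag], collapse = ", ")
    ))
  }
  p <- function(nm) unlist(df[df$landmark == nm, c("x", "y")], use.names = FALSE)
  if (identical(p("fulcrum"), p("femoral_head"))) {
    abort("degenerate geometry: fulcrum coincides with femoral_head")
  }
  ant <- p("s1_anterior")
  post <- p("s1_posterior")
  if (all(ant == post)) abort("degenerate geometry: s1_anterior coincides with s1_posterior")
  if (ant[1] <= post[1]) {
    abort("s1_anterior must be anterior to (greater x than) s1_posterior")
  }
  mid <- (ant + post) / 2
  if (sqrt(sum((mid - p("femoral_head"))^2)) < 1e-9) {
    abort("degenerate geometry: S1 endplate midpoint coincides with femoral_head")
  }
  if (!inherits(df, "bpo_landmarks")) class(df) <- c("bpo_landmarks", class(df))
  invisible(df)
}

# fetch a named landmark as c(x, y)
.lm_point <- function(landmarks, name) {
  i <- match(name, landmarks$landmark)
  c(unname(landmarks$x[i]), unname(landmarks$y[i]))
}

#' Measure spinopelvic sagittal parameters from landmarks
#'
#' Computes the standard radiographic parameters from a landmark set:
#' pelvic incidence (PI), pelvic tilt (PT), sacral slope (SS), sagittal
#' vertical axis (SVA), T1 pelvic angle (TPA), and T1 spinopelvic
#' inclination (T1SPi). PI is the angle at the S1-endplate midpoint between
#' the endplate perpendicular and the line to the femoral head (measured
#' signed so the identity PI = PT + SS is preserved even in degenerate
#' configurations; it is positive for any plausible anatomy); PT is
#' positive when the midpoint lies posterior to the vertical through the
#' femoral head; SS is positive when the endplate descends anteriorly (the
#' orientation under which PI = PT + SS holds with these sign conventions);
#' SVA is the horizontal offset of the plumb landmark from the posterior S1
#' corner.
#'
#' @param landmarks A [landmark_set()] table.
#' @param ll_deg Lumbar lordosis in degrees, carried as a constant (the spine
#'   is modelled as rigid).
#' @param plumbline `"c7"` (default) or `"t1"`: which centroid defines the
#'   SVA plumbline.
#' @return A one-row tibble with columns `pi_deg`, `pt_deg`, `ss_deg`,
#'   `sva_mm`, `tpa_deg`, `t1spi_deg`, `pi_minus_ll_deg`, `ll_deg`.
#' @export
measure_parameters <- function(landmarks, ll_deg, plumbline = c("c7", "t1")) {
  plumbline <- match.arg(plumbline)
  landmarks <- validate_landmarks(landmarks)
  stopifnot(is.numeric(ll_deg), length(ll_deg) == 1, is.finite(ll_deg))

  fh <- .lm_point(landmarks, "femoral_head")
  ant <- .lm_point(landmarks, "s1_anterior")
  post <- .lm_point(landmarks, "s1_posterior")
  t1 <- .lm_point(landmarks, "t1_centroid")
  c7 <- .lm_point(landmarks, "c7_centroid")
  mid <- (ant + post) / 2

  u <- mid - fh # femoral head -> S1 midpoint
  if (sqrt(sum(u^2)) < 1e-9) {
    abort("degenerate geometry: S1 endplate midpoint coincides with femoral_head")
  }
  pt <- atan2(-u[1], u[2]) # positive when midpoint posterior to vertical

  v <- ant - post # endplate, posterior -> anterior
  ss <- atan2(-v[2], v[1]) # positive when endplate descends anteriorly

  # signed angle (CCW) from the caudally-directed endplate perpendicular to
  # the ray midpoint -> femoral head; positive for all plausible anatomy
  n_caudal <- c(v[2], -v[1]) / sqrt(sum(v^2))
  ray <- -u / sqrt(sum(u^2))
  pi_ang <- atan2(
    n_caudal[1] * ray[2] - n_caudal[2] * ray[1],
    sum(n_caudal * ray)
  )

  if (abs(pi_ang - (pt + ss)) > .deg2rad(1e-9)) {
    abort("inconsistent endplate orientation: PI does not equal PT + SS for this geometry")
  }

  w1 <- t1 - fh
  if (sqrt(sum(w1^2)) < 1e-9) {
    abort("degenerate geometry: t1_centroid coincides with femoral_head")
  }
  # signed angle at the femoral head between the rays to the S1 midpoint and
  # to T1 (positive when the T1 ray is anterior of the S1-midpoint ray, the
  # situation in sagittal deformity); equals PT + T1SPi
  tpa <- .wrap_pi(atan2(u[2], u[1]) - atan2(w1[2], w1[1]))
  t1spi <- atan2(w1[1], w1[2]) # positive when T1 anterior to the femoral head

  plumb_x <- if (plumbline == "c7") c7[1] else t1[1]
  sva <- plumb_x - post[1]

  pi_deg <- .rad2deg(pi_ang)
  tibble(
    pi_deg = pi_deg,
    pt_deg = .rad2deg(pt),
    ss_deg = .rad2deg(ss),
    sva_mm = sva,
    tpa_deg = .rad2deg(tpa),
    t1spi_deg = .rad2deg(t1spi),
    pi_minus_ll_deg = pi_deg - ll_deg,
    ll_deg = ll_deg
  )
}

#' Simulate the osteotomy as a rigid rotation of the cranial fragment
#'
#' Opens an anterior wedge of `oa_deg` degrees at the fulcrum: every
#' cranial-fragment landmark is rotated counterclockwise (in the anterior-x,
#' cranial-y frame) about the fulcrum, displacing the trunk posteriorly.
#' Caudal landmarks and the fulcrum are unchanged.
#'
#' @inheritParams measure_parameters
#' @param oa_deg Opening angle in degrees, `0 <= oa_deg <= oa_cap_deg`.
#' @param oa_cap_deg Hard cap on the opening angle (default 60).
#' @return A new `bpo_landmarks` tibble.
#' @export
apply_osteotomy <- function(landmarks, oa_deg, oa_cap_deg = 60) {
  landmarks <- validate_landmarks(landmarks)
  stopifnot(is.numeric(oa_deg), length(oa_deg) == 1, is.finite(oa_deg))
  if (oa_deg < 0 || oa_deg > oa_cap_deg) {
    abort(sprintf("opening angle %.3f deg outside [0, %.3f]", oa_deg, oa_cap_deg))
  }
  if (oa_deg == 0) {
    return(landmarks)
  }
  fulcrum <- .lm_point(landmarks, "fulcrum")
  out <- landmarks
  idx <- out$fragment == "cranial"
  rot <- .rotate_about(cbind(out$x[idx], out$y[idx]), .deg2rad(oa_deg), fulcrum)
  out$x[idx] <- rot[, 1]
  out$y[idx] <- rot[, 2]
  out
}

#' Direct-geometry prediction of parameters over an opening-angle grid
#'
#' The normative geometric oracle: for each opening angle in the grid, the
#' cranial fragment is rotated about the fulcrum and the parameters are
#' re-measured from the rotated landmarks. The row at 0 degrees equals the
#' baseline measurement exactly.
#'
#' @inheritParams measure_parameters
#' @param oa_grid_deg Nonempty ascending numeric vector of opening angles
#'   (degrees).
#' @param oa_cap_deg Hard cap passed to [apply_osteotomy()].
#' @return A tibble of class `bpo_prediction`, one row per opening angle.
#' @export
oracle_predict <- function(landmarks, ll_deg, oa_grid_deg,
                           plumbline = c("c7", "t1"), oa_cap_deg = 60) {
  plumbline <- match.arg(plumbline)
  if (length(oa_grid_deg) == 0) abort("oa_grid_deg must be nonempty")
  if (is.unsorted(oa_grid_deg, strictly = FALSE)) {
    abort("oa_grid_deg must be sorted ascending")
  }
  landmarks <- validate_landmarks(landmarks)
  rows <- purrr::map(oa_grid_deg, function(oa) {
    measure_parameters(
      apply_osteotomy(landmarks, oa, oa_cap_deg = oa_cap_deg),
      ll_deg = ll_deg, plumbline = plumbline
    )
  })
  out <- dplyr::bind_cols(
    tibble(oa_deg = oa_grid_deg),
    dplyr::bind_rows(rows)
  )
  class(out) <- c("bpo_prediction", class(out))
  out
}

#' Remove compensatory pelvic tilt by whole-image rotation
#'
#' Rotates the entire landmark set (both fragments and the fulcrum) about the
#' femoral head until the measured pelvic tilt equals `target_pt_deg`. This is
#' the standard pre-planning step that unmasks the true extent of a sagittal
#' deformity hidden by compensatory pelvic retroversion: planning on the
#' compensated image under-corrects. Pelvic incidence is invariant under this
#' rotation.
#'
#' @inheritParams measure_parameters
#' @param target_pt_deg Desired pelvic tilt in degrees after rotation.
#' @return A new `bpo_landmarks` tibble with `pt_deg == target_pt_deg`.
#' @export
decompensate_pt <- function(landmarks, target_pt_deg) {
  landmarks <- validate_landmarks(landmarks)
  stopifnot(is.numeric(target_pt_deg), length(target_pt_deg) == 1, is.finite(target_pt_deg))
  current <- measure_parameters(landmarks, ll_deg = 0)$pt_deg
  rho <- .deg2rad(target_pt_deg - current) # CCW rotation adds to PT
  fh <- .lm_point(landmarks, "femoral_head")
  out <- landmarks
  rot <- .rotate_about(cbind(out$x, out$y), rho, fh)
  out$x <- rot[, 1]
  out$y <- rot[, 2]
  out
}
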