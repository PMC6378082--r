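#' Muscle attachment tables
#'
#' One row per one-dimensional muscle segment crossing the osteotomy site,
#' with a cranial attachment (on the rotating fragment) and a caudal
#' attachment (on the fixed fragment), as 3-D coordinates in mm: x anterior,
#' y cranial, z perpendicular to the sagittal plane. Gluteus medius and
#' maximus are broad and are subdivided into anterior/middle/posterior
#' sections; tensor fasciae latae and piriformis are single segments.
#'
#' @param df Data frame with columns `name`, `group` (one of `GMed`, `GMax`,
#'   `TFL`, `P`), `section` (`anterior`, `middle`, `posterior`, or `whole`),
#'   `cranial_x`, `cranial_y`, `cranial_z`, `caudal_x`, `caudal_y`,
#'   `caudal_z`.
#' @param complete If `TRUE`, additionally require the full fixture
#'   structure: three sections for each of GMed and GMax present, one
#'   (`whole`) for TFL and P.
#' @return A validated tibble of class `bpo_attachments`.
#' @export
muscle_attachments <- function(df, complete = FALSE) {
  df <- as_tibble(df)
  need <- c(
    "name", "group", "section",
    "cranial_x", "cranial_y", "cranial_z",
    "caudal_x", "caudal_y", "caudal_z"
  )
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("attachment table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("attachment table is empty")
  if (anyDuplicated(df$name)) {
    abort(sprintf(
      "duplicated segment name(s): %s",
      paste(unique(df$name[duplicated(df$name)]), collapse = ", ")
    ))
  }
  bad_group <- setdiff(unique(df$group), c("GMed", "GMax", "TFL", "P"))
  if (length(bad_group)) {
    abort(sprintf("unknown muscle group(s): %s", paste(bad_group, collapse = ", ")))
  }
  multi <- df$group %in% c("GMed", "GMax")
  bad_sec <- (multi & !df$section %in% c("anterior", "middle", "posterior")) |
    (!multi & df$section != "whole")
  if (any(bad_sec)) {
    abort(sprintf(
      "invalid section for segment(s): %s",
      paste(df$name[bad_sec], collapse = ", ")
    ))
  }
  coords <- as.matrix(df[, need[-(1:3)]])
  if (!all(is.finite(coords))) abort("attachment coordinates must be finite")
  same <- df$cranial_x == df$caudal_x & df$cranial_y == df$caudal_y &
    df$cranial_z == df$caudal_z
  if (any(same)) {
    abort(sprintf(
      "cranial and caudal points coincide for: %s",
      paste(df$name[same], collapse = ", ")
    ))
  }
  if (complete) {
    for (g in c("GMed", "GMax")) {
      secs <- sort(df$section[df$group == g])
      if (!identical(secs, sort(c("anterior", "middle", "posterior")))) {
        abort(sprintf("group %s must have exactly the anterior, middle and posterior sections", g))
      }
    }
    for (g in c("TFL", "P")) {
      if (sum(df$group == g) != 1) abort(sprintf("group %s must have exactly one segment", g))
    }
  }
  if (!inherits(df, "bpo_attachments")) class(df) <- c("bpo_attachments", class(df))
  df
}

#' Baseline geometry of muscle segments about the fulcrum
#'
#' Projects each segment's attachments onto the sagittal plane and expresses
#' it in fulcrum-centred polar terms: `l1` (fulcrum to cranial attachment),
#' `l2` (fulcrum to caudal attachment), the signed included angle `beta`
#' (counterclockwise from the caudal ray to the cranial ray), the
#' out-of-plane offset `delta_z`, and the baseline 3-D length
#' `L0 = sqrt(l1^2 + l2^2 - 2 l1 l2 cos(beta) + delta_z^2)`.
#'
#' The sign of `beta` is what separates lengthening from shortening muscles:
#' every cranial attachment rotates by the same +OA, so a segment lengthens
#' at small opening angles iff `sin(beta) > 0`.
#'
#' @param attachments A [muscle_attachments()] table.
#' @param fulcrum Numeric `c(x, y)`: the sagittal-plane fulcrum (mm).
#' @return A tibble of class `bpo_muscle_geometry` with columns `name`,
#'   `group`, `section`, `l1_mm`, `l2_mm`, `beta_deg`, `delta_z_mm`,
#'   `l0_mm`.
#' @export
baseline_geometry <- function(attachments, fulcrum) {
  df <- muscle_attachments(attachments)
  stopifnot(is.numeric(fulcrum), length(fulcrum) == 2, all(is.finite(fulcrum)))
  d1x <- df$cranial_x - fulcrum[1]
  d1y <- df$cranial_y - fulcrum[2]
  d2x <- df$caudal_x - fulcrum[1]
  d2y <- df$caudal_y - fulcrum[2]
  l1 <- sqrt(d1x^2 + d1y^2)
  l2 <- sqrt(d2x^2 + d2y^2)
  bad <- l1 < 1e-9 | l2 < 1e-9
  if (any(bad)) {
    abort(sprintf(
      "attachment projects onto the fulcrum for segment(s): %s",
      paste(df$name[bad], collapse = ", ")
    ))
  }
  beta <- .wrap_pi(atan2(d1y, d1x) - atan2(d2y, d2x))
  dz <- abs(df$cranial_z - df$caudal_z)
  l0 <- sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(beta) + dz^2)
  out <- tibble(
    name = df$name, group = df$group, section = df$section,
    l1_mm = l1, l2_mm = l2, beta_deg = .rad2deg(beta),
    delta_z_mm = dz, l0_mm = l0
  )
  class(out) <- c("bpo_muscle_geometry", class(out))
  out
}

#' Post-osteotomy muscle segment length
#'
#' Law-of-cosines length after opening the wedge by `oa_deg`: the in-plane
#' chord becomes `l = sqrt(l1^2 + l2^2 - 2 l1 l2 cos(beta + OA))` (the
#' cranial attachment rotates counterclockwise with the fragment, the same
#' sign convention as [apply_osteotomy()]) and the 3-D length is
#' `d = sqrt(l^2 + delta_z^2)`.
#'
#' @param geom A [baseline_geometry()] table.
#' @param oa_deg Single opening angle in degrees.
#' @return Numeric vector of segment lengths (mm), one per row of `geom`.
#' @export
stretched_length <- function(geom, oa_deg) {
  df <- as_tibble(geom)
  stopifnot(
    all(c("l1_mm", "l2_mm", "beta_deg", "delta_z_mm") %in% names(df)),
    is.numeric(oa_deg), length(oa_deg) == 1, is.finite(oa_deg)
  )
  ang <- .deg2rad(df$beta_deg + oa_deg)
  chord2 <- df$l1_mm^2 + df$l2_mm^2 - 2 * df$l1_mm * df$l2_mm * cos(ang)
  sqrt(pmax(chord2, 0) + df$delta_z_mm^2)
}

#' Stretch-ratio curves over an opening-angle grid
#'
#' Computes per segment and opening angle the post-osteotomy length `d`, the
#' stretch ratio `lambda = d / L0`, the classification (lengthening,
#' shortening, or isometric when `|lambda - 1| <= tol_isometric`) and whether
#' the ratio reaches the critical stretch `1 + critical_sr` beyond which
#' muscle function is considered at risk.
#'
#' @inheritParams baseline_geometry
#' @param oa_grid_deg Numeric vector of opening angles (degrees).
#' @param critical_sr Critical stretch ratio as a fraction (default 0.254,
#'   i.e. 25.4% beyond resting length; some sources round to 25%).
#' @param tol_isometric Tolerance on `|lambda - 1|` for the isometric label.
#' @return A tibble of class `bpo_muscle_curve` with columns `segment`,
#'   `group`, `section`, `oa_deg`, `length_mm`, `stretch_ratio`,
#'   `classification`, `exceeds_critical`.
#' @export
stretch_ratio_curve <- function(attachments, fulcrum, oa_grid_deg,
                                critical_sr = 0.254, tol_isometric = 1e-6) {
  if (length(oa_grid_deg) == 0) abort("oa_grid_deg must be nonempty")
  stopifnot(is.numeric(critical_sr), critical_sr > 0, critical_sr < 1)
  geom <- baseline_geometry(attachments, fulcrum)
  out <- purrr::map_dfr(oa_grid_deg, function(oa) {
    d <- stretched_length(geom, oa)
    lambda <- d / geom$l0_mm
    tibble(
      segment = geom$name, group = geom$group, section = geom$section,
      oa_deg = oa, length_mm = d, stretch_ratio = lambda,
      classification = dplyr::case_when(
        abs(lambda - 1) <= tol_isometric ~ "isometric",
        lambda > 1 ~ "lengthening",
        TRUE ~ "shortening"
      ),
      exceeds_critical = lambda >= 1 + critical_sr
    )
  })
  class(out) <- c("bpo_muscle_curve", class(out))
  out
}

#' Safety summary of muscle stretch results
#'
#' Shortening segments are considered safe (their attachment points approach
#' each other and the muscle bears no stretch); lengthening segments are
#' flagged unsafe only when their stretch ratio reaches the critical value
#' used when the curves were computed.
#'
#' @param results A `bpo_muscle_curve` tibble from [stretch_ratio_curve()].
#' @return A list of class `bpo_muscle_safety` with a per-segment tibble
#'   (`segment`, `max_stretch_ratio`, `oa_at_max_deg`, `ever_exceeds`,
#'   `safe`), the overall `max_stretch_ratio` and `max_stretch_segment`, and
#'   `n_unsafe`.
#' @export
classify_safety <- function(results) {
  df <- as_tibble(results)
  need <- c("segment", "oa_deg", "stretch_ratio", "exceeds_critical")
  stopifnot(all(need %in% names(df)))
  per <- df |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      max_stretch_ratio = max(.data$stretch_ratio),
      oa_at_max_deg = .data$oa_deg[which.max(.data$stretch_ratio)],
      ever_exceeds = any(.data$exceeds_critical),
      .groups = "drop"
    ) |>
    dplyr::mutate(safe = !.data$ever_exceeds)
  i <- which.max(per$max_stretch_ratio)
  out <- list(
    per_segment = per,
    n_unsafe = sum(!per$safe),
    unsafe_segments = per$segment[!per$safe],
    max_stretch_ratio = per$max_stretch_ratio[i],
    max_stretch_segment = per$segment[i]
  )
  class(out) <- "bpo_muscle_safety"
  out
}

#' @export
print.bpo_muscle_safety <- function(x, ...) {
  cat(sprintf(
    "%d of %d segments flagged unsafe; max stretch ratio %.4f (%s)\n",
    x$n_unsafe, nrow(x$per_segment), x$max_stretch_ratio, x$max_stretch_segment
  ))
  invisible(x)
}
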