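#' Read and write landmark files
#'
#' Landmark files are JSON objects with `"units": "mm"`,
#' `"frame": "x_anterior_y_cranial"`, and one `[x, y]` pair per named
#' landmark. Unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a validated `bpo_landmarks` tibble;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("landmark file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(obj)) abort("malformed landmark file: expected a JSON object")
  allowed <- c("units", "frame", .bpo_landmark_names)
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown key(s) in landmark file: %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(obj$units) || !identical(obj$units, "mm")) {
    abort(sprintf(
      "landmark file units must be \"mm\" (got %s)",
      if (is.null(obj$units)) "none" else deparse(obj$units)
    ))
  }
  if (is.null(obj$frame) || !identical(obj$frame, "x_anterior_y_cranial")) {
    abort("landmark file frame must be \"x_anterior_y_cranial\"")
  }
  missing <- setdiff(.bpo_landmark_names, names(obj))
  if (length(missing)) {
    abort(sprintf("missing landmark(s) in file: %s", paste(missing, collapse = ", ")))
  }
  for (nm in .bpo_landmark_names) {
    if (!is.numeric(obj[[nm]]) || length(obj[[nm]]) != 2) {
      abort(sprintf("landmark '%s' must be a numeric [x, y] pair", nm))
    }
  }
  landmark_set(
    femoral_head = obj$femoral_head, fulcrum = obj$fulcrum,
    s1_anterior = obj$s1_anterior, s1_posterior = obj$s1_posterior,
    t1_centroid = obj$t1_centroid, c7_centroid = obj$c7_centroid
  )
}

#' @rdname read_landmarks
#' @param landmarks A `bpo_landmarks` tibble.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(landmarks)
  obj <- c(
    list(units = "mm", frame = "x_anterior_y_cranial"),
    setNames(
      purrr::map(.bpo_landmark_names, function(nm) .lm_point(landmarks, nm)),
      .bpo_landmark_names
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write muscle attachment files
#'
#' Attachment files are JSON arrays of segment objects with `name`, `group`,
#' `section`, and `cranial` / `caudal` `[x, y, z]` coordinate triplets in
#' mm.
#'
#' @param path File path.
#' @param complete Require the full 8-segment fixture structure (see
#'   [muscle_attachments()]).
#' @return `read_attachments()` returns a validated `bpo_attachments`
#'   tibble; `write_attachments()` returns `path` invisibly.
#' @export
read_attachments <- function(path, complete = FALSE) {
  if (!file.exists(path)) abort(sprintf("attachment file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || length(obj) == 0) {
    abort("attachment file must be a nonempty JSON array of segments")
  }
  rows <- purrr::map_dfr(obj, function(seg) {
    need <- c("name", "group", "section", "cranial", "caudal")
    missing <- setdiff(need, names(seg))
    if (length(missing)) {
      abort(sprintf("segment missing field(s): %s", paste(missing, collapse = ", ")))
    }
    cr <- unlist(seg$cranial)
    ca <- unlist(seg$caudal)
    if (length(cr) != 3 || length(ca) != 3 || !is.numeric(cr) || !is.numeric(ca)) {
      abort(sprintf("segment '%s': cranial/caudal must be numeric [x, y, z]", seg$name))
    }
    tibble(
      name = seg$name, group = seg$group, section = seg$section,
      cranial_x = cr[1], cranial_y = cr[2], cranial_z = cr[3],
      caudal_x = ca[1], caudal_y = ca[2], caudal_z = ca[3]
    )
  })
  muscle_attachments(rows, complete = complete)
}

#' @rdname read_attachments
#' @param attachments A `bpo_attachments` tibble.
#' @export
write_attachments <- function(attachments, path) {
  df <- muscle_attachments(attachments)
  segs <- purrr::map(seq_len(nrow(df)), function(i) {
    list(
      name = df$name[i], group = df$group[i], section = df$section[i],
      cranial = c(df$cranial_x[i], df$cranial_y[i], df$cranial_z[i]),
      caudal = c(df$caudal_x[i], df$caudal_y[i], df$caudal_z[i])
    )
  })
  jsonlite::write_json(segs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read planning criteria from YAML
#'
#' Missing keys take the [criteria()] defaults; unknown keys are rejected.
#' A threshold may be given as `.na` (YAML NA) to disable that constraint.
#'
#' @param path YAML file path.
#' @return A `bpo_criteria` object.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) abort(sprintf("criteria file not found: %s", path))
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  allowed <- c(
    "sva_min_mm", "sva_max_mm", "tpa_max_deg", "pt_max_deg",
    "pi_minus_ll_max_deg", "oa_cap_deg"
  )
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown key(s) in criteria file: %s", paste(unknown, collapse = ", ")))
  }
  do.call(criteria, obj)
}

# fixed-format numeric rendering shared by the CSV writers (6 decimals,
# diff-stable)
.fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.6f", x) else x
}

.write_fixed_csv <- function(df, path, columns) {
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    abort(sprintf("missing column(s) for writer: %s", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df[, columns])
  out[] <- lapply(out, .fmt_num)
  readr::write_csv(out, path)
  invisible(path)
}

#' CSV writers with fixed column order
#'
#' `write_prediction()` writes a parameter-vs-opening-angle table with
#' header `oa_deg, pi_deg, pt_deg, ss_deg, sva_mm, tpa_deg, t1spi_deg,
#' pi_minus_ll_deg`; `write_linear_models()` writes `parameter, slope,
#' intercept, r_squared, oa_min_deg, oa_max_deg`; `write_muscle_curve()`
#' writes `segment, oa_deg, length_mm, stretch_ratio, classification,
#' exceeds_critical`. Numbers are rendered with 6 decimals so outputs are
#' diff-stable.
#'
#' @param table,models,results The corresponding result tibbles.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(table, path) {
  .write_fixed_csv(as_tibble(table), path, c(
    "oa_deg", "pi_deg", "pt_deg", "ss_deg", "sva_mm", "tpa_deg",
    "t1spi_deg", "pi_minus_ll_deg"
  ))
}

#' @rdname write_prediction
#' @export
write_linear_models <- function(models, path) {
  .write_fixed_csv(as_tibble(models), path, c(
    "parameter", "slope", "intercept", "r_squared", "oa_min_deg", "oa_max_deg"
  ))
}

#' @rdname write_prediction
#' @export
write_muscle_curve <- function(results, path) {
  .write_fixed_csv(as_tibble(results), path, c(
    "segment", "oa_deg", "length_mm", "stretch_ratio", "classification",
    "exceeds_critical"
  ))
}

#' Read back a prediction CSV
#'
#' @param path CSV path written by [write_prediction()].
#' @param ll_deg Optional lumbar lordosis to restore the `ll_deg` column.
#' @return A `bpo_prediction` tibble.
#' @export
read_prediction <- function(path, ll_deg = NULL) {
  if (!file.exists(path)) abort(sprintf("prediction file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(ll_deg)) df$ll_deg <- ll_deg
  class(df) <- c("bpo_prediction", class(df))
  df
}
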