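#' Sagittal-balance criteria for opening-angle planning
#'
#' The thresholds that confine the allowable opening angle: SVA within
#' `[sva_min_mm, sva_max_mm]`, TPA below `tpa_max_deg`, PT below
#' `pt_max_deg`, and PI-LL below `pi_minus_ll_max_deg`, searched over
#' `[0, oa_cap_deg]`. Defaults are the standard radiographic goals
#' (|SVA| < 50 mm, TPA < 14 deg, PT < 20 deg, PI-LL < 9 deg). Set a
#' threshold to `NA` to disable that constraint. Inequalities are evaluated
#' as closed at the bounds; the distinction from strict inequalities is below
#' solver tolerance.
#'
#' @param sva_min_mm,sva_max_mm SVA window in mm.
#' @param tpa_max_deg,pt_max_deg,pi_minus_ll_max_deg Upper thresholds in
#'   degrees (or `NA` to disable).
#' @param oa_cap_deg Upper end of the searched opening-angle range (degrees).
#' @return A list of class `bpo_criteria`.
#' @export
criteria <- function(sva_min_mm = -50, sva_max_mm = 50, tpa_max_deg = 14,
                     pt_max_deg = 20, pi_minus_ll_max_deg = 9,
                     oa_cap_deg = 40) {
  num1 <- function(x, nm) {
    if (length(x) != 1 || (!is.na(x) && (!is.numeric(x) || !is.finite(x)))) {
      abort(sprintf("criteria field '%s' must be a single finite number or NA", nm))
    }
    as.numeric(x)
  }
  out <- list(
    sva_min_mm = num1(sva_min_mm, "sva_min_mm"),
    sva_max_mm = num1(sva_max_mm, "sva_max_mm"),
    tpa_max_deg = num1(tpa_max_deg, "tpa_max_deg"),
    pt_max_deg = num1(pt_max_deg, "pt_max_deg"),
    pi_minus_ll_max_deg = num1(pi_minus_ll_max_deg, "pi_minus_ll_max_deg"),
    oa_cap_deg = num1(oa_cap_deg, "oa_cap_deg")
  )
  if (is.na(out$oa_cap_deg) || out$oa_cap_deg <= 0) {
    abort("oa_cap_deg must be a positive number")
  }
  if (!is.na(out$sva_min_mm) && !is.na(out$sva_max_mm) &&
    out$sva_min_mm >= out$sva_max_mm) {
    abort("sva_min_mm must be less than sva_max_mm")
  }
  class(out) <- "bpo_criteria"
  out
}

#' Find where a monotone parameter curve meets a threshold
#'
#' Bisection solver shared by all planner engines. The predictor must be
#' monotone over `[0, oa_cap_deg]` (checked on a 0.5-degree grid). For
#' `direction = "falls_below"` the predictor must be non-increasing and the
#' returned value is the first opening angle at which it is `<= threshold`;
#' for `"rises_above"`, non-decreasing and first `>= threshold`. Returns 0 if
#' the threshold is already met at 0, and `NA` if it is never met within the
#' cap.
#'
#' @param predictor Function mapping a numeric vector of opening angles
#'   (degrees) to parameter values.
#' @param threshold Scalar threshold in the parameter's units.
#' @param direction `"falls_below"` or `"rises_above"`.
#' @param oa_cap_deg Search cap (degrees).
#' @param tol_deg Bisection tolerance on the opening angle (degrees).
#' @param name Parameter name used in error messages.
#' @return Crossing opening angle in degrees, or `NA_real_`.
#' @export
threshold_crossing <- function(predictor, threshold,
                               direction = c("falls_below", "rises_above"),
                               oa_cap_deg = 40, tol_deg = 1e-6,
                               name = "parameter") {
  direction <- match.arg(direction)
  stopifnot(is.function(predictor), is.numeric(threshold), length(threshold) == 1)
  grid <- seq(0, oa_cap_deg, by = 0.5)
  if (grid[length(grid)] < oa_cap_deg) grid <- c(grid, oa_cap_deg)
  vals <- predictor(grid)
  if (!all(is.finite(vals))) abort(sprintf("predictor for %s returned non-finite values", name))
  d <- diff(vals)
  mono_tol <- 1e-9
  if (direction == "falls_below") {
    if (any(d > mono_tol)) {
      abort(sprintf("predictor for %s is not non-increasing on [0, %.1f]", name, oa_cap_deg))
    }
    met <- function(x) predictor(x) <= threshold
  } else {
    if (any(d < -mono_tol)) {
      abort(sprintf("predictor for %s is not non-decreasing on [0, %.1f]", name, oa_cap_deg))
    }
    met <- function(x) predictor(x) >= threshold
  }
  if (met(0)) {
    return(0)
  }
  if (!met(oa_cap_deg)) {
    return(NA_real_)
  }
  lo <- 0
  hi <- oa_cap_deg
  while (hi - lo > tol_deg) {
    mid <- (lo + hi) / 2
    if (met(mid)) hi <- mid else lo <- mid
  }
  hi
}

# constraint table used by the planner; `sense` is the inequality applied to
# the parameter column
.bpo_constraints <- function(crit) {
  tibble(
    constraint = c("sva_max", "sva_min", "tpa_max", "pt_max", "pi_minus_ll_max"),
    column = c("sva_mm", "sva_mm", "tpa_deg", "pt_deg", "pi_minus_ll_deg"),
    threshold = c(
      crit$sva_max_mm, crit$sva_min_mm, crit$tpa_max_deg,
      crit$pt_max_deg, crit$pi_minus_ll_max_deg
    ),
    sense = c("le", "ge", "le", "le", "le")
  )
}

#' Prediction engines for the planner
#'
#' Wrap a landmark set (geometric oracle), a derived-geometry object
#' (closed form) or a fitted linear-model table into a common engine
#' interface: a function mapping a vector of opening angles to a parameter
#' tibble.
#'
#' @inheritParams measure_parameters
#' @param geom A `bpo_geometry` object.
#' @param models A `bpo_linear_fit` tibble.
#' @name planner_engines
NULL

#' @rdname planner_engines
#' @export
oracle_engine <- function(landmarks, ll_deg, plumbline = c("c7", "t1")) {
  plumbline <- match.arg(plumbline)
  landmarks <- validate_landmarks(landmarks)
  force(ll_deg)
  function(oa_deg) {
    oracle_predict(landmarks, ll_deg, oa_deg, plumbline = plumbline)
  }
}

#' @rdname planner_engines
#' @export
closed_form_engine <- function(geom, ll_deg) {
  stopifnot(inherits(geom, "bpo_geometry"))
  force(ll_deg)
  function(oa_deg) closed_form_predict(geom, ll_deg, oa_deg)
}

#' @rdname planner_engines
#' @param ll_deg Lumbar lordosis (degrees); for the linear engine it is only
#'   needed when a PI model is present, to derive PI-LL.
#' @export
linear_engine <- function(models, ll_deg = NULL) {
  df <- as_tibble(models)
  function(oa_deg) {
    out <- evaluate_linear(df, oa_deg)
    if (!is.null(ll_deg) && "pi_deg" %in% names(out)) {
      out$pi_minus_ll_deg <- out$pi_deg - ll_deg
    }
    out
  }
}

#' Feasible opening-angle range under sagittal-balance criteria
#'
#' Intersects the per-constraint feasible subintervals of `[0, oa_cap]`.
#' Decreasing parameters bounded above (SVA max, TPA, PI-LL) contribute lower
#' bounds (the smallest opening angle that corrects them); the increasing PT
#' and the continued fall of SVA through its lower limit contribute upper
#' bounds. Each crossing is located by [threshold_crossing()]; infeasibility
#' is a result, not an error. When a feasible interval is found it is
#' verified on a 0.1-degree grid.
#'
#' @param engine An engine function from [oracle_engine()],
#'   [closed_form_engine()] or [linear_engine()].
#' @param crit A [criteria()] object.
#' @return A list of class `bpo_plan`: `feasible`, `oa_min_deg`,
#'   `oa_max_deg`, `crossings` (tibble), `binding_lower`, `binding_upper`.
#' @export
feasible_oa_range <- function(engine, crit = criteria()) {
  stopifnot(is.function(engine), inherits(crit, "bpo_criteria"))
  cap <- crit$oa_cap_deg
  cons <- .bpo_constraints(crit)
  cons <- cons[!is.na(cons$threshold), , drop = FALSE]
  probe <- engine(c(0, cap / 2, cap))
  missing <- setdiff(unique(cons$column), names(probe))
  if (length(missing)) {
    abort(sprintf(
      "engine does not provide column(s) %s needed by active criteria (disable with NA)",
      paste(missing, collapse = ", ")
    ))
  }

  lower <- 0
  upper <- cap
  binding_lower <- "oa_zero"
  binding_upper <- "oa_cap"
  feasible <- TRUE
  crossings <- numeric(0)

  for (i in seq_len(nrow(cons))) {
    col <- cons$column[i]
    th <- cons$threshold[i]
    sense <- cons$sense[i]
    nm <- cons$constraint[i]
    pred <- function(oa) engine(oa)[[col]]
    increasing <- pred(cap) >= pred(0)

    if (sense == "le" && !increasing) {
      cr <- threshold_crossing(pred, th, "falls_below", cap, name = nm)
      crossings[nm] <- cr
      if (is.na(cr)) {
        feasible <- FALSE
        lower <- cap
        binding_lower <- nm
      } else if (cr > lower) {
        lower <- cr
        binding_lower <- nm
      }
    } else if (sense == "le" && increasing) {
      if (pred(0) > th) {
        feasible <- FALSE
        crossings[nm] <- NA_real_
        upper <- -Inf
        binding_upper <- nm
      } else {
        cr <- threshold_crossing(pred, th, "rises_above", cap, name = nm)
        crossings[nm] <- cr
        if (!is.na(cr) && cr < upper) {
          upper <- cr
          binding_upper <- nm
        }
      }
    } else if (sense == "ge" && !increasing) {
      if (pred(0) < th) {
        feasible <- FALSE
        crossings[nm] <- NA_real_
        upper <- -Inf
        binding_upper <- nm
      } else {
        cr <- threshold_crossing(pred, th, "falls_below", cap, name = nm)
        crossings[nm] <- cr
        if (!is.na(cr) && cr < upper) {
          upper <- cr
          binding_upper <- nm
        }
      }
    } else { # sense == "ge" && increasing
      cr <- threshold_crossing(pred, th, "rises_above", cap, name = nm)
      crossings[nm] <- cr
      if (is.na(cr)) {
        feasible <- FALSE
        lower <- cap
        binding_lower <- nm
      } else if (cr > lower) {
        lower <- cr
        binding_lower <- nm
      }
    }
  }

  feasible <- feasible && lower <= upper
  if (feasible) {
    grid <- seq(lower, upper, by = 0.1)
    if (grid[length(grid)] < upper) grid <- c(grid, upper)
    vals <- engine(grid)
    slack <- 1e-3
    for (i in seq_len(nrow(cons))) {
      v <- vals[[cons$column[i]]]
      ok <- if (cons$sense[i] == "le") {
        all(v <= cons$threshold[i] + slack)
      } else {
        all(v >= cons$threshold[i] - slack)
      }
      if (!ok) {
        abort(sprintf(
          "internal planner error: constraint %s violated inside the returned interval",
          cons$constraint[i]
        ))
      }
    }
  }

  out <- list(
    feasible = feasible,
    oa_min_deg = if (feasible) lower else NA_real_,
    oa_max_deg = if (feasible) upper else NA_real_,
    crossings = tibble(
      constraint = names(crossings),
      crossing_oa_deg = unname(crossings)
    ),
    binding_lower = binding_lower,
    binding_upper = binding_upper,
    criteria = crit
  )
  class(out) <- "bpo_plan"
  out
}

#' @export
print.bpo_plan <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "Feasible opening-angle range: %.2f to %.2f deg (lower bound: %s, upper bound: %s)\n",
      x$oa_min_deg, x$oa_max_deg, x$binding_lower, x$binding_upper
    ))
  } else {
    cat(sprintf(
      "No feasible opening angle (most restrictive: %s vs %s)\n",
      x$binding_lower, x$binding_upper
    ))
  }
  invisible(x)
}

#' Plain-text planning report
#'
#' Deterministic summary of a plan: baseline parameters (first row of the
#' prediction table), active criteria, per-constraint crossing angles, and
#' the feasible interval (or the most restrictive pair of constraints when
#' infeasible).
#'
#' @param plan A `bpo_plan` from [feasible_oa_range()].
#' @param table A `bpo_prediction` tibble whose first row is the baseline.
#' @param crit The [criteria()] used.
#' @return Character vector of report lines, class `bpo_report`.
#' @export
build_report <- function(plan, table, crit = plan$criteria) {
  stopifnot(inherits(plan, "bpo_plan"))
  df <- as_tibble(table)
  if (nrow(df) == 0) abort("prediction table is empty")
  base <- df[1, ]
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    "bilateral pelvic osteotomy planning report",
    "==========================================",
    sprintf("baseline (OA = %s deg):", fmt(base$oa_deg)),
    sprintf(
      "  SVA %s mm | PI %s | PT %s | SS %s | TPA %s | PI-LL %s deg",
      fmt(base$sva_mm), fmt(base$pi_deg), fmt(base$pt_deg),
      fmt(base$ss_deg), fmt(base$tpa_deg), fmt(base$pi_minus_ll_deg)
    ),
    "criteria:",
    sprintf("  %.0f mm <= SVA <= %.0f mm", crit$sva_min_mm, crit$sva_max_mm),
    sprintf("  TPA <= %s deg", format(crit$tpa_max_deg)),
    sprintf("  PT <= %s deg", format(crit$pt_max_deg)),
    sprintf("  PI-LL <= %s deg", format(crit$pi_minus_ll_max_deg)),
    sprintf("  0 <= OA <= %.0f deg", crit$oa_cap_deg),
    "constraint crossings (deg):"
  )
  cr <- plan$crossings
  for (i in seq_len(nrow(cr))) {
    lines <- c(lines, sprintf(
      "  %-16s %s", cr$constraint[i],
      if (is.na(cr$crossing_oa_deg[i])) "not reached" else fmt(cr$crossing_oa_deg[i])
    ))
  }
  lines <- c(lines, if (plan$feasible) {
    sprintf(
      "feasible opening-angle range: %s to %s deg (binding: %s / %s)",
      fmt(plan$oa_min_deg), fmt(plan$oa_max_deg),
      plan$binding_lower, plan$binding_upper
    )
  } else {
    sprintf(
      "INFEASIBLE: no opening angle satisfies all criteria (most restrictive pair: %s vs %s)",
      plan$binding_lower, plan$binding_upper
    )
  })
  class(lines) <- c("bpo_report", class(lines))
  lines
}

#' @export
print.bpo_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
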