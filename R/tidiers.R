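#' Broom-style methods for fitted objects
#'
#' `tidy()` on a `bpo_linear_fit` returns one row per modelled parameter
#' (term, slope, intercept, r.squared); `glance()` summarises the fit set.
#' `tidy()` on a `bpo_plan` returns the per-constraint crossing angles;
#' `glance()` returns the one-row plan summary. `tidy()` on a
#' `bpo_geometry` returns the derived scalars in long form.
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @name bposim-tidiers
NULL

#' @rdname bposim-tidiers
#' @method tidy bpo_linear_fit
#' @export
tidy.bpo_linear_fit <- function(x, ...) {
  df <- as_tibble(x)
  tibble(
    term = df$parameter,
    slope = df$slope,
    intercept = df$intercept,
    r.squared = df$r_squared
  )
}

#' @rdname bposim-tidiers
#' @method glance bpo_linear_fit
#' @export
glance.bpo_linear_fit <- function(x, ...) {
  df <- as_tibble(x)
  tibble(
    n_parameters = nrow(df),
    min_r_squared = if (all(is.na(df$r_squared))) NA_real_ else min(df$r_squared, na.rm = TRUE),
    oa_min_deg = min(df$oa_min_deg),
    oa_max_deg = max(df$oa_max_deg)
  )
}

#' @rdname bposim-tidiers
#' @method tidy bpo_plan
#' @export
tidy.bpo_plan <- function(x, ...) {
  x$crossings
}

#' @rdname bposim-tidiers
#' @method glance bpo_plan
#' @export
glance.bpo_plan <- function(x, ...) {
  tibble(
    feasible = x$feasible,
    oa_min_deg = x$oa_min_deg,
    oa_max_deg = x$oa_max_deg,
    binding_lower = x$binding_lower,
    binding_upper = x$binding_upper
  )
}

#' @rdname bposim-tidiers
#' @method tidy bpo_geometry
#' @export
tidy.bpo_geometry <- function(x, ...) {
  scalars <- c(
    "a", "b", "L", "L_prime", "L_c7", "k", "k_prime", "k_dprime",
    "alpha1", "alpha2", "alpha3", "alpha4", "alpha5", "alpha6"
  )
  tibble(
    term = scalars,
    value = vapply(scalars, function(nm) x[[nm]], numeric(1)),
    unit = c(rep("mm", 5), rep("ratio", 3), rep("rad", 6))
  )
}

#' @rdname bposim-tidiers
#' @method tidy bpo_muscle_safety
#' @export
tidy.bpo_muscle_safety <- function(x, ...) {
  x$per_segment
}

#' @rdname bposim-tidiers
#' @method glance bpo_muscle_safety
#' @export
glance.bpo_muscle_safety <- function(x, ...) {
  tibble(
    n_segments = nrow(x$per_segment),
    n_unsafe = x$n_unsafe,
    max_stretch_ratio = x$max_stretch_ratio,
    max_stretch_segment = x$max_stretch_segment
  )
}
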