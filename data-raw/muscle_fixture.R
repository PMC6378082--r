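# Construction of the packaged synthetic muscle attachment fixture
# (inst/extdata/muscle_attachments_synthetic.json).
#
# The fixture stands in for subject-specific musculoskeletal-model geometry,
# which is not publicly available. Each of the 8 segments (GMed x3, GMax x3,
# TFL, piriformis) is defined in fulcrum-centred polar terms (l1, l2, signed
# beta, delta_z) and the signed included angle beta is solved so that at a
# 20-degree opening the stretch ratio hits a prescribed target:
# anterior GMed +8%, TFL +4%, middle GMed isometric (beta = -10 deg, exact
# by symmetry), posterior GMed -6%, anterior GMax -5%, middle GMax -6%,
# posterior GMax -8%, piriformis -5%. Coordinates are then laid out in the
# synthetic patient frame (femoral head at origin, fulcrum 55 mm from it at
# 35 deg posterior of vertical).
#
# Run from the package root: Rscript data-raw/muscle_fixture.R

deg2rad <- function(x) x * pi / 180

fulcrum <- 55 * c(-sin(deg2rad(35)), cos(deg2rad(35)))

stretch20 <- function(beta_deg, l1, l2, dz, oa_deg = 20) {
  d <- function(ang_deg) {
    sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(deg2rad(ang_deg)) + dz^2)
  }
  d(beta_deg + oa_deg) / d(beta_deg)
}

solve_beta <- function(target, l1, l2, dz, bracket) {
  uniroot(
    function(b) stretch20(b, l1, l2, dz) - target,
    interval = bracket, tol = 1e-12
  )$root
}

spec <- list(
  #                name           group   section     l1   l2  dz  target  bracket        z1
  list("gmed_anterior",  "GMed", "anterior",  85,  70, 10, 1.08, c(90, 174),     55),
  list("gmed_middle",    "GMed", "middle",    80,  30, 30, NA,   NULL,           55),
  list("gmed_posterior", "GMed", "posterior", 75,  65, 14, 0.94, c(-170, -90), 55),
  list("gmax_anterior",  "GMax", "anterior",  70,  95, 20, 0.95, c(-170, -90), 45),
  list("gmax_middle",    "GMax", "middle",    78, 105, 25, 0.94, c(-170, -90), 40),
  list("gmax_posterior", "GMax", "posterior", 88, 115, 30, 0.92, c(-170, -90), 35),
  list("tfl",            "TFL",  "whole",     95,  60,  8, 1.04, c(90, 174),     60),
  list("piriformis",     "P",    "whole",     45,  85, 35, 0.95, c(-170, -90), 20)
)

theta_caudal_deg <- -70 # direction of the caudal attachments from the fulcrum

segments <- lapply(spec, function(s) {
  names(s) <- c("name", "group", "section", "l1", "l2", "dz", "target", "bracket", "z1")
  beta <- if (is.na(s$target)) -10 else solve_beta(s$target, s$l1, s$l2, s$dz, s$bracket)
  th2 <- deg2rad(theta_caudal_deg)
  th1 <- deg2rad(theta_caudal_deg + beta)
  cranial <- c(fulcrum + s$l1 * c(cos(th1), sin(th1)), s$z1)
  caudal <- c(fulcrum + s$l2 * c(cos(th2), sin(th2)), s$z1 + s$dz)
  list(
    name = s$name, group = s$group, section = s$section,
    cranial = cranial, caudal = caudal,
    beta_deg = beta, lambda20 = stretch20(beta, s$l1, s$l2, s$dz)
  )
})

# sanity: pattern at 20 deg and critical stretch within 0..40 deg
check <- vapply(segments, function(s) s$lambda20, numeric(1))
names(check) <- vapply(segments, `[[`, character(1), "name")
print(round(check, 6))
stopifnot(
  check[["gmed_anterior"]] > 1, check[["tfl"]] > 1,
  abs(check[["gmed_middle"]] - 1) < 1e-12,
  all(check[c(
    "gmed_posterior", "gmax_anterior", "gmax_middle",
    "gmax_posterior", "piriformis"
  )] < 1)
)
for (s in segments) {
  lams <- vapply(seq(0, 40, by = 0.5), function(oa) {
    sp <- spec[[which(vapply(spec, `[[`, character(1), 1) == s$name)]]
    names(sp) <- c("name", "group", "section", "l1", "l2", "dz", "target", "bracket", "z1")
    stretch20(s$beta_deg, sp$l1, sp$l2, sp$dz, oa_deg = oa)
  }, numeric(1))
  stopifnot(max(lams) < 1.254)
}

out <- lapply(segments, function(s) s[c("name", "group", "section", "cranial", "caudal")])
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(out, "inst/extdata/muscle_attachments_synthetic.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("wrote inst/extdata/muscle_attachments_synthetic.json\n")
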