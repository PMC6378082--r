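test_that("baseline geometry solves elementary triangles", {
  # 3-4-5 right triangle in plane
  att <- one_segment(cranial = c(0, 3, 0), caudal = c(4, 0, 0))
  g <- baseline_geometry(att, fulcrum = c(0, 0))
  expect_equal(g$l1_mm, 3)
  expect_equal(g$l2_mm, 4)
  expect_equal(abs(g$beta_deg), 90)
  expect_equal(g$l0_mm, 5)

  # out-of-plane Pythagoras: in-plane chord 3, delta z 4
  att2 <- one_segment(cranial = c(0, 3, 0), caudal = c(0, 6, 4))
  g2 <- baseline_geometry(att2, fulcrum = c(0, 0))
  expect_equal(g2$beta_deg, 0)
  expect_equal(g2$delta_z_mm, 4)
  expect_equal(g2$l0_mm, 5)

  # closed form equals the raw 3-D distance
  att3 <- one_segment(cranial = c(-37, 81, 12), caudal = c(22, -45, 61))
  g3 <- baseline_geometry(att3, fulcrum = c(-31, 45))
  expect_lt(abs(g3$l0_mm - sqrt(sum((c(-37, 81, 12) - c(22, -45, 61))^2))), 1e-9)

  expect_error(
    baseline_geometry(one_segment(cranial = c(0, 0, 10)), fulcrum = c(0, 0)),
    "fulcrum"
  )
})

test_that("stretched length follows the law of cosines and its limits", {
  att <- one_segment(cranial = c(0, 3, 0), caudal = c(4, 0, 0))
  g <- baseline_geometry(att, fulcrum = c(0, 0))
  expect_equal(stretched_length(g, 0), g$l0_mm)
  # beta = +90 (CCW from caudal to cranial); opening 90 more makes it collinear
  expect_equal(stretched_length(g, 90), 7, tolerance = 1e-12)
})

test_that("stretched length matches the brute-force 3-D rotate-and-measure oracle", {
  segs <- random_segments(1000, seed = 7)
  fulcrum <- c(0, 0)
  keep <- with(segs, sqrt(cranial_x^2 + cranial_y^2) > 5 & sqrt(caudal_x^2 + caudal_y^2) > 5)
  segs <- segs[keep, ]
  g <- baseline_geometry(segs, fulcrum)
  oas <- withr::with_seed(8, runif(nrow(segs), 0, 40))
  worst <- 0
  for (i in seq_len(nrow(segs))) {
    d_model <- stretched_length(g[i, ], oas[i])
    th <- oas[i] * pi / 180
    cr <- c(
      cos(th) * segs$cranial_x[i] - sin(th) * segs$cranial_y[i],
      sin(th) * segs$cranial_x[i] + cos(th) * segs$cranial_y[i],
      segs$cranial_z[i]
    )
    d_oracle <- sqrt(sum((cr - c(segs$caudal_x[i], segs$caudal_y[i], segs$caudal_z[i]))^2))
    worst <- max(worst, abs(d_model - d_oracle))
  }
  expect_lt(worst, 1e-9)
})

test_that("sign of beta decides lengthening vs shortening; mirror symmetry holds", {
  segs <- random_segments(200, seed = 9)
  fulcrum <- c(0, 0)
  keep <- with(segs, sqrt(cranial_x^2 + cranial_y^2) > 5 & sqrt(caudal_x^2 + caudal_y^2) > 5)
  segs <- segs[keep, ]
  g <- baseline_geometry(segs, fulcrum)
  ok_beta <- abs(sin(g$beta_deg * pi / 180)) > 0.05
  g <- g[ok_beta, ]
  d_eps <- stretched_length(g, 0.01)
  lengthens <- d_eps > g$l0_mm
  expect_identical(lengthens, sin(g$beta_deg * pi / 180) > 0)

  # mirror: negating beta and the opening angle leaves the length unchanged
  g_m <- g
  g_m$beta_deg <- -g$beta_deg
  for (oa in c(5, 17, 33)) {
    expect_equal(stretched_length(g, oa), stretched_length(g_m, -oa), tolerance = 1e-12)
  }
})

test_that("every segment is isometric at zero opening", {
  curve0 <- stretch_ratio_curve(default_muscle_fixture(), default_fulcrum(), 0)
  expect_true(all(abs(curve0$stretch_ratio - 1) < 1e-12))
  expect_true(all(curve0$classification == "isometric"))
})

test_that("the packaged fixture reproduces the reference pattern at 20 degrees", {
  fix <- default_muscle_fixture()
  expect_equal(nrow(fix), 8)
  expect_equal(sort(unique(fix$group)), c("GMax", "GMed", "P", "TFL"))
  g <- baseline_geometry(fix, default_fulcrum())
  expect_true(all(g$l0_mm > 0))

  curve <- stretch_ratio_curve(fix, default_fulcrum(), 20)
  cls <- setNames(curve$classification, curve$segment)
  expect_equal(unname(cls[c("gmed_anterior", "tfl")]), rep("lengthening", 2))
  expect_equal(unname(cls["gmed_middle"]), "isometric")
  expect_equal(
    unname(cls[c(
      "gmed_posterior", "gmax_anterior", "gmax_middle",
      "gmax_posterior", "piriformis"
    )]),
    rep("shortening", 5)
  )
  expect_equal(sum(cls == "lengthening"), 2)
  expect_equal(sum(cls == "shortening"), 5)
  expect_equal(sum(cls == "isometric"), 1)

  # magnitudes: +8% / +4% lengthening, -6 -5 -6 -8 -5 % shortening
  lam <- setNames(curve$stretch_ratio, curve$segment)
  target <- c(
    gmed_anterior = 1.08, tfl = 1.04, gmed_middle = 1.00,
    gmed_posterior = 0.94, gmax_anterior = 0.95, gmax_middle = 0.94,
    gmax_posterior = 0.92, piriformis = 0.95
  )
  expect_lt(max(abs(lam[names(target)] - target)), 0.03)
})

test_that("no fixture segment approaches the critical stretch in the planning range", {
  curve <- stretch_ratio_curve(
    default_muscle_fixture(), default_fulcrum(), seq(0, 40, by = 0.5)
  )
  expect_false(any(curve$exceeds_critical))
  safety <- classify_safety(curve)
  expect_equal(safety$n_unsafe, 0)
  expect_lt(safety$max_stretch_ratio, 1.254)
  expect_equal(safety$max_stretch_segment, "gmed_anterior")

  # a clearly over-stretched segment is flagged
  att <- one_segment(cranial = c(0, 30, 0), caudal = c(30, 0, 0))
  hot <- stretch_ratio_curve(att, c(0, 0), c(0, 80), critical_sr = 0.254)
  expect_true(any(hot$exceeds_critical))
  expect_equal(classify_safety(hot)$n_unsafe, 1)
})

test_that("attachment validation enforces vocabulary and structure", {
  expect_error(muscle_attachments(one_segment(group = "Quad")), "unknown muscle group")
  expect_error(muscle_attachments(one_segment(group = "GMed", section = "whole")), "section")
  expect_error(
    muscle_attachments(dplyr::bind_rows(one_segment(), one_segment())),
    "duplicated"
  )
  expect_error(
    muscle_attachments(one_segment(cranial = c(1, 2, 3), caudal = c(1, 2, 3))),
    "coincide"
  )
  expect_error(muscle_attachments(one_segment()[0, ]), "empty")
})
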