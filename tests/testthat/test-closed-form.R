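test_that("derived geometry reports the expected distances and ratios", {
  # fulcrum at origin, femoral head 50 mm below, S1 midpoint 80 mm above
  lm <- landmark_set(
    femoral_head = c(0, -50), fulcrum = c(0, 0),
    s1_anterior = c(17.5, 80), s1_posterior = c(-17.5, 80),
    t1_centroid = c(10, 300), c7_centroid = c(15, 320)
  )
  g <- derive_geometry(lm)
  expect_equal(g$a, 50)
  expect_equal(g$b, 80)
  expect_equal(g$k, 1.6)
  expect_equal(g$k_prime, 0.625)
  expect_lt(abs(g$k * g$k_prime - 1), 1e-12)
  expect_lt(abs(g$k_dprime * g$L - g$a), 1e-12)
  expect_equal(g$L_prime, sqrt(17.5^2 + 80^2))
})

test_that("alpha angles reconstruct the landmark ray directions", {
  lm <- std_patient()
  g <- derive_geometry(lm)
  fc <- c(lm$x[lm$landmark == "fulcrum"], lm$y[lm$landmark == "fulcrum"])
  fh <- c(lm$x[lm$landmark == "femoral_head"], lm$y[lm$landmark == "femoral_head"])
  t1 <- c(lm$x[lm$landmark == "t1_centroid"], lm$y[lm$landmark == "t1_centroid"])
  post <- c(lm$x[lm$landmark == "s1_posterior"], lm$y[lm$landmark == "s1_posterior"])
  ant <- c(lm$x[lm$landmark == "s1_anterior"], lm$y[lm$landmark == "s1_anterior"])
  mid <- (ant + post) / 2
  dir_fh <- atan2(fh[2] - fc[2], fh[1] - fc[1])
  wrap <- function(x) atan2(sin(x), cos(x))
  # rotating the fulcrum->femoral-head ray by alpha2 / alpha6 reproduces the
  # fulcrum->S1-mid and fulcrum->T1 rays
  expect_lt(abs(wrap(dir_fh + g$alpha2 - atan2(mid[2] - fc[2], mid[1] - fc[1]))), 1e-9)
  expect_lt(abs(wrap(dir_fh + g$alpha6 - atan2(t1[2] - fc[2], t1[1] - fc[1]))), 1e-9)
  # alpha4 is the anterior inclination of the fulcrum->posterior-corner ray
  # shifted by a quarter turn
  expect_lt(abs(wrap(g$alpha4 - pi / 2 - atan2(post[1] - fc[1], post[2] - fc[2]))), 1e-9)
})

test_that("closed form equals the geometric oracle across seeded patients", {
  specs <- random_specs(20, seed = 42)
  grid <- 0:40
  worst_ang <- 0
  worst_sva <- 0
  for (i in seq_len(nrow(specs))) {
    lm <- make_patient(patient_spec(
      pi_deg = specs$pi_deg[i], pt_deg = specs$pt_deg[i],
      sva_mm = specs$sva_mm[i], ll_deg = specs$ll_deg[i]
    ))
    orc <- oracle_predict(lm, specs$ll_deg[i], grid)
    cf <- closed_form_predict(derive_geometry(lm), specs$ll_deg[i], grid)
    for (col in c("pi_deg", "pt_deg", "tpa_deg", "t1spi_deg", "ss_deg")) {
      worst_ang <- max(worst_ang, max(abs(orc[[col]] - cf[[col]])))
    }
    worst_sva <- max(worst_sva, max(abs(orc$sva_mm - cf$sva_mm)))
  }
  expect_lt(worst_ang, 1e-6)
  expect_lt(worst_sva, 1e-3)
})

test_that("closed form at zero opening equals the baseline measurement", {
  lm <- std_patient()
  base <- measure_parameters(lm, 30)
  cf <- closed_form_predict(derive_geometry(lm), 30, 0)
  for (col in c("pi_deg", "pt_deg", "ss_deg", "tpa_deg", "t1spi_deg")) {
    expect_lt(abs(cf[[col]] - base[[col]]), 1e-6)
  }
  expect_lt(abs(cf$sva_mm - base$sva_mm), 1e-6)
})

test_that("the TPA grouping cancels as the printed expressions suggest", {
  # TPA = T1SPA - alpha5 - beta + pi/2, with beta the femoral-head angle of
  # the fulcrum/femoral-head/S1-mid triangle measured on the rotated image
  lm <- std_patient()
  g <- derive_geometry(lm)
  for (oa in c(0, 10, 25, 40)) {
    rot <- apply_osteotomy(lm, oa)
    fh <- c(rot$x[rot$landmark == "femoral_head"], rot$y[rot$landmark == "femoral_head"])
    fc <- c(rot$x[rot$landmark == "fulcrum"], rot$y[rot$landmark == "fulcrum"])
    ant <- c(rot$x[rot$landmark == "s1_anterior"], rot$y[rot$landmark == "s1_anterior"])
    post <- c(rot$x[rot$landmark == "s1_posterior"], rot$y[rot$landmark == "s1_posterior"])
    mid <- (ant + post) / 2
    beta <- atan2(fc[2] - fh[2], fc[1] - fh[1]) - atan2(mid[2] - fh[2], mid[1] - fh[1])
    beta <- atan2(sin(beta), cos(beta))
    cf <- closed_form_predict(g, 30, oa)
    lhs <- cf$tpa_deg * pi / 180
    rhs <- cf$t1spi_deg * pi / 180 - g$alpha5 - beta + pi / 2
    expect_lt(abs(atan2(sin(lhs - rhs), cos(lhs - rhs))), 1e-9)
  }
})

test_that("linear fits recover exact lines and near-linearity of the model", {
  # exact line
  tab <- tibble::tibble(oa_deg = 0:10, y = 2 * (0:10) + 3)
  fit <- fit_linear(tab, parameters = "y")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r_squared, 1)

  # too few / constant grids are rejected
  expect_error(fit_linear(tab[1:2, ], parameters = "y"), "3 distinct")
  expect_error(
    fit_linear(tibble::tibble(oa_deg = rep(1, 5), y = 1:5), parameters = "y"),
    "3 distinct"
  )

  # geometric model is near-linear over the practical range, and the fitted
  # PT and PI slopes differ by exactly one degree per degree
  lm <- std_patient()
  tab <- oracle_predict(lm, 30, 0:40)
  fit <- fit_linear(tab)
  expect_true(all(fit$r_squared > 0.99))
  s <- setNames(fit$slope, fit$parameter)
  expect_lt(abs((s[["pt_deg"]] - s[["pi_deg"]]) - 1), 0.02)
})

test_that("evaluating linear models is plain slope-intercept arithmetic", {
  m <- example_linear_models()
  expect_equal(evaluate_linear(m, 21, "sva_mm"), 49.5, tolerance = 1e-12)
  expect_equal(evaluate_linear(m, 0, "sva_mm"), 223.8)
  wide <- evaluate_linear(m, c(0, 10))
  expect_equal(wide$pt_deg, c(10.4, 13.4))
  expect_error(evaluate_linear(m, 5, "nope"), "no linear model")
})
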