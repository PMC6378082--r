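# Shared fixtures, built in code.

# the standard deformity patient used across tests
std_patient <- function() {
  make_patient(patient_spec(pi_deg = 55, pt_deg = 25, sva_mm = 224, ll_deg = 30))
}

# random but constructible patient specs (wider than the cohort defaults)
random_specs <- function(n, seed) {
  withr::with_seed(seed, {
    pt <- runif(n, 5, 40)
    ss <- runif(n, 15, 60)
    tibble::tibble(
      pi_deg = pt + ss,
      pt_deg = pt,
      sva_mm = runif(n, -100, 350),
      ll_deg = runif(n, 0, 60)
    )
  })
}

# a simple valid attachment row for edge-case tests
one_segment <- function(name = "seg", group = "TFL", section = "whole",
                        cranial = c(0, 3, 0), caudal = c(4, 0, 0)) {
  tibble::tibble(
    name = name, group = group, section = section,
    cranial_x = cranial[1], cranial_y = cranial[2], cranial_z = cranial[3],
    caudal_x = caudal[1], caudal_y = caudal[2], caudal_z = caudal[3]
  )
}

# random one-segment attachment tables paired with their raw coordinates
random_segments <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      name = paste0("seg", seq_len(n)),
      group = "TFL", section = "whole",
      cranial_x = runif(n, -150, 150),
      cranial_y = runif(n, -150, 150),
      cranial_z = runif(n, 0, 80),
      caudal_x = runif(n, -150, 150),
      caudal_y = runif(n, -150, 150),
      caudal_z = runif(n, 0, 80)
    )
  })
}
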