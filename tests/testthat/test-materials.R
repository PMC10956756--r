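test_that("material constructors enforce physical bounds", {
  expect_error(material_model("yeoh", C0 = -0.1, C1 = 0.2),
               class = "pelvifem_parameter_error")
  expect_error(material_model("yeoh", C0 = 0.1, C1 = -0.2),
               class = "pelvifem_parameter_error")
  expect_error(material_model("linear_elastic", E = 0),
               class = "pelvifem_parameter_error")
  expect_error(material_model("linear_elastic", E = 1, nu = 0.5),
               class = "pelvifem_parameter_error")
  expect_error(material_model("linear_elastic", E = 1, nu = -0.1),
               class = "pelvifem_parameter_error")
})

test_that("the default table carries the printed tissue parameters", {
  mats <- default_materials()
  expect_equal(c(mats$vagina$C0, mats$vagina$C1), c(0.111, 0.27))
  expect_equal(c(mats$bladder$C0, mats$bladder$C1), c(0.0375, 0.07))
  expect_equal(c(mats$rectum$C0, mats$rectum$C1), c(0.085, 0.056))
  expect_equal(mats$pelvic_floor$E, 0.1)
  expect_equal(mats$fascia_pubocervical$E, 0.18)
  expect_equal(mats$pelvic_floor$nu, 0.45)
  expect_equal(mats$suture$E, 1000)
})

test_that("Yeoh energy density behaves as a two-term polynomial in I1 - 3", {
  vag <- material_model("yeoh", C0 = 0.111, C1 = 0.27)
  expect_equal(yeoh_energy_density(3, vag), 0)
  expect_equal(yeoh_energy_density(3.5, vag), 0.111 * 0.5 + 0.27 * 0.25)
  # strictly increasing for I1 > 3
  I1 <- seq(3, 5, length.out = 40)
  expect_true(all(diff(yeoh_energy_density(I1, vag)) > 0))
  # C1 = 0 reduces to neo-Hookean: linear in (I1 - 3)
  nh <- material_model("yeoh", C0 = 0.2, C1 = 0)
  W <- yeoh_energy_density(c(3.2, 3.4, 3.6), nh)
  expect_equal(diff(W), rep(0.2 * 0.2, 2))
  expect_error(yeoh_energy_density(2.5, vag), class = "pelvifem_state_error")
  expect_error(yeoh_energy_density(3.5, material_model("linear_elastic", E = 1)),
               class = "pelvifem_state_error")
})

test_that("membrane stress matches the analytic incompressible reduction", {
  vag <- material_model("yeoh", C0 = 0.111, C1 = 0.27)
  # reference configuration is stress-free
  s0 <- membrane_stress(1, 1, vag)
  expect_equal(c(s0$sigma1, s0$sigma2), c(0, 0))
  expect_equal(s0$lambda3, 1)

  # uniaxial closed form: sigma = 2 (l^2 - 1/l)(C0 + 2 C1 (I1 - 3))
  l <- 1.3
  I1 <- l^2 + 2 / l
  su <- membrane_stress(l, 1 / sqrt(l), vag)
  expect_equal(su$sigma1,
               2 * (l^2 - 1 / l) * (0.111 + 2 * 0.27 * (I1 - 3)),
               tolerance = 1e-8)
  expect_equal(su$sigma2, 0, tolerance = 1e-10)

  # equibiaxial: sigma matches central differencing of the energy density
  l <- 1.2
  sb <- membrane_stress(l, l, vag)
  h <- 1e-6
  Wof <- function(l1, l2) yeoh_energy_density(l1^2 + l2^2 + 1 / (l1 * l2)^2, vag)
  # incompressible (J = 1): Cauchy sigma1 = l1 dW/dl1 at fixed l2
  dW <- (Wof(l + h, l) - Wof(l - h, l)) / (2 * h)
  sigma_fd <- l * dW
  expect_equal(sb$sigma1, sigma_fd, tolerance = 1e-6)
  expect_equal(sb$sigma1, sb$sigma2, tolerance = 1e-12)

  expect_error(membrane_stress(-1, 1, vag), class = "pelvifem_state_error")
})

test_that("truss force law is E A (lambda - 1), zero when slack", {
  sut <- material_model("linear_elastic", E = 1000, tension_only = TRUE)
  expect_equal(truss_force(1, sut, 0.2), 0)
  expect_equal(truss_force(0.9, sut, 0.2), 0)
  expect_equal(truss_force(1.05, sut, 0.2), 10)
  lin <- material_model("linear_elastic", E = 2)
  expect_equal(truss_force(0.9, lin, 3), 2 * 3 * (-0.1))
  expect_error(truss_force(1.1, material_model("yeoh", C0 = 1, C1 = 0), 1),
               class = "pelvifem_state_error")
})
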