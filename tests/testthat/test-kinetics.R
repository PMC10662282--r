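test_that("transformation flux follows Michaelis-Menten kinetics", {
  expect_equal(transformation_flux(0, 2, 5, 1), 0)
  expect_equal(transformation_flux(1, 2, 1, 1), 1)      # N = Ks: half Vmax*E
  expect_equal(transformation_flux(1, 2, 1e12, 1), 2, tolerance = 1e-9)
  expect_lte(transformation_flux(3, 2, 50, 1), 2 * 3)   # bound Vmax*E
  expect_equal(transformation_flux(2, 1, 0, 1), 0)
  expect_error(transformation_flux(-1, 2, 1, 1), "nonnegative")
  expect_error(transformation_flux(1, 2, 1, 0), "positive")
})

test_that("ammonium saturation inhibits N fixation", {
  expect_equal(bnf_inhibition_factor(0, 1), 1)
  expect_equal(bnf_inhibition_factor(1, 1), 0.5)
  expect_equal(bnf_inhibition_factor(9, 1), 0.1)
  NH4 <- seq(0, 20, by = 0.5)
  expect_true(all(diff(bnf_inhibition_factor(NH4, 2)) < 0))
  expect_error(bnf_inhibition_factor(-1, 1), "nonnegative")
})

test_that("enzyme pool dynamics conserve the production budget", {
  f6 <- rep(1 / 6, 6)
  expect_equal(enzyme_derivatives(rep(0, 6), f6, 100, 0.01, 0),
               rep(1 / 6, 6))
  expect_equal(enzyme_derivatives(rep(2, 6), f6, 0, 0.01, 0.1),
               rep(-0.2, 6))
  # budget identity: sum of (dE + rE*E) equals pEP*B for arbitrary f
  set.seed(3)
  for (i in 1:25) {
    w <- runif(6); f <- w / sum(w)
    E <- runif(6, 0, 5); B <- runif(1, 0, 500)
    dE <- enzyme_derivatives(E, f, B, 0.01, 0.07)
    expect_equal(sum(dE + 0.07 * E), 0.01 * B, tolerance = 1e-12)
  }
})

test_that("a quiescent system has zero derivatives", {
  p <- kinetic_params()
  frc <- dead_forcing(B = 0)
  y <- initial_state(N = c(1, 1, 1, 0, 0, p$N2_boundary),
                     E = rep(0, 6), ON = 0)
  y[c("NO", "N2O")] <- 0
  d <- codeal_rhs(100, y, p, frc, "A1")$deriv
  expect_equal(unname(d[c(1:3, 6:15)]), rep(0, 13))
  expect_equal(unname(d[4:5]), rep(0, 2))  # no gas pools, no efflux
})

test_that("the dynamic-N2 closed cycle conserves total nitrogen exactly", {
  p <- kinetic_params(N2_boundary = "dynamic", gNO = 0, gN2O = 0)
  frc <- dead_forcing()
  set.seed(11)
  for (i in 1:20) {
    y <- initial_state(N = runif(6, 0, 10), E = runif(6, 0, 3),
                       ON = runif(1, 0, 50))
    ev <- codeal_rhs(runif(1, 0, 1000), y, p, frc,
                     sample(c("A0", "A1", "A2"), 1))
    expect_equal(sum(ev$deriv[1:6]) + ev$deriv[13], 0, tolerance = 1e-12)
    expect_true(all(ev$fluxes >= 0))
    # flux bound
    expect_true(all(ev$fluxes[c("F_nit", "F_nar", "F_nir", "F_nor",
                                "F_nos", "F_fix")] <=
                      p$Vmax * pmax(y[7:12], 0) + 1e-12))
  }
})

test_that("pool balances match an independently assembled budget", {
  p <- kinetic_params()
  frc <- make_forcing(scenario_spec(years = 1))
  y <- initial_state(N = c(3, 8, 0.2, 0.02, 0.03, 20), E = rep(1, 6),
                     ON = 30)
  t <- 100
  ev <- codeal_rhs(t, y, p, frc, "A1")
  # hand-assembled fluxes from first principles
  N <- unname(y[1:6]); E <- unname(y[7:12])
  frt <- codeal:::forcing_at(frc, t)
  mm <- function(i) p$Vmax[i] * E[i] * N[i] / (p$Ks[i] + N[i])
  F_nit <- mm(1); F_nar <- mm(2); F_nir <- mm(3); F_nor <- mm(4)
  F_nos <- mm(5)
  F_fix <- mm(6) * (1 - N[1] / (N[1] + p$Ks[1]))
  F_min <- p$kmin * 30
  U1 <- p$Vup_NH4 * frt[["fplant"]] * N[1] / (p$Kup_NH4 + N[1])
  U2 <- p$Vup_NO3 * frt[["fplant"]] * N[2] / (p$Kup_NO3 + N[2])
  expect_equal(unname(ev$fluxes[c("F_nit", "F_nar", "F_nir", "F_nor",
                                  "F_nos", "F_fix", "F_min",
                                  "U_NH4", "U_NO3")]),
               c(F_nit, F_nar, F_nir, F_nor, F_nos, F_fix, F_min, U1, U2),
               tolerance = 1e-12)
  expect_equal(unname(ev$deriv[1]),
               F_min + F_fix - F_nit - U1 + frt[["I_NH4"]],
               tolerance = 1e-12)
  expect_equal(unname(ev$deriv[2]),
               F_nit - F_nar - U2 + frt[["I_NO3"]], tolerance = 1e-12)
  expect_equal(unname(ev$deriv[3]), F_nar - F_nir, tolerance = 1e-12)
  expect_equal(unname(ev$deriv[4]), F_nir - F_nor - p$gNO * N[4],
               tolerance = 1e-12)
  expect_equal(unname(ev$deriv[5]), F_nor - F_nos - p$gN2O * N[5],
               tolerance = 1e-12)
  expect_equal(unname(ev$deriv[6]), 0)   # boundary-mode dinitrogen
  expect_equal(unname(ev$deriv[13]), frt[["L"]] - F_min, tolerance = 1e-12)
})

test_that("turning ammonium inhibition on never increases fixation", {
  frc <- dead_forcing()
  y <- initial_state(N = c(4, 2, 0.1, 0.01, 0.01, 20), E = rep(1, 6),
                     ON = 10)
  f_on <- codeal_rhs(1, y, kinetic_params(bnf_inhibition = TRUE),
                     frc, "A1")$fluxes[["F_fix"]]
  f_off <- codeal_rhs(1, y, kinetic_params(bnf_inhibition = FALSE),
                      frc, "A1")$fluxes[["F_fix"]]
  expect_lt(f_on, f_off)
  expect_equal(f_on, f_off * bnf_inhibition_factor(4, 1))
})

test_that("the lean solver closure reproduces the reference right-hand
           side at randomized states", {
  p <- kinetic_params()
  frc <- make_forcing(scenario_spec(years = 2))
  set.seed(21)
  for (i in 1:20) {
    y <- initial_state(N = runif(6, 0, 20), E = runif(6, 0, 4),
                       ON = runif(1, 0, 60))
    t <- runif(1, 0, 730)
    for (s in c("A0", "A1", "A2")) {
      ref <- codeal_rhs(t, y, p, frc, s)$deriv
      fast <- codeal:::make_deriv_fn(p, frc, s)(t, as.numeric(y),
                                                NULL)[[1]]
      expect_equal(fast, unname(ref), tolerance = 1e-13)
    }
  }
})

test_that("forcing lookups outside the span are rejected", {
  frc <- dead_forcing(t1 = 10)
  expect_error(codeal:::forcing_at(frc, 11), "outside span")
  p <- kinetic_params()
  expect_error(codeal_rhs(20, initial_state(), p, frc, "A1"),
               "outside span")
})
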