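# Flux laws: GHK channels, pump, cotransporters, potentials, derivatives.

test_that("GHK channel fluxes reproduce the resting decomposition", {
  u <- u_rest
  # K+ channel at rest (printed pk, rounded U)
  k_ch <- channel_fluxes(0.0115, u, ci = 147, co = 5.8, valence = +1)
  expect_near(k_ch$influx, 0.1381, 2e-3)
  expect_near(k_ch$efflux, -0.6477, 2e-3)
  # Na+ channel net at rest
  na_ch <- channel_fluxes(0.0017, u, ci = 38, co = 140, valence = +1)
  expect_near(na_ch$net, 0.4679, 2e-3)
  # decomposition identity and signs at negative potential
  for (f in list(k_ch, na_ch)) {
    expect_equal(f$net, f$influx + f$efflux)
    expect_gte(f$influx, 0)
    expect_lte(f$efflux, 0)
  }
})

test_that("channel flux tends to the diffusive limit at zero potential", {
  # as u -> 0 the GHK flux reduces to downhill diffusion p*(co - ci),
  # positive into the cell, for either valence
  for (val in c(1, -1)) {
    direct <- channel_fluxes(0.02, 1e-6, 147, 5.8, val)$net
    series <- channel_fluxes(0.02, 1e-6 / 10, 147, 5.8, val)$net
    limit <- 0.02 * (5.8 - 147)
    expect_near(direct / limit, 1, 1e-5)
    expect_near(series / limit, 1, 1e-6)
    # exactly at u = 0 the series expansion applies
    expect_equal(channel_fluxes(0.02, 0, 147, 5.8, val)$net, limit,
                 tolerance = 1e-12)
  }
  # equilibrium: no gradient, no potential, no net flux
  expect_equal(channel_fluxes(0.5, 0, 88, 88, +1)$net, 0)
})

test_that("channel flux validates its inputs", {
  expect_error(channel_fluxes(-0.1, 0, 1, 1, 1), "'p'")
  expect_error(channel_fluxes(0.1, 0, -1, 1, 1), "'ci'")
  expect_error(channel_fluxes(0.1, 0, 1, 1, 2), "valence")
  expect_error(channel_fluxes(0.1, Inf, 1, 1, 1), "'u'")
})

test_that("pump fluxes follow -beta*[Na]i and beta*[Na]i/gamma", {
  p <- pump_fluxes(0.039, 38, 1.5)
  expect_equal(p$na_efflux, -1.4820, tolerance = 1e-10)
  expect_equal(p$k_influx, 0.9880, tolerance = 1e-10)
  # direct product at elevated internal Na (cross-checks the late
  # hyperosmolar time point, where the trajectory prints about -3.542)
  p2 <- pump_fluxes(0.039, 91, 1.5)
  expect_equal(p2$na_efflux, -3.549, tolerance = 1e-10)
  expect_equal(p2$k_influx, 2.366, tolerance = 1e-10)
  expect_equal(pump_fluxes(0, 120)$na_efflux, 0)
  expect_equal(pump_fluxes(0, 120)$k_influx, 0)
  expect_error(pump_fluxes(0.039, 38, gamma = 0), "gamma")
})

test_that("cotransporter fluxes are bilinear in the concentration products", {
  st <- resting_state()
  pr <- printed_full_params()
  co <- cotransporter_fluxes(pr, medium_rpmi(), st)
  expect_near(co$nc$influx, 1.1368, 1e-4)
  expect_near(co$nc$efflux, -0.1197, 1e-4)
  expect_near(co$nkcc$influx, 0.0874, 1e-4)
  expect_near(co$nkcc$efflux, -0.0905, 1e-4)
  expect_near(co$kc$influx, 0.0538, 1e-4)
  # exact bilinear forms
  expect_equal(co$nc$influx, 7e-5 * 140 * 116)
  expect_equal(co$nkcc$efflux, -8e-9 * 38 * 147 * 45^2)
  # equilibrium: internal products equal to external products -> zero nets
  meq <- medium(38, 147, 45, 80)
  steq <- cell_state(na = 38, k = 147, cl = 45, v = 10,
                     z = (45 - 38 - 147) * 10 / 1000)
  coeq <- cotransporter_fluxes(pr, meq, steq)
  for (pw in coeq) expect_equal(pw$net, 0, tolerance = 1e-12)
})

test_that("electrochemical potentials and driving forces match the resting state", {
  st <- resting_state()
  mu <- electrochemical_potentials(st, medium_rpmi(), U = -45.0)
  expect_near(mu[["mu_na"]], -79.9, 0.2)
  expect_near(mu[["mu_k"]], 41.3, 0.2)
  expect_near(mu[["mu_cl"]], 19.8, 0.2)
  expect_equal(mu[["mu_nc"]], mu[["mu_na"]] + mu[["mu_cl"]])
  expect_equal(mu[["mu_kc"]], mu[["mu_k"]] + mu[["mu_cl"]])
  expect_equal(mu[["mu_nkcc"]], mu[["mu_na"]] + mu[["mu_k"]] + 2 * mu[["mu_cl"]])
  # NKCC sits near equilibrium in the normal medium
  expect_lt(abs(mu[["mu_nkcc"]]), 2)
  # trivial: no gradients, no potential
  m0 <- medium(38, 147, 45, 80)
  s0 <- cell_state(na = 38, k = 147, cl = 45, v = 10,
                   z = (45 - 38 - 147) * 10 / 1000)
  expect_equal(unname(electrochemical_potentials(s0, m0, 0)), rep(0, 6))
  expect_error(electrochemical_potentials(
    cell_state(na = 0, k = 147, cl = 45, v = 10, z = -1), medium_rpmi(), 0),
    "concentrations")
})

test_that("flux table satisfies its structural invariants", {
  set.seed(421)
  pr <- printed_full_params()
  for (i in 1:12) {
    st <- random_admissible_state()
    md <- medium(runif(1, 80, 260), runif(1, 2, 12), runif(1, 60, 230),
                 runif(1, 0, 250))
    ft <- flux_table(st, pr, md)
    df <- as.data.frame(ft)
    # unidirectional decomposition
    expect_equal(df$net, df$influx + df$efflux, tolerance = 1e-12)
    expect_true(all(df$influx >= 0))
    expect_true(all(df$efflux <= 0))
    # per-ion totals equal the sum of pathway nets
    tot <- attr(ft, "total_net")
    for (ion in c("na", "k", "cl"))
      expect_equal(tot[[ion]], sum(df$net[df$ion == ion]), tolerance = 1e-12)
    # cotransporter stoichiometry: same net for every carried ion,
    # Cl twice for NKCC -> zero net charge through each cotransporter
    g <- function(ion, pw) df$net[df$ion == ion & df$pathway == pw]
    expect_equal(g("na", "nc"), g("cl", "nc"))
    expect_equal(g("k", "kc"), g("cl", "kc"))
    expect_equal(g("na", "nkcc"), g("k", "nkcc"))
    expect_equal(2 * g("na", "nkcc"), g("cl", "nkcc"))
    charge <- g("na", "nc") - g("cl", "nc") + g("k", "kc") - g("cl", "kc") +
      g("na", "nkcc") + g("k", "nkcc") - g("cl", "nkcc")
    expect_equal(charge, 0)
  }
})

test_that("content derivatives vanish at the fitted resting state and for dead membranes", {
  mod <- u937_model()
  d <- content_derivatives(mod$state, mod$params, mod$medium, u = mod$u)
  expect_near(unname(d), c(0, 0, 0), 1e-8)
  # all transport off
  dead <- transport_params(0, 0, 0, beta = 0)
  d0 <- content_derivatives(resting_state(), dead, medium_rpmi(), u = -1)
  expect_equal(unname(d0), c(0, 0, 0))
  # immediately after the +100 mM NaCl jump, Cl streams into the cell
  st <- apply_medium_jump(mod$state, medium_nacl100())
  dj <- content_derivatives(st, mod$params, medium_nacl100(),
                            u = solve_potential(st, mod$params,
                                                medium_nacl100())$u)
  expect_gt(dj[["qcl"]], 0)
})

test_that("OSOR is pump K influx over passive K influx", {
  # arithmetic on the printed unidirectional fluxes as the oracle
  oracle <- 0.9880 / (0.1381 + 0.0538 + 0.0874)
  ft <- flux_table(resting_state(), printed_full_params(), medium_rpmi(),
                   u = u_rest)
  expect_near(compute_osor(ft), oracle, 0.01)
  # blocked pump
  ft0 <- flux_table(resting_state(),
                    transport_params(0.0017, 0.0115, 0.011, beta = 0,
                                     inc = 7e-5, ikc = 8e-5, inkcc = 8e-9),
                    medium_rpmi(), u = u_rest)
  expect_equal(compute_osor(ft0), 0)
  # pump-only membrane: all K influx is ouabain-sensitive
  ftp <- flux_table(resting_state(), transport_params(0, 0, 0, beta = 0.039),
                    medium_rpmi(), u = u_rest)
  expect_identical(compute_osor(ftp), Inf)
})
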