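test_that("G-to-concentration conversion and its inverse are exact", {
  expect_equal(concentration_from_g(1, 1), 1.0364e-7, tolerance = 1e-4)
  expect_equal(concentration_from_g(2.8, 10), 2.902e-6, tolerance = 1e-3)
  expect_equal(concentration_from_g(0, 123), 0)
  expect_equal(g_from_concentration(1.0364270e-6, 10), 1.0, tolerance = 1e-6)
  for (G in c(0.3, 2.72, 7)) {
    expect_equal(g_from_concentration(concentration_from_g(G, 5), 5), G)
  }
  expect_error(g_from_concentration(1e-6, 0), "total_dose")
  # full-pulse normalization: half the dose delivered, same divisor =>
  # half the G a dose-so-far normalization would give
  C_half <- concentration_from_g(2, 5)  # state after half of a 10 Gy pulse
  expect_equal(g_from_concentration(C_half, 10),
               g_from_concentration(C_half, 5) / 2)
})

test_that("the RHS reproduces textbook derivative fields", {
  net <- parse_reaction_table(c("@species A 0 0 0", "@species B 0 0 0",
                                "d1, A -> B, 5.0, s-1"))
  f <- build_rhs(net)
  dy <- f(0, state_vector(net, c(A = 1e-6)), NULL)[[1]]
  expect_equal(dy, c(-5e-6, 5e-6))

  net1a <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
  dy <- f1a <- build_rhs(net1a)(0, state_vector(net1a, c(OH = 1e-5)), NULL)[[1]]
  expect_equal(dy[1], -2 * 5.5e9 * 1e-10)   # d[OH]/dt = -2 k [OH]^2
  expect_equal(dy[2], +5.5e9 * 1e-10)       # d[H2O2]/dt = +k [OH]^2

  # injection term: G_X converted to mol/L/Gy times the dose rate
  inj <- concentration_from_g(2.72, 1) * (10 / 1.8e-6)
  f_inj <- build_rhs(net1a, c(OH = inj))
  dy0 <- f_inj(0, state_vector(net1a), NULL)[[1]]
  expect_equal(unname(dy0[1]), 2.72 * 1.0364270e-7 * 5.5555556e6,
               tolerance = 1e-6)
})

test_that("a reaction-free system stays constant over ten time decades", {
  net <- parse_reaction_table("@species A 0 0 0")
  s <- integrate_kinetics(net, c(A = 3e-7), t_grid = 10^seq(-9, 1))
  expect_equal(s$A, rep(3e-7, nrow(s)))
})

test_that("the integrator matches first- and second-order closed forms to 0.1%", {
  # second order: 1/[OH](t) = 1/[OH]0 + 2 k t, eight decades
  net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
  C0 <- 1e-5
  tg <- 10^seq(-9, -1, length.out = 81)
  s <- integrate_kinetics(net, c(OH = C0), tg)
  exact <- C0 / (1 + 2 * 5.5e9 * C0 * s$time_s)
  expect_lt(max(abs(s$OH - exact) / exact), 1e-3)
  # the spec point: at t = 1/(2 k C0) the concentration has halved
  t_half <- 1 / (2 * 5.5e9 * C0)
  s2 <- integrate_kinetics(net, c(OH = C0), c(1e-9, t_half))
  expect_equal(s2$OH[2], C0 / 2, tolerance = 1e-3)

  # first order: A -> B exponential decay over eight decades
  netd <- parse_reaction_table(c("@species A 0 0 0", "@species B 0 0 0",
                                 "d1, A -> B, 5.0, s-1"))
  tg1 <- 10^seq(-5, 0.5, length.out = 60)  # k t from 5e-5 to ~16
  sd <- integrate_kinetics(netd, c(A = 1e-6), tg1)
  exact1 <- 1e-6 * exp(-5 * sd$time_s)
  expect_lt(max(abs(sd$A - exact1) / exact1), 1e-3)
  expect_equal(sd$A + sd$B, rep(1e-6, nrow(sd)), tolerance = 1e-9)
})

test_that("element totals are conserved when no water-exchange reactions run", {
  rows <- c(
    "1a, OH + OH -> H2O2, 5.50e9, M-1s-1",
    "1b, OH + O2- -> O2 + OH-, 1.07e10, M-1s-1",
    "2b, HO2 + O2- -> HO2- + O2, 9.70e7, M-1s-1",
    "E4, eaq + H2O2 -> OH + OH-, 1.1e10, M-1s-1",
    "E5, eaq + O2 -> O2-, 1.9e10, M-1s-1",
    "H4, H + O2 -> HO2, 2.1e10, M-1s-1",
    "P1, HO2 + HO2 -> H2O2 + O2, 8.3e5, M-1s-1"
  )
  net <- parse_reaction_table(rows)
  init <- c(OH = 2e-6, eaq = 1.5e-6, H = 4e-7, O2 = 1.25e-5,
            "O2-" = 1e-7, HO2 = 5e-8, H2O2 = 3e-7)
  s <- integrate_kinetics(net, init, 10^seq(-8, 0, length.out = 40))
  sp <- attr(s, "species")
  comp <- default_network()$species  # composition lookup
  H_tot <- as.matrix(s[, sp]) %*% comp[sp, "H"]
  O_tot <- as.matrix(s[, sp]) %*% comp[sp, "O"]
  expect_lt(diff(range(H_tot)) / H_tot[1], 1e-7)
  expect_lt(diff(range(O_tot)) / O_tot[1], 1e-7)
})

test_that("hand-off initialization adds converted yields to the background", {
  net <- default_network()
  bg <- background_state(net)
  expect_equal(unname(bg$conc["H3O+"]), 1e-7)
  expect_equal(unname(bg$conc["OH-"]), 1e-7)
  expect_equal(unname(bg$conc["O2"]), 1.25e-5)

  zero <- handoff_initialize(net, primary_yields(OH = 0), dose = 10)
  expect_equal(zero$conc, state_vector(net, bg$conc))

  st <- handoff_initialize(net, primary_yields(OH = 2.5), dose = 10)
  expect_equal(unname(st$conc["OH"]), 2.59e-6, tolerance = 1e-3)
  expect_equal(st$time, 5e-6)
})

test_that("instantaneous pulses enter as discrete concentration increments", {
  net <- parse_reaction_table("@species A 0 0 0")
  train <- make_pulse_train(5, 0)
  yields <- primary_yields(A = 2)
  s <- integrate_kinetics(net, c(A = 0), 10^seq(-9, 0, length.out = 19),
                          train = train, yields = yields)
  expect_equal(s$A, rep(concentration_from_g(2, 5), nrow(s)))
})

test_that("total injected dose is conserved through structured delivery", {
  # inert species: injected amount must equal G * dose exactly, bunching
  # and pulse structure notwithstanding
  net <- parse_reaction_table("@species A 0 0 0")
  yields <- primary_yields(A = 1)
  train <- make_pulse_train(2, 1.8e-6, n_pulses = 3, frequency = 100)
  s <- integrate_kinetics(net, c(A = 0), c(1e-9, 0.05), train = train,
                          yields = yields)
  expect_equal(s$A[nrow(s)], concentration_from_g(1, 6), tolerance = 1e-6)
})

test_that("least squares on the linearized decay recovers the rate constant", {
  net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
  C0 <- 1e-5
  tg <- seq(1e-6, 2e-4, length.out = 50)
  s <- integrate_kinetics(net, c(OH = C0), tg)
  fit <- stats::lm(I(1 / OH) ~ time_s, data = s)
  k_hat <- unname(coef(fit)[2]) / 2
  expect_lt(abs(k_hat - 5.5e9) / 5.5e9, 0.01)
})

test_that("G-value series use the full-pulse normalization and background reference", {
  net <- default_network()
  train <- make_pulse_train(10, 1.8e-6)
  yields <- default_primary_yields()
  bg <- background_state(net)
  s <- integrate_kinetics(net, bg, c(1e-9, 1.8e-6, 1e-5), train = train,
                          yields = yields)
  g <- g_values(s)
  # at pulse end most injected OH is still present at 10 Gy (a few percent
  # is already lost to fast recombination at this dose)
  expect_lte(g$OH[2], 2.72)
  expect_gte(g$OH[2], 2.4)
  # O2 G is a net change (negative once scavenging sets in), not an
  # absolute level
  expect_lte(g$O2[3], 0)
})

test_that("integration failures surface a diagnostic", {
  net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
  expect_error(
    suppressWarnings(
      integrate_kinetics(net, c(OH = 1e-3), c(1e-9, 1e2), maxsteps = 4)),
    "integration failed at")
})
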