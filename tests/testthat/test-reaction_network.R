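test_that("a single-reaction row parses into a resolved network", {
  net <- parse_reaction_table("OH + OH -> H2O2, 5.50e9, M-1s-1")
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$species), 2)
  expect_equal(nrow(net$reactions), 1)
  expect_equal(net$reactions$k, 5.50e9)
  # net stoichiometry: OH loses 2, H2O2 gains 1
  expect_equal(unname(net$S["OH", 1]), -2)
  expect_equal(unname(net$S["H2O2", 1]), 1)
})

test_that("an empty table yields an empty network with a zero-column matrix", {
  net <- parse_reaction_table("# only a comment")
  expect_equal(nrow(net$reactions), 0)
  expect_equal(ncol(net$S), 0)
})

test_that("parse errors name the offending row or token", {
  expect_error(parse_reaction_table("A + B -> C, -1, M-1s-1"),
               "non-positive rate constant")
  expect_error(parse_reaction_table("Xx + OH -> H2O2, 1e9, M-1s-1"),
               "unknown species token 'Xx'")
  expect_error(parse_reaction_table("OH + OH H2O2, 1e9, M-1s-1"), "malformed")
  expect_error(parse_reaction_table("OH + OH -> H2O2, 1e9, furlongs"),
               "unit tag")
})

test_that("species declarations in-file extend the registry", {
  net <- parse_reaction_table(c(
    "@species A 0 0 0",
    "@species B 0 0 0",
    "d1, A -> B, 2.5, s-1"
  ))
  expect_equal(net$species$name, c("A", "B"))
  expect_true(all(validate_balance(net)$balanced))
})

test_that("balance report matches hand-computed deltas", {
  net <- default_network()
  rep <- validate_balance(net)
  # H3O+ + O2- -> HO2 + H2O: H 3->3, O 3->3, charge 0->0
  r2a <- rep[rep$label == "2a", ]
  expect_equal(c(r2a$dH, r2a$dO, r2a$dcharge), c(0, 0, 0))
  expect_true(r2a$balanced)
  # OH + O2- -> O2 + OH-: H 1->1, O 3->3, charge -1->-1
  expect_true(rep[rep$label == "1b", "balanced"])
  # constructed counterexample: OH -> H2O2 is short one H and one O
  bad <- validate_balance(parse_reaction_table("f1, OH -> H2O2, 1e5, s-1"))
  expect_false(bad$balanced)
  expect_equal(c(bad$dH, bad$dO), c(1, 1))
})

test_that("the packaged network is fully balanced and holds the printed constants", {
  net <- default_network()
  expect_true(all(validate_balance(net)$balanced))
  k <- setNames(net$reactions$k, net$reactions$label)
  expect_equal(unname(k["1a"]), 5.50e9)
  expect_equal(unname(k["1b"]), 1.07e10)
  expect_equal(unname(k["2a"]), 4.78e10)
  expect_equal(unname(k["2b"]), 9.70e7)
  expect_equal(unname(k["2c"]), 5.00e10)
  expect_equal(unname(k["2d"]), 1.36e6)
})

test_that("mass-action rates follow the identical-reactant and solvent conventions", {
  net <- default_network()
  r <- reaction_rates(net, c(OH = 1e-6))
  # r = k [OH]^2; the species loses 2r via the stoichiometry matrix
  expect_equal(unname(r["1a"]), 5.50e9 * (1e-6)^2)
  expect_equal(unname(net$S["OH", "1a"] * r["1a"]), -1.10e-2)
  # 2d: HO2- + H2O with water at its fixed 55.3 M
  r2 <- reaction_rates(net, c("HO2-" = 1e-9))
  expect_equal(unname(r2["2d"]), 1.36e6 * 1e-9 * 55.3)
  # any reactant at 0 M => rate 0
  expect_equal(unname(r["2a"]), 0)
})

test_that("rates are homogeneous of degree equal to molecularity", {
  net <- default_network()
  set.seed(7)
  dyn <- net$species$name[is.na(net$species$const_conc)]
  conc <- stats::setNames(10^stats::runif(length(dyn), -9, -5), dyn)
  r1 <- reaction_rates(net, conc)
  r2 <- reaction_rates(net, conc * 3)
  order2 <- net$reactions$unit == "M-1s-1"
  # water-only kinetic slots are fixed, so find reactions with 2 dynamic slots
  n_dyn <- vapply(net$reactions$reactants, function(rs) {
    sum(is.na(net$species[rs, "const_conc"]))
  }, 0L)
  deg <- pmin(n_dyn, ifelse(order2, 2L, 1L))
  expect_equal(r2, r1 * 3^deg, tolerance = 1e-12)
})

test_that("negative concentrations violate the rate contract", {
  net <- default_network()
  expect_error(reaction_rates(net, c(OH = -1e-9)), "negative")
})

test_that("element-weighted column sums of the stoichiometry matrix vanish", {
  net <- default_network()
  expect_true(all(abs(t(net$S) %*% net$species$H) == 0))
  expect_true(all(abs(t(net$S) %*% net$species$O) == 0))
  expect_true(all(abs(t(net$S) %*% net$species$charge) == 0))
})

test_that("pin_species switches a species to a fixed reservoir", {
  net <- pin_species(default_network(), "H3O+" = 1e-7)
  expect_equal(net$species["H3O+", "const_conc"], 1e-7)
  # pinned species now contributes its fixed value to 2a
  r <- reaction_rates(net, c("O2-" = 1e-8))
  expect_equal(unname(r["2a"]), 4.78e10 * 1e-7 * 1e-8)
})
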