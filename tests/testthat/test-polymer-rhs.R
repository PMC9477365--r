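# Algebra of the polymerization right-hand side: scaling functions, site
# accounting, conservation identities, and the direct oligomer-balance
# oracle.

test_that("size-scaling functions match their boundary behaviour", {
  expect_equal(scale_olig(2), 1)
  expect_equal(scale_olig(20), 1 / 19)
  expect_equal(scale_olig(11), 10 / 19)
  expect_equal(scale_prot(1), 1)
  expect_equal(scale_prot(10), 1 / 10)
  expect_equal(scale_prot(6), 1 / 2)
  expect_error(scale_olig(1))
  expect_error(scale_olig(21))
  expect_error(scale_prot(0))
  expect_error(scale_prot(11))
})

test_that("steric multiplier interpolates between full binding and blockage", {
  expect_equal(steric_multiplier(variant_spec(0), 0.3), 1)
  for (r in c(0, 0.3, 1, 2))
    expect_equal(steric_multiplier(variant_spec(r), 1), 1)
  expect_equal(steric_multiplier(variant_spec(2), 0), 0)
  v <- variant_spec(0.3)
  expect_equal(v$P_gg + v$P_gp + v$P_pp, 1)
  expect_equal(v$f_g, 0.15)
  expect_error(variant_spec(2.5), "\\[0, 2\\]")
  expect_error(steric_multiplier(variant_spec(1), 1.5), "\\[0, 1\\]")
})

test_that("pool composition fractions handle degenerate pools", {
  expect_equal(phi_b(0, 5), 0)
  expect_equal(phi_b(3, 3), 0.5)
  expect_equal(phi_b(0, 0), 0)
  expect_equal(phi_p(0, 0, 0.5), 0)
  expect_equal(phi_p(2, 3, 1), 1)
  expect_equal(phi_p(0, 4, 0.3), 1)
  expect_equal(phi_p(5, 0, 0), 0)
})

test_that("site accounting reproduces the wild-type coefficients", {
  v <- variant_spec(0.3)
  y <- polymer_state(0, 0)
  y["f"] <- 1
  s <- site_accounting(y, v)
  expect_equal(unname(s), c(2, 0, 0.3, 0))

  y <- polymer_state(0, 0)
  y["Cfrb"] <- 0.6; y["Cfrn"] <- 0.4   # 1 uM of fiber monomers
  s <- site_accounting(y, v)
  expect_equal(s[["N_E1"]], 1.7)
  expect_equal(s[["N_E"]], 0.3)
  expect_equal(s[["N_G"]], 0.3)
  expect_equal(s[["N_G1"]], 0)

  # no gamma-prime chains, no gamma-prime sites
  y <- random_polymer_state()
  s0 <- site_accounting(y, variant_spec(0))
  expect_equal(unname(s0[c("N_E", "N_G1", "N_G")]), c(0, 0, 0))
})

test_that("conservation identities hold exactly on random states", {
  set.seed(21)
  p <- kinetic_params()
  for (k in 1:8) {
    v <- variant_spec(sample(c(0, 0.3, 1, 2), 1))
    y <- random_polymer_state()
    d <- polymer_rhs(y, p, v)
    # thrombin is conserved across all of its states
    thr <- c("T", "Efab", "Efb", "BE1", "BE", "BG1", "BG", "B")
    expect_equal(sum(d[thr]), 0, tolerance = 1e-12 * sum(abs(d[thr])))
    # fibrin(ogen) monomers are conserved
    fib <- c("fab", "fb", "f", "Efab", "Efb", "Cb", "Cf",
             "Cfb", "Cfn", "Cfrb", "Cfrn")
    expect_equal(sum(d[fib]), 0, tolerance = 1e-12 * sum(abs(d[fib])))
    # the oligomer monomer counters track the size-weighted oligomer count
    dsum <- sum((2:10) * d[paste0("f", 2:10)])
    expect_equal(d[["Cb"]] + d[["Cf"]], dsum,
                 tolerance = 1e-10 * max(1, abs(dsum)))
  }
})

test_that("assembled oligomer balance equals the direct per-species assembly", {
  set.seed(33)
  p <- kinetic_params()
  for (k in 1:6) {
    v <- variant_spec(runif(1, 0, 2))
    y <- random_polymer_state()
    d <- polymer_rhs(y, p, v)
    d_direct <- oligomer_rhs_direct(y, p, v)
    expect_equal(d[paste0("f", 2:10)], d_direct, tolerance = 1e-12)
  }
})

test_that("enzyme kinetics respect the two-step scheme", {
  p <- kinetic_params()
  v <- variant_spec(0)
  # no enzyme anywhere: cleavage derivatives vanish
  y <- polymer_state(0, 1)
  d <- polymer_rhs(y, p, v)
  expect_equal(unname(d[c("fab", "fb", "f", "Efab", "Efb", "T")]),
               rep(0, 6))
  # only the FpB monomer reaction is active
  y <- polymer_state(1, 0)
  y["fb"] <- 0.5
  d <- polymer_rhs(y, p, v)
  expect_lt(d[["fb"]], 0)
  expect_gt(d[["Efb"]], 0)
  expect_equal(d[["fab"]], 0)

  # decomposition positivity guard
  expect_error(kinetic_params(kon_enz = 1, Km_a = 1, kcat_a = 50), "kon_enz")
})

test_that("FpB cleavage flux follows the bound-state scales", {
  p <- kinetic_params(S_alpha = 1, S_gamma = 1, tie_beta = TRUE)
  v <- variant_spec(1)
  y <- polymer_state(0, 0)
  y[c("BE1", "BE", "B")] <- 1
  y["Cb"] <- 4                          # all polymer fibrin I
  d <- polymer_rhs(y, p, v)
  # each bound state cleaves at kcat_b and dissociates; fracI = 1
  expect_equal(d[["Cf"]], 3 * p$kcat_b, tolerance = 1e-12)
  expect_equal(d[["BE1"]], -p$kcat_b - p$binding$k_off_E * 1,
               tolerance = 1e-12)
  # released bivalent thrombin splits by R_biv between free and BG; the
  # remaining BG gain is ordinary B -> BG dissociation
  expect_equal(d[["BG"]],
               p$binding$k_off_E * 1 + (1 - p$R_biv) * p$kcat_b,
               tolerance = 1e-12)
  # with R_biv = 1 every bivalent cleavage releases to solution
  p1 <- kinetic_params(S_alpha = 1, S_gamma = 1, R_biv = 1)
  d1 <- polymer_rhs(y, p1, v)
  expect_equal(d1[["BG"]], p1$binding$k_off_E * 1, tolerance = 1e-12)
  # zero bound thrombin, zero flux
  y2 <- polymer_state(0, 0); y2["Cb"] <- 4
  expect_equal(polymer_rhs(y2, p, v)[["Cf"]], 0)
})

test_that("a thrombin-free system never polymerizes", {
  sim <- polymerize(thrombin_nM = 0, fibrinogen_uM = 2, r = 0.3,
                    t_end = 600, n_out = 20)
  tr <- sim$trajectory
  expect_equal(max(abs(tr$fab - 2)), 0, tolerance = 1e-10)
  expect_equal(max(tr$Cfrb + tr$Cfrn), 0, tolerance = 1e-12)
})

test_that("quasi-steady-state cleavage matches the Michaelis-Menten form", {
  # polymerization and thrombin-polymer binding switched off: pure two-step
  # enzyme conversion at T << Km decays at the pseudo-first-order MM rate
  p <- kinetic_params(k_pi = 0, k_pg = 0, k_fi = 0, k_fg = 0,
                      binding = junction_rates(k_on_E = 0, k_on_G = 0,
                                               k_off_E = 1, k_off_G = 1,
                                               k_on_E2 = 0, k_on_G2 = 0))
  sim <- polymerize(thrombin_nM = 1, fibrinogen_uM = 0.05, r = 0,
                    t_end = 4000, n_out = 80, params = p)
  tr <- sim$trajectory
  lam <- p$kcat_a * 1e-3 / p$Km_a
  expected <- 0.05 * exp(-lam * tr$time)
  expect_lt(max(abs(tr$fab + tr$Efab - expected)), 0.02 * 0.05)
})
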