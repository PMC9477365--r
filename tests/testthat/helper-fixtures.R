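# Shared helpers: random fixtures built in code.

# random but physiologically-scaled junction rates (kept moderate so chains
# absorb within a bounded number of events)
random_junction_rates <- function() {
  junction_rates(k_on_E = runif(1, 0.5, 2), K_d_E = runif(1, 2, 5),
                 k_on_G = runif(1, 0.5, 2), K_d_G = runif(1, 5, 12),
                 F_E = runif(1, 0.5, 2), F_G = runif(1, 0.5, 2),
                 k_on_E2 = runif(1, 20, 120), k_on_G2 = runif(1, 20, 120))
}

# random positive polymerization state (uM scale) for RHS algebra checks
random_polymer_state <- function() {
  y <- polymer_state(thrombin_nM = 1, fibrinogen_uM = 3)
  y[] <- runif(length(y), 0, 2)
  y["T"] <- runif(1, 0, 1e-3)
  y[c("Efab", "Efb", "BE1", "BE", "BG1", "BG", "B")] <-
    runif(7, 0, 1e-3)
  y
}

# reduced-cost fitting scenario used by the fit tests
fast_scenario <- function() {
  clot_scenario(t_end = 1500, n_out = 100, rtol = 1e-5, atol = 1e-8)
}

# independent direct assembly of the oligomer balance (formation by one
# monomer, combination of two smaller oligomers with 1/2 on identical
# pairs, loss to monomer growth, loss to all oligomer-oligomer channels
# with the size scaling on protofibril-forming pairs, and loss to
# protofibril elongation); written as plain per-species loops so it shares
# no code path with the package RHS
oligomer_rhs_direct <- function(y, params, variant) {
  steric <- steric_multiplier(variant, params$S_bind)
  kpi <- params$k_pi * steric
  kpg <- params$k_pg * steric
  fo <- setNames(as.numeric(y[paste0("f", 2:10)]), 2:10)
  M <- y[["fb"]] + y[["f"]]
  w <- function(N) if (N <= 10) 1 else scale_olig(N)
  d <- setNames(numeric(9), paste0("f", 2:10))
  for (i in 2:10) {
    form <- if (i == 2) {
      kpi * (y[["fb"]]^2 + y[["f"]]^2 + y[["fb"]] * y[["f"]])
    } else {
      kpi * fo[[as.character(i - 1)]] * M
    }
    for (j in 2:10) {
      k <- i - j
      if (k >= 2 && j <= k)
        form <- form + kpi * fo[[as.character(j)]] * fo[[as.character(k)]] *
          (if (j == k) 0.5 else 1)
    }
    loss <- if (i <= 10) kpi * fo[[as.character(i)]] * M else 0
    for (j in 2:10)
      loss <- loss + kpi * w(i + j) * fo[[as.character(i)]] * fo[[as.character(j)]]
    loss <- loss + kpg * scale_prot(i) * fo[[as.character(i)]] * y[["fn"]]
    d[[paste0("f", i)]] <- form - loss
  }
  d
}
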