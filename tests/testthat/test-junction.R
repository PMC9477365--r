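# Single-molecule junction model: construction, Gillespie runs, and the
# exact absorbing-chain oracle.

test_that("junction models expose the documented state spaces and rates", {
  r <- junction_rates()
  aa <- junction_model("AA", k_r = 1, rates = r)
  expect_identical(aa$states, c("R", "T", "B_E1"))
  # two E-domain sites double the binding rate
  expect_equal(aa$Q["T", "B_E1"], 2 * r$k_on_E * r$F_E)
  expect_equal(aa$Q["T", "R"], 1)

  ap <- junction_model("AP", k_r = 1, rates = r)
  expect_identical(ap$states, c("R", "T", "B_E1", "B_E", "B_G", "B"))
  # sequential bivalent steps are present
  expect_gt(ap$Q["B_E", "B"], 0)
  expect_gt(ap$Q["B_G", "B"], 0)
  expect_equal(ap$Q["T", "B_E1"], r$k_on_E * r$F_E)

  # zero on-rate removes the binding edge: only B_E1 -> T and T -> R remain
  aa0 <- junction_model("AA", k_r = 1,
                        rates = junction_rates(k_on_E = 0, k_off_E = 5))
  expect_equal(aa0$Q["T", "B_E1"], 0)
  expect_equal(sum(aa0$Q > 0), 2)

  expect_error(junction_model("AA", k_r = -1), "positive")
  expect_error(junction_rates(k_on_E = -2), "negative")
  expect_error(junction_model("XX"))
})

test_that("mean-absorption oracle matches closed forms", {
  # no rebinding: total time is two sequential exponential waits
  m <- junction_model("AA", k_r = 2, rates = junction_rates(k_on_E = 0, k_off_E = 5))
  o <- ctmc_mean_absorption(m, "B_E1")
  expect_equal(o$total, 1 / 5 + 1 / 2, tolerance = 1e-12)

  # per-visit competing risks from T: expected free time per visit 1/(k_r +
  # 2 k_on F_E), expected number of visits 1/p with p = k_r/(k_r + 2 kon F)
  r <- junction_rates(k_on_E = 1, F_E = 2, k_off_E = 4)
  kr <- 2 * r$k_on_E * r$F_E          # k_r equal to the binding rate
  m <- junction_model("AA", k_r = kr, rates = r)
  o <- ctmc_mean_absorption(m, "T")
  lamT <- kr + 2 * r$k_on_E * r$F_E
  visits <- lamT / kr
  expect_equal(o$state_times[["T"]], visits / lamT, tolerance = 1e-10)
  expect_equal(o$state_times[["B_E1"]],
               (visits - 1) / r$k_off_E, tolerance = 1e-10)

  # instantaneous unbinding limit: total time from T approaches 1/k_r
  fast <- junction_rates(k_off_E = 1e8, k_off_G = 1e8)
  m <- junction_model("AP", k_r = 0.5, rates = fast)
  expect_equal(ctmc_mean_absorption(m, "T")$total, 2, tolerance = 1e-5)

  # unreachable absorbing state is singular
  m <- junction_model("AA", k_r = 1)
  m$Q["T", "R"] <- 0
  expect_error(ctmc_mean_absorption(m, "T"), "singular|unreachable")
})

test_that("SSA sojourns partition exactly and match the oracle mean", {
  set.seed(42)
  m <- junction_model("AP", k_r = 0.5)
  rec <- ssa_run(m)
  # the categories partition the sojourn (exact up to summation order)
  expect_lt(abs(sum(rec$category_times) - rec$total), 1e-12 * rec$total)
  expect_lt(abs(sum(rec$state_times) - rec$total), 1e-12 * rec$total)
  expect_true(all(rec$state_times >= 0))
  expect_error(ssa_run(m, "R"), "absorbing")

  # sequential-wait closed form, Monte Carlo vs analytic
  m0 <- junction_model("AA", k_r = 2, rates = junction_rates(k_on_E = 0, k_off_E = 5))
  tot <- replicate(600, ssa_run(m0, "B_E1")$total)
  expect_lt(abs(mean(tot) - 0.7), 3 * sd(tot) / sqrt(length(tot)))
})

test_that("SSA agrees with the absorbing-chain oracle over random models", {
  set.seed(7)
  for (k in 1:5) {
    rates <- random_junction_rates()
    m <- junction_model("AP", k_r = runif(1, 0.3, 2), rates = rates)
    o <- ctmc_mean_absorption(m, "B_E")
    occ <- replicate(2000, ssa_run(m, "B_E")$total)
    se <- sd(occ) / sqrt(length(occ))
    expect_lt(abs(mean(occ) - o$total), 3 * se)
  }
})

test_that("mean time to removal is non-increasing in the removal rate", {
  # analytic oracle over the full seven-decade grid
  for (kind in c("AA", "AP")) {
    tot <- vapply(removal_rate_grid(), function(kr)
      ctmc_mean_absorption(junction_model(kind, k_r = kr))$total, numeric(1))
    expect_true(all(diff(tot) < 0))
  }
  # bivalent junctions hold thrombin longer at every removal rate
  tot_aa <- vapply(removal_rate_grid(), function(kr)
    ctmc_mean_absorption(junction_model("AA", k_r = kr), "T")$total, numeric(1))
  tot_ap <- vapply(removal_rate_grid(), function(kr)
    ctmc_mean_absorption(junction_model("AP", k_r = kr), "T")$total, numeric(1))
  expect_true(all(tot_ap >= tot_aa))
  # the free (removal-susceptible) fraction vanishes as k_r grows
  frac_free <- vapply(c(1e-2, 1e2, 1e5), function(kr)
    ctmc_mean_absorption(junction_model("AP", k_r = kr))$category_fractions[["free"]],
    numeric(1))
  expect_true(all(diff(frac_free) < 0))
  expect_lt(frac_free[3], 1e-3)
})

test_that("removal-rate sweeps are reproducible and correctly categorized", {
  set.seed(11)
  seqs <- sample_seq_rates(100)
  set.seed(1)
  s1 <- sweep_removal_rates("AP", c(0.5, 5), n_reps = 50, seq_samples = seqs)
  set.seed(1)
  s2 <- sweep_removal_rates("AP", c(0.5, 5), n_reps = 50, seq_samples = seqs)
  expect_identical(s1$summary, s2$summary)

  # category fractions partition each sojourn
  expect_equal(s1$summary$frac_free + s1$summary$frac_low + s1$summary$frac_high,
               rep(1, 2), tolerance = 1e-12)

  # AA junctions have no high-affinity-associated states
  aa <- sweep_removal_rates("AA", c(0.5, 5), n_reps = 50)
  expect_equal(aa$summary$frac_high, c(0, 0))
  expect_true(all(diff(aa$summary$mean_time_s) < 0))

  expect_error(sweep_removal_rates("AP", c(0.5), n_reps = 10),
               "sequential-rate")
  expect_error(sweep_removal_rates("AA", numeric(0)), "grid")
})

test_that("category groupings follow the configured definition", {
  m_fig <- junction_model("AP", 1, categories = junction_categories("bivalent"))
  m_met <- junction_model("AP", 1, categories = junction_categories("methods"))
  o_fig <- ctmc_mean_absorption(m_fig, "B_E")
  o_met <- ctmc_mean_absorption(m_met, "B_E")
  expect_equal(o_fig$total, o_met$total)   # grouping never changes dynamics
  # under the methods grouping B_E and B_G count as low-affinity
  expect_gt(o_met$category_times[["low"]], o_fig$category_times[["low"]])
  expect_lt(o_met$category_times[["high"]], o_fig$category_times[["high"]])
})

test_that("wild-type averaging is a convex combination of AA and AP", {
  set.seed(3)
  seqs <- sample_seq_rates(50)
  aa <- sweep_removal_rates("AA", c(0.5, 5), n_reps = 40)
  ap <- sweep_removal_rates("AP", c(0.5, 5), n_reps = 40, seq_samples = seqs)
  expect_equal(wildtype_average(aa, ap, 1)$summary, aa$summary)
  expect_equal(wildtype_average(aa, ap, 0)$summary, ap$summary)
  wt <- wildtype_average(aa, ap, 0.85)
  expect_equal(wt$summary$mean_time_s,
               0.85 * aa$summary$mean_time_s + 0.15 * ap$summary$mean_time_s)
  # the 85:15 arithmetic on the headline junction means: 4 min and 1.5 h
  expect_equal(0.85 * 240 + 0.15 * 5400, 1014)
  ap2 <- ap; ap2$summary$k_r <- ap2$summary$k_r * 2
  expect_error(wildtype_average(aa, ap2), "grid")
  expect_error(wildtype_average(aa, ap, 1.2), "weight")
})

test_that("sequential-rate files round-trip and validate", {
  f <- tempfile(fileext = ".csv")
  set.seed(5)
  write.csv(sample_seq_rates(20), f, row.names = FALSE)
  d <- read_seq_rates(f)
  expect_named(d, c("k_on_E2", "k_on_G2"))
  expect_equal(nrow(d), 20)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_seq_rates(bad), "k_on_E2")
})

test_that("clot residence estimate scales junction times to the clot", {
  est <- clot_residence_estimate(bound_time_s = c(60, 1000),
                                 clot_length_um = 10,
                                 junction_spacing_nm = 22.5,
                                 volume_fraction = 0.02)
  expect_equal(est$n_opportunities, 10000 / 22.5)
  expect_equal(est$total_bound_s, c(60, 1000) * 10000 / 22.5)
  expect_equal(est$residence_h, est$total_bound_h * 0.02)
  expect_equal(est$half_life_h, est$residence_h * log(2))
  expect_error(clot_residence_estimate(bound_time_s = -5), "positive")
})
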