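# Clot-time fitting machinery on synthetic datasets.

test_that("synthetic datasets are reproducible and self-consistent", {
  sc <- fast_scenario()
  set.seed(9)
  d1 <- synth_clot_dataset(noise_sd = 0.02, fibrinogen_uM = c(10, 16),
                           scenario = sc)
  set.seed(9)
  d2 <- synth_clot_dataset(noise_sd = 0.02, fibrinogen_uM = c(10, 16),
                           scenario = sc)
  expect_identical(d1, d2)
  expect_identical(attr(d1, "provenance"), "synthetic")
  expect_error(synth_clot_dataset(fibrinogen_uM = c(1, 8)), "2-18")

  # noiseless data are exactly reproduced by the generating parameters
  d0 <- synth_clot_dataset(noise_sd = 0, fibrinogen_uM = c(10, 16),
                           scenario = sc)
  sse <- clot_objective(fibrintrap:::fit_theta(kinetic_params()), d0,
                        scenario = sc)
  expect_lt(sse, 1e-8)
  # gamma-prime variant clots more slowly at the upper fibrinogen range
  expect_true(all(d0$clot_time_ratio > 1))
})

test_that("objective validates inputs and penalizes failed design points", {
  expect_error(clot_objective(fibrintrap:::fit_theta(kinetic_params()),
                              data.frame()), "empty")
  # an unintegrable parameter set returns the penalty, not an error
  th <- fibrintrap:::fit_theta(kinetic_params())
  th["R_biv"] <- 5          # outside the box: rejected via penalty
  d <- data.frame(fibrinogen_uM = 8, clot_time_ratio = 1.2)
  expect_equal(clot_objective(th, d, fast_scenario()), 1e4)
})

test_that("perturbing a parameter away from the optimum increases the SSE", {
  sc <- fast_scenario()
  d0 <- synth_clot_dataset(noise_sd = 0, fibrinogen_uM = c(10, 16),
                           scenario = sc)
  th <- fibrintrap:::fit_theta(kinetic_params())
  base <- clot_objective(th, d0, sc)
  th2 <- th; th2["S_bind"] <- th2["S_bind"] * 2
  expect_gt(clot_objective(th2, d0, sc), base)
})

test_that("start perturbation is seeded and respects log-space for rates", {
  th <- fibrintrap:::fit_theta(kinetic_params())
  set.seed(4); p1 <- fibrintrap:::perturb_start(th, 0.1)
  set.seed(4); p2 <- fibrintrap:::perturb_start(th, 0.1)
  expect_identical(p1, p2)
  expect_true(all(p1[c("k_pi", "k_pg", "k_fi", "k_fg")] > 0))
  expect_identical(fibrintrap:::perturb_start(th, 0), th)
})

test_that("dataset files round-trip through both CSV schemas", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(fibrinogen_uM = c(2, 8),
                       clot_time_gAgP_s = c(240, 420),
                       clot_time_gAgA_s = c(200, 300)), f, row.names = FALSE)
  d <- read_clot_dataset(f)
  expect_equal(d$clot_time_ratio, c(1.2, 1.4))
  expect_identical(attr(d, "provenance"), "measured-file")
  write.csv(data.frame(fibrinogen_uM = c(2, 2),
                       clot_time_ratio = c(1.2, 1.3)), f, row.names = FALSE)
  expect_error(read_clot_dataset(f), "unique")
})

test_that("qualitative criteria and filtering run on reduced probes", {
  crit <- qualitative_criteria(kinetic_params(),
                               thrombin_nM = c(1, 100), r_grid = c(0, 1),
                               t_end = 900)
  expect_type(crit$pass_thrombin, "logical")
  expect_length(crit$m_thrombin, 2)
  expect_true(crit$pass_thrombin)   # more thrombin, thinner fibers

  # hand-built fit object: the filter annotates and drops non-passing sets
  fake <- structure(list(results = list(list(
    par = fibrintrap:::fit_theta(kinetic_params()), sse = 0,
    converged = TRUE, start_index = 1)),
    anchor = kinetic_params(), dataset = NULL), class = "clotfit")
  filtered <- qualitative_filter(fake, thrombin_nM = c(1, 100),
                                 r_grid = c(0, 1), t_end = 900)
  expect_true(length(filtered$results) <= 1)
  if (length(filtered$results) == 1)
    expect_true(filtered$results[[1]]$criteria$pass_thrombin)
})
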