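# Scenario presets and a small JSON-configured scenario runner.

#' Junction sojourn sweep scenario (AA, AP and wild-type)
#'
#' Sweeps the removal rate over seven orders of magnitude for both junction
#' kinds and forms the 85:15 wild-type weighted average.
#'
#' @param n_reps replicates per removal rate.
#' @param k_r_grid removal-rate grid, 1/s.
#' @param rates [junction_rates()].
#' @param seq_samples sequential-rate sample (default: the placeholder
#'   sampler).
#' @param weight_aa AA weight for the wild-type average.
#' @return list with `junction_sweep` objects `aa`, `ap`, `wildtype`.
#' @export
scenario_junction_sweep <- function(n_reps = 2000,
                                    k_r_grid = removal_rate_grid(),
                                    rates = junction_rates(),
                                    seq_samples = sample_seq_rates(),
                                    weight_aa = 0.85) {
  aa <- sweep_removal_rates("AA", k_r_grid, n_reps, rates)
  ap <- sweep_removal_rates("AP", k_r_grid, n_reps, rates, seq_samples)
  list(aa = aa, ap = ap, wildtype = wildtype_average(aa, ap, weight_aa))
}

#' Fibrinopeptide-cleavage scenario (low thrombin, dilute fibrinogen)
#'
#' Simulates 0.1 nM thrombin with 0.1 mg/ml fibrinogen for a set of
#' gamma-prime ratios and reports cleavage completion times and the
#' late-phase free-thrombin percentage.
#'
#' @param r_values gamma-prime ratios to simulate.
#' @param thrombin_nM,fibrinogen_mgml scenario concentrations.
#' @param t_end window, s.
#' @param params [kinetic_params()].
#' @return list with `sims` (named by ratio) and `summary` data.frame
#'   (`r`, `FpA_done_min`, `FpB_done_min`, `free_thrombin_pct_final`).
#' @export
scenario_fpb_cleavage <- function(r_values = c(0, 1, 2), thrombin_nM = 0.1,
                                  fibrinogen_mgml = 0.1, t_end = 10800,
                                  params = kinetic_params()) {
  sims <- lapply(r_values, function(r)
    polymerize(thrombin_nM = thrombin_nM, fibrinogen_mgml = fibrinogen_mgml,
               r = r, t_end = t_end, n_out = 600, params = params))
  names(sims) <- paste0("r", r_values)
  summ <- do.call(rbind, lapply(seq_along(r_values), function(i) {
    m <- sims[[i]]$metrics
    data.frame(r = r_values[i],
               FpA_done_min = completion_time(m$time, m$FpA_pct) / 60,
               FpB_done_min = completion_time(m$time, m$FpB_pct) / 60,
               free_thrombin_pct_final = m$free_thrombin_pct[nrow(m)])
  }))
  list(sims = sims, summary = summ)
}

#' Trapped-thrombin sweep scenario
#'
#' The two structural sweeps: thrombin varied at wild-type gamma-prime
#' content, and gamma-prime ratio varied at fixed thrombin, both at fixed
#' fibrinogen. Reports the late-time (end-of-window) trapped fraction and
#' protofibril number for every condition. The default 30-minute window is
#' long enough for every condition except the lowest-thrombin one to reach
#' its plateau; that condition is reported mid-assembly, with its trapped
#' fraction still below the 1 nM case.
#'
#' @param thrombin_nM thrombin sweep, nM.
#' @param r_grid gamma-prime ratio sweep.
#' @param fibrinogen_uM fixed fibrinogen, uM.
#' @param r_fixed ratio for the thrombin sweep.
#' @param thrombin_fixed_nM thrombin for the ratio sweep.
#' @param t_end window, s.
#' @param params [kinetic_params()].
#' @return data.frame, one row per condition: `sweep`, `thrombin_nM`, `r`,
#'   `m_final`, `phi_Tfiber`, `phi_trap_pct`.
#' @export
scenario_trapped_sweeps <- function(thrombin_nM = c(0.1, 1, 10, 100),
                                    r_grid = c(0, 0.3, 1, 2),
                                    fibrinogen_uM = 3.29, r_fixed = 0.3,
                                    thrombin_fixed_nM = 1, t_end = 1800,
                                    params = kinetic_params()) {
  run1 <- function(thr, r, sweep) {
    sim <- polymerize(thrombin_nM = thr, fibrinogen_uM = fibrinogen_uM,
                      r = r, t_end = t_end, n_out = 300, params = params)
    m <- sim$metrics
    last <- nrow(m)
    data.frame(sweep = sweep, thrombin_nM = thr, r = r,
               m_final = m$m[last], phi_Tfiber = m$phi_Tfiber[last],
               phi_trap_pct = 100 * m$phi_trap[last])
  }
  rbind(
    do.call(rbind, lapply(thrombin_nM, run1, r = r_fixed, sweep = "thrombin")),
    do.call(rbind, lapply(r_grid, function(r)
      run1(thrombin_fixed_nM, r, "gamma_prime"))))
}

#' Batroxobin (reptilase) surrogate parameters
#'
#' Batroxobin cleaves FpA but not FpB and binds fibrin through its active
#' site region only: FpB catalysis is zeroed, the E-domain dissociation
#' constant is lowered, and the gamma-prime/exosite-2 interactions (direct
#' and sequential) are switched off since batroxobin has no exosite 2.
#'
#' @param params base [kinetic_params()].
#' @param K_d_E lowered E-domain dissociation constant, uM.
#' @return modified `kinetic_params`.
#' @export
preset_batroxobin <- function(params = kinetic_params(), K_d_E = 0.28) {
  binding <- modifyList(params$binding,
                        list(k_off_E = params$binding$k_on_E * K_d_E,
                             k_on_G = 0, k_off_G = 0,
                             k_on_E2 = 0, k_on_G2 = 0))
  kinetic_params(kcat_a = params$kcat_a, Km_a = params$Km_a,
                 kcat_b = 0, Km_b = params$Km_b, kon_enz = params$kon_enz,
                 k_pi = params$k_pi, k_pg = params$k_pg,
                 k_fi = params$k_fi, k_fg = params$k_fg,
                 S_agg = params$S_agg, S_alpha = params$S_alpha,
                 S_gamma = params$S_gamma, R_biv = params$R_biv,
                 S_bind = params$S_bind, tie_beta = params$tie_beta,
                 binding = binding, N_crit = params$N_crit)
}

# scenario runner ------------------------------------------------------------

scenario_schema <- list(
  junction = c("n_reps", "kr_min", "kr_max", "kr_count", "rates_file"),
  polymerization = c("thrombin_nM", "fibrinogen_uM", "fibrinogen_mgml",
                     "ratio_r", "t_end_s", "batroxobin"),
  fit = c("dataset_file", "n_starts", "perturb_sd", "noise_sd",
          "fibrinogen_grid"))

#' Run a scenario from a JSON configuration file
#'
#' The configuration must provide `name`, `model` (one of `"junction"`,
#' `"polymerization"`, `"fit"`), and `seed`; remaining keys configure the
#' selected module. Outputs (CSV trajectories/sweeps plus a JSON summary and
#' a log of the resolved configuration) are written to `out_dir` only after
#' the whole run succeeds.
#'
#' @param config path to a JSON configuration file, or an equivalent list.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a character vector of written file paths.
#' @export
run_scenario <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
         else config
  required <- c("name", "model", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("scenario config is missing required key(s): ",
         paste(missing, collapse = ", "))
  if (!cfg$model %in% names(scenario_schema))
    stop("unknown scenario model: ", cfg$model)
  extra <- setdiff(names(cfg), c(required, scenario_schema[[cfg$model]]))
  if (length(extra))
    stop("scenario config has unknown key(s): ", paste(extra, collapse = ", "))
  set.seed(cfg$seed)

  outputs <- list()   # name -> object; written only after success
  summary <- list(name = cfg$name, model = cfg$model, seed = cfg$seed)
  if (cfg$model == "junction") {
    grid <- 10^seq(log10(cfg$kr_min %||% 1e-2), log10(cfg$kr_max %||% 1e5),
                   length.out = cfg$kr_count %||% 9)
    seqs <- if (!is.null(cfg$rates_file)) read_seq_rates(cfg$rates_file)
            else {
              warning("no sequential-rate file given; using the documented ",
                      "placeholder sample")
              sample_seq_rates()
            }
    res <- scenario_junction_sweep(n_reps = cfg$n_reps %||% 2000,
                                   k_r_grid = grid, seq_samples = seqs)
    for (nm in names(res)) outputs[[paste0(nm, "_sweep.csv")]] <- res[[nm]]$summary
    summary$mean_time_s <- lapply(res, function(x)
      setNames(x$summary$mean_time_s, format(x$summary$k_r)))
  } else if (cfg$model == "polymerization") {
    params <- kinetic_params()
    if (isTRUE(cfg$batroxobin)) params <- preset_batroxobin(params)
    rs <- cfg$ratio_r %||% 0.3
    for (r in rs) {
      sim <- polymerize(thrombin_nM = cfg$thrombin_nM %||% 0.1,
                        fibrinogen_uM = cfg$fibrinogen_uM,
                        fibrinogen_mgml = cfg$fibrinogen_mgml,
                        r = r, t_end = cfg$t_end_s %||% 7200, params = params)
      m <- sim$metrics
      outputs[[sprintf("trajectory_r%s.csv", format(r))]] <-
        cbind(sim$trajectory, m[-1])
      summary[[sprintf("r%s", format(r))]] <- list(
        clot_time_s = tryCatch(clot_time(m$time, m$Cfr),
                               error = function(e) NA),
        FpA_done_min = completion_time(m$time, m$FpA_pct) / 60,
        FpB_done_min = completion_time(m$time, m$FpB_pct) / 60,
        final_m = m$m[nrow(m)], final_phi_trap = m$phi_trap[nrow(m)])
    }
  } else {
    dataset <- if (!is.null(cfg$dataset_file)) read_clot_dataset(cfg$dataset_file)
               else synth_clot_dataset(noise_sd = cfg$noise_sd %||% 0,
                                       fibrinogen_uM = cfg$fibrinogen_grid %||%
                                         seq(2, 18, length.out = 5))
    fit <- fit_clot_times(dataset, n_starts = cfg$n_starts %||% 1,
                          perturb_sd = cfg$perturb_sd %||% 0.1)
    outputs[["fit_results.csv"]] <- do.call(rbind, lapply(fit$results,
      function(x) data.frame(start_index = x$start_index, sse = x$sse,
                             converged = x$converged, t(x$par))))
    summary$best <- as.list(coef(fit))
    summary$best_sse <- fit$results[[1]]$sse
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(outputs)) {
    p <- file.path(out_dir, paste0(cfg$name, "_", nm))
    write.csv(outputs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log <- list(config = cfg, summary = summary,
              package_version = as.character(utils::packageVersion("fibrintrap")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  p <- file.path(out_dir, paste0(cfg$name, "_summary.json"))
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
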