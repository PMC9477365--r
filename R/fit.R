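# Multistart constrained least-squares estimation of the nine polymerization
# parameters against clot-time-ratio data, plus the qualitative selection
# criteria used to discriminate between candidate fits.

FIT_PARS <- c("k_pi", "k_pg", "k_fi", "k_fg", "S_agg", "S_alpha", "S_gamma",
              "R_biv", "S_bind")
LOG_PARS <- c("k_pi", "k_pg", "k_fi", "k_fg")  # perturbed in log-space

fit_theta <- function(params) unlist(params[FIT_PARS])

theta_to_params <- function(theta, template) {
  stopifnot(length(theta) == length(FIT_PARS))
  names(theta) <- FIT_PARS
  do.call(kinetic_params, modifyList(
    as.list(theta),
    list(S_beta = unname(theta["S_alpha"]),
         kcat_a = template$kcat_a, Km_a = template$Km_a,
         kcat_b = template$kcat_b, Km_b = template$Km_b,
         kon_enz = template$kon_enz, binding = template$binding,
         N_crit = template$N_crit, tie_beta = template$tie_beta)))
}

fit_bounds <- function(allow_S_agg_gt1 = FALSE) {
  lower <- setNames(rep(0, length(FIT_PARS)), FIT_PARS)
  upper <- setNames(rep(Inf, length(FIT_PARS)), FIT_PARS)
  upper[c("R_biv", "S_bind")] <- 1
  if (!allow_S_agg_gt1) upper["S_agg"] <- 1
  lower[LOG_PARS] <- 1e-8
  list(lower = lower, upper = upper)
}

#' Scenario template for clot-time fitting
#'
#' The clot-time-ratio experiments compare fractionated gamma_A/gamma-prime
#' fibrin(ogen) (r = 1) with gamma_A/gamma_A (r = 0) at 1 nM thrombin over a
#' range of fibrinogen concentrations.
#'
#' @param thrombin_nM thrombin used for both variants.
#' @param r_num,r_den gamma-prime ratios of the numerator / denominator
#'   variant of the clot-time ratio.
#' @param t_end simulation window, s (extended once if no plateau).
#' @param n_out output grid size.
#' @param rtol,atol solver tolerances for fitting runs.
#' @return list of scenario settings.
#' @export
clot_scenario <- function(thrombin_nM = 1, r_num = 1, r_den = 0,
                          t_end = 2700, n_out = 240,
                          rtol = 1e-7, atol = 1e-10) {
  list(thrombin_nM = thrombin_nM, r_num = r_num, r_den = r_den,
       t_end = t_end, n_out = n_out, rtol = rtol, atol = atol)
}

clot_time_for <- function(fib_uM, r, params, sc) {
  for (tend in c(sc$t_end, 3 * sc$t_end)) {
    sim <- polymerize(thrombin_nM = sc$thrombin_nM, fibrinogen_uM = fib_uM,
                      r = r, t_end = tend, n_out = sc$n_out,
                      params = params, rtol = sc$rtol, atol = sc$atol)
    ct <- tryCatch(clot_time(sim$metrics$time, sim$metrics$Cfr),
                   error = function(e) NA_real_)
    if (!is.na(ct)) return(ct)
  }
  NA_real_
}

#' Model clot-time ratios over a fibrinogen grid
#'
#' @param params a [kinetic_params()].
#' @param fibrinogen_uM fibrinogen grid, uM.
#' @param scenario a [clot_scenario()].
#' @return data.frame `fibrinogen_uM`, `clot_time_num_s`,
#'   `clot_time_den_s`, `clot_time_ratio`.
#' @export
model_clot_ratios <- function(params, fibrinogen_uM,
                              scenario = clot_scenario()) {
  num <- vapply(fibrinogen_uM, clot_time_for, numeric(1),
                r = scenario$r_num, params = params, sc = scenario)
  den <- vapply(fibrinogen_uM, clot_time_for, numeric(1),
                r = scenario$r_den, params = params, sc = scenario)
  data.frame(fibrinogen_uM = fibrinogen_uM, clot_time_num_s = num,
             clot_time_den_s = den, clot_time_ratio = num / den)
}

#' Sum-of-squares objective for clot-time-ratio data
#'
#' Simulates both fibrin(ogen) variants at each fibrinogen concentration of
#' the dataset and returns the sum of squared differences between model and
#' data clot-time ratios. A design point whose simulation fails to clot
#' within the (extended) window contributes a large documented penalty
#' rather than an error.
#'
#' @param theta named parameter vector over
#'   `k_pi, k_pg, k_fi, k_fg, S_agg, S_alpha, S_gamma, R_biv, S_bind`
#'   (`S_beta` is tied to `S_alpha`).
#' @param dataset a clot-time dataset (see [synth_clot_dataset()] /
#'   [read_clot_dataset()]).
#' @param scenario a [clot_scenario()].
#' @param template a [kinetic_params()] supplying the non-fitted constants.
#' @param penalty contribution of a failed design point.
#' @return scalar SSE.
#' @export
clot_objective <- function(theta, dataset, scenario = clot_scenario(),
                           template = kinetic_params(), penalty = 1e4) {
  if (is.null(dataset) || nrow(dataset) == 0)
    stop("empty clot-time dataset")
  params <- tryCatch(theta_to_params(theta, template),
                     error = function(e) NULL)
  if (is.null(params)) return(penalty * nrow(dataset))
  mod <- tryCatch(
    model_clot_ratios(params, dataset$fibrinogen_uM, scenario),
    error = function(e) NULL)
  if (is.null(mod)) return(penalty * nrow(dataset))
  res <- mod$clot_time_ratio - dataset$clot_time_ratio
  sum(ifelse(is.na(res), penalty, res^2))
}

#' Generate a synthetic clot-time-ratio dataset
#'
#' Stands in for digitized clot-time measurements: simulates both variants
#' at 1 nM thrombin across a fibrinogen grid and adds i.i.d. Gaussian noise
#' to the ratios. Tagged `provenance = "synthetic"`.
#'
#' @param params generating [kinetic_params()].
#' @param noise_sd standard deviation of the additive ratio noise.
#' @param fibrinogen_uM grid, uM (must lie within 2--18 uM).
#' @param scenario a [clot_scenario()].
#' @return data.frame `fibrinogen_uM`, `clot_time_ratio` with attribute
#'   `provenance`.
#' @export
synth_clot_dataset <- function(params = kinetic_params(), noise_sd = 0,
                               fibrinogen_uM = seq(2, 18, length.out = 5),
                               scenario = clot_scenario()) {
  if (any(fibrinogen_uM < 2 | fibrinogen_uM > 18))
    stop("fibrinogen grid must lie within 2-18 uM")
  mod <- model_clot_ratios(params, fibrinogen_uM, scenario)
  out <- data.frame(fibrinogen_uM = fibrinogen_uM,
                    clot_time_ratio = mod$clot_time_ratio +
                      rnorm(length(fibrinogen_uM), 0, noise_sd))
  attr(out, "provenance") <- "synthetic"
  out
}

#' Read a clot-time dataset from CSV
#'
#' Accepts either `fibrinogen_uM,clot_time_ratio` or
#' `fibrinogen_uM,clot_time_gAgP_s,clot_time_gAgA_s` (ratios computed).
#'
#' @param file CSV path.
#' @return data.frame `fibrinogen_uM`, `clot_time_ratio` with attribute
#'   `provenance = "measured-file"`.
#' @export
read_clot_dataset <- function(file) {
  d <- read.csv(file)
  if (!"fibrinogen_uM" %in% names(d))
    stop("dataset must have a fibrinogen_uM column")
  if (!"clot_time_ratio" %in% names(d)) {
    if (!all(c("clot_time_gAgP_s", "clot_time_gAgA_s") %in% names(d)))
      stop("dataset needs clot_time_ratio or clot_time_gAgP_s/clot_time_gAgA_s")
    d$clot_time_ratio <- d$clot_time_gAgP_s / d$clot_time_gAgA_s
  }
  if (any(d$fibrinogen_uM <= 0) || anyDuplicated(d$fibrinogen_uM) ||
      any(d$clot_time_ratio <= 0))
    stop("concentrations must be positive and unique; ratios positive")
  out <- d[c("fibrinogen_uM", "clot_time_ratio")]
  attr(out, "provenance") <- "measured-file"
  out
}

perturb_start <- function(anchor_theta, sd_frac) {
  th <- anchor_theta
  for (nm in names(th)) {
    if (sd_frac == 0) next
    if (nm %in% LOG_PARS) {
      th[nm] <- exp(rnorm(1, log(th[nm]), sd_frac))
    } else {
      th[nm] <- th[nm] + rnorm(1, 0, sd_frac * max(th[nm], 0.1))
    }
  }
  th
}

#' Multistart constrained least-squares fit of the polymerization parameters
#'
#' Runs a bound-constrained local minimizer from `n_starts` starting points,
#' each a Gaussian perturbation of the anchor parameter values (log-space
#' for the four rate constants), enforcing non-negativity and the `[0, 1]`
#' boxes on `R_biv` and `S_bind`. Results are returned sorted by SSE.
#'
#' @param dataset clot-time dataset.
#' @param n_starts number of starting points (the first is unperturbed).
#' @param perturb_sd relative perturbation scale (0.1 = 10%).
#' @param anchor [kinetic_params()] providing the anchor values and the
#'   non-fitted constants.
#' @param scenario a [clot_scenario()].
#' @param allow_S_agg_gt1 lift the `S_agg <= 1` bound (control case).
#' @param method optimizer: `"L-BFGS-B"` (bound-constrained quasi-Newton,
#'   default) or `"Nelder-Mead"` (derivative-free; bound violations are
#'   handled through the objective's penalty, so it needs far fewer
#'   objective evaluations near a flat optimum).
#' @param control passed to [stats::optim()].
#' @return Object of class `clotfit`.
#' @export
fit_clot_times <- function(dataset, n_starts = 1, perturb_sd = 0.1,
                           anchor = kinetic_params(),
                           scenario = clot_scenario(),
                           allow_S_agg_gt1 = FALSE,
                           method = c("L-BFGS-B", "Nelder-Mead"),
                           control = list(maxit = 40)) {
  if (is.null(dataset) || nrow(dataset) == 0)
    stop("empty clot-time dataset")
  if (n_starts < 1) stop("n_starts must be at least 1")
  method <- match.arg(method)
  b <- fit_bounds(allow_S_agg_gt1)
  anchor_theta <- fit_theta(anchor)
  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) anchor_theta else perturb_start(anchor_theta, perturb_sd)
    th0 <- pmin(pmax(th0, b$lower), b$upper)
    fit <- tryCatch(
      if (method == "L-BFGS-B")
        optim(th0, clot_objective, dataset = dataset, scenario = scenario,
              template = anchor, method = "L-BFGS-B",
              lower = b$lower, upper = b$upper, control = control)
      else
        optim(th0, clot_objective, dataset = dataset, scenario = scenario,
              template = anchor, method = "Nelder-Mead", control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      results[[s]] <- list(start = th0, par = th0,
                           sse = clot_objective(th0, dataset, scenario, anchor),
                           converged = FALSE, start_index = s)
    } else {
      results[[s]] <- list(start = th0, par = fit$par, sse = fit$value,
                           converged = fit$convergence == 0, start_index = s)
    }
  }
  ord <- order(vapply(results, `[[`, numeric(1), "sse"))
  structure(list(results = results[ord], dataset = dataset,
                 anchor = anchor, scenario = scenario),
            class = "clotfit")
}

#' @export
coef.clotfit <- function(object, ...) object$results[[1]]$par

#' @export
print.clotfit <- function(x, ...) {
  best <- x$results[[1]]
  cat("Clot-time-ratio fit (", length(x$results), " start(s), ",
      nrow(x$dataset), " design points)\n", sep = "")
  cat("  best SSE:", format(best$sse, digits = 4),
      if (best$converged) "(converged)" else "(not converged)", "\n")
  print(round(best$par, 4))
  invisible(x)
}

#' @export
summary.clotfit <- function(object, top = length(object$results), ...) {
  pars <- t(vapply(object$results[seq_len(top)], `[[`,
                   numeric(length(FIT_PARS)), "par"))
  colnames(pars) <- FIT_PARS
  q <- apply(pars, 2, quantile, probs = c(0.25, 0.5, 0.75))
  res <- list(best = object$results[[1]]$par,
              sse = vapply(object$results, `[[`, numeric(1), "sse"),
              quartiles = q)
  class(res) <- "summary.clotfit"
  res
}

#' @export
print.summary.clotfit <- function(x, ...) {
  cat("Best parameters:\n")
  print(round(x$best, 4))
  cat("SSE across starts:", format(x$sse, digits = 4), "\n")
  cat("Ensemble quartiles:\n")
  print(round(x$quartiles, 4))
  invisible(x)
}

#' Qualitative selection criteria on fitted parameter sets
#'
#' A candidate parameter set is retained only if the final protofibril
#' number is strictly decreasing (i) in thrombin over `thrombin_nM` at fixed
#' wild-type fibrinogen and (ii) in the gamma-prime ratio over `r_grid` at
#' fixed thrombin.
#'
#' @param params a [kinetic_params()].
#' @param thrombin_nM thrombin sweep, nM.
#' @param r_grid gamma-prime ratio sweep.
#' @param fibrinogen_uM fixed fibrinogen, uM.
#' @param r_fixed ratio used in the thrombin sweep.
#' @param thrombin_fixed_nM thrombin used in the ratio sweep.
#' @param t_end sweep window, s.
#' @return list with `pass_thrombin`, `pass_gamma`, `m_thrombin`, `m_r`.
#' @export
qualitative_criteria <- function(params,
                                 thrombin_nM = c(0.1, 1, 10, 100),
                                 r_grid = c(0, 0.3, 1, 2),
                                 fibrinogen_uM = 3.29, r_fixed = 0.3,
                                 thrombin_fixed_nM = 1, t_end = 1800) {
  final_m <- function(thr, r) {
    sim <- polymerize(thrombin_nM = thr, fibrinogen_uM = fibrinogen_uM,
                      r = r, t_end = t_end, n_out = 200, params = params)
    m <- sim$metrics$m
    m[length(m)]
  }
  m_thr <- vapply(thrombin_nM, final_m, numeric(1), r = r_fixed)
  m_r <- vapply(r_grid, final_m, numeric(1), thr = thrombin_fixed_nM)
  list(pass_thrombin = all(diff(m_thr) < 0),
       pass_gamma = all(diff(m_r) < 0),
       m_thrombin = setNames(m_thr, thrombin_nM),
       m_r = setNames(m_r, r_grid))
}

#' Filter multistart results by the qualitative criteria
#'
#' @param fit a `clotfit` (or list of parameter vectors).
#' @param ... passed to [qualitative_criteria()].
#' @return the fit with non-passing candidates dropped; each retained result
#'   gains `criteria` flags. With no probe sweeps possible the input is
#'   returned unchanged with a warning.
#' @export
qualitative_filter <- function(fit, ...) {
  stopifnot(inherits(fit, "clotfit"))
  if (length(fit$results) == 0) {
    warning("no candidates to filter")
    return(fit)
  }
  keep <- logical(length(fit$results))
  for (i in seq_along(fit$results)) {
    params <- theta_to_params(fit$results[[i]]$par, fit$anchor)
    crit <- tryCatch(qualitative_criteria(params, ...),
                     error = function(e) list(pass_thrombin = FALSE,
                                              pass_gamma = FALSE))
    fit$results[[i]]$criteria <- crit
    keep[i] <- isTRUE(crit$pass_thrombin) && isTRUE(crit$pass_gamma)
  }
  fit$results <- fit$results[keep]
  fit
}
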