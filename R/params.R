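# Kinetic parameters, fibrin(ogen) variant description and unit helpers for
# the polymerization ODE model.

#' Kinetic parameters of the fibrin polymerization model
#'
#' All rates use uM and seconds. The polymerization rates default to the
#' best-fit estimates (`k_pi` monomer/oligomer end-to-end binding, `k_pg`
#' protofibril elongation, `k_fi` fiber initiation from two protofibrils,
#' `k_fg` lateral addition of a protofibril to a fiber), together with the
#' fitted scales `S_agg` (efficiency of fibrin I lateral aggregation),
#' `S_alpha`/`S_beta`/`S_gamma` (FpB catalytic scales for `BE1`-, `BE`- and
#' bivalently bound thrombin), `R_biv` (fraction of bivalently bound
#' thrombin released to solution upon FpB cleavage) and `S_bind` (steric
#' inhibition of end-to-end binding by gamma-prime chains). Use
#' [baseline_params()] for the pre-estimation values.
#'
#' Fibrinopeptide cleavage follows a two-step enzyme scheme; `Km` and `kcat`
#' are per fibrin(ogen) molecule. Since each E-domain carries two
#' symmetric cleavage sites, the per-molecule Michaelis constants are half
#' the per-site literature values (FpA: kcat 84/s, per-site Km 7.2 uM). The
#' reversible step is decomposed as `k_off = k_on_enz * Km - kcat`, which
#' must be positive.
#'
#' @param kcat_a,Km_a FpA cleavage turnover (1/s) and per-molecule Michaelis
#'   constant (uM).
#' @param kcat_b,Km_b same for FpB cleavage.
#' @param kon_enz association rate of the enzyme step, 1/(uM s).
#' @param k_pi,k_pg,k_fi,k_fg polymerization rates, 1/(uM s).
#' @param S_agg,S_alpha,S_beta,S_gamma,R_biv,S_bind dimensionless scales.
#' @param tie_beta if `TRUE` (default), `S_beta` is tied to `S_alpha` (all
#'   E-domain bound thrombin cleaves FpB at the same rate).
#' @param binding list from [junction_rates()] with the thrombin-fibrin
#'   binding constants (the `F_E`/`F_G` entries are ignored here).
#' @param N_crit critical protofibril length, monomers.
#' @param fiber_fpb if `TRUE` (default), bound thrombin also converts
#'   fibrin I that has been incorporated into fibers (the cleavage flux is
#'   partitioned across the oligomer, protofibril and fiber pools, so all
#'   fibrinopeptide B is eventually released). With `FALSE`, fibrin I
#'   entering a fiber leaves the fibrinopeptide bookkeeping, as in the
#'   model's bare update rule.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat_a = 84, Km_a = 3.6,
                           kcat_b = 25, Km_b = 3.75,
                           kon_enz = 50,
                           k_pi = 2.953, k_pg = 0.4581,
                           k_fi = 0.0091, k_fg = 32.607,
                           S_agg = 0.0921,
                           S_alpha = 1.0164, S_beta = S_alpha,
                           S_gamma = 0.9900,
                           R_biv = 0.7126, S_bind = 0.2524,
                           tie_beta = TRUE,
                           binding = junction_rates(),
                           N_crit = 11,
                           fiber_fpb = TRUE) {
  if (tie_beta) S_beta <- S_alpha
  p <- list(kcat_a = kcat_a, Km_a = Km_a, kcat_b = kcat_b, Km_b = Km_b,
            kon_enz = kon_enz,
            koff_a = kon_enz * Km_a - kcat_a,
            koff_b = kon_enz * Km_b - kcat_b,
            k_pi = k_pi, k_pg = k_pg, k_fi = k_fi, k_fg = k_fg,
            S_agg = S_agg, S_alpha = S_alpha, S_beta = S_beta,
            S_gamma = S_gamma, R_biv = R_biv, S_bind = S_bind,
            tie_beta = tie_beta, binding = binding, N_crit = N_crit,
            fiber_fpb = fiber_fpb)
  rates <- unlist(p[c("kcat_a", "Km_a", "kcat_b", "Km_b", "kon_enz",
                      "k_pi", "k_pg", "k_fi", "k_fg",
                      "S_agg", "S_alpha", "S_beta", "S_gamma")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("kinetic parameters must be finite and non-negative")
  if (p$koff_a <= 0 || p$koff_b <= 0)
    stop("enzyme decomposition requires kon_enz * Km > kcat")
  if (R_biv < 0 || R_biv > 1) stop("R_biv must lie in [0, 1]")
  if (S_bind < 0 || S_bind > 1) stop("S_bind must lie in [0, 1]")
  if (N_crit < 3) stop("critical protofibril length must exceed 2 monomers")
  class(p) <- "kinetic_params"
  p
}

#' Pre-estimation (baseline) parameter values
#'
#' The polymerization rates of the earlier oligomerization model and neutral
#' scales: `S_agg = 0.5`, unit FpB scales, `R_biv = 0`, `S_bind = 1`.
#'
#' @param ... overrides passed to [kinetic_params()].
#' @export
baseline_params <- function(...) {
  kinetic_params(k_pi = 2.409, k_pg = 60.22, k_fi = 6.022e-4, k_fg = 12.00,
                 S_agg = 0.5, S_alpha = 1, S_gamma = 1, R_biv = 0,
                 S_bind = 1, ...)
}

#' Fibrin(ogen) variant: gamma-prime content and end-to-end bond probabilities
#'
#' A variant is described by the ratio `r` of gamma-prime sites to E-domains
#' per monomer: 0 (gamma_A/gamma_A), 0.3 (wild type), 1 (fractionated
#' gamma_A/gamma-prime), 2 (gamma-prime/gamma-prime). The fraction of gamma
#' chains that are gamma-prime is `f_g = r/2`. Assuming one gamma chain from
#' each partner participates in an end-to-end bond and chains are drawn
#' independently, the probabilities that a bond involves zero, one, or two
#' gamma-prime chains are `P_gg = (1-f_g)^2`, `P_gp = 2 f_g (1-f_g)`,
#' `P_pp = f_g^2`.
#'
#' @param r gamma-prime sites per E-domain per monomer, in `[0, 2]`.
#' @return A list of class `variant_spec` with `r`, `f_g`, `P_gg`, `P_gp`,
#'   `P_pp`.
#' @export
variant_spec <- function(r = 0.3) {
  if (!is.finite(r) || r < 0 || r > 2)
    stop("gamma-prime ratio r must lie in [0, 2]")
  f_g <- r / 2
  structure(list(r = r, f_g = f_g,
                 P_gg = (1 - f_g)^2, P_gp = 2 * f_g * (1 - f_g),
                 P_pp = f_g^2),
            class = "variant_spec")
}

#' Unit conversions for model inputs
#'
#' Fibrinogen mass concentrations are converted with a molecular weight of
#' 340 kDa (0.1 mg/ml is about 0.294 uM); thrombin activity converts as
#' 1 U/ml = 10 nM.
#'
#' @param mg_ml fibrinogen, mg/ml.
#' @param mw_kDa molecular weight, kDa.
#' @return concentration in uM.
#' @export
fibrinogen_mgml_to_uM <- function(mg_ml, mw_kDa = 340) mg_ml / mw_kDa * 1000

#' @rdname fibrinogen_mgml_to_uM
#' @param U_ml thrombin activity, U/ml.
#' @export
thrombin_Uml_to_nM <- function(U_ml) 10 * U_ml
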