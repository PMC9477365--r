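# Single-molecule stochastic binding model of thrombin at fibrin
# monomer-monomer junctions, plus the exact absorbing-Markov-chain solution
# used as its oracle.

#' Kinetic rate constants for thrombin-fibrin junction binding
#'
#' Bivalent binding scheme rates. Off-rates default to `k_on * K_d` using the
#' dissociation constants K_d,E = 2.8 uM (thrombin exosite 1 with an
#' E-domain site) and K_d,G = 9 uM (thrombin exosite 2 with a gamma-prime
#' site). The on-rates, the effective junction site concentrations `F_E` and
#' `F_G`, and the sequential (bivalent-closing) rates `k_on_E2`/`k_on_G2`
#' are not fixed by the dissociation constants; the defaults here are
#' documented package choices (see the methods vignette).
#'
#' @param k_on_E,k_on_G association rates, 1/(uM s).
#' @param K_d_E,K_d_G dissociation constants, uM.
#' @param k_off_E,k_off_G dissociation rates, 1/s; default `k_on * K_d`.
#' @param F_E,F_G effective E-domain / gamma-prime site concentrations at a
#'   junction, uM.
#' @param k_on_E2,k_on_G2 sequential binding rates closing the bivalent
#'   state from `B_G` and `B_E` respectively, 1/s.
#' @return A named list of rates.
#' @export
junction_rates <- function(k_on_E = 1, K_d_E = 2.8, k_on_G = 1, K_d_G = 9,
                           k_off_E = k_on_E * K_d_E,
                           k_off_G = k_on_G * K_d_G,
                           F_E = 2, F_G = 2,
                           k_on_E2 = 700, k_on_G2 = 700) {
  r <- list(k_on_E = k_on_E, k_off_E = k_off_E,
            k_on_G = k_on_G, k_off_G = k_off_G,
            F_E = F_E, F_G = F_G,
            k_on_E2 = k_on_E2, k_on_G2 = k_on_G2)
  bad <- vapply(r, function(x) !is.finite(x) || x < 0, logical(1))
  if (any(bad))
    stop("negative or non-finite junction rate(s): ",
         paste(names(r)[bad], collapse = ", "))
  r
}

#' State-category groupings for junction sojourn times
#'
#' Two groupings are in use for classifying bound states. The `"bivalent"`
#' grouping treats the bivalent-associated states `B_E`, `B_G`, `B` as
#' high-affinity and only `B_E1` as low-affinity; the `"methods"` grouping
#' counts only the fully bivalent state `B` as high-affinity. The free state
#' `T` (susceptible to removal) is its own category in both.
#'
#' @param grouping `"bivalent"` (default) or `"methods"`.
#' @return A list with character vectors `free`, `low`, `high`.
#' @export
junction_categories <- function(grouping = c("bivalent", "methods")) {
  grouping <- match.arg(grouping)
  if (grouping == "bivalent")
    list(free = "T", low = "B_E1", high = c("B_E", "B_G", "B"))
  else
    list(free = "T", low = c("B_E1", "B_G", "B_E"), high = "B")
}

#' Build the CTMC of one thrombin molecule at a fibrin junction
#'
#' An AA junction (gamma_A/gamma_A fibrin) exposes two E-domain sites and no
#' gamma-prime site: states `R` (removed, absorbing), `T` (free), `B_E1`.
#' The two E-domain sites are accounted for by doubling the `T -> B_E1`
#' rate. An AP junction (gamma_A/gamma-prime fibrin) adds the states `B_E`
#' (E-domain bound near a gamma-prime site), `B_G` (gamma-prime bound) and
#' `B` (bivalently bound), reachable through the sequential transitions
#' `B_E -> B` and `B_G -> B`.
#'
#' @param kind `"AA"` or `"AP"`.
#' @param k_r removal rate from the free state, 1/s; must be > 0.
#' @param rates a list from [junction_rates()].
#' @param categories a list from [junction_categories()].
#' @return An object of class `junction_model` with elements `kind`,
#'   `states`, `Q` (transition-rate matrix, rows = from), `k_r`, `rates`,
#'   `categories`.
#' @export
junction_model <- function(kind = c("AA", "AP"), k_r = 1e-2,
                           rates = junction_rates(),
                           categories = junction_categories()) {
  kind <- match.arg(kind)
  if (!is.finite(k_r) || k_r <= 0) stop("k_r must be a positive rate")
  rates <- do.call(junction_rates, rates[intersect(names(rates),
                                                   names(formals(junction_rates)))])
  states <- if (kind == "AA") c("R", "T", "B_E1")
            else c("R", "T", "B_E1", "B_E", "B_G", "B")
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  Q["T", "R"] <- k_r
  if (kind == "AA") {
    Q["T", "B_E1"] <- 2 * rates$k_on_E * rates$F_E  # two E-domain sites
    Q["B_E1", "T"] <- rates$k_off_E
  } else {
    Q["T", "B_E1"] <- rates$k_on_E * rates$F_E
    Q["T", "B_E"]  <- rates$k_on_E * rates$F_G
    Q["T", "B_G"]  <- rates$k_on_G * rates$F_G
    Q["B_E1", "T"] <- rates$k_off_E
    Q["B_E", "T"]  <- rates$k_off_E
    Q["B_E", "B"]  <- rates$k_on_G2
    Q["B_G", "T"]  <- rates$k_off_G
    Q["B_G", "B"]  <- rates$k_on_E2
    Q["B", "B_E"]  <- rates$k_off_G
    Q["B", "B_G"]  <- rates$k_off_E
  }
  structure(list(kind = kind, states = states, Q = Q, k_r = k_r,
                 rates = rates, categories = categories),
            class = "junction_model")
}

#' @export
print.junction_model <- function(x, ...) {
  cat("Thrombin-fibrin junction CTMC (", x$kind, " junction)\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  removal rate k_r:", format(x$k_r), "1/s\n")
  invisible(x)
}

default_start <- function(model) {
  # AA runs start E-domain bound; AP runs start in the E-domain state
  # adjacent to a gamma-prime site (a bound state, configurable).
  if (model$kind == "AA") "B_E1" else "B_E"
}

categorize_times <- function(model, state_times) {
  cats <- model$categories
  c(free = sum(state_times[cats$free]),
    low  = sum(state_times[intersect(cats$low, model$states)]),
    high = sum(state_times[intersect(cats$high, model$states)]))
}

#' Simulate one thrombin sojourn at a junction until removal
#'
#' Runs the Gillespie direct method from `initial_state` until the absorbing
#' removed state `R` is entered, and returns the occupation time of every
#' state. By construction the per-category times partition the total time to
#' removal exactly.
#'
#' @param model a [junction_model()].
#' @param initial_state starting state; must not be `R`. Defaults to `B_E1`
#'   for AA junctions and `B_E` for AP junctions.
#' @return A list of class `sojourn_record`: `total` (s), `state_times`
#'   (named, s), `category_times` (free/low/high, s).
#' @export
ssa_run <- function(model, initial_state = default_start(model)) {
  stopifnot(inherits(model, "junction_model"))
  if (!initial_state %in% model$states)
    stop("unknown initial state: ", initial_state)
  if (initial_state == "R") stop("cannot start in the absorbing state R")
  occ <- ssa_trajectory_cpp(model$Q, match(initial_state, model$states) - 1L,
                            match("R", model$states) - 1L)
  names(occ) <- model$states
  structure(list(total = sum(occ), state_times = occ,
                 category_times = categorize_times(model, occ)),
            class = "sojourn_record")
}

#' Exact mean occupation times before removal (absorbing-chain solve)
#'
#' Solves the linear system for the expected time spent in each transient
#' state before absorption in `R`, starting from `initial_state`. This is
#' the analytic oracle for [ssa_run()]: with generator `Q` restricted to the
#' transient states, the matrix of expected occupation times is
#' `solve(-Q_TT)`.
#'
#' @inheritParams ssa_run
#' @return A list: `total` (s), `state_times` (named, transient states),
#'   `category_times`, `category_fractions`.
#' @export
ctmc_mean_absorption <- function(model, initial_state = default_start(model)) {
  stopifnot(inherits(model, "junction_model"))
  if (!initial_state %in% model$states)
    stop("unknown initial state: ", initial_state)
  if (initial_state == "R") stop("cannot start in the absorbing state R")
  trans <- setdiff(model$states, "R")
  Qtt <- model$Q[trans, trans, drop = FALSE]
  diag(Qtt) <- -rowSums(model$Q[trans, , drop = FALSE])
  M <- tryCatch(solve(-Qtt), error = function(e)
    stop("absorbing state unreachable: occupation system is singular"))
  occ <- M[initial_state, ]
  names(occ) <- trans
  full <- setNames(numeric(length(model$states)), model$states)
  full[trans] <- occ
  cat_t <- categorize_times(model, full)
  list(total = sum(occ), state_times = occ, category_times = cat_t,
       category_fractions = cat_t / sum(occ))
}

#' Placeholder sample of sequential bivalent-binding rate pairs
#'
#' The sequential rates that close the bivalent state were estimated
#' elsewhere as a joint distribution that is not reproduced here; this
#' sampler is a documented stand-in (independent log-normals centred on the
#' default rates) in the same CSV schema accepted by [read_seq_rates()].
#'
#' @param n number of pairs (2650 mirrors the size of the original sample).
#' @param meanlog,sdlog log-normal parameters shared by both rates.
#' @return data.frame with columns `k_on_E2`, `k_on_G2` (1/s).
#' @export
sample_seq_rates <- function(n = 2650, meanlog = log(700), sdlog = 0.5) {
  data.frame(k_on_E2 = rlnorm(n, meanlog, sdlog),
             k_on_G2 = rlnorm(n, meanlog, sdlog))
}

#' Read a CSV of sequential-binding rate pairs
#'
#' @param file path to a CSV with header `k_on_E2,k_on_G2`, units 1/s.
#' @return data.frame with those two columns.
#' @export
read_seq_rates <- function(file) {
  d <- read.csv(file)
  if (!all(c("k_on_E2", "k_on_G2") %in% names(d)))
    stop("sequential-rate file must have columns k_on_E2,k_on_G2")
  if (nrow(d) == 0 || any(d$k_on_E2 < 0) || any(d$k_on_G2 < 0))
    stop("sequential-rate file is empty or contains negative rates")
  d[c("k_on_E2", "k_on_G2")]
}

#' Default removal-rate grid
#'
#' Nine log-spaced removal rates spanning seven orders of magnitude,
#' 1e-2 to 1e5 per second.
#' @param n number of grid points.
#' @return numeric vector, 1/s.
#' @export
removal_rate_grid <- function(n = 9) 10^seq(-2, 5, length.out = n)

#' Sweep removal rates and summarise thrombin sojourn statistics
#'
#' For each removal rate, runs `n_reps` independent sojourns to absorption
#' and reports the mean time to removal with a percentile credibility
#' interval (2.5--97.5) plus the mean fraction of the sojourn spent free,
#' bound to low-affinity sites, and bound to high-affinity-associated sites.
#' For AP junctions each replicate draws a sequential-rate pair from
#' `seq_samples`.
#'
#' @param kind `"AA"` or `"AP"`.
#' @param k_r_grid removal rates, 1/s.
#' @param n_reps replicates per rate.
#' @param rates a list from [junction_rates()].
#' @param seq_samples data.frame of sampled `k_on_E2`,`k_on_G2` pairs;
#'   required for AP junctions.
#' @param initial_state starting state (default per kind).
#' @param categories category grouping, see [junction_categories()].
#' @return An object of class `junction_sweep`: a data.frame `summary` with
#'   columns `k_r, mean_time_s, ci_lo, ci_hi, frac_free, frac_low,
#'   frac_high`, plus `kind` and `n_reps`.
#' @export
sweep_removal_rates <- function(kind = c("AA", "AP"),
                                k_r_grid = removal_rate_grid(),
                                n_reps = 2000,
                                rates = junction_rates(),
                                seq_samples = NULL,
                                initial_state = NULL,
                                categories = junction_categories()) {
  kind <- match.arg(kind)
  if (length(k_r_grid) == 0) stop("empty removal-rate grid")
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (kind == "AP") {
    if (is.null(seq_samples) || nrow(seq_samples) == 0)
      stop("AP junction sweeps require a non-empty set of sequential-rate samples")
  }
  rows <- vector("list", length(k_r_grid))
  for (g in seq_along(k_r_grid)) {
    model <- junction_model(kind, k_r = k_r_grid[g], rates = rates,
                            categories = categories)
    start <- if (is.null(initial_state)) default_start(model) else initial_state
    init <- match(start, model$states) - 1L
    if (kind == "AP") {
      draw <- seq_samples[sample.int(nrow(seq_samples), n_reps, replace = TRUE), ]
      seq_idx <- c(match("B_E", model$states), match("B", model$states),
                   match("B_G", model$states), match("B", model$states)) - 1L
      occ <- ssa_batch_cpp(model$Q, init, 0L, n_reps, seq_idx,
                           cbind(draw$k_on_G2, draw$k_on_E2))
    } else {
      occ <- ssa_batch_cpp(model$Q, init, 0L, n_reps, integer(0),
                           matrix(0, 0, 2))
    }
    colnames(occ) <- model$states
    totals <- rowSums(occ)
    cats <- model$categories
    fr <- function(states) {
      st <- intersect(states, model$states)
      if (length(st) == 0) return(numeric(nrow(occ)))
      rowSums(occ[, st, drop = FALSE]) / totals
    }
    rows[[g]] <- data.frame(
      k_r = k_r_grid[g],
      mean_time_s = mean(totals),
      ci_lo = unname(quantile(totals, 0.025)),
      ci_hi = unname(quantile(totals, 0.975)),
      frac_free = mean(fr(cats$free)),
      frac_low = mean(fr(cats$low)),
      frac_high = mean(fr(cats$high)))
  }
  structure(list(summary = do.call(rbind, rows), kind = kind,
                 n_reps = n_reps),
            class = "junction_sweep")
}

#' Weighted average of AA and AP junction sweeps (wild-type fibrin)
#'
#' Wild-type fibrin(ogen) carries gamma-prime chains on about 15% of its
#' gamma chains, so wild-type junction statistics are estimated as a
#' weighted average of the AA and AP sweeps (default 85:15).
#'
#' @param aa,ap `junction_sweep` objects on identical removal-rate grids.
#' @param weight_aa weight on the AA sweep, in `[0, 1]`.
#' @return A `junction_sweep` with `kind = "wild-type"`.
#' @export
wildtype_average <- function(aa, ap, weight_aa = 0.85) {
  stopifnot(inherits(aa, "junction_sweep"), inherits(ap, "junction_sweep"))
  if (weight_aa < 0 || weight_aa > 1) stop("weight_aa must be in [0, 1]")
  if (!isTRUE(all.equal(aa$summary$k_r, ap$summary$k_r)))
    stop("removal-rate grids of the two sweeps differ")
  w <- weight_aa
  s <- aa$summary
  for (col in setdiff(names(s), "k_r"))
    s[[col]] <- w * aa$summary[[col]] + (1 - w) * ap$summary[[col]]
  structure(list(summary = s, kind = "wild-type",
                 n_reps = min(aa$n_reps, ap$n_reps)),
            class = "junction_sweep")
}

#' @export
print.junction_sweep <- function(x, ...) {
  cat("Junction sojourn sweep (", x$kind, ", ", x$n_reps,
      " replicates per rate)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a junction sweep summary to CSV
#' @param x a `junction_sweep`.
#' @param file output path.
#' @export
write_junction_sweep <- function(x, file) {
  stopifnot(inherits(x, "junction_sweep"))
  write.csv(x$summary, file, row.names = FALSE)
  invisible(file)
}

#' Back-of-envelope in-clot thrombin residence estimate
#'
#' Scales a single-junction mean bound time up to a whole clot: a thrombin
#' molecule travelling a given distance through the clot can engage a
#' binding junction every half fibrin-monomer length, so the number of
#' binding opportunities is `clot_length / junction_spacing`. The total
#' bound time is the per-junction bound time times that count; multiplying
#' by the fibrin volume fraction gives the expected in-clot residence, and
#' assuming first-order removal the half-life is `ln 2` times the residence.
#'
#' @param bound_time_s per-junction mean bound time, s (scalar or range).
#' @param clot_length_um distance traversed in the clot, um.
#' @param junction_spacing_nm spacing between binding junctions, nm
#'   (default 22.5, half the fibrin monomer length).
#' @param volume_fraction fibrin volume fraction of the clot.
#' @return A list: `n_opportunities`, `total_bound_s`, `total_bound_h`,
#'   `residence_h`, `half_life_h` (each the same length as `bound_time_s`).
#' @export
clot_residence_estimate <- function(bound_time_s = c(60, 1000),
                                    clot_length_um = 10,
                                    junction_spacing_nm = 22.5,
                                    volume_fraction = 0.02) {
  if (any(c(bound_time_s, clot_length_um, junction_spacing_nm,
            volume_fraction) <= 0))
    stop("all inputs must be positive")
  n_opp <- clot_length_um * 1000 / junction_spacing_nm
  total_s <- bound_time_s * n_opp
  total_h <- total_s / 3600
  residence_h <- total_h * volume_fraction
  list(n_opportunities = n_opp,
       total_bound_s = total_s,
       total_bound_h = total_h,
       residence_h = residence_h,
       half_life_h = residence_h * log(2))
}
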