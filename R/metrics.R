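# Fiber-structure metrics: protofibril number, clot time, circle-packing
# inaccessible fraction, and trapped-thrombin estimation.

#' Protofibril number per fiber
#'
#' The ratio of the cumulative count of protofibrils incorporated into
#' fibers to the fiber concentration, `m = P_fr / f_r`, defined as 0 while
#' no fibers exist. A proxy for fiber thickness.
#'
#' @param Pfr cumulative protofibrils in fibers, uM.
#' @param fr fiber concentration, uM.
#' @return protofibril number (vectorized).
#' @export
protofibril_number <- function(Pfr, fr) ifelse(fr > 0, Pfr / pmax(fr, 0), 0)

#' Clot time from a polymerization readout
#'
#' The interpolated time at which a readout (by default fiber-incorporated
#' monomer mass, the turbidity surrogate) first reaches half its final
#' value. The readout must have plateaued within the simulated window.
#'
#' @param time time grid, s.
#' @param readout non-negative readout on the same grid.
#' @param plateau_tol maximum allowed relative growth over the last 5% of
#'   the window for the curve to count as plateaued.
#' @return clot time, s.
#' @export
clot_time <- function(time, readout, plateau_tol = 0.02) {
  stopifnot(length(time) == length(readout))
  readout <- pmax(readout, 0)
  final <- readout[length(readout)]
  if (final <= 0) stop("readout never rises; no clot forms in the window")
  tail_start <- max(1L, which(time >= 0.95 * max(time))[1])
  if ((final - readout[tail_start]) / final > plateau_tol)
    stop("readout has not plateaued; rerun with a longer t_end")
  half <- final / 2
  i <- which(readout >= half)[1]
  if (i == 1) return(time[1])
  # linear interpolation across the crossing
  t0 <- time[i - 1]; t1 <- time[i]
  y0 <- readout[i - 1]; y1 <- readout[i]
  t0 + (half - y0) / (y1 - y0) * (t1 - t0)
}

#' Inaccessible protofibrils in a fiber cross-section
#'
#' Protofibrils are idealized as equal circles packed in concentric
#' hexagonal layers (layer k holds 6k circles around a central one). Free
#' thrombin is assumed to reach only the outermost two occupied layers, so
#' with `L` occupied layers the `N_I` protofibrils interior to layer `L - 1`
#' are inaccessible. `I = N_I / N_pf`, with `I(0) = 0` by convention.
#'
#' @param N_pf protofibril count (non-negative integer, vectorized).
#' @return data.frame with columns `N_pf`, `N_I`, `I`.
#' @export
pack_inaccessible <- function(N_pf) {
  if (any(N_pf < 0)) stop("N_pf must be non-negative")
  N_pf <- as.integer(round(N_pf))
  hex_cum <- function(L) ifelse(L < 0, 0, 3 * L * (L + 1) + 1)
  one <- function(n) {
    if (n == 0) return(0L)
    L <- 0
    while (hex_cum(L) < n) L <- L + 1
    if (L <= 1) 0L else as.integer(hex_cum(L - 2))
  }
  NI <- vapply(N_pf, one, integer(1))
  data.frame(N_pf = N_pf, N_I = NI,
             I = ifelse(N_pf > 0, NI / N_pf, 0))
}

#' Interpolated inaccessible fraction over protofibril number
#'
#' Piecewise-linear interpolation of the inaccessible fraction evaluated at
#' (possibly non-integer) protofibril numbers `m`. The interpolation anchors
#' are the complete-layer packings (N = 1, 7, 19, 37, ..., where the
#' hexagonal count is exact and `I = N_I / N` from [pack_inaccessible()]);
#' between anchors a partially filled outer layer does not yet shield the
#' ring two levels below it, so the anchor interpolation — unlike the raw
#' integer counts — is monotone non-decreasing in `m`.
#'
#' @param m protofibril number(s), >= 0.
#' @return `I(m)` in `[0, 1]`.
#' @export
inaccessible_fraction <- function(m) {
  if (any(m < 0)) stop("protofibril number must be non-negative")
  L <- 0:max(25, ceiling(sqrt(max(m, 1) / 3)) + 2)
  anchors <- 3 * L * (L + 1) + 1        # complete hexagonal packings
  tab <- pack_inaccessible(anchors)
  approx(c(0, tab$N_pf), c(0, tab$I), xout = m, rule = 2)$y
}

#' Trapped-thrombin fraction of a state
#'
#' Combines the binding-site accounting with the packing geometry: the
#' fraction of each bound-thrombin species residing on fibers is the fiber
#' share of its site pool (`phi_BE1 = (2 - r) C_fr / N_E1`, `phi_BE = r C_fr
#' / N_E`, `phi_BG = r C_fr / N_G`, and 0 for `BG1`, which only exists on
#' free monomers). The fiber-bound fraction of all bound thrombin,
#' `phi_Tfiber`, times the inaccessible packing fraction `I(m)` gives the
#' trapped fraction `phi_trap`.
#'
#' @param state named state vector (or trajectory data.frame).
#' @param variant a [variant_spec()].
#' @param m protofibril number (same length as rows of `state`).
#' @return data.frame with `phi_Tfiber` and `phi_trap`.
#' @export
trapped_fraction <- function(state, variant, m) {
  sites <- site_accounting(state, variant)
  if (is.null(dim(sites))) sites <- matrix(sites, 1,
                                           dimnames = list(NULL, names(sites)))
  g <- if (is.data.frame(state) || is.matrix(state))
    function(nm) state[, nm] else function(nm) state[[nm]]
  r <- variant$r
  Cfr <- pmax(g("Cfrb") + g("Cfrn"), 0)
  sfr <- function(a, b) ifelse(b > 0, pmin(a / pmax(b, .Machine$double.xmin), 1), 0)
  phiBE1 <- sfr((2 - r) * Cfr, sites[, "N_E1"])
  phiBE <- sfr(r * Cfr, sites[, "N_E"])
  phiBG <- sfr(r * Cfr, sites[, "N_G"])
  Tb <- pmax(g("BE1") + g("BE") + g("BG1") + g("BG") + g("B"), 0)
  Tf <- pmax(g("BE1"), 0) * phiBE1 + pmax(g("BE"), 0) * phiBE +
    pmax(g("BG"), 0) * phiBG + pmax(g("B"), 0) * phiBG
  phi_Tfiber <- sfr(Tf, Tb)
  data.frame(phi_Tfiber = phi_Tfiber,
             phi_trap = inaccessible_fraction(m) * phi_Tfiber)
}

#' Derived structural and cleavage metrics of a trajectory
#'
#' @param sim a `polymer_sim`.
#' @return data.frame with `time`, `FpA_pct`, `FpB_pct`,
#'   `free_thrombin_pct`, `Cfr` (fiber monomer mass, uM), `m` (protofibril
#'   number), `phi_Tfiber`, `phi_trap`.
#' @export
structure_metrics <- function(sim) {
  tr <- sim$trajectory
  Ftot <- sim$totals["fibrinogen_uM"]
  Ttot <- sim$totals["thrombin_uM"]
  clip <- function(x) pmax(x, 0)
  FpA <- 100 * (1 - clip(tr$fab + tr$Efab) / Ftot)
  # with fiber_fpb off, fibrin I entering fibers leaves the fibrinopeptide
  # bookkeeping, so the tracked-FpB percentage excludes the fiber pool
  unc <- tr$fab + tr$Efab + tr$fb + tr$Efb + tr$Cb + tr$Cfb
  if (isTRUE(sim$params$fiber_fpb)) unc <- unc + tr$Cfrb
  FpB <- 100 * (1 - clip(unc) / Ftot)
  freeT <- 100 * clip(tr$T) / Ttot
  m <- protofibril_number(tr$Pfr, tr$fr)
  tf <- trapped_fraction(tr, sim$variant, m)
  data.frame(time = tr$time, FpA_pct = FpA, FpB_pct = FpB,
             free_thrombin_pct = pmin(freeT, 100),
             Cfr = clip(tr$Cfrb + tr$Cfrn), m = m,
             phi_Tfiber = tf$phi_Tfiber, phi_trap = tf$phi_trap)
}

#' Time at which a cleavage percentage first exceeds a threshold
#'
#' Linear interpolation of the crossing; `NA` if never reached.
#'
#' @param time time grid, s.
#' @param pct percentage time series.
#' @param threshold completion threshold (default 99%).
#' @return time, s.
#' @export
completion_time <- function(time, pct, threshold = 99) {
  i <- which(pct >= threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  y0 <- pct[i - 1]; y1 <- pct[i]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Write trajectory metrics to CSV
#' @param sim a `polymer_sim`.
#' @param file output path.
#' @export
write_metrics <- function(sim, file) {
  write.csv(cbind(sim$metrics,
                  clot_readout = sim$metrics$Cfr), file, row.names = FALSE)
  invisible(file)
}
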