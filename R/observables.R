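# Observables: tip force, force-distance profiles, density profiles, brush
# height, graft-end meandering, solvent penetration.

#' Instantaneous force on the tip wall
#'
#' The magnitude of the wall-normal force exerted on the tip plane:
#' `F = sum over particles within 1 rc of the tip of a_w (1 - gap)`, the
#' derivative of the soft wall potential. Always non-negative.
#'
#' @param system A `brush_system`.
#' @param interactions Interaction table (defaults to the system's).
#' @return Force in kBT/rc.
#' @export
tip_force <- function(system, interactions = system$interactions) {
  cpp_tip_force(unclass(system), unclass(interactions))
}

block_se <- function(x, n_blocks = 10) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for an uncertainty estimate")
  nb <- max(2, min(n_blocks, n %/% 2))
  len <- n %/% nb
  means <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1) * len + 1):(b * len)]), numeric(1))
  stats::sd(means) / sqrt(nb)
}

#' Force-distance profile from a set of runs
#'
#' Aggregates per-separation tip-force streams into a mean force and a
#' block-averaged standard error per point. The tip wall feels the bulk
#' solvent's osmotic pressure at every separation, so the profile reports
#' the *excess* force: by default the largest-h point (the uncompressed
#' reference, which must lie beyond brush contact) is taken as baseline and
#' subtracted from every point.
#'
#' @param runs List of `gcmc_run` objects, one per separation (at least 2),
#'   each with at least 2 samples.
#' @param n_blocks Number of blocks for the standard-error estimate.
#' @param baseline `"largest_h"` (default), `"none"`, or a number to
#'   subtract (kBT/rc).
#' @param units A [unit_system()] for the nm axis.
#' @return An object of class `force_profile`: data.frame with `h_rc`,
#'   `h_nm`, `F` (excess force, kBT/rc), `SE`, `P` (excess pressure,
#'   kBT/rc^3), `n_samples`, plus attributes `area` (rc^2) and `baseline`.
#' @export
force_profile <- function(runs, n_blocks = 10, baseline = "largest_h",
                          units = unit_system()) {
  stopifnot(length(runs) >= 2)
  h <- vapply(runs, function(r) r$h, numeric(1))
  o <- order(h)
  runs <- runs[o]; h <- h[o]
  if (any(diff(h) <= 0)) stop("separations must be distinct")
  area <- prod(runs[[1]]$box)
  Fm <- vapply(runs, function(r) {
    if (nrow(r$samples) < 2) stop("single sample: no uncertainty estimate")
    mean(r$samples$tip_force)
  }, numeric(1))
  SE <- vapply(runs, function(r) block_se(r$samples$tip_force, n_blocks),
               numeric(1))
  ns <- vapply(runs, function(r) nrow(r$samples), numeric(1))
  b <- if (identical(baseline, "largest_h")) Fm[length(Fm)]
       else if (identical(baseline, "none")) 0
       else as.numeric(baseline)
  out <- data.frame(h_rc = h, h_nm = to_physical(h, units),
                    F = Fm - b, SE = SE, P = (Fm - b) / area,
                    n_samples = ns)
  attr(out, "area") <- area
  attr(out, "baseline") <- b
  attr(out, "n_blocks") <- n_blocks
  class(out) <- c("force_profile", "data.frame")
  out
}

#' Derjaguin transform of a pressure profile
#'
#' Converts the flat-plate excess pressure `P(h)` into the force on a large
#' sphere: `F(h)/R = 2 pi * integral_h^{h_max} P(u) du`, by the trapezoid
#' rule over the sweep grid. The grid should extend into the zero-force
#' tail; if the last pressure is not negligible a warning with a truncation
#' bound is attached.
#'
#' @param profile A [force_profile()].
#' @param R_um Probe radius in micrometres (reporting only; `F/R` itself is
#'   radius-independent).
#' @param units A [unit_system()] for the N/m conversion.
#' @return The profile with added columns `F_over_R` (kBT/rc^2) and
#'   `F_over_R_mN_per_m`, and attribute `R_um`.
#' @export
derjaguin_transform <- function(profile, R_um = 2.5, units = unit_system()) {
  stopifnot(inherits(profile, "force_profile"))
  h <- profile$h_rc; P <- profile$P
  n <- length(h)
  FR <- numeric(n)
  for (k in seq_len(n - 1)) {
    seg <- k:n
    FR[k] <- 2 * pi * sum(diff(h[seg]) * (utils::head(P[seg], -1) +
                                            utils::tail(P[seg], -1)) / 2)
  }
  tailP <- abs(P[n])
  if (tailP > 1e-6 * max(abs(P)))
    warning(sprintf(
      "grid may not reach the zero-force tail; truncation bound ~%.3g kBT/rc^2",
      2 * pi * tailP * diff(range(h))))
  # kBT/rc^2 -> N/m (per unit R): kBT_J / rc_m^2; reported in mN/m
  rc_m <- units$rc_nm * 1e-9
  conv <- units$kBT_J / rc_m^2
  profile$F_over_R <- FR
  profile$F_over_R_mN_per_m <- FR * conv * 1e3
  attr(profile, "R_um") <- R_um
  profile
}

#' Density profile from a run
#'
#' z-binned number densities of brush beads and solvent, averaged over the
#' run's samples. Uses the histograms accumulated by the engine (at the
#' run's `bin_width`); pass a different `bin_width` only for runs recorded
#' with `record_frames = TRUE`, in which case the frames are re-binned.
#'
#' @param run A `gcmc_run` with at least 10 samples.
#' @param bin_width Bin width in rc; default the run's.
#' @return An object of class `density_profile`: data.frame with `z` (bin
#'   centres, rc), `rho_brush`, `rho_solvent` (rc^-3); attributes `area`,
#'   `h`, `bin_width`, `n_samples`.
#' @export
density_profile <- function(run, bin_width = NULL) {
  stopifnot(inherits(run, "gcmc_run"))
  if (run$n_hist_samples < 1) stop("run has no samples")
  area <- prod(run$box)
  if (is.null(bin_width) || isTRUE(all.equal(bin_width, run$bin_width))) {
    bw <- run$bin_width
    cb <- run$hist_brush; cs <- run$hist_solvent
  } else {
    if (bin_width <= 0) stop("bin width must be positive")
    if (is.null(run$frames))
      stop("re-binning requires a run recorded with record_frames = TRUE")
    bw <- bin_width
    nb <- max(1L, as.integer(ceiling(run$h / bw - 1e-9)))
    cb <- numeric(nb); cs <- numeric(nb)
    brush <- run$system$species > 0
    for (fr in run$frames) {
      b <- pmin(nb, floor(fr[, 3] / bw) + 1)
      cb <- cb + tabulate(b[brush], nb)
      cs <- cs + tabulate(b[!brush], nb)
    }
  }
  nb <- length(cb)
  vol <- area * bw
  out <- data.frame(z = (seq_len(nb) - 0.5) * bw,
                    rho_brush = cb / (run$n_hist_samples * vol),
                    rho_solvent = cs / (run$n_hist_samples * vol))
  attr(out, "area") <- area
  attr(out, "h") <- run$h
  attr(out, "bin_width") <- bw
  attr(out, "n_samples") <- run$n_hist_samples
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Equilibrium brush height from a density profile
#'
#' Two estimators of the uncompressed brush length L: the z at which the
#' cumulative brush-bead density reaches 98% of its total (primary; robust
#' to sparse tails, computed by linear interpolation of the cumulative
#' across the crossing bin) and the first-moment estimator `2 <z>`.
#' Meaningful at the largest separation of a sweep, where the brush is not
#' compressed by the tip.
#'
#' @param profile A [density_profile()].
#' @param quantile Cumulative fraction for the primary estimator.
#' @return List with `L_q` (quantile estimator, rc), `L_moment` (`2 <z>`,
#'   rc) and `quantile`.
#' @export
brush_height <- function(profile, quantile = 0.98) {
  stopifnot(inherits(profile, "density_profile"), quantile > 0, quantile < 1)
  rho <- profile$rho_brush
  total <- sum(rho)
  if (total <= 0) stop("empty brush profile")
  bw <- attr(profile, "bin_width")
  cum <- cumsum(rho)
  target <- quantile * total
  k <- which(cum >= target)[1]
  prev <- if (k > 1) cum[k - 1] else 0
  Lq <- (k - 1) * bw + (target - prev) / (cum[k] - prev) * bw
  Lm <- 2 * sum(rho * profile$z) / total
  list(L_q = Lq, L_moment = Lm, quantile = quantile)
}

#' Graft-end meandering trace
#'
#' The xy positions of one chain's graft bead at every sample, unwrapped
#' across the periodic images, together with the mean-square displacement
#' as a function of lag (averaged over time origins). Solid-brush traces
#' are constant with MSD identically zero.
#'
#' @param run A `gcmc_run`.
#' @param chain_id Chain whose graft end to follow (default 1).
#' @return An object of class `meander_trace`: data.frame with `sample`,
#'   `x`, `y` (unwrapped, rc); attributes `msd` (data.frame lag, msd),
#'   `sample_interval`, `chain_id`.
#' @export
graft_trace <- function(run, chain_id = 1) {
  stopifnot(inherits(run, "gcmc_run"))
  graft_chain <- run$system$chain_id[run$graft_ids]
  g <- match(chain_id, graft_chain)
  if (is.na(g)) stop("no such chain: ", chain_id)
  x <- run$graft_trace[, 2 * g - 1]
  y <- run$graft_trace[, 2 * g]
  unwrap <- function(v, L) {
    d <- diff(v)
    d <- d - L * round(d / L)
    v[1] + c(0, cumsum(d))
  }
  xu <- unwrap(x, run$box[1])
  yu <- unwrap(y, run$box[2])
  n <- length(xu)
  lags <- seq_len(max(1, n - 1))
  msd <- vapply(lags, function(tau) {
    idx <- seq_len(n - tau)
    mean((xu[idx + tau] - xu[idx])^2 + (yu[idx + tau] - yu[idx])^2)
  }, numeric(1))
  out <- data.frame(sample = seq_len(n), x = xu, y = yu)
  attr(out, "msd") <- data.frame(lag = lags, msd = msd)
  attr(out, "sample_interval") <- run$params$sample_interval
  attr(out, "chain_id") <- chain_id
  class(out) <- c("meander_trace", "data.frame")
  out
}

#' Mean solvent count in a z-window
#'
#' Integrates the solvent density over `[window[1], window[2]]` and
#' multiplies by the lateral area, giving the mean number of solvent
#' particles in that slab. Partial bins at the window edges contribute
#' proportionally.
#'
#' @param profile A [density_profile()].
#' @param window Length-2 numeric, within `[0, h]`, increasing.
#' @return Mean solvent count (dimensionless).
#' @export
solvent_penetration <- function(profile, window) {
  stopifnot(inherits(profile, "density_profile"), length(window) == 2)
  h <- attr(profile, "h")
  if (window[2] <= window[1]) stop("empty window")
  if (window[1] < 0 || window[2] > h + 1e-9)
    stop("window must lie within [0, h]")
  bw <- attr(profile, "bin_width")
  lo <- profile$z - bw / 2
  hi <- profile$z + bw / 2
  overlap <- pmax(0, pmin(hi, window[2]) - pmax(lo, window[1]))
  sum(profile$rho_solvent * overlap) * attr(profile, "area")
}
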