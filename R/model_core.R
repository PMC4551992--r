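#' Unit system for the reduced-unit model
#'
#' All internal computation uses reduced units: lengths in units of the bead
#' interaction radius `rc` and energies in units of the thermal energy `kBT`.
#' The unit system records the physical size of one `rc` so that inputs given
#' in nanometres (tip-surface separations, grafting densities, cell area) can
#' be mapped in and results mapped back out.
#'
#' @param rc_nm Physical bead interaction radius in nm. Default 0.646 nm
#'   (6.46 angstrom), the coarse-grained bead size of the model.
#' @param temperature_K Absolute temperature used only when converting
#'   energies or forces to SI units; the sampler itself never sees it because
#'   `kBT = 1` in reduced units.
#' @return An object of class `unit_system`.
#' @examples
#' u <- unit_system()
#' to_reduced(2.8, u)   # lower end of the tip-surface sweep, in rc
#' @export
unit_system <- function(rc_nm = 0.646, temperature_K = 298.15) {
  stopifnot(is.numeric(rc_nm), length(rc_nm) == 1, rc_nm > 0,
            is.numeric(temperature_K), temperature_K > 0)
  structure(
    list(rc_nm = rc_nm, kBT = 1, mass = 1, temperature_K = temperature_K,
         kBT_J = 1.380649e-23 * temperature_K),
    class = "unit_system")
}

#' Convert a physical length in nm to reduced units (rc)
#'
#' @param length_nm Non-negative length(s) in nm.
#' @param units A [unit_system()].
#' @return Length(s) in rc.
#' @export
to_reduced <- function(length_nm, units = unit_system()) {
  stopifnot(inherits(units, "unit_system"))
  if (any(length_nm < 0)) stop("length must be non-negative")
  length_nm / units$rc_nm
}

#' Convert a reduced length (rc) back to nm
#'
#' @param length_rc Non-negative length(s) in rc.
#' @param units A [unit_system()].
#' @return Length(s) in nm.
#' @export
to_physical <- function(length_rc, units = unit_system()) {
  stopifnot(inherits(units, "unit_system"))
  if (any(length_rc < 0)) stop("length must be non-negative")
  length_rc * units$rc_nm
}

#' Soft-repulsion interaction table
#'
#' Conservative repulsion amplitudes `a_ij` (in kBT/rc) for every species
#' pair, plus the amplitudes of the two confining walls. Species 1 is the
#' solvent; species `1 + k` is brush population `k`. By convention all
#' same-type contacts share one amplitude and solvent-brush contacts are
#' slightly more repulsive, reflecting a solvent that is marginally poorer
#' for the brush than for itself.
#'
#' @param n_populations Number of brush populations (1 for the uniform brush,
#'   3 for the three-length brush).
#' @param a_same Amplitude for same-type contacts (default 25, the standard
#'   companion of a reduced solvent density of 3).
#' @param a_solvent_brush Amplitude for solvent-brush contacts (default 28).
#' @param a_wall_surface Amplitude of the soft grafting-surface wall.
#' @param a_wall_tip Amplitude of the soft tip wall.
#' @param exclude_bonded If `TRUE`, bonded neighbours do not interact through
#'   the pair potential (off by default; soft chains usually keep it).
#' @return An object of class `interaction_table`.
#' @export
interaction_table <- function(n_populations = 1, a_same = 25,
                              a_solvent_brush = 28,
                              a_wall_surface = 25, a_wall_tip = 25,
                              exclude_bonded = FALSE) {
  stopifnot(n_populations >= 1, a_same >= 0, a_solvent_brush >= 0,
            a_wall_surface >= 0, a_wall_tip >= 0)
  if (a_solvent_brush < a_same)
    stop("solvent-brush repulsion must be at least the same-type repulsion")
  S <- n_populations + 1
  a <- matrix(a_same, S, S)
  a[1, -1] <- a_solvent_brush
  a[-1, 1] <- a_solvent_brush
  structure(
    list(a = a, a_wall_surface = a_wall_surface, a_wall_tip = a_wall_tip,
         exclude_bonded = exclude_bonded),
    class = "interaction_table")
}

#' Brush architecture: populations of grafted chains
#'
#' A brush is described by one or more chain populations, each with a number
#' of beads per chain `N`, a grafting density `Gamma` (chains per nm^2) and a
#' bond spring constant `kappa` (kBT/rc^2), plus a mobility class: "liquid"
#' grafts diffuse laterally on the surface, "solid" grafts are immobile.
#'
#' @param populations A data.frame with columns `N`, `Gamma`, `kappa`.
#' @param mobility `"liquid"` or `"solid"`.
#' @return An object of class `brush_architecture`.
#' @seealso [normal_architecture()], [cancer_architecture()]
#' @export
brush_architecture <- function(populations, mobility = c("liquid", "solid")) {
  mobility <- match.arg(mobility)
  stopifnot(is.data.frame(populations),
            all(c("N", "Gamma", "kappa") %in% names(populations)))
  if (any(populations$N < 1)) stop("every N must be >= 1")
  if (any(populations$Gamma <= 0)) stop("grafting density must be positive")
  if (any(populations$kappa <= 0)) stop("spring constant must be positive")
  structure(
    list(populations = populations[, c("N", "Gamma", "kappa")],
         mobility = mobility),
    class = "brush_architecture")
}

#' Uniform brush preset (normal epithelial cell)
#'
#' One population: chains of N = 27 beads at grafting density
#' Gamma = 0.78 nm^-2 with soft springs (kappa = 100 kBT/rc^2).
#'
#' @param mobility `"liquid"` (default; biological brushes) or `"solid"`.
#' @param kappa Bond spring constant; default 100.
#' @return A `brush_architecture`.
#' @export
normal_architecture <- function(mobility = "liquid", kappa = 100) {
  brush_architecture(
    data.frame(N = 27, Gamma = 0.78, kappa = kappa),
    mobility = mobility)
}

#' Three-length brush preset (cancerous epithelial cell)
#'
#' Three populations: N = 5, 30, 42 beads at grafting densities
#' Gamma = 1.76, 0.49, 0.20 nm^-2. All bonds share one spring constant:
#' kappa = 100 for the soft variant, kappa = 2000 for the stiff variant
#' (kappa_stiff = 20 kappa_soft).
#'
#' @param stiffness `"soft"` or `"stiff"`.
#' @param mobility `"liquid"` (default) or `"solid"`.
#' @return A `brush_architecture`.
#' @export
cancer_architecture <- function(stiffness = c("soft", "stiff"),
                                mobility = "liquid") {
  stiffness <- match.arg(stiffness)
  kappa <- if (stiffness == "soft") 100 else 2000
  brush_architecture(
    data.frame(N = c(5, 30, 42),
               Gamma = c(1.76, 0.49, 0.20),
               kappa = kappa),
    mobility = mobility)
}

#' Tip model
#'
#' The simulated tip is a planar soft wall at height `h` (the probe's contact
#' area is much larger than the simulation cell); the nominal probe radius
#' enters only when reporting `F/R` through the Derjaguin transform.
#'
#' @param R_um Nominal probe radius in micrometres (default 2.5).
#' @return An object of class `tip_model`.
#' @export
tip_model <- function(R_um = 2.5) {
  stopifnot(is.numeric(R_um), length(R_um) == 1, R_um > 0)
  structure(list(R_um = R_um, geometry = "planar"), class = "tip_model")
}

#' Full simulation parameter set
#'
#' Collects every physical and algorithmic constant of a run in reduced
#' units. Lengths are in rc, energies in kBT. The lateral box is the square
#' cross-section of the studied cell patch (area 20.5 nm^2 by default, i.e.
#' about 7.0 rc per side); z is bounded by the grafting surface at 0 and the
#' tip wall at `h`.
#'
#' @param units A [unit_system()].
#' @param interactions An [interaction_table()]; if `NULL`, one matching the
#'   architecture's population count is created with default amplitudes.
#' @param architecture A [brush_architecture()].
#' @param tip A [tip_model()].
#' @param area_nm2 Lateral cell area in nm^2 (default 20.5).
#' @param h Tip-surface separation in rc. Default is the middle of the sweep.
#' @param h_range_nm The sweep range of tip-surface separations, in nm
#'   (default 2.8 to 17.5).
#' @param activity Solvent activity z (controls the chemical potential,
#'   mu = kBT log z up to the de Broglie constant). The default is calibrated
#'   so that the default interacting fluid (a = 25) sits at reduced bulk
#'   density rho rc^3 = 3; see [calibrate_activity()].
#' @param target_density Reduced solvent bulk density the activity is meant
#'   to reproduce (used when pre-filling boxes).
#' @param max_displacement Initial Monte Carlo trial displacement in rc.
#' @param n_equilibration,n_production Sweep counts.
#' @param sample_interval Sweeps between samples.
#' @param gc_fraction Insertion/deletion attempts per sweep as a fraction of
#'   the current solvent count.
#' @param seed Integer seed; identical (configuration, seed) pairs give
#'   bit-identical runs.
#' @param bond_rest_length Harmonic bond rest length r0 in rc (default 0).
#' @param bin_width Density-profile bin width in rc.
#' @param graft_jitter Uniform jitter applied to the graft lattice, in rc.
#' @return An object of class `simulation_parameters`.
#' @export
simulation_parameters <- function(units = unit_system(),
                                  interactions = NULL,
                                  architecture = normal_architecture(),
                                  tip = tip_model(),
                                  area_nm2 = 20.5,
                                  h = NULL,
                                  h_range_nm = c(2.8, 17.5),
                                  activity = default_activity(),
                                  target_density = 3,
                                  max_displacement = 0.35,
                                  n_equilibration = 800,
                                  n_production = 2000,
                                  sample_interval = 10,
                                  gc_fraction = 0.1,
                                  seed = 1,
                                  bond_rest_length = 0,
                                  bin_width = 0.25,
                                  graft_jitter = 0.1) {
  stopifnot(inherits(units, "unit_system"),
            inherits(architecture, "brush_architecture"),
            inherits(tip, "tip_model"))
  if (is.null(interactions))
    interactions <- interaction_table(
      n_populations = nrow(architecture$populations))
  stopifnot(inherits(interactions, "interaction_table"))
  side_rc <- to_reduced(sqrt(area_nm2), units)
  h_range_rc <- to_reduced(h_range_nm, units)
  if (is.null(h)) h <- mean(h_range_rc)
  p <- structure(
    list(units = units, interactions = interactions,
         architecture = architecture, tip = tip,
         area_nm2 = area_nm2, box_xy = c(side_rc, side_rc),
         h = h, h_range_rc = h_range_rc,
         activity = activity, target_density = target_density,
         max_displacement = max_displacement,
         n_equilibration = n_equilibration, n_production = n_production,
         sample_interval = sample_interval, gc_fraction = gc_fraction,
         seed = seed, bond_rest_length = bond_rest_length,
         bin_width = bin_width, graft_jitter = graft_jitter),
    class = "simulation_parameters")
  p
}

#' Default solvent activity for the standard fluid
#'
#' The activity that holds the default soft fluid (same-type repulsion
#' a = 25 kBT/rc) at reduced bulk density rho rc^3 = 3. The value was
#' obtained once with [calibrate_activity()] on a brush-free box and is
#' re-verified by the package's test suite; pass your own activity whenever
#' the interaction amplitudes change.
#'
#' @return The calibrated activity (a scalar).
#' @export
default_activity <- function() 6.0e5

#' Validate a simulation parameter set
#'
#' Checks every structural invariant (positive lengths and densities, wall
#' and box geometry, sane sweep schedule, chain counts that round to at
#' least one chain) and returns the parameters invisibly when everything
#' holds; otherwise throws a single error listing every failed check.
#'
#' @param params A [simulation_parameters()] object.
#' @return `params`, invisibly, when valid.
#' @export
validate_parameters <- function(params) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  chk(inherits(params, "simulation_parameters"),
      "not a simulation_parameters object")
  if (length(problems)) stop(paste(problems, collapse = "; "))

  u <- params$units
  chk(u$rc_nm > 0, "rc_nm must be positive")
  pops <- params$architecture$populations
  chk(all(pops$N >= 1), "every N must be >= 1")
  chk(all(pops$Gamma > 0), "grafting density must be positive")
  chk(all(pops$kappa > 0), "spring constant must be positive")
  a <- params$interactions$a
  chk(isTRUE(all.equal(a, t(a))), "interaction matrix must be symmetric")
  chk(all(a >= 0), "interaction amplitudes must be non-negative")
  chk(nrow(a) == nrow(pops) + 1,
      "interaction matrix size must be populations + 1")
  if (nrow(a) >= 2)
    chk(all(a[1, -1] >= a[1, 1]),
        "solvent-brush repulsion must be >= solvent-solvent repulsion")
  chk(params$area_nm2 > 0, "cell area must be positive")
  chk(all(params$box_xy > 0), "box lengths must be positive")
  chk(abs(prod(params$box_xy) - params$area_nm2 / u$rc_nm^2) <
        1e-9 * params$area_nm2 / u$rc_nm^2,
      "lateral box area inconsistent with cell area")
  chk(params$h > 0, "h must be positive")
  chk(diff(params$h_range_rc) > 0, "h range must be increasing")
  chk(params$activity >= 0, "activity must be non-negative")
  chk(params$max_displacement > 0, "max_displacement must be positive")
  chk(params$n_equilibration >= 0 && params$n_production >= 0,
      "sweep counts must be non-negative")
  chk(params$sample_interval >= 1, "sample_interval must be >= 1")
  chk(params$bond_rest_length >= 0, "bond rest length must be non-negative")
  chk(params$bin_width > 0, "bin width must be positive")
  counts <- try(chain_counts(params$architecture, params$area_nm2),
                silent = TRUE)
  if (inherits(counts, "try-error"))
    chk(FALSE, "chain count rounds to zero for at least one population")

  if (length(problems))
    stop("invalid parameters: ", paste(problems, collapse = "; "))
  invisible(params)
}

#' Chains per population for a given cell area
#'
#' The number of chains of population i is `round(Gamma_i * area)`, the
#' nearest integer to the expected count, and must be at least 1.
#'
#' @param architecture A [brush_architecture()].
#' @param area_nm2 Cell area in nm^2.
#' @return Integer vector of chain counts, one per population.
#' @examples
#' chain_counts(normal_architecture(), 20.5)          # 16
#' chain_counts(cancer_architecture("soft"), 20.5)    # 36 10 4
#' @export
chain_counts <- function(architecture, area_nm2 = 20.5) {
  stopifnot(inherits(architecture, "brush_architecture"), area_nm2 > 0)
  counts <- round(architecture$populations$Gamma * area_nm2)
  if (any(counts < 1))
    stop("chain count rounds to zero: an empty brush is not a brush")
  as.integer(counts)
}

#' @export
print.simulation_parameters <- function(x, ...) {
  pops <- x$architecture$populations
  cat("simulation_parameters\n")
  cat(sprintf("  box: %.3f x %.3f rc (area %.1f nm^2), h = %.3f rc\n",
              x$box_xy[1], x$box_xy[2], x$area_nm2, x$h))
  cat(sprintf("  brush: %d population(s), mobility %s\n",
              nrow(pops), x$architecture$mobility))
  for (i in seq_len(nrow(pops)))
    cat(sprintf("    N = %d, Gamma = %.2f nm^-2, kappa = %g kBT/rc^2\n",
                pops$N[i], pops$Gamma[i], pops$kappa[i]))
  cat(sprintf("  activity = %.4g, seed = %d\n", x$activity, x$seed))
  invisible(x)
}
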