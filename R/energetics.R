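#' Soft-repulsive pair potential
#'
#' The conservative (DPD-type) soft repulsion between two beads,
#' `U(r) = (a/2) (1 - r)^2` below the cutoff (r < 1) and 0 beyond, in reduced
#' units (r in rc, U in kBT). Finite at full overlap (`U(0) = a/2`),
#' continuous and once-differentiable at the cutoff.
#'
#' @param r Centre-centre distance(s) in rc; must be non-negative.
#' @param a Repulsion amplitude in kBT/rc; must be non-negative.
#' @return Energy in kBT.
#' @examples
#' pair_potential(0, 25)    # 12.5
#' pair_potential(0.5, 25)  # 3.125
#' @export
pair_potential <- function(r, a) {
  if (any(r < 0)) stop("distance must be non-negative")
  if (any(a < 0)) stop("amplitude must be non-negative")
  ifelse(r < 1, 0.5 * a * (1 - r)^2, 0)
}

#' Harmonic bond potential
#'
#' `U(r) = (kappa/2) (r - r0)^2` for a freely rotating harmonic spring.
#'
#' @param r Bond length(s) in rc; non-negative.
#' @param kappa Spring constant in kBT/rc^2.
#' @param r0 Rest length in rc (default 0).
#' @return Energy in kBT.
#' @export
bond_potential <- function(r, kappa, r0 = 0) {
  if (any(r < 0)) stop("bond length must be non-negative")
  0.5 * kappa * (r - r0)^2
}

#' Soft wall potential
#'
#' The confining walls use the same soft quadratic family as the pair term:
#' `U(gap) = (a_w/2) (1 - gap)^2` for `gap < 1`, 0 otherwise. The gap may be
#' negative - a particle can penetrate past the nominal plane, which is what
#' makes the surface deformable.
#'
#' @param gap Distance(s) to the wall plane in rc; may be negative.
#' @param a_w Wall amplitude in kBT/rc.
#' @return Energy in kBT.
#' @export
wall_potential <- function(gap, a_w) {
  if (any(a_w < 0)) stop("amplitude must be non-negative")
  ifelse(gap < 1, 0.5 * a_w * (1 - gap)^2, 0)
}

#' Total potential energy of a particle system
#'
#' Sums the pair term over all minimum-image pairs within the cutoff
#' (periodic in x and y only), the harmonic bond terms, and the two wall
#' terms, returning the breakdown by component. The surface wall acts on
#' non-grafted particles only (graft beads live in the surface plane); the
#' tip wall acts on every particle.
#'
#' @param system A `brush_system` (see [build_normal_system()]).
#' @param interactions An [interaction_table()]; defaults to the table the
#'   system was built with.
#' @return A list of class `energy_breakdown` with components `pair`, `bond`,
#'   `wall_surface`, `wall_tip` and `total` (kBT).
#' @export
total_energy <- function(system, interactions = system$interactions) {
  stopifnot(inherits(system, "brush_system"),
            inherits(interactions, "interaction_table"))
  out <- cpp_energy_breakdown(unclass(system), unclass(interactions))
  structure(out, class = "energy_breakdown")
}

#' Incremental energy change for a proposed move
#'
#' Computes `total_energy(after) - total_energy(before)` using only the
#' neighbourhood of the affected particle. Three move kinds are supported:
#' a displacement of particle `i` to `new_pos`, an insertion of a solvent
#' particle at `new_pos`, and a deletion of particle `i`.
#'
#' @param system A `brush_system`.
#' @param move One of `"displace"`, `"insert"`, `"delete"`.
#' @param i Particle index (1-based), for displacement and deletion.
#' @param new_pos Numeric length-3 position, for displacement and insertion.
#' @param interactions Interaction table (defaults to the system's).
#' @return Energy change in kBT.
#' @export
delta_energy <- function(system, move = c("displace", "insert", "delete"),
                         i = NULL, new_pos = NULL,
                         interactions = system$interactions) {
  move <- match.arg(move)
  sys <- unclass(system)
  tab <- unclass(interactions)
  switch(move,
    displace = {
      stopifnot(!is.null(i), !is.null(new_pos), length(new_pos) == 3)
      if (system$mobility[i] == 2L)
        stop("cannot displace a solid-graft particle")
      cpp_delta_displacement(sys, tab, as.integer(i), as.numeric(new_pos))
    },
    insert = {
      stopifnot(!is.null(new_pos), length(new_pos) == 3)
      cpp_insertion_energy(sys, tab, as.numeric(new_pos))
    },
    delete = {
      stopifnot(!is.null(i))
      if (system$species[i] != 0L) stop("only solvent particles can be deleted")
      -cpp_particle_energy(sys, tab, as.integer(i))
    })
}

#' Enumerate interacting pairs
#'
#' Returns every pair of particles whose minimum-image distance is below the
#' cutoff (1 rc), each pair exactly once. The cell-list route falls back to
#' an all-pairs scan when the box is too small for 3 cells per lateral
#' dimension; `method = "all"` forces the brute-force enumeration (used as
#' the correctness oracle in the test suite).
#'
#' @param system A `brush_system`.
#' @param method `"cell"` (default) or `"all"`.
#' @return A two-column integer matrix of 1-based particle indices.
#' @export
build_cell_list <- function(system, method = c("cell", "all")) {
  method <- match.arg(method)
  m <- cpp_pair_list(unclass(system), unclass(system$interactions), method)
  colnames(m) <- c("i", "j")
  m
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "energy (kBT): pair %.6g + bond %.6g + wall_surface %.6g + wall_tip %.6g = %.6g\n",
    x$pair, x$bond, x$wall_surface, x$wall_tip, x$total))
  invisible(x)
}
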