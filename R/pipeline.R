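# Orchestration: sweep the tip-surface separation, aggregate observables,
# fit the theory layer, and compare conditions.

#' Experiment configuration
#'
#' A plain-list description of one experiment (preset, mobility, stiffness,
#' separation grid, schedule, seed) that can be serialized to JSON and back
#' without loss. Lengths may be supplied in rc or nm via `h_unit`.
#'
#' @param preset `"normal"` (uniform brush) or `"cancer"` (three lengths).
#' @param stiffness `"soft"` or `"stiff"` (cancer preset only; normal is
#'   soft).
#' @param mobility `"liquid"` or `"solid"` grafts.
#' @param h_grid Separations to sweep; default 8 points spanning 2.8-17.5 nm.
#' @param h_unit `"rc"` or `"nm"`.
#' @param seed Integer seed for the whole experiment.
#' @param n_equilibration,n_production,sample_interval Schedule per point.
#' @param activity Solvent activity (default [default_activity()]).
#' @param ... Further [simulation_parameters()] overrides (e.g. `bin_width`,
#'   `bond_rest_length`, `gc_fraction`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("normal", "cancer"),
                              stiffness = c("soft", "stiff"),
                              mobility = c("liquid", "solid"),
                              h_grid = NULL, h_unit = c("nm", "rc"),
                              seed = 1,
                              n_equilibration = 800, n_production = 2000,
                              sample_interval = 10,
                              activity = default_activity(), ...) {
  preset <- match.arg(preset)
  stiffness <- match.arg(stiffness)
  mobility <- match.arg(mobility)
  h_unit <- match.arg(h_unit)
  if (is.null(h_grid)) {
    h_grid <- seq(2.8, 17.5, length.out = 8)
    h_unit <- "nm"
  }
  structure(
    list(preset = preset, stiffness = stiffness, mobility = mobility,
         h_grid = h_grid, h_unit = h_unit, seed = seed,
         n_equilibration = n_equilibration, n_production = n_production,
         sample_interval = sample_interval, activity = activity,
         extra = list(...)),
    class = "experiment_config")
}

config_to_params <- function(config, h_rc) {
  arch <- if (config$preset == "normal")
    normal_architecture(mobility = config$mobility)
  else
    cancer_architecture(config$stiffness, mobility = config$mobility)
  args <- c(list(architecture = arch, h = h_rc, seed = config$seed,
                 n_equilibration = config$n_equilibration,
                 n_production = config$n_production,
                 sample_interval = config$sample_interval,
                 activity = config$activity),
            config$extra)
  do.call(simulation_parameters, args)
}

#' Run a full compression experiment
#'
#' Builds the configured system at every separation of the grid, runs the
#' grand-canonical chain at each, and aggregates: the excess force-distance
#' profile with Derjaguin `F/R`, the density profile and brush height at the
#' largest (uncompressed) separation, a graft-meandering trace, and an
#' Alexander-de Gennes fit of the `F/R` curve. Deterministic given the
#' configuration (including its seed): re-running reproduces every number.
#'
#' @param config An [experiment_config()] or a path to a JSON file written
#'   by [write_config()].
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV plus the resolved configuration as JSON.
#' @param fit Fit the theory layer (default TRUE); failures are recorded in
#'   the bundle rather than raised.
#' @return An object of class `experiment_bundle`.
#' @export
run_experiment <- function(config, outdir = NULL, fit = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "experiment_config"))
  units <- unit_system()
  h_rc <- if (config$h_unit == "nm") to_reduced(config$h_grid, units)
          else config$h_grid
  h_rc <- sort(h_rc)

  runs <- vector("list", length(h_rc))
  failures <- list()
  for (k in seq_along(h_rc)) {
    params <- config_to_params(config, h_rc[k])
    sys <- build_system(params)
    runs[[k]] <- tryCatch(run_chain(sys, params),
                          error = function(e) e)
    if (inherits(runs[[k]], "error"))
      failures[[sprintf("h=%.3f", h_rc[k])]] <- conditionMessage(runs[[k]])
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (sum(ok) < 2) stop("too few successful runs: ",
                        paste(unlist(failures), collapse = "; "))
  profile <- force_profile(runs[ok])
  profile <- derjaguin_transform(profile, units = units)

  ref <- runs[ok][[sum(ok)]]  # largest h: uncompressed reference
  density <- density_profile(ref)
  heights <- brush_height(density)
  trace <- graft_trace(ref, chain_id = 1)

  fit_res <- NULL
  if (fit) {
    n_pop <- if (config$preset == "normal") 1 else 3
    curve <- data.frame(h = profile$h_rc, F_over_R = profile$F_over_R)
    fit_res <- tryCatch(
      fit_force_profile(curve, n_populations = n_pop),
      error = function(e) {
        failures$fit <<- conditionMessage(e)
        NULL
      })
  }

  bundle <- structure(
    list(config = config, h_rc = h_rc[ok], runs = runs[ok],
         profile = profile, density = density, heights = heights,
         trace = trace, fit = fit_res, failures = failures,
         provenance = list(seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("brushmc")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "experiment_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write an experiment bundle's tables to a directory
#'
#' Emits self-describing TSV tables (force profile, density profile,
#' meander trace, per-run observable streams) plus the resolved
#' configuration as JSON.
#'
#' @param bundle An `experiment_bundle`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(bundle$config, file.path(outdir, "config.json"))
  write_table_tsv(bundle$profile, file.path(outdir, "force_profile.tsv"),
                  comment = c("excess tip force vs separation",
                              "h_rc [rc], h_nm [nm], F [kBT/rc], SE [kBT/rc]",
                              "P [kBT/rc^3], F_over_R [kBT/rc^2]"))
  write_table_tsv(bundle$density, file.path(outdir, "density_profile.tsv"),
                  comment = c(sprintf("densities at h = %.4f rc (reference)",
                                      attr(bundle$density, "h")),
                              "z [rc], rho_brush [rc^-3], rho_solvent [rc^-3]"))
  write_table_tsv(bundle$trace, file.path(outdir, "meander_trace.tsv"),
                  comment = "graft-end xy trace [rc], unwrapped")
  for (k in seq_along(bundle$runs))
    write_table_tsv(bundle$runs[[k]]$samples,
                    file.path(outdir, sprintf("samples_h%02d.tsv", k)),
                    comment = sprintf(
                      "h = %.4f rc; sweep, n_solvent, energy [kBT], tip_force [kBT/rc]",
                      bundle$runs[[k]]$h))
  invisible(outdir)
}

#' Compare two matched conditions
#'
#' Per-separation force differences with pooled uncertainties for a named
#' contrast (e.g. soft vs stiff, liquid vs solid, normal vs cancer). Each
#' side is one experiment bundle or a list of bundles (replicate seeds)
#' sharing the same separation grid. Verdict per separation: `"greater"`,
#' `"lesser"`, or `"indistinguishable"` at 2 pooled standard errors.
#'
#' @param a,b An `experiment_bundle` or list of bundles (side A and B).
#' @param contrast Label for the comparison.
#' @param normalized Compare normalized profiles (each side's excess force
#'   divided by its maximum) instead of raw forces.
#' @return An object of class `condition_comparison`: data.frame with
#'   `h_rc`, `mean_a`, `mean_b`, `diff`, `SE`, `verdict`.
#' @export
compare_conditions <- function(a, b, contrast = "A_vs_B",
                               normalized = FALSE) {
  as_group <- function(x)
    if (inherits(x, "experiment_bundle")) list(x) else x
  ga <- as_group(a); gb <- as_group(b)
  href <- ga[[1]]$profile$h_rc
  for (bd in c(ga, gb))
    if (!isTRUE(all.equal(bd$profile$h_rc, href)))
      stop("bundles do not share a separation grid")
  pool <- function(grp) {
    Fm <- sapply(grp, function(bd) {
      f <- bd$profile$F
      if (normalized) f / max(f) else f
    })
    SE <- sapply(grp, function(bd) {
      s <- bd$profile$SE
      if (normalized) s / max(bd$profile$F) else s
    })
    Fm <- matrix(Fm, nrow = length(href))
    SE <- matrix(SE, nrow = length(href))
    n <- ncol(SE)
    # propagated per-run errors plus between-replicate scatter: finite
    # blocks underestimate slow modes, the replicate spread recovers them
    se_prop <- sqrt(rowSums(SE^2)) / n
    se_rep <- if (n > 1) apply(Fm, 1, stats::sd) / sqrt(n) else 0
    list(mean = rowMeans(Fm), se = sqrt(se_prop^2 + se_rep^2))
  }
  pa <- pool(ga); pb <- pool(gb)
  d <- pa$mean - pb$mean
  se <- sqrt(pa$se^2 + pb$se^2)
  verdict <- ifelse(abs(d) <= 2 * se, "indistinguishable",
                    ifelse(d > 0, "greater", "lesser"))
  out <- data.frame(h_rc = href, mean_a = pa$mean, mean_b = pb$mean,
                    diff = d, SE = se, verdict = verdict)
  attr(out, "contrast") <- contrast
  attr(out, "normalized") <- normalized
  class(out) <- c("condition_comparison", "data.frame")
  out
}
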