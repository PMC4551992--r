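# Plain-text interchange: extended-XYZ snapshots, TSV tables with
# self-describing headers, and JSON round-tripping of configurations.

#' Write a snapshot as extended XYZ
#'
#' One frame: particle count, a comment line carrying the box, wall
#' separation, seed and sweep index, then one `label x y z` line per
#' particle (coordinates in rc). Labels are `S` for solvent and `B<k>` for
#' brush population k, with `*` appended for graft beads. Snapshot exchange
#' only - bond topology is not representable in XYZ.
#'
#' @param system A `brush_system`.
#' @param path Output file.
#' @param seed,sweep Provenance for the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, seed = NA, sweep = NA) {
  n <- nrow(system$positions)
  lab <- ifelse(system$species == 0L, "S",
                paste0("B", system$species))
  lab <- paste0(lab, ifelse(system$mobility > 0L, "*", ""))
  comment <- sprintf("box_xy=%.9g,%.9g h=%.9g seed=%s sweep=%s",
                     system$box[1], system$box[2], system$h,
                     as.character(seed), as.character(sweep))
  lines <- c(as.character(n), comment,
             sprintf("%s %.12g %.12g %.12g", lab,
                     system$positions[, 1], system$positions[, 2],
                     system$positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended-XYZ snapshot
#'
#' Inverse of [write_xyz()] for positions, species and graft flags; bonds
#' and the interaction table are not stored in XYZ and come back empty.
#'
#' @param path File written by [write_xyz()].
#' @return A `brush_system` without bonds.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  comment <- lines[2]
  getval <- function(key) {
    m <- regmatches(comment, regexpr(paste0(key, "=[^ ]+"), comment))
    sub(paste0(key, "="), "", m)
  }
  box <- as.numeric(strsplit(getval("box_xy"), ",")[[1]])
  h <- as.numeric(getval("h"))
  parts <- strsplit(lines[2 + seq_len(n)], " +")
  lab <- vapply(parts, `[`, character(1), 1)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  graft <- grepl("\\*$", lab)
  lab <- sub("\\*$", "", lab)
  species <- integer(length(lab))
  brushy <- lab != "S"
  species[brushy] <- as.integer(sub("^B", "", lab[brushy]))
  mobility <- ifelse(graft, 1L, 0L)
  ord <- order(species == 0L)  # brush first
  pos <- pos[ord, , drop = FALSE]
  species <- species[ord]; mobility <- mobility[ord]
  n_brush <- sum(species > 0L)
  new_brush_system(pos, species, mobility, matrix(numeric(0), 0, 4),
                   box, h, n_brush,
                   chain_id = rep(NA_integer_, n_brush),
                   interactions = interaction_table(
                     n_populations = max(1L, max(species))))
}

#' Write a data.frame as TSV with a commented header
#'
#' @param df Data.frame.
#' @param path Output file.
#' @param comment Character vector of comment lines (written with a leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path Input file.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Serialize an experiment configuration to JSON
#'
#' Lossless round trip: `read_config(write_config(cfg, f))` reproduces the
#' configuration to full double precision.
#'
#' @param config An [experiment_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an experiment configuration from JSON
#' @param path File written by [write_config()].
#' @return An [experiment_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- experiment_config(
    preset = raw$preset, stiffness = raw$stiffness,
    mobility = raw$mobility, h_grid = as.numeric(raw$h_grid),
    h_unit = raw$h_unit, seed = raw$seed,
    n_equilibration = raw$n_equilibration,
    n_production = raw$n_production,
    sample_interval = raw$sample_interval,
    activity = raw$activity)
  if (length(raw$extra)) cfg$extra <- raw$extra
  cfg
}
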