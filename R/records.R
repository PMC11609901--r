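#' Construct a run sequence
#'
#' A run sequence is the ordered table of analyses from one instrument run
#' (one autosampler tray), together with run-level metadata: the HTC
#' reactor type, the equilibration water used, the autosampler type and the
#' run date. A typical sequence is a calibration-standard block, then
#' samples with an interleaved quality-control standard, then a closing
#' standard block.
#'
#' @param records A data frame with one row per analysis and columns
#'   `position` (1-based, strictly increasing, unique), `material_id`,
#'   `role` (one of `"standard"`, `"qc"`, `"sample"`, `"blank"`), the raw
#'   permil deltas `d2H_raw`, `d13C_raw`, `d18O_raw` (`NA` = channel
#'   absent), peak areas `area_H2`, `area_CO` (arbitrary units, `>= 0`),
#'   `mass_mg`, and optionally `time_offset` (minutes since the samples
#'   were placed in the autosampler).
#' @param reactor `"glassy_carbon"` or `"chromium"`. A chromium-filled
#'   reactor traps sample oxygen as chromium oxide, so no CO is formed and
#'   only the `d2H_raw` channel may carry values.
#' @param equilibration_water_id Identifier of the equilibration water used
#'   for this run (see [read_waters()]), or `NULL` if the samples were not
#'   equilibrated.
#' @param autosampler `"zero_blank"` (evacuated, helium-filled) or
#'   `"argon_hood"` (argon-flushed tray cover).
#' @param run_date Optional date string, kept as metadata.
#' @param seed Optional integer recorded by the simulator.
#' @return An object of class `run_sequence`: a list with elements
#'   `records` (a tibble), `reactor`, `equilibration_water_id`,
#'   `autosampler`, `run_date`, `seed`.
#' @seealso [generate_run()], [reduce_run()], [read_run_csv()]
#' @export
run_sequence <- function(records,
                         reactor = c("glassy_carbon", "chromium"),
                         equilibration_water_id = NULL,
                         autosampler = c("argon_hood", "zero_blank"),
                         run_date = NULL,
                         seed = NULL) {
  reactor <- match.arg(reactor)
  autosampler <- match.arg(autosampler)
  records <- as_run_records(records)

  if (nrow(records) == 0) stop("run has no records", call. = FALSE)
  if (anyDuplicated(records$position) ||
      any(diff(records$position) <= 0)) {
    stop("record positions must be strictly increasing and unique",
         call. = FALSE)
  }
  for (col in unname(RAW_COLS)) {
    v <- records[[col]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite permil value in column ", col, call. = FALSE)
    }
  }
  for (col in c("area_H2", "area_CO")) {
    v <- records[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop("negative peak area in column ", col, call. = FALSE)
    }
  }
  if (reactor == "chromium" &&
      (any(!is.na(records$d13C_raw)) || any(!is.na(records$d18O_raw)))) {
    stop("chromium-reactor runs carry d2H only: no CO is formed, so ",
         "d13C_raw and d18O_raw must be absent", call. = FALSE)
  }

  structure(
    list(
      records = records,
      reactor = reactor,
      equilibration_water_id = equilibration_water_id,
      autosampler = autosampler,
      run_date = run_date,
      seed = seed
    ),
    class = "run_sequence"
  )
}

# Coerce a data frame of analyses to the canonical record schema.
as_run_records <- function(records) {
  records <- as.data.frame(records)
  required <- c("position", "material_id", "role")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("run records lack required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_role <- !records$role %in% c("standard", "qc", "sample", "blank")
  if (any(bad_role)) {
    stop("invalid role in row(s) ", paste(which(bad_role), collapse = ", "),
         ": must be standard/qc/sample/blank", call. = FALSE)
  }
  numeric_cols <- c("position", "time_offset", unname(RAW_COLS),
                    "area_H2", "area_CO", "mass_mg")
  for (col in numeric_cols) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
    records[[col]] <- as.numeric(records[[col]])
  }
  records$material_id <- as.character(records$material_id)
  records$role <- as.character(records$role)
  tibble::as_tibble(records[, c("position", "time_offset", "material_id",
                                "role", "d2H_raw", "d13C_raw", "d18O_raw",
                                "area_H2", "area_CO", "mass_mg")])
}

#' @export
print.run_sequence <- function(x, ...) {
  cat(sprintf("<run_sequence> %d analyses | reactor: %s | autosampler: %s\n",
              nrow(x$records), x$reactor, x$autosampler))
  if (!is.null(x$equilibration_water_id)) {
    cat("  equilibration water:", x$equilibration_water_id, "\n")
  }
  if (!is.null(x$seed)) cat("  simulator seed:", x$seed, "\n")
  roles <- table(x$records$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Isotope channels present in a run
#'
#' A channel is present when at least one record carries a raw delta for
#' it. Chromium-reactor runs can only present the `H2` channel.
#'
#' @param run A [run_sequence()].
#' @return Character vector, subset of `c("H2", "C13", "O18")`.
#' @export
run_isotopes <- function(run) {
  stopifnot(inherits(run, "run_sequence"))
  present <- vapply(RAW_COLS, function(col) any(!is.na(run$records[[col]])),
                    logical(1))
  names(RAW_COLS)[present]
}

#' Build a reference-material registry
#'
#' Reference materials carry the certified delta values (VSMOW scale for
#' hydrogen and oxygen, VPDB for carbon) used for two-point calibration,
#' plus the material class, the exchangeable-hydrogen fraction `x_e`
#' (when characterised by two-water equilibration), and elemental N and S
#' contents used by the interference screen. Materials that carry no
#' hydroxyl groups (e.g. polyethylene foil) do not exchange hydrogen at
#' all: set `exchanges_h = FALSE`, which forces `x_e = 0`.
#'
#' @param materials A data frame with columns `id`, `material_class`
#'   (`"cellulose"`, `"sugar"`, `"wood"`, `"leaf"`, or `"other"`), the
#'   certified permil values `d2H`, `d13C`, `d18O` (`NA` where not
#'   certified), `x_e` (fraction in `[0, 1)`, `NA` if unknown),
#'   `n_content_pct`, `s_content_pct`, and logical `exchanges_h`.
#' @return A tibble of class `material_registry`.
#' @seealso [default_materials()], [read_materials()]
#' @export
reference_materials <- function(materials) {
  materials <- as.data.frame(materials)
  if (!all(c("id", "material_class") %in% names(materials))) {
    stop("materials need at least `id` and `material_class`", call. = FALSE)
  }
  classes <- c("cellulose", "sugar", "wood", "leaf", "other")
  if (any(!materials$material_class %in% classes)) {
    stop("material_class must be one of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("d2H", "d13C", "d18O", "x_e", "n_content_pct",
                "s_content_pct")) {
    if (!col %in% names(materials)) materials[[col]] <- NA_real_
    materials[[col]] <- as.numeric(materials[[col]])
  }
  if (!"exchanges_h" %in% names(materials)) materials$exchanges_h <- TRUE
  materials$exchanges_h <- as.logical(materials$exchanges_h)
  materials$x_e[!materials$exchanges_h] <- 0

  if (anyDuplicated(materials$id)) {
    stop("duplicate material id(s)", call. = FALSE)
  }
  xe <- materials$x_e
  if (any(!is.na(xe) & (xe < 0 | xe >= 1))) {
    stop("x_e must lie in [0, 1)", call. = FALSE)
  }
  for (col in c("d2H", "d13C", "d18O")) {
    v <- materials[[col]]
    if (any(!is.na(v) & abs(v) > 1000)) {
      stop("certified ", col, " outside [-1000, 1000] permil",
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(materials[, c("id", "material_class", "d2H",
                                         "d13C", "d18O", "x_e",
                                         "n_content_pct", "s_content_pct",
                                         "exchanges_h")])
  out$id <- as.character(out$id)
  class(out) <- c("material_registry", class(out))
  out
}

#' Build an equilibration-water registry
#'
#' @param waters A data frame with columns `id`, `d2H` (permil VSMOW,
#'   `> -1000`) and optionally `uncertainty` (permil).
#' @return A tibble of class `water_registry`.
#' @seealso [default_waters()], [read_waters()]
#' @export
equilibration_waters <- function(waters) {
  waters <- as.data.frame(waters)
  if (!all(c("id", "d2H") %in% names(waters))) {
    stop("waters need `id` and `d2H`", call. = FALSE)
  }
  if (!"uncertainty" %in% names(waters)) waters$uncertainty <- NA_real_
  waters$d2H <- as.numeric(waters$d2H)
  waters$uncertainty <- as.numeric(waters$uncertainty)
  if (any(!is.finite(waters$d2H)) || any(waters$d2H <= -1000)) {
    stop("water d2H must be finite and > -1000 permil", call. = FALSE)
  }
  if (anyDuplicated(waters$id)) stop("duplicate water id(s)", call. = FALSE)
  out <- tibble::as_tibble(waters[, c("id", "d2H", "uncertainty")])
  out$id <- as.character(out$id)
  class(out) <- c("water_registry", class(out))
  out
}

#' Default registries for simulation and examples
#'
#' `default_materials()` returns a small registry patterned on a routine
#' HTC-triple standard set: two in-house celluloses spanning the hydrogen
#' and oxygen ranges, a sucrose, a polyethylene foil (non-exchanging, used
#' for hydrogen offset control; it contains no oxygen), a sucrose
#' quality-control standard, and a nitrogen-rich bulk material for
#' interference tests. `default_waters()` returns the two isotopically
#' distant equilibration waters used for two-water characterisation
#' (delta-2H of -160 and -412 permil).
#'
#' @return A [reference_materials()] or [equilibration_waters()] registry.
#' @export
default_materials <- function() {
  reference_materials(data.frame(
    id = c("CEL-A", "CEL-B", "SUC-A", "PEF", "QC-SUC", "INSECT"),
    material_class = c("cellulose", "cellulose", "sugar", "other", "sugar",
                       "other"),
    d2H = c(-130, -60, -100, -100.3, -85, -121.3),
    d13C = c(-28, -22, -12, -32.15, -25.5, -24),
    d18O = c(22, 32, 36, NA, 34, 18),
    x_e = c(0.20, 0.20, 0.36, 0, 0.36, 0.17),
    n_content_pct = c(0, 0, 0, 0, 0, 10.42),
    s_content_pct = c(0, 0, 0, 0, 0, 0.4),
    exchanges_h = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  ))
}

#' @rdname default_materials
#' @export
default_waters <- function() {
  equilibration_waters(data.frame(
    id = c("W1", "W2"),
    d2H = c(-160, -412),
    uncertainty = c(1, 1)
  ))
}

# Look up one material row; error with the offending id if absent.
material_row <- function(materials, id) {
  i <- match(id, materials$id)
  if (is.na(i)) {
    stop("material_id not in registry: ", id, call. = FALSE)
  }
  materials[i, ]
}

water_delta <- function(waters, id) {
  i <- match(id, waters$id)
  if (is.na(i)) stop("water id not in registry: ", id, call. = FALSE)
  waters$d2H[i]
}
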