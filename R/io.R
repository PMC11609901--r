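#' Read and write run-sequence files
#'
#' Run sequences are stored as comma-delimited UTF-8 text with a dot
#' decimal separator and permil values as plain numbers. Run-level metadata
#' (reactor, equilibration water, autosampler, run date, simulator seed)
#' travels in `# key: value` comment lines before the header. Columns:
#' `position`, `time_offset`, `material_id`, `role`, `d2H_raw`,
#' `d13C_raw`, `d18O_raw`, `area_H2`, `area_CO`, `mass_mg`; an empty cell
#' is an absent value (e.g. the CO channels of a chromium run).
#' `read_run_csv(write_run_csv(run))` is the identity.
#'
#' @param path File path.
#' @param run A [run_sequence()].
#' @param materials Optional [reference_materials()] registry; when given,
#'   any non-blank `material_id` absent from it is a hard error naming the
#'   id and row.
#' @return `read_run_csv()`: a [run_sequence()]. `write_run_csv()`: `path`,
#'   invisibly.
#' @export
read_run_csv <- function(path, materials = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (nzchar(key) && nzchar(val)) meta[[key]] <- val
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  required <- c("position", "material_id", "role", "d2H_raw", "d13C_raw",
                "d18O_raw", "area_H2", "area_CO", "mass_mg")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(materials)) {
    bad <- which(!tab$material_id %in% materials$id & tab$role != "blank")
    if (length(bad)) {
      stop("unknown material_id in row(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(tab$material_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  run_sequence(
    tab,
    reactor = meta$reactor %||% "glassy_carbon",
    equilibration_water_id = meta$equilibration_water_id,
    autosampler = meta$autosampler %||% "argon_hood",
    run_date = meta$run_date,
    seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed)
  )
}

#' @rdname read_run_csv
#' @export
write_run_csv <- function(run, path) {
  stopifnot(inherits(run, "run_sequence"))
  meta <- c(
    sprintf("# reactor: %s", run$reactor),
    if (!is.null(run$equilibration_water_id))
      sprintf("# equilibration_water_id: %s", run$equilibration_water_id),
    sprintf("# autosampler: %s", run$autosampler),
    if (!is.null(run$run_date)) sprintf("# run_date: %s", run$run_date),
    if (!is.null(run$seed)) sprintf("# seed: %d", run$seed)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(run$records), con, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write and read reduced results
#'
#' Reduced results are written as plain CSV with columns `position`,
#' `material_id`, `role`, `d13C`, `d18O`, `d2H_e`, `d2H_ne`, `x_e_used`
#' and `flags` (`;`-separated, empty when clean).
#'
#' @param results A reduced-results table or a [reduce_run()] object.
#' @param path File path.
#' @return `write_results()`: `path`, invisibly. `read_results()`: a
#'   tibble.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "reduced_run")) results <- results$results
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(flags = "character"))
  tab$flags[is.na(tab$flags)] <- ""
  tibble::as_tibble(tab)
}

#' Read registries from YAML configuration
#'
#' Reference materials and equilibration waters are configured as YAML
#' lists. A materials file holds one entry per material:
#' ```yaml
#' - id: CEL-A
#'   material_class: cellulose
#'   d2H: -130
#'   d13C: -28
#'   d18O: 22
#'   x_e: 0.20
#'   n_content_pct: 0
#'   exchanges_h: true
#' ```
#' and a waters file one entry per water (`id`, `d2H`, `uncertainty`).
#' Missing numeric fields are absent (`NA`).
#'
#' @param path YAML file path.
#' @return [reference_materials()] or [equilibration_waters()] registry.
#' @export
read_materials <- function(path) {
  entries <- yaml::read_yaml(path)
  reference_materials(yaml_entries_to_df(
    entries, c("id", "material_class", "d2H", "d13C", "d18O", "x_e",
               "n_content_pct", "s_content_pct", "exchanges_h")))
}

#' @rdname read_materials
#' @export
read_waters <- function(path) {
  entries <- yaml::read_yaml(path)
  equilibration_waters(yaml_entries_to_df(
    entries, c("id", "d2H", "uncertainty")))
}

#' @rdname read_materials
#' @param materials A [reference_materials()] registry to write.
#' @param waters An [equilibration_waters()] registry to write.
#' @export
write_materials <- function(materials, path) {
  yaml::write_yaml(df_to_yaml_entries(as.data.frame(materials)), path)
  invisible(path)
}

#' @rdname read_materials
#' @export
write_waters <- function(waters, path) {
  yaml::write_yaml(df_to_yaml_entries(as.data.frame(waters)), path)
  invisible(path)
}

df_to_yaml_entries <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    row[!vapply(row, function(x) is.na(x), logical(1))]
  })
}

yaml_entries_to_df <- function(entries, fields) {
  if (length(entries) == 0) stop("empty registry file", call. = FALSE)
  rows <- lapply(entries, function(e) {
    out <- lapply(fields, function(f) if (is.null(e[[f]])) NA else e[[f]])
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
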