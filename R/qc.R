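#' Validate the structure of a run sequence
#'
#' Checks the sequence against the standard design: a calibration-standard
#' block at both ends, a quality-control standard present and interleaved
#' at roughly the configured interval, and calibration standards spanning a
#' sufficient isotope range per channel (narrow spans make the two-point
#' calibration ill-conditioned). All findings are warnings, never errors.
#'
#' @param run A [run_sequence()].
#' @param materials A [reference_materials()] registry (for certified
#'   spans).
#' @param qc_interval Expected QC spacing among the samples; default 12.
#' @param min_span Named minimum certified spans in permil per channel;
#'   defaults 50 for `H2`, 5 for `C13` and `O18`.
#' @return A list of class `sequence_validation` with elements `warnings`
#'   (character vector, empty when the sequence is clean) and `ok`.
#' @export
validate_sequence <- function(run, materials = default_materials(),
                              qc_interval = 12,
                              min_span = c(H2 = 50, C13 = 5, O18 = 5)) {
  stopifnot(inherits(run, "run_sequence"))
  recs <- run$records
  warnings <- character(0)

  member <- block_membership(recs$role)
  blocks <- end_blocks(member)
  if (length(blocks$start) == 0 ||
      !any(recs$role[blocks$start] == "standard")) {
    warnings <- c(warnings, "no opening standard block")
  }
  if (is.null(blocks$end)) {
    if (length(blocks$start) < nrow(recs)) {
      warnings <- c(warnings, "no terminal standard block")
    }
  } else if (!any(recs$role[blocks$end] == "standard")) {
    warnings <- c(warnings, "no terminal standard block")
  }

  qc_pos <- recs$position[recs$role == "qc"]
  if (length(qc_pos) == 0) {
    warnings <- c(warnings, "no quality-control analyses in sequence")
  } else if (any(recs$role == "sample")) {
    gaps <- diff(sort(c(qc_pos, min(recs$position), max(recs$position))))
    if (max(gaps) > 2 * (qc_interval + 1)) {
      warnings <- c(warnings, sprintf(
        "QC spacing up to %d positions exceeds ~%d-sample interval",
        max(gaps), qc_interval))
    }
  }

  std_ids <- unique(recs$material_id[recs$role == "standard"])
  std <- materials[materials$id %in% std_ids, ]
  cert_cols <- c(H2 = "d2H", C13 = "d13C", O18 = "d18O")
  for (iso in run_isotopes(run)) {
    v <- std[[cert_cols[[iso]]]]
    v <- v[!is.na(v)]
    span <- if (length(v) >= 2) diff(range(v)) else 0
    if (span < min_span[[iso]]) {
      warnings <- c(warnings, sprintf(
        "calibration span %.1f permil for %s below recommended %.0f",
        span, iso, min_span[[iso]]))
    }
  }

  structure(list(warnings = warnings, ok = length(warnings) == 0),
            class = "sequence_validation")
}

#' @export
print.sequence_validation <- function(x, ...) {
  if (x$ok) {
    cat("<sequence_validation> ok, no warnings\n")
  } else {
    cat("<sequence_validation>", length(x$warnings), "warning(s):\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Run precision from repeated quality-control analyses
#'
#' The run precision per isotope is the sample standard deviation (n-1
#' denominator) of the calibrated values of the quality-control standard —
#' a material analysed repeatedly throughout the run but never used in the
#' calibration fits. For hydrogen the SD of both the calibrated
#' equilibrated value (`d2H_e`) and the final nonexchangeable value
#' (`d2H_ne`) are reported; the exchange correction rescales the
#' equilibrated SD by `1/(1 - x_e)`.
#'
#' @param results A reduced-results table (or a [reduce_run()] object).
#' @param qc_material Material id of the quality-control standard; default:
#'   the single material with role `"qc"`.
#' @param min_n Minimum number of replicates per channel; with fewer the
#'   SD is reported as `NA` with a warning. Default 3.
#' @return A tibble with columns `isotope` (`d13C`, `d18O`, `d2H_e`,
#'   `d2H_ne`), `n` and `sd` (permil).
#' @export
qc_precision <- function(results, qc_material = NULL, min_n = 3) {
  if (inherits(results, "reduced_run")) results <- results$results
  results <- as.data.frame(results)
  qc <- results[results$role == "qc", , drop = FALSE]
  if (is.null(qc_material)) {
    ids <- unique(qc$material_id)
    if (length(ids) != 1) {
      stop("specify `qc_material`: found ", length(ids),
           " QC materials", call. = FALSE)
    }
    qc_material <- ids
  }
  qc <- qc[qc$material_id == qc_material, , drop = FALSE]
  cols <- c("d13C", "d18O", "d2H_e", "d2H_ne")
  out <- tibble::tibble(
    isotope = cols,
    n = vapply(cols, function(cl) sum(!is.na(qc[[cl]])), integer(1),
               USE.NAMES = FALSE),
    sd = vapply(cols, function(cl) {
      v <- qc[[cl]][!is.na(qc[[cl]])]
      if (length(v) < min_n) NA_real_ else stats::sd(v)
    }, numeric(1), USE.NAMES = FALSE)
  )
  if (any(out$n > 0 & out$n < min_n)) {
    warning("fewer than ", min_n,
            " QC replicates on some channel(s): SD not reported",
            call. = FALSE)
  }
  out
}

#' Element content from peak areas
#'
#' Total element concentration (mass %) of an analysis, from its
#' mass-spectrometer peak area relative to a reference analysis of known
#' content: `content = ref_content * (area/mass) / (ref_area/ref_mass)`.
#'
#' @param area,mass Peak area (arbitrary units, `> 0`) and sample mass
#'   (mg, `> 0`) of the analysis.
#' @param ref_area,ref_mass,ref_content The same for the reference
#'   analysis, plus its known element content in %.
#' @return Element content in mass %.
#' @examples
#' element_content(1000, 1, 2000, 2, 6)  # same area/mass ratio -> 6
#' @export
element_content <- function(area, mass, ref_area, ref_mass, ref_content) {
  vals <- c(area, mass, ref_area, ref_mass)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("areas and masses must be finite and > 0", call. = FALSE)
  }
  ref_content * (area / mass) / (ref_area / ref_mass)
}

#' Compare nonexchangeable delta-2H between HTC reactors
#'
#' Joins reduced results (or per-material summaries) from a glassy-carbon
#' run and a chromium run on the shared materials and tabulates the
#' per-material mean delta-2H_ne of each reactor, their difference
#' (`diff = glassy carbon - chromium`, the convention used throughout),
#' the exchangeable fractions when available, and the nitrogen content
#' from the registry. Differences beyond ~2 permil point to
#' reactor-dependent chemistry such as HCN formation from nitrogen-rich
#' material. A `diff_display` column rounds the difference to 0.1 permil
#' for reporting; `diff` stays unrounded.
#'
#' @param carbon,chromium Reduced-results tables ([reduce_run()] output or
#'   its `results` element), or any data frame with `material_id` and
#'   `d2H_ne` columns (one row per analysis or per material). Rows with
#'   missing `d2H_ne` are dropped.
#' @param materials Optional [reference_materials()] registry supplying
#'   `n_content_pct`.
#' @return A tibble with columns `material_id`, `d2H_ne_carbon`,
#'   `d2H_ne_chromium`, `diff`, `diff_display`, `x_e_carbon`,
#'   `x_e_chromium`, `n_pct`. Empty (with a warning) when no materials are
#'   shared.
#' @export
reactor_difference_table <- function(carbon, chromium, materials = NULL) {
  side <- function(res) {
    if (inherits(res, "reduced_run")) res <- res$results
    res <- as.data.frame(res)
    m <- material_means(res, "d2H_ne")
    xe_col <- intersect(c("x_e_used", "x_e"), names(res))[1]
    xe <- rep(NA_real_, nrow(m))
    if (!is.na(xe_col)) {
      xm <- material_means(res, xe_col)
      xe <- xm$mean[match(m$material_id, xm$material_id)]
    }
    tibble::tibble(material_id = m$material_id, d2H_ne = m$mean,
                   x_e = xe)
  }
  a <- side(carbon)
  b <- side(chromium)
  shared <- intersect(a$material_id, b$material_id)
  if (length(shared) == 0) {
    warning("no shared materials between the two runs", call. = FALSE)
    return(tibble::tibble(material_id = character(0),
                          d2H_ne_carbon = numeric(0),
                          d2H_ne_chromium = numeric(0),
                          diff = numeric(0), diff_display = numeric(0),
                          x_e_carbon = numeric(0),
                          x_e_chromium = numeric(0), n_pct = numeric(0)))
  }
  ia <- match(shared, a$material_id)
  ib <- match(shared, b$material_id)
  d <- a$d2H_ne[ia] - b$d2H_ne[ib]
  n_pct <- if (is.null(materials)) rep(NA_real_, length(shared)) else
    materials$n_content_pct[match(shared, materials$id)]
  tibble::tibble(
    material_id = shared,
    d2H_ne_carbon = a$d2H_ne[ia],
    d2H_ne_chromium = b$d2H_ne[ib],
    diff = d,
    diff_display = round(d, 1),
    x_e_carbon = a$x_e[ia],
    x_e_chromium = b$x_e[ib],
    n_pct = n_pct
  )
}

#' Nitrogen-bias regression of the reactor difference
#'
#' Ordinary least-squares regression of the glassy-carbon-minus-chromium
#' difference in delta-2H_ne (permil, response) on the nitrogen content of
#' the material (mass %, predictor). A positive slope quantifies the
#' hydrogen-isotope bias of nitrogen-rich materials in a glassy-carbon
#' reactor (HCN formation diverts sample hydrogen from H2).
#'
#' @param table A data frame with columns `diff` and `n_pct` (e.g. from
#'   [reactor_difference_table()] or [read_reactor_table()]).
#' @return A list with `slope` (permil per %N), `intercept` (permil),
#'   `r_squared` and `n`. Fewer than 3 points is an error; exactly 2
#'   points fit a line exactly and report `r_squared = 1` with a
#'   degenerate-fit warning.
#' @export
nitrogen_bias_regression <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("diff", "n_pct") %in% names(table)))
  keep <- !is.na(table$diff) & !is.na(table$n_pct)
  d <- table$diff[keep]
  n_pct <- table$n_pct[keep]
  if (length(d) < 2) {
    stop("regression failure: need >= 3 materials with N content and diff",
         call. = FALSE)
  }
  if (length(d) == 2) {
    warning("degenerate fit: only 2 points, r_squared reported as 1",
            call. = FALSE)
  }
  fit <- stats::lm(d ~ n_pct)
  ssr <- sum(fit$residuals^2)
  sst <- sum((d - mean(d))^2)
  r2 <- if (sst == 0) {
    if (ssr == 0) 1 else 0
  } else if (length(d) == 2) 1 else 1 - ssr / sst
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(d))
}

#' Interference screen for a run's materials
#'
#' On glassy-carbon runs, materials with high nitrogen content are at risk
#' of a hydrogen-isotope bias from HCN formation; the flag carries the bias
#' predicted by the packaged reactor-comparison regression
#' ([nitrogen_bias_regression()] on [read_reactor_table()]). Materials with
#' high sulfur content are flagged for possible H2S interference. A
#' chromium-filled reactor scavenges all reactive elements except hydrogen,
#' so chromium runs are not flagged. For unknown or newly applied
#' materials, comparing a glassy-carbon against a chromium run directly is
#' recommended.
#'
#' @param materials A [reference_materials()] registry (or subset) to
#'   screen.
#' @param reactor `"glassy_carbon"` or `"chromium"`, or a [run_sequence()]
#'   whose reactor is used.
#' @param n_threshold Nitrogen content (%) above which to flag; default 5.
#' @param s_threshold Sulfur content (%) above which to flag; default 1.
#' @return A tibble with `material_id`, `n_pct`, `s_pct`,
#'   `predicted_bias` (permil, `NA` when not N-flagged) and `flags`.
#' @export
interference_flags <- function(materials, reactor = "glassy_carbon",
                               n_threshold = 5, s_threshold = 1) {
  if (inherits(reactor, "run_sequence")) reactor <- reactor$reactor
  reactor <- match.arg(reactor, c("glassy_carbon", "chromium"))
  materials <- as.data.frame(materials)
  n <- nrow(materials)
  flags <- rep("", n)
  bias <- rep(NA_real_, n)
  if (reactor == "glassy_carbon" && n > 0) {
    reg <- nitrogen_bias_regression(read_reactor_table())
    n_pct <- materials$n_content_pct
    s_pct <- materials$s_content_pct
    hi_n <- !is.na(n_pct) & n_pct > n_threshold
    bias[hi_n] <- reg$slope * n_pct[hi_n] + reg$intercept
    flags[hi_n] <- sprintf(
      "N interference risk (%.1f%% N): predicted d2H bias %+.1f permil",
      n_pct[hi_n], bias[hi_n])
    hi_s <- !is.na(s_pct) & s_pct > s_threshold
    flags <- add_flag(flags, hi_s, "possible H2S interference (high S)")
  }
  tibble::tibble(material_id = materials$id,
                 n_pct = materials$n_content_pct,
                 s_pct = materials$s_content_pct,
                 predicted_bias = bias, flags = flags)
}

#' Packaged reactor-comparison table
#'
#' Reads the packaged comparison of delta-2H_ne values determined with
#' glassy-carbon and chromium HTC reactors for five materials spanning
#' nitrogen contents from 0.2% to 10.4% (beech wood, algae, leaves, fungus,
#' insect), including the per-reactor means, SDs, exchangeable fractions
#' and the published difference column. This table anchors the
#' nitrogen-bias regression used by [interference_flags()].
#'
#' @param path Path to an alternative CSV with the same layout.
#' @return A tibble with columns `material_id`, `d2H_ne_carbon`,
#'   `sd_carbon`, `d2H_ne_chromium`, `sd_chromium`, `x_e_carbon`,
#'   `sd_x_e_carbon`, `x_e_chromium`, `sd_x_e_chromium`, `n_pct`, `diff`.
#' @export
read_reactor_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2.csv", package = "tripleiso",
                        mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
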