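#' First-order memory correction
#'
#' Continuous-flow IRMS analyses carry over a small fraction of the
#' previous analysis's isotopic signal (typically 1--3%). The routine
#' correction adds the difference between the current and the previous
#' analysis, scaled by the memory fraction `m`:
#' \deqn{corrected_i = measured_i + m\,(measured_i - measured_{i-1}).}
#' The first analysis (no predecessor) is returned unchanged. `NA` entries
#' (absent channel) are skipped: the predecessor is the most recent
#' non-missing value.
#'
#' The correction is not idempotent; it must be applied exactly once. The
#' returned vector carries a `memory_corrected` attribute as a
#' processing-state guard, and passing an already-corrected series in is an
#' error.
#'
#' @param series Numeric vector of permil values in run order.
#' @param m Memory fraction, `0 <= m < 0.5`.
#' @return Corrected numeric vector with attribute
#'   `memory_corrected = TRUE`.
#' @examples
#' apply_memory_correction(c(0, -100), 0.02)  # c(0, -102)
#' @seealso [fit_memory_fraction()]
#' @export
apply_memory_correction <- function(series, m) {
  if (isTRUE(attr(series, "memory_corrected"))) {
    stop("series is already memory-corrected; the correction must be ",
         "applied exactly once", call. = FALSE)
  }
  if (length(m) != 1 || is.na(m) || m < 0 || m >= 0.5) {
    stop("memory fraction m must be a single value in [0, 0.5)",
         call. = FALSE)
  }
  out <- series
  prev <- NA_real_
  for (i in seq_along(series)) {
    x <- series[[i]]
    if (is.na(x)) next
    if (!is.na(prev)) out[[i]] <- x + m * (x - prev)
    prev <- x
  }
  attr(out, "memory_corrected") <- TRUE
  out
}

#' Fit the memory fraction of a run
#'
#' The memory fraction is determined iteratively as the value that yields
#' the lowest pooled within-material standard deviation of the calibration
#' standards after memory (and, when applicable, drift) correction. A grid
#' `0, 0.001, ..., 0.05` is scanned and the best grid point is then refined
#' by a bounded continuous search within one grid step, so that a run with
#' purely deterministic carry-over is inverted to machine precision. Ties
#' are broken toward smaller `m`.
#'
#' @param run A [run_sequence()].
#' @param isotope One of `"H2"`, `"C13"`, `"O18"`.
#' @param materials A [reference_materials()] registry (used to restrict
#'   the objective to calibration standards certified for the isotope).
#' @param grid Candidate memory fractions (non-negative, `< 0.5`).
#' @param drift_threshold Passed through to the drift stage inside the
#'   objective; see [drift_correction()].
#' @param steady_state_minutes Records earlier than this (argon-hood
#'   autosampler, cellulose class) are excluded from the objective; see
#'   [reduce_run()].
#' @param refine If `TRUE` (default), refine the grid optimum by
#'   [stats::optimize()] within one grid step.
#' @return A list with `m` (the fitted fraction), `pooled_sd` (the
#'   objective at the optimum, permil) and `flags` (character; non-empty
#'   when the fit was skipped for lack of replicates, in which case
#'   `m = 0`).
#' @export
fit_memory_fraction <- function(run, isotope,
                                materials = default_materials(),
                                grid = seq(0, 0.05, by = 0.001),
                                drift_threshold = 0.005,
                                steady_state_minutes = 120,
                                refine = TRUE) {
  stopifnot(inherits(run, "run_sequence"), isotope %in% ISOTOPES)
  recs <- run$records
  y <- recs[[RAW_COLS[[isotope]]]]
  fit_mask <- standard_fit_mask(run, isotope, materials,
                                steady_state_minutes)
  block_member <- block_membership(recs$role)

  counts <- table(recs$material_id[fit_mask & !is.na(y)])
  if (length(counts) == 0 || max(counts) < 3) {
    return(list(m = 0, pooled_sd = NA_real_,
                flags = "memory fit skipped: no reference material with >= 3 replicates"))
  }

  objective <- function(m) {
    cor <- apply_memory_correction(y, m)
    dc <- drift_correction(cor, recs$position, recs$material_id,
                           block_member, fit_ok = fit_mask,
                           threshold = drift_threshold)
    pooled_within_sd(dc$values[fit_mask], recs$material_id[fit_mask])
  }

  vals <- vapply(grid, objective, numeric(1))
  best <- which(vals == min(vals))[1]  # ties toward smaller m
  m_hat <- grid[best]
  sd_hat <- vals[best]

  if (refine && length(grid) > 1) {
    step <- max(diff(grid))
    lo <- max(0, m_hat - step)
    hi <- min(max(grid), m_hat + step)
    opt <- stats::optimize(objective, interval = c(lo, hi), tol = 1e-10)
    if (opt$objective < sd_hat) {
      m_hat <- opt$minimum
      sd_hat <- opt$objective
    }
  }
  list(m = m_hat, pooled_sd = sd_hat, flags = character(0))
}

# Pooled within-group standard deviation (n-1 denominators), ignoring NA
# values and groups with fewer than 2 observations.
pooled_within_sd <- function(x, group) {
  keep <- !is.na(x)
  x <- x[keep]
  group <- group[keep]
  ss <- 0
  df <- 0
  for (g in unique(group)) {
    v <- x[group == g]
    if (length(v) >= 2) {
      ss <- ss + sum((v - mean(v))^2)
      df <- df + length(v) - 1
    }
  }
  if (df == 0) return(NA_real_)
  sqrt(ss / df)
}

#' Position-based linear drift correction
#'
#' Instrument drift over a run is modelled as linear in analysis position.
#' The slope is estimated from the calibration standards analysed in both
#' the opening and the closing standard block: for every material present
#' in both blocks, the difference of the block means divided by the
#' difference of the block mean positions, averaged over materials. When
#' the estimated slope is smaller in magnitude than `threshold` the series
#' is returned unchanged and flagged (drift is corrected "if necessary");
#' with a single standard block no correction is attempted.
#'
#' @param values Numeric permil series in run order (one isotope channel).
#' @param positions Analysis positions (1-based).
#' @param material Material id per analysis.
#' @param block_member Logical: analysis belongs to a standard block
#'   (standards and QC at the run ends).
#' @param fit_ok Logical: analysis is eligible for the slope fit
#'   (calibration standards only, not flagged).
#' @param threshold Minimum absolute slope (permil per position) for the
#'   correction to be applied; default 0.005.
#' @return A list with `values` (corrected or unchanged), `slope`
#'   (estimated permil/position, `NA` when not estimable), `applied`
#'   (logical) and `flags` (character vector).
#' @export
drift_correction <- function(values, positions, material, block_member,
                             fit_ok = block_member, threshold = 0.005) {
  n <- length(values)
  stopifnot(length(positions) == n, length(material) == n,
            length(block_member) == n, length(fit_ok) == n)
  blocks <- end_blocks(block_member)
  flags <- character(0)
  if (is.null(blocks$end)) {
    return(list(values = values, slope = NA_real_, applied = FALSE,
                flags = "no drift correction: single standard block"))
  }

  slope <- estimate_block_slope(values, positions, material,
                                blocks, fit_ok)
  if (is.na(slope)) {
    return(list(values = values, slope = NA_real_, applied = FALSE,
                flags = "no drift correction: no material in both standard blocks"))
  }
  if (abs(slope) < threshold) {
    return(list(values = values, slope = slope, applied = FALSE,
                flags = "no drift applied"))
  }
  p0 <- min(positions)
  list(values = values - slope * (positions - p0), slope = slope,
       applied = TRUE, flags = flags)
}

# Indices of the leading and trailing contiguous standard blocks.
# Returns list(start = idx, end = idx or NULL if the run has one block).
end_blocks <- function(block_member) {
  n <- length(block_member)
  if (!block_member[1]) return(list(start = integer(0), end = NULL))
  start_end <- match(FALSE, block_member) - 1
  if (is.na(start_end)) start_end <- n  # whole run is one block
  start <- seq_len(start_end)
  if (start_end == n) return(list(start = start, end = NULL))
  if (!block_member[n]) return(list(start = start, end = NULL))
  end_start <- n - match(FALSE, rev(block_member)) + 2
  list(start = start, end = end_start:n)
}

estimate_block_slope <- function(values, positions, material, blocks,
                                 fit_ok) {
  sel_s <- intersect(blocks$start, which(fit_ok & !is.na(values)))
  sel_e <- intersect(blocks$end, which(fit_ok & !is.na(values)))
  shared <- intersect(unique(material[sel_s]), unique(material[sel_e]))
  if (length(shared) == 0) return(NA_real_)
  slopes <- vapply(shared, function(id) {
    i_s <- sel_s[material[sel_s] == id]
    i_e <- sel_e[material[sel_e] == id]
    dp <- mean(positions[i_e]) - mean(positions[i_s])
    if (dp == 0) return(NA_real_)
    (mean(values[i_e]) - mean(values[i_s])) / dp
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0) return(NA_real_)
  mean(slopes)
}

#' Two-point scale calibration
#'
#' Fits the affine map from memory/drift-corrected measured permil values
#' to the certified VSMOW/VPDB values of the calibration standards:
#' `certified = gain * measured + offset`. With exactly two standards the
#' line is solved exactly; with more, by ordinary least squares. For HTC
#' delta-13C the constant admixture of reactor carbon (a fraction `f` of
#' the CO carbon with a fixed delta) compresses the measured scale by
#' `(1 - f)`, so the fitted gain equals `1/(1 - f)` and the calibration
#' absorbs the reactor contribution; `reactor_fraction_from_gain()` reads
#' `f` back off the gain.
#'
#' @param measured Per-material mean measured values (permil), after
#'   memory and drift correction.
#' @param certified Certified values (permil) of the same materials.
#' @return A list with `gain`, `offset`, `n` (number of standards) and
#'   `residual_sd` (permil; `NA` for an exact two-point fit).
#' @examples
#' # two standards distorted by 15% reactor carbon with delta -25:
#' fit_two_point_calibration(c(-12.25, -29.25), c(-10, -30))
#' @export
fit_two_point_calibration <- function(measured, certified) {
  keep <- !is.na(measured) & !is.na(certified)
  measured <- measured[keep]
  certified <- certified[keep]
  if (length(measured) < 2) {
    stop("calibration failure: need >= 2 calibration materials",
         call. = FALSE)
  }
  if (length(unique(certified)) < 2 || length(unique(measured)) < 2) {
    stop("calibration failure: calibration materials do not span a range",
         call. = FALSE)
  }
  if (length(measured) == 2) {
    gain <- diff(certified) / diff(measured)
    offset <- certified[1] - gain * measured[1]
    resid_sd <- NA_real_
  } else {
    fit <- stats::lm(certified ~ measured)
    gain <- unname(coef(fit)[2])
    offset <- unname(coef(fit)[1])
    resid_sd <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  }
  if (!is.finite(gain) || gain <= 0) {
    stop("calibration failure: non-positive gain", call. = FALSE)
  }
  list(gain = gain, offset = offset, n = length(measured),
       residual_sd = resid_sd)
}

#' @rdname fit_two_point_calibration
#' @param gain A fitted delta-13C calibration gain.
#' @export
reactor_fraction_from_gain <- function(gain) 1 - 1 / gain

#' Reduce a run sequence to calibrated isotope values
#'
#' Runs the full data-reduction pipeline on each isotope channel present
#' in the run, in fixed order: (1) memory correction with the fitted
#' memory fraction ([fit_memory_fraction()]); (2) position-based linear
#' drift correction ([drift_correction()]); (3) two-point scale
#' calibration against the run's calibration standards
#' ([fit_two_point_calibration()]) — for hydrogen the standards are
#' compared at their forward-equilibrated certified values, so standards
#' with different exchangeable fractions calibrate exactly; (4) for
#' hydrogen, the exchangeable-hydrogen correction
#' ([nonexchangeable_delta()]) with the per-material `x_e` (explicit
#' override, else registry value, else class default).
#'
#' Quality-control analyses are never used in any fit. On argon-hood runs,
#' cellulose-class analyses earlier than `steady_state_minutes` are flagged
#' `"pre-steady-state"` and excluded from all fits (incomplete autosampler
#' steady state biases the apparent exchangeable fraction); their reduced
#' values are still reported. Chromium-reactor runs reduce the hydrogen
#' channel only.
#'
#' @param run A [run_sequence()].
#' @param materials A [reference_materials()] registry covering every
#'   non-blank `material_id` in the run.
#' @param waters An [equilibration_waters()] registry.
#' @param x_e Optional exchangeable-fraction override: a single fraction
#'   applied to every exchanging material, or a named vector keyed by
#'   `material_id`. Takes precedence over registry values and class
#'   defaults (apparent `x_e` varies with equilibration conditions between
#'   runs, so a run-level estimate from [estimate_run_xe()] is preferred
#'   when available).
#' @param alpha_ew Exchangeable-hydrogen/water fractionation factor,
#'   default [default_alpha_ew()].
#' @param steady_state_minutes Steady-state window (minutes) for the
#'   argon-hood exclusion rule; default 120.
#' @param drift_threshold Minimum absolute drift slope (permil/position)
#'   for the drift correction to be applied; default 0.005.
#' @param memory_grid Grid for the memory-fraction fit.
#' @param refine_memory Refine the memory fit beyond the grid (default
#'   `TRUE`).
#' @return An object of class `reduced_run`: a list with
#'   * `results` — a tibble with one row per analysis: `position`,
#'     `material_id`, `role`, `d13C`, `d18O` (calibrated permil), `d2H_e`
#'     (calibrated equilibrated permil), `d2H_ne` (nonexchangeable permil),
#'     `x_e_used`, and `flags` (`;`-separated QC warnings);
#'   * `calibration` — a `calibration_model` with the per-isotope gain,
#'     offset, fitted memory fraction, drift slope, and the implied
#'     reactor-carbon fraction for delta-13C;
#'   * `validation` — the [validate_sequence()] report.
#' @export
reduce_run <- function(run,
                       materials = default_materials(),
                       waters = default_waters(),
                       x_e = NULL,
                       alpha_ew = default_alpha_ew(),
                       steady_state_minutes = 120,
                       drift_threshold = 0.005,
                       memory_grid = seq(0, 0.05, by = 0.001),
                       refine_memory = TRUE) {
  stopifnot(inherits(run, "run_sequence"))
  recs <- run$records
  n <- nrow(recs)

  unknown <- setdiff(recs$material_id[recs$role != "blank"], materials$id)
  if (length(unknown)) {
    stop("material_id not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  validation <- validate_sequence(run, materials = materials)
  flags <- rep("", n)
  pre_ss <- pre_steady_state(run, materials, steady_state_minutes)
  flags <- add_flag(flags, pre_ss, "pre-steady-state")

  isotopes <- run_isotopes(run)
  block_member <- block_membership(recs$role)
  out <- recs[, c("position", "material_id", "role")]
  out$d13C <- NA_real_
  out$d18O <- NA_real_
  out$d2H_e <- NA_real_
  model <- list()

  for (iso in isotopes) {
    y <- recs[[RAW_COLS[[iso]]]]
    fit_mask <- standard_fit_mask(run, iso, materials,
                                  steady_state_minutes)

    mem <- fit_memory_fraction(run, iso, materials, grid = memory_grid,
                               drift_threshold = drift_threshold,
                               steady_state_minutes = steady_state_minutes,
                               refine = refine_memory)
    if (length(mem$flags)) {
      flags <- add_flag(flags, !is.na(y), paste0(iso, ": ", mem$flags))
    }
    corrected <- apply_memory_correction(y, mem$m)

    dc <- drift_correction(corrected, recs$position, recs$material_id,
                           block_member, fit_ok = fit_mask,
                           threshold = drift_threshold)
    if (length(dc$flags)) {
      flags <- add_flag(flags, !is.na(y), paste0(iso, ": ", dc$flags))
    }

    cal_in <- calibration_inputs(run, iso, dc$values, fit_mask, materials,
                                 waters, x_e, alpha_ew)
    cal <- tryCatch(
      fit_two_point_calibration(cal_in$measured, cal_in$certified),
      error = function(e) e
    )
    if (inherits(cal, "error")) {
      flags <- add_flag(flags, !is.na(y),
                        paste0(iso, ": channel skipped: ",
                               conditionMessage(cal)))
      model[[iso]] <- list(gain = NA_real_, offset = NA_real_,
                           memory_fraction = mem$m,
                           drift_slope = dc$slope,
                           drift_applied = dc$applied,
                           n_standards = 0,
                           reactor_carbon_fraction = NA_real_)
      next
    }

    calibrated <- cal$gain * dc$values + cal$offset
    attributes(calibrated) <- NULL
    out[[CAL_COLS[[iso]]]] <- calibrated
    model[[iso]] <- list(
      gain = cal$gain, offset = cal$offset,
      memory_fraction = mem$m,
      drift_slope = dc$slope, drift_applied = dc$applied,
      n_standards = cal$n,
      reactor_carbon_fraction =
        if (iso == "C13" && run$reactor == "glassy_carbon")
          reactor_fraction_from_gain(cal$gain) else NA_real_
    )
  }

  # exchangeable-hydrogen correction on the calibrated hydrogen channel
  out$d2H_ne <- NA_real_
  out$x_e_used <- NA_real_
  if ("H2" %in% isotopes && any(!is.na(out$d2H_e))) {
    ex <- exchange_dispatch(out, recs, run, materials, waters, x_e,
                            alpha_ew)
    out$d2H_ne <- ex$d2H_ne
    out$x_e_used <- ex$x_e_used
    flags <- paste_flags(flags, ex$flags)
  }

  out$flags <- flags
  out <- out[, c("position", "material_id", "role", "d13C", "d18O",
                 "d2H_e", "d2H_ne", "x_e_used", "flags")]
  structure(
    list(results = tibble::as_tibble(out),
         calibration = structure(model, class = "calibration_model",
                                 reactor = run$reactor),
         validation = validation),
    class = "reduced_run"
  )
}

# --- internal helpers --------------------------------------------------

# Analyses flagged as before autosampler steady state: argon-hood runs,
# cellulose-class materials, time earlier than the window.
pre_steady_state <- function(run, materials, steady_state_minutes) {
  recs <- run$records
  if (run$autosampler != "argon_hood" || is.null(steady_state_minutes) ||
      is.na(steady_state_minutes)) {
    return(rep(FALSE, nrow(recs)))
  }
  cls <- materials$material_class[match(recs$material_id, materials$id)]
  !is.na(recs$time_offset) & recs$time_offset < steady_state_minutes &
    !is.na(cls) & cls == "cellulose"
}

# Calibration standards eligible for fits on one isotope channel.
standard_fit_mask <- function(run, isotope, materials,
                              steady_state_minutes) {
  recs <- run$records
  mat <- materials[match(recs$material_id, materials$id), ]
  cert_col <- c(H2 = "d2H", C13 = "d13C", O18 = "d18O")[[isotope]]
  ok <- recs$role == "standard" & !is.na(mat[[cert_col]]) &
    !is.na(recs[[RAW_COLS[[isotope]]]])
  ok & !pre_steady_state(run, materials, steady_state_minutes)
}

block_membership <- function(role) role %in% c("standard", "qc")

# Per-material measured means and certified targets for the calibration
# fit. For hydrogen the certified nonexchangeable value is pushed through
# the forward mixing model with the run water and the standard's x_e, so
# the fit is done in equilibrated-delta space.
calibration_inputs <- function(run, isotope, values, fit_mask, materials,
                               waters, x_e_override, alpha_ew) {
  recs <- run$records
  ids <- unique(recs$material_id[fit_mask])
  measured <- vapply(ids, function(id) {
    mean(values[fit_mask & recs$material_id == id])
  }, numeric(1))
  cert_col <- c(H2 = "d2H", C13 = "d13C", O18 = "d18O")[[isotope]]
  certified <- vapply(ids, function(id) {
    mat <- material_row(materials, id)
    cert <- mat[[cert_col]]
    if (isotope != "H2" || is.na(cert)) return(cert)
    xe <- resolve_xe(mat, x_e_override)
    if (is.na(xe) || xe < 0 || xe >= 1) return(NA_real_)
    if (xe == 0) return(cert)
    if (is.null(run$equilibration_water_id)) return(NA_real_)
    dw <- water_delta(waters, run$equilibration_water_id)
    forward_equilibrated_delta(cert, dw, xe, alpha_ew)
  }, numeric(1))
  list(measured = measured, certified = certified, ids = ids)
}

# Per-record exchange correction of the calibrated hydrogen channel.
exchange_dispatch <- function(out, recs, run, materials, waters,
                              x_e_override, alpha_ew) {
  n <- nrow(out)
  d2H_ne <- rep(NA_real_, n)
  x_e_used <- rep(NA_real_, n)
  flags <- rep("", n)
  dw <- if (is.null(run$equilibration_water_id)) NA_real_ else
    water_delta(waters, run$equilibration_water_id)

  for (i in seq_len(n)) {
    e <- out$d2H_e[i]
    if (is.na(e)) next
    if (out$role[i] == "blank" &&
        !out$material_id[i] %in% materials$id) {
      next
    }
    mat <- material_row(materials, out$material_id[i])
    xe <- resolve_xe(mat, x_e_override)
    x_e_used[i] <- xe
    if (is.na(xe)) {
      flags[i] <- "x_e unknown: no exchange correction"
      next
    }
    if (xe >= 1) {
      flags[i] <- "x_e >= 1: exchange correction failed"
      next
    }
    if (xe < 0) flags[i] <- "x_e outside [0,1)"
    if (xe == 0) {
      d2H_ne[i] <- e
      next
    }
    if (is.na(dw)) {
      flags[i] <- "no equilibration water: cannot correct exchange"
      next
    }
    d2H_ne[i] <- suppressWarnings(
      nonexchangeable_delta(e, dw, xe, alpha_ew)
    )
  }
  list(d2H_ne = d2H_ne, x_e_used = x_e_used, flags = flags)
}

add_flag <- function(flags, where, flag) {
  if (!any(where)) return(flags)
  flags[where] <- ifelse(flags[where] == "", flag,
                         paste(flags[where], flag, sep = ";"))
  flags
}

paste_flags <- function(a, b) {
  ifelse(b == "", a, ifelse(a == "", b, paste(a, b, sep = ";")))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> reactor:", attr(x, "reactor") %||% "?", "\n")
  for (iso in names(x)) {
    m <- x[[iso]]
    cat(sprintf(
      "  %-3s gain %.5f offset %8.3f | m %.4f | drift %s%s%s\n",
      iso, m$gain, m$offset, m$memory_fraction,
      if (is.na(m$drift_slope)) "n/a" else sprintf("%+.4f", m$drift_slope),
      if (isTRUE(m$drift_applied)) " (applied)" else "",
      if (!is.na(m$reactor_carbon_fraction))
        sprintf(" | reactor C fraction %.3f", m$reactor_carbon_fraction)
      else ""
    ))
  }
  invisible(x)
}

#' @export
print.reduced_run <- function(x, ...) {
  cat(sprintf("<reduced_run> %d analyses\n", nrow(x$results)))
  print(x$calibration)
  nw <- length(x$validation$warnings)
  cat(if (nw) sprintf("  %d sequence warning(s)\n", nw) else
    "  sequence valid\n")
  invisible(x)
}
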