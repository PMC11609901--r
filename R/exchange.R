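#' Exchangeable-hydrogen correction
#'
#' Hydroxyl-bound hydrogen in carbohydrates exchanges with ambient water,
#' so the measured delta-2H of an equilibrated sample is a two-pool mixture
#' of the carbon-bound (nonexchangeable) hydrogen and hydrogen equilibrated
#' with the water vapour. With `x_e` the exchangeable fraction and
#' `alpha_ew` the equilibrium fractionation factor between exchangeable
#' sample hydrogen and water (1.082 for cellulose and, by assumption, other
#' carbohydrates), the equilibrated value is
#' \deqn{\delta^2H_e = (1-x_e)\,\delta^2H_{ne} +
#'   x_e\,(\alpha_{e-w}\,\delta^2H_w + 1000\,(\alpha_{e-w}-1)).}
#'
#' `exchanged_fraction()` inverts two equilibrations with isotopically
#' distant waters for `x_e`:
#' \deqn{x_e = \frac{\delta^2H_{e1}-\delta^2H_{e2}}
#'   {\alpha_{e-w}(\delta^2H_{w1}-\delta^2H_{w2})}.}
#' `nonexchangeable_delta()` then recovers the carbon-bound signal from a
#' single equilibration and a known `x_e`:
#' \deqn{\delta^2H_{ne} = \frac{\delta^2H_{e1} -
#'   x_e\,\alpha_{e-w}\,\delta^2H_{w1} - 1000\,x_e\,(\alpha_{e-w}-1)}
#'   {1-x_e}.}
#' `forward_equilibrated_delta()` is the forward mixing model (the exact
#' algebraic inverse of `nonexchangeable_delta()`), used by the run
#' simulator. All deltas are in permil on the VSMOW scale.
#'
#' Out-of-range `x_e` estimates (outside `[0, 1)`) are returned as-is so a
#' batch reduction can complete; callers flag them (they usually indicate
#' noise or an equilibration failure), they are never silently clamped.
#'
#' @param d_e1,d_e2 Measured delta-2H (permil) of the sample equilibrated
#'   with water 1 / water 2.
#' @param d_w1,d_w2 delta-2H (permil) of equilibration waters 1 and 2;
#'   must differ for `exchanged_fraction()`.
#' @param d_w delta-2H (permil) of the equilibration water.
#' @param d_ne Nonexchangeable (carbon-bound) delta-2H in permil.
#' @param x_e Exchangeable-hydrogen fraction in `[0, 1)`. Negative values
#'   proceed with a warning; `x_e >= 1` is an error.
#' @param alpha_ew Fractionation factor between exchangeable hydrogen and
#'   water, `> 0`; default [default_alpha_ew()].
#' @return `exchanged_fraction()`: the fraction `x_e` (dimensionless,
#'   unclamped). `nonexchangeable_delta()`: delta-2H_ne in permil.
#'   `forward_equilibrated_delta()`: equilibrated delta-2H in permil.
#' @examples
#' e1 <- forward_equilibrated_delta(-100, -160, 0.2)  # -98.224
#' e2 <- forward_equilibrated_delta(-100, -412, 0.2)  # -152.7568
#' exchanged_fraction(e1, e2, -160, -412)             # 0.2
#' nonexchangeable_delta(e1, -160, 0.2)               # -100
#' @export
exchanged_fraction <- function(d_e1, d_e2, d_w1, d_w2,
                               alpha_ew = default_alpha_ew()) {
  if (any(alpha_ew <= 0)) stop("alpha_ew must be > 0", call. = FALSE)
  if (any(d_w1 == d_w2)) {
    stop("degenerate waters: d_w1 must differ from d_w2", call. = FALSE)
  }
  (d_e1 - d_e2) / (alpha_ew * (d_w1 - d_w2))
}

#' @rdname exchanged_fraction
#' @export
nonexchangeable_delta <- function(d_e1, d_w1, x_e,
                                  alpha_ew = default_alpha_ew()) {
  if (any(x_e >= 1)) stop("x_e must be < 1", call. = FALSE)
  if (any(x_e < 0)) {
    warning("negative x_e: proceeding, result should be flagged",
            call. = FALSE)
  }
  (d_e1 - x_e * alpha_ew * d_w1 - 1000 * x_e * (alpha_ew - 1)) / (1 - x_e)
}

#' @rdname exchanged_fraction
#' @export
forward_equilibrated_delta <- function(d_ne, d_w, x_e,
                                       alpha_ew = default_alpha_ew()) {
  if (any(x_e < 0) || any(x_e >= 1)) {
    stop("x_e must lie in [0, 1)", call. = FALSE)
  }
  (1 - x_e) * d_ne + x_e * (alpha_ew * d_w + 1000 * (alpha_ew - 1))
}

#' Defaults for the exchange correction
#'
#' `default_alpha_ew()` returns the exchangeable-hydrogen/water
#' fractionation factor, 1.082, measured for cellulose and assumed to hold
#' for other carbohydrates (all exchange via hydroxyl groups). It may need
#' adaptation for compounds with other functional groups.
#'
#' `class_default_xe()` returns the typical exchangeable fraction for a
#' material class, used when a sample has no two-water characterisation of
#' its own: 0.20 for cellulose, 0.15 for wood, 0.36 for sugars. Leaf and
#' other bulk materials have no reliable class default and return `NA`;
#' supply a registry `x_e` or an explicit override for those. Run-to-run
#' shifts in apparent `x_e` usually reflect equilibration conditions rather
#' than the material, so per-run overrides take precedence downstream.
#'
#' @param material_class Character vector of material classes.
#' @return `default_alpha_ew()`: a scalar. `class_default_xe()`: numeric
#'   vector of fractions (`NA` where no default exists).
#' @export
default_alpha_ew <- function() 1.082

#' @rdname default_alpha_ew
#' @export
class_default_xe <- function(material_class) {
  defaults <- c(cellulose = 0.20, wood = 0.15, sugar = 0.36,
                leaf = NA_real_, other = NA_real_)
  unname(defaults[material_class])
}

# x_e used for one material row, honouring precedence:
# explicit override > registry value > class default.
# `override` may be a single value or a named vector keyed by material id.
resolve_xe <- function(mat, override = NULL) {
  if (!is.null(override)) {
    if (!is.null(names(override))) {
      if (mat$id %in% names(override)) return(unname(override[[mat$id]]))
    } else {
      if (isTRUE(mat$exchanges_h)) return(override[[1]])
      return(0)
    }
  }
  if (!isTRUE(mat$exchanges_h)) return(0)
  if (!is.na(mat$x_e)) return(mat$x_e)
  class_default_xe(mat$material_class)
}

#' Estimate per-material exchangeable fractions from two runs
#'
#' Given reduced results of the same materials from two runs equilibrated
#' with isotopically distant waters, applies the two-water estimator to the
#' calibrated equilibrated delta-2H means of each shared material.
#'
#' @param results1,results2 Reduced-result tables (see [reduce_run()])
#'   from runs equilibrated with `water1`/`water2`.
#' @param water1,water2 delta-2H (permil) of the two equilibration waters.
#' @param alpha_ew Fractionation factor, default [default_alpha_ew()].
#' @return A tibble with `material_id`, `n1`, `n2`, and the estimated
#'   `x_e` per shared material (unclamped; values outside `[0, 1)` carry a
#'   flag).
#' @export
estimate_run_xe <- function(results1, results2, water1, water2,
                            alpha_ew = default_alpha_ew()) {
  m1 <- material_means(results1, "d2H_e")
  m2 <- material_means(results2, "d2H_e")
  shared <- intersect(m1$material_id, m2$material_id)
  if (length(shared) == 0) {
    warning("no shared materials between the two runs", call. = FALSE)
  }
  i1 <- match(shared, m1$material_id)
  i2 <- match(shared, m2$material_id)
  xe <- exchanged_fraction(m1$mean[i1], m2$mean[i2], water1, water2,
                           alpha_ew)
  flag <- ifelse(!is.na(xe) & (xe < 0 | xe >= 1), "x_e outside [0,1)", "")
  tibble::tibble(material_id = shared, n1 = m1$n[i1], n2 = m2$n[i2],
                 x_e = xe, flags = flag)
}

# Per-material mean of one column of a reduced-results table.
material_means <- function(results, col) {
  results <- as.data.frame(results)
  keep <- !is.na(results[[col]])
  results <- results[keep, , drop = FALSE]
  ids <- unique(results$material_id)
  tibble::tibble(
    material_id = ids,
    n = vapply(ids, function(id) sum(results$material_id == id),
               integer(1), USE.NAMES = FALSE),
    mean = vapply(ids, function(id) {
      mean(results[[col]][results$material_id == id])
    }, numeric(1), USE.NAMES = FALSE)
  )
}
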