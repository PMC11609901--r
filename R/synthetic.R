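#' Configuration for the forward run simulator
#'
#' Collects the instrument-effect and sequence-design parameters used by
#' [generate_run()]. Defaults describe a routine HTC-triple run: Gaussian
#' noise at the long-term quality-control precisions (3.0 permil for
#' delta-2H, 0.2 for delta-13C, 0.3 for delta-18O), a 2% memory fraction
#' (middle of the typical 1--3% range), no drift, a glassy-carbon reactor
#' contributing 15% of the CO carbon at delta-13C of -25 permil, a
#' standard block of four calibration materials in triplicate plus one
#' quality-control analysis at both run ends, a QC analysis every 12
#' samples, a 12-minute analysis cadence, and a 120-minute wait before the
#' first analysis so the argon-hood autosampler is at steady state (the
#' wait is dropped when equilibration loss is being simulated).
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_samples Number of sample analyses.
#' @param qc_interval Insert one QC analysis after every `qc_interval`
#'   samples.
#' @param noise_sd Named per-isotope Gaussian noise SD in permil
#'   (`H2`, `C13`, `O18`).
#' @param memory_fraction True carry-over fraction `m` (recursive form:
#'   each measurement is `(1-m)` of the current signal plus `m` of the
#'   previous measurement).
#' @param drift_slope Linear drift in permil per position, a scalar applied
#'   to every channel or a named per-isotope vector.
#' @param reactor `"glassy_carbon"` or `"chromium"` (chromium emits the
#'   hydrogen channel only).
#' @param reactor_carbon_fraction Fraction `f` of CO carbon contributed by
#'   the reactor and filling on glassy-carbon runs, `0 <= f < 0.5`.
#' @param reactor_delta13C delta-13C (permil) of the reactor carbon.
#' @param water_id Equilibration water id (see [default_waters()]), or
#'   `NULL` for an unequilibrated run.
#' @param autosampler `"argon_hood"` or `"zero_blank"`.
#' @param standard_ids Calibration materials in each standard block.
#' @param qc_id Quality-control material (required; never calibrated
#'   against).
#' @param block_replicates Replicates of each calibration material per
#'   block.
#' @param sample_ids Sample material ids; `NULL` (default) generates
#'   `n_samples` synthetic cellulose samples with truth drawn uniformly
#'   from realistic ranges (delta-2H_ne -140 to -60, delta-13C -30 to -20,
#'   delta-18O 20 to 35 permil).
#' @param minutes_per_analysis Analysis cadence in minutes.
#' @param start_delay_minutes Minutes between placing the samples in the
#'   autosampler and the first analysis; default 120, or 0 when
#'   `equilibration_loss` is enabled.
#' @param equilibration_loss `NULL`, or a list
#'   `list(initial_xe=, steadystate_xe=, relaxation_minutes=)` enabling a
#'   time-dependent effective exchangeable fraction for cellulose-class
#'   materials on the argon-hood autosampler (see
#'   [equilibration_loss_xe()]).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_samples = 24,
                             qc_interval = 12,
                             noise_sd = c(H2 = 3.0, C13 = 0.2, O18 = 0.3),
                             memory_fraction = 0.02,
                             drift_slope = 0,
                             reactor = c("glassy_carbon", "chromium"),
                             reactor_carbon_fraction = 0.15,
                             reactor_delta13C = -25,
                             water_id = "W1",
                             autosampler = c("argon_hood", "zero_blank"),
                             standard_ids = c("CEL-A", "CEL-B", "SUC-A",
                                              "PEF"),
                             qc_id = "QC-SUC",
                             block_replicates = 3,
                             sample_ids = NULL,
                             minutes_per_analysis = 12,
                             start_delay_minutes = NULL,
                             equilibration_loss = NULL) {
  reactor <- match.arg(reactor)
  autosampler <- match.arg(autosampler)
  noise_sd <- expand_iso(noise_sd, default = 0)
  drift_slope <- expand_iso(drift_slope, default = 0)
  if (qc_interval < 1) stop("qc_interval must be >= 1", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (reactor_carbon_fraction < 0 || reactor_carbon_fraction >= 0.5) {
    stop("reactor_carbon_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  if (memory_fraction < 0 || memory_fraction >= 0.5) {
    stop("memory_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(equilibration_loss)) {
    stopifnot(all(c("initial_xe", "steadystate_xe", "relaxation_minutes")
                  %in% names(equilibration_loss)),
              equilibration_loss$relaxation_minutes > 0)
  }
  if (is.null(start_delay_minutes)) {
    start_delay_minutes <- if (is.null(equilibration_loss)) 120 else 0
  }
  structure(
    list(seed = as.integer(seed), n_samples = n_samples,
         qc_interval = qc_interval, noise_sd = noise_sd,
         memory_fraction = memory_fraction, drift_slope = drift_slope,
         reactor = reactor,
         reactor_carbon_fraction = reactor_carbon_fraction,
         reactor_delta13C = reactor_delta13C, water_id = water_id,
         autosampler = autosampler, standard_ids = standard_ids,
         qc_id = qc_id, block_replicates = block_replicates,
         sample_ids = sample_ids,
         minutes_per_analysis = minutes_per_analysis,
         start_delay_minutes = start_delay_minutes,
         equilibration_loss = equilibration_loss),
    class = "generator_config"
  )
}

# Recycle a scalar, or complete a named vector, over the three channels.
expand_iso <- function(x, default = 0) {
  if (is.null(names(x))) {
    if (length(x) != 1) stop("expected a scalar or a named vector",
                             call. = FALSE)
    return(setNames(rep(as.numeric(x), 3), ISOTOPES))
  }
  out <- setNames(rep(default, 3), ISOTOPES)
  bad <- setdiff(names(x), ISOTOPES)
  if (length(bad)) stop("unknown isotope name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out[names(x)] <- as.numeric(x)
  out
}

#' Time-dependent effective exchangeable fraction (equilibration loss)
#'
#' On an argon-flushed autosampler tray, equilibrated cellulose loses part
#' of its exchange signal during roughly the first two hours before
#' reaching a steady state (apparent `x_e` dropping from, e.g., 0.13 at the
#' first analysis to 0.07 at steady state). The simulator models this as an
#' exponential relaxation
#' \deqn{x_e(t) = x_{ss} + (x_0 - x_{ss})\, e^{-t/\tau}, \quad
#'   \tau = relaxation\_minutes / 3,}
#' so the transient is ~95% relaxed at `t = relaxation_minutes`. The
#' exponential shape and time constant are simulator conventions chosen to
#' reproduce the observed endpoint behaviour.
#'
#' @param t Minutes since the samples were placed in the autosampler.
#' @param initial_xe Apparent exchangeable fraction at `t = 0`.
#' @param steadystate_xe Steady-state exchangeable fraction.
#' @param relaxation_minutes Width of the relaxation window (`> 0`);
#'   default 120.
#' @return Effective `x_e` at time(s) `t`.
#' @export
equilibration_loss_xe <- function(t, initial_xe, steadystate_xe,
                                  relaxation_minutes = 120) {
  if (any(relaxation_minutes <= 0)) {
    stop("relaxation_minutes must be > 0", call. = FALSE)
  }
  tau <- relaxation_minutes / 3
  steadystate_xe + (initial_xe - steadystate_xe) * exp(-t / tau)
}

#' Simulate an instrument run with known truth
#'
#' Builds the standard sequence design — an opening standard block, samples
#' with a QC analysis interleaved every `qc_interval` samples, and a
#' closing standard block — and pushes the true isotope values of every
#' analysis through the forward instrument model, in order: (1) two-pool
#' exchange mixing of the hydrogen channel with the equilibration water
#' (skipped for non-exchanging materials; time-dependent effective `x_e`
#' when equilibration loss is enabled); (2) reactor-carbon mixing of the
#' delta-13C channel on glassy-carbon runs,
#' `measured = (1-f)*true + f*reactor_delta13C`; (3) linear drift in
#' position; (4) recursive memory carry-over,
#' `y_i = (1-m)*v_i + m*y_{i-1}`; (5) i.i.d. Gaussian noise per channel.
#' Chromium runs emit the hydrogen channel only. The generator is
#' deterministic for a given seed.
#'
#' @param config A [generator_config()].
#' @param materials A [reference_materials()] registry containing the
#'   configured standards and QC material.
#' @param waters An [equilibration_waters()] registry resolving
#'   `config$water_id`.
#' @return A list with
#'   * `run` — the raw [run_sequence()];
#'   * `truth` — a tibble of true values per material: `material_id`,
#'     `role`, `d2H_ne`, `d13C`, `d18O`, `x_e`;
#'   * `materials` — the input registry extended with the generated sample
#'     materials (class only; no certified values), suitable for
#'     [reduce_run()].
#' @export
generate_run <- function(config = generator_config(),
                         materials = default_materials(),
                         waters = default_waters()) {
  stopifnot(inherits(config, "generator_config"))
  if (!config$qc_id %in% materials$id) {
    stop("generation error: registry lacks the QC material ",
         config$qc_id, call. = FALSE)
  }
  missing_std <- setdiff(config$standard_ids, materials$id)
  if (length(missing_std)) {
    stop("generation error: registry lacks standard(s): ",
         paste(missing_std, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  # --- sequence design -------------------------------------------------
  block <- c(rep(config$standard_ids, each = config$block_replicates),
             config$qc_id)
  block_roles <- c(rep("standard",
                       length(config$standard_ids) * config$block_replicates),
                   "qc")
  if (is.null(config$sample_ids)) {
    n <- config$n_samples
    sample_ids <- sprintf("SAMPLE-%02d", seq_len(n))
  } else {
    sample_ids <- config$sample_ids
    n <- length(sample_ids)
  }
  mid_ids <- character(0)
  mid_roles <- character(0)
  for (i in seq_len(n)) {
    mid_ids <- c(mid_ids, sample_ids[i])
    mid_roles <- c(mid_roles, "sample")
    if (i %% config$qc_interval == 0 && i < n) {
      mid_ids <- c(mid_ids, config$qc_id)
      mid_roles <- c(mid_roles, "qc")
    }
  }
  ids <- c(block, mid_ids, block)
  roles <- c(block_roles, mid_roles, block_roles)
  npos <- length(ids)
  positions <- seq_len(npos)
  time_offset <- config$start_delay_minutes +
    (positions - 1) * config$minutes_per_analysis

  # --- truth table -----------------------------------------------------
  reg_ids <- unique(ids[ids %in% materials$id])
  reg <- materials[match(reg_ids, materials$id), ]
  truth <- tibble::tibble(
    material_id = reg$id,
    role = ifelse(reg$id == config$qc_id, "qc", "standard"),
    d2H_ne = reg$d2H, d13C = reg$d13C, d18O = reg$d18O,
    x_e = ifelse(reg$exchanges_h,
                 ifelse(is.na(reg$x_e),
                        class_default_xe(reg$material_class), reg$x_e),
                 0)
  )
  new_ids <- setdiff(ids, materials$id)
  if (length(new_ids)) {
    truth_new <- tibble::tibble(
      material_id = new_ids,
      role = "sample",
      d2H_ne = runif(length(new_ids), -140, -60),
      d13C = runif(length(new_ids), -30, -20),
      d18O = runif(length(new_ids), 20, 35),
      x_e = class_default_xe("cellulose")
    )
    truth <- rbind(truth, truth_new)
    materials <- reference_materials(rbind(
      as.data.frame(materials),
      data.frame(id = new_ids, material_class = "cellulose",
                 d2H = NA_real_, d13C = NA_real_, d18O = NA_real_,
                 x_e = NA_real_, n_content_pct = 0, s_content_pct = 0,
                 exchanges_h = TRUE)
    ))
  }

  ti <- match(ids, truth$material_id)
  cls <- materials$material_class[match(ids, materials$id)]
  dw <- if (is.null(config$water_id)) NA_real_ else
    water_delta(waters, config$water_id)

  # --- forward instrument model ---------------------------------------
  # (1) exchange mixing of the hydrogen channel
  xe_eff <- truth$x_e[ti]
  if (!is.null(config$equilibration_loss) &&
      config$autosampler == "argon_hood") {
    el <- config$equilibration_loss
    is_cel <- !is.na(cls) & cls == "cellulose" & xe_eff > 0
    xe_eff[is_cel] <- equilibration_loss_xe(
      time_offset[is_cel], el$initial_xe, el$steadystate_xe,
      el$relaxation_minutes)
  }
  v_H <- truth$d2H_ne[ti]
  mix <- xe_eff > 0 & !is.na(v_H) & !is.na(dw)
  v_H[mix] <- forward_equilibrated_delta(v_H[mix], dw, xe_eff[mix])

  # (2) reactor-carbon mixing of the delta-13C channel
  v_C <- truth$d13C[ti]
  if (config$reactor == "glassy_carbon") {
    f <- config$reactor_carbon_fraction
    v_C <- (1 - f) * v_C + f * config$reactor_delta13C
  }
  v_O <- truth$d18O[ti]

  chans <- list(H2 = v_H, C13 = v_C, O18 = v_O)
  if (config$reactor == "chromium") {
    chans$C13 <- rep(NA_real_, npos)
    chans$O18 <- rep(NA_real_, npos)
  }
  for (iso in ISOTOPES) {
    v <- chans[[iso]]
    # (3) linear drift in position
    v <- v + config$drift_slope[[iso]] * (positions - 1)
    # (4) recursive memory carry-over
    m <- config$memory_fraction
    if (m > 0) {
      prev <- NA_real_
      for (i in seq_len(npos)) {
        if (is.na(v[i])) next
        if (!is.na(prev)) v[i] <- (1 - m) * v[i] + m * prev
        prev <- v[i]
      }
    }
    # (5) Gaussian noise
    if (config$noise_sd[[iso]] > 0) {
      ok <- !is.na(v)
      v[ok] <- v[ok] + rnorm(sum(ok), 0, config$noise_sd[[iso]])
    }
    chans[[iso]] <- v
  }

  mass_mg <- rep(1, npos)
  records <- data.frame(
    position = positions, time_offset = time_offset,
    material_id = ids, role = roles,
    d2H_raw = chans$H2, d13C_raw = chans$C13, d18O_raw = chans$O18,
    area_H2 = 2000 * mass_mg,
    area_CO = if (config$reactor == "chromium") NA_real_ else
      3000 * mass_mg,
    mass_mg = mass_mg
  )
  run <- run_sequence(records, reactor = config$reactor,
                      equilibration_water_id = config$water_id,
                      autosampler = config$autosampler,
                      seed = config$seed)
  list(run = run, truth = truth, materials = materials)
}
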