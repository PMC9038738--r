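#' Membrane model parameters
#'
#' Geometry and material parameters of the clamped circular elastomer
#' (PDMS) membrane that supports the construct. The strain-volume map used
#' here is purely kinematic (spherical-cap geometry), so only the diameter
#' enters the map; modulus and thickness are carried for documentation and
#' future force estimates. The deformable diameter is 22 or 24 mm depending
#' on construct size; the membrane's initial elastic modulus is about
#' 1 MPa. Membrane thickness has no standard value and must be supplied by
#' the user if needed.
#'
#' @param membrane_diameter_mm deformable membrane diameter, mm (default 22).
#' @param initial_elastic_modulus_MPa initial elastic modulus, MPa
#'   (default 1).
#' @param thickness_mm membrane thickness, mm (optional, no default).
#' @return A `membrane_params` list.
#' @export
membrane_params <- function(membrane_diameter_mm = 22,
                            initial_elastic_modulus_MPa = 1,
                            thickness_mm = NA_real_) {
  if (membrane_diameter_mm <= 0) stop("diameter must be positive")
  if (initial_elastic_modulus_MPa <= 0) stop("modulus must be positive")
  structure(list(membrane_diameter_mm = membrane_diameter_mm,
                 initial_elastic_modulus_MPa = initial_elastic_modulus_MPa,
                 thickness_mm = thickness_mm),
            class = "membrane_params")
}

# Closed-form spherical-cap kinematics for a clamped circular membrane of
# radius a inflated to apex height h (same length unit throughout):
#   cap volume      V(h) = pi h (3 a^2 + h^2) / 6
#   sphere radius   R(h) = (a^2 + h^2) / (2 h)
#   meridional arc  s(h) = 2 R asin(a / R)
#   radial strain   e(h) = (s - 2 a) / (2 a)
cap_volume <- function(h, a) pi * h * (3 * a^2 + h^2) / 6

cap_strain <- function(h, a) {
  out <- numeric(length(h))
  pos <- h > 0
  hp <- h[pos]
  R <- (a^2 + hp^2) / (2 * hp)
  out[pos] <- (2 * R * asin(pmin(1, a / R)) - 2 * a) / (2 * a)
  out
}

#' Average radial strain induced by a reservoir volume change
#'
#' Kinematic spherical-cap surrogate for the full nonlinear membrane
#' analysis: the inflated membrane is taken as a spherical cap over the
#' clamped circle of radius `a`, the apex height `h` is solved from the
#' displaced cap volume `dV = pi h (3 a^2 + h^2) / 6`, and the average
#' radial (meridional) strain is the relative elongation of the meridian
#' arc, `(s - 2a) / (2a)` with `s = 2 R asin(a / R)`,
#' `R = (a^2 + h^2) / (2h)`. At the hemisphere (`h = a`) the strain is
#' `(pi - 2) / 2`, about 57.1%.
#'
#' @param delta_volume_uL reservoir volume change, microliters, `>= 0`
#'   (vectorized).
#' @param params a [membrane_params()].
#' @return A `membrane_state` data.frame: `delta_volume_uL`,
#'   `cap_height_mm`, `radial_strain` (dimensionless),
#'   `radial_strain_percent`.
#' @export
cap_strain_from_volume <- function(delta_volume_uL, params = membrane_params()) {
  if (any(delta_volume_uL < 0)) stop("delta_volume_uL must be >= 0")
  a <- params$membrane_diameter_mm / 2            # mm; 1 uL == 1 mm^3
  h <- vapply(delta_volume_uL, function(v) {
    if (v == 0) return(0)
    # V(h) is strictly increasing; bracket by the hemisphere and beyond
    upper <- a
    while (cap_volume(upper, a) < v) upper <- upper * 2
    stats::uniroot(function(hh) cap_volume(hh, a) - v, c(0, upper),
                   tol = 1e-12)$root
  }, numeric(1))
  strain <- cap_strain(h, a)
  structure(data.frame(delta_volume_uL = delta_volume_uL,
                       cap_height_mm = h, radial_strain = strain,
                       radial_strain_percent = 100 * strain),
            class = c("membrane_state", "data.frame"))
}

#' Reservoir volume change required for a target radial strain
#'
#' Exact inversion of [cap_strain_from_volume()]: solves the cap height `h`
#' with strain `e(h)` equal to the target (root-finding on the closed-form
#' strain, tolerance 1e-12), then maps `h` to the cap volume in closed
#' form. Round-trip error `|strain(volume_for_strain(e)) - e|` is below
#' 1e-8. The model covers strains up to the hemisphere limit
#' `(pi - 2) / 2` (about 57.1%).
#'
#' @param target_strain_percent target strain in percent, in
#'   `[0, 100 (pi - 2) / 2)` (vectorized).
#' @param params a [membrane_params()].
#' @return Volume change(s) in microliters.
#' @export
volume_for_strain <- function(target_strain_percent,
                              params = membrane_params()) {
  eps <- target_strain_percent / 100
  emax <- (pi - 2) / 2
  if (any(eps < 0) || any(eps >= emax))
    stop(sprintf("target strain must be in [0%%, %.1f%%)", 100 * emax))
  a <- params$membrane_diameter_mm / 2
  h <- vapply(eps, function(e) {
    if (e == 0) return(0)
    stats::uniroot(function(hh) cap_strain(hh, a) - e, c(1e-12, a),
                   tol = 1e-13)$root
  }, numeric(1))
  cap_volume(h, a)
}

# Fast monotone-interpolated strain% -> volume map for long waveforms.
# Max interpolation error checked in tests (< 1e-6 strain units).
volume_interpolator <- function(params) {
  a <- params$membrane_diameter_mm / 2
  h <- seq(0, a, length.out = 4000)
  s <- 100 * cap_strain(h, a)
  v <- cap_volume(h, a)
  fn <- stats::splinefun(s, v, method = "hyman")
  function(strain_percent) {
    out <- fn(strain_percent)
    out[strain_percent <= 0] <- 0
    out
  }
}

#' Mechanical stimulation protocol specification
#'
#' An ordered list of phases, each one of:
#' \describe{
#'   \item{ramp}{`phase_ramp(start_percent, end_percent, duration_s)` —
#'     linear strain ramp; the slow conditioning ramp is 0% to 10% over
#'     7 h.}
#'   \item{rest}{`phase_rest(duration_s)` — zero strain; the conditioning
#'     day pairs the 7 h ramp with 17 h rest.}
#'   \item{cyclic}{`phase_cyclic(strain_percent, stretches_per_cycle,
#'     cycle_duration_s, cycles_per_day, days)` — the training pattern:
#'     a cycle of `stretches_per_cycle` stretch-release events evenly
#'     spaced in `cycle_duration_s`, repeated `cycles_per_day` times per
#'     day (cycles evenly spaced over each 24 h) for `days` days. The
#'     printed training protocol is 10 stretches in 10 min (1/min), 3
#'     cycles/day, 5% strain.}
#' }
#'
#' @param ... phase objects created by [phase_ramp()], [phase_rest()],
#'   [phase_cyclic()].
#' @return A `protocol_spec` list of phases.
#' @export
protocol_spec <- function(...) {
  phases <- list(...)
  if (length(phases) == 1L && is.list(phases[[1]]) &&
      !inherits(phases[[1]], "protocol_phase"))
    phases <- phases[[1]]
  for (p in phases)
    if (!inherits(p, "protocol_phase")) stop("all phases must be protocol phases")
  structure(list(phases = phases), class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param start_percent,end_percent ramp endpoints, percent strain, `>= 0`.
#' @param duration_s phase duration, seconds, `> 0`.
#' @export
phase_ramp <- function(start_percent, end_percent, duration_s) {
  if (start_percent < 0 || end_percent < 0) stop("strains must be >= 0")
  if (duration_s <= 0) stop("duration must be positive")
  structure(list(type = "ramp", start_percent = start_percent,
                 end_percent = end_percent, duration_s = duration_s),
            class = c("protocol_phase", "list"))
}

#' @rdname protocol_spec
#' @export
phase_rest <- function(duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  structure(list(type = "rest", duration_s = duration_s),
            class = c("protocol_phase", "list"))
}

#' @rdname protocol_spec
#' @param strain_percent peak strain of each stretch, percent, `>= 0`.
#' @param stretches_per_cycle stretch events per cycle.
#' @param cycle_duration_s cycle length, seconds.
#' @param cycles_per_day cycles per 24 h day.
#' @param days number of days.
#' @param stretch_duration_s duration of the triangular stretch-release
#'   event inside its slot (default 4 s: 2 s up, 2 s down); the intra-
#'   stretch waveform is a design choice, not a published value.
#' @export
phase_cyclic <- function(strain_percent, stretches_per_cycle,
                         cycle_duration_s, cycles_per_day = 1, days = 1,
                         stretch_duration_s = 4) {
  if (strain_percent < 0) stop("strains must be >= 0")
  if (stretches_per_cycle < 1 || cycle_duration_s <= 0 ||
      cycles_per_day < 1 || days < 1) stop("invalid cyclic phase")
  slot <- cycle_duration_s / stretches_per_cycle
  if (stretch_duration_s > slot)
    stop("stretch_duration_s exceeds the per-stretch slot")
  if (cycles_per_day * cycle_duration_s > 86400)
    stop("cycles do not fit in a day (overlapping phases)")
  structure(list(type = "cyclic", strain_percent = strain_percent,
                 stretches_per_cycle = as.integer(stretches_per_cycle),
                 cycle_duration_s = cycle_duration_s,
                 cycles_per_day = as.integer(cycles_per_day),
                 days = as.integer(days),
                 stretch_duration_s = stretch_duration_s),
            class = c("protocol_phase", "list"))
}

# Duration of one phase, seconds.
phase_duration <- function(p) {
  switch(p$type,
         ramp = p$duration_s,
         rest = p$duration_s,
         cyclic = p$days * 86400)
}

# Triangular stretch pulse evaluated at times t relative to pulse start.
triangle_pulse <- function(t, peak, duration) {
  half <- duration / 2
  up <- t >= 0 & t <= half
  down <- t > half & t <= duration
  out <- numeric(length(t))
  out[up] <- peak * t[up] / half
  out[down] <- peak * (duration - t[down]) / half
  out
}

#' Compile a stimulation protocol into a strain/volume waveform
#'
#' Renders the phase list onto a uniform time grid: ramps are linear in
#' strain, rests are zero, and each cyclic stretch is a symmetric
#' triangular ramp-and-release centred at the start of its slot (peak on
#' the grid whenever `stretch_duration_s / 2` is a multiple of `dt`). The
#' reservoir volume column is attached through the spherical-cap model
#' (monotone-spline inverse of the exact map). Every stretch event is
#' logged with its peak time and cycle/day indices.
#'
#' @param spec a [protocol_spec()].
#' @param params a [membrane_params()].
#' @param dt_s time step, seconds (default 1).
#' @return A `stimulation_waveform` list: `time_s`, `strain_percent`,
#'   `delta_volume_uL`, `event_log` (data.frame with `time_s`, `day`,
#'   `cycle`, `stretch`, `peak_strain_percent`), `phases` (per-phase start
#'   times).
#' @export
compile_protocol <- function(spec, params = membrane_params(), dt_s = 1) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (dt_s <= 0) stop("dt_s must be positive")
  durations <- vapply(spec$phases, phase_duration, numeric(1))
  total <- sum(durations)
  if (total == 0) {
    return(structure(list(time_s = numeric(0), strain_percent = numeric(0),
                          delta_volume_uL = numeric(0),
                          event_log = data.frame(time_s = numeric(0),
                                                 day = integer(0),
                                                 cycle = integer(0),
                                                 stretch = integer(0),
                                                 peak_strain_percent = numeric(0)),
                          phases = data.frame(start_s = numeric(0),
                                              type = character(0))),
                     class = "stimulation_waveform"))
  }
  time_s <- seq(0, total, by = dt_s)
  strain <- numeric(length(time_s))
  events <- list()
  t0 <- 0
  for (p in spec$phases) {
    dur <- phase_duration(p)
    in_phase <- time_s >= t0 & time_s < t0 + dur
    tl <- time_s[in_phase] - t0
    if (p$type == "ramp") {
      strain[in_phase] <- p$start_percent +
        (p$end_percent - p$start_percent) * tl / p$duration_s
      # the grid point landing exactly on the phase end carries the peak
      at_end <- abs(time_s - (t0 + dur)) < 1e-9
      if (any(at_end)) strain[at_end] <- pmax(strain[at_end], p$end_percent)
    } else if (p$type == "cyclic") {
      slot <- p$cycle_duration_s / p$stretches_per_cycle
      cycle_gap <- 86400 / p$cycles_per_day
      for (day in seq_len(p$days)) for (cyc in seq_len(p$cycles_per_day)) {
        cyc_start <- (day - 1) * 86400 + (cyc - 1) * cycle_gap
        for (st in seq_len(p$stretches_per_cycle)) {
          pulse_start <- cyc_start + (st - 1) * slot
          events[[length(events) + 1L]] <- data.frame(
            time_s = t0 + pulse_start + p$stretch_duration_s / 2,
            day = day, cycle = cyc, stretch = st,
            peak_strain_percent = p$strain_percent)
          sel <- tl >= pulse_start & tl <= pulse_start + p$stretch_duration_s
          if (any(sel))
            strain[in_phase][sel] <- pmax(
              strain[in_phase][sel],
              triangle_pulse(tl[sel] - pulse_start, p$strain_percent,
                             p$stretch_duration_s))
        }
      }
    }
    t0 <- t0 + dur
  }
  vol <- volume_interpolator(params)(strain)
  event_log <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), day = integer(0), cycle = integer(0),
               stretch = integer(0), peak_strain_percent = numeric(0))
  structure(list(time_s = time_s, strain_percent = strain,
                 delta_volume_uL = vol, event_log = event_log,
                 phases = data.frame(
                   start_s = cumsum(c(0, durations[-length(durations)])),
                   type = vapply(spec$phases, `[[`, character(1), "type"))),
            class = "stimulation_waveform")
}

#' @export
print.stimulation_waveform <- function(x, ...) {
  cat(sprintf(
    "<stimulation_waveform> %d samples over %.0f s, peak %.2f%%, %d stretch events\n",
    length(x$time_s), if (length(x$time_s)) max(x$time_s) else 0,
    if (length(x$strain_percent)) max(x$strain_percent) else 0,
    nrow(x$event_log)))
  invisible(x)
}

#' Check a protocol against bioreactor capability limits
#'
#' Flags phases whose peak strain or stretch frequency exceed the system
#' limits. The rig was validated up to 30% radial strain and 16 cycles per
#' minute; those are the defaults.
#'
#' @param spec a [protocol_spec()].
#' @param max_strain_percent strain limit, percent.
#' @param max_cycles_per_min frequency limit, stretch events per minute.
#' @return A `capability_report` list: `pass` and a per-phase data.frame
#'   `phases` with `type`, `peak_strain_percent`, `cycles_per_min`,
#'   `strain_ok`, `frequency_ok`.
#' @export
capability_check <- function(spec, max_strain_percent = 30,
                             max_cycles_per_min = 16) {
  stopifnot(inherits(spec, "protocol_spec"))
  rows <- lapply(spec$phases, function(p) {
    peak <- switch(p$type, ramp = max(p$start_percent, p$end_percent),
                   rest = 0, cyclic = p$strain_percent)
    freq <- if (p$type == "cyclic")
      p$stretches_per_cycle / (p$cycle_duration_s / 60) else 0
    data.frame(type = p$type, peak_strain_percent = peak,
               cycles_per_min = freq,
               strain_ok = peak <= max_strain_percent,
               frequency_ok = freq <= max_cycles_per_min)
  })
  phases <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), peak_strain_percent = numeric(0),
               cycles_per_min = numeric(0), strain_ok = logical(0),
               frequency_ok = logical(0))
  structure(list(pass = all(phases$strain_ok & phases$frequency_ok),
                 phases = phases,
                 limits = c(max_strain_percent = max_strain_percent,
                            max_cycles_per_min = max_cycles_per_min)),
            class = "capability_report")
}

#' The published two-phase stimulation protocol
#'
#' Convenience constructor for the protocol applied to dynamic constructs:
#' a conditioning week (days 3-7 of culture) of daily 0% to 10% slow ramps
#' over 7 h followed by 17 h rest, then a training week (days 8-14) of 3
#' cycles/day, each 10 stretches in 10 min (1 stretch/min) at 5% strain.
#'
#' @param ramp_days number of conditioning days (default 5).
#' @param training_days number of training days (default 7).
#' @return A [protocol_spec()].
#' @export
standard_protocol <- function(ramp_days = 5, training_days = 7) {
  phases <- list()
  for (i in seq_len(ramp_days)) {
    phases <- c(phases, list(phase_ramp(0, 10, 7 * 3600),
                             phase_rest(17 * 3600)))
  }
  if (training_days > 0)
    phases <- c(phases, list(phase_cyclic(5, 10, 600, cycles_per_day = 3,
                                          days = training_days)))
  protocol_spec(phases)
}
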