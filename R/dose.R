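#' Intranasal dosing specification
#'
#' Captures the droplet-based intranasal administration schedule: the
#' solution is delivered as small droplets to alternating nares at a
#' fixed interval over a session. The delivered protein mass is computed
#' from the total session volume x concentration; droplet size and
#' timing are carried as metadata only (the session label "about 20 min"
#' in such protocols includes handling time, so the volume, not the
#' nominal duration / interval quotient, is authoritative).
#'
#' @param session_volume_ul total solution volume delivered per session
#'   in microlitres; default 24 (8 droplets of 3 uL).
#' @param concentration_mg_ml solution concentration in mg/mL; default
#'   16.67.
#' @param sessions number of sessions in the study; default 3 (one per
#'   week for three weeks).
#' @param droplet_volume_ul volume per droplet in microlitres (metadata).
#' @param interval_min minutes between droplets (metadata).
#' @param session_min nominal session duration in minutes (metadata).
#' @return list of class `dose_spec`.
#' @export
dose_spec <- function(session_volume_ul = 24, concentration_mg_ml = 16.67,
                      sessions = 3, droplet_volume_ul = 3,
                      interval_min = 2, session_min = 20) {
  if (session_volume_ul < 0 || droplet_volume_ul < 0) {
    stop("volumes must be >= 0")
  }
  if (concentration_mg_ml <= 0 || sessions <= 0 || interval_min <= 0 ||
      session_min <= 0) {
    stop("concentration, sessions, interval and session duration must be > 0")
  }
  structure(list(session_volume_ul = session_volume_ul,
                 concentration_mg_ml = concentration_mg_ml,
                 sessions = sessions,
                 droplet_volume_ul = droplet_volume_ul,
                 interval_min = interval_min, session_min = session_min),
            class = "dose_spec")
}

#' Delivered protein mass per session and per study
#'
#' Session mass (mg) = session volume (uL) x concentration (mg/mL) / 1000;
#' study mass = session mass x sessions. With the defaults (24 uL of
#' 16.67 mg/mL solution, 3 sessions) this gives 0.40008 mg per session,
#' about 0.4 mg, and about 1.2 mg per study.
#'
#' @param spec a [dose_spec()].
#' @return list with `droplets` (implied droplet count),
#'   `session_volume_ul`, `session_mass_mg`, `study_mass_mg`.
#' @export
session_dose <- function(spec = dose_spec()) {
  stopifnot(inherits(spec, "dose_spec"))
  session_mg <- spec$session_volume_ul * spec$concentration_mg_ml / 1000
  droplets <- if (spec$droplet_volume_ul > 0) {
    spec$session_volume_ul / spec$droplet_volume_ul
  } else NA_real_
  list(droplets = droplets,
       session_volume_ul = spec$session_volume_ul,
       session_mass_mg = session_mg,
       study_mass_mg = session_mg * spec$sessions)
}
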