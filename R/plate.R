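#' Simulated microwell plate state
#'
#' Bookkeeping for plate-reader cultures maintained by a pipetting robot:
#' per-well volume, optical density, antibiotic concentration, and the time
#' since the well was last diluted. Evaporation removes water only, so
#' solutes (cells, drug) concentrate as volume shrinks; every liquid-handling
#' action updates concentrations by conservation of amount.
#'
#' @param wells character vector of well names.
#' @param volume_ul initial volumes, uL (recycled; nominal 200).
#' @param od initial blank-subtracted OD_600 values (recycled).
#' @param antibiotic initial drug concentrations, mg/L (recycled).
#' @param blank_od blank (medium-only) OD_600 reading (recycled).
#' @param evaporation_ul_h true evaporation rate, uL/h (default 10).
#' @param nominal_ul nominal working volume, uL (default 200).
#' @return A `plate_state` object: a data.frame of wells plus plate-level
#'   fields in attributes.
#' @export
plate_state <- function(wells, volume_ul = 200, od = 0, antibiotic = 0,
                        blank_od = 0, evaporation_ul_h = 10,
                        nominal_ul = 200) {
  df <- data.frame(well = wells, volume_ul = volume_ul, od = od,
                   antibiotic = antibiotic, blank_od = blank_od,
                   since_dilution_h = 0, stringsAsFactors = FALSE)
  if (any(df$volume_ul <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (any(df$antibiotic < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(df, class = c("plate_state", "data.frame"),
            evaporation_ul_h = evaporation_ul_h, nominal_ul = nominal_ul)
}

#' Advance plate evaporation
#'
#' Removes `evaporation_ul_h * dt` uL of water from every well; cell and drug
#' concentrations rise by the inverse volume ratio (conservation of amount).
#' Growth is not modeled here: the plate simulator tracks liquid-handling
#' bookkeeping; any growth/kill response is applied by the caller between
#' steps via `update_od()`.
#'
#' @param plate a [plate_state()].
#' @param dt elapsed time, h.
#' @export
plate_evaporate <- function(plate, dt) {
  ev <- attr(plate, "evaporation_ul_h")
  v_new <- pmax(plate$volume_ul - ev * dt, 1e-6)
  scale <- plate$volume_ul / v_new
  plate$od <- plate$od * scale
  plate$antibiotic <- plate$antibiotic * scale
  plate$volume_ul <- v_new
  plate$since_dilution_h <- plate$since_dilution_h + dt
  plate
}

# add `vol` uL of medium with drug concentration `conc` to well rows `i`
mix_into <- function(plate, i, vol, conc = 0, od_added = 0) {
  v0 <- plate$volume_ul[i]
  v1 <- v0 + vol
  plate$od[i] <- (plate$od[i] * v0 + od_added * vol) / v1
  plate$antibiotic[i] <- (plate$antibiotic[i] * v0 + conc * vol) / v1
  plate$volume_ul[i] <- v1
  plate
}

#' Evaporation-compensated dilution protocol
#'
#' The robot's maintenance rule for long-running plate cultures:
#' * if the median blank-subtracted OD across the well group exceeds
#'   `threshold`, every well is diluted — add 100 uL of medium (carrying the
#'   well's configured antibiotic concentration), mix, then remove
#'   `100 - E` uL where `E` is the estimated evaporation since the last
#'   dilution (`evap_estimate_ul_h` x time since last dilution). Removal of
#'   well-mixed culture changes no concentration; when the estimate matches
#'   the true rate the volume returns exactly to nominal.
#' * otherwise, if `force_after_h` (default 10 h) have elapsed with no
#'   dilution, 100 uL of medium are added with no removal (the volume left
#'   after that much evaporation would be too low to pipette reliably).
#'
#' If the evaporation estimate exceeds 100 uL the removal volume is clamped
#' at zero and a warning is recorded in the returned action.
#'
#' @param plate a [plate_state()].
#' @param threshold OD threshold for dilution (paper values 0.05 or 0.1).
#' @param media_antibiotic named numeric (per well) or scalar: drug
#'   concentration of the feed medium, mg/L.
#' @param add_ul volume added per action, uL (default 100).
#' @param evap_estimate_ul_h the robot's estimate of the evaporation rate,
#'   uL/h (default 10 — matching the true default rate).
#' @param force_after_h forced-feed interval, h (default 10).
#' @return List with `action` (`"dilute"`, `"force-feed"`, or `"none"`),
#'   `plate` (updated state) and `warnings` (character).
#' @export
plate_dilution_protocol <- function(plate, threshold,
                                    media_antibiotic = 0, add_ul = 100,
                                    evap_estimate_ul_h = 10,
                                    force_after_h = 10) {
  conc <- rep_len(media_antibiotic, nrow(plate))
  med_od <- stats::median(plate$od)   # od is already blank-subtracted
  warnings <- character(0)
  if (med_od > threshold) {
    for (i in seq_len(nrow(plate))) {
      E <- evap_estimate_ul_h * plate$since_dilution_h[i]
      plate <- mix_into(plate, i, add_ul, conc[i])
      remove <- add_ul - E
      if (remove <= 0) {
        warnings <- c(warnings, sprintf(
          "well %s: evaporation estimate %.1f uL >= %.0f uL, removal clamped to 0",
          plate$well[i], E, add_ul))
        remove <- 0
      }
      plate$volume_ul[i] <- plate$volume_ul[i] - remove   # mixed removal:
      plate$since_dilution_h[i] <- 0                      # concentrations keep
    }
    return(list(action = "dilute", plate = plate, warnings = warnings))
  }
  if (any(plate$since_dilution_h >= force_after_h)) {
    for (i in which(plate$since_dilution_h >= force_after_h)) {
      plate <- mix_into(plate, i, add_ul, conc[i])
      plate$since_dilution_h[i] <- 0
    }
    return(list(action = "force-feed", plate = plate, warnings = warnings))
  }
  list(action = "none", plate = plate, warnings = warnings)
}

#' Treat a well with an antibiotic (or medium-only) bolus
#'
#' Adds 50 uL (default) of treatment solution at concentration `dose` to one
#' well; drug and cell concentrations update by conservation (cells are
#' diluted by the volume ratio, drug mixes in).
#'
#' @param plate a [plate_state()].
#' @param well well name.
#' @param dose drug concentration of the added solution, mg/L (0 for
#'   medium-only).
#' @param vol_ul added volume, uL (default 50).
#' @export
treat_well <- function(plate, well, dose, vol_ul = 50) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  i <- match(well, plate$well)
  if (is.na(i)) stop("unknown well: ", well, call. = FALSE)
  mix_into(plate, i, vol_ul, dose)
}

#' Set measured ODs on the plate (growth applied externally)
#'
#' @param plate a [plate_state()].
#' @param od new OD_600 values (recycled over wells).
#' @export
update_od <- function(plate, od) {
  plate$od <- rep_len(od, nrow(plate))
  plate
}

#' Clean a plate-reader OD series
#'
#' Blank-subtracts each measurement with its time-aligned control-well
#' reading, and removes aberrant early points: measurements whose *raw* OD
#' exceeds 3e-3 during the first 2 h of the experiment (an instrument
#' artifact window; later spikes are retained as data).
#'
#' @param times measurement times, h.
#' @param od raw OD_600 measurements.
#' @param blank OD_600 of the medium-only control well, same length.
#' @param spike_threshold raw-OD threshold (default 3e-3).
#' @param spike_window_h artifact window from experiment start, h (default 2).
#' @return data.frame with `t` and `od` (cleaned, flagged rows removed), plus
#'   attribute `removed` (count of removed measurements).
#' @export
clean_od <- function(times, od, blank, spike_threshold = 3e-3,
                     spike_window_h = 2) {
  if (length(times) != length(od) || length(od) != length(blank))
    stop("times, od and blank must be aligned (equal lengths)", call. = FALSE)
  bad <- times < spike_window_h & od > spike_threshold
  out <- data.frame(t = times[!bad], od = od[!bad] - blank[!bad])
  attr(out, "removed") <- sum(bad)
  out
}
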