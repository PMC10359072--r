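#' Construct an rTMS protocol
#'
#' A stimulation protocol is a train structure: `trains` trains of
#' `pulses_per_train` pulses delivered at `stimulation_frequency_hz`, separated
#' by `inter_train_interval_s` seconds. Intermittent theta-burst stimulation
#' (iTBS) nests bursts inside trains: bursts of `pulses_per_burst` pulses at
#' `intra_burst_hz` are delivered at `burst_rate_hz`, so the effective train
#' duration is `(pulses_per_train / pulses_per_burst) / burst_rate_hz` seconds.
#'
#' @param name One of `"iTBS"`, `"high_frequency"`, `"low_frequency"`.
#' @param motor_threshold_fraction Stimulation intensity as a fraction of the
#'   resting motor threshold (e.g. 0.8 for 80% RMT).
#' @param stimulation_frequency_hz Pulse frequency in Hz (for iTBS this is the
#'   intra-burst frequency; the burst structure governs timing).
#' @param trains,pulses_per_train Number of trains and pulses per train.
#' @param inter_train_interval_s Pause after each train, seconds.
#' @param side `"ipsilesional"` or `"contralesional"` stimulation site.
#' @param target Cortical target label; `"M1"` (primary motor cortex).
#' @param burst_rate_hz,pulses_per_burst,intra_burst_hz iTBS burst structure;
#'   ignored for plain repetitive protocols.
#' @return A list of class `tms_protocol`.
#' @seealso [total_pulses()], [session_duration_minutes()], [tms_protocols()]
#' @export
tms_protocol <- function(name = c("iTBS", "high_frequency", "low_frequency"),
                         motor_threshold_fraction,
                         stimulation_frequency_hz,
                         trains, pulses_per_train, inter_train_interval_s,
                         side = c("ipsilesional", "contralesional"),
                         target = "M1",
                         burst_rate_hz = if (name == "iTBS") 5 else NA_real_,
                         pulses_per_burst = if (name == "iTBS") 3 else NA_real_,
                         intra_burst_hz = if (name == "iTBS") 50 else NA_real_) {
  name <- match.arg(name)
  side <- match.arg(side)
  counts <- c(trains = trains, pulses_per_train = pulses_per_train)
  if (any(!is.finite(counts)) || any(counts <= 0) || any(counts != round(counts))) {
    rlang::abort("trains and pulses_per_train must be positive integers")
  }
  if (!is.finite(inter_train_interval_s) || inter_train_interval_s < 0) {
    rlang::abort("inter_train_interval_s must be non-negative")
  }
  if (!is.finite(motor_threshold_fraction) || motor_threshold_fraction <= 0) {
    rlang::abort("motor_threshold_fraction must be positive")
  }
  if (name == "iTBS") {
    if (any(!is.finite(c(burst_rate_hz, pulses_per_burst))) ||
        burst_rate_hz <= 0 || pulses_per_burst <= 0) {
      rlang::abort("iTBS needs positive burst_rate_hz and pulses_per_burst")
    }
    if (pulses_per_train %% pulses_per_burst != 0) {
      rlang::abort("iTBS pulses_per_train must be divisible by pulses_per_burst")
    }
  } else if (!is.finite(stimulation_frequency_hz) || stimulation_frequency_hz <= 0) {
    rlang::abort("stimulation_frequency_hz must be positive")
  }
  structure(
    list(
      name = name,
      motor_threshold_fraction = motor_threshold_fraction,
      stimulation_frequency_hz = stimulation_frequency_hz,
      trains = as.integer(trains),
      pulses_per_train = as.integer(pulses_per_train),
      inter_train_interval_s = inter_train_interval_s,
      side = side,
      target = target,
      burst_rate_hz = burst_rate_hz,
      pulses_per_burst = pulses_per_burst,
      intra_burst_hz = intra_burst_hz
    ),
    class = "tms_protocol"
  )
}

#' The three study protocols
#'
#' The protocols administered in the treatment arms: iTBS at 80% RMT
#' (20 trains of 30 pulses as 5 Hz bursts of 3 pulses at 50 Hz, 8 s intervals,
#' ipsilesional M1), high-frequency 10 Hz at 90% RMT (100 trains of 10 pulses,
#' 10 s intervals, ipsilesional M1) and low-frequency 1 Hz at 90% RMT
#' (100 trains of 10 pulses, 2 s intervals, contralesional M1).
#'
#' @return A named list of three [tms_protocol()] objects.
#' @examples
#' sapply(tms_protocols(), total_pulses)
#' sapply(tms_protocols(), session_duration_minutes)
#' @export
tms_protocols <- function() {
  list(
    iTBS = tms_protocol("iTBS", 0.80, 50, trains = 20, pulses_per_train = 30,
                        inter_train_interval_s = 8, side = "ipsilesional"),
    high_frequency = tms_protocol("high_frequency", 0.90, 10, trains = 100,
                                  pulses_per_train = 10,
                                  inter_train_interval_s = 10,
                                  side = "ipsilesional"),
    low_frequency = tms_protocol("low_frequency", 0.90, 1, trains = 100,
                                 pulses_per_train = 10,
                                 inter_train_interval_s = 2,
                                 side = "contralesional")
  )
}

#' Total pulses delivered in one session
#'
#' @param protocol A [tms_protocol()].
#' @return `trains * pulses_per_train`.
#' @export
total_pulses <- function(protocol) {
  stopifnot(inherits(protocol, "tms_protocol"))
  protocol$trains * protocol$pulses_per_train
}

#' Session duration in whole minutes
#'
#' Active time per train is `pulses_per_train / stimulation_frequency_hz`
#' (for iTBS, `(pulses_per_train / pulses_per_burst) / burst_rate_hz`); the
#' inter-train interval is counted after every train, including the last, and
#' the total is floored to whole minutes. This is the convention under which
#' the three study protocols last 3, 18 and 20 minutes.
#'
#' @param protocol A [tms_protocol()].
#' @return Whole minutes (integer-valued numeric).
#' @export
session_duration_minutes <- function(protocol) {
  stopifnot(inherits(protocol, "tms_protocol"))
  active_s <- if (protocol$name == "iTBS") {
    (protocol$pulses_per_train / protocol$pulses_per_burst) / protocol$burst_rate_hz
  } else {
    protocol$pulses_per_train / protocol$stimulation_frequency_hz
  }
  total_s <- protocol$trains * (active_s + protocol$inter_train_interval_s)
  floor(total_s / 60)
}

#' Summarize a set of protocols as a table
#'
#' @param protocols A list of [tms_protocol()] objects (default: the three
#'   study protocols).
#' @return A tibble with one row per protocol including derived `total_pulses`
#'   and `duration_min`.
#' @export
tms_protocol_table <- function(protocols = tms_protocols()) {
  purrr::map_dfr(protocols, function(p) {
    tibble::tibble(
      protocol = p$name,
      motor_threshold = p$motor_threshold_fraction,
      frequency_hz = p$stimulation_frequency_hz,
      trains = p$trains,
      pulses_per_train = p$pulses_per_train,
      inter_train_interval_s = p$inter_train_interval_s,
      total_pulses = total_pulses(p),
      duration_min = session_duration_minutes(p),
      side = p$side,
      target = p$target
    )
  })
}
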