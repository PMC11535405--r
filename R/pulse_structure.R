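## Temporal structure of irradiation: rectangular pulse trains, bunch
## emission times and the dose-rate profile that drives the chemistry.

#' Construct a rectangular pulse train
#'
#' @param dose_per_pulse Dose per pulse, Gy (> 0).
#' @param width Pulse width, s; 0 denotes an instantaneous pulse (all
#'   electrons share one emission time and the dose enters as a discrete
#'   deposit).
#' @param n_pulses Number of pulses (>= 1).
#' @param frequency Pulse repetition frequency, Hz; required when
#'   `n_pulses > 1`. Pulse i starts at (i-1)/frequency.
#' @return Object of class `pulse_train` with fields `dose_per_pulse`,
#'   `width`, `n_pulses`, `frequency`, `starts` (pulse start times, s) and
#'   `shape = "rectangular"`.
#' @examples
#' make_pulse_train(10, 1.8e-6)                 # single 10 Gy, 1.8 us pulse
#' make_pulse_train(1, 1.8e-6, 10, 100)         # 10 pulses at 100 Hz
#' @export
make_pulse_train <- function(dose_per_pulse, width, n_pulses = 1,
                             frequency = NA_real_) {
  stopifnot(dose_per_pulse > 0, width >= 0, n_pulses >= 1)
  if (n_pulses > 1) {
    if (is.na(frequency) || frequency <= 0) {
      stop("frequency required (and > 0) for multi-pulse trains")
    }
    if (width >= 1 / frequency) {
      stop(sprintf("pulses overlap: width %g s >= period %g s",
                   width, 1 / frequency))
    }
  }
  starts <- if (n_pulses > 1) (seq_len(n_pulses) - 1) / frequency else 0
  structure(
    list(dose_per_pulse = dose_per_pulse, width = width,
         n_pulses = as.integer(n_pulses), frequency = frequency,
         starts = starts, shape = "rectangular"),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  w <- if (x$width == 0) "instantaneous" else sprintf("%.3g s wide", x$width)
  cat(sprintf("<pulse_train> %d x %.3g Gy, %s", x$n_pulses,
              x$dose_per_pulse, w))
  if (x$n_pulses > 1) cat(sprintf(", %.4g Hz", x$frequency))
  cat("\n")
  invisible(x)
}

#' Sample electron bunch emission times within a pulse train
#'
#' Electrons are grouped into bunches of `per_bunch` that share one emission
#' time; `ceiling(n_electrons / per_bunch)` bunch times are placed in each
#' pulse window. The last bunch carries the remainder when `per_bunch` does
#' not divide `n_electrons`. Placement is uniform random in the window
#' (`mode = "uniform"`, the rectangular default) or evenly spaced
#' (`mode = "even"`). A zero-width pulse puts every bunch at the pulse start.
#' Draws come from the session RNG; fix with [set.seed()] for
#' reproducibility.
#'
#' @param n_electrons Electrons per pulse (>= 1).
#' @param per_bunch Electrons per bunch (>= 1).
#' @param pulse A `pulse_train` (only its first pulse window is used unless
#'   `pulse_index` is given).
#' @param mode "uniform" or "even".
#' @param pulse_index Which pulse of the train to populate (default 1).
#' @return Object of class `bunch_schedule`: list with sorted
#'   `emission_times` (s), `electrons_per_bunch` (per-bunch electron counts,
#'   same length) and `n_electrons`.
#' @examples
#' set.seed(1)
#' s <- sample_emission_times(5000, 500, make_pulse_train(10, 1.8e-6))
#' length(s$emission_times)  # 10
#' @export
sample_emission_times <- function(n_electrons, per_bunch, pulse,
                                  mode = c("uniform", "even"),
                                  pulse_index = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pulse, "pulse_train"), n_electrons >= 1, per_bunch >= 1,
            pulse_index >= 1, pulse_index <= pulse$n_pulses)
  n_bunches <- ceiling(n_electrons / per_bunch)
  counts <- rep(per_bunch, n_bunches)
  counts[n_bunches] <- n_electrons - per_bunch * (n_bunches - 1)
  t0 <- pulse$starts[pulse_index]
  if (pulse$width == 0) {
    times <- rep(t0, n_bunches)
  } else if (mode == "uniform") {
    times <- sort(stats::runif(n_bunches, t0, t0 + pulse$width))
  } else {
    # even: bunch centers of n equal sub-intervals
    times <- t0 + pulse$width * (seq_len(n_bunches) - 0.5) / n_bunches
  }
  structure(
    list(emission_times = times, electrons_per_bunch = counts,
         n_electrons = as.integer(n_electrons), mode = mode),
    class = "bunch_schedule"
  )
}

#' Instantaneous dose rate of a rectangular pulse train
#'
#' Returns `dose_per_pulse / width` inside any pulse window and 0 outside.
#' Instantaneous (zero-width) pulses have no finite dose rate; they are
#' handled as discrete deposits by the integrator, and calling this profile
#' on such a train is an error.
#'
#' @param train A `pulse_train` with `width > 0`.
#' @param t Time(s), s (vectorized).
#' @return Dose rate(s), Gy/s.
#' @examples
#' dose_rate_profile(make_pulse_train(10, 1.8e-6), 1e-6)  # 5.556e6 Gy/s
#' @export
dose_rate_profile <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"))
  if (train$width == 0) {
    stop("instantaneous pulse has no finite dose rate; use the event path")
  }
  rate <- train$dose_per_pulse / train$width
  inside <- vapply(t, function(ti) {
    any(ti >= train$starts & ti < train$starts + train$width)
  }, logical(1))
  ifelse(inside, rate, 0)
}

#' The four study irradiation scenarios
#'
#' The single-pulse electron-linac scenarios investigated: dose-per-pulse
#' 0.17, 1, 5 and 10 Gy, all with a 1.8 us rectangular pulse (the 5 Gy case
#' also exists as an instantaneous variant), electron bunching 1/10/50/500
#' per bunch, and the nominal source-to-surface distance of each setup as an
#' annotation.
#'
#' @return data.frame with columns `name`, `dose_per_pulse_Gy`,
#'   `pulse_width_s`, `electrons_per_bunch`, `ssd_cm`, `instantaneous`.
#' @examples
#' scenario_table()
#' @export
scenario_table <- function() {
  data.frame(
    name = c("0.17Gy", "1Gy", "5Gy", "5Gy-instant", "10Gy"),
    dose_per_pulse_Gy = c(0.17, 1, 5, 5, 10),
    pulse_width_s = c(1.8e-6, 1.8e-6, 1.8e-6, 0, 1.8e-6),
    electrons_per_bunch = c(1L, 10L, 50L, 50L, 500L),
    ssd_cm = c(190, 95, 46, 46, 34),
    instantaneous = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build the pulse train of a named scenario
#'
#' @param name One of `scenario_table()$name`.
#' @return A `pulse_train`.
#' @export
scenario_pulse_train <- function(name) {
  tab <- scenario_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(tab$name, collapse = ", ")))
  }
  make_pulse_train(row$dose_per_pulse_Gy, row$pulse_width_s)
}
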