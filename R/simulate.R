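#' Synthetic beat-stream generator configuration
#'
#' Parameters of the two rhythm models the generator emulates:
#'
#' * **Sinus rhythm (NSR)** — heart rate drifts slowly around a mean
#'   (sinusoidal respiratory-scale drift) with small beat-to-beat Gaussian
#'   variability, so successive beats occupy only a handful of adjacent
#'   5-bpm states.
#' * **Atrial fibrillation (AF)** — ventricular response is highly
#'   irregular and nearly memoryless; RR intervals are drawn i.i.d. uniform
#'   over a wide range (default 300-1000 ms, i.e. 60-200 bpm), spreading
#'   occupancy across dozens of states.
#'
#' @param seed integer RNG seed; `NA` leaves the current RNG state alone.
#' @param n_beats default stream length for the single-rhythm generators.
#' @param nsr_hr_mean mean sinus heart rate, bpm. Default 70.
#' @param nsr_hr_sd beat-to-beat HR standard deviation, bpm. Default 2.
#' @param nsr_drift_amp amplitude of the slow HR drift, bpm. Default 3.
#' @param nsr_drift_period drift period in beats. Default 60.
#' @param af_rr_min,af_rr_max bounds of the AF RR distribution, ms.
#'   Defaults 300 and 1000.
#' @param episode_spec data frame with columns `rhythm` (`"NSR"`/`"AF"`)
#'   and `n_beats`, consumed by [gen_paroxysmal()]. Default
#'   NSR 500 / AF 500 / NSR 500.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = NA_integer_, n_beats = 2000L,
                       nsr_hr_mean = 70, nsr_hr_sd = 2,
                       nsr_drift_amp = 3, nsr_drift_period = 60,
                       af_rr_min = 300, af_rr_max = 1000,
                       episode_spec = data.frame(
                         rhythm = c("NSR", "AF", "NSR"),
                         n_beats = c(500L, 500L, 500L))) {
  if (n_beats <= 0L) stop("`n_beats` must be positive", call. = FALSE)
  if (af_rr_min >= af_rr_max) stop("`af_rr_min` must be < `af_rr_max`", call. = FALSE)
  if (nsr_hr_sd < 0) stop("`nsr_hr_sd` must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(episode_spec),
            all(c("rhythm", "n_beats") %in% names(episode_spec)))
  structure(list(seed = seed, n_beats = as.integer(n_beats),
                 nsr_hr_mean = nsr_hr_mean, nsr_hr_sd = nsr_hr_sd,
                 nsr_drift_amp = nsr_drift_amp,
                 nsr_drift_period = nsr_drift_period,
                 af_rr_min = af_rr_min, af_rr_max = af_rr_max,
                 episode_spec = episode_spec),
            class = "sim_config")
}

maybe_seed <- function(config) {
  if (!is.na(config$seed)) set.seed(as.integer(config$seed))
}

nsr_rr <- function(config, n) {
  i <- seq_len(n) - 1L
  hr <- config$nsr_hr_mean +
    config$nsr_drift_amp * sin(2 * pi * i / config$nsr_drift_period) +
    stats::rnorm(n, 0, config$nsr_hr_sd)
  hr <- pmax(hr, 20)  # guard: HR cannot drift non-physiologically low
  60000 / hr
}

af_rr <- function(config, n) {
  stats::runif(n, config$af_rr_min, config$af_rr_max)
}

#' Generate a sinus-rhythm beat stream
#'
#' Heart rate follows `mean + drift_amp * sin(2*pi*i/period) + N(0, sd)`
#' per beat, converted to RR intervals; all beats are labelled `NONAF`.
#'
#' @param config a [sim_config()]; its `seed` (if not `NA`) seeds the RNG.
#' @param n number of beats; defaults to `config$n_beats`.
#' @param record_id record identifier.
#' @return a [beat_stream()] with `NONAF` labels.
#' @examples
#' gen_nsr(sim_config(seed = 1), n = 10)
#' @export
gen_nsr <- function(config = sim_config(), n = config$n_beats,
                    record_id = "sim_nsr") {
  if (n <= 0L) stop("`n` must be positive", call. = FALSE)
  maybe_seed(config)
  beat_stream(nsr_rr(config, n), labels = rep("NONAF", n),
              record_id = record_id)
}

#' Generate an atrial-fibrillation beat stream
#'
#' RR intervals are drawn i.i.d. uniform on
#' `[af_rr_min, af_rr_max]` — the simplest model of AF's near-memoryless
#' irregular ventricular response; all beats are labelled `AF`.
#'
#' @inheritParams gen_nsr
#' @return a [beat_stream()] with `AF` labels.
#' @examples
#' gen_af(sim_config(seed = 1), n = 10)
#' @export
gen_af <- function(config = sim_config(), n = config$n_beats,
                   record_id = "sim_af") {
  if (n <= 0L) stop("`n` must be positive", call. = FALSE)
  maybe_seed(config)
  beat_stream(af_rr(config, n), labels = rep("AF", n), record_id = record_id)
}

#' Generate a paroxysmal-AF beat stream
#'
#' Concatenates sinus-rhythm and AF segments according to
#' `config$episode_spec`, carrying a single RNG stream across segments so
#' the whole record is reproducible from one seed. Ground-truth labels
#' switch exactly at the episode boundaries (cumulative segment lengths).
#'
#' @param config a [sim_config()]; `episode_spec` defines the segments.
#' @param record_id record identifier.
#' @return a [beat_stream()] with per-beat ground-truth labels.
#' @examples
#' bs <- gen_paroxysmal(sim_config(seed = 42))
#' table(bs$labels)
#' @export
gen_paroxysmal <- function(config = sim_config(), record_id = "sim_parox") {
  spec <- config$episode_spec
  if (nrow(spec) == 0L) stop("`episode_spec` must be nonempty", call. = FALSE)
  if (any(spec$n_beats <= 0L)) stop("episode lengths must be positive", call. = FALSE)
  bad <- which(!spec$rhythm %in% c("NSR", "AF"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown rhythm %s in episode_spec", dQuote(spec$rhythm[bad[1L]])),
         call. = FALSE)
  }
  maybe_seed(config)
  rr <- numeric(0); labels <- character(0)
  for (j in seq_len(nrow(spec))) {
    n <- spec$n_beats[j]
    if (spec$rhythm[j] == "NSR") {
      rr <- c(rr, nsr_rr(config, n))
      labels <- c(labels, rep("NONAF", n))
    } else {
      rr <- c(rr, af_rr(config, n))
      labels <- c(labels, rep("AF", n))
    }
  }
  beat_stream(rr, labels = labels, record_id = record_id)
}
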