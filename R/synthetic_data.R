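# Synthetic paired SaO2/SpO2 study generator. Produces measurement
# tables with the statistical structure a desaturation validation study
# assumes: first-order physiological lag toward each Severinghaus
# target, device bias growing at low saturation, trailing-window
# averaging lag, and saturation-dependent missingness.

#' Parametric oximeter error model
#'
#' Describes a simulated pulse oximeter. The displayed reading is a
#' trailing moving average of the true saturation over
#' `averaging_window` seconds (the mechanism behind lag during rapid
#' desaturation), shifted by a saturation-dependent bias
#' \eqn{b(s) = b_0 + m \cdot \max(0, 95 - s)} and Gaussian noise, then
#' rounded to the display resolution. The attempt fails (a missing
#' reading) with probability `missingness_base`, raised by
#' `missingness_low_sat_boost` when the true saturation is below 70.
#'
#' @param bias_at_full_sat Bias \eqn{b_0} in percent at high saturation.
#' @param bias_slope Additional bias per percentage point of
#'   desaturation below 95 (captures growing overestimation at low
#'   SaO2).
#' @param noise_sd Reading noise standard deviation, percent.
#' @param averaging_window Trailing averaging window, seconds (>= 0).
#' @param missingness_base Baseline probability of a failed attempt.
#' @param missingness_low_sat_boost Extra failure probability when true
#'   SaO2 < 70.
#' @param display_rounding Display resolution in percent (1 = integer
#'   display, as consumer and clinical oximeters show).
#' @param sensor_type `"transmissive"` (finger clip) or `"reflectance"`
#'   (wrist sensor); only used by the regulatory threshold check.
#' @return An object of class `oxi_device_model`.
#' @export
device_error_model <- function(bias_at_full_sat = 0,
                               bias_slope = 0,
                               noise_sd = 0,
                               averaging_window = 0,
                               missingness_base = 0,
                               missingness_low_sat_boost = 0,
                               display_rounding = 1,
                               sensor_type = c("transmissive", "reflectance")) {
  sensor_type <- match.arg(sensor_type)
  probs <- c(missingness_base, missingness_low_sat_boost)
  if (any(probs < 0) || any(probs > 1)) {
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (averaging_window < 0) stop("`averaging_window` must be >= 0", call. = FALSE)
  structure(
    list(
      bias_at_full_sat = bias_at_full_sat,
      bias_slope = bias_slope,
      noise_sd = noise_sd,
      averaging_window = averaging_window,
      missingness_base = missingness_base,
      missingness_low_sat_boost = missingness_low_sat_boost,
      display_rounding = display_rounding,
      sensor_type = sensor_type
    ),
    class = "oxi_device_model"
  )
}

#' Participant physiological model
#'
#' @param participant_id Identifier string.
#' @param ita Individual typology angle, degrees.
#' @param response_time_constant First-order time constant (seconds) of
#'   the participant's true SaO2 relaxing toward each step's
#'   Severinghaus target; must be > 0.
#' @param sao2_measurement_noise_sd Blood-gas analyzer measurement noise
#'   standard deviation, percent (>= 0).
#' @return An object of class `oxi_participant`.
#' @export
participant_model <- function(participant_id,
                              ita = 0,
                              response_time_constant = 40,
                              sao2_measurement_noise_sd = 0.3) {
  if (response_time_constant <= 0) {
    stop("`response_time_constant` must be > 0 seconds", call. = FALSE)
  }
  if (sao2_measurement_noise_sd < 0) {
    stop("`sao2_measurement_noise_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      ita = ita,
      response_time_constant = response_time_constant,
      sao2_measurement_noise_sd = sao2_measurement_noise_sd
    ),
    class = "oxi_participant"
  )
}

#' Default nine-participant cohort
#'
#' Nine participants whose ITA values span the tan/light/intermediate/
#' brown bands observed in a typical healthy-volunteer cohort, each with
#' a first-order desaturation response constant of 40 s and 0.3 percent
#' blood-gas measurement noise.
#'
#' @return List of `oxi_participant` objects.
#' @export
default_participants <- function() {
  itas <- c(23, 54, -27, -8, 12, 39, 2, -1, 7)
  lapply(seq_along(itas), function(i) {
    participant_model(sprintf("P%02d", i), ita = itas[i])
  })
}

#' Default pair of simulated devices
#'
#' A transmissive finger oximeter with small bias, short averaging
#' window and near-zero missingness, and a reflectance wrist device with
#' larger saturation-dependent bias, a longer window and substantial
#' missingness at low saturation. Magnitudes are chosen to emulate the
#' error structure reported for clinical-grade finger oximeters versus
#' consumer wrist wearables under induced hypoxemia.
#'
#' @return Named list of `oxi_device_model` objects
#'   (`finger`, `watch`).
#' @export
default_device_models <- function() {
  list(
    finger = device_error_model(
      bias_at_full_sat = 0.5, bias_slope = 0.08, noise_sd = 2.0,
      averaging_window = 10, missingness_base = 0.005,
      missingness_low_sat_boost = 0.01, sensor_type = "transmissive"
    ),
    watch = device_error_model(
      bias_at_full_sat = 0.8, bias_slope = 0.15, noise_sd = 3.0,
      averaging_window = 15, missingness_base = 0.04,
      missingness_low_sat_boost = 0.12, sensor_type = "reflectance"
    )
  )
}

# Deterministic substream seed from a master seed and a label, so that
# adding a participant or device does not perturb the streams of the
# others. Plain polynomial string hash folded below 2^31.
substream_seed <- function(seed, ...) {
  label <- paste(..., sep = "/")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147480009
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147480009)
}

#' Simulate a participant's true SaO2 trace over a protocol
#'
#' The true saturation relaxes first-order toward each plateau's
#' Severinghaus target: the target switches as soon as the gas system
#' starts moving toward the next level (the inter-plateau gap), and the
#' trace follows with time constant `response_time_constant`. The trace
#' itself is deterministic; measurement noise enters only when the trace
#' is sampled.
#'
#' @param protocol An `oxi_protocol`.
#' @param participant An `oxi_participant`.
#' @param dt Time step in seconds; must be positive and shorter than the
#'   shortest plateau.
#' @param start_sao2 Saturation at time zero (default: the first step's
#'   target, i.e. the participant starts on-protocol).
#' @return Data.frame with columns `time` (s) and `sao2` (percent),
#'   class `oxi_trace`.
#' @export
simulate_true_trace <- function(protocol, participant, dt = 1,
                                start_sao2 = NULL) {
  stopifnot(inherits(protocol, "oxi_protocol"),
            inherits(participant, "oxi_participant"))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (dt >= min(protocol$duration)) {
    stop("`dt` must be shorter than the shortest plateau", call. = FALSE)
  }
  tl <- protocol_timeline(protocol)
  times <- seq(0, tl$total_duration, by = dt)
  targets <- protocol$estimated_sao2
  # target in force at each grid time: the plateau being approached/held
  idx <- findInterval(times, tl$approach_start)
  idx[idx < 1L] <- 1L
  target_at <- targets[idx]
  tau <- participant$response_time_constant
  s <- numeric(length(times))
  s[1] <- if (is.null(start_sao2)) target_at[1] else start_sao2
  decay <- exp(-dt / tau)
  for (i in seq_along(times)[-1]) {
    s[i] <- target_at[i] + (s[i - 1] - target_at[i]) * decay
  }
  structure(
    data.frame(time = times, sao2 = s),
    dt = dt,
    class = c("oxi_trace", "data.frame")
  )
}

trace_value <- function(trace, time) {
  stats::approx(trace$time, trace$sao2, xout = time, rule = 2)$y
}

#' Draw arterial reference samples from a true trace
#'
#' Emulates blood-gas sampling: the trace value at each requested time
#' plus Gaussian analyzer noise, rounded to 0.1 percent (the precision a
#' blood gas analyzer reports).
#'
#' @param trace An `oxi_trace`.
#' @param sample_times Times in seconds, all within the trace span.
#' @param participant An `oxi_participant` (supplies the noise SD).
#' @param seed Integer seed for the noise draws.
#' @return Data.frame with columns `time`, `sao2`.
#' @export
sample_reference <- function(trace, sample_times, participant, seed = 1L) {
  stopifnot(inherits(trace, "oxi_trace"), inherits(participant, "oxi_participant"))
  if (any(sample_times < min(trace$time)) || any(sample_times > max(trace$time))) {
    stop("sample times fall outside the trace span", call. = FALSE)
  }
  truth <- trace_value(trace, sample_times)
  sd <- participant$sao2_measurement_noise_sd
  noise <- if (sd > 0) {
    set.seed(substream_seed(seed, participant$participant_id, "abg"))
    stats::rnorm(length(sample_times), 0, sd)
  } else 0
  sao2 <- round(pmin(100, pmax(0.1, truth + noise)), 1)
  data.frame(time = sample_times, sao2 = sao2)
}

#' Simulate one device reading attempt
#'
#' The displayed value is the mean of the true trace over the trailing
#' window `[time - W, time]`, plus the model's saturation-dependent bias
#' and noise, rounded to the display resolution and clipped to
#' `[0, 100]`. With the model's (saturation-dependent) missingness
#' probability the attempt instead returns `NA`.
#'
#' @param trace An `oxi_trace`.
#' @param time Attempt time in seconds; must be at least
#'   `averaging_window` after the trace start.
#' @param model An `oxi_device_model`.
#' @param seed Integer seed (noise and missingness draws).
#' @return Integer-valued percent, or `NA` for a failed attempt.
#' @export
simulate_device_reading <- function(trace, time, model, seed = 1L) {
  stopifnot(inherits(trace, "oxi_trace"), inherits(model, "oxi_device_model"))
  if (any(time - model$averaging_window < min(trace$time))) {
    stop("attempt time precedes the averaging window span", call. = FALSE)
  }
  set.seed(substream_seed(seed, "reading", sprintf("%.3f", time)))
  vapply(time, function(t) {
    truth_now <- trace_value(trace, t)
    p_miss <- model$missingness_base +
      if (truth_now < 70) model$missingness_low_sat_boost else 0
    if (stats::runif(1) < p_miss) return(NA_real_)
    w <- model$averaging_window
    window_mean <- if (w > 0) {
      grid <- seq(t - w, t, by = attr(trace, "dt") %||% 1)
      mean(trace_value(trace, grid))
    } else truth_now
    bias <- model$bias_at_full_sat +
      model$bias_slope * max(0, 95 - truth_now)
    noise <- if (model$noise_sd > 0) stats::rnorm(1, 0, model$noise_sd) else 0
    raw <- window_mean + bias + noise
    r <- model$display_rounding
    min(100, max(0, round(raw / r) * r))
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic validation study dataset
#'
#' Runs the protocol for every participant, draws the shared arterial
#' reference samples, and attempts one reading per device at every
#' sample slot, yielding the complete measurement table the analysis
#' pipeline consumes. One master seed drives deterministic
#' per-participant and per-device substreams, so the table is
#' reproducible and adding a participant does not perturb the others.
#'
#' @param participants List of `oxi_participant` (default:
#'   [default_participants()]).
#' @param protocol An `oxi_protocol` (default: [build_protocol()]).
#' @param device_models Named list of `oxi_device_model`, one per device
#'   (default: [default_device_models()]).
#' @param seed Master integer seed.
#' @param dt Trace resolution in seconds.
#' @return Data.frame of measurement records with columns
#'   `participant_id`, `device`, `plateau`, `sample`, `time_s`,
#'   `petO2_mmHg`, `sao2_pct`, `spo2_pct` (NA = failed attempt),
#'   `phase`, sorted by (participant, device, time).
#' @examples
#' ds <- generate_study_dataset(seed = 7)
#' table(ds$device) # 324 attempted records per device (9 x 36)
#' @export
generate_study_dataset <- function(participants = default_participants(),
                                   protocol = build_protocol(),
                                   device_models = default_device_models(),
                                   seed = 1L,
                                   dt = 1) {
  if (length(participants) < 1L) stop("need at least one participant", call. = FALSE)
  if (is.null(names(device_models)) || any(names(device_models) == "")) {
    stop("`device_models` must be a named list (one model per device)", call. = FALSE)
  }
  tl <- protocol_timeline(protocol)
  spp <- attr(protocol, "samples_per_plateau")
  out <- list()
  for (pt in participants) {
    trace <- simulate_true_trace(protocol, pt, dt = dt)
    times <- unlist(tl$sample_times)
    plateau <- rep(seq_len(nrow(protocol)), each = spp)
    samp <- rep(seq_len(spp), nrow(protocol))
    pseed <- substream_seed(seed, pt$participant_id)
    ref <- sample_reference(trace, times, pt, seed = pseed)
    for (dev in names(device_models)) {
      model <- device_models[[dev]]
      dseed <- substream_seed(seed, pt$participant_id, dev)
      spo2 <- vapply(seq_along(times), function(k) {
        simulate_device_reading(trace, times[k], model,
                                seed = substream_seed(dseed, "k", k))
      }, numeric(1))
      out[[paste(pt$participant_id, dev)]] <- data.frame(
        participant_id = pt$participant_id,
        device = dev,
        plateau = plateau,
        sample = samp,
        time_s = as.integer(round(times)),
        petO2_mmHg = protocol$peto2_target[plateau],
        sao2_pct = ref$sao2,
        spo2_pct = spo2,
        phase = protocol$phase[plateau],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$device, res$time_s), ]
  rownames(res) <- NULL
  res
}
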