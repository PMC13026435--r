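# Oxygen dissociation model, desaturation protocol construction, and
# ITA skin-tone classification: the deterministic domain layer.

#' Severinghaus oxyhemoglobin dissociation approximation
#'
#' Maps oxygen partial pressure to hemoglobin oxygen saturation using the
#' classic one-line Severinghaus (1979) approximation
#' \deqn{S = 100 \left(\frac{23400}{P^3 + 150P} + 1\right)^{-1}}
#' where \eqn{P} is the oxygen tension in mm Hg. In a controlled
#' sequential-gas-delivery protocol the set end-tidal oxygen tension
#' (PetO2) is a practical proxy for alveolar and hence arterial oxygen
#' tension, so this function gives the expected arterial saturation at
#' each protocol step.
#'
#' @param peto2 Oxygen tension in mm Hg; numeric vector, all values
#'   finite and strictly positive.
#' @return Saturation in percent, strictly inside (0, 100); strictly
#'   increasing in `peto2` and approaching 100 as `peto2` grows.
#' @examples
#' severinghaus_sao2(c(45, 40, 34)) # approximately 81, 75, 65 when rounded
#' @export
severinghaus_sao2 <- function(peto2) {
  if (!is.numeric(peto2) || length(peto2) == 0L) {
    stop("`peto2` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(peto2)) || any(peto2 <= 0)) {
    stop("`peto2` must be finite and > 0 mm Hg", call. = FALSE)
  }
  100 / (23400 / (peto2^3 + 150 * peto2) + 1)
}

#' Invert the Severinghaus saturation map
#'
#' Finds the oxygen tension whose Severinghaus saturation equals `sao2`.
#' The forward map is strictly monotone, so the inverse is obtained by
#' root finding; used by the simulator to translate target saturations
#' back into PetO2 settings.
#'
#' @param sao2 Saturation in percent, strictly inside (0, 100).
#' @return Oxygen tension in mm Hg such that
#'   `severinghaus_sao2(result)` reproduces `sao2` to within 1e-6.
#' @export
inverse_severinghaus <- function(sao2) {
  if (!is.numeric(sao2) || length(sao2) == 0L) {
    stop("`sao2` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(sao2)) || any(sao2 <= 0) || any(sao2 >= 100)) {
    stop("`sao2` must be finite and strictly between 0 and 100", call. = FALSE)
  }
  vapply(sao2, function(s) {
    # S = 100/(23400/(P^3+150P)+1)  =>  P^3 + 150P = 23400 S/(100-S),
    # a depressed cubic with one real positive root.
    rhs <- 23400 * s / (100 - s)
    stats::uniroot(
      function(p) p^3 + 150 * p - rhs,
      lower = 1e-9, upper = 2000, tol = 1e-12
    )$root
  }, numeric(1))
}

# ITA class boundaries, upper bound first. Printed intervals are half-open
# with a strict upper bound ("41 to <55"); the ">55" class is strict too,
# so each boundary value belongs to the interval below it except that 55,
# 41, 28, 10, -30 each fall in the class whose printed range includes them:
# >55 very_light, [41,55] light, [28,41) intermediate, [10,28) tan,
# [-30,10) brown, <-30 dark.
.ita_classes <- data.frame(
  label    = c("very_light", "light", "intermediate", "tan", "brown", "dark"),
  ita_low  = c(55, 41, 28, 10, -30, -Inf),
  ita_high = c(Inf, 55, 41, 28, 10, -30),
  stringsAsFactors = FALSE
)

#' Six-band skin-tone classification table
#'
#' Individual typology angle (ITA) class intervals in degrees, from
#' very light to dark. The intervals partition the ITA axis with
#' boundaries at 55, 41, 28, 10 and -30 degrees.
#'
#' @return A data.frame with columns `label`, `ita_low`, `ita_high`.
#' @export
skin_tone_classes <- function() .ita_classes

#' Classify a skin tone from its individual typology angle
#'
#' @param ita Individual typology angle in degrees (finite numeric
#'   vector), as reported by a colorimeter.
#' @return Character vector of class labels, one of `very_light`,
#'   `light`, `intermediate`, `tan`, `brown`, `dark`.
#' @examples
#' classify_ita(c(23, 54, -27)) # tan, light, brown
#' @export
classify_ita <- function(ita) {
  if (!is.numeric(ita) || length(ita) == 0L) {
    stop("`ita` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(ita))) {
    stop("`ita` must be finite (degrees)", call. = FALSE)
  }
  vapply(ita, function(x) {
    if (x > 55) "very_light"
    else if (x >= 41) "light"
    else if (x >= 28) "intermediate"
    else if (x >= 10) "tan"
    else if (x >= -30) "brown"
    else "dark"
  }, character(1))
}

#' Build a controlled-desaturation protocol
#'
#' Constructs the three-phase stepwise PetO2 protocol used for pulse
#' oximeter validation: Phase 1 is a monotone desaturation staircase
#' (PetO2 90, 60, 50, 45, 40, 37, 34, 32 mm Hg), Phase 2 a 250 mm Hg
#' recovery hold long enough to count as two sampling plateaus, and
#' Phase 3 an interrupted desaturation sequence
#' (90, 60, 50, 60, 50, 45, 40, 250 mm Hg) that reverses direction
#' mid-descent. Each plateau carries the Severinghaus-estimated
#' saturation for its PetO2 target. The default yields 18 sampling
#' plateaus and, at 2 arterial samples per plateau, 36 expected samples
#' per participant.
#'
#' @param phase1_peto2,phase3_peto2 PetO2 step sequences (mm Hg) for the
#'   desaturation phases.
#' @param phase2_peto2 Recovery hold PetO2 (mm Hg), encoded as
#'   `phase2_plateaus` consecutive sampling plateaus.
#' @param phase2_plateaus Number of sampling plateaus the extended
#'   recovery hold is counted as.
#' @param step_duration Full step cycle in seconds (default 180 s, the
#'   nominal 3 minutes per step), covering the gas transition and the
#'   steady hold.
#' @param samples_per_plateau Arterial samples drawn at each plateau
#'   (default 2: one once the level stabilizes, one a minute later).
#' @param inter_plateau_gap Seconds within each step that the gas
#'   system needs to reach and stabilize the new target (default
#'   120 s); the steady hold is the remainder of the step.
#' @param recovery_gap Rest interval in seconds between Phase 2 and
#'   Phase 3 (default 1800 s).
#' @return An object of class `oxi_protocol`: a data.frame of steps with
#'   columns `phase`, `step_index`, `peto2_target`, `duration`,
#'   `estimated_sao2`, plus attributes `samples_per_plateau`,
#'   `inter_plateau_gap`, `recovery_gap`.
#' @examples
#' p <- build_protocol()
#' nrow(p)                  # 18 plateaus
#' expected_sample_count(p) # 36
#' @export
build_protocol <- function(phase1_peto2 = c(90, 60, 50, 45, 40, 37, 34, 32),
                           phase2_peto2 = 250,
                           phase2_plateaus = 2L,
                           phase3_peto2 = c(90, 60, 50, 60, 50, 45, 40, 250),
                           step_duration = 180,
                           samples_per_plateau = 2L,
                           inter_plateau_gap = 120,
                           recovery_gap = 1800) {
  peto2 <- c(phase1_peto2, rep(phase2_peto2, phase2_plateaus), phase3_peto2)
  if (length(peto2) > 0 && (any(!is.finite(peto2)) || any(peto2 <= 0))) {
    stop("PetO2 targets must be finite and > 0 mm Hg", call. = FALSE)
  }
  if (!is.finite(step_duration) || step_duration <= 0) {
    stop("`step_duration` must be > 0 seconds", call. = FALSE)
  }
  if (samples_per_plateau < 1L) {
    stop("`samples_per_plateau` must be >= 1", call. = FALSE)
  }
  if (inter_plateau_gap < 0 || recovery_gap < 0) {
    stop("gaps must be non-negative seconds", call. = FALSE)
  }
  phase <- c(
    rep(1L, length(phase1_peto2)),
    rep(2L, phase2_plateaus),
    rep(3L, length(phase3_peto2))
  )
  steps <- data.frame(
    phase = phase,
    step_index = unlist(lapply(
      split(seq_along(phase), phase),
      function(i) seq_along(i) - 1L
    ), use.names = FALSE),
    peto2_target = peto2,
    duration = rep(step_duration, length.out = length(peto2)),
    estimated_sao2 = if (length(peto2)) severinghaus_sao2(peto2) else numeric(0),
    stringsAsFactors = FALSE
  )
  structure(
    steps,
    samples_per_plateau = as.integer(samples_per_plateau),
    inter_plateau_gap = inter_plateau_gap,
    recovery_gap = recovery_gap,
    class = c("oxi_protocol", "data.frame")
  )
}

#' @export
print.oxi_protocol <- function(x, ...) {
  cat(sprintf(
    "Controlled desaturation protocol: %d plateaus, %d sample(s) per plateau (%d expected samples)\n",
    nrow(x), attr(x, "samples_per_plateau"), expected_sample_count(x)
  ))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Expected number of arterial samples for a protocol
#'
#' @param protocol An `oxi_protocol` from [build_protocol()].
#' @return Number of plateaus times samples per plateau.
#' @export
expected_sample_count <- function(protocol) {
  stopifnot(inherits(protocol, "oxi_protocol"))
  nrow(protocol) * attr(protocol, "samples_per_plateau")
}

# Absolute timeline of a protocol. Each step's nominal duration covers
# the whole cycle: the gas system starts moving toward the new target at
# the step start (approach_start), the level is considered stabilized
# after `inter_plateau_gap` seconds (plateau_start), and the step ends
# right before the next transition (plateau_end). Arterial samples sit
# at the end of the step, 60 s apart (for the default 2 per plateau:
# one at stabilization, one a minute later just before the transition),
# so consecutive cross-plateau samples are ~2 minutes apart as in a
# standard step-down desaturation sequence. The 30-minute rest interval
# is inserted before the first Phase 3 step.
protocol_timeline <- function(protocol) {
  stopifnot(inherits(protocol, "oxi_protocol"))
  gap <- attr(protocol, "inter_plateau_gap")
  recovery <- attr(protocol, "recovery_gap")
  n <- nrow(protocol)
  approach_start <- plateau_start <- plateau_end <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    if (i > 1L && protocol$phase[i] == 3L && protocol$phase[i - 1L] == 2L) {
      t <- t + recovery
    }
    approach_start[i] <- t
    plateau_start[i] <- t + min(gap, protocol$duration[i])
    plateau_end[i] <- t + protocol$duration[i]
    t <- plateau_end[i]
  }
  spp <- attr(protocol, "samples_per_plateau")
  sample_times <- lapply(plateau_end, function(e) e - 60 * (spp:1 - 1L))
  list(
    approach_start = approach_start,
    plateau_start = plateau_start,
    plateau_end = plateau_end,
    sample_times = sample_times,
    total_duration = t
  )
}
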