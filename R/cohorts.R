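#' Published flight-tone cohort parameters
#'
#' Summary statistics (mean, SD, n) of *Anopheles gambiae* fundamental
#' flight-tone frequencies by sex, temperature and circadian phase, as
#' measured from single-sex cage recordings. These are the population
#' parameters the synthetic generators default to and the inputs to the
#' Monte-Carlo ratio analyses; "swarm" is the 1-hour window centred on the
#' circadian sunset (ZT13), "other" the rest of the day. The playback rows
#' describe males exposed to a 550-Hz artificial female tone.
#'
#' @return A data.frame with columns `cohort`, `sex`, `temp_c`, `phase`,
#'   `state`, `mean_hz`, `sd_hz`, `n`.
#' @export
#' @examples
#' cohort_params()
cohort_params <- function() {
  out <- read.csv(text = "cohort,sex,temp_c,phase,state,mean_hz,sd_hz,n
female_swarm_28,female,28,swarm,swarming,556,40,3040
female_other_28,female,28,other,baseline,547,51,2339
male_swarm_28,male,28,swarm,swarming,844,55,1600
male_other_28,male,28,other,baseline,751,80,445
female_swarm_22,female,22,swarm,swarming,464,37,1137
female_other_22,female,22,other,baseline,475,37,447
male_swarm_22,male,22,swarm,swarming,653,39,454
male_other_22,male,22,other,baseline,595,52,83
male_playback_swarm_28,male,28,swarm,activated,900,58,928
male_nostim_swarm_28,male,28,swarm,swarming,843,58,2318
male_playback_other_28,male,28,other,activated,886,48,92
male_nostim_other_28,male,28,other,baseline,779,54,354",
    stringsAsFactors = FALSE)
  out
}

#' Male antennal-nerve sensitivity window
#'
#' The male auditory nerve responds only to low-frequency flagellar
#' vibration: compound responses are confined to roughly 65-400 Hz with a
#' plateau of maximal sensitivity between roughly 150 and 300 Hz. Audible
#' distortion products are scored against this window.
#'
#' @param lo_hz,hi_hz Outer response limits (Hz).
#' @param plateau_lo_hz,plateau_hi_hz Plateau of maximal response (Hz).
#' @return An object of class `nerve_window`.
#' @export
nerve_window <- function(lo_hz = 65, hi_hz = 400,
                         plateau_lo_hz = 150, plateau_hi_hz = 300) {
  if (!(lo_hz < plateau_lo_hz && plateau_lo_hz < plateau_hi_hz &&
        plateau_hi_hz < hi_hz))
    stop_invalid("nerve window must satisfy lo < plateau_lo < plateau_hi < hi")
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz,
                 plateau_lo_hz = plateau_lo_hz,
                 plateau_hi_hz = plateau_hi_hz),
            class = "nerve_window")
}

#' Male flight-tone frequency states
#'
#' Males occupy three circadian/behavioural frequency states: a daytime
#' baseline, an elevated swarming state around sunset, and an activated
#' state after hearing a female-like tone. Females show only negligible
#' daily variation around ~550 Hz.
#'
#' @return Named numeric vector of state means in Hz.
#' @export
male_state_means <- function() {
  c(baseline = 751, swarming = 844, activated = 900)
}
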