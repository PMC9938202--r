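## Synthetic drinking cohorts for schedule-induced polydipsia style
## experiments, with the planted escalator set kept as ground truth.

#' Specification of a synthetic drinking cohort
#'
#' Defaults describe a standard cohort: 48 animals, 2 baseline sessions,
#' 21 daily training sessions, a quarter of the population escalating from
#' session 8 onward (the point at which high drinkers typically diverge) at
#' about 2 mL/session on a 10 mL regulatory baseline — reaching roughly
#' 3.5 times the baseline by the end of training — with 1.5 mL
#' session-to-session noise.
#'
#' @param nAnimals Number of animals (default 48).
#' @param nSessions Training sessions (default 21).
#' @param baselineSessions Habituation sessions before training (default 2).
#' @param hdFraction Fraction of animals planted as escalators
#'   (default 0.25).
#' @param escalationOnset Training session after which escalators rise
#'   (default 8).
#' @param escalationRate Mean escalation in mL/session (default 2).
#' @param baselineIntake Regulatory intake in mL (default 10).
#' @param noiseSd Gaussian noise s.d. in mL (default 1.5).
#' @param seed Integer seed.
#' @return A [BehaviorSpec-class].
#' @export
behaviorSpec <- function(nAnimals = 48, nSessions = 21, baselineSessions = 2,
                         hdFraction = 0.25, escalationOnset = 8,
                         escalationRate = 2, baselineIntake = 10,
                         noiseSd = 1.5, seed = 1) {
  new("BehaviorSpec", nAnimals = as.integer(nAnimals),
      nSessions = as.integer(nSessions),
      baselineSessions = as.integer(baselineSessions),
      hdFraction = hdFraction,
      escalationOnset = as.integer(escalationOnset),
      escalationRate = escalationRate, baselineIntake = baselineIntake,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Generate a synthetic drinking cohort
#'
#' Every animal drinks `baselineIntake` mL per session in expectation;
#' planted escalators additionally gain a strictly positive per-session
#' increment after `escalationOnset`. Escalators receive distinct rates
#' (spread over `escalationRate` times 1 to 1.5) so that their final
#' rankings are well defined even without noise. Intakes are clipped at 0.
#' Deterministic given `spec@seed`.
#'
#' @param spec A [BehaviorSpec-class].
#' @return A [BehaviorCohort-class]; [intakeTable()] gives the long-format
#'   table, [escalators()] the planted escalator ids.
#' @export
generateBehavior <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nAnimals
    ids <- sprintf("rat%02d", seq_len(n))
    nEsc <- floor(spec@hdFraction * n)
    esc <- sort(sample(ids, nEsc))
    rates <- setNames(numeric(n), ids)
    if (nEsc > 0)
      rates[esc] <- spec@escalationRate *
        seq(1, 1.5, length.out = nEsc)[sample.int(nEsc)]
    sessions <- seq_len(spec@baselineSessions + spec@nSessions)
    phase <- rep(c("baseline", "training"),
                 c(spec@baselineSessions, spec@nSessions))
    trainSession <- sessions - spec@baselineSessions   # <= 0 during baseline
    rows <- expand.grid(session = sessions, animal_id = ids,
                        stringsAsFactors = FALSE)[, 2:1]
    ## escalators diverge from the population at the onset session itself
    past <- pmax(rows$session - spec@baselineSessions -
                   spec@escalationOnset + 1, 0)
    mu <- spec@baselineIntake + rates[rows$animal_id] * past
    intake <- pmax(mu + rnorm(nrow(rows), 0, spec@noiseSd), 0)
    tab <- data.frame(animal_id = rows$animal_id, session = rows$session,
                      phase = phase[rows$session],
                      intake_ml = unname(intake))
    new("BehaviorCohort", intake = tab, escalators = esc, spec = spec)
  })
}
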