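#' Score one trial from a network trajectory
#'
#' A "response" at bin t means the readout crosses the threshold
#' (\eqn{y_t \ge} threshold). On Go trials (SL, LS, MM, LL, XL) the trial is
#' correct iff the network responds inside the response window and never
#' before the onset of the final cue offset's window gate: any response before
#' the second cue starts (before the single cue ends, on XL) is premature and
#' an error. On the SS match trial any response at any time is an error.
#'
#' @param traj a \linkS4class{Trajectory} carrying its trial spec
#' @param threshold Go threshold on the readout; the default is half the
#'   target amplitude
#' @return a list (class \code{"TrialScore"}) with fields \code{trialType},
#'   \code{respondedInWindow}, \code{prematureResponse}, \code{correct},
#'   \code{peakOutput}, \code{peakTime}, \code{probe}
#' @export
scoreTrial <- function(traj, threshold = 0.5) {
  spec <- traj@spec
  ev <- spec$eventTimes
  dt <- spec$dt
  y <- traj@output
  resp <- y >= threshold
  win <- binSpan(ev$response_window[1], ev$response_window[2], dt)
  gate <- if (spec$trialType == "XL") ev$cue1[2] else ev$cue2[1]
  pre <- seq_len(as.integer(round(gate / dt)))
  respondedInWindow <- any(resp[win])
  premature <- any(resp[pre])
  correct <- if (spec$isGo) respondedInWindow && !premature else !any(resp)
  structure(list(trialType = spec$trialType,
                 respondedInWindow = respondedInWindow,
                 prematureResponse = premature, correct = correct,
                 peakOutput = max(y), peakTime = (which.max(y) - 1L) * dt,
                 probe = isTRUE(spec$probe)),
            class = "TrialScore")
}

#' Summarise a session of trial scores
#'
#' Reports exact per-type and trial-weighted overall accuracies, the
#' probability of a response in the window per type, and a coarse strategy
#' label: \code{"lick_after_long"} when SL and SS accuracies are at least 0.9
#' while LS accuracy is at most 0.1 (the signature of responding after every
#' long cue), \code{"optimal"} when every type is at least 0.9 accurate,
#' \code{"other"} otherwise.
#'
#' @param scores non-empty list of \code{scoreTrial} results
#' @return a list (class \code{"SessionSummary"})
#' @export
sessionPerformance <- function(scores) {
  if (length(scores) == 0) stop("empty score list")
  types <- vapply(scores, `[[`, "", "trialType")
  correct <- vapply(scores, `[[`, NA, "correct")
  inWin <- vapply(scores, `[[`, NA, "respondedInWindow")
  perType <- tapply(correct, types, mean)
  respProb <- tapply(inWin, types, mean)
  overall <- mean(correct)
  acc <- function(tt) if (tt %in% names(perType)) perType[[tt]] else NA_real_
  label <- if (!is.na(acc("SL")) && !is.na(acc("SS")) && !is.na(acc("LS")) &&
               acc("SL") >= 0.9 && acc("SS") >= 0.9 && acc("LS") <= 0.1)
    "lick_after_long"
  else if (all(perType >= 0.9)) "optimal" else "other"
  structure(list(perTypeAccuracy = as.list(perType),
                 overallAccuracy = overall,
                 responseProbPerType = as.list(respProb),
                 strategyLabel = label, nTrials = length(scores)),
            class = "SessionSummary")
}

#' Sweep a cue duration and locate the response threshold
#'
#' Builds noise-free trials in which one cue's duration is varied, runs the
#' network without noise, and records the peak readout in the response window
#' (the \code{responseWindow} seconds following the final cue offset). Also
#' reports the smallest duration whose peak crosses the Go threshold.
#'
#' \code{whichCue = "second"} varies the second cue with the first held short
#' (so 2 s reproduces SS and 5 s reproduces SL); \code{"first"} varies the
#' first cue with the second held short; \code{"single"} uses a one-cue trial
#' of the given duration (the XL layout).
#'
#' @param model a trained \linkS4class{RNNModel}
#' @param whichCue which cue to vary
#' @param durations durations to test (s)
#' @param task a \linkS4class{TaskConfig}
#' @param threshold Go threshold
#' @return list with \code{sweep} (data.frame duration, peak) and
#'   \code{crossingDuration} (smallest supra-threshold duration, NA if none)
#' @export
cueDurationSweep <- function(model, whichCue = c("second", "first", "single"),
                             durations = seq(2, 5, by = 0.1),
                             task = taskConfig(), threshold = 0.5) {
  whichCue <- match.arg(whichCue)
  peaks <- vapply(durations, function(d) {
    d <- round(d / task@dt) * task@dt
    tr <- switch(whichCue,
                 second = makeTrial("SL", task, cue2 = d),
                 first = makeTrial("LS", task, cue1 = d),
                 single = makeTrial("XL", task, cue1 = d))
    traj <- runTrial(model, tr, unitNoise = FALSE)
    win <- binSpan(tr@spec$eventTimes$response_window[1],
                   tr@spec$eventTimes$response_window[2], task@dt)
    max(traj@output[win])
  }, 0)
  hit <- which(peaks >= threshold)
  list(sweep = data.frame(duration = durations, peak = peaks),
       crossingDuration = if (length(hit)) durations[hit[1]] else NA_real_,
       threshold = threshold, whichCue = whichCue)
}

#' Response probabilities on probe sessions
#'
#' Simulates noisy 5-trial probe blocks (2 SS, 1 SL, 1 LS, 1 probe) for each
#' requested probe type and reports, per trial type, the probability of a
#' response inside the response window. Probe trials are unrewarded and are
#' scored by window response only.
#'
#' @param model a trained \linkS4class{RNNModel}
#' @param probeTypes probe types to interleave
#' @param nBlocks probe blocks per probe type
#' @param task a \linkS4class{TaskConfig}
#' @param threshold Go threshold
#' @param unitNoise include private unit noise
#' @return named numeric vector of response probabilities per trial type
#' @export
probeEvaluation <- function(model, probeTypes = c("MM", "LL", "XL"),
                            nBlocks = 10L, task = taskConfig(),
                            threshold = 0.5, unitNoise = TRUE) {
  hits <- list(); counts <- list()
  for (pt in probeTypes) {
    for (b in seq_len(nBlocks)) {
      for (tr in makeProbeBlock(pt, task)) {
        sc <- scoreTrial(runTrial(model, tr, unitNoise = unitNoise),
                         threshold)
        tt <- sc$trialType
        hits[[tt]] <- c(hits[[tt]], sc$respondedInWindow)
      }
    }
  }
  vapply(hits, mean, 0)
}
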