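#' @import methods
#' @importFrom stats prcomp rnorm runif rpois sd cor aov t.test TukeyHSD median quantile setNames
#' @importFrom utils head tail
#' @useDynLib tdnmsRNN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Task configuration for the tDNMS trial layout
#'
#' Holds the temporal layout of a temporal delayed non-match-to-sample (tDNMS)
#' trial on a discrete time grid: bin width, trial length, start-cue and
#' timed-cue placement, the short/long cue durations, the interstimulus
#' interval, the response window, and the input-noise and target scales.
#' All event times must be non-negative multiples of \code{dt} and the full
#' event layout must fit inside the trial.
#'
#' @slot dt seconds per time bin
#' @slot trialLen total trial duration in seconds
#' @slot nBins number of time bins (\code{trialLen / dt})
#' @slot startCueOnset,startCueDur start-cue placement in seconds
#' @slot firstCueOnset onset of the first timed cue in seconds
#' @slot shortDur,longDur the "short" and "long" cue durations in seconds
#' @slot isi interstimulus interval between the two timed cues in seconds
#' @slot responseWindow duration of the response window in seconds
#' @slot inputNoiseSigma std of the additive Gaussian input noise
#' @slot targetAmplitude height of the boxcar target inside the response window
#' @export
setClass("TaskConfig", representation(
  dt = "numeric", trialLen = "numeric", nBins = "integer",
  startCueOnset = "numeric", startCueDur = "numeric", firstCueOnset = "numeric",
  shortDur = "numeric", longDur = "numeric", isi = "numeric",
  responseWindow = "numeric", inputNoiseSigma = "numeric",
  targetAmplitude = "numeric"))

setValidity("TaskConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (abs(object@nBins * object@dt - object@trialLen) > 1e-9)
    msg <- c(msg, "nBins * dt must equal trialLen")
  if (object@shortDur >= object@longDur)
    msg <- c(msg, "shortDur must be smaller than longDur")
  mult <- c(object@startCueOnset, object@startCueDur, object@firstCueOnset,
            object@shortDur, object@longDur, object@isi, object@responseWindow)
  if (any(abs(mult / object@dt - round(mult / object@dt)) > 1e-8))
    msg <- c(msg, "all event times and durations must be multiples of dt")
  if (any(c(object@startCueDur, object@shortDur, object@longDur, object@isi,
            object@responseWindow) <= 0))
    msg <- c(msg, "durations must be positive")
  if (object@startCueOnset + object@startCueDur > object@firstCueOnset + 1e-9)
    msg <- c(msg, "start cue must end before the first timed cue begins")
  if (object@inputNoiseSigma < 0) msg <- c(msg, "inputNoiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single tDNMS trial as an input/target tensor
#'
#' @slot inputs numeric matrix [nBins x 2]: channel 1 is the start cue,
#'   channel 2 the timed cue; one-hot before noise is added
#' @slot target numeric vector [nBins]: the response-window target function
#' @slot spec list describing the trial (type, cue durations, event times,
#'   Go/No-Go flag, probe flag)
#' @slot noisy logical: has input noise been added
#' @export
setClass("TrialTensor", representation(
  inputs = "matrix", target = "numeric", spec = "list", noisy = "logical"))

setValidity("TrialTensor", function(object) {
  if (nrow(object@inputs) != length(object@target))
    return("inputs and target must have the same number of bins")
  if (ncol(object@inputs) != 2) return("inputs must have exactly 2 channels")
  if (!object@noisy && !all(object@inputs %in% c(0, 1)))
    return("clean inputs must be one-hot (0/1)")
  TRUE
})

#' A shaping curriculum: an ordered schedule of training phases
#'
#' @slot name curriculum label (one of \code{"NS"}, \code{"S_FT"},
#'   \code{"SL_FT"}, \code{"LS_FT"}, \code{"ONLY_SHAPING"})
#' @slot phases data.frame with columns \code{phase}, \code{nBlocks},
#'   \code{blockSize} and a list-column \code{types} holding the exact trial
#'   multiset of one block of that phase
#' @export
setClass("Curriculum", representation(name = "character", phases = "data.frame"))

setValidity("Curriculum", function(object) {
  ph <- object@phases
  need <- c("phase", "nBlocks", "types", "blockSize")
  if (!all(need %in% names(ph))) return("phases must have phase/nBlocks/types/blockSize")
  if (any(ph$nBlocks < 1)) return("each phase needs at least one block")
  ok <- vapply(seq_len(nrow(ph)),
               function(i) length(ph$types[[i]]) == ph$blockSize[i], logical(1))
  if (!all(ok)) return("each phase's trial multiset must have blockSize entries")
  TRUE
})

#' Parameters of the leaky recurrent network
#'
#' The network follows the discrete-time leaky update
#' \deqn{h_{t+1} = (1-\gamma) h_t + \gamma \tanh(W_{in} x_t + W_{rec} h_t + b + \xi_t)}
#' with a memoryless linear readout \eqn{y_t = w_{out} \cdot h_t + b_{out}}.
#'
#' @slot wIn input weights, matrix [N x 2]
#' @slot wRec recurrent weights, matrix [N x N]
#' @slot b unit biases, numeric [N]
#' @slot wOut readout weights, numeric [N]
#' @slot bOut readout bias, scalar
#' @slot gamma leak constant in (0, 1]; (1 - gamma) is the per-step retention
#' @slot unitNoiseSigma std of the private per-unit noise injected inside the
#'   activation argument
#' @slot nUnits number of recurrent units N
#' @slot activation nonlinearity name; always \code{"tanh"}
#' @export
setClass("RNNModel", representation(
  wIn = "matrix", wRec = "matrix", b = "numeric", wOut = "numeric",
  bOut = "numeric", gamma = "numeric", unitNoiseSigma = "numeric",
  nUnits = "integer", activation = "character"))

setValidity("RNNModel", function(object) {
  N <- object@nUnits
  msg <- character()
  if (!identical(dim(object@wRec), c(N, N))) msg <- c(msg, "wRec must be N x N")
  if (!identical(dim(object@wIn), c(N, 2L))) msg <- c(msg, "wIn must be N x 2")
  if (length(object@b) != N || length(object@wOut) != N)
    msg <- c(msg, "b and wOut must have length N")
  if (object@gamma <= 0 || object@gamma > 1) msg <- c(msg, "gamma must lie in (0, 1]")
  if (object@unitNoiseSigma < 0) msg <- c(msg, "unitNoiseSigma must be >= 0")
  if (!all(is.finite(object@wIn)) || !all(is.finite(object@wRec)) ||
      !all(is.finite(object@b)) || !all(is.finite(object@wOut)) ||
      !is.finite(object@bOut))
    msg <- c(msg, "all parameters must be finite")
  if (!identical(object@activation, "tanh")) msg <- c(msg, "activation must be tanh")
  if (length(msg)) msg else TRUE
})

#' A simulated trajectory: hidden states and readout over time
#'
#' @slot hidden unit activations, matrix [T x N]
#' @slot output readout values, numeric [T]
#' @slot inputsUsed the (possibly noisy) inputs driving the run, matrix [T x 2]
#' @slot noiseFlags named logical vector (inputNoise, unitNoise)
#' @slot spec the TrialSpec list of the simulated trial, or a free-run descriptor
#' @export
setClass("Trajectory", representation(
  hidden = "matrix", output = "numeric", inputsUsed = "matrix",
  noiseFlags = "logical", spec = "list"))

setValidity("Trajectory", function(object) {
  if (nrow(object@hidden) != length(object@output))
    return("hidden and output must share the time dimension")
  TRUE
})

#' Training record: block-wise MSE trace and phase-boundary checkpoints
#'
#' @slot blockMSE per-block mean squared output error (no regularisation)
#' @slot checkpoints named list of RNNModel snapshots; always contains
#'   \code{"final"} and, when a shaping phase exists, \code{"shaping_end"}
#'   (the "Only Shaping" network)
#' @slot curriculum the Curriculum trained on
#' @slot trialTypeLog list (one character vector per block) of the trial types
#'   actually presented, in order
#' @slot seed integer seed the run was launched with
#' @slot config list of the TrainConfig values used
#' @export
setClass("TrainRecord", representation(
  blockMSE = "numeric", checkpoints = "list", curriculum = "Curriculum",
  trialTypeLog = "list", seed = "integer", config = "list"))

#' Set of located fixed/slow points with linear-stability summaries
#'
#' @slot locations matrix [nPoints x N] of accepted point locations
#' @slot speed squared speed q(h) = 0.5 ||F(h)||^2 at each point
#' @slot stability character: stable / unstable / saddle / marginal
#' @slot eigenvalues list of complex spectra of the linearised update map
#' @slot isSlowPoint logical; TRUE when q is above exact-zero numerical noise
#' @slot inputMode "cue_on" or "cue_off"
#' @slot readout readout value at each point
#' @slot unconverged data.frame of candidates that failed the q threshold
#'   (final q reported, never silently dropped)
#' @export
setClass("FixedPointSet", representation(
  locations = "matrix", speed = "numeric", stability = "character",
  eigenvalues = "list", isSlowPoint = "logical", inputMode = "character",
  readout = "numeric", unconverged = "data.frame"))

#' PCA of pooled trial-averaged hidden states
#'
#' @slot loadings matrix [N x k] of component loadings
#' @slot center the mean state subtracted before projection
#' @slot varExplained per-component variance fractions (all N components)
#' @slot k number of retained components
#' @slot source short descriptor of the trajectories used
#' @export
setClass("PCAResult", representation(
  loadings = "matrix", center = "numeric", varExplained = "numeric",
  k = "integer", source = "character"))

setValidity("PCAResult", function(object) {
  ve <- object@varExplained
  if (any(diff(ve) > 1e-8)) return("varExplained must be non-increasing")
  if (sum(ve) > 1 + 1e-6) return("varExplained fractions must sum to <= 1")
  TRUE
})

#' Dataset for elapsed-time decoding
#'
#' @slot activity numeric array [trials x bins x units]
#' @slot timeLabels elapsed time per bin, rounded to the nearest second
#' @slot trialTypes trial-type label per trial
#' @export
setClass("DecodingDataset", representation(
  activity = "array", timeLabels = "numeric", trialTypes = "character"))

#' Within/across-context time-decoding result
#'
#' @slot withinError mean absolute decoding error (s) when the training
#'   decoder's trial type matches the tested trials
#' @slot acrossError mean absolute error (s) over mismatched train/test pairs
#' @slot allTrialsError error of the decoder trained on all trial types
#' @slot perCell data.frame of per (decoder, testType) errors and bin counts
#' @slot confusion 4-d count array [decoder x testType x trueTime x predTime]
#' @export
setClass("DecodingResult", representation(
  withinError = "numeric", acrossError = "numeric", allTrialsError = "numeric",
  perCell = "data.frame", confusion = "array"))

#' Specification of a synthetic temporally tuned spiking population
#'
#' Emulates a population of time cells: each tuned unit has a Gaussian firing
#' field on the trial clock; in \code{"shared_across_types"} mode a unit keeps
#' one field for every trial type (an abstract, context-independent time code),
#' in \code{"context_specific"} mode each trial type gets an independently
#' drawn field centre. A fraction of units are non-task-responsive and fire at
#' baseline only.
#'
#' @slot nUnits number of units
#' @slot fieldCenters numeric [nUnits] preferred times (s) tiling the trial
#' @slot fieldWidth Gaussian sigma of the rate field (s)
#' @slot peakRate,baselineRate firing rates in Hz
#' @slot sharingMode "shared_across_types" or "context_specific"
#' @slot noiseUnitFraction fraction of pure-baseline units
#' @slot trialJitter per-trial jitter of the field centre (s, Gaussian sd)
#' @export
setClass("PopulationSpec", representation(
  nUnits = "integer", fieldCenters = "numeric", fieldWidth = "numeric",
  peakRate = "numeric", baselineRate = "numeric", sharingMode = "character",
  noiseUnitFraction = "numeric", trialJitter = "numeric"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@peakRate < 0 || object@baselineRate < 0) msg <- c(msg, "rates must be >= 0")
  if (object@noiseUnitFraction < 0 || object@noiseUnitFraction > 1)
    msg <- c(msg, "noiseUnitFraction must lie in [0, 1]")
  if (!object@sharingMode %in% c("shared_across_types", "context_specific"))
    msg <- c(msg, "unknown sharingMode")
  if (length(object@fieldCenters) != object@nUnits)
    msg <- c(msg, "fieldCenters must have one entry per unit")
  if (length(msg)) msg else TRUE
})

#' Binned, smoothed, z-scored firing-rate tensor
#'
#' @slot rates numeric array [trials x bins x units]
#' @slot binWidth bin width in seconds
#' @slot smoothing named numeric (sigma, window) of the Gaussian kernel, in s
#' @slot zeroVarianceUnits indices of units flagged during z-scoring (no spikes)
#' @slot trialTypes trial-type label per trial
#' @export
setClass("RateMatrix", representation(
  rates = "array", binWidth = "numeric", smoothing = "numeric",
  zeroVarianceUnits = "integer", trialTypes = "character"))

#' A detected limit cycle
#'
#' @slot orbit matrix [periodBins x N]: one period of the closed orbit
#' @slot period orbit period in seconds
#' @slot inputMode the clamped-input mode the cycle lives under
#' @slot recurrenceError max state distance between the orbit and its repeat
#' @slot tolerance the closure tolerance actually applied (state-space units)
#' @export
setClass("LimitCycle", representation(
  orbit = "matrix", period = "numeric", inputMode = "character",
  recurrenceError = "numeric", tolerance = "numeric"))

setValidity("LimitCycle", function(object) {
  if (object@period <= 0) return("period must be positive")
  if (object@recurrenceError > object@tolerance + 1e-12)
    return("closure error exceeds the stated tolerance")
  TRUE
})
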