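# Reduced-scale cohorts shared across test files.  Training and the derived
# analyses are cached in this environment so each (curriculum, seed) pair is
# trained exactly once per test run.  Reduced scale: 100 shaping + 250
# full-task blocks; cohort seeds are fixed study conditions.

.cache <- new.env(parent = emptyenv())

cohortSeeds <- 11:14

trainedRecord <- function(name, seed) {
  key <- paste0("rec_", name, "_", seed)
  if (is.null(.cache[[key]])) {
    shaping <- if (name == "NS") 0L else 100L
    .cache[[key]] <- trainCurriculum(
      curriculum(name, 350L, 100L), taskConfig(),
      trainConfig(totalBlocks = 350L, shapingBlocks = shaping, seed = seed))
  }
  .cache[[key]]
}

trainedModel <- function(name, seed) checkpoints(trainedRecord(name, seed))$final

# noisy 15-block session dataset per network, reused by decoding, tangling
# and dimensionality checks
cohortDataset <- function(name, seed) {
  key <- paste0("ds_", name, "_", seed)
  if (is.null(.cache[[key]])) {
    set.seed(seed + 5000L)
    .cache[[key]] <- buildDecodingDataset(trainedModel(name, seed),
                                          taskConfig(), nBlocks = 15L)
  }
  .cache[[key]]
}

cohortDecoding <- function(name, seed) {
  key <- paste0("dec_", name, "_", seed)
  if (is.null(.cache[[key]])) {
    set.seed(seed + 6000L)
    .cache[[key]] <- decodeWithinAcross(cohortDataset(name, seed))
  }
  .cache[[key]]
}

cohortMotifs <- function(name, seed) {
  key <- paste0("mot_", name, "_", seed)
  if (is.null(.cache[[key]])) {
    set.seed(seed + 7000L)
    .cache[[key]] <- dynamicalMotifs(trainedModel(name, seed))
  }
  .cache[[key]]
}

pooledStates <- function(ds, nTrials = dim(ds@activity)[1]) {
  do.call(rbind, lapply(seq_len(nTrials), function(i) ds@activity[i, , ]))
}

# brute-force tangling oracle: literal double loop over all (t, t') pairs
tanglingBruteForce <- function(states, dt = 0.1, epsCoef = 0.1,
                               trialIndex = NULL) {
  eps <- epsCoef * mean(rowSums(states^2))
  keep <- if (is.null(trialIndex)) rep(TRUE, nrow(states) - 1L)
          else diff(trialIndex) == 0
  V <- (diff(states) / dt)[keep, , drop = FALSE]
  X <- states[-1L, , drop = FALSE][keep, , drop = FALSE]
  n <- nrow(V)
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sum((V[i, ] - V[j, ])^2) / (sum((X[i, ] - X[j, ])^2) + eps)
      if (r > best) best <- r
    }
    q[i] <- best
  }
  q
}

# synthetic spike-population bundle (shared / context-specific), cached
spikeBundle <- function(mode) {
  key <- paste0("spk_", mode)
  if (is.null(.cache[[key]])) {
    set.seed(if (mode == "shared_across_types") 4242L else 4243L)
    session <- rep(c("SS", "SS", "SL", "LS"), 15L)
    spec <- populationSpec(sharingMode = mode)
    spikes <- generatePopulation(spec, session)
    rm_ <- preprocessSpikes(spikes, length(session), session,
                            nUnits = spec@nUnits)
    keep <- selectTaskResponsive(rm_)
    sub <- new("RateMatrix", rates = rm_@rates[, , keep, drop = FALSE],
               binWidth = rm_@binWidth, smoothing = rm_@smoothing,
               zeroVarianceUnits = integer(0), trialTypes = rm_@trialTypes)
    dec <- decodeWithinAcross(buildDecodingDataset(sub))
    .cache[[key]] <- list(spec = spec, spikes = spikes, rates = rm_,
                          keep = keep, decoding = dec, session = session)
  }
  .cache[[key]]
}

# a fabricated trajectory holding a given output trace over a trial's spec
fakeTrajectory <- function(tensor, y) {
  new("Trajectory", hidden = matrix(0, length(y), 1L), output = y,
      inputsUsed = tensor@inputs,
      noiseFlags = c(inputNoise = FALSE, unitNoise = FALSE),
      spec = tensor@spec)
}

# output of an agent that responds for 0.5 s after the offset of every
# long (5 s) cue and never otherwise
lickAfterLongOutput <- function(tensor, task = taskConfig()) {
  y <- numeric(task@nBins)
  ev <- tensor@spec$eventTimes
  for (cue in c("cue1", "cue2")) {
    if (is.null(ev[[cue]])) next
    if (abs(diff(ev[[cue]]) - task@longDur) < 1e-9) {
      i0 <- round(ev[[cue]][2] / task@dt) + 1L
      y[i0:min(task@nBins, i0 + 4L)] <- 1
    }
  }
  y
}
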