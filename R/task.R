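#' Create a tDNMS task configuration
#'
#' Defaults give the standard layout: 20 s trials at 0.1 s bins (200 bins), a
#' 0.2 s start cue at t = 0, the first timed cue at 3 s, short/long cue
#' durations of 2 s and 5 s, a 3 s interstimulus interval, a 3 s response
#' window opening at the offset of the final cue, Gaussian input noise with
#' sd 0.15 and a unit-amplitude boxcar target.
#'
#' @param dt seconds per time bin
#' @param trialLen trial duration (s)
#' @param startCueOnset,startCueDur start-cue placement (s)
#' @param firstCueOnset onset of the first timed cue (s)
#' @param shortDur,longDur short and long cue durations (s)
#' @param isi interstimulus interval (s)
#' @param responseWindow response-window duration (s)
#' @param inputNoiseSigma sd of additive Gaussian input noise
#' @param targetAmplitude height of the target boxcar
#' @return a \linkS4class{TaskConfig}
#' @export
taskConfig <- function(dt = 0.1, trialLen = 20, startCueOnset = 0,
                       startCueDur = 0.2, firstCueOnset = 3, shortDur = 2,
                       longDur = 5, isi = 3, responseWindow = 3,
                       inputNoiseSigma = 0.15, targetAmplitude = 1) {
  new("TaskConfig", dt = dt, trialLen = trialLen,
      nBins = as.integer(round(trialLen / dt)),
      startCueOnset = startCueOnset, startCueDur = startCueDur,
      firstCueOnset = firstCueOnset, shortDur = shortDur, longDur = longDur,
      isi = isi, responseWindow = responseWindow,
      inputNoiseSigma = inputNoiseSigma, targetAmplitude = targetAmplitude)
}

trialTypes <- c("SS", "SL", "LS", "MM", "LL", "XL")

cueDurations <- function(trialType, config) {
  S <- config@shortDur; L <- config@longDur
  switch(trialType,
         SS = c(S, S), SL = c(S, L), LS = c(L, S),
         MM = c(3.5, 3.5), LL = c(L, L), XL = c(10, NA_real_),
         stop("unknown trial type: ", trialType))
}

# Event layout of one trial: list of (label, onset, offset), all in seconds.
trialEvents <- function(trialType, config, cue1 = NULL, cue2 = NULL) {
  d <- cueDurations(trialType, config)
  if (!is.null(cue1)) d[1] <- cue1
  if (!is.null(cue2) && trialType != "XL") d[2] <- cue2
  c1on <- config@firstCueOnset
  c1off <- c1on + d[1]
  ev <- list(start_cue = c(config@startCueOnset,
                           config@startCueOnset + config@startCueDur),
             cue1 = c(c1on, c1off))
  if (trialType == "XL") {
    respOn <- c1off
  } else {
    c2on <- c1off + config@isi
    c2off <- c2on + d[2]
    ev$isi <- c(c1off, c2on)
    ev$cue2 <- c(c2on, c2off)
    respOn <- c2off
  }
  ev$response_window <- c(respOn, respOn + config@responseWindow)
  for (nm in names(ev)) {
    if (ev[[nm]][2] > config@trialLen + 1e-9)
      stop("trial layout overflow: event '", nm, "' of ", trialType,
           " ends at ", ev[[nm]][2], " s but the trial is only ",
           config@trialLen, " s")
  }
  attr(ev, "cueDurs") <- d
  ev
}

binSpan <- function(onset, offset, dt) {
  # bins covering [onset, offset): half-open so adjacent events never overlap
  i0 <- as.integer(round(onset / dt)) + 1L
  i1 <- as.integer(round(offset / dt))
  if (i1 < i0) integer(0) else i0:i1
}

#' Build one clean (noise-free) tDNMS trial
#'
#' The two input channels are one-hot: channel 1 carries the brief start cue,
#' channel 2 the timed cue (both cue epochs, or the single epoch on XL trials).
#' The target is a boxcar of height \code{targetAmplitude} spanning the
#' response window on Go trials (SL, LS, MM, LL, XL) and identically zero on
#' the SS match trial. Deterministic.
#'
#' @param trialType one of "SS", "SL", "LS", "MM", "LL", "XL"
#' @param config a \linkS4class{TaskConfig}
#' @param cue1,cue2 optional overrides of the cue durations (s), used by the
#'   cue-duration sweeps
#' @param probe flag the trial as an unrewarded probe
#' @return a \linkS4class{TrialTensor}
#' @export
makeTrial <- function(trialType, config = taskConfig(), cue1 = NULL,
                      cue2 = NULL, probe = FALSE) {
  trialType <- match.arg(trialType, trialTypes)
  ev <- trialEvents(trialType, config, cue1, cue2)
  nb <- config@nBins
  dt <- config@dt
  inputs <- matrix(0, nb, 2, dimnames = list(NULL, c("start", "timed")))
  inputs[binSpan(ev$start_cue[1], ev$start_cue[2], dt), 1] <- 1
  inputs[binSpan(ev$cue1[1], ev$cue1[2], dt), 2] <- 1
  if (!is.null(ev$cue2)) inputs[binSpan(ev$cue2[1], ev$cue2[2], dt), 2] <- 1
  target <- numeric(nb)
  isGo <- trialType != "SS"
  if (isGo)
    target[binSpan(ev$response_window[1], ev$response_window[2], dt)] <-
      config@targetAmplitude
  d <- attr(ev, "cueDurs")
  spec <- list(trialType = trialType, cue1Dur = d[1], cue2Dur = d[2],
               isGo = isGo, probe = probe, eventTimes = ev[names(ev)],
               dt = dt, trialLen = config@trialLen)
  new("TrialTensor", inputs = inputs, target = target, spec = spec,
      noisy = FALSE)
}

#' Add i.i.d. Gaussian noise to a trial's input channels
#'
#' Every input entry (both channels, every bin) is perturbed by an independent
#' draw from N(0, sigma); the target is untouched. Uses R's global random
#' stream, so results are reproducible under \code{set.seed}.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param sigma noise sd (>= 0)
#' @return the noisy \linkS4class{TrialTensor}
#' @export
addInputNoise <- function(tensor, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(tensor)
  tensor@inputs <- tensor@inputs + matrix(
    rnorm(length(tensor@inputs), 0, sigma), nrow(tensor@inputs))
  tensor@noisy <- TRUE
  tensor
}

#' Build one shuffled block of trials
#'
#' The block contains exactly the multiset \code{types} in a uniformly random
#' order, with fresh input noise drawn per trial (unless \code{noise = FALSE}).
#'
#' @param types character vector, the exact trial multiset of the block,
#'   e.g. \code{c("SS","SS","SL","LS")} for a full-task block
#' @param config a \linkS4class{TaskConfig}
#' @param noise add input noise with \code{config@inputNoiseSigma}
#' @return list of \linkS4class{TrialTensor}
#' @export
makeBlock <- function(types, config = taskConfig(), noise = TRUE) {
  if (length(types) == 0) stop("empty trial-type set for block")
  order <- sample(length(types))
  lapply(types[order], function(tt) {
    tr <- makeTrial(tt, config)
    if (noise) tr <- addInputNoise(tr, config@inputNoiseSigma) else tr
  })
}

#' Build one 5-trial probe block
#'
#' Composition is \{SS, SS, SL, LS, probe\} in uniformly shuffled order;
#' the probe trial (MM, LL or XL) is flagged unrewarded. With one probe per
#' 5-trial block, probes make up 20\% of a session's trials.
#'
#' @param probeType "MM", "LL" or "XL"
#' @param config a \linkS4class{TaskConfig}
#' @param noise add input noise
#' @return list of 5 \linkS4class{TrialTensor}
#' @export
makeProbeBlock <- function(probeType, config = taskConfig(), noise = TRUE) {
  probeType <- match.arg(probeType, c("MM", "LL", "XL"))
  types <- c("SS", "SS", "SL", "LS", probeType)
  order <- sample(5L)
  lapply(order, function(i) {
    tr <- makeTrial(types[i], config, probe = types[i] == probeType)
    if (noise) addInputNoise(tr, config@inputNoiseSigma) else tr
  })
}

fullTaskBlock <- c("SS", "SS", "SL", "LS")
shapingBlock <- c("SL", "SL", "LS", "LS")

#' Construct a shaping curriculum
#'
#' Five curricula are supported: \code{NS} (no shaping; the full task
#' throughout), \code{S_FT} (no-match shaping on SL and LS, then the full
#' task), \code{SL_FT} and \code{LS_FT} (single-type shaping, then the full
#' task), and \code{ONLY_SHAPING} (the shaping phase alone). At full scale
#' training lasts 1000 blocks of 4 trials with shaping, when present,
#' replacing the first 300 blocks; pass smaller \code{totalBlocks} /
#' \code{shapingBlocks} for reduced-scale runs.
#'
#' @param name curriculum name
#' @param totalBlocks total training blocks
#' @param shapingBlocks blocks of the shaping phase (ignored for NS)
#' @return a \linkS4class{Curriculum}
#' @export
curriculum <- function(name = c("NS", "S_FT", "SL_FT", "LS_FT", "ONLY_SHAPING"),
                       totalBlocks = 1000L, shapingBlocks = 300L) {
  name <- match.arg(name)
  totalBlocks <- as.integer(totalBlocks)
  shapingBlocks <- as.integer(shapingBlocks)
  shapeTypes <- switch(name,
                       S_FT = shapingBlock, ONLY_SHAPING = shapingBlock,
                       SL_FT = rep("SL", 4L), LS_FT = rep("LS", 4L), NULL)
  phases <- if (name == "NS") {
    data.frame(phase = "full_task", nBlocks = totalBlocks, blockSize = 4L)
  } else if (name == "ONLY_SHAPING") {
    data.frame(phase = "shaping", nBlocks = shapingBlocks, blockSize = 4L)
  } else {
    data.frame(phase = c("shaping", "full_task"),
               nBlocks = c(shapingBlocks, totalBlocks - shapingBlocks),
               blockSize = 4L)
  }
  phases$types <- if (name == "NS") list(fullTaskBlock)
                  else if (name == "ONLY_SHAPING") list(shapeTypes)
                  else list(shapeTypes, fullTaskBlock)
  new("Curriculum", name = name, phases = phases)
}

#' @describeIn curriculum total number of blocks in a curriculum
#' @param x a Curriculum
#' @export
totalBlocks <- function(x) sum(x@phases$nBlocks)

#' Serialize a TaskConfig or Curriculum to a YAML file
#' @param x object to write
#' @param path file path
#' @export
writeConfigYAML <- function(x, path) {
  lst <- if (is(x, "TaskConfig")) {
    sapply(slotNames(x), function(s) slot(x, s), simplify = FALSE)
  } else if (is(x, "Curriculum")) {
    list(name = x@name,
         phases = lapply(seq_len(nrow(x@phases)), function(i)
           list(phase = x@phases$phase[i], nBlocks = x@phases$nBlocks[i],
                blockSize = x@phases$blockSize[i],
                types = x@phases$types[[i]])))
  } else stop("unsupported object")
  yaml::write_yaml(c(list(class = class(x)[1]), lst), path)
}

#' Read a TaskConfig or Curriculum back from YAML
#' @param path file path written by \code{writeConfigYAML}
#' @export
readConfigYAML <- function(path) {
  lst <- yaml::read_yaml(path)
  if (identical(lst$class, "TaskConfig")) {
    do.call(taskConfig, lst[setdiff(names(lst), c("class", "nBins"))])
  } else if (identical(lst$class, "Curriculum")) {
    phases <- data.frame(
      phase = vapply(lst$phases, `[[`, "", "phase"),
      nBlocks = vapply(lst$phases, function(p) as.integer(p$nBlocks), 1L),
      blockSize = vapply(lst$phases, function(p) as.integer(p$blockSize), 1L))
    phases$types <- lapply(lst$phases, function(p) unlist(p$types))
    new("Curriculum", name = lst$name, phases = phases)
  } else stop("unrecognised YAML config")
}
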