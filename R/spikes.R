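#' Specify a synthetic temporally tuned population
#'
#' Defaults emulate a population of cortical time cells recorded over a 20 s
#' trial: tuned units with Gaussian firing fields (sd \code{fieldWidth})
#' whose centres tile the trial, a peak rate well above baseline, a modest
#' per-trial jitter of the field centre, and a fraction of non-task-responsive
#' units firing at baseline throughout. In \code{"shared_across_types"} mode a
#' unit's field centre is identical on every trial type; in
#' \code{"context_specific"} mode each trial type receives an independently
#' drawn centre (no abstract time code).
#'
#' @param nUnits number of units
#' @param fieldWidth Gaussian sd of the rate field (s)
#' @param peakRate peak firing rate (Hz)
#' @param baselineRate baseline rate (Hz)
#' @param sharingMode "shared_across_types" or "context_specific"
#' @param noiseUnitFraction fraction of baseline-only units
#' @param trialJitter per-trial field-centre jitter sd (s)
#' @param trialLen trial length used to tile the field centres (s)
#' @param fieldCenters optional explicit centres (s), one per unit
#' @return a \linkS4class{PopulationSpec}
#' @export
populationSpec <- function(nUnits = 64L, fieldWidth = 1.5, peakRate = 15,
                           baselineRate = 0.5,
                           sharingMode = c("shared_across_types",
                                           "context_specific"),
                           noiseUnitFraction = 0.2, trialJitter = 0.3,
                           trialLen = 20, fieldCenters = NULL) {
  sharingMode <- match.arg(sharingMode)
  nUnits <- as.integer(nUnits)
  if (is.null(fieldCenters))
    fieldCenters <- seq(0, trialLen, length.out = nUnits + 2L)[-c(1L, nUnits + 2L)]
  new("PopulationSpec", nUnits = nUnits, fieldCenters = fieldCenters,
      fieldWidth = fieldWidth, peakRate = peakRate,
      baselineRate = baselineRate, sharingMode = sharingMode,
      noiseUnitFraction = noiseUnitFraction, trialJitter = trialJitter)
}

#' Generate inhomogeneous-Poisson spike trains for a session
#'
#' Each tuned unit fires as an inhomogeneous Poisson process with intensity
#' \code{baseline + (peak - baseline) * exp(-(t - c)^2 / (2 sd^2))}, where the
#' centre c is the unit's field centre for the current trial's type, jittered
#' independently per trial. The last \code{noiseUnitFraction} of units are
#' noise units with flat baseline intensity. Spike times have 1 ms resolution
#' on the trial-relative clock.
#'
#' @param spec a \linkS4class{PopulationSpec}
#' @param session character vector of trial types, one per trial
#' @param trialLen trial duration (s)
#' @return data.frame with columns unit, trial, time (s), plus the per-type
#'   field-centre table as attribute \code{"centers"}
#' @export
generatePopulation <- function(spec, session, trialLen = 20) {
  nU <- spec@nUnits
  types <- unique(session)
  isNoise <- seq_len(nU) > round((1 - spec@noiseUnitFraction) * nU)
  centers <- matrix(spec@fieldCenters, nU, length(types),
                    dimnames = list(NULL, types))
  if (spec@sharingMode == "context_specific")
    for (j in seq_along(types))
      centers[, j] <- runif(nU, 0, trialLen)
  grid <- seq(0.0005, trialLen - 0.0005, by = 0.001)   # 1 ms bin centres
  out <- vector("list", length(session) * nU)
  k <- 0L
  for (tr in seq_along(session)) {
    ctr <- centers[, session[tr]]
    for (u in seq_len(nU)) {
      if (isNoise[u]) {
        lam <- rep(spec@baselineRate, length(grid))
      } else {
        c0 <- ctr[u] + rnorm(1, 0, spec@trialJitter)
        lam <- spec@baselineRate + (spec@peakRate - spec@baselineRate) *
          exp(-(grid - c0)^2 / (2 * spec@fieldWidth^2))
      }
      total <- sum(lam) * 0.001
      n <- rpois(1L, total)
      if (n > 0) {
        k <- k + 1L
        out[[k]] <- data.frame(
          unit = u, trial = tr,
          time = sort(sample(grid, n, replace = TRUE, prob = lam)))
      }
    }
  }
  spikes <- do.call(rbind, out[seq_len(k)])
  attr(spikes, "centers") <- centers
  attr(spikes, "noiseUnits") <- which(isNoise)
  spikes
}

# Gaussian kernel on the analysis-bin grid, truncated to the stated window
# and renormalised so flat inputs stay flat (also at trial edges, where the
# convolution renormalises over the in-range taps).
gaussKernel <- function(sigma, window, binWidth) {
  half <- floor((window / 2) / binWidth)
  x <- (-half:half) * binWidth
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

smoothTrace <- function(v, kernel) {
  half <- (length(kernel) - 1L) / 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- kernel[j - i + half + 1L]
    out[i] <- sum(v[j] * w) / sum(w)
  }
  out
}

#' Bin, smooth and z-score a session of spike trains
#'
#' Spike times are grouped into \code{binWidth} (default 0.5 s) bins per
#' trial and converted to rates, smoothed with a Gaussian kernel of sd
#' \code{sigma} truncated to \code{window} and renormalised within the
#' window, then z-scored per unit over the pooled session. Units that never
#' spike are flagged rather than divided by zero.
#'
#' @param spikes spike table from \code{generatePopulation} (columns unit,
#'   trial, time) or \code{readSpikeTable}
#' @param nTrials number of trials in the session
#' @param trialTypes trial-type label per trial
#' @param trialLen trial duration (s)
#' @param binWidth analysis bin (s)
#' @param sigma,window Gaussian smoothing sd and truncation window (s)
#' @param nUnits population size (defaults to the largest unit id seen)
#' @return a \linkS4class{RateMatrix}
#' @export
preprocessSpikes <- function(spikes, nTrials, trialTypes, trialLen = 20,
                             binWidth = 0.5, sigma = 2, window = 8,
                             nUnits = max(spikes$unit)) {
  nb <- as.integer(round(trialLen / binWidth))
  kern <- gaussKernel(sigma, window, binWidth)
  rates <- array(0, c(nTrials, nb, nUnits))
  binIdx <- pmin(nb, floor(spikes$time / binWidth) + 1L)
  counts <- tapply(rep(1, nrow(spikes)),
                   list(factor(spikes$trial, seq_len(nTrials)),
                        factor(binIdx, seq_len(nb)),
                        factor(spikes$unit, seq_len(nUnits))),
                   sum, default = 0)
  for (u in seq_len(nUnits))
    for (tr in seq_len(nTrials))
      rates[tr, , u] <- smoothTrace(counts[tr, , u] / binWidth, kern)
  zeroVar <- integer(0)
  for (u in seq_len(nUnits)) {
    v <- rates[, , u]
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) {
      zeroVar <- c(zeroVar, u)
      rates[, , u] <- 0
    } else {
      rates[, , u] <- (v - mean(v)) / s
    }
  }
  new("RateMatrix", rates = rates, binWidth = binWidth,
      smoothing = c(sigma = sigma, window = window),
      zeroVarianceUnits = zeroVar, trialTypes = as.character(trialTypes))
}

#' Select task-responsive units by trial-to-trial reliability
#'
#' For each unit, computes the Pearson correlation between the rate traces of
#' every pair of trials and keeps units whose mean pairwise correlation
#' exceeds the threshold (default 0.25). Pairs involving a zero-variance
#' trace are skipped.
#'
#' @param rates a \linkS4class{RateMatrix}
#' @param threshold retention threshold on the mean correlation
#' @return integer vector of retained unit indices, with the per-unit mean
#'   correlations as attribute \code{"meanCor"}
#' @export
selectTaskResponsive <- function(rates, threshold = 0.25) {
  nU <- dim(rates@rates)[3]
  mc <- vapply(seq_len(nU), function(u) {
    M <- rates@rates[, , u]                 # trials x bins
    ok <- apply(M, 1L, sd) > 1e-12
    if (sum(ok) < 2) return(NA_real_)
    cm <- cor(t(M[ok, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }, 0)
  keep <- which(!is.na(mc) & mc > threshold)
  attr(keep, "meanCor") <- mc
  keep
}

#' Pseudo-population tuning curves and their PCA dimensionality
#'
#' Pools the selected units of one or more sessions into a virtual
#' population: trials are partitioned into \code{nSplits} splits (balanced
#' within trial type); per split, each unit's trial-averaged tuning curve is
#' computed for every trial type and the per-type curves are concatenated in
#' time; PCA is run on the resulting [concatenated bins x units] matrix per
#' split and the variance fraction of the first three components reported.
#'
#' @param sessions list of entries, each \code{list(rates = RateMatrix,
#'   units = integer)} (units as from \code{selectTaskResponsive})
#' @param nSplits number of trial splits
#' @param nUnits optional down-sample so cohorts compare equal unit counts
#' @return list: \code{varFirst3} (per split), \code{tuning} (per split, the
#'   concatenated tuning-curve matrix), \code{nUnits}
#' @export
buildPseudopopulation <- function(sessions, nSplits = 4L, nUnits = NULL) {
  pieces <- list()
  for (s in sessions) {
    rm_ <- s$rates
    units <- s$units
    if (!length(units)) next
    pieces[[length(pieces) + 1L]] <- list(rates = rm_, units = units)
  }
  if (!length(pieces)) stop("no retained units in any session")
  totalUnits <- sum(vapply(pieces, function(p) length(p$units), 0L))
  if (!is.null(nUnits)) {
    if (nUnits > totalUnits) stop("cannot down-sample to more units than available")
    # drop units uniformly from the pooled list
    keepFlat <- sort(sample(totalUnits, nUnits))
  } else keepFlat <- seq_len(totalUnits)
  typeSet <- sort(unique(unlist(lapply(pieces, function(p) p$rates@trialTypes))))
  # one disjoint split assignment per session, balanced within trial type
  for (i in seq_along(pieces)) {
    types <- pieces[[i]]$rates@trialTypes
    split <- integer(length(types))
    for (tt in unique(types)) {
      idx <- sample(which(types == tt))
      split[idx] <- rep_len(seq_len(nSplits), length(idx))
    }
    pieces[[i]]$split <- split
  }
  tuning <- vector("list", nSplits)
  for (sp in seq_len(nSplits)) {
    cols <- list()
    off <- 0L
    for (p in pieces) {
      types <- p$rates@trialTypes
      sel <- which(p$split == sp)
      if (length(sel) < length(typeSet))
        stop("insufficient trials per split")
      curves <- do.call(rbind, lapply(typeSet, function(tt) {
        tri <- sel[types[sel] == tt]
        if (!length(tri)) stop("insufficient trials per split for type ", tt)
        apply(p$rates@rates[tri, , p$units, drop = FALSE], c(2L, 3L), mean)
      }))
      cols[[length(cols) + 1L]] <- curves
      off <- off + length(p$units)
    }
    M <- do.call(cbind, cols)[, keepFlat, drop = FALSE]
    tuning[[sp]] <- M
  }
  varFirst3 <- vapply(tuning, function(M) {
    pc <- prcomp(M, center = TRUE, scale. = FALSE)
    sum(pc$sdev[1:3]^2) / sum(pc$sdev^2)
  }, 0)
  list(varFirst3 = varFirst3, tuning = tuning, nUnits = length(keepFlat))
}

#' Read/write spike tables in a columnar text format
#'
#' Plain whitespace-separated columns: unit id, trial id, spike time (s).
#'
#' @param spikes spike data.frame
#' @param path file path
#' @export
writeSpikeTable <- function(spikes, path) {
  utils::write.table(spikes[, c("unit", "trial", "time")], path,
                     row.names = FALSE, quote = FALSE)
}

#' @rdname writeSpikeTable
#' @export
readSpikeTable <- function(path) {
  utils::read.table(path, header = TRUE,
                    colClasses = c("integer", "integer", "numeric"))
}
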