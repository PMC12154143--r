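test_that("the Poisson generator matches its intensity integral", {
  # one flat 20 Hz unit over 100 x 20 s trials: ~40000 spikes +/- 3 sd
  set.seed(1)
  spec <- populationSpec(nUnits = 1L, peakRate = 20, baselineRate = 20,
                         noiseUnitFraction = 0)
  spk <- generatePopulation(spec, rep("SL", 100L))
  n <- nrow(spk)
  expect_lt(abs(n - 40000), 3 * sqrt(40000))
  expect_true(all(spk$time >= 0 & spk$time <= 20))

  # peak == baseline makes tuned units look exactly like noise units
  set.seed(2)
  specFlat <- populationSpec(nUnits = 8L, peakRate = 2, baselineRate = 2,
                             noiseUnitFraction = 0.5)
  spkF <- generatePopulation(specFlat, rep(c("SL", "LS"), 10L))
  counts <- table(factor(spkF$unit, 1:8))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("shared-mode field centres agree across trial types", {
  set.seed(3)
  session <- rep(c("SL", "LS"), 30L)
  spec <- populationSpec(nUnits = 16L, noiseUnitFraction = 0,
                         trialJitter = 0.2)
  spk <- generatePopulation(spec, session)
  est <- function(types) vapply(1:16, function(u) {
    s <- spk[spk$unit == u & session[spk$trial] %in% types, "time"]
    mean(s)
  }, 0)
  cSL <- est("SL"); cLS <- est("LS")
  # centre-of-mass estimates from disjoint trial types agree within jitter
  # (edge fields are pulled inwards by trial truncation, identically so
  # for both estimates)
  expect_lt(median(abs(cSL - cLS)), 3 * spec@trialJitter)

  set.seed(4)
  specCS <- populationSpec(nUnits = 16L, noiseUnitFraction = 0,
                           sharingMode = "context_specific")
  spkCS <- generatePopulation(specCS, session)
  ctr <- attr(spkCS, "centers")
  expect_false(isTRUE(all.equal(ctr[, "SL"], ctr[, "LS"])))
})

test_that("smoothing equals brute-force convolution with the truncated kernel", {
  set.seed(5)
  kern <- tdnmsRNN:::gaussKernel(2, 8, 0.5)
  expect_equal(sum(kern), 1)
  v <- rpois(40, 3)
  got <- tdnmsRNN:::smoothTrace(v, kern)
  half <- (length(kern) - 1) / 2
  want <- vapply(seq_along(v), function(i) {
    num <- 0; den <- 0
    for (o in -half:half) {
      j <- i + o
      if (j >= 1 && j <= length(v)) {
        num <- num + v[j] * kern[o + half + 1]
        den <- den + kern[o + half + 1]
      }
    }
    num / den
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
  # flat inputs stay flat, also at the edges
  expect_equal(tdnmsRNN:::smoothTrace(rep(4, 40), kern), rep(4, 40))
})

test_that("preprocessing bins, smooths and z-scores per unit", {
  # a single spike becomes a kernel bump centred on its bin, mass preserved
  spikes <- data.frame(unit = 1L, trial = 1L, time = 10.1)
  rm0 <- preprocessSpikes(spikes, 1L, "SL", nUnits = 2L)
  expect_equal(dim(rm0@rates), c(1L, 40L, 2L))
  expect_equal(rm0@zeroVarianceUnits, 2L)      # the spikeless unit is flagged
  expect_true(all(rm0@rates[, , 2] == 0))

  kern <- tdnmsRNN:::gaussKernel(2, 8, 0.5)
  raw <- numeric(40); raw[21] <- 1 / 0.5       # one spike in bin 21, rate units
  want <- tdnmsRNN:::smoothTrace(raw, kern)
  got <- rm0@rates[1, , 1]
  expect_equal(got, (want - mean(want)) / sd(want), tolerance = 1e-12)

  set.seed(6)
  spec <- populationSpec(nUnits = 6L, noiseUnitFraction = 0)
  session <- rep(c("SS", "SL", "LS"), 8L)
  rm1 <- preprocessSpikes(generatePopulation(spec, session),
                          length(session), session, nUnits = 6L)
  for (u in 1:6) {
    expect_lt(abs(mean(rm1@rates[, , u])), 1e-10)
    expect_equal(sd(rm1@rates[, , u]), 1, tolerance = 1e-10)
  }
})

test_that("reliability selection retains tuned units and rejects noise", {
  bundle <- spikeBundle("shared_across_types")
  nUnits <- bundle$spec@nUnits
  noiseUnits <- attr(bundle$spikes, "noiseUnits")
  tuned <- setdiff(seq_len(nUnits), noiseUnits)
  expect_false(any(bundle$keep %in% noiseUnits))
  expect_gt(mean(tuned %in% bundle$keep), 0.8)

  # a unit with identical traces on every trial has mean correlation 1
  rates <- array(rep(sin(seq(0, 3, length.out = 40)), each = 6), c(6, 40, 1))
  rmx <- new("RateMatrix", rates = rates, binWidth = 0.5,
             smoothing = c(sigma = 2, window = 8),
             zeroVarianceUnits = integer(0), trialTypes = rep("SL", 6))
  keep <- selectTaskResponsive(rmx)
  expect_equal(keep, 1L, ignore_attr = TRUE)
  expect_equal(attr(keep, "meanCor")[1], 1)

  # retention probability rises with the peak/baseline ratio
  set.seed(7)
  session <- rep(c("SL", "LS"), 15L)
  frac <- vapply(c(1, 4, 12), function(pk) {
    spec <- populationSpec(nUnits = 24L, peakRate = pk, baselineRate = 1,
                           noiseUnitFraction = 0)
    rm_ <- preprocessSpikes(generatePopulation(spec, session),
                            length(session), session, nUnits = 24L)
    length(selectTaskResponsive(rm_)) / 24
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.5)
  expect_gt(frac[3], 0.8)
})

test_that("pseudo-populations split reproducibly and rank cohorts by sharing", {
  # identical trials in every split give identical per-split variance fractions
  tune <- outer(seq(0, 1, length.out = 40), rnorm(5))
  rates <- array(0, c(8, 40, 5))
  for (i in 1:8) rates[i, , ] <- tune
  rmx <- new("RateMatrix", rates = rates, binWidth = 0.5,
             smoothing = c(sigma = 2, window = 8),
             zeroVarianceUnits = integer(0),
             trialTypes = rep(c("SS", "SL"), 4))
  set.seed(8)
  pp <- buildPseudopopulation(list(list(rates = rmx, units = 1:5)),
                              nSplits = 4L)
  expect_length(pp$varFirst3, 4L)
  expect_equal(max(pp$varFirst3) - min(pp$varFirst3), 0, tolerance = 1e-12)

  set.seed(9)
  shared <- spikeBundle("shared_across_types")
  specific <- spikeBundle("context_specific")
  nCommon <- min(length(shared$keep), length(specific$keep))
  ppS <- buildPseudopopulation(list(list(rates = shared$rates,
                                         units = shared$keep)),
                               nSplits = 4L, nUnits = nCommon)
  ppC <- buildPseudopopulation(list(list(rates = specific$rates,
                                         units = specific$keep)),
                               nSplits = 4L, nUnits = nCommon)
  expect_gt(median(ppS$varFirst3), median(ppC$varFirst3))
  expect_error(buildPseudopopulation(list(list(rates = rmx, units = 1:5)),
                                     nSplits = 40L), "insufficient")
})

test_that("spike tables round-trip through the columnar text format", {
  set.seed(10)
  spk <- data.frame(unit = sample(5, 20, TRUE), trial = sample(3, 20, TRUE),
                    time = round(runif(20, 0, 20), 3))
  tmp <- tempfile(fileext = ".tsv")
  writeSpikeTable(spk, tmp)
  back <- readSpikeTable(tmp)
  expect_equal(back$time, spk$time)
  expect_equal(back$unit, spk$unit)
})
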