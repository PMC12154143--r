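test_that("trial layouts place events at the configured times", {
  task <- taskConfig()
  ss <- makeTrial("SS", task)
  expect_equal(nrow(ss@inputs), 200L)
  # timed channel high on two 2 s epochs separated by the 3 s ISI
  timed <- ss@inputs[, 2]
  expect_equal(which(timed == 1), c(31:50, 81:100))
  expect_true(all(ss@target == 0))
  expect_false(ss@spec$isGo)

  xl <- makeTrial("XL", task)
  expect_equal(which(xl@inputs[, 2] == 1), 31:130)   # one 10 s epoch from 3 s
  expect_equal(which(xl@target == 1), 131:160)       # 3 s window after offset
  expect_true(xl@spec$isGo)

  sl <- makeTrial("SL", task)
  expect_equal(which(sl@inputs[, 2] == 1), c(31:50, 81:130))
  expect_equal(sum(sl@target), task@targetAmplitude * task@responseWindow / task@dt)
  # start cue: 0.2 s from t = 0 on channel 1, for every type
  for (tt in c("SS", "SL", "LS", "MM", "LL", "XL"))
    expect_equal(which(makeTrial(tt, task)@inputs[, 1] == 1), 1:2)
})

test_that("clean inputs are binary and target mass is exact on every type", {
  task <- taskConfig()
  for (tt in c("SS", "SL", "LS", "MM", "LL", "XL")) {
    tr <- makeTrial(tt, task)
    expect_true(all(tr@inputs %in% c(0, 1)))
    expected <- if (tt == "SS") 0 else task@targetAmplitude * 30
    expect_equal(sum(tr@target), expected)
  }
})

test_that("layout overflow is a configuration error naming the event", {
  task <- taskConfig()
  expect_error(makeTrial("SL", task, cue2 = 12), "overflow.*response_window")
  expect_error(taskConfig(shortDur = 5, longDur = 2), "shortDur")
  expect_error(taskConfig(dt = 0.3), "multiples|trialLen")
})

test_that("input noise has the configured scale and leaves the target alone", {
  task <- taskConfig()
  tr <- makeTrial("SL", task)
  expect_identical(addInputNoise(tr, 0), tr)
  expect_error(addInputNoise(tr, -1), "sigma")

  set.seed(1)
  diffs <- unlist(lapply(1:30, function(i)
    addInputNoise(tr, 0.15)@inputs - tr@inputs))
  expect_gt(length(diffs), 1e4)
  expect_lt(abs(sd(diffs) - 0.15) / 0.15, 0.05)

  set.seed(7); a <- addInputNoise(tr, 0.15)
  set.seed(7); b <- addInputNoise(tr, 0.15)
  expect_identical(a@inputs, b@inputs)
  expect_identical(a@target, tr@target)
})

test_that("blocks have exact composition and near-uniform orderings", {
  task <- taskConfig()
  set.seed(2)
  blk <- makeBlock(c("SS", "SS", "SL", "LS"), task)
  expect_setequal(vapply(blk, function(x) x@spec$trialType, ""),
                  c("SS", "SS", "SL", "LS"))
  expect_equal(sort(vapply(blk, function(x) x@spec$trialType, "")),
               c("LS", "SL", "SS", "SS"))
  shp <- makeBlock(rep("SL", 4), task)
  expect_true(all(vapply(shp, function(x) x@spec$trialType, "") == "SL"))
  expect_error(makeBlock(character(0), task), "empty")

  # all 12 distinguishable orderings of {SS,SS,SL,LS} occur near-uniformly
  set.seed(3)
  orders <- replicate(1000, paste(
    vapply(makeBlock(c("SS", "SS", "SL", "LS"), task, noise = FALSE),
           function(x) x@spec$trialType, ""), collapse = ""))
  tab <- table(orders)
  expect_equal(length(tab), 12L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("probe blocks carry 2 SS, 1 SL, 1 LS and a flagged probe", {
  task <- taskConfig()
  set.seed(4)
  for (pt in c("MM", "LL", "XL")) {
    blk <- makeProbeBlock(pt, task)
    types <- vapply(blk, function(x) x@spec$trialType, "")
    expect_equal(sort(types), sort(c("SS", "SS", "SL", "LS", pt)))
    probeFlag <- vapply(blk, function(x) isTRUE(x@spec$probe), NA)
    expect_equal(sum(probeFlag), 1L)
    expect_equal(types[probeFlag], pt)
  }
  expect_error(makeProbeBlock("ZZ", task))
  mm <- makeTrial("MM", task)
  expect_equal(c(mm@spec$cue1Dur, mm@spec$cue2Dur), c(3.5, 3.5))
  ll <- makeTrial("LL", task)
  expect_equal(c(ll@spec$cue1Dur, ll@spec$cue2Dur), c(5, 5))
  expect_equal(diff(mm@spec$eventTimes$isi), 3)
})

test_that("curricula follow the block schedule and serialise through YAML", {
  cur <- curriculum("S_FT")
  expect_equal(totalBlocks(cur), 1000L)
  expect_equal(cur@phases$nBlocks, c(300L, 700L))
  expect_equal(sort(cur@phases$types[[1]]), c("LS", "LS", "SL", "SL"))
  expect_equal(sort(cur@phases$types[[2]]), c("LS", "SL", "SS", "SS"))
  expect_equal(totalBlocks(curriculum("NS")), 1000L)
  expect_equal(curriculum("SL_FT")@phases$types[[1]], rep("SL", 4))

  tmp <- tempfile(fileext = ".yaml")
  writeConfigYAML(cur, tmp)
  expect_equal(readConfigYAML(tmp)@phases$types, cur@phases$types)
  tmp2 <- tempfile(fileext = ".yaml")
  writeConfigYAML(taskConfig(), tmp2)
  expect_equal(readConfigYAML(tmp2), taskConfig())
})
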