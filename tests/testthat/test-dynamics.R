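test_that("tangling equals the brute-force double loop", {
  set.seed(1)
  # random smooth trajectories, several sizes, with and without trial breaks
  for (T_ in c(40L, 120L, 500L)) {
    X <- apply(matrix(rnorm(T_ * 5), T_, 5), 2, cumsum) / sqrt(T_)
    tp <- tangling(X, chunkSize = 37L)    # odd chunk size: exercise seams
    expect_equal(tp$q, tanglingBruteForce(X), tolerance = 1e-12)
  }
  X <- apply(matrix(rnorm(90 * 4), 90, 4), 2, cumsum)
  idx <- rep(1:3, each = 30)
  expect_equal(tangling(X, trialIndex = idx)$q,
               tanglingBruteForce(X, trialIndex = idx), tolerance = 1e-12)
})

test_that("tangling is zero on a line, constant on a circle, maximal at a crossing", {
  # straight line at constant velocity: all derivatives identical
  line <- outer(seq(0, 1, length.out = 50), c(1, 2, -1))
  expect_equal(max(tangling(line)$q), 0)

  # constant-speed circle (sampled over one full wrap so the backward
  # differences cover every angle): symmetry forces constant Q
  th <- (0:100) * 2 * pi / 100
  circ <- cbind(cos(th), sin(th))
  q <- tangling(circ)$q
  expect_lt(diff(range(q)) / mean(q), 1e-8)

  # figure-eight: the self-crossing bins carry the maximum
  t2 <- seq(0, 2 * pi, length.out = 201)[-201]
  fig8 <- cbind(sin(t2), sin(t2) * cos(t2))
  tp <- tangling(fig8)
  bf <- tanglingBruteForce(fig8)
  expect_equal(tp$q, bf, tolerance = 1e-12)
  crossBins <- which(rowSums(fig8[-1, ]^2) < 0.01)
  expect_true(which.max(tp$q) %in% crossBins)

  expect_error(tangling(matrix(0, 10, 3)), "zero")
})

test_that("fixed points of simple networks match their closed forms", {
  # zero-weight network: unique stable point at the origin, eigenvalues 1-g
  set.seed(2)
  m <- rnnInit(6L)
  m@wIn[] <- 0; m@wRec[] <- 0; m@b[] <- 0
  fp <- findFixedPoints(m, matrix(rnorm(30, sd = 0.5), 5, 6), "cue_off")
  expect_equal(nPoints(fp), 1L)
  expect_lt(max(abs(fp@locations)), 1e-8)
  expect_equal(fp@stability, "stable")
  expect_equal(sort(Re(fp@eigenvalues[[1]])), rep(0.8, 6), tolerance = 1e-10)
})

test_that("scalar-network fixed points agree with bisection of h = tanh(wh)", {
  w <- 2
  m <- new("RNNModel", wIn = matrix(0, 1, 2), wRec = matrix(w, 1, 1),
           b = 0, wOut = 1, bOut = 0, gamma = 0.2, unitNoiseSigma = 0,
           nUnits = 1L, activation = "tanh")
  # independent oracle: bisection on f(h) = tanh(wh) - h over (0.1, 1)
  f <- function(h) tanh(w * h) - h
  lo <- 0.1; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  hstar <- (lo + hi) / 2

  fp <- findFixedPoints(m, matrix(c(-0.9, -0.4, 0, 0.4, 0.9), 5, 1),
                        "cue_off")
  locs <- sort(drop(fp@locations))
  expect_equal(length(locs), 3L)
  expect_equal(locs, c(-hstar, 0, hstar), tolerance = 1e-6)
  stab <- fp@stability[order(drop(fp@locations))]
  expect_equal(stab, c("stable", "unstable", "stable"))
})

test_that("linearisation matches a finite-difference Jacobian", {
  set.seed(3)
  m <- rnnInit(8L)
  h <- rnorm(8, sd = 0.3); x <- c(0, 1)
  eps <- 1e-6
  J <- matrix(0, 8, 8)
  for (j in 1:8) {
    hp <- h; hp[j] <- hp[j] + eps
    hm <- h; hm[j] <- hm[j] - eps
    J[, j] <- (rnnStep(m, hp, x) - rnnStep(m, hm, x)) / (2 * eps)
  }
  evNum <- sort(Mod(eigen(J, only.values = TRUE)$values))
  evAna <- sort(Mod(linearizeAt(m, h, x)))
  expect_equal(evAna, evNum, tolerance = 1e-6)

  # saturated units: diagonal gains collapse to 1 - gamma
  msat <- m; msat@b <- rep(10, 8)
  evSat <- linearizeAt(msat, numeric(8), c(0, 0))
  expect_equal(Mod(evSat), rep(1 - m@gamma, 8), tolerance = 1e-6)

  mz <- m; mz@wIn[] <- 0; mz@wRec[] <- 0; mz@b[] <- 0
  expect_equal(Re(linearizeAt(mz, numeric(8), c(0, 0))), rep(0.8, 8))
})

test_that("limit-cycle detection recovers a hand-built planar oscillator", {
  # rotation by 2*pi/25 with gain 1.5 and tanh saturation: a stable orbit
  th <- 2 * pi / 25
  m <- new("RNNModel", wIn = matrix(0, 2, 2),
           wRec = 1.5 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
           b = c(0, 0), wOut = c(1, 0), bOut = 0, gamma = 1,
           unitNoiseSigma = 0, nUnits = 2L, activation = "tanh")
  lc <- detectLimitCycle(m, c(0.5, 0), nSteps = 2000L, relTol = 0.01)
  expect_false(is.null(lc))

  # oracle: period from upward zero crossings of the second coordinate
  H <- hiddenStates(freeRun(m, c(0.5, 0), c(0, 0), 2000L))
  w <- H[501:2000, 2]
  ups <- which(w[-1] > 0 & w[-length(w)] <= 0)
  oraclePeriod <- mean(diff(ups)) * 0.1
  ratio <- lc@period / oraclePeriod
  expect_gte(round(ratio), 1)
  expect_lt(abs(ratio - round(ratio)), 0.05)   # detected lag = whole orbits

  # a network resting at a stable fixed point reports no cycle
  set.seed(4)
  mz <- rnnInit(6L); mz@wIn[] <- 0; mz@wRec[] <- mz@wRec * 0.2
  expect_null(detectLimitCycle(mz, rnorm(6), nSteps = 400L))
})

test_that("shaped networks hold cue-off limit cycles; unshaped ones do not", {
  mot <- cohortMotifs("S_FT", cohortSeeds[1])
  expect_true(mot$summary$cycle[mot$summary$mode == "cue_off"])
  motNS <- cohortMotifs("NS", cohortSeeds[1])
  expect_false(motNS$summary$cycle[motNS$summary$mode == "cue_off"])
  # unshaped networks settle onto attracting points under both modes
  expect_gte(motNS$summary$nStable[1], 1L)
})

test_that("PCA geometry behaves as an orthogonal transform", {
  set.seed(5)
  # data confined to a 2-plane
  f1 <- sin(seq(0, 3, length.out = 60)); f2 <- cos(seq(0, 5, length.out = 60))
  v1 <- rnorm(10); v2 <- rnorm(10)
  H <- outer(f1, v1) + outer(f2, v2)
  traj <- new("Trajectory", hidden = H, output = numeric(60),
              inputsUsed = matrix(0, 60, 2),
              noiseFlags = c(inputNoise = FALSE, unitNoise = FALSE),
              spec = list(trialType = "synthetic"))
  pca <- pcaGeometry(list(traj), k = 10L)
  expect_equal(varianceCaptured(pca, 2L), 1, tolerance = 1e-12)
  expect_lt(pca@varExplained[3], 1e-12)

  # reconstruction from all components is lossless
  scores <- crossProject(traj, pca)
  recon <- sweep(scores %*% t(pca@loadings), 2, -pca@center)
  expect_equal(recon, H, tolerance = 1e-8)
  expect_error(pcaGeometry(list(traj), k = 11L), "k")
})

test_that("cross-projection is the identity on the source's own space", {
  set.seed(6)
  m <- rnnInit(16L)
  trajs <- lapply(c("SS", "SL", "LS"), function(tt)
    runTrial(m, makeTrial(tt, taskConfig()), unitNoise = FALSE))
  pca <- pcaGeometry(trajs, k = 3L)
  own <- crossProject(trajs, pca)
  pooled <- do.call(rbind, lapply(trajs, hiddenStates))
  direct <- sweep(pooled, 2, pca@center) %*% pca@loadings
  expect_equal(do.call(rbind, own), direct)

  centred <- matrix(pca@center, 5, 16, byrow = TRUE)
  expect_equal(crossProject(centred, pca), matrix(0, 5, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(crossProject(matrix(0, 2, 7), pca), "dimension")
})

test_that("full-task training shrinks response-window variance on SS trials", {
  # the shaping-only checkpoint, viewed in the final network's own PCA space,
  # loses SS-trial variance near the response window after full-task training
  rec <- trainedRecord("S_FT", cohortSeeds[1])
  task <- taskConfig()
  final <- checkpoints(rec)$final
  os <- checkpoints(rec)$shaping_end
  trajsF <- lapply(c("SS", "SL", "LS"), function(tt)
    runTrial(final, makeTrial(tt, task), unitNoise = FALSE))
  pca <- pcaGeometry(trajsF, k = 3L)
  ssBins <- 101:130      # the SS response window (10-13 s)
  # variance along PC3, the response axis separating Go deflections
  varNear <- function(model) {
    traj <- runTrial(model, makeTrial("SS", task), unitNoise = FALSE)
    z <- crossProject(traj, pca)
    stats::var(z[ssBins, 3])
  }
  expect_lt(varNear(final), varNear(os))
})

test_that("flow fields of a zero-weight network point to the origin", {
  set.seed(7)
  m <- rnnInit(6L)
  m@wIn[] <- 0; m@wRec[] <- 0; m@b[] <- 0
  pca <- new("PCAResult", loadings = diag(6)[, 1:3], center = numeric(6),
             varExplained = rep(1 / 6, 6), k = 3L, source = "synthetic")
  ff <- flowField(m, pca, plane = c(1L, 2L), gridX = -2:2, gridY = -2:2,
                  inputMode = "cue_off")
  expect_equal(ff$dx, -m@gamma * ff$x, tolerance = 1e-12)
  expect_equal(ff$dy, -0.2 * ff$y, tolerance = 1e-12)
  # the embedded fixed point (origin) has zero in-plane velocity
  expect_equal(ff$dx[ff$x == 0 & ff$y == 0], 0)
})
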