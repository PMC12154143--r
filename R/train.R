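#' Training configuration
#'
#' Gradient descent uses adaptive moment estimation (Adam) over batches of
#' \code{batchSize} trials taken in block order (two batches per 4-trial
#' block), with L2 regularisation of weight \code{l2Lambda} applied to the
#' trainable weight matrices and to the mean squared hidden activation.
#'
#' Because each Adam update moves a parameter by at most roughly the step
#' size, the total parameter displacement available to a run is about
#' \code{learningRate * 2 * totalBlocks}; the default step size of 1e-3 gives
#' reduced-scale runs (a few hundred blocks) enough displacement to learn the
#' task. See the methods vignette for the reasoning.
#'
#' @param learningRate Adam step size
#' @param l2Lambda L2 weight for weights and activations
#' @param batchSize trials per gradient step
#' @param totalBlocks training blocks
#' @param shapingBlocks blocks of the shaping phase (0 or the shaping length)
#' @param seed integer seed
#' @param adamBeta1,adamBeta2,adamEps Adam moment constants
#' @param clipNorm global gradient-norm clip (guards long-horizon BPTT)
#' @return a list of class \code{"TrainConfig"}
#' @export
trainConfig <- function(learningRate = 1e-3, l2Lambda = 1e-3, batchSize = 2L,
                        totalBlocks = 1000L, shapingBlocks = 300L, seed = 1L,
                        adamBeta1 = 0.9, adamBeta2 = 0.999, adamEps = 1e-8,
                        clipNorm = 10) {
  structure(list(learningRate = learningRate, l2Lambda = l2Lambda,
                 batchSize = as.integer(batchSize),
                 totalBlocks = as.integer(totalBlocks),
                 shapingBlocks = as.integer(shapingBlocks),
                 seed = as.integer(seed), adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2, adamEps = adamEps,
                 clipNorm = clipNorm),
            class = "TrainConfig")
}

#' Training loss of one trajectory
#'
#' Mean over bins of the squared output error, plus
#' \code{l2Lambda * (sum of squared trainable weights + mean squared hidden
#' activation)}. Biases carry no weight penalty.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param target target vector, same length as the trajectory
#' @param model the \linkS4class{RNNModel} (for the weight penalty)
#' @param l2Lambda regularisation weight
#' @return scalar loss
#' @export
lossTrajectory <- function(traj, target, model, l2Lambda = 1e-3) {
  if (length(target) != length(traj@output)) stop("target length mismatch")
  if (any(!is.finite(traj@hidden)))
    stop("non-finite activations in trajectory")
  mse <- mean((traj@output - target)^2)
  act <- mean(traj@hidden^2)
  wts <- sum(model@wIn^2) + sum(model@wRec^2) + sum(model@wOut^2)
  mse + l2Lambda * (act + wts)
}

# ---- parameter vector packing -------------------------------------------

packParams <- function(model)
  c(as.numeric(model@wIn), as.numeric(model@wRec), model@b, model@wOut,
    model@bOut)

unpackParams <- function(theta, model) {
  N <- model@nUnits
  i <- 0L
  model@wIn <- matrix(theta[i + seq_len(2L * N)], N, 2L); i <- i + 2L * N
  model@wRec <- matrix(theta[i + seq_len(N * N)], N, N); i <- i + N * N
  model@b <- theta[i + seq_len(N)]; i <- i + N
  model@wOut <- theta[i + seq_len(N)]; i <- i + N
  model@bOut <- theta[i + 1L]
  model
}

# Analytic BPTT gradient for a batch of trials, averaged; returns the packed
# gradient plus the mean loss and mean output MSE.
batchGradient <- function(model, tensors, l2Lambda, unitNoise = TRUE) {
  N <- model@nUnits
  acc <- NULL
  loss <- 0; mse <- 0
  for (tr in tensors) {
    X <- tr@inputs
    Xi <- if (unitNoise && model@unitNoiseSigma > 0)
      matrix(rnorm(nrow(X) * N, 0, model@unitNoiseSigma), nrow(X))
    else matrix(0, 0, 0)
    g <- cpp_bptt_grad(model@wIn, model@wRec, model@b, model@wOut, model@bOut,
                       model@gamma, X, Xi, tr@target, l2Lambda)
    v <- c(as.numeric(g$gWIn), as.numeric(g$gWRec), g$gB, g$gWOut, g$gBOut)
    acc <- if (is.null(acc)) v else acc + v
    loss <- loss + g$loss; mse <- mse + g$mse
  }
  n <- length(tensors)
  list(grad = acc / n, loss = loss / n, mse = mse / n)
}

#' Train a network on a curriculum by backpropagation through time
#'
#' Runs Adam over the curriculum's blocks: each block's trial multiset is
#' shuffled, corrupted with fresh input noise, and consumed in batches of
#' \code{batchSize} trials with fresh unit noise on every step. Records the
#' per-block mean output MSE, the trial types presented, and parameter
#' snapshots at every phase boundary (the snapshot at the end of a shaping
#' phase is the "Only Shaping" network) plus the final parameters.
#' Reproducible from \code{config$seed}.
#'
#' @param curriculum a \linkS4class{Curriculum}
#' @param task a \linkS4class{TaskConfig}
#' @param config a \code{trainConfig()}
#' @param model optional starting \linkS4class{RNNModel}; a fresh 128-unit
#'   network is initialised from the seed when omitted
#' @return a \linkS4class{TrainRecord}
#' @export
trainCurriculum <- function(curriculum, task = taskConfig(),
                            config = trainConfig(), model = NULL) {
  set.seed(config$seed)
  if (is.null(model)) model <- rnnInit()
  theta <- packParams(model)
  mAdam <- numeric(length(theta)); vAdam <- numeric(length(theta))
  step <- 0L
  b1 <- config$adamBeta1; b2 <- config$adamBeta2; eps <- config$adamEps

  phases <- curriculum@phases
  nTotal <- sum(phases$nBlocks)
  blockMSE <- numeric(nTotal)
  typeLog <- vector("list", nTotal)
  checkpoints <- list()
  blk <- 0L
  for (p in seq_len(nrow(phases))) {
    for (bp in seq_len(phases$nBlocks[p])) {
      blk <- blk + 1L
      tensors <- makeBlock(phases$types[[p]], task)
      typeLog[[blk]] <- vapply(tensors, function(x) x@spec$trialType, "")
      batches <- split(tensors,
                       ceiling(seq_along(tensors) / config$batchSize))
      mseAcc <- 0
      for (batch in batches) {
        model <- unpackParams(theta, model)
        g <- batchGradient(model, batch, config$l2Lambda)
        if (!is.finite(g$loss) || g$loss > 1e3)
          stop("training diverged at block ", blk, " (loss = ", g$loss, ")")
        mseAcc <- mseAcc + g$mse * length(batch)
        gr <- g$grad
        nrm <- sqrt(sum(gr^2))
        if (nrm > config$clipNorm) gr <- gr * (config$clipNorm / nrm)
        step <- step + 1L
        mAdam <- b1 * mAdam + (1 - b1) * gr
        vAdam <- b2 * vAdam + (1 - b2) * gr^2
        mHat <- mAdam / (1 - b1^step)
        vHat <- vAdam / (1 - b2^step)
        theta <- theta - config$learningRate * mHat / (sqrt(vHat) + eps)
      }
      blockMSE[blk] <- mseAcc / length(tensors)
    }
    model <- unpackParams(theta, model)
    nm <- if (phases$phase[p] == "shaping") "shaping_end"
          else paste0(phases$phase[p], "_end")
    checkpoints[[nm]] <- model
  }
  checkpoints[["final"]] <- model
  new("TrainRecord", blockMSE = blockMSE, checkpoints = checkpoints,
      curriculum = curriculum, trialTypeLog = typeLog,
      seed = config$seed, config = unclass(config))
}

#' Mean full-task output MSE of a trained network
#'
#' Mean trial MSE (no regularisation term) over \code{nBlocks} fresh noisy
#' full-task blocks, with both input and unit noise on.
#'
#' @param model an \linkS4class{RNNModel}
#' @param task a \linkS4class{TaskConfig}
#' @param nBlocks number of evaluation blocks
#' @param unitNoise include private unit noise
#' @return scalar mean MSE
#' @export
evaluateMSE <- function(model, task = taskConfig(), nBlocks = 10L,
                        unitNoise = TRUE) {
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  tot <- 0
  for (b in seq_len(nBlocks)) {
    for (tr in makeBlock(fullTaskBlock, task)) {
      traj <- runTrial(model, tr, unitNoise = unitNoise)
      tot <- tot + mean((traj@output - tr@target)^2)
    }
  }
  tot / (nBlocks * length(fullTaskBlock))
}

#' @describeIn trainCurriculum per-block MSE trace of a record
#' @param record a TrainRecord
#' @export
blockMSE <- function(record) record@blockMSE

#' @describeIn trainCurriculum named list of checkpoints of a record
#' @export
checkpoints <- function(record) record@checkpoints

setMethod("show", "TrainRecord", function(object) {
  n <- length(object@blockMSE)
  cat("TrainRecord:", object@curriculum@name, "curriculum,", n, "blocks;",
      "final-10-block MSE", signif(mean(tail(object@blockMSE, 10)), 4),
      "; checkpoints:", paste(names(object@checkpoints), collapse = ", "),
      "\n")
})
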