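#' Initialize a leaky recurrent network
#'
#' The recurrent matrix is a random orthogonal matrix (QR of a Gaussian matrix
#' with the sign convention that makes the factorisation unique), input weights
#' are uniform on \eqn{[-1/\sqrt{N}, 1/\sqrt{N}]}, readout weights are a small
#' uniform on \eqn{[-0.1/\sqrt{N}, 0.1/\sqrt{N}]}, and both biases start at
#' zero. Uses R's global random stream.
#'
#' @param nUnits number of recurrent units (default 128)
#' @param gamma leak constant (default 0.2)
#' @param unitNoiseSigma sd of the private unit noise (default 0.3)
#' @return an \linkS4class{RNNModel}
#' @export
rnnInit <- function(nUnits = 128L, gamma = 0.2, unitNoiseSigma = 0.3) {
  nUnits <- as.integer(nUnits)
  if (nUnits < 1) stop("nUnits must be >= 1")
  qr_ <- qr(matrix(rnorm(nUnits^2), nUnits))
  q <- qr.Q(qr_)
  # fix the sign ambiguity so Q is uniquely determined by the Gaussian draw
  wRec <- q %*% diag(sign(diag(qr.R(qr_))), nUnits)
  bound <- 1 / sqrt(nUnits)
  new("RNNModel",
      wIn = matrix(runif(2L * nUnits, -bound, bound), nUnits, 2L),
      wRec = wRec, b = numeric(nUnits),
      wOut = runif(nUnits, -0.1 * bound, 0.1 * bound), bOut = 0,
      gamma = gamma, unitNoiseSigma = unitNoiseSigma, nUnits = nUnits,
      activation = "tanh")
}

#' One step of the leaky-unit update
#'
#' Returns exactly \eqn{(1-\gamma) h + \gamma \tanh(W_{in} x + W_{rec} h + b + \xi)}.
#' A pure function of its arguments; the reference implementation against
#' which the compiled simulation and all linearisations are checked.
#'
#' @param model an \linkS4class{RNNModel}
#' @param h state vector [N]
#' @param x input vector [2]
#' @param xi private-noise vector [N] (defaults to zero)
#' @return the next state vector
#' @export
rnnStep <- function(model, h, x, xi = numeric(model@nUnits)) {
  if (length(h) != model@nUnits || length(x) != 2L ||
      length(xi) != model@nUnits)
    stop("shape mismatch in rnnStep")
  g <- model@gamma
  (1 - g) * h + g * tanh(drop(model@wIn %*% x) + drop(model@wRec %*% h) +
                         model@b + xi)
}

#' Simulate one trial
#'
#' The hidden state is reset to zero at trial start. When \code{unitNoise} is
#' TRUE an independent N(0, \code{unitNoiseSigma}) draw is injected inside the
#' activation argument for every unit at every step.
#'
#' @param model an \linkS4class{RNNModel}
#' @param tensor a \linkS4class{TrialTensor}
#' @param unitNoise draw private unit noise
#' @return a \linkS4class{Trajectory}
#' @export
runTrial <- function(model, tensor, unitNoise = TRUE) {
  X <- tensor@inputs
  Xi <- if (unitNoise && model@unitNoiseSigma > 0)
    matrix(rnorm(nrow(X) * model@nUnits, 0, model@unitNoiseSigma), nrow(X))
  else matrix(0, 0, 0)
  res <- cpp_rnn_forward(model@wIn, model@wRec, model@b, model@wOut,
                         model@bOut, model@gamma, X, Xi,
                         numeric(model@nUnits))
  new("Trajectory", hidden = res$hidden, output = drop(res$output),
      inputsUsed = X,
      noiseFlags = c(inputNoise = tensor@noisy, unitNoise = unitNoise),
      spec = tensor@spec)
}

#' Autonomous free run with a clamped input
#'
#' Iterates the noise-free update from \code{h0} with the input held fixed;
#' used to validate fixed points and to detect limit cycles (the standard
#' validation run lasts twice the trial length).
#'
#' @param model an \linkS4class{RNNModel}
#' @param h0 initial state [N]
#' @param fixedInput clamped input vector [2]
#' @param nSteps number of steps (>= 1)
#' @return a \linkS4class{Trajectory} with a free-run descriptor in its spec
#' @export
freeRun <- function(model, h0, fixedInput = c(0, 0), nSteps) {
  if (nSteps < 1) stop("nSteps must be >= 1")
  H <- cpp_free_run(model@wIn, model@wRec, model@b, model@gamma,
                    h0, fixedInput, as.integer(nSteps))
  new("Trajectory", hidden = H, output = drop(H %*% model@wOut) + model@bOut,
      inputsUsed = matrix(fixedInput, nSteps, 2, byrow = TRUE),
      noiseFlags = c(inputNoise = FALSE, unitNoise = FALSE),
      spec = list(trialType = "free_run", fixedInput = fixedInput,
                  nSteps = nSteps))
}

# input vector for a dynamics "mode": timed cue clamped on or off, start cue 0
modeInput <- function(inputMode = c("cue_off", "cue_on")) {
  inputMode <- match.arg(inputMode)
  c(0, if (inputMode == "cue_on") 1 else 0)
}

#' Persist / restore model checkpoints
#'
#' Checkpoints are written with \code{saveRDS} so they restore bit-exactly,
#' alongside free-form metadata (curriculum name, block index, seed, ...).
#'
#' @param model an \linkS4class{RNNModel}
#' @param path file path
#' @param ... metadata fields stored with the parameters
#' @export
saveCheckpoint <- function(model, path, ...) {
  saveRDS(list(model = model, meta = list(...)), path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' @describeIn runTrial hidden-state matrix of a trajectory
#' @param traj a Trajectory
#' @export
hiddenStates <- function(traj) traj@hidden

#' @describeIn runTrial readout time series of a trajectory
#' @export
readoutSeries <- function(traj) traj@output

setMethod("show", "RNNModel", function(object) {
  cat("Leaky RNN:", object@nUnits, "units, gamma =", object@gamma,
      ", unit noise sd =", object@unitNoiseSigma, "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@hidden), "bins x", ncol(object@hidden),
      "units; trial type", object@spec$trialType, "\n")
})

setMethod("show", "TaskConfig", function(object) {
  cat("tDNMS task:", object@nBins, "bins of", object@dt, "s;",
      "cues", object@shortDur, "/", object@longDur, "s, ISI", object@isi,
      "s, response window", object@responseWindow, "s\n")
})

setMethod("show", "Curriculum", function(object) {
  cat("Curriculum", object@name, "-", sum(object@phases$nBlocks), "blocks:\n")
  for (i in seq_len(nrow(object@phases)))
    cat("  ", object@phases$phase[i], ": ", object@phases$nBlocks[i],
        " blocks of {", paste(object@phases$types[[i]], collapse = ", "),
        "}\n", sep = "")
})
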