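#' Build a time-decoding dataset from a network or a rate tensor
#'
#' For a network source, simulates \code{nBlocks} noisy full-task blocks
#' (the default 15 blocks give 60 trials: 30 SS, 15 SL, 15 LS) and stacks the
#' hidden states into a [trials x bins x units] tensor. For a
#' \linkS4class{RateMatrix} source (the spike pipeline) the stored tensor is
#' used as-is. Each bin is labelled with its elapsed trial time rounded to
#' the nearest second, computed at the bin centre.
#'
#' @param source an \linkS4class{RNNModel} or a \linkS4class{RateMatrix}
#' @param task a \linkS4class{TaskConfig} (network source only)
#' @param nBlocks number of simulated blocks (network source only)
#' @param unitNoise include private unit noise (network source only)
#' @return a \linkS4class{DecodingDataset}
#' @export
buildDecodingDataset <- function(source, task = taskConfig(), nBlocks = 15L,
                                 unitNoise = TRUE) {
  if (is(source, "RateMatrix")) {
    bins <- dim(source@rates)[2]
    tmid <- (seq_len(bins) - 0.5) * source@binWidth
    return(new("DecodingDataset", activity = source@rates,
               timeLabels = round(tmid), trialTypes = source@trialTypes))
  }
  trials <- list(); types <- character(0)
  for (b in seq_len(nBlocks)) {
    for (tr in makeBlock(fullTaskBlock, task)) {
      trials[[length(trials) + 1L]] <-
        hiddenStates(runTrial(source, tr, unitNoise = unitNoise))
      types <- c(types, tr@spec$trialType)
    }
  }
  act <- array(0, c(length(trials), task@nBins, source@nUnits))
  for (i in seq_along(trials)) act[i, , ] <- trials[[i]]
  tmid <- (seq_len(task@nBins) - 0.5) * task@dt
  new("DecodingDataset", activity = act, timeLabels = round(tmid),
      trialTypes = types)
}

# ---- regularised linear discriminant classifier --------------------------
# Standard LDA with the pooled within-class covariance shrunk toward its
# diagonal: Sigma_r = (1 - shrinkage) * Sigma + shrinkage * diag(Sigma).
# Keeps the discriminant well-posed when bins outnumber... when features
# approach the sample count or units are strongly correlated.

ldaFit <- function(X, labels, shrinkage = 0.1) {
  classes <- sort(unique(labels))
  mu <- t(vapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                 numeric(ncol(X))))
  Xc <- X - mu[match(labels, classes), , drop = FALSE]
  Sigma <- crossprod(Xc) / (nrow(X) - length(classes))
  Sigma <- (1 - shrinkage) * Sigma + shrinkage * diag(diag(Sigma), ncol(X))
  diag(Sigma) <- diag(Sigma) + 1e-10          # guard exact zeros
  W <- solve(Sigma, t(mu))                    # features x classes
  prior <- as.numeric(table(factor(labels, classes))) / length(labels)
  const <- -0.5 * colSums(t(mu) * W) + log(prior)
  list(classes = classes, W = W, const = const, shrinkage = shrinkage)
}

ldaPredict <- function(fit, X) {
  scores <- X %*% fit$W + rep(fit$const, each = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Within- and across-context decoding of elapsed trial time
#'
#' Splits trials into \code{nFolds} cross-validation folds (by trial,
#' balanced over trial types). In every fold four linear-discriminant time
#' classifiers are fitted on the training trials — one per trial type and one
#' on all types — and each is evaluated on every held-out trial. Errors where
#' the training type matches the tested trial's type are pooled into the
#' within-context error; mismatched pairs give the across-context error; the
#' all-types decoder is reported separately. All errors are mean absolute
#' errors in seconds on the 1 s label grid.
#'
#' @param data a \linkS4class{DecodingDataset}
#' @param nFolds number of folds (>= 2)
#' @param shrinkage covariance shrinkage toward the diagonal, in [0, 1]
#' @return a \linkS4class{DecodingResult}
#' @export
decodeWithinAcross <- function(data, nFolds = 10L, shrinkage = 0.1) {
  if (nFolds < 2) stop("need at least 2 folds")
  nTrials <- dim(data@activity)[1]
  bins <- dim(data@activity)[2]
  types <- data@trialTypes
  typeSet <- sort(unique(types))
  # balanced fold assignment: shuffle within type, deal round-robin
  fold <- integer(nTrials)
  for (tt in typeSet) {
    idx <- sample(which(types == tt))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  labGrid <- sort(unique(data@timeLabels))
  decoders <- c(typeSet, "all")
  confusion <- array(0L, c(length(decoders), length(typeSet),
                           length(labGrid), length(labGrid)),
                     dimnames = list(decoders, typeSet, labGrid, labGrid))
  errSum <- matrix(0, length(decoders), length(typeSet),
                   dimnames = list(decoders, typeSet))
  errN <- matrix(0L, length(decoders), length(typeSet),
                 dimnames = list(decoders, typeSet))
  flat <- function(trialIdx) {
    X <- apply(data@activity[trialIdx, , , drop = FALSE], 3L, identity)
    dim(X) <- c(length(trialIdx) * bins, dim(data@activity)[3])
    X
  }
  labs <- function(trialIdx) rep(data@timeLabels, each = length(trialIdx))
  # note: flat() stacks trials fastest within each bin, matching labs()
  for (f in seq_len(nFolds)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    if (!length(testIdx)) next
    fits <- list()
    for (dec in decoders) {
      tri <- if (dec == "all") trainIdx else trainIdx[types[trainIdx] == dec]
      fits[[dec]] <- if (length(tri) >= 2) ldaFit(flat(tri), labs(tri), shrinkage)
    }
    for (tt in typeSet) {
      tei <- testIdx[types[testIdx] == tt]
      if (!length(tei)) next                  # cell missing in this fold
      Xte <- flat(tei); yte <- labs(tei)
      for (dec in decoders) {
        if (is.null(fits[[dec]])) next
        pred <- ldaPredict(fits[[dec]], Xte)
        errSum[dec, tt] <- errSum[dec, tt] + sum(abs(pred - yte))
        errN[dec, tt] <- errN[dec, tt] + length(yte)
        tb <- table(factor(yte, labGrid), factor(pred, labGrid))
        confusion[dec, tt, , ] <- confusion[dec, tt, , ] + tb
      }
    }
  }
  err <- errSum / errN
  typeDec <- decoders[decoders != "all"]
  within <- mean(diag(err[typeDec, typeDec, drop = FALSE]))
  acrossMask <- outer(typeDec, typeDec, "!=")
  across <- mean(err[typeDec, typeDec][acrossMask])
  perCell <- data.frame(decoder = rep(decoders, times = length(typeSet)),
                        testType = rep(typeSet, each = length(decoders)),
                        mae = as.numeric(err),
                        nBins = as.integer(errN))
  new("DecodingResult", withinError = within, acrossError = across,
      allTrialsError = mean(err["all", ]), perCell = perCell,
      confusion = confusion)
}

#' @describeIn decodeWithinAcross within-context mean absolute error (s)
#' @param x a DecodingResult
#' @export
withinError <- function(x) x@withinError

#' @describeIn decodeWithinAcross across-context mean absolute error (s)
#' @export
acrossError <- function(x) x@acrossError

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult: within ", round(object@withinError, 3),
      " s, across ", round(object@acrossError, 3),
      " s, all-trials ", round(object@allTrialsError, 3), " s\n", sep = "")
})
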