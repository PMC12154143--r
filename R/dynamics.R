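#' Trajectory tangling
#'
#' Tangling at time t is
#' \deqn{Q(t) = \max_{t'} \frac{\|\dot x_t - \dot x_{t'}\|^2}{\|x_t - x_{t'}\|^2 + \epsilon}}
#' with derivatives taken as backward differences
#' \eqn{\dot x_t = (x_t - x_{t-\Delta t})/\Delta t} and
#' \eqn{\epsilon} set to \code{epsCoef} times the average squared magnitude of
#' the states. High tangling means nearby states carry very different flows —
#' the signature of a re-used region of state space. The maximum runs over
#' every other time point of the supplied state set, so rows from several
#' trials can be stacked to compute tangling across a whole session
#' (derivatives are taken within each trial when \code{trialIndex} is given,
#' never across trial boundaries).
#'
#' @param states numeric matrix [T x D] of states (rows ordered in time)
#' @param dt time step between consecutive rows (s)
#' @param epsCoef epsilon as a fraction of the mean squared state magnitude
#' @param trialIndex optional integer vector [T] marking which trial each row
#'   belongs to; differences across a trial boundary are dropped
#' @param chunkSize rows per block of the pairwise computation (memory knob,
#'   does not affect results)
#' @return list of class \code{"TanglingProfile"}: \code{q} (one value per
#'   differentiable time point), \code{eps}, \code{dt}, \code{meanQ}
#' @export
tangling <- function(states, dt = 0.1, epsCoef = 0.1, trialIndex = NULL,
                     chunkSize = 1000L) {
  if (nrow(states) < 3) stop("need at least 3 time points")
  if (dt <= 0) stop("dt must be positive")
  eps <- epsCoef * mean(rowSums(states^2))
  if (eps == 0) stop("all-zero states: epsilon would vanish")
  keep <- if (is.null(trialIndex)) rep(TRUE, nrow(states) - 1L)
          else diff(trialIndex) == 0
  V <- diff(states) / dt
  V <- V[keep, , drop = FALSE]
  X <- states[-1L, , drop = FALSE][keep, , drop = FALSE]
  n <- nrow(V)
  rx <- rowSums(X^2); rv <- rowSums(V^2)
  q <- numeric(n)
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    Dx <- outer(rx[idx], rx, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    Dv <- outer(rv[idx], rv, "+") - 2 * tcrossprod(V[idx, , drop = FALSE], V)
    R <- pmax(Dv, 0) / (pmax(Dx, 0) + eps)
    R[cbind(seq_along(idx), idx)] <- -Inf   # exclude t' = t
    q[idx] <- apply(R, 1L, max)
  }
  structure(list(q = q, dt = dt, eps = eps, epsCoef = epsCoef,
                 meanQ = mean(q), n = n),
            class = "TanglingProfile")
}

# ---- fixed points --------------------------------------------------------

# Jacobian of the one-step update at state h under clamped input x:
# J = (1-g) I + g diag(1 - tanh^2(a)) wRec,  a = wIn x + wRec h + b
updateJacobian <- function(model, h, x) {
  g <- model@gamma
  a <- drop(model@wIn %*% x) + drop(model@wRec %*% h) + model@b
  (1 - g) * diag(model@nUnits) + g * ((1 - tanh(a)^2) * model@wRec)
}

#' Eigenvalues of the linearised update map at a point
#'
#' Linearises the one-step map around \code{hStar} with the input clamped
#' (input perturbations are not propagated) and returns the complex spectrum
#' of the Jacobian. In discrete time a point attracts when every eigenvalue
#' has modulus below 1.
#'
#' @param model an \linkS4class{RNNModel}
#' @param hStar state vector to linearise around
#' @param x clamped input vector [2]
#' @return complex eigenvalues, decreasing modulus
#' @export
linearizeAt <- function(model, hStar, x = c(0, 0)) {
  ev <- eigen(updateJacobian(model, hStar, x), only.values = TRUE)$values
  ev[order(-Mod(ev))]
}

#' Sample fixed-point candidates from task trajectories
#'
#' Takes every \code{stride}-th state of the noise-free trajectories of the
#' three standard trial types, plus \code{nRandom} random convex combinations
#' of pairs of those states.
#'
#' @param model an \linkS4class{RNNModel}
#' @param task a \linkS4class{TaskConfig}
#' @param stride keep every stride-th bin
#' @param nRandom number of convex-combination candidates
#' @return matrix [nCandidates x N]
#' @export
sampleCandidates <- function(model, task = taskConfig(), stride = 5L,
                             nRandom = 50L) {
  pts <- do.call(rbind, lapply(c("SS", "SL", "LS"), function(tt) {
    H <- hiddenStates(runTrial(model, makeTrial(tt, task), unitNoise = FALSE))
    H[seq(1L, nrow(H), by = stride), , drop = FALSE]
  }))
  if (nRandom > 0) {
    i <- sample(nrow(pts), nRandom, replace = TRUE)
    j <- sample(nrow(pts), nRandom, replace = TRUE)
    lam <- runif(nRandom)
    pts <- rbind(pts, lam * pts[i, , drop = FALSE] +
                   (1 - lam) * pts[j, , drop = FALSE])
  }
  pts
}

#' Locate fixed and slow points of the clamped dynamics
#'
#' Minimises the squared speed \eqn{q(h) = \tfrac12\|F(h)\|^2}, with
#' \eqn{F(h)} the one-step displacement of the noise-free update under the
#' clamped input, by adaptive-moment gradient descent run jointly over all
#' candidates, followed by a Newton polish of near-converged candidates.
#' Points reaching \code{q < qTol} are accepted, near-duplicates within
#' \code{mergeTol} are merged (keeping the slowest), and each accepted point
#' is classified by the eigenvalue moduli of the linearised map and validated
#' by a 200-step free run (movement below \code{validTol}). Candidates that
#' fail the q threshold or the free-run validation are reported in the
#' \code{unconverged} slot with their final q — never silently dropped.
#'
#' @param model an \linkS4class{RNNModel}
#' @param candidates matrix [C x N] of starting states (e.g. from
#'   \code{sampleCandidates})
#' @param inputMode \code{"cue_off"} (input all-zero) or \code{"cue_on"}
#'   (timed channel clamped to 1; the start channel is 0 in both modes)
#' @param qTol acceptance threshold on q
#' @param mergeTol Euclidean duplicate-merging distance
#' @param maxIter Adam iterations
#' @param lr Adam step size
#' @param validTol maximum 200-step free-run movement of an accepted point
#' @return a \linkS4class{FixedPointSet}
#' @export
findFixedPoints <- function(model, candidates, inputMode = c("cue_off", "cue_on"),
                            qTol = 1e-6, mergeTol = 1e-2, maxIter = 1500L,
                            lr = 0.02, validTol = 1e-3) {
  inputMode <- match.arg(inputMode)
  x <- modeInput(inputMode)
  g <- model@gamma
  drive <- drop(model@wIn %*% x) + model@b
  W <- model@wRec; Wt <- t(W)
  H <- t(candidates)                      # N x C
  C <- ncol(H)

  Fof <- function(H) g * (tanh(W %*% H + drive) - H)
  m <- H * 0; v <- H * 0
  for (it in seq_len(maxIter)) {
    S <- tanh(W %*% H + drive)
    Fm <- g * (S - H)
    G <- g * (Wt %*% ((1 - S^2) * Fm) - Fm)   # gradient of q per column
    m <- 0.9 * m + 0.1 * G
    v <- 0.999 * v + 0.001 * G^2
    H <- H - lr * (m / (1 - 0.9^it)) / (sqrt(v / (1 - 0.999^it)) + 1e-8)
  }
  # Newton polish of candidates already near a root of F
  qv <- 0.5 * colSums(Fof(H)^2)
  for (ci in which(qv < 1e-3)) {
    h <- H[, ci]
    for (itn in 1:30) {
      Fh <- drop(Fof(matrix(h)))
      if (0.5 * sum(Fh^2) < 1e-24) break
      J <- updateJacobian(model, h, x)
      dh <- tryCatch(solve(J - diag(model@nUnits), -Fh),
                     error = function(e) NULL)
      if (is.null(dh)) break
      if (sqrt(sum(dh^2)) > 1) dh <- dh / sqrt(sum(dh^2))  # damp huge steps
      h <- h + dh
    }
    H[, ci] <- h
  }
  qv <- 0.5 * colSums(Fof(H)^2)

  ord <- order(qv)
  keep <- integer(0)
  for (ci in ord) {
    if (qv[ci] >= qTol) next
    if (length(keep) == 0 ||
        min(sqrt(colSums((H[, keep, drop = FALSE] - H[, ci])^2))) > mergeTol)
      keep <- c(keep, ci)
  }

  loc <- list(); spd <- numeric(0); stab <- character(0); eig <- list()
  slow <- logical(0); rout <- numeric(0)
  unconv <- data.frame(q = numeric(0), movement = numeric(0),
                       reason = character(0))
  for (ci in ord) {
    isKept <- ci %in% keep
    if (!isKept && qv[ci] < qTol) next    # merged duplicate
    h <- H[, ci]
    if (qv[ci] >= qTol) {
      unconv <- rbind(unconv, data.frame(q = qv[ci], movement = NA_real_,
                                         reason = "q above threshold"))
      next
    }
    run <- freeRun(model, h, x, 200L)
    move <- max(sqrt(rowSums(sweep(run@hidden, 2L, h)^2)))
    if (move >= validTol) {
      unconv <- rbind(unconv, data.frame(q = qv[ci], movement = move,
                                         reason = "failed free-run validation"))
      next
    }
    ev <- linearizeAt(model, h, x)
    mods <- Mod(ev)
    tol <- 1e-4
    cls <- if (any(mods > 1 + tol) && any(mods < 1 - tol)) "saddle"
           else if (all(mods < 1 - tol)) "stable"
           else if (all(mods > 1 + tol)) "unstable"
           else "marginal"
    loc[[length(loc) + 1L]] <- h
    spd <- c(spd, qv[ci]); stab <- c(stab, cls)
    eig[[length(eig) + 1L]] <- ev
    slow <- c(slow, qv[ci] > 1e-10)
    rout <- c(rout, sum(model@wOut * h) + model@bOut)
  }
  new("FixedPointSet",
      locations = if (length(loc)) do.call(rbind, loc)
                  else matrix(0, 0, model@nUnits),
      speed = spd, stability = stab, eigenvalues = eig, isSlowPoint = slow,
      inputMode = inputMode, readout = rout, unconverged = unconv)
}

#' @describeIn findFixedPoints number of accepted points
#' @param x a FixedPointSet
#' @export
nPoints <- function(x) nrow(x@locations)

setMethod("show", "FixedPointSet", function(object) {
  cat("FixedPointSet (", object@inputMode, "): ", nPoints(object),
      " accepted point(s)", sep = "")
  if (nPoints(object))
    cat(" [", paste(object@stability, collapse = ", "), "]", sep = "")
  cat("; ", nrow(object@unconverged), " unconverged candidate(s)\n", sep = "")
})

# ---- limit cycles --------------------------------------------------------

#' Detect a limit cycle by autonomous free run
#'
#' Runs the noise-free network from \code{h0} with the input clamped,
#' discards a transient prefix, and searches for the smallest lag tau at
#' which the whole window recurs: \eqn{\max_t \|h(t+\tau) - h(t)\| <} tol,
#' with the tolerance scaled to the typical state norm of the window
#' (\code{relTol} times the mean norm). A stationary endpoint (the window
#' never leaves the final state) means the run settled onto a fixed point and
#' returns NULL, as does failure to find any recurring lag.
#'
#' The default run length is twice the standard 200-bin trial. Trajectories
#' spiral onto their attracting orbit slowly, so a longer \code{nSteps}
#' (2000 is used by the cohort analyses) tightens the achievable closure.
#'
#' @param model an \linkS4class{RNNModel}
#' @param h0 starting state (e.g. the end state of a task trial)
#' @param inputMode clamped-input mode
#' @param nSteps free-run length in bins
#' @param transientFrac fraction of the run discarded as transient
#' @param relTol closure tolerance as a fraction of the mean state norm
#' @param dt seconds per bin (to express the period in seconds)
#' @return a \linkS4class{LimitCycle}, or NULL when the run is stationary or
#'   never recurs at the tolerance
#' @export
detectLimitCycle <- function(model, h0, inputMode = c("cue_off", "cue_on"),
                             nSteps = 400L, transientFrac = 0.25,
                             relTol = 0.01, dt = 0.1) {
  inputMode <- match.arg(inputMode)
  if (nSteps < 4) stop("free run too short")
  H <- freeRun(model, h0, modeInput(inputMode), nSteps)@hidden
  W <- H[(floor(nSteps * transientFrac) + 1L):nSteps, , drop = FALSE]
  nW <- nrow(W)
  typNorm <- mean(sqrt(rowSums(W^2)))
  if (typNorm < 1e-12) return(NULL)               # collapsed to the origin
  tol <- relTol * typNorm
  if (max(sqrt(rowSums(sweep(W, 2L, W[nW, ])^2))) < tol) return(NULL)
  r <- rowSums(W^2)
  D2 <- outer(r, r, "+") - 2 * tcrossprod(W)      # pairwise squared distances
  for (tau in 2:floor(nW / 2)) {
    i <- seq_len(nW - tau)
    dmax <- sqrt(max(pmax(D2[cbind(i, i + tau)], 0)))
    if (dmax < tol) {
      orbit <- W[(nW - tau + 1L):nW, , drop = FALSE]
      # a real orbit must have amplitude well above the closure tolerance,
      # otherwise this is a contracting spiral caught mid-decay
      ro <- rowSums(orbit^2)
      diam <- sqrt(max(pmax(outer(ro, ro, "+") - 2 * tcrossprod(orbit), 0)))
      if (diam <= 5 * tol) return(NULL)
      return(new("LimitCycle", orbit = orbit, period = tau * dt,
                 inputMode = inputMode, recurrenceError = dmax,
                 tolerance = tol))
    }
  }
  NULL
}

setMethod("show", "LimitCycle", function(object) {
  cat("LimitCycle (", object@inputMode, "): period ", object@period,
      " s over ", nrow(object@orbit), " bins; closure ",
      signif(object@recurrenceError, 3), " (tol ",
      signif(object@tolerance, 3), ")\n", sep = "")
})

# ---- PCA geometry --------------------------------------------------------

#' PCA of pooled hidden states
#'
#' With \code{average = TRUE} the hidden states are averaged within trial type
#' and the per-type averages stacked over time before PCA — the right view for
#' displaying the task-locked state-space geometry and for cross-projection.
#' With \code{average = FALSE} every supplied trajectory's states are pooled
#' unaveraged; this is the view used when quantifying dimensionality of noisy
#' task activity, where single-trial dispersion is the signal of interest
#' (averaging would hide exactly the noise-driven excursions that make an
#' unshaped network high-dimensional).
#'
#' @param trajectories list of \linkS4class{Trajectory} (several trials per
#'   type; single trials are used as-is)
#' @param k number of components to retain in the loadings
#' @param average average within trial type before pooling
#' @return a \linkS4class{PCAResult}
#' @export
pcaGeometry <- function(trajectories, k = 3L, average = TRUE) {
  types <- vapply(trajectories, function(tr) tr@spec$trialType, "")
  X <- if (average) {
    do.call(rbind, lapply(unique(types), function(tt) {
      hs <- lapply(trajectories[types == tt], hiddenStates)
      Reduce(`+`, hs) / length(hs)
    }))
  } else do.call(rbind, lapply(trajectories, hiddenStates))
  N <- ncol(X)
  if (k > N) stop("k exceeds the number of units")
  if (nrow(X) < k) stop("need at least k pooled bins")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAResult", loadings = pc$rotation[, seq_len(k), drop = FALSE],
      center = pc$center, varExplained = ve, k = as.integer(k),
      source = paste(unique(types), collapse = "+"))
}

#' @describeIn pcaGeometry variance fraction captured by the first m components
#' @param pca a PCAResult
#' @param m number of leading components
#' @export
varianceCaptured <- function(pca, m = 3L) sum(pca@varExplained[seq_len(m)])

#' Project trajectories into a (possibly foreign) PCA space
#'
#' Centres the source hidden states by the target PCA's mean and projects
#' them onto its loadings. Used to project the states of an earlier training
#' checkpoint into the state space of the fully trained network.
#'
#' @param source list of \linkS4class{Trajectory}, or one Trajectory, or a
#'   bare state matrix; the unit dimension must match the target loadings
#' @param targetPca a \linkS4class{PCAResult}
#' @return list of score matrices [T x k] (or a single matrix when
#'   \code{source} is not a list)
#' @export
crossProject <- function(source, targetPca) {
  projOne <- function(H) {
    if (ncol(H) != nrow(targetPca@loadings))
      stop("unit dimension mismatch with target loadings")
    sweep(H, 2L, targetPca@center) %*% targetPca@loadings
  }
  if (is(source, "Trajectory")) return(projOne(hiddenStates(source)))
  if (is.matrix(source)) return(projOne(source))
  lapply(source, function(tr) projOne(hiddenStates(tr)))
}

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult (", object@source, "): first ", object@k, " PCs explain ",
      round(100 * varianceCaptured(object, object@k), 1), "% of variance\n",
      sep = "")
})

# ---- flow fields ---------------------------------------------------------

#' One-step flow field on a PCA plane
#'
#' Embeds a lattice of plane coordinates into full state space through the
#' inverse PCA map (off-plane coordinates held at the projection of a
#' reference state, by default the PCA mean, i.e. zero), advances each point
#' one noise-free step under the clamped input, and projects the displacement
#' back onto the plane.
#'
#' @param model an \linkS4class{RNNModel}
#' @param pca a \linkS4class{PCAResult}
#' @param plane indices of the two plane axes (within the retained PCs)
#' @param gridX,gridY lattice coordinates along the two axes
#' @param inputMode clamped-input mode
#' @param reference state whose off-plane projection anchors the plane
#' @return data.frame with columns x, y, dx, dy
#' @export
flowField <- function(model, pca, plane = c(1L, 2L),
                      gridX = seq(-8, 8, length.out = 13),
                      gridY = seq(-8, 8, length.out = 13),
                      inputMode = c("cue_off", "cue_on"),
                      reference = NULL) {
  inputMode <- match.arg(inputMode)
  if (any(plane > pca@k)) stop("plane axes must be retained components")
  x <- modeInput(inputMode)
  U <- pca@loadings
  zRef <- if (is.null(reference)) numeric(pca@k)
          else drop(crossProject(matrix(reference, 1L), pca))
  grid <- expand.grid(x = gridX, y = gridY)
  out <- t(apply(grid, 1L, function(gz) {
    z <- zRef
    z[plane] <- c(gz[["x"]], gz[["y"]])
    h <- pca@center + drop(U %*% z)
    disp <- rnnStep(model, h, x) - h
    drop(crossprod(U[, plane, drop = FALSE], disp))
  }))
  data.frame(x = grid$x, y = grid$y, dx = out[, 1L], dy = out[, 2L])
}

# ---- motif census --------------------------------------------------------

#' Dynamical-motif census of a trained network
#'
#' For each clamped-input mode, locates fixed/slow points from task-derived
#' candidates and probes for a limit cycle starting from the end state of a
#' noise-free SL trial. Returns the full objects plus a one-row summary
#' (counts of stable points per mode, cycle presence and period).
#'
#' @param model an \linkS4class{RNNModel}
#' @param task a \linkS4class{TaskConfig}
#' @param freeRunSteps free-run length for cycle detection (bins)
#' @param ... passed to \code{findFixedPoints}
#' @return list with \code{fixedPoints}, \code{cycles}, \code{summary}
#' @export
dynamicalMotifs <- function(model, task = taskConfig(), freeRunSteps = 2000L,
                            ...) {
  cand <- sampleCandidates(model, task)
  h0 <- tail(hiddenStates(runTrial(model, makeTrial("SL", task),
                                   unitNoise = FALSE)), 1L)[1L, ]
  fps <- list(); cyc <- list()
  for (mode in c("cue_off", "cue_on")) {
    fps[[mode]] <- findFixedPoints(model, cand, mode, ...)
    cyc[mode] <- list(detectLimitCycle(model, h0, mode,
                                       nSteps = freeRunSteps, dt = task@dt))
  }
  summary <- data.frame(
    mode = c("cue_off", "cue_on"),
    nStable = vapply(fps, function(f) sum(f@stability == "stable"), 0L),
    nOther = vapply(fps, function(f) sum(f@stability != "stable"), 0L),
    cycle = vapply(cyc, Negate(is.null), NA),
    period = vapply(cyc, function(cc) if (is.null(cc)) NA_real_ else cc@period,
                    0))
  list(fixedPoints = fps, cycles = cyc, summary = summary)
}
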