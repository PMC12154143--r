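#' Define a cohort experiment plan
#'
#' A plan names the curricula to train, the seeds of each cohort, the scale
#' (\code{"reduced"}: 100 shaping + 250 full-task blocks; \code{"full"}:
#' 300 + 700), and which analyses to run on every trained network.
#'
#' @param name plan label
#' @param cohorts named list: curriculum name -> integer seeds (unique within
#'   a cohort)
#' @param scale "reduced" or "full"
#' @param analyses subset of c("mse", "decoding", "tangling", "pca",
#'   "motifs", "sweep", "probes")
#' @param task a \linkS4class{TaskConfig}
#' @param blocks optional named vector \code{c(total = , shaping = )}
#'   overriding the scale's block counts (smoke runs)
#' @return list of class \code{"ExperimentPlan"}
#' @export
experimentPlan <- function(name, cohorts,
                           scale = c("reduced", "full"),
                           analyses = c("mse", "decoding", "tangling", "pca",
                                        "motifs", "sweep"),
                           task = taskConfig(), blocks = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.list(cohorts), length(names(cohorts)) == length(cohorts))
  for (seeds in cohorts)
    if (anyDuplicated(seeds)) stop("seeds must be unique within a cohort")
  if (is.null(blocks))
    blocks <- if (scale == "reduced") c(total = 350L, shaping = 100L)
              else c(total = 1000L, shaping = 300L)
  structure(list(name = name, cohorts = cohorts, scale = scale,
                 blocks = blocks, analyses = analyses, task = task),
            class = "ExperimentPlan")
}

# per-network analysis battery; returns a named list of scalar metrics plus
# the variance-explained curve
analyseNetwork <- function(model, task, analyses, seed) {
  out <- list()
  if ("mse" %in% analyses) {
    set.seed(seed + 7L)
    out$mse <- evaluateMSE(model, task, nBlocks = 5L)
  }
  if (any(c("tangling", "pca", "decoding") %in% analyses)) {
    set.seed(seed + 11L)
    ds <- buildDecodingDataset(model, task, nBlocks = 15L)
  }
  if ("decoding" %in% analyses) {
    set.seed(seed + 13L)
    dec <- decodeWithinAcross(ds)
    out$withinError <- withinError(dec)
    out$acrossError <- acrossError(dec)
  }
  if ("tangling" %in% analyses) {
    nTr <- min(20L, dim(ds@activity)[1])
    bins <- dim(ds@activity)[2]
    X <- do.call(rbind, lapply(seq_len(nTr), function(i) ds@activity[i, , ]))
    out$meanTangling <- tangling(X, dt = task@dt,
                                 trialIndex = rep(seq_len(nTr),
                                                  each = bins))$meanQ
  }
  if ("pca" %in% analyses) {
    # dimensionality of noisy single-trial task activity (pooled, unaveraged)
    X <- do.call(rbind, lapply(seq_len(dim(ds@activity)[1]),
                               function(i) ds@activity[i, , ]))
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    out$varFirst3 <- sum(ve[1:3])
    attr(out, "varCurve") <- cumsum(ve[1:10])
  }
  if ("motifs" %in% analyses) {
    set.seed(seed + 17L)
    mot <- dynamicalMotifs(model, task)
    out$cycleCueOff <- mot$summary$cycle[mot$summary$mode == "cue_off"]
    out$nStableCueOn <- mot$summary$nStable[mot$summary$mode == "cue_on"]
  }
  if ("sweep" %in% analyses)
    out$crossingDuration <-
      cueDurationSweep(model, "second", task = task)$crossingDuration
  if ("probes" %in% analyses) {
    set.seed(seed + 19L)
    pr <- probeEvaluation(model, nBlocks = 5L, task = task)
    for (tt in names(pr)) out[[paste0("respProb_", tt)]] <- pr[[tt]]
  }
  out
}

#' Train and compare cohorts of networks
#'
#' Trains every (curriculum, seed) pair of the plan, runs the selected
#' analyses on each final network, and computes between-cohort comparison
#' statistics: two-sided Welch t-tests per metric for every cohort pair, a
#' one-way analysis with Tukey honest-significant-difference correction when
#' more than two cohorts are present, and (when PCA is among the analyses) a
#' two-way mixed-design ANOVA of the cumulative variance-explained curves
#' (cohort x number of PCs, networks as the repeated-measures unit). Failed
#' seeds are flagged and statistics computed on completers. Re-running an
#' identical plan reproduces every table exactly.
#'
#' @param plan an \code{experimentPlan()}
#' @return list with \code{metrics} (per-network data.frame),
#'   \code{varianceCurves}, \code{tTests}, \code{tukey}, \code{mixedAnova},
#'   \code{failures}, \code{records} (named list of TrainRecord)
#' @export
runCohortComparison <- function(plan) {
  task <- plan$task
  rows <- list(); curves <- list(); records <- list(); failures <- list()
  for (cohortName in names(plan$cohorts)) {
    for (seed in plan$cohorts[[cohortName]]) {
      id <- paste0(cohortName, "_", seed)
      res <- tryCatch({
        shp <- if (cohortName == "NS") 0L else plan$blocks[["shaping"]]
        rec <- trainCurriculum(
          curriculum(cohortName, plan$blocks[["total"]],
                     plan$blocks[["shaping"]]),
          task,
          trainConfig(totalBlocks = plan$blocks[["total"]],
                      shapingBlocks = shp, seed = seed))
        met <- analyseNetwork(checkpoints(rec)$final, task, plan$analyses,
                              seed)
        list(rec = rec, met = met)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[id]] <- conditionMessage(res)
        next
      }
      records[[id]] <- res$rec
      row <- data.frame(cohort = cohortName, seed = seed,
                        finalMSE = mean(tail(blockMSE(res$rec), 10L)))
      for (nm in names(res$met)) row[[nm]] <- res$met[[nm]]
      rows[[id]] <- row
      if (!is.null(attr(res$met, "varCurve")))
        curves[[id]] <- data.frame(cohort = cohortName, seed = seed,
                                   pc = 1:10,
                                   cumVar = attr(res$met, "varCurve"))
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  numCols <- setdiff(names(metrics)[vapply(metrics, is.numeric, NA)], "seed")
  cohortsPresent <- unique(metrics$cohort)
  tTests <- list(); tukey <- list()
  if (length(cohortsPresent) >= 2) {
    prs <- utils::combn(cohortsPresent, 2L, simplify = FALSE)
    for (mcol in numCols) {
      for (pr in prs) {
        a <- metrics[[mcol]][metrics$cohort == pr[1]]
        b <- metrics[[mcol]][metrics$cohort == pr[2]]
        if (sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2 &&
            (sd(a, na.rm = TRUE) > 0 || sd(b, na.rm = TRUE) > 0)) {
          tt <- t.test(a, b)
          tTests[[paste(mcol, pr[1], pr[2], sep = ".")]] <-
            data.frame(metric = mcol, cohortA = pr[1], cohortB = pr[2],
                       meanA = mean(a, na.rm = TRUE),
                       meanB = mean(b, na.rm = TRUE),
                       t = unname(tt$statistic), p = tt$p.value)
        }
      }
      if (length(cohortsPresent) > 2) {
        df <- data.frame(y = metrics[[mcol]],
                         cohort = factor(metrics$cohort))
        if (all(tapply(df$y, df$cohort, function(v) sum(is.finite(v))) >= 2))
          tukey[[mcol]] <- TukeyHSD(aov(y ~ cohort, df))$cohort
      }
    }
  }
  mixedAnova <- NULL
  vc <- do.call(rbind, curves)
  if (!is.null(vc) && length(unique(vc$cohort)) >= 2) {
    vc$network <- factor(paste0(vc$cohort, "_", vc$seed))
    vc$pcF <- factor(vc$pc)
    mixedAnova <- summary(aov(cumVar ~ cohort * pcF + Error(network),
                              data = vc))
  }
  list(metrics = metrics, varianceCurves = vc,
       tTests = if (length(tTests)) do.call(rbind, tTests) else NULL,
       tukey = tukey, mixedAnova = mixedAnova, failures = failures,
       records = records, plan = plan)
}

#' Probe-session behaviour summary for a trained network
#'
#' Runs probe-block sessions for the requested probe types and reports
#' response probabilities for every trial type encountered (the standard
#' SS/SL/LS plus the probes).
#'
#' @param model a trained \linkS4class{RNNModel}
#' @param probeTypes probe types to interleave (may be empty: standard trials
#'   only)
#' @param nBlocks blocks per probe type (or full-task blocks when no probes)
#' @param task a \linkS4class{TaskConfig}
#' @param threshold Go threshold
#' @return named numeric vector of response probabilities
#' @export
runProbeSession <- function(model, probeTypes = c("MM", "LL", "XL"),
                            nBlocks = 10L, task = taskConfig(),
                            threshold = 0.5) {
  if (length(probeTypes) == 0) {
    hits <- list()
    for (b in seq_len(nBlocks)) {
      for (tr in makeBlock(fullTaskBlock, task)) {
        sc <- scoreTrial(runTrial(model, tr), threshold)
        hits[[sc$trialType]] <- c(hits[[sc$trialType]], sc$respondedInWindow)
      }
    }
    return(vapply(hits, mean, 0))
  }
  probeEvaluation(model, probeTypes, nBlocks, task, threshold)
}
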