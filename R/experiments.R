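# Desk-scale studies on synthetic data: the regression study, the sex
# study with attention-driven feature discovery and probe comparison, and
# the wave-blanking study.

#' Regression study: train, evaluate against ZeroR, explain
#'
#' Cross-validates one model per interval/amplitude task, compares each to
#' the ZeroR baseline, and computes ECGradCAM maps plus localization
#' scores (attention mass inside the task's defining wave window, and
#' whether the attention argmax falls inside it) on held-out records.
#'
#' @param dataset an [EcgDataset-class] of median beats.
#' @param tasks regression task names (columns of `measurements(dataset)`).
#' @param config a [trainConfig()] template; its task field is overridden
#'   per task.
#' @param nExplain held-out records to explain per task.
#' @return list: `report` (EvalReport data.frame, one row per task),
#'   `cv` (per-task [crossValidate()] results), `attention` (per task, a
#'   list of [AttentionMap-class]), `localization` (data.frame of window
#'   scores and argmax hits).
#' @export
runRegressionStudy <- function(dataset, tasks = c("qrs", "rAmp", "tAmp"),
                               config = trainConfig("qrs", folds = 2),
                               nExplain = 20L) {
  cvs <- list(); maps <- list(); locRows <- list()
  for (task in tasks) {
    cfg <- config
    cfg$task <- task
    if (cfg$arch@head != "regression")
      cfg$arch <- deskArchitecture(head = "regression",
                                   nResidualModules = cfg$arch@nResidualModules,
                                   dropoutRate = cfg$arch@dropoutRate)
    cvs[[task]] <- crossValidate(dataset, cfg)
    net <- cvs[[task]]$models[[1]]
    if (!is.null(net)) {
      va <- splitFolds(length(dataset), cfg$folds, cfg$seed)[[1]]$validation
      pick <- va[seq_len(min(nExplain, length(va)))]
      maps[[task]] <- lapply(pick, function(i)
        perLeadMaps(net, records(dataset)[[i]]))
      sc <- vapply(seq_along(pick), function(j) {
        i <- pick[j]
        fid <- fiducials(dataset)[[i]]
        win <- taskWindow(task, fid)
        m <- maps[[task]][[j]]
        amax <- (which.max(averagedMap(m)) - 1) * 1000 / sampleRate(records(dataset)[[i]])
        c(score = localizationScore(m, win),
          frac = diff(win) / (ncol(perLead(m)) * 1000 / sampleRate(records(dataset)[[i]])),
          hit = as.numeric(amax >= win[1] && amax <= win[2]))
      }, numeric(3))
      locRows[[task]] <- data.frame(task = task,
                                    meanScore = mean(sc["score", ]),
                                    meanWindowFrac = mean(sc["frac", ]),
                                    argmaxHitRate = mean(sc["hit", ]))
    }
  }
  list(report = do.call(rbind, lapply(cvs, `[[`, "report")),
       cv = cvs, attention = maps,
       localization = do.call(rbind, locRows))
}

# out-of-fold logistic-regression probe on ground-truth features
probeSex <- function(meas, formula, folds) {
  oof <- numeric(nrow(meas))
  rows <- lapply(seq_along(folds), function(i) {
    # quasi-separation on strongly planted effects is expected and benign
    fit <- suppressWarnings(
      stats::glm(formula, family = stats::binomial(),
                 data = meas[folds[[i]]$train, ]))
    p <- stats::predict(fit, meas[folds[[i]]$validation, ],
                        type = "response")
    oof[folds[[i]]$validation] <<- p
    cm <- classificationMetrics(p, meas$sex[folds[[i]]$validation])
    data.frame(fold = i, accuracy = cm["accuracy"], auc = cm["auc"])
  })
  fm <- do.call(rbind, rows)
  rownames(fm) <- NULL
  list(report = evalReportRow("sex", fm), folds = fm, predictions = oof)
}

#' Sex study: CNN vs simple logistic probes, with attention analysis
#'
#' Trains the sex classifier, then fits two logistic-regression probes on
#' generator ground-truth features — QRS duration alone, and QRS duration
#' plus R/S amplitudes and timings — using the same folds, to ask how much
#' of the network's accuracy the probe features explain. Also computes
#' localization scores of the classifier's attention over the P, QRS and T
#' windows of held-out records, where the planted class difference (R-wave
#' downslope) predicts QRS dominance.
#'
#' @param dataset an [EcgDataset-class] generated with non-zero
#'   `sexEffect`.
#' @param config a [trainConfig()] for the CNN (task forced to "sex").
#' @param nExplain held-out records for the attention analysis.
#' @return list: `network` (CNN cv result), `probeDuration`, `probeRich`
#'   (probe results), `localization` (mean P/QRS/T window scores),
#'   `attention` (list of maps).
#' @export
runSexStudy <- function(dataset, config = trainConfig("sex", folds = 2),
                        nExplain = 20L) {
  meas <- measurements(dataset)
  if (length(unique(meas$sex)) < 2L)
    stop("degenerate class balance")
  cfg <- config
  cfg$task <- "sex"
  if (cfg$arch@head != "classification")
    cfg$arch <- deskArchitecture(head = "classification",
                                 nResidualModules = cfg$arch@nResidualModules,
                                 dropoutRate = cfg$arch@dropoutRate)
  cv <- crossValidate(dataset, cfg)
  folds <- splitFolds(length(dataset), cfg$folds, cfg$seed,
                      strata = meas$sex)
  pDur <- probeSex(meas, sex ~ qrs, folds)
  pRich <- probeSex(meas, sex ~ qrs + rAmp + sAmp + rTime + sTime, folds)
  net <- cv$models[[1]]
  maps <- NULL; loc <- NULL
  if (!is.null(net)) {
    va <- folds[[1]]$validation
    pick <- va[seq_len(min(nExplain, length(va)))]
    maps <- lapply(pick, function(i) perLeadMaps(net, records(dataset)[[i]]))
    sc <- vapply(seq_along(pick), function(j) {
      fid <- fiducials(dataset)[[pick[j]]]
      m <- maps[[j]]
      c(P = localizationScore(m, c(fid@pOn, fid@pOff)),
        QRS = localizationScore(m, c(fid@qrsOn, fid@qrsOff)),
        T = localizationScore(m, c(2 * fid@tPeak - fid@tOff, fid@tOff)))
    }, numeric(3))
    loc <- rowMeans(sc)
  }
  list(network = cv, probeDuration = pDur, probeRich = pRich,
       localization = loc, attention = maps)
}

#' Wave-blanking study over trained models
#'
#' Runs [blankingStudy()] for the supplied task models and summarizes
#' whether the expected pattern holds: for each regression task the
#' largest error inflation occurs when its defining wave is blanked, and
#' the sex accuracy collapses only under QRS blanking.
#'
#' @param models named list of trained networks (or per-fold lists), as
#'   produced by [runRegressionStudy()]/[runSexStudy()].
#' @param dataset an [EcgDataset-class].
#' @param waves waves to blank.
#' @return list: `report` (the BlankingReport), `diagonalDominant` (named
#'   logical per regression task), `definingWave` (which wave dominates).
#' @export
runBlankingStudy <- function(models, dataset,
                             waves = c("none", "P", "QRS", "T")) {
  report <- blankingStudy(models, dataset, waves)
  # intervals bounded by two different waves accept either of them
  definingWave <- list(qt = c("T", "QRS"), pr = c("P", "QRS"),
                       qrs = "QRS", hr = "QRS", stj = "QRS",
                       tAmp = "T", rAmp = "QRS", sex = "QRS")
  tasks <- unique(report$task)
  dd <- vapply(tasks, function(task) {
    sub <- report[report$task == task & report$wave != "none", ]
    if (task == "sex") {
      # accuracy: the defining wave should cause the largest drop
      sub$wave[which.min(sub$value)] %in% definingWave[[task]]
    } else {
      sub$wave[which.max(sub$value)] %in% definingWave[[task]]
    }
  }, logical(1))
  names(dd) <- tasks
  list(report = report, diagonalDominant = dd,
       definingWave = definingWave[tasks])
}
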