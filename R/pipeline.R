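#' @include AllClasses.R features.R selection.R evaluation.R ensemble.R
NULL

#' Configuration of the staged feature-selection protocol
#'
#' @param coarseGrid top-percent sweep (default 10 to 80 by 10).
#' @param fineGrid fine sweep 1 to 9 by 1, triggered for a feature set whose
#'   coarse optimum sits at the lowest grid point.
#' @param rankMethods ranking methods for the stage-1 sweep.
#' @param regularizers sparse-support selectors.
#' @param rfeRankers linear rankers refined by RFECV in stage 2.
#' @param rfeStep features removed per RFE round.
#' @param evalClassifier [ClassifierSpec-class] scoring every subset
#'   (default Gaussian-kernel SVM).
#' @param baselineClassifiers roster names for the no-feature-selection
#'   baseline table.
#' @param folds CV folds.
#' @param seed protocol seed.
#' @param fineTriggerAtBoundary run the fine sweep when the coarse optimum is
#'   at the grid boundary.
#' @return a `ProtocolConfig` list.
#' @export
protocolConfig <- function(coarseGrid = seq(10, 80, by = 10),
                           fineGrid = 1:9,
                           rankMethods = c("variance", "chi2", "mic",
                                           "lr", "linsvm", "rf"),
                           regularizers = c("lasso", "lassolars", "elasticnet"),
                           rfeRankers = c("lr", "linsvm"),
                           rfeStep = 1L,
                           evalClassifier = classifierSpec("svm"),
                           baselineClassifiers = c("gnb", "knn", "dt", "lr",
                                                   "svm", "rf", "gbdt", "xgb"),
                           folds = 5L, seed = 1L,
                           fineTriggerAtBoundary = TRUE) {
  stopifnot(length(coarseGrid) >= 1L, length(rankMethods) >= 1L)
  structure(list(coarseGrid = coarseGrid, fineGrid = fineGrid,
                 rankMethods = rankMethods, regularizers = regularizers,
                 rfeRankers = rfeRankers, rfeStep = as.integer(rfeStep),
                 evalClassifier = evalClassifier,
                 baselineClassifiers = baselineClassifiers,
                 folds = as.integer(folds), seed = as.integer(seed),
                 fineTriggerAtBoundary = isTRUE(fineTriggerAtBoundary)),
            class = "ProtocolConfig")
}

.metricRow <- function(report) {
  m <- report@pooled
  data.frame(ACC = m@ACC * 100, MCC = m@MCC, SP = m@SP * 100, SN = m@SN * 100)
}

.rankingFor <- function(table, method, seed) {
  switch(method,
    variance = scoreVariance(table),
    chi2     = scoreChi2(table),
    mic      = scoreMIC(table),
    lr       = ,
    linsvm   = ,
    rf       = scoreEmbedded(table, method, seed = seed),
    stop("unknown ranking method: ", method))
}

#' Run the full staged feature-selection protocol
#'
#' Executes, per source: descriptor extraction (sigmoid normalization + 29d
#' assembly and the d-feature average-only set), MinMax normalization,
#' no-feature-selection baselines over the classifier roster, the stage-1
#' top-percent sweep over all ranking methods (with the fine 1-9% sweep when
#' a coarse optimum sits at the boundary), sparse-regularizer selections, and
#' stage-2 RFECV refinements of the best stage-1 subsets of the linear
#' rankers. Every subset is scored by pooled k-fold CV accuracy of the
#' evaluation classifier.
#'
#' @param sources named list; each element a list of raw
#'   [ResidueMatrix-class] objects sharing one representation dimension.
#' @param seqs sequences aligned with every source's matrices
#'   (`AAStringSet`).
#' @param labels binary labels aligned with the matrices.
#' @param config a [protocolConfig()].
#' @param fsSets names of the tables to run feature selection on; default:
#'   every `<source>_All` table plus any `<source>_Avg` table with more than
#'   100 features. The remaining tables get baselines only.
#' @param outDir optional directory for TSV/JSON reports.
#' @return list with `tables` (raw), `normTables`, `normalizers`, `reports`
#'   (`nfs`, `stage1`, `regularizers`, `stage2` data frames), `rankings`,
#'   `selections`, `fsSets`, `nfsOnlySets`, `labels`, `config`.
#' @export
runProtocol <- function(sources, seqs, labels, config = protocolConfig(),
                        fsSets = NULL, outDir = NULL) {
  stopifnot(is.list(sources), length(names(sources)) == length(sources))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  seed <- config$seed

  # Step 1: extract both descriptor sets per source
  tables <- list()
  for (src in names(sources)) {
    mats <- lapply(sources[[src]], function(m)
      if (isNormalized(m)) m else sigmoidNormalize(m))
    d <- ncol(residueValues(mats[[1]]))
    tables[[paste0(src, "_All")]] <-
      buildFeatureTable(mats, seqs, labels, spec = featureSetSpec(d))
    tables[[paste0(src, "_Avg")]] <-
      buildFeatureTable(mats, seqs, labels,
                        spec = featureSetSpec(d, categories = "avg"))
  }
  if (is.null(fsSets)) {
    nf <- vapply(tables, nrow, integer(1))
    fsSets <- names(tables)[grepl("_All$", names(tables)) | nf > 100L]
  }
  nfsOnlySets <- setdiff(names(tables), fsSets)
  normalizers <- lapply(tables, minmaxFit)
  normTables <- lapply(names(tables), function(nm)
    minmaxApply(normalizers[[nm]], tables[[nm]]))
  names(normTables) <- names(tables)

  # NFS baselines over the roster
  message("[nfs] baselines on ", length(tables), " feature sets")
  nfs <- do.call(rbind, lapply(names(tables), function(nm) {
    do.call(rbind, lapply(config$baselineClassifiers, function(cl) {
      rep_ <- crossValidate(normTables[[nm]], classifierSpec(cl),
                            folds = config$folds, seed = seed,
                            normalize = "none")
      cbind(data.frame(set = nm, classifier = cl,
                       nFeatures = nrow(tables[[nm]])), .metricRow(rep_))
    }))
  }))

  # Stage 1: importance sweeps
  rankings <- list()
  stage1 <- NULL
  selections <- list()
  for (nm in fsSets) {
    message("[stage1] ", nm)
    tab <- normTables[[nm]]
    for (meth in config$rankMethods) {
      rk <- .rankingFor(tab, meth, seed)
      rankings[[paste0(nm, "/", meth)]] <- rk
      grid <- sort(config$coarseGrid)
      rows <- lapply(grid, function(p) {
        sel <- selectTopPercent(rk, p)
        rep_ <- crossValidate(tab[sel@selectedNames, ],
                              config$evalClassifier, folds = config$folds,
                              seed = seed, normalize = "none")
        cbind(data.frame(set = nm, method = meth, percent = p,
                         origin = sel@origin,
                         nFeatures = length(sel@selectedNames)),
              .metricRow(rep_))
      })
      df <- do.call(rbind, rows)
      if (config$fineTriggerAtBoundary &&
          df$percent[which.max(df$ACC)] == min(grid) &&
          length(config$fineGrid)) {
        fine <- lapply(sort(config$fineGrid), function(p) {
          sel <- selectTopPercent(rk, p)
          rep_ <- crossValidate(tab[sel@selectedNames, ],
                                config$evalClassifier, folds = config$folds,
                                seed = seed, normalize = "none")
          cbind(data.frame(set = nm, method = meth, percent = p,
                           origin = sel@origin,
                           nFeatures = length(sel@selectedNames)),
                .metricRow(rep_))
        })
        df <- rbind(do.call(rbind, fine), df)
      }
      stage1 <- rbind(stage1, df)
    }
  }

  # Regularizer selections
  regs <- NULL
  for (nm in fsSets) {
    message("[regularizers] ", nm)
    tab <- normTables[[nm]]
    for (meth in config$regularizers) {
      sel <- selectByRegularizer(tab, meth, seed = seed)
      selections[[paste0(nm, "/", sel@origin)]] <- sel
      if (!length(sel@selectedNames)) next
      rep_ <- crossValidate(tab[sel@selectedNames, ], config$evalClassifier,
                            folds = config$folds, seed = seed,
                            normalize = "none")
      regs <- rbind(regs,
        cbind(data.frame(set = nm, method = sel@origin,
                         nFeatures = length(sel@selectedNames)),
              .metricRow(rep_)))
    }
  }

  # Stage 2: RFECV on the best stage-1 subsets of the linear rankers
  stage2 <- NULL
  for (nm in fsSets) {
    message("[stage2] ", nm)
    tab <- normTables[[nm]]
    nfsRow <- nfs[nfs$set == nm & nfs$classifier == config$evalClassifier@name, ]
    stage2 <- rbind(stage2,
      cbind(data.frame(set = nm, origin = "NFS",
                       nFeatures = nrow(tables[[nm]])),
            nfsRow[, c("ACC", "MCC", "SP", "SN")]))
    for (rr in config$rfeRankers) {
      cand <- stage1[stage1$set == nm & stage1$method == rr, ]
      if (!nrow(cand)) next
      bestP <- cand$percent[which.max(cand$ACC)]
      rk <- rankings[[paste0(nm, "/", rr)]]
      startSel <- selectTopPercent(rk, bestP)
      selections[[paste0(nm, "/", startSel@origin)]] <- startSel
      startRow <- cand[cand$percent == bestP, ]
      stage2 <- rbind(stage2,
        cbind(data.frame(set = nm, origin = startSel@origin,
                         nFeatures = startRow$nFeatures),
              startRow[, c("ACC", "MCC", "SP", "SN")]))
      rfe <- rfeCV(tab, startSel, ranker = rr, folds = config$folds,
                   step = config$rfeStep, seed = seed,
                   scorer = config$evalClassifier)
      selections[[paste0(nm, "/", rfe@origin)]] <- rfe
      rep_ <- crossValidate(tab[rfe@selectedNames, ], config$evalClassifier,
                            folds = config$folds, seed = seed,
                            normalize = "none")
      stage2 <- rbind(stage2,
        cbind(data.frame(set = nm, origin = rfe@origin,
                         nFeatures = length(rfe@selectedNames)),
              .metricRow(rep_)))
    }
  }

  out <- list(tables = tables, normTables = normTables,
              normalizers = normalizers,
              reports = list(nfs = nfs, stage1 = stage1,
                             regularizers = regs, stage2 = stage2),
              rankings = rankings, selections = selections,
              fsSets = fsSets, nfsOnlySets = nfsOnlySets,
              labels = as.integer(labels), config = config)
  if (!is.null(outDir)) writeProtocolReports(out, outDir)
  out
}

#' Write protocol reports as TSV/JSON
#' @param proto result of [runProtocol()].
#' @param dir output directory.
#' @export
writeProtocolReports <- function(proto, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# seed=%d folds=%d classifier=%s", proto$config$seed,
                 proto$config$folds, proto$config$evalClassifier@name)
  for (nm in names(proto$reports)) {
    df <- proto$reports[[nm]]
    if (is.null(df)) next
    f <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(hdr, f)
    suppressWarnings(
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
  }
  jsonlite::write_json(
    lapply(proto$selections, function(s)
      list(origin = s@origin, n = length(s@selectedNames))),
    file.path(dir, "selections.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build the soft-voting member registry from protocol outputs
#'
#' In the faithful configuration — four full feature sets each contributing
#' one NFS model, three regularizer-support models, the two best stage-1
#' subsets of the linear rankers and their two RFECV refinements, plus the
#' two small average-only sets contributing their NFS models — the registry
#' holds 4 x 8 + 2 = 34 members. Every member's final model is trained on the
#' entire normalized training table restricted to its subset; its recorded
#' cv_acc is the pooled CV accuracy from the stage reports.
#'
#' @param proto result of [runProtocol()].
#' @return list of [MemberModel-class]; feed to [buildEnsemble()].
#' @export
buildMemberRegistry <- function(proto) {
  cfg <- proto$config
  members <- list()
  addMember <- function(setName, origin, featNames, acc) {
    full <- paste0(setName, "/", origin)
    if (acc <= 0)
      stop("member ", full, " has nonpositive CV accuracy")
    prefixed <- paste0(setName, ":", featNames)
    tab <- proto$normTables[[setName]]
    fit <- fitClassifier(cfg$evalClassifier,
                         featureMatrix(tab)[, featNames, drop = FALSE],
                         classLabels(tab), seed = cfg$seed)
    fit@featureNames <- prefixed
    st <- proto$normalizers[[setName]]
    keep <- match(featNames, st@featureNames)
    sub <- new("NormalizerState", featureNames = prefixed,
               mins = st@mins[keep], maxs = st@maxs[keep])
    if (full %in% vapply(members, function(m) m@origin, character(1)))
      stop("duplicate member origin: ", full)
    members[[length(members) + 1L]] <<- memberModel(full, prefixed, fit, sub, acc)
  }
  s2 <- proto$reports$stage2
  regs <- proto$reports$regularizers
  for (nm in proto$fsSets) {
    rows <- s2[s2$set == nm, ]
    if (!nrow(rows)) stop("no stage-2 rows for set ", nm)
    for (i in seq_len(nrow(rows))) {
      origin <- rows$origin[i]
      featNames <- if (origin == "NFS") featureNames(proto$tables[[nm]])
        else featureNames(proto$selections[[paste0(nm, "/", origin)]])
      if (is.null(featNames)) stop("missing selection for member ", nm, "/", origin)
      addMember(nm, origin, featNames, rows$ACC[i] / 100)
    }
    rrows <- regs[regs$set == nm, ]
    for (i in seq_len(nrow(rrows))) {
      sel <- proto$selections[[paste0(nm, "/", rrows$method[i])]]
      if (is.null(sel)) stop("missing selection for member ", nm, "/", rrows$method[i])
      addMember(nm, rrows$method[i], featureNames(sel), rrows$ACC[i] / 100)
    }
  }
  nfs <- proto$reports$nfs
  for (nm in proto$nfsOnlySets) {
    row <- nfs[nfs$set == nm & nfs$classifier == cfg$evalClassifier@name, ]
    if (!nrow(row)) stop("no NFS baseline for set ", nm)
    addMember(nm, "NFS", featureNames(proto$tables[[nm]]), row$ACC[1] / 100)
  }
  members
}

#' Assemble the raw descriptor matrix an ensemble consumes
#'
#' Concatenates, per feature set of the protocol, the raw (unnormalized)
#' descriptor columns with set-prefixed names (`<set>:<feature>`), matching
#' the member feature names produced by [buildMemberRegistry()].
#'
#' @param sources named list of raw [ResidueMatrix-class] lists (same source
#'   names as the protocol run).
#' @param seqs aligned sequences.
#' @param proto the protocol result whose table layout to reproduce.
#' @return samples x features numeric matrix with prefixed column names.
#' @export
assembleEnsembleInput <- function(sources, seqs, proto) {
  blocks <- list()
  for (src in names(sources)) {
    mats <- lapply(sources[[src]], function(m)
      if (isNormalized(m)) m else sigmoidNormalize(m))
    d <- ncol(residueValues(mats[[1]]))
    for (suffix in c("_All", "_Avg")) {
      nm <- paste0(src, suffix)
      if (!nm %in% names(proto$tables)) next
      spec <- if (suffix == "_All") featureSetSpec(d)
        else featureSetSpec(d, categories = "avg")
      tab <- buildFeatureTable(mats, seqs, rep(0L, length(mats)), spec = spec)
      v <- featureMatrix(tab)
      colnames(v) <- paste0(nm, ":", colnames(v))
      blocks[[nm]] <- v
    }
  }
  do.call(cbind, blocks)
}
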