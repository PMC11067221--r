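## Pipeline orchestration: prepare -> train -> predict -> evaluate, plus
## baselines, with CAFA-style prediction TSVs. Each step is an exported
## function; inst/cli/tensorgo.R wraps them for shell use.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Prepare dataset artifacts from raw inputs
#'
#' Runs the label pipeline: evidence filtering, true-path propagation,
#' label-space selection (with root exclusion and the frequency threshold),
#' label encoding, information content, multi-view assembly and
#' cluster-grouped fold planning. The roster is the set of annotated proteins
#' present in every view, in view-file order.
#'
#' @param oboPath path to the OBO ontology file.
#' @param annotationsPath path to the protein/term/evidence TSV.
#' @param viewPaths named character vector of feature-table paths.
#' @param clustersPath path to the cluster TSV.
#' @param namespace "MFO", "CCO" or "BPO".
#' @param minCount label-frequency threshold (30 for MFO/CCO, 60 for BPO by
#'   convention).
#' @param nFolds,seed fold-plan settings.
#' @param allowed evidence codes to keep.
#' @return list with dag, space (IC attached), dataset, foldPlan.
#' @export
runPrepare <- function(oboPath, annotationsPath, viewPaths, clustersPath,
                       namespace, minCount, nFolds = 10L, seed = 1L,
                       allowed = experimentalEvidenceCodes) {
  dag <- .stage("parse_obo", parseOBO(oboPath))
  records <- .stage("read_annotations", readAnnotations(annotationsPath))
  annots <- .stage("filter_evidence", filterEvidence(records, allowed))
  annots <- .stage("propagate_true_path", propagateTruePath(annots, dag))
  space <- .stage("select_label_space",
                  selectLabelSpace(annots, dag, namespace, minCount))
  views <- .stage("read_views", lapply(viewPaths, readFeatureTable))
  names(views) <- names(viewPaths)
  rosterIds <- .stage("roster", {
    ids <- rownames(views[[1]])
    for (v in views) ids <- ids[ids %in% rownames(v)]
    ids <- ids[ids %in% names(annotations(annots))]
    if (!length(ids)) stop("no proteins shared by views and annotations")
    ids
  })
  Y <- .stage("encode_labels", encodeLabels(annots, space, rosterIds))
  ic <- .stage("information_content",
               informationContent(annots, dag, space))
  space <- attachIC(space, ic)
  clusters <- .stage("read_clusters", readClusters(clustersPath))
  dataset <- .stage("assemble_dataset",
                    assembleDataset(views, Y, rosterIds, clusters))
  foldPlan <- .stage("cluster_cv_folds",
                     clusterCVFolds(clusters, rosterIds, nFolds = nFolds,
                                    seed = seed))
  list(dag = dag, space = space, dataset = dataset, foldPlan = foldPlan)
}

#' Train a model on one fold
#'
#' Fits on the fold's training proteins with validation-based model
#' selection, then (by default) refits on train + validation before the
#' model is archived -- the protocol used with held-out test evaluation.
#'
#' @param prepared list from [runPrepare()] (or an equivalent in-memory
#'   study).
#' @param fold fold index into the prepared fold plan.
#' @param cfg list from [ltrControl()].
#' @param archivePath optional path for [saveLTRModel()].
#' @param refit if FALSE, skip the final refit on train + validation.
#' @param intercept if TRUE (default), views are augmented with a unit
#'   feature (see [addInterceptFeature()]) so the polynomial includes
#'   lower-degree terms; recorded in the archive and honored by
#'   [runPredict()].
#' @param activationA,activationB model activations.
#' @return list with model, report (validation phase) and refitReport.
#' @export
runTrain <- function(prepared, fold = 1L, cfg = ltrControl(),
                     archivePath = NULL, refit = TRUE, intercept = TRUE,
                     activationA = "identity", activationB = "identity") {
  ds <- prepared$dataset
  if (intercept) ds <- addInterceptFeature(ds)
  f <- folds(prepared$foldPlan)[[fold]]
  dims <- vapply(viewList(ds), ncol, integer(1))
  model <- ltrModel(dims, ncol(labelMatrix(ds)), cfg,
                    activationA = activationA, activationB = activationB)
  fit <- ltrFit(model, ds, trainIds = f$train, valIds = f$validation,
                cfg = cfg)
  refitReport <- NULL
  if (refit && length(f$validation)) {
    fit2 <- ltrFit(fit$model, ds,
                   trainIds = c(f$train, f$validation), cfg = cfg)
    model <- fit2$model
    refitReport <- fit2$report
  } else {
    model <- fit$model
  }
  if (!is.null(archivePath)) {
    saveLTRModel(model, archivePath,
                 cfg = c(cfg, list(intercept = intercept)))
  }
  list(model = model, report = fit$report, refitReport = refitReport,
       intercept = intercept)
}

#' Predict with consistency post-processing and write a prediction TSV
#'
#' Scores are clipped to [0,1], made hierarchically consistent by
#' [propagateScoresMax()], and written as \code{protein_id term_id score}
#' rows with scores rounded half-even to 3 decimals; zero scores are omitted
#' (CAFA submission convention).
#'
#' @param model an [LTRModel-class] or a path to a model archive.
#' @param dataset a [MultiViewDataset-class] (typically the test subset).
#' @param space the [LabelSpace-class] the model predicts over.
#' @param file output TSV path (NULL to skip writing).
#' @param intercept augment the views with the unit feature the model was
#'   trained with; "auto" (default) infers it from the model/view widths.
#' @return the post-processed score matrix, invisibly when writing.
#' @export
runPredict <- function(model, dataset, space, file = NULL,
                       intercept = "auto") {
  if (is.character(model)) model <- loadLTRModel(model)$model
  if (identical(intercept, "auto")) {
    widths <- vapply(viewList(dataset), ncol, integer(1))
    intercept <- all(viewDims(model) == widths + 1L)
  }
  if (intercept) dataset <- addInterceptFeature(dataset)
  S <- ltrPredict(model, dataset, clip = TRUE)
  S <- propagateScoresMax(S, space)
  colnames(S) <- goTerms(space)
  if (!is.null(file)) {
    writePredictionsTSV(S, file)
    return(invisible(S))
  }
  S
}

#' Write / read a CAFA-style prediction TSV
#'
#' @param S score matrix with protein rownames and term colnames.
#' @param file path.
#' @return \code{readPredictionsTSV} returns a data.frame with columns
#'   protein_id, term_id, score.
#' @export
writePredictionsTSV <- function(S, file) {
  stopifnot(!is.null(rownames(S)), !is.null(colnames(S)))
  lines <- character(0)
  for (i in seq_len(nrow(S))) {
    sc <- round(S[i, ], 3)
    keep <- which(sc > 0)
    if (length(keep)) {
      lines <- c(lines, paste(rownames(S)[i], colnames(S)[keep],
                              formatC(sc[keep], format = "f", digits = 3),
                              sep = "\t"))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writePredictionsTSV
#' @export
readPredictionsTSV <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(protein_id = character(0), term_id = character(0),
                      score = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("parse error line ", which(lengths(parts) != 3L)[1],
         ": expected 3 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(protein_id = m[, 1], term_id = m[, 2],
             score = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

#' Evaluate a prediction TSV against truth artifacts
#'
#' Reconstructs the dense score matrix over the test roster and label space
#' (missing pairs are zero), then computes every protein-centric metric.
#'
#' @param predictions path to a prediction TSV, or a data.frame from
#'   [readPredictionsTSV()].
#' @param Y binary truth matrix over the test roster (protein rownames, term
#'   colnames).
#' @param space [LabelSpace-class] with IC attached for the weighted metrics.
#' @param cfg list from [evalControl()]; its ic defaults to the space's.
#' @return a [MetricsReport-class].
#' @export
runEvaluate <- function(predictions, Y, space, cfg = evalControl()) {
  pred <- if (is.character(predictions)) readPredictionsTSV(predictions)
  else predictions
  unknownP <- setdiff(unique(pred$protein_id), rownames(Y))
  if (length(unknownP)) {
    stop("prediction protein(s) outside the test roster: ",
         paste(head(unknownP, 5), collapse = ", "), call. = FALSE)
  }
  unknownT <- setdiff(unique(pred$term_id), goTerms(space))
  if (length(unknownT)) {
    stop("unknown term id(s) in predictions: ",
         paste(head(unknownT, 5), collapse = ", "), call. = FALSE)
  }
  S <- matrix(0, nrow(Y), length(goTerms(space)),
              dimnames = list(rownames(Y), goTerms(space)))
  if (nrow(pred)) {
    S[cbind(pred$protein_id, pred$term_id)] <- pred$score
  }
  if (is.null(cfg$ic) && length(space@ic)) cfg$ic <- space@ic
  evaluateScores(Y[, goTerms(space), drop = FALSE], S, cfg)
}

#' Run a baseline scorer in the prediction-TSV dialect
#'
#' \code{kind = "naive"} scores every test protein with training-term
#' frequencies; \code{"blast-full"} transfers the best hit's labels (binary
#' 1.000 scores); \code{"blast-partial"} scores each term with the maximum
#' identity to an annotated subject.
#'
#' @param kind one of "naive", "blast-full", "blast-partial".
#' @param Ytrain binary training label matrix with protein rownames.
#' @param testIds ordered test protein ids.
#' @param hits data.frame from [readBlastTabular()] (blast kinds only).
#' @param file optional output TSV path.
#' @return score matrix (invisibly when writing).
#' @export
runBaseline <- function(kind = c("naive", "blast-full", "blast-partial"),
                        Ytrain, testIds, hits = NULL, file = NULL) {
  kind <- match.arg(kind)
  if (kind != "naive" && is.null(hits)) {
    stop("configuration error: '", kind, "' requires a hit table",
         call. = FALSE)
  }
  S <- switch(kind,
    "naive" = naiveScores(Ytrain, testIds),
    "blast-full" = blastFull(hits, Ytrain, testIds),
    "blast-partial" = blastPartial(hits, Ytrain, testIds)
  )
  if (!is.null(file)) {
    writePredictionsTSV(S, file)
    return(invisible(S))
  }
  S
}
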