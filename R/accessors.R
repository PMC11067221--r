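#' Accessors for tensorGO classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param name view name (for \code{getView}).
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))
#' @rdname accessors
#' @export
setMethod("goTerms", "OntologyDAG", function(x) x@terms)
#' @rdname accessors
#' @export
setMethod("goTerms", "LabelSpace", function(x) x@terms)

#' @rdname accessors
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))
#' @rdname accessors
#' @export
setMethod("goRoots", "OntologyDAG", function(x) x@roots)

#' @rdname accessors
#' @export
setGeneric("goParents", function(x) standardGeneric("goParents"))
#' @rdname accessors
#' @export
setMethod("goParents", "OntologyDAG", function(x) x@parents)

#' @rdname accessors
#' @export
setGeneric("goNamespace", function(x) standardGeneric("goNamespace"))
#' @rdname accessors
#' @export
setMethod("goNamespace", "OntologyDAG", function(x) x@termNamespace)
#' @rdname accessors
#' @export
setMethod("goNamespace", "LabelSpace", function(x) x@namespace)

#' @rdname accessors
#' @export
setGeneric("altIdMap", function(x) standardGeneric("altIdMap"))
#' @rdname accessors
#' @export
setMethod("altIdMap", "OntologyDAG", function(x) x@altIds)

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@annotations)

#' @rdname accessors
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))
#' @rdname accessors
#' @export
setMethod("isPropagated", "AnnotationSet", function(x) x@propagated)

#' @rdname accessors
#' @export
setGeneric("termIndex", function(x) standardGeneric("termIndex"))
#' @rdname accessors
#' @export
setMethod("termIndex", "LabelSpace", function(x) {
  setNames(seq_along(x@terms), x@terms)
})

#' @rdname accessors
#' @export
setGeneric("ancestorsInSpace", function(x) standardGeneric("ancestorsInSpace"))
#' @rdname accessors
#' @export
setMethod("ancestorsInSpace", "LabelSpace", function(x) x@ancestorsInSpace)

#' @rdname accessors
#' @export
setGeneric("termIC", function(x) standardGeneric("termIC"))
#' @rdname accessors
#' @export
setMethod("termIC", "LabelSpace", function(x) {
  if (length(x@ic)) setNames(x@ic, x@terms) else NULL
})

#' @rdname accessors
#' @export
setGeneric("roster", function(x) standardGeneric("roster"))
#' @rdname accessors
#' @export
setMethod("roster", "MultiViewDataset", function(x) x@roster)

#' @rdname accessors
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))
#' @rdname accessors
#' @export
setMethod("viewNames", "MultiViewDataset", function(x) names(x@views))

#' @rdname accessors
#' @export
setGeneric("getView", function(x, name) standardGeneric("getView"))
#' @rdname accessors
#' @export
setMethod("getView", "MultiViewDataset", function(x, name) {
  if (!name %in% names(x@views)) {
    stop("no view named '", name, "'", call. = FALSE)
  }
  x@views[[name]]
})

#' @rdname accessors
#' @export
setGeneric("viewList", function(x) standardGeneric("viewList"))
#' @rdname accessors
#' @export
setMethod("viewList", "MultiViewDataset", function(x) x@views)

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setMethod("labelMatrix", "MultiViewDataset", function(x) x@Y)

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setMethod("clusterIds", "MultiViewDataset", function(x) {
  if (length(x@clusters)) x@clusters else NULL
})

#' @rdname accessors
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))
#' @rdname accessors
#' @export
setMethod("folds", "FoldPlan", function(x) x@folds)

#' @rdname accessors
#' @export
setGeneric("viewDims", function(x) standardGeneric("viewDims"))
#' @rdname accessors
#' @export
setMethod("viewDims", "LTRModel", function(x) {
  vapply(x@U, nrow, integer(1))
})

#' @rdname accessors
#' @export
setGeneric("ltrRank", function(x) standardGeneric("ltrRank"))
#' @rdname accessors
#' @export
setMethod("ltrRank", "LTRModel", function(x) length(x@lambda))

#' Convert a MetricsReport to a one-row data.frame
#'
#' @param x a MetricsReport.
#' @param row.names,optional,... passed through for the generic signature.
#' @return a one-row data.frame with metric columns.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    fmax = x@fmax, tau_fmax = x@tauFmax,
    wfmax = x@wfmax, tau_wfmax = x@tauWfmax,
    smin = x@smin, tau_smin = x@tauSmin,
    auprc = x@auprc, auroc = x@auroc, coverage = x@coverage
  )
}

setMethod("show", "OntologyDAG", function(object) {
  nEdges <- sum(lengths(object@parents))
  cat("OntologyDAG with", length(object@terms), "terms,", nEdges,
      "is-a edges\n")
  for (ns in names(object@roots)) {
    cat("  ", ns, " root: ", object@roots[[ns]], " (",
        sum(object@termNamespace == ns), " terms)\n", sep = "")
  }
  if (length(object@altIds)) {
    cat("  ", length(object@altIds), "alternate ids mapped\n")
  }
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@annotations), "proteins,",
      sum(lengths(object@annotations)), "annotations",
      if (object@propagated) "(true-path propagated)" else "(raw)", "\n")
})

setMethod("show", "LabelSpace", function(object) {
  cat("LabelSpace [", object@namespace, "]: ", length(object@terms),
      " terms", if (length(object@ic)) ", IC attached" else "", "\n", sep = "")
})

setMethod("show", "MultiViewDataset", function(object) {
  cat("MultiViewDataset:", length(object@roster), "proteins,",
      length(object@views), "view(s),", ncol(object@Y), "labels\n")
  for (nm in names(object@views)) {
    cat("  view '", nm, "': ", ncol(object@views[[nm]]), " features\n",
        sep = "")
  }
  if (length(object@clusters)) {
    cat("  clusters:", length(unique(object@clusters)), "\n")
  }
})

setMethod("show", "LTRModel", function(object) {
  cat("LTRModel: ", length(object@U), " view(s), rank n_t = ",
      length(object@lambda), ", n_y = ", nrow(object@Q), "\n", sep = "")
  cat("  view dims: ", paste(vapply(object@U, nrow, integer(1)),
                             collapse = ", "), "\n", sep = "")
  cat("  activations: A = ", object@activationA, ", B = ",
      object@activationB, "\n", sep = "")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@nFolds, "folds (seed", object@seed, ")\n")
  f1 <- object@folds[[1]]
  cat("  fold 1 sizes: train", length(f1$train), "/ validation",
      length(f1$validation), "/ test", length(f1$test), "\n")
})

setMethod("show", "ReducerModel", function(object) {
  cat("ReducerModel:", object@inputDim, "->", object@targetDim,
      "(", length(object@W), "layers )\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  Fmax     %.4f  (tau = %s)\n", object@fmax,
              format(object@tauFmax)))
  cat(sprintf("  WFmax    %.4f  (tau = %s)\n", object@wfmax,
              format(object@tauWfmax)))
  cat(sprintf("  Smin     %.4f  (tau = %s)\n", object@smin,
              format(object@tauSmin)))
  cat(sprintf("  AUPRC    %.4f\n", object@auprc))
  cat(sprintf("  AUROC    %.4f\n", object@auroc))
  cat(sprintf("  coverage %.4f\n", object@coverage))
})
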