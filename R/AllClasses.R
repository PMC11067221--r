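#' @import methods
#' @importFrom stats rnorm runif rbinom rpois quantile sd cor setNames
#' @importFrom utils read.delim write.table head tail
#' @importFrom igraph graph_from_data_frame is_dag components
#' @importFrom jsonlite write_json
NULL

#' Gene Ontology DAG (is-a relations only)
#'
#' Holds the is-a graph over GO terms for the three subontologies (MFO, CCO,
#' BPO). Only \code{is_a} edges are retained; \code{part_of} and other
#' relationship types are deliberately ignored, and obsolete terms are absent.
#'
#' @slot terms character vector of canonical term ids.
#' @slot termName named character, term id -> human-readable name.
#' @slot termNamespace named character, term id -> one of "MFO","CCO","BPO".
#' @slot parents named list, term id -> character vector of is-a parents
#'   (empty for namespace roots).
#' @slot roots named character, namespace -> root term id.
#' @slot altIds named character, alternate id -> canonical id.
#'
#' @seealso [parseOBO()], [propagateTruePath()], [selectLabelSpace()]
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    termName = "character",
    termNamespace = "character",
    parents = "list",
    roots = "character",
    altIds = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  msg <- character(0)
  ids <- object@terms
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated term ids")
  if (!all(names(object@parents) == ids)) {
    msg <- c(msg, "parents must be named by terms, in order")
  }
  allPar <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allPar) && !all(allPar %in% ids)) {
    bad <- setdiff(allPar, ids)
    msg <- c(msg, paste0("parent term(s) not in DAG: ",
                         paste(head(bad, 3), collapse = ", ")))
  }
  # roots have no parents; non-roots have at least one in-namespace parent
  for (ns in names(object@roots)) {
    r <- object@roots[[ns]]
    if (length(object@parents[[r]]) != 0L) {
      msg <- c(msg, paste0("root ", r, " has parents"))
    }
  }
  nonroot <- setdiff(ids, object@roots)
  nPar <- lengths(object@parents[nonroot])
  if (any(nPar == 0L)) {
    msg <- c(msg, paste0("non-root term without parent: ",
                         nonroot[which(nPar == 0L)[1]]))
  }
  # acyclicity via igraph
  if (length(ids) > 1L) {
    g <- .dagIgraph(object)
    if (!igraph::is_dag(g)) {
      msg <- c(msg, "ontology graph contains a cycle")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Protein GO annotation set
#'
#' Maps protein ids to sets of GO term ids, with optional per-record evidence
#' codes. After [propagateTruePath()] every protein's term set is closed under
#' is-a ancestors (a consistent sub-graph of the DAG).
#'
#' @slot annotations named list, protein id -> character vector of term ids.
#' @slot evidence data.frame with columns protein_id, term_id, evidence_code
#'   (zero rows once propagation has discarded record-level provenance).
#' @slot propagated logical flag; TRUE after true-path propagation.
#'
#' @seealso [filterEvidence()], [propagateTruePath()], [encodeLabels()]
#' @export
setClass("AnnotationSet",
  representation(
    annotations = "list",
    evidence = "data.frame",
    propagated = "logical"
  ),
  prototype(
    evidence = data.frame(protein_id = character(0), term_id = character(0),
                          evidence_code = character(0)),
    propagated = FALSE
  )
)

setValidity("AnnotationSet", function(object) {
  if (is.null(names(object@annotations)) && length(object@annotations)) {
    return("annotations must be a named list (protein ids)")
  }
  if (anyDuplicated(names(object@annotations))) {
    return("duplicated protein ids")
  }
  TRUE
})

#' Ordered label space over one GO namespace
#'
#' The selected prediction targets for one subontology: an ordered term list
#' (topological order, lexicographic tie-break), the within-space transitive
#' ancestor relation, and optional per-term conditional information content.
#' Namespace roots are never included.
#'
#' @slot namespace one of "MFO","CCO","BPO".
#' @slot terms ordered character vector of term ids (positions 1..n_y).
#' @slot ancestorsInSpace list of integer vectors: position -> positions of
#'   all in-space ancestors (transitively closed, self excluded).
#' @slot ic numeric vector of per-term information content in bits (length 0
#'   until [informationContent()] has been attached).
#'
#' @seealso [selectLabelSpace()], [informationContent()], [propagateScoresMax()]
#' @export
setClass("LabelSpace",
  representation(
    namespace = "character",
    terms = "character",
    ancestorsInSpace = "list",
    ic = "numeric"
  ),
  prototype(ic = numeric(0))
)

setValidity("LabelSpace", function(object) {
  n <- length(object@terms)
  if (anyDuplicated(object@terms)) return("duplicated terms in label space")
  if (length(object@ancestorsInSpace) != n) {
    return("ancestorsInSpace must have one entry per term")
  }
  for (i in seq_len(n)) {
    a <- object@ancestorsInSpace[[i]]
    if (length(a) && (any(a < 1L) || any(a > n) || any(a == i))) {
      return("ancestorsInSpace entries must index other in-space terms")
    }
  }
  if (length(object@ic) && length(object@ic) != n) {
    return("ic must have one value per term")
  }
  if (length(object@ic) && any(object@ic < -1e-9, na.rm = TRUE)) {
    return("information content must be non-negative")
  }
  TRUE
})

#' Aligned multi-view dataset
#'
#' A roster of proteins with one feature matrix per view (rows aligned to the
#' roster), a binary multi-label target matrix Y, and optional cluster ids
#' used for homology-aware cross-validation. Views may have different widths,
#' which is why this is not a SummarizedExperiment.
#'
#' @slot roster ordered character vector of protein ids.
#' @slot views named list of numeric matrices, each m x n_xd with rownames
#'   equal to the roster.
#' @slot Y numeric matrix m x n_y (rownames = roster); binary 0/1 for GO
#'   label prediction, real-valued for regression targets.
#' @slot clusters named character, protein id -> cluster id (length 0 if
#'   unknown).
#'
#' @seealso [assembleDataset()], [clusterCVFolds()], [ltrFit()]
#' @export
setClass("MultiViewDataset",
  representation(
    roster = "character",
    views = "list",
    Y = "matrix",
    clusters = "character"
  ),
  prototype(clusters = character(0))
)

setValidity("MultiViewDataset", function(object) {
  m <- length(object@roster)
  if (anyDuplicated(object@roster)) return("duplicated protein ids in roster")
  if (length(object@views) == 0L) return("at least one view is required")
  if (is.null(names(object@views)) || anyDuplicated(names(object@views))) {
    return("views must be uniquely named")
  }
  for (nm in names(object@views)) {
    Xv <- object@views[[nm]]
    if (!is.matrix(Xv) || !is.numeric(Xv)) {
      return(paste0("view '", nm, "' is not a numeric matrix"))
    }
    if (nrow(Xv) != m) return(paste0("view '", nm, "' row count != roster"))
    if (!identical(rownames(Xv), object@roster)) {
      return(paste0("view '", nm, "' rows are not aligned to the roster"))
    }
    if (!all(is.finite(Xv))) return(paste0("view '", nm, "' has non-finite values"))
  }
  if (nrow(object@Y) != m) return("Y row count != roster")
  if (!all(is.finite(object@Y))) return("Y has non-finite entries")
  if (length(object@clusters)) {
    if (!all(object@roster %in% names(object@clusters))) {
      return("clusters must cover the roster")
    }
  }
  TRUE
})

#' Latent tensor reconstruction model
#'
#' Factorized multi-view polynomial regression. For each view d the factor
#' matrix P^(d) = V^(d) U^(d)' D^(d) is stored through its parts: U (per-feature
#' factors, unit-norm rows), the diagonal per-feature scales, and V (per-rank
#' factors, unit-norm rows). The CP core weights lambda and the output
#' projection Q (unit-norm columns) complete the model; activations A (inner)
#' and B (outer) are identity or ReLU.
#'
#' @slot U list of matrices n_xd x k_d, unit-norm rows.
#' @slot scaleD list of numeric vectors length n_xd (diagonal scales).
#' @slot V list of matrices n_t x k_d, unit-norm rows.
#' @slot lambda numeric vector length n_t (CP core weights, unconstrained sign).
#' @slot Q matrix n_y x n_t, unit-norm columns.
#' @slot activationA,activationB "identity" or "relu".
#'
#' @seealso [ltrModel()], [ltrForward()], [ltrFit()], [explicitWeightTensor()]
#' @export
setClass("LTRModel",
  representation(
    U = "list",
    scaleD = "list",
    V = "list",
    lambda = "numeric",
    Q = "matrix",
    activationA = "character",
    activationB = "character"
  )
)

setValidity("LTRModel", function(object) {
  nd <- length(object@U)
  if (length(object@V) != nd || length(object@scaleD) != nd) {
    return("U, V and scaleD must have one entry per view")
  }
  nt <- length(object@lambda)
  for (d in seq_len(nd)) {
    if (nrow(object@V[[d]]) != nt) return("V rows must equal length(lambda)")
    if (ncol(object@U[[d]]) != ncol(object@V[[d]])) {
      return("U and V must share the inner dimension k_d")
    }
    if (length(object@scaleD[[d]]) != nrow(object@U[[d]])) {
      return("scaleD length must equal the view dimension")
    }
    if (!all(is.finite(object@U[[d]])) || !all(is.finite(object@V[[d]])) ||
        !all(is.finite(object@scaleD[[d]]))) {
      return("non-finite model parameters")
    }
  }
  if (ncol(object@Q) != nt) return("Q must have n_t columns")
  if (!all(is.finite(object@lambda)) || !all(is.finite(object@Q))) {
    return("non-finite model parameters")
  }
  ok <- c(identity = TRUE, relu = TRUE)
  if (!(object@activationA %in% names(ok)) ||
      !(object@activationB %in% names(ok))) {
    return("activations must be 'identity' or 'relu'")
  }
  TRUE
})

#' Cluster-grouped cross-validation plan
#'
#' Per fold, the protein roster is partitioned into train / validation / test
#' such that no sequence cluster spans the (train+validation) side and the
#' test side, preserving homology separation.
#'
#' @slot folds list of lists with elements train, validation, test (character
#'   vectors of protein ids).
#' @slot nFolds integer.
#' @slot seed integer seed the plan was drawn with.
#' @export
setClass("FoldPlan",
  representation(folds = "list", nFolds = "integer", seed = "integer")
)

#' Autoencoder dimensionality reducer
#'
#' Fully connected autoencoder (ReLU between layers, linear output layers)
#' used to compress sparse binary fingerprints or PPI adjacency rows into
#' dense vectors. Weights are stored per layer; the first \code{nEncoder}
#' layers form the encoder.
#'
#' @slot W list of weight matrices (in_dim x out_dim per layer).
#' @slot b list of bias vectors.
#' @slot nEncoder integer; number of encoder layers.
#' @slot inputDim,targetDim integers.
#' @slot seed integer.
#' @slot lossTrajectory numeric; mean reconstruction loss per epoch (element 1
#'   is the pre-training loss).
#' @export
setClass("ReducerModel",
  representation(
    W = "list", b = "list", nEncoder = "integer",
    inputDim = "integer", targetDim = "integer",
    seed = "integer", lossTrajectory = "numeric"
  )
)

#' Protein-centric evaluation report
#'
#' CAFA-style metrics for one score matrix against one truth matrix.
#' All of fmax, wfmax, auprc, auroc, coverage lie in [0,1]; smin >= 0 bits.
#' Optimal thresholds are NA when no threshold produced a valid point.
#'
#' @slot fmax,tauFmax,wfmax,tauWfmax,smin,tauSmin,auprc,auroc,coverage numeric
#'   scalars.
#' @seealso [evaluateScores()]
#' @export
setClass("MetricsReport",
  representation(
    fmax = "numeric", tauFmax = "numeric",
    wfmax = "numeric", tauWfmax = "numeric",
    smin = "numeric", tauSmin = "numeric",
    auprc = "numeric", auroc = "numeric", coverage = "numeric"
  )
)

# internal: igraph of the DAG with edges child -> parent
.dagIgraph <- function(dag) {
  edges <- .dagEdges(dag)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = dag@terms))
}

# internal: two-column data.frame of (child, parent) is-a edges
.dagEdges <- function(dag) {
  np <- lengths(dag@parents)
  data.frame(
    child = rep(names(dag@parents), np),
    parent = unlist(dag@parents, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
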