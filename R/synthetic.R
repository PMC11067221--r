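## Synthetic study generator: toy is-a DAGs, planted low-rank LTR models,
## multi-view Gaussian/Bernoulli features, hierarchically consistent labels,
## cluster assignments and alignment hit tables -- every input the pipeline
## consumes, with no downloads.

.NAMESPACE_LONG <- c(MFO = "molecular_function", CCO = "cellular_component",
                     BPO = "biological_process")

#' Synthetic study configuration
#'
#' The defaults define the reference desk-scale study: 1000 proteins, two
#' 20-dimensional Gaussian views, a planted rank-4 model, a depth-3
#' branching-3 ontology (39 non-root terms), top-20\% per-term positives,
#' 5\% label noise and 80 sequence clusters.
#'
#' @param seed integer master seed.
#' @param m number of proteins.
#' @param viewDims integer vector of per-view feature dimensions.
#' @param nT planted CP rank.
#' @param dagDepth,dagBranching layered DAG shape below the single root.
#' @param multiParentProb probability that a non-root term gets a second
#'   parent from the layer above.
#' @param labelNoise per-(protein, term) flip probability applied to label
#'   frontiers, re-closed afterwards.
#' @param labelQuantile per-term score quantile above which a label is
#'   positive (0.8 = top 20\% of proteins positive per term).
#' @param nClusters number of sequence clusters.
#' @param binaryViews if TRUE, views are Bernoulli(0.1) indicators instead of
#'   standard Gaussians.
#' @param namespace subontology tag for the toy DAG.
#' @return list of settings.
#' @export
simControl <- function(seed = 1L, m = 1000L, viewDims = c(20L, 20L),
                       nT = 4L, dagDepth = 3L, dagBranching = 3L,
                       multiParentProb = 0.2, labelNoise = 0.05,
                       labelQuantile = 0.8, nClusters = 80L,
                       binaryViews = FALSE, namespace = "MFO") {
  stopifnot(dagDepth >= 1L, dagBranching >= 1L,
            labelNoise >= 0, labelNoise <= 1,
            labelQuantile > 0, labelQuantile <= 1,
            nClusters <= m)
  list(seed = as.integer(seed), m = as.integer(m),
       viewDims = as.integer(viewDims), nT = as.integer(nT),
       dagDepth = as.integer(dagDepth),
       dagBranching = as.integer(dagBranching),
       multiParentProb = multiParentProb, labelNoise = labelNoise,
       labelQuantile = labelQuantile, nClusters = as.integer(nClusters),
       binaryViews = binaryViews, namespace = namespace)
}

#' Generate a toy is-a ontology
#'
#' Single-root layered DAG: layer l holds branching^l terms, each with one
#' seeded-random parent in the layer above and, with probability
#' \code{multiParentProb}, a second parent. Valid input for every ontology
#' operation, and emittable as OBO text via [writeOBO()].
#'
#' @param cfg list from [simControl()] (uses dagDepth, dagBranching,
#'   multiParentProb, namespace, seed).
#' @return an [OntologyDAG-class].
#' @export
makeToyOntology <- function(cfg = simControl()) {
  .withSeed(cfg$seed, {
    ids <- "GO:0000001"
    parents <- list("GO:0000001" = character(0))
    prev <- ids
    counter <- 1L
    for (l in seq_len(cfg$dagDepth)) {
      layer <- character(0)
      for (k in seq_len(cfg$dagBranching^l)) {
        counter <- counter + 1L
        id <- sprintf("GO:%07d", counter)
        p <- if (length(prev) == 1L) prev else sample(prev, 1)
        ps <- p
        if (length(prev) > 1L && runif(1) < cfg$multiParentProb) {
          extra <- sample(setdiff(prev, p), 1)
          ps <- c(ps, extra)
        }
        parents[[id]] <- ps
        layer <- c(layer, id)
      }
      prev <- layer
      ids <- c(ids, layer)
    }
    ns <- setNames(rep(cfg$namespace, length(ids)), ids)
    nm <- setNames(paste0("synthetic term ", seq_along(ids)), ids)
    new("OntologyDAG", terms = ids, termName = nm, termNamespace = ns,
        parents = parents[ids],
        roots = setNames("GO:0000001", cfg$namespace),
        altIds = character(0))
  })
}

#' Write an ontology as OBO 1.2 text
#'
#' Inverse of [parseOBO()] on the tags it honors; re-parsing reproduces the
#' edge set and namespaces exactly.
#'
#' @param dag an [OntologyDAG-class].
#' @param file path.
#' @export
writeOBO <- function(dag, file) {
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (id in dag@terms) {
    out <- c(out, "", "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag@termName[[id]]),
             paste0("namespace: ", .NAMESPACE_LONG[[dag@termNamespace[[id]]]]))
    for (p in dag@parents[[id]]) {
      out <- c(out, paste0("is_a: ", p, " ! ", dag@termName[[p]]))
    }
  }
  writeLines(out, file)
  invisible(file)
}

#' Label space spanning all non-root terms of a namespace
#'
#' Used for synthetic studies where every generated term is a target
#' regardless of annotation frequency.
#'
#' @param dag an [OntologyDAG-class].
#' @param namespace subontology tag.
#' @return a [LabelSpace-class].
#' @export
labelSpaceFromDAG <- function(dag, namespace = names(goRoots(dag))[1]) {
  nsTerms <- dag@terms[dag@termNamespace == namespace]
  terms <- setdiff(.topoOrder(dag, nsTerms), dag@roots[[namespace]])
  anc <- .ancestorList(dag)
  idx <- setNames(seq_along(terms), terms)
  ancSpace <- lapply(terms, function(t) unname(idx[intersect(anc[[t]], terms)]))
  new("LabelSpace", namespace = namespace, terms = terms,
      ancestorsInSpace = ancSpace, ic = numeric(0))
}

#' Plant a ground-truth LTR model
#'
#' Constraints hold exactly; lambda is drawn away from zero
#' (0.5 <= |lambda_t| <= 1.5, random signs) so the planted signal is
#' identifiable.
#'
#' @param cfg list from [simControl()] (uses viewDims, nT, seed).
#' @param nY output dimension (e.g. the label-space size).
#' @param activationA,activationB activations of the planted model.
#' @return an [LTRModel-class].
#' @export
plantModel <- function(cfg = simControl(), nY,
                       activationA = "identity", activationB = "identity") {
  .withSeed(cfg$seed + 17L, {
    nd <- length(cfg$viewDims)
    nt <- cfg$nT
    U <- vector("list", nd); V <- vector("list", nd); sc <- vector("list", nd)
    for (d in seq_len(nd)) {
      k <- min(nt, cfg$viewDims[d])
      U[[d]] <- .unitRows(matrix(rnorm(cfg$viewDims[d] * k),
                                 cfg$viewDims[d], k))
      V[[d]] <- .unitRows(matrix(rnorm(nt * k), nt, k))
      sc[[d]] <- runif(cfg$viewDims[d], 0.5, 1.5) / sqrt(cfg$viewDims[d])
    }
    lambda <- runif(nt, 0.5, 1.5) * sample(c(-1, 1), nt, replace = TRUE)
    Q <- .unitCols(matrix(rnorm(nY * nt), nY, nt))
    new("LTRModel", U = U, scaleD = sc, V = V, lambda = lambda, Q = Q,
        activationA = activationA, activationB = activationB)
  })
}

#' Sample a multi-view dataset from a planted model
#'
#' Views are drawn i.i.d. (standard normal, or Bernoulli(0.1) for binary
#' views); the planted model's raw scores are min-max scaled to [0,1] per
#' term, made hierarchically consistent by [propagateScoresMax()], and
#' thresholded at the per-term \code{labelQuantile}; labels are then closed
#' under ancestors. Optional label noise flips positive frontier terms off
#' and negative terms on (followed by re-closure), so Y is ancestor-closed by
#' construction. Cluster ids come from [simulateClusters()].
#'
#' @param cfg list from [simControl()].
#' @param truth an [LTRModel-class] (e.g. from [plantModel()]) with
#'   \code{nY = length(goTerms(space))}.
#' @param space the toy [LabelSpace-class] (from [labelSpaceFromDAG()]).
#' @return a [MultiViewDataset-class].
#' @export
sampleMultiview <- function(cfg, truth, space) {
  nY <- length(space@terms)
  stopifnot(nrow(truth@Q) == nY)
  ids <- sprintf("P%04d", seq_len(cfg$m))
  views <- .withSeed(cfg$seed + 29L, {
    lapply(seq_along(cfg$viewDims), function(d) {
      X <- if (cfg$binaryViews) {
        matrix(rbinom(cfg$m * cfg$viewDims[d], 1, 0.1),
               cfg$m, cfg$viewDims[d])
      } else {
        matrix(rnorm(cfg$m * cfg$viewDims[d]), cfg$m, cfg$viewDims[d])
      }
      dimnames(X) <- list(ids, paste0("f", seq_len(cfg$viewDims[d])))
      X
    })
  })
  names(views) <- paste0("view", seq_along(views))

  raw <- ltrPredict(truth, views)
  # per-term min-max scaling so every term has positives below quantile 1
  rng <- apply(raw, 2, range)
  span <- rng[2, ] - rng[1, ]
  degenerate <- span < .Machine$double.eps
  if (any(degenerate)) {
    message("sampleMultiview: ", sum(degenerate),
            " term(s) with constant scores -> all-zero label column")
    span[degenerate] <- 1
  }
  S <- sweep(sweep(raw, 2, rng[1, ]), 2, span, "/")
  S <- propagateScoresMax(S, space)
  thr <- vapply(seq_len(nY), function(j) {
    if (degenerate[j]) Inf else quantile(S[, j], cfg$labelQuantile,
                                         names = FALSE, type = 7)
  }, numeric(1))
  Y <- matrix(0, cfg$m, nY, dimnames = list(ids, space@terms))
  Y[sweep(S, 2, thr, ">=")] <- 1
  Y <- .closeRows(Y, space)

  if (cfg$labelNoise > 0) {
    Y <- .withSeed(cfg$seed + 31L, .applyLabelNoise(Y, space, cfg$labelNoise))
  }

  clusters <- simulateClusters(cfg$m, cfg$nClusters, cfg$seed + 37L)
  names(clusters) <- ids
  assembleDataset(views, Y, ids, clusters = clusters)
}

# ancestor-closure of every row of a binary label matrix
.closeRows <- function(Y, space) {
  n <- ncol(Y)
  for (j in seq_len(n)) {
    anc <- space@ancestorsInSpace[[j]]
    if (length(anc)) {
      pos <- Y[, j] == 1
      if (any(pos)) Y[pos, anc] <- 1
    }
  }
  Y
}

# frontier 1->0 flips and 0->1 flips with re-closure
.applyLabelNoise <- function(Y, space, p) {
  n <- ncol(Y)
  desc <- vector("list", n)
  for (i in seq_len(n)) {
    for (a in space@ancestorsInSpace[[i]]) desc[[a]] <- c(desc[[a]], i)
  }
  for (i in seq_len(nrow(Y))) {
    pos <- which(Y[i, ] == 1)
    frontier <- pos[vapply(pos, function(j) {
      !length(desc[[j]]) || !any(Y[i, desc[[j]]] == 1)
    }, logical(1))]
    drop <- frontier[runif(length(frontier)) < p]
    if (length(drop)) Y[i, drop] <- 0
    neg <- which(Y[i, ] == 0)
    add <- neg[runif(length(neg)) < p]
    if (length(add)) {
      Y[i, add] <- 1
      for (j in add) {
        anc <- space@ancestorsInSpace[[j]]
        if (length(anc)) Y[i, anc] <- 1
      }
    }
  }
  Y
}

#' Seeded cluster assignment
#'
#' Multinomial assignment of m proteins to n clusters; every cluster is
#' guaranteed non-empty.
#'
#' @param m number of proteins.
#' @param nClusters number of clusters (<= m).
#' @param seed integer.
#' @return character vector of cluster ids, length m.
#' @export
simulateClusters <- function(m, nClusters, seed = 1L) {
  stopifnot(nClusters <= m)
  .withSeed(seed, {
    base <- c(seq_len(nClusters),
              if (m > nClusters) sample.int(nClusters, m - nClusters,
                                            replace = TRUE))
    sprintf("C%03d", sample(base))
  })
}

#' Synthetic alignment hit table
#'
#' Random tabular hits from each query to training subjects: identities
#' uniform in [25, 100], e-values log-uniform in [1e-10, 1e-1] (so some hits
#' exceed the conventional 0.001 cutoff and exercise the filter), bit scores
#' increasing with identity.
#'
#' @param queryIds,subjectIds protein id vectors.
#' @param hitsPerQuery expected hits per query.
#' @param seed integer.
#' @return data.frame in 12-column tabular layout.
#' @export
simulateHitTable <- function(queryIds, subjectIds, hitsPerQuery = 3L,
                             seed = 1L) {
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(queryIds, function(q) {
      k <- max(0L, rpois(1, hitsPerQuery))
      if (!k) return(NULL)
      subj <- sample(subjectIds, min(k, length(subjectIds)))
      pid <- round(runif(length(subj), 25, 100), 1)
      data.frame(query = q, subject = subj, pident = pid,
                 length = sample(100:400, length(subj), replace = TRUE),
                 mismatch = sample(0:50, length(subj), replace = TRUE),
                 gapopen = sample(0:5, length(subj), replace = TRUE),
                 qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                 evalue = 10^runif(length(subj), -10, -1),
                 bitscore = round(pid * 2 + runif(length(subj), 0, 20), 1),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) rows <- data.frame()
    rows
  })
}

#' Write a complete fixture bundle
#'
#' Emits, under \code{dir}: the toy ontology (\code{ontology.obo}), the
#' annotation TSV derived from the generated labels (evidence code EXP),
#' per-view feature tables, the cluster TSV, a synthetic 12-column alignment
#' hit table and a JSON manifest recording the seed and configuration. The
#' bundle is exactly what the pipeline commands consume.
#'
#' @param cfg list from [simControl()].
#' @param dir writable directory (created if needed).
#' @return named list of file paths (plus the in-memory study objects as
#'   attribute "study").
#' @export
writeFixtureBundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- makeToyOntology(cfg)
  space <- labelSpaceFromDAG(dag, cfg$namespace)
  truth <- plantModel(cfg, nY = length(goTerms(space)))
  dataset <- sampleMultiview(cfg, truth, space)

  paths <- list(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    views = file.path(dir, paste0(viewNames(dataset), ".tsv")),
    clusters = file.path(dir, "clusters.tsv"),
    hits = file.path(dir, "hits.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  writeOBO(dag, paths$obo)

  Y <- labelMatrix(dataset)
  ann <- character(0)
  for (i in seq_len(nrow(Y))) {
    terms <- colnames(Y)[Y[i, ] == 1]
    if (length(terms)) {
      ann <- c(ann, paste(rownames(Y)[i], terms, "EXP", sep = "\t"))
    }
  }
  writeLines(c("# protein_id\tterm_id\tevidence_code", ann),
             paths$annotations)

  for (d in seq_along(paths$views)) {
    writeFeatureTable(getView(dataset, viewNames(dataset)[d]),
                      paths$views[d])
  }
  writeClusters(clusterIds(dataset), paths$clusters)

  ids <- roster(dataset)
  nQ <- max(1L, round(length(ids) * 0.2))
  hits <- simulateHitTable(ids[seq_len(nQ)], ids[-seq_len(nQ)],
                           seed = cfg$seed + 41L)
  hitLines <- if (nrow(hits)) {
    apply(hits, 1, function(r) paste(trimws(r), collapse = "\t"))
  } else character(0)
  writeLines(hitLines, paths$hits)

  jsonlite::write_json(
    list(seed = cfg$seed, config = cfg,
         nTerms = length(goTerms(space)), m = cfg$m),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  attr(paths, "study") <- list(dag = dag, space = space, truth = truth,
                               dataset = dataset)
  paths
}
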