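## Feature views: fingerprint indicator matrices, PPI adjacency, autoencoder
## dimensionality reduction, file readers, cluster-grouped CV splits, and
## multi-view dataset assembly.

#' Binary fingerprint indicator matrix
#'
#' Expands per-protein feature-id sets (e.g. InterPro domain/family hits)
#' into a 0/1 matrix over a fixed vocabulary. The vocabulary should be built
#' from the training split only; feature ids outside it are dropped (default,
#' with a message) or raise an error.
#'
#' @param records named list, protein id -> character vector of feature ids.
#' @param vocabulary ordered character vector of feature ids (columns).
#' @param onUnknown "drop" (default) or "error".
#' @return binary matrix (length(records) x length(vocabulary)) with dimnames.
#' @export
binaryFingerprintMatrix <- function(records, vocabulary,
                                    onUnknown = c("drop", "error")) {
  onUnknown <- match.arg(onUnknown)
  if (!length(vocabulary)) stop("vocabulary is empty", call. = FALSE)
  unknown <- setdiff(unique(unlist(records, use.names = FALSE)), vocabulary)
  if (length(unknown)) {
    if (onUnknown == "error") {
      stop("feature id(s) outside vocabulary: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    message("binaryFingerprintMatrix: dropped ", length(unknown),
            " unknown feature id(s)")
  }
  X <- matrix(0, nrow = length(records), ncol = length(vocabulary),
              dimnames = list(names(records), vocabulary))
  for (i in seq_along(records)) {
    X[i, vocabulary %in% records[[i]]] <- 1
  }
  X
}

#' PPI adjacency matrix over a fixed roster
#'
#' Builds the symmetric m x m adjacency matrix of a protein-protein
#' interaction graph. Edges touching proteins outside the roster are ignored
#' and self-loops dropped (both with a message). Proteins absent from the
#' network get zero rows: no interaction evidence.
#'
#' @param edges data.frame with columns p1, p2 and optionally weight.
#' @param rosterIds ordered protein ids (rows/columns).
#' @return symmetric numeric matrix with dimnames.
#' @export
ppiAdjacency <- function(edges, rosterIds) {
  A <- matrix(0, length(rosterIds), length(rosterIds),
              dimnames = list(rosterIds, rosterIds))
  if (nrow(edges)) {
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    inR <- edges$p1 %in% rosterIds & edges$p2 %in% rosterIds
    if (any(!inR)) {
      message("ppiAdjacency: ignored ", sum(!inR),
              " edge(s) outside the roster")
    }
    self <- edges$p1 == edges$p2
    if (any(self & inR)) {
      message("ppiAdjacency: dropped ", sum(self & inR), " self-loop(s)")
    }
    keep <- inR & !self
    for (k in which(keep)) {
      A[edges$p1[k], edges$p2[k]] <- w[k]
      A[edges$p2[k], edges$p1[k]] <- w[k]
    }
  }
  A
}

#' Settings for the autoencoder reducer
#'
#' @param hidden integer vector of encoder hidden widths (mirrored in the
#'   decoder). The conventional full-scale setting is c(4096, 2048); tests
#'   use much smaller widths.
#' @param epochs,batchSize,stepSize optimizer settings (Adam).
#' @param loss "mse" (default) or "bce" for binary inputs.
#' @return list of settings.
#' @export
reducerControl <- function(hidden = c(4096L, 2048L), epochs = 100L,
                           batchSize = 64L, stepSize = 1e-3,
                           loss = c("mse", "bce")) {
  list(hidden = as.integer(hidden), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), stepSize = stepSize,
       loss = match.arg(loss))
}

#' Train an autoencoder dimensionality reducer
#'
#' Fully connected autoencoder with ReLU between layers (embedding and
#' reconstruction layers are linear), trained by mini-batch Adam on the
#' reconstruction loss. Used to compress sparse binary fingerprint vectors or
#' PPI adjacency rows to dense vectors (conventionally of size 1000).
#'
#' @param X numeric matrix (m x n_xd) with protein rownames.
#' @param targetDim embedding width (< ncol(X)).
#' @param settings list from [reducerControl()].
#' @param seed integer; training is deterministic given the seed.
#' @return a [ReducerModel-class] with the per-epoch loss trajectory
#'   (element 1 = loss at initialization).
#' @export
trainReducer <- function(X, targetDim, settings = reducerControl(),
                         seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  if (targetDim >= ncol(X)) {
    # allowed (used for overcomplete sanity fits) but worth noting
    message("trainReducer: targetDim >= input width")
  }
  widths <- c(ncol(X), settings$hidden, as.integer(targetDim),
              rev(settings$hidden), ncol(X))
  nEnc <- length(settings$hidden) + 1L
  nLay <- length(widths) - 1L

  model <- .withSeed(seed, {
    W <- vector("list", nLay); b <- vector("list", nLay)
    for (l in seq_len(nLay)) {
      # He-style init keeps ReLU activations in range
      W[[l]] <- matrix(rnorm(widths[l] * widths[l + 1], 0,
                             sqrt(2 / widths[l])), widths[l], widths[l + 1])
      b[[l]] <- numeric(widths[l + 1])
    }
    list(W = W, b = b)
  })

  fwd <- function(W, b, Xb) {
    acts <- vector("list", nLay + 1L)
    pres <- vector("list", nLay)
    acts[[1]] <- Xb
    for (l in seq_len(nLay)) {
      pre <- acts[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(Xb))
      pres[[l]] <- pre
      # ReLU after every layer except the embedding and the output layer
      acts[[l + 1]] <- if (l == nEnc || l == nLay) pre else .relu(pre)
    }
    list(acts = acts, pres = pres)
  }
  lossOf <- function(W, b, Xb) {
    R <- fwd(W, b, Xb)$acts[[nLay + 1L]]
    if (settings$loss == "bce") {
      P <- 1 / (1 + exp(-R))
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      -mean(Xb * log(P) + (1 - Xb) * log(1 - P))
    } else {
      mean((R - Xb)^2)
    }
  }

  W <- model$W; b <- model$b
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(x) x * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8; stepN <- 0L
  traj <- lossOf(W, b, X)

  .withSeed(seed + 1L, {
    for (ep in seq_len(settings$epochs)) {
      ord <- sample.int(nrow(X))
      batches <- split(ord, ceiling(seq_along(ord) / settings$batchSize))
      for (bi in batches) {
        Xb <- X[bi, , drop = FALSE]
        f <- fwd(W, b, Xb)
        R <- f$acts[[nLay + 1L]]
        if (settings$loss == "bce") {
          P <- 1 / (1 + exp(-R))
          delta <- (P - Xb) / length(Xb)
        } else {
          delta <- 2 * (R - Xb) / length(Xb)
        }
        for (l in rev(seq_len(nLay))) {
          gW <- crossprod(f$acts[[l]], delta)
          gB <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            if (!((l - 1L) == nEnc || (l - 1L) == nLay)) {
              delta <- delta * .reluGrad(f$pres[[l - 1L]])
            }
          }
          stepN2 <- stepN + 1L
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
          corr1 <- 1 - beta1^stepN2; corr2 <- 1 - beta2^stepN2
          W[[l]] <- W[[l]] - settings$stepSize * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + epsA)
          b[[l]] <- b[[l]] - settings$stepSize * (mB[[l]] / corr1) /
            (sqrt(vB[[l]] / corr2) + epsA)
        }
        stepN <- stepN + 1L
      }
      l <- lossOf(W, b, X)
      if (!is.finite(l)) {
        stop("training error: non-finite reconstruction loss at epoch ", ep,
             call. = FALSE)
      }
      traj <- c(traj, l)
    }
  })

  new("ReducerModel", W = W, b = b, nEncoder = nEnc,
      inputDim = ncol(X), targetDim = as.integer(targetDim),
      seed = as.integer(seed), lossTrajectory = traj)
}

#' Apply a trained reducer's encoder
#'
#' @param model a [ReducerModel-class].
#' @param X matrix whose width matches the model input width.
#' @return matrix (nrow(X) x targetDim), rownames preserved.
#' @export
reduceView <- function(model, X) {
  if (ncol(X) != model@inputDim) {
    stop("shape error: input width ", ncol(X), " != model input width ",
         model@inputDim, call. = FALSE)
  }
  H <- X
  for (l in seq_len(model@nEncoder)) {
    H <- H %*% model@W[[l]] + rep(model@b[[l]], each = nrow(H))
    if (l < model@nEncoder) H <- .relu(H)
  }
  rownames(H) <- rownames(X)
  H
}

#' Read a tab-separated feature table
#'
#' Header row of column names; first column \code{protein_id}; remaining
#' cells numeric. Row order in the file becomes the roster order.
#'
#' @param file path.
#' @return numeric matrix with protein rownames.
#' @export
readFeatureTable <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("parse error: empty feature table",
                               call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "protein_id") {
    stop("parse error line 1: first column must be 'protein_id'",
         call. = FALSE)
  }
  nCol <- length(header)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- character(length(body))
  X <- matrix(NA_real_, length(body), nCol - 1L,
              dimnames = list(NULL, header[-1]))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != nCol) {
      stop("parse error line ", i + 1L, ": expected ", nCol,
           " columns, found ", length(row), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      stop("parse error line ", i + 1L, ": non-numeric cell", call. = FALSE)
    }
    ids[i] <- row[1]
    X[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    stop("parse error: duplicated protein id '", ids[anyDuplicated(ids)],
         "'", call. = FALSE)
  }
  rownames(X) <- ids
  X
}

#' Write a feature table (inverse of [readFeatureTable()])
#'
#' @param X numeric matrix with protein rownames and feature colnames.
#' @param file path.
#' @export
writeFeatureTable <- function(X, file) {
  header <- paste(c("protein_id", colnames(X)), collapse = "\t")
  rows <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], format(X[i, ], digits = 12, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
}

#' Read a cluster assignment file
#'
#' Two tab-separated columns (representative, member) as emitted by sequence
#' clustering tools; the representative id doubles as the cluster id.
#'
#' @param file path.
#' @return named character, protein id -> cluster id.
#' @export
readClusters <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("parse error line ", which(lengths(parts) != 2L)[1],
         ": expected 2 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  if (anyDuplicated(m[, 2])) {
    stop("parse error: protein '", m[anyDuplicated(m[, 2]), 2],
         "' assigned to more than one cluster", call. = FALSE)
  }
  setNames(m[, 1], m[, 2])
}

#' Write a cluster assignment file
#'
#' @param clusters named character, protein id -> cluster id.
#' @param file path.
#' @export
writeClusters <- function(clusters, file) {
  writeLines(paste(unname(clusters), names(clusters), sep = "\t"), file)
}

#' Cluster-grouped cross-validation folds
#'
#' Sequence clusters (not proteins) are shuffled with the seed and dealt
#' round-robin into \code{nFolds} groups; fold i uses group i's proteins as
#' the test set (about 1/nFolds of the clusters). From the remaining
#' training-side clusters, whole clusters are drawn until at least
#' \code{valFraction} of the training proteins form the validation set. No
#' cluster ever spans the train+validation side and the test side, preserving
#' homology separation.
#'
#' @param clusters named character, protein id -> cluster id (must cover the
#'   roster).
#' @param rosterIds ordered protein ids.
#' @param nFolds number of folds (>= 2).
#' @param testFraction informational; must equal 1/nFolds within rounding
#'   (dealing governs the test share).
#' @param valFraction fraction of training-side proteins carved out
#'   cluster-wise for validation.
#' @param seed integer.
#' @return a [FoldPlan-class].
#' @export
clusterCVFolds <- function(clusters, rosterIds, nFolds = 10L,
                           testFraction = 1 / nFolds, valFraction = 0.10,
                           seed = 1L) {
  nFolds <- as.integer(nFolds)
  stopifnot(nFolds >= 2L)
  missing <- setdiff(rosterIds, names(clusters))
  if (length(missing)) {
    stop("configuration error: proteins without cluster id: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (abs(testFraction - 1 / nFolds) > 0.5 / nFolds) {
    stop("configuration error: testFraction must be about 1/nFolds ",
         "(clusters are dealt into nFolds groups)", call. = FALSE)
  }
  cl <- clusters[rosterIds]
  ids <- sort(unique(unname(cl)))
  if (length(ids) < nFolds) {
    stop("configuration error: fewer clusters (", length(ids),
         ") than folds (", nFolds, ")", call. = FALSE)
  }
  shuffled <- .withSeed(seed, sample(ids))
  group <- rep(seq_len(nFolds), length.out = length(shuffled))
  foldList <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    testCl <- shuffled[group == f]
    trainCl <- setdiff(shuffled, testCl)
    testIds <- rosterIds[cl %in% testCl]
    trainSide <- rosterIds[cl %in% trainCl]
    valTarget <- valFraction * length(trainSide)
    valCl <- character(0)
    if (valTarget > 0) {
      ordCl <- .withSeed(seed * 1000L + f, sample(trainCl))
      got <- 0L
      for (cid in ordCl) {
        if (got >= valTarget) break
        valCl <- c(valCl, cid)
        got <- got + sum(cl[trainSide] == cid)
      }
    }
    valIds <- trainSide[cl[trainSide] %in% valCl]
    trainIds <- setdiff(trainSide, valIds)
    foldList[[f]] <- list(train = trainIds, validation = valIds,
                          test = testIds)
  }
  new("FoldPlan", folds = foldList, nFolds = nFolds, seed = as.integer(seed))
}

#' Assemble an aligned multi-view dataset
#'
#' Re-indexes every view and the label matrix to the roster order and
#' verifies alignment; any protein missing from a view is an error naming
#' both the protein and the view.
#'
#' @param views named list of numeric matrices with protein rownames.
#' @param Y binary label matrix with protein rownames.
#' @param rosterIds ordered protein ids.
#' @param clusters optional named character protein id -> cluster id.
#' @return a [MultiViewDataset-class].
#' @export
assembleDataset <- function(views, Y, rosterIds, clusters = NULL) {
  stopifnot(is.list(views), !is.null(names(views)))
  outViews <- list()
  for (nm in names(views)) {
    Xv <- views[[nm]]
    missing <- setdiff(rosterIds, rownames(Xv))
    if (length(missing)) {
      stop("assembly error: protein '", missing[1], "' missing from view '",
           nm, "'", call. = FALSE)
    }
    outViews[[nm]] <- Xv[rosterIds, , drop = FALSE]
  }
  missingY <- setdiff(rosterIds, rownames(Y))
  if (length(missingY)) {
    stop("assembly error: protein '", missingY[1],
         "' missing from the label matrix", call. = FALSE)
  }
  Y2 <- Y[rosterIds, , drop = FALSE]
  cl <- if (is.null(clusters)) character(0) else {
    missC <- setdiff(rosterIds, names(clusters))
    if (length(missC)) {
      stop("assembly error: protein '", missC[1], "' has no cluster id",
           call. = FALSE)
    }
    clusters[rosterIds]
  }
  new("MultiViewDataset", roster = rosterIds, views = outViews, Y = Y2,
      clusters = cl)
}

#' Append a constant intercept feature to every view
#'
#' Adds a unit coordinate to each view. Under the pure cross-view product
#' model this recovers all lower-degree polynomial terms (per-view linear
#' effects and per-label intercepts) exactly, the standard factorization
#' machine device; without it the model cannot express per-term base rates.
#'
#' @param dataset a [MultiViewDataset-class].
#' @return a [MultiViewDataset-class] with one extra unit column per view.
#' @export
addInterceptFeature <- function(dataset) {
  views <- lapply(viewList(dataset), function(X) {
    X2 <- cbind(X, 1)
    colnames(X2) <- c(colnames(X), ".intercept")
    X2
  })
  assembleDataset(views, labelMatrix(dataset), roster(dataset),
                  clusters = clusterIds(dataset))
}

#' Subset a multi-view dataset by protein ids
#'
#' @param dataset a [MultiViewDataset-class].
#' @param ids protein ids to keep (order preserved as given).
#' @return a [MultiViewDataset-class].
#' @export
subsetDataset <- function(dataset, ids) {
  stopifnot(all(ids %in% roster(dataset)))
  views <- lapply(viewList(dataset), function(v) v[ids, , drop = FALSE])
  cl <- clusterIds(dataset)
  assembleDataset(views, labelMatrix(dataset)[ids, , drop = FALSE], ids,
                  clusters = cl)
}
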