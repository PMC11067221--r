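## Latent tensor reconstruction: factorized multi-view polynomial regression
## with two-level factor decomposition, optional ReLU activations, unit-norm
## constraints enforced by projection, and a mini-batch gradient trainer.
##
## Forward map per sample (view d, inner activation A, outer activation B):
##   z^(d) = scale^(d) * x^(d)
##   a^(d) = A(U^(d)' z^(d))          length k_d
##   h^(d) = B(V^(d) a^(d))           length n_t
##   s     = lambda * h^(1) * ... * h^(n_d)   (elementwise)
##   yhat  = Q s                      length n_y
## With identity activations this equals <T, x^(1) (x) ... (x) x^(n_d)>
## contracted against Q, where T is the CP tensor of explicitWeightTensor().

#' Training configuration for the LTR model
#'
#' @param nT CP rank n_t (number of rank-one components).
#' @param kD inner factor dimension per view; a single integer is recycled.
#'   Default NULL = min(nT, view dim), fixed at model initialization.
#' @param cLambda regularization weight on lambda (C_lambda >= 0).
#' @param batchSize mini-batch size.
#' @param epochs number of training epochs.
#' @param stepSize optimizer step size.
#' @param optimizer "adam" (default), "momentum" or "sgd".
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param tolerance feasibility tolerance for the unit-norm constraints.
#' @return list of class settings used by [ltrModel()] and [ltrFit()].
#' @export
ltrControl <- function(nT = 8L, kD = NULL, cLambda = 0, batchSize = 128L,
                       epochs = 100L, stepSize = 1e-3,
                       optimizer = c("adam", "momentum", "sgd"),
                       seed = 1L, tolerance = 1e-6) {
  stopifnot(nT >= 1L, cLambda >= 0, batchSize >= 1L, epochs >= 0L,
            stepSize > 0)
  list(nT = as.integer(nT), kD = kD, cLambda = cLambda,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       stepSize = stepSize, optimizer = match.arg(optimizer),
       seed = as.integer(seed), tolerance = tolerance)
}

#' Initialize an LTR model
#'
#' Factors are drawn from a seeded Gaussian and projected onto the unit-norm
#' constraint set; lambda starts small positive; per-feature scales start at
#' 1/sqrt(n_xd) so view activations are O(1) for standardized features.
#'
#' @param viewDims integer vector of per-view feature dimensions n_xd.
#' @param nY output dimension (number of labels).
#' @param cfg list from [ltrControl()].
#' @param activationA,activationB "identity" or "relu" (inner / outer
#'   activation).
#' @return an [LTRModel-class].
#' @export
ltrModel <- function(viewDims, nY, cfg = ltrControl(),
                     activationA = c("identity", "relu"),
                     activationB = c("identity", "relu")) {
  activationA <- match.arg(activationA)
  activationB <- match.arg(activationB)
  stopifnot(all(viewDims >= 1L), nY >= 1L)
  nd <- length(viewDims)
  nt <- cfg$nT
  kD <- if (is.null(cfg$kD)) pmin(nt, viewDims) else
    rep_len(as.integer(cfg$kD), nd)
  if (any(kD > viewDims)) {
    message("ltrModel: k_d exceeds the view dimension for view(s) ",
            paste(which(kD > viewDims), collapse = ", "))
  }
  model <- .withSeed(cfg$seed, {
    U <- vector("list", nd); V <- vector("list", nd); sc <- vector("list", nd)
    for (d in seq_len(nd)) {
      U[[d]] <- matrix(rnorm(viewDims[d] * kD[d]), viewDims[d], kD[d])
      V[[d]] <- matrix(rnorm(nt * kD[d]), nt, kD[d])
      sc[[d]] <- rep(1 / sqrt(viewDims[d]), viewDims[d])
    }
    lambda <- runif(nt, 0.05, 0.15)
    Q <- matrix(rnorm(nY * nt), nY, nt)
    new("LTRModel", U = U, scaleD = sc, V = V, lambda = lambda, Q = Q,
        activationA = activationA, activationB = activationB)
  })
  projectConstraints(model, seed = cfg$seed)
}

#' Project a model onto its norm constraints
#'
#' Rescales every row of each V^(d) and U^(d) and every column of Q to unit
#' Euclidean norm. Zero rows/columns are replaced by a seeded random unit
#' vector. Idempotent on feasible models.
#'
#' @param model an [LTRModel-class].
#' @param seed seed for the zero-row replacement draw.
#' @return a feasible [LTRModel-class].
#' @export
projectConstraints <- function(model, seed = 0L) {
  for (d in seq_along(model@U)) {
    model@U[[d]] <- .unitRows(model@U[[d]], seed = seed + d)
    model@V[[d]] <- .unitRows(model@V[[d]], seed = seed + 100L + d)
  }
  model@Q <- .unitCols(model@Q, seed = seed + 200L)
  model
}

#' Maximum constraint residual
#'
#' Largest absolute deviation from 1 of any constrained row/column norm.
#'
#' @param model an [LTRModel-class].
#' @return non-negative scalar.
#' @export
constraintResidual <- function(model) {
  res <- 0
  for (d in seq_along(model@U)) {
    res <- max(res, abs(sqrt(rowSums(model@U[[d]]^2)) - 1),
               abs(sqrt(rowSums(model@V[[d]]^2)) - 1))
  }
  max(res, abs(sqrt(colSums(model@Q^2)) - 1))
}

# batched forward pass; views: list of (b x n_xd) matrices.
# Returns intermediates needed by the backward pass.
.ltrForwardBatch <- function(model, views, keep = FALSE) {
  nd <- length(model@U)
  b <- nrow(views[[1]])
  nt <- length(model@lambda)
  Z <- vector("list", nd); Apre <- vector("list", nd)
  Aact <- vector("list", nd); Hpre <- vector("list", nd)
  H <- vector("list", nd)
  G <- matrix(1, b, nt)
  for (d in seq_len(nd)) {
    if (ncol(views[[d]]) != nrow(model@U[[d]])) {
      stop("shape error in view ", d, ": expected width ",
           nrow(model@U[[d]]), ", got ", ncol(views[[d]]), call. = FALSE)
    }
    Z[[d]] <- views[[d]] * rep(model@scaleD[[d]], each = b)
    Apre[[d]] <- Z[[d]] %*% model@U[[d]]
    Aact[[d]] <- .activate(Apre[[d]], model@activationA)
    Hpre[[d]] <- Aact[[d]] %*% t(model@V[[d]])
    H[[d]] <- .activate(Hpre[[d]], model@activationB)
    G <- G * H[[d]]
  }
  S <- G * rep(model@lambda, each = b)
  Yhat <- S %*% t(model@Q)
  if (keep) list(Yhat = Yhat, Z = Z, Apre = Apre, Aact = Aact,
                 Hpre = Hpre, H = H, G = G, S = S)
  else Yhat
}

#' Forward evaluation on one sample
#'
#' @param model an [LTRModel-class].
#' @param x list of n_d numeric vectors, one per view.
#' @return numeric vector of length n_y.
#' @export
ltrForward <- function(model, x) {
  stopifnot(length(x) == length(model@U))
  views <- lapply(x, function(v) matrix(v, nrow = 1))
  drop(.ltrForwardBatch(model, views))
}

#' Predict scores for a dataset
#'
#' Batched evaluation of the forward map; identical to per-sample evaluation.
#'
#' @param model an [LTRModel-class].
#' @param newdata a [MultiViewDataset-class] or a list of aligned view
#'   matrices.
#' @param clip if TRUE, clip scores into [0,1] (appropriate when training
#'   targets are binary labels under squared error); default FALSE.
#' @return score matrix (m x n_y), rownames from the roster when available.
#' @export
ltrPredict <- function(model, newdata, clip = FALSE) {
  views <- if (is(newdata, "MultiViewDataset")) viewList(newdata)
  else newdata
  if (length(views) != length(model@U)) {
    stop("view count mismatch: model has ", length(model@U),
         ", data has ", length(views), call. = FALSE)
  }
  S <- .ltrForwardBatch(model, views)
  if (clip) S <- pmin(pmax(S, 0), 1)
  if (!is.null(rownames(views[[1]]))) rownames(S) <- rownames(views[[1]])
  S
}

#' Regularized mean-squared-error objective
#'
#' (1 / (2 m n_y)) ||Y - Yhat||_F^2 + (C_lambda / (2 n_t)) ||lambda||^2.
#'
#' @param model an [LTRModel-class].
#' @param dataset a [MultiViewDataset-class].
#' @param cLambda regularization weight.
#' @return non-negative scalar; 0 iff the fit is perfect and lambda = 0.
#' @export
ltrObjective <- function(model, dataset, cLambda = 0) {
  Y <- labelMatrix(dataset)
  Yhat <- ltrPredict(model, dataset)
  nt <- length(model@lambda)
  sum((Y - Yhat)^2) / (2 * nrow(Y) * ncol(Y)) +
    cLambda / (2 * nt) * sum(model@lambda^2)
}

# analytic gradients of the mini-batch objective; returns list mirroring the
# parameter structure. Derivation: chain rule through the forward map above.
.ltrGradients <- function(model, views, Y, cLambda) {
  nd <- length(model@U)
  b <- nrow(Y)
  nt <- length(model@lambda)
  f <- .ltrForwardBatch(model, views, keep = TRUE)
  Rm <- (f$Yhat - Y) / (b * ncol(Y))
  gQ <- t(Rm) %*% f$S
  dS <- Rm %*% model@Q
  gLambda <- colSums(dS * f$G) + (cLambda / nt) * model@lambda
  dG <- dS * rep(model@lambda, each = b)
  gU <- vector("list", nd); gV <- vector("list", nd)
  gScale <- vector("list", nd)
  for (d in seq_len(nd)) {
    Pother <- matrix(1, b, nt)
    for (d2 in seq_len(nd)) if (d2 != d) Pother <- Pother * f$H[[d2]]
    dH <- dG * Pother
    dHpre <- dH * .activateGrad(f$Hpre[[d]], model@activationB)
    gV[[d]] <- t(dHpre) %*% f$Aact[[d]]
    dAact <- dHpre %*% model@V[[d]]
    dApre <- dAact * .activateGrad(f$Apre[[d]], model@activationA)
    gU[[d]] <- t(f$Z[[d]]) %*% dApre
    dZ <- dApre %*% t(model@U[[d]])
    gScale[[d]] <- colSums(dZ * views[[d]])
  }
  list(U = gU, V = gV, scaleD = gScale, lambda = gLambda, Q = gQ,
       loss = sum((f$Yhat - Y)^2) / (2 * b * ncol(Y)))
}

#' Fit an LTR model by projected mini-batch gradient descent
#'
#' Per epoch: seeded shuffle of the training rows, gradient steps on
#' mini-batches of the regularized MSE objective, then projection of all
#' factors back onto the unit-norm constraints. When validation ids are
#' given, the model with the lowest validation objective across epochs is
#' returned; otherwise the final model.
#'
#' @param model an [LTRModel-class] (e.g. from [ltrModel()]).
#' @param dataset a [MultiViewDataset-class].
#' @param trainIds protein ids to train on (default: whole roster).
#' @param valIds optional protein ids for validation selection.
#' @param cfg list from [ltrControl()].
#' @return list with elements \code{model} and \code{report}; the report has
#'   \code{objective} (training objective after each epoch),
#'   \code{valObjective}, \code{constraintResidual} (after each epoch's
#'   projection), \code{seed} and \code{epochs}.
#' @export
ltrFit <- function(model, dataset, trainIds = NULL, valIds = NULL,
                   cfg = ltrControl()) {
  if (is.null(trainIds)) trainIds <- roster(dataset)
  stopifnot(length(trainIds) > 0)
  train <- subsetDataset(dataset, trainIds)
  val <- if (length(valIds)) subsetDataset(dataset, valIds) else NULL
  Xtr <- viewList(train)
  Ytr <- labelMatrix(train)
  m <- nrow(Ytr)

  opt <- .makeOptimizer(cfg, model)
  objTrace <- numeric(0); valTrace <- numeric(0); resTrace <- numeric(0)
  bestVal <- Inf; bestModel <- model

  if (cfg$epochs > 0L) {
    for (ep in seq_len(cfg$epochs)) {
      ord <- .withSeed(cfg$seed + ep, sample.int(m))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
      for (bi in batches) {
        views <- lapply(Xtr, function(v) v[bi, , drop = FALSE])
        g <- .ltrGradients(model, views, Ytr[bi, , drop = FALSE],
                           cfg$cLambda)
        model <- opt$step(model, g)
        model <- projectConstraints(model, seed = cfg$seed + ep)
      }
      obj <- ltrObjective(model, train, cfg$cLambda)
      if (!is.finite(obj)) {
        stop("numeric failure: training objective diverged at epoch ", ep,
             " (last finite objectives: ",
             paste(signif(tail(objTrace, 3), 4), collapse = ", "), ")",
             call. = FALSE)
      }
      objTrace <- c(objTrace, obj)
      resTrace <- c(resTrace, constraintResidual(model))
      if (!is.null(val)) {
        vo <- ltrObjective(model, val, cfg$cLambda)
        valTrace <- c(valTrace, vo)
        if (vo < bestVal) {
          bestVal <- vo
          bestModel <- model
        }
      }
    }
  }
  final <- if (!is.null(val) && is.finite(bestVal)) bestModel else model
  list(
    model = final,
    report = list(objective = objTrace, valObjective = valTrace,
                  constraintResidual = resTrace, seed = cfg$seed,
                  epochs = cfg$epochs)
  )
}

# optimizer state machinery shared across all parameters
.makeOptimizer <- function(cfg, model) {
  flat <- function(model) {
    c(lapply(model@U, identity), lapply(model@V, identity),
      lapply(model@scaleD, identity), list(model@lambda), list(model@Q))
  }
  inject <- function(model, params) {
    nd <- length(model@U)
    model@U <- params[seq_len(nd)]
    model@V <- params[nd + seq_len(nd)]
    model@scaleD <- params[2 * nd + seq_len(nd)]
    model@lambda <- params[[3 * nd + 1]]
    model@Q <- params[[3 * nd + 2]]
    model
  }
  gradsOf <- function(g) {
    c(g$U, g$V, g$scaleD, list(g$lambda), list(g$Q))
  }
  state <- NULL
  step <- function(model, g) {
    p <- flat(model)
    gr <- gradsOf(g)
    if (is.null(state)) {
      state <<- list(m = lapply(gr, function(x) x * 0),
                     v = lapply(gr, function(x) x * 0), t = 0L)
    }
    state$t <<- state$t + 1L
    lr <- cfg$stepSize
    for (i in seq_along(p)) {
      if (cfg$optimizer == "adam") {
        state$m[[i]] <<- 0.9 * state$m[[i]] + 0.1 * gr[[i]]
        state$v[[i]] <<- 0.999 * state$v[[i]] + 0.001 * gr[[i]]^2
        mh <- state$m[[i]] / (1 - 0.9^state$t)
        vh <- state$v[[i]] / (1 - 0.999^state$t)
        p[[i]] <- p[[i]] - lr * mh / (sqrt(vh) + 1e-8)
      } else if (cfg$optimizer == "momentum") {
        state$m[[i]] <<- 0.9 * state$m[[i]] + gr[[i]]
        p[[i]] <- p[[i]] - lr * state$m[[i]]
      } else {
        p[[i]] <- p[[i]] - lr * gr[[i]]
      }
    }
    inject(model, p)
  }
  list(step = step)
}

#' Explicit CP weight tensor (identity activations)
#'
#' Materializes T = sum_t lambda_t (x)_d p_t^(d) with
#' p_t^(d) = row t of P^(d) = V^(d) U^(d)' D^(d). The contraction
#' <T, x^(1) (x) ... (x) x^(n_d)> equals the forward output before the
#' output projection (i.e. with Q replaced by an all-ones vector). Refuses
#' tensors with more than 1e6 entries.
#'
#' @param model an [LTRModel-class] with identity activations.
#' @return dense array of shape n_x1 x ... x n_xnd (a plain vector for a
#'   single view).
#' @export
explicitWeightTensor <- function(model) {
  if (model@activationA != "identity" || model@activationB != "identity") {
    stop("explicit weight tensor is defined for identity activations only",
         call. = FALSE)
  }
  dims <- vapply(model@U, nrow, integer(1))
  if (prod(dims) > 1e6) {
    stop("size guard: tensor would have ", prod(dims), " entries (> 1e6)",
         call. = FALSE)
  }
  P <- .factorMatrices(model)
  nt <- length(model@lambda)
  Tarr <- array(0, dim = dims)
  for (t in seq_len(nt)) {
    op <- Reduce(outer, lapply(P, function(Pd) Pd[t, ]))
    Tarr <- Tarr + model@lambda[t] * op
  }
  Tarr
}

# per-view factor matrices P^(d) = V U' D_scale  (n_t x n_xd)
.factorMatrices <- function(model) {
  lapply(seq_along(model@U), function(d) {
    P <- model@V[[d]] %*% t(model@U[[d]])
    P * rep(model@scaleD[[d]], each = nrow(P))
  })
}

#' Single polynomial coefficient of the factorized model
#'
#' w_{j_1..j_nd} = sum_t lambda_t p_{j_1,t}^(1) ... p_{j_nd,t}^(nd); equals
#' the corresponding entry of [explicitWeightTensor()] without materializing
#' the tensor.
#'
#' @param model an [LTRModel-class] with identity activations.
#' @param idx integer vector of length n_d (1-based feature indices).
#' @return scalar coefficient.
#' @export
polynomialCoefficient <- function(model, idx) {
  if (model@activationA != "identity" || model@activationB != "identity") {
    stop("polynomial coefficients are defined for identity activations only",
         call. = FALSE)
  }
  dims <- vapply(model@U, nrow, integer(1))
  stopifnot(length(idx) == length(dims))
  if (any(idx < 1L) || any(idx > dims)) {
    stop("index out of range", call. = FALSE)
  }
  P <- .factorMatrices(model)
  terms <- rep(1, length(model@lambda))
  for (d in seq_along(P)) terms <- terms * P[[d]][, idx[d]]
  sum(model@lambda * terms)
}

#' Save / load an LTR model archive
#'
#' Single-file archive with a versioned header recording shapes, activation
#' flags and the training configuration.
#'
#' @param model an [LTRModel-class].
#' @param path file path.
#' @param cfg optional training configuration to store alongside.
#' @return \code{loadLTRModel} returns a list with elements \code{model} and
#'   \code{cfg}.
#' @export
saveLTRModel <- function(model, path, cfg = NULL) {
  obj <- list(
    format = "tensorGO-ltr", version = 1L,
    viewDims = vapply(model@U, nrow, integer(1)),
    nT = length(model@lambda), nY = nrow(model@Q),
    activationA = model@activationA, activationB = model@activationB,
    U = model@U, scaleD = model@scaleD, V = model@V,
    lambda = model@lambda, Q = model@Q, cfg = cfg
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveLTRModel
#' @export
loadLTRModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "tensorGO-ltr")) {
    stop("not a tensorGO model archive: ", path, call. = FALSE)
  }
  model <- new("LTRModel", U = obj$U, scaleD = obj$scaleD, V = obj$V,
               lambda = obj$lambda, Q = obj$Q,
               activationA = obj$activationA, activationB = obj$activationB)
  list(model = model, cfg = obj$cfg)
}
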