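# shared internal helpers

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# derivative mask of relu evaluated at the pre-activation
.reluGrad <- function(pre) {
  (pre > 0) * 1
}

.activate <- function(x, kind) {
  if (kind == "relu") .relu(x) else x
}

.activateGrad <- function(pre, kind) {
  if (kind == "relu") .reluGrad(pre) else array(1, dim = dim(pre))
}

# row-wise L2 normalization; zero rows replaced by a seeded random unit vector
.unitRows <- function(M, seed = NULL) {
  nr <- sqrt(rowSums(M^2))
  zero <- nr < .Machine$double.eps
  if (any(zero)) {
    repl <- .withSeed(if (is.null(seed)) 0L else seed, {
      matrix(rnorm(sum(zero) * ncol(M)), ncol = ncol(M))
    })
    M[zero, ] <- repl
    nr[zero] <- sqrt(rowSums(M[zero, , drop = FALSE]^2))
  }
  M / nr
}

.unitCols <- function(M, seed = NULL) {
  t(.unitRows(t(M), seed = seed))
}

# row-wise max of a numeric matrix (no matrixStats dependency)
.rowMax <- function(M) {
  do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
}
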