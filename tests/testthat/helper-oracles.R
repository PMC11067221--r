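# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops, recursion and
# explicit set arithmetic only.

# ancestor closure of one term by breadth-first search over the parent map
oracleAncestors <- function(parents, id) {
  seen <- character(0)
  frontier <- parents[[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- unique(unlist(lapply(frontier, function(p) parents[[p]])))
    frontier <- setdiff(frontier, seen)
  }
  seen
}

# is `anc` an ancestor of `id`? path search on the parent map
oracleIsAncestor <- function(parents, id, anc) {
  anc %in% oracleAncestors(parents, id)
}

# per-protein, per-term max over self and all in-space descendants
oracleDescendantMax <- function(S, dag, spaceTerms) {
  out <- S
  for (i in seq_len(nrow(S))) {
    for (j in seq_along(spaceTerms)) {
      vals <- S[i, j]
      for (k in seq_along(spaceTerms)) {
        if (k != j &&
            oracleIsAncestor(dag@parents, spaceTerms[k], spaceTerms[j])) {
          vals <- c(vals, S[i, k])
        }
      }
      out[i, j] <- max(vals)
    }
  }
  out
}

# exhaustive per-threshold counting for all protein-centric metrics
oracleCurves <- function(Y, S, ic, taus) {
  m <- nrow(Y); n <- ncol(Y)
  pr <- rc <- wpr <- wrc <- ru <- mi <- rep(NA_real_, length(taus))
  mTau <- integer(length(taus))
  for (t in seq_along(taus)) {
    prs <- c(); wprs <- c()
    rcs <- numeric(m); wrcs <- numeric(m)
    rus <- numeric(m); mis <- numeric(m)
    called <- 0L
    for (i in seq_len(m)) {
      pred <- which(S[i, ] >= taus[t])
      true <- which(Y[i, ] == 1)
      tp <- intersect(pred, true)
      if (length(pred) > 0) {
        called <- called + 1L
        prs <- c(prs, length(tp) / length(pred))
      }
      rcs[i] <- if (length(true)) length(tp) / length(true) else 1
      predMass <- sum(ic[pred]); trueMass <- sum(ic[true])
      if (predMass > 0) wprs <- c(wprs, sum(ic[tp]) / predMass)
      wrcs[i] <- if (trueMass > 0) sum(ic[tp]) / trueMass else 1
      rus[i] <- sum(ic[setdiff(true, pred)])
      mis[i] <- sum(ic[setdiff(pred, true)])
    }
    mTau[t] <- called
    pr[t] <- if (length(prs)) sum(prs) / length(prs) else NA_real_
    rc[t] <- sum(rcs) / m
    wpr[t] <- if (length(wprs)) sum(wprs) / length(wprs) else NA_real_
    wrc[t] <- sum(wrcs) / m
    ru[t] <- sum(rus) / m
    mi[t] <- sum(mis) / m
  }
  list(tau = taus, pr = pr, rc = rc, wpr = wpr, wrc = wrc,
       ru = ru, mi = mi, m = mTau)
}

oracleFmax <- function(pr, rc, m) {
  best <- 0
  for (t in seq_along(pr)) {
    if (m[t] == 0 || is.na(pr[t])) next
    if (pr[t] + rc[t] == 0) next
    f <- 2 * pr[t] * rc[t] / (pr[t] + rc[t])
    if (f > best) best <- f
  }
  best
}

oracleSmin <- function(ru, mi) {
  best <- Inf
  for (t in seq_along(ru)) {
    s <- sqrt(ru[t]^2 + mi[t]^2)
    if (s < best) best <- s
  }
  best
}

oracleAuprc <- function(pr, rc, m, taus) {
  ord <- order(taus, decreasing = TRUE)
  total <- 0; rcPrev <- 0
  for (t in ord) {
    if (m[t] == 0 || is.na(pr[t])) next
    total <- total + pr[t] * (rc[t] - rcPrev)
    rcPrev <- rc[t]
  }
  abs(total)
}

# all-pairs rank comparison, ties counted 1/2
oracleAuroc <- function(Y, S) {
  pos <- S[Y == 1]; neg <- S[Y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# nested-loop contraction <T, x1 (x) x2 (x) ...>
oracleContract <- function(Tarr, xs) {
  dims <- vapply(xs, length, integer(1))
  idx <- rep(1L, length(dims))
  total <- 0
  repeat {
    prod <- do.call(`[`, c(list(Tarr), as.list(idx)))
    for (d in seq_along(xs)) prod <- prod * xs[[d]][idx[d]]
    total <- total + prod
    d <- 1L
    repeat {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= dims[d]) break
      idx[d] <- 1L
      d <- d + 1L
      if (d > length(dims)) return(total)
    }
  }
}

# random binary-truth / score fixture in which every protein has >= 1 true term
randomYS <- function(m, n, seed) {
  set.seed(seed)
  Y <- matrix(rbinom(m * n, 1, 0.4), m, n)
  for (i in seq_len(m)) if (sum(Y[i, ]) == 0) Y[i, sample(n, 1)] <- 1
  S <- matrix(round(runif(m * n), 2), m, n)
  list(Y = Y, S = S, ic = round(runif(n, 0, 3), 3))
}

# small random study built through the synthetic module
randomStudy <- function(seed, m = 60, depth = 2, branching = 3,
                        viewDims = c(6, 5), nT = 3, noise = 0.05,
                        nClusters = 12) {
  cfg <- simControl(seed = seed, m = m, viewDims = viewDims, nT = nT,
                    dagDepth = depth, dagBranching = branching,
                    labelNoise = noise, nClusters = nClusters)
  dag <- makeToyOntology(cfg)
  space <- labelSpaceFromDAG(dag)
  truth <- plantModel(cfg, nY = length(goTerms(space)))
  ds <- suppressMessages(sampleMultiview(cfg, truth, space))
  list(cfg = cfg, dag = dag, space = space, truth = truth, dataset = ds)
}
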