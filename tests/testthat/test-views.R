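# Feature views, autoencoder reduction, file IO and cluster-grouped folds.

test_that("fingerprint matrix is a vocabulary indicator", {
  rec <- list(p1 = "f2", p2 = character(0))
  X <- binaryFingerprintMatrix(rec, c("f1", "f2"))
  expect_equal(unname(X), rbind(c(0, 1), c(0, 0)))

  set.seed(11)
  vocab <- paste0("f", 1:15)
  rec <- lapply(1:10, function(i) sample(vocab, sample(0:6, 1)))
  names(rec) <- paste0("p", 1:10)
  X <- binaryFingerprintMatrix(rec, vocab)
  for (i in 1:10) for (j in 1:15) {
    expect_equal(X[i, j], as.numeric(vocab[j] %in% rec[[i]]))
  }
  expect_message(binaryFingerprintMatrix(list(p = "zz"), vocab), "dropped")
  expect_error(binaryFingerprintMatrix(list(p = "zz"), vocab,
                                       onUnknown = "error"), "zz")
})

test_that("PPI adjacency is symmetric with oracle degree sums", {
  A <- ppiAdjacency(data.frame(p1 = "a", p2 = "b"), c("a", "b"))
  expect_equal(unname(A), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(ppiAdjacency(data.frame(p1 = character(0),
                                              p2 = character(0)),
                                   c("a", "b"))),
               matrix(0, 2, 2))
  set.seed(21)
  ros <- paste0("p", 1:12)
  ed <- data.frame(p1 = sample(ros, 30, TRUE), p2 = sample(ros, 30, TRUE))
  A <- suppressMessages(ppiAdjacency(ed, ros))
  expect_identical(A, t(A))
  keep <- ed[ed$p1 != ed$p2, ]
  for (p in ros) {
    partners <- unique(c(keep$p2[keep$p1 == p], keep$p1[keep$p2 == p]))
    expect_equal(sum(A[p, ] > 0), length(partners))
  }
})

test_that("autoencoder training reduces loss deterministically", {
  set.seed(31)
  X <- matrix(rbinom(200 * 50, 1, 0.15), 200, 50)
  rownames(X) <- paste0("p", 1:200)
  ctl <- reducerControl(hidden = c(24L), epochs = 50L, batchSize = 32L,
                        stepSize = 1e-3)
  mod <- trainReducer(X, 8, ctl, seed = 5)
  traj <- mod@lossTrajectory
  expect_lt(tail(traj, 1), traj[1])
  # loss trajectory decreases in >= 90% of epochs
  expect_gte(mean(diff(traj) < 0), 0.9)
  mod2 <- trainReducer(X, 8, ctl, seed = 5)
  expect_identical(mod@W, mod2@W)
  expect_false(identical(mod@W, trainReducer(X, 8, ctl, seed = 6)@W))
})

test_that("overcomplete linear autoencoder reconstructs almost perfectly", {
  set.seed(41)
  X <- matrix(rnorm(60 * 5), 60, 5)
  ctl <- reducerControl(hidden = integer(0), epochs = 800L, batchSize = 60L,
                        stepSize = 2e-2)
  mod <- suppressMessages(trainReducer(X, 5, ctl, seed = 2))
  expect_lt(tail(mod@lossTrajectory, 1), 1e-3)
})

test_that("encoder application is shape-correct, batch-consistent, linear at 0", {
  set.seed(51)
  X <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(paste0("p", 1:20),
                                                      NULL))
  ctl <- reducerControl(hidden = c(6L), epochs = 2L, batchSize = 10L)
  mod <- trainReducer(X, 3, ctl, seed = 9)
  H <- reduceView(mod, X)
  expect_equal(dim(H), c(20L, 3L))
  expect_equal(rownames(H), rownames(X))
  rowwise <- t(vapply(seq_len(nrow(X)), function(i) {
    drop(reduceView(mod, X[i, , drop = FALSE]))
  }, numeric(3)))
  expect_equal(unname(H), rowwise, tolerance = 1e-12)
  expect_error(reduceView(mod, X[, 1:5]), "shape")
  # zero biases -> zero row maps to zero embedding
  modZ <- mod
  modZ@b <- lapply(modZ@b, function(x) x * 0)
  expect_equal(unname(reduceView(modZ, matrix(0, 1, 10))),
               matrix(0, 1, 3))
})

test_that("feature tables round-trip and fail with line numbers", {
  X <- matrix(c(1.5, -2, 0, 3.25, 10, 7), 2, 3,
              dimnames = list(c("pA", "pB"), c("f1", "f2", "f3")))
  f <- tempfile()
  writeFeatureTable(X, f)
  expect_equal(readFeatureTable(f), X)
  writeLines(c("protein_id\tf1", "p1\t1", "p2\tx"), f)
  expect_error(readFeatureTable(f), "line 3")
  writeLines(c("protein_id\tf1", "p1\t1\t2"), f)
  expect_error(readFeatureTable(f), "line 2")
  writeLines(c("protein_id\tf1", "p1\t1", "p1\t2"), f)
  expect_error(readFeatureTable(f), "duplicated")
  unlink(f)
})

test_that("cluster files parse representative/member pairs", {
  f <- tempfile()
  writeLines(c("r1\tp1", "r1\tp2", "r2\tp3"), f)
  expect_equal(readClusters(f), c(p1 = "r1", p2 = "r1", p3 = "r2"))
  writeLines(c("r1\tp1", "r2\tp1"), f)
  expect_error(readClusters(f), "more than one cluster")
  unlink(f)
})

test_that("cluster CV folds preserve homology separation", {
  # 10 singleton clusters, 10 folds -> singleton test sets
  ros <- paste0("p", 1:10)
  cl <- setNames(paste0("c", 1:10), ros)
  plan <- clusterCVFolds(cl, ros, nFolds = 10, seed = 3)
  for (f in folds(plan)) {
    expect_length(f$test, 1)
    expect_setequal(c(f$train, f$validation, f$test), ros)
  }

  # giant cluster is never split across train and test
  ros <- paste0("p", 1:30)
  cl <- setNames(c(rep("big", 21), paste0("c", 1:9)), ros)
  plan <- clusterCVFolds(cl, ros, nFolds = 5, seed = 7)
  for (f in folds(plan)) {
    sides <- unique(c(
      if (length(intersect(ros[cl == "big"], c(f$train, f$validation)))) "tr",
      if (length(intersect(ros[cl == "big"], f$test))) "te"))
    expect_length(sides, 1)
  }

  # 200 proteins / 37 clusters: exhaustive membership audit
  set.seed(99)
  ros <- sprintf("p%03d", 1:200)
  cl <- setNames(sample(paste0("c", 1:37), 200, TRUE), ros)
  cl[1:37] <- paste0("c", 1:37)
  plan <- clusterCVFolds(cl, ros, nFolds = 10, seed = 11)
  testClustersSeen <- character(0)
  for (f in folds(plan)) {
    expect_setequal(c(f$train, f$validation, f$test), ros)
    expect_length(intersect(cl[c(f$train, f$validation)], cl[f$test]), 0)
    expect_length(intersect(cl[f$validation], cl[f$train]), 0)
    expect_length(intersect(testClustersSeen, unique(cl[f$test])), 0)
    testClustersSeen <- c(testClustersSeen, unique(cl[f$test]))
  }
  expect_setequal(testClustersSeen, unique(cl))
  # same seed -> identical plan
  plan2 <- clusterCVFolds(cl, ros, nFolds = 10, seed = 11)
  expect_identical(folds(plan), folds(plan2))
  expect_error(clusterCVFolds(cl[1:5], ros[1:5], nFolds = 10),
               "fewer clusters")
})

test_that("dataset assembly aligns shuffled views and reports missing ids", {
  set.seed(61)
  ros <- paste0("p", 1:8)
  X1 <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(sample(ros), NULL))
  X2 <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(sample(ros), NULL))
  Y <- matrix(rbinom(8 * 4, 1, 0.5), 8, 4, dimnames = list(sample(ros),
                                                           paste0("t", 1:4)))
  ds <- assembleDataset(list(a = X1, b = X2), Y, ros)
  expect_equal(roster(ds), ros)
  expect_equal(getView(ds, "a"), X1[ros, ])
  expect_equal(labelMatrix(ds), Y[ros, ])
  expect_error(assembleDataset(list(a = X1[1:7, ], b = X2), Y, ros),
               "view 'a'")
})

test_that("intercept augmentation appends a unit column per view", {
  study <- randomStudy(71, m = 20, nClusters = 4)
  dsA <- addInterceptFeature(study$dataset)
  for (nm in viewNames(dsA)) {
    X <- getView(dsA, nm)
    expect_equal(ncol(X), ncol(getView(study$dataset, nm)) + 1L)
    expect_true(all(X[, ncol(X)] == 1))
  }
})
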