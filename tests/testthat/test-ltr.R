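# Latent tensor reconstruction core: initialization, forward map, explicit
# tensor oracles, objective, constraint projection and the trainer.

test_that("initialization is seeded, feasible and seed-sensitive", {
  cfg <- ltrControl(nT = 3, seed = 4)
  m1 <- ltrModel(c(5, 7), 4, cfg)
  m2 <- ltrModel(c(5, 7), 4, cfg)
  expect_identical(m1, m2)
  expect_lt(constraintResidual(m1), 1e-6)
  m3 <- ltrModel(c(5, 7), 4, ltrControl(nT = 3, seed = 5))
  expect_false(identical(m1@lambda, m3@lambda))
})

handModel <- function(activationA = "identity", activationB = "identity") {
  new("LTRModel",
      U = list(matrix(c(1, 0), 2, 1)), scaleD = list(c(1, 1)),
      V = list(matrix(1, 1, 1)), lambda = 1,
      Q = matrix(1, 1, 1),
      activationA = activationA, activationB = activationB)
}

test_that("forward map reproduces hand evaluations and the ReLU gate", {
  expect_equal(ltrForward(handModel(), list(c(3, 5))), 3)
  expect_equal(ltrForward(handModel("relu", "relu"), list(c(-3, 5))), 0)
  # scale acts before U
  m <- handModel()
  m@scaleD <- list(c(2, 1))
  expect_equal(ltrForward(m, list(c(3, 5))), 6)
})

test_that("factorized forward equals the explicit tensor contraction", {
  for (seed in 1:10) {
    cfg <- simControl(seed = seed, viewDims = c(3, 4), nT = 2)
    model <- plantModel(cfg, nY = 1)
    model@Q <- matrix(1, 1, 2)
    Tarr <- explicitWeightTensor(model)
    set.seed(seed + 500)
    x <- list(rnorm(3), rnorm(4))
    expect_equal(ltrForward(model, x), oracleContract(Tarr, x),
                 tolerance = 1e-8)
  }
})

test_that("batched prediction equals the per-sample loop and commutes with
           permutation", {
  cfg <- simControl(seed = 3, viewDims = c(4, 3), nT = 3)
  model <- plantModel(cfg, nY = 5)
  set.seed(33)
  ids <- paste0("p", 1:20)
  views <- list(v1 = matrix(rnorm(80), 20, 4, dimnames = list(ids, NULL)),
                v2 = matrix(rnorm(60), 20, 3, dimnames = list(ids, NULL)))
  S <- ltrPredict(model, views)
  loop <- t(vapply(1:20, function(i) {
    ltrForward(model, list(views$v1[i, ], views$v2[i, ]))
  }, numeric(5)))
  expect_equal(unname(S), loop, tolerance = 1e-10)
  perm <- sample(ids)
  Sp <- ltrPredict(model, lapply(views, function(v) v[perm, ]))
  expect_equal(Sp, S[perm, ])
  expect_error(ltrPredict(model, views[1]), "view count")
})

test_that("objective matches its closed form", {
  cfg <- simControl(seed = 5, viewDims = c(3, 3), nT = 2)
  model <- plantModel(cfg, nY = 2)
  ids <- paste0("p", 1:6)
  set.seed(8)
  views <- list(a = matrix(rnorm(18), 6, 3, dimnames = list(ids, NULL)),
                b = matrix(rnorm(18), 6, 3, dimnames = list(ids, NULL)))
  Yhat <- ltrPredict(model, views)
  dsPerfect <- assembleDataset(views, Yhat, ids)
  modelZ <- model; modelZ@lambda <- rep(0, 2)
  Y0 <- ltrPredict(modelZ, views)  # all zeros
  expect_equal(ltrObjective(modelZ, assembleDataset(views, Y0, ids), 0), 0)
  # Y zeros, Yhat all ones -> 0.5
  onesModel <- handModel()
  ids1 <- paste0("q", 1:4)
  v1 <- list(x = matrix(1, 4, 2, dimnames = list(ids1, NULL)))
  dsz <- assembleDataset(v1, matrix(0, 4, 1, dimnames = list(ids1, "t")),
                         ids1)
  expect_equal(ltrObjective(onesModel, dsz, 0), 0.5)
  # random instance vs directly coded formula
  Yr <- matrix(rnorm(12), 6, 2, dimnames = list(ids, NULL))
  ds <- assembleDataset(views, Yr, ids)
  cl <- 0.37
  oracle <- sum((Yr - Yhat)^2) / (2 * 6 * 2) +
    cl / (2 * 2) * sum(model@lambda^2)
  expect_equal(ltrObjective(model, ds, cl), oracle, tolerance = 1e-12)
})

test_that("constraint projection normalizes, is idempotent, fixes zeros", {
  m <- handModel()
  m@U <- list(matrix(c(3, 4), 2, 1))
  # rows of U are per-feature: here two rows [3],[4] -> normalized to 1
  p <- projectConstraints(m)
  expect_equal(p@U[[1]], matrix(c(1, 1), 2, 1))
  # a 2-column row [3,4] normalizes to [0.6, 0.8]
  m2 <- new("LTRModel", U = list(matrix(c(3, 4), 1, 2)),
            scaleD = list(1), V = list(matrix(c(1, 0), 1, 2)),
            lambda = 1, Q = matrix(1, 1, 1),
            activationA = "identity", activationB = "identity")
  expect_equal(projectConstraints(m2)@U[[1]], matrix(c(0.6, 0.8), 1, 2))
  # idempotence on a feasible random model
  cfg <- simControl(seed = 6, viewDims = c(4, 4), nT = 3)
  feas <- plantModel(cfg, nY = 3)
  again <- projectConstraints(feas)
  expect_equal(again, feas, tolerance = 1e-12)
  # random infeasible model becomes feasible in one projection
  bad <- feas
  set.seed(9)
  bad@U <- lapply(bad@U, function(u) u * matrix(runif(length(u), 0.1, 5),
                                                nrow(u)))
  bad@V <- lapply(bad@V, function(v) v * 3)
  bad@Q <- bad@Q * 0.2
  expect_lt(constraintResidual(projectConstraints(bad)), 1e-10)
  # zero row replaced by a unit vector
  zr <- feas
  zr@V[[1]][2, ] <- 0
  fixed <- projectConstraints(zr, seed = 21)
  expect_equal(sqrt(sum(fixed@V[[1]][2, ]^2)), 1, tolerance = 1e-12)
})

test_that("training fits a planted model and respects the contract edges", {
  cfg <- simControl(seed = 11, m = 600, viewDims = c(8, 8), nT = 2,
                    nClusters = 10)
  truth <- plantModel(cfg, nY = 3)
  set.seed(12)
  ids <- sprintf("p%03d", 1:600)
  views <- list(v1 = matrix(rnorm(600 * 8), 600, 8,
                            dimnames = list(ids, NULL)),
                v2 = matrix(rnorm(600 * 8), 600, 8,
                            dimnames = list(ids, NULL)))
  Y <- ltrPredict(truth, views)
  ds <- assembleDataset(views, Y, ids)
  ctl <- ltrControl(nT = 2, cLambda = 0, batchSize = 64, epochs = 150,
                    stepSize = 1e-2, seed = 3)
  model <- ltrModel(c(8, 8), 3, ctl)

  # epochs = 0 returns the initial model unchanged
  ctl0 <- ltrControl(nT = 2, epochs = 0, seed = 3)
  fit0 <- ltrFit(model, ds, cfg = ctl0)
  expect_identical(fit0$model, model)
  expect_length(fit0$report$objective, 0)

  fit <- ltrFit(model, ds, trainIds = ids[1:500], cfg = ctl)
  expect_lt(tail(fit$report$objective, 1), 1e-3)
  held <- subsetDataset(ds, ids[501:600])
  expect_gt(cor(as.vector(ltrPredict(fit$model, held)),
                as.vector(Y[501:600, ])), 0.99)
  expect_true(all(fit$report$constraintResidual < 1e-6))
})

test_that("lambda shrinks under regularization with zero targets", {
  cfg <- simControl(seed = 14, viewDims = c(5, 5), nT = 3)
  ids <- paste0("p", 1:100)
  set.seed(15)
  views <- list(a = matrix(rnorm(500), 100, 5, dimnames = list(ids, NULL)),
                b = matrix(rnorm(500), 100, 5, dimnames = list(ids, NULL)))
  ds <- assembleDataset(views, matrix(0, 100, 2,
                                      dimnames = list(ids, c("a", "b"))),
                        ids)
  ctl <- ltrControl(nT = 3, cLambda = 0.5, batchSize = 50, epochs = 40,
                    stepSize = 1e-2, seed = 2)
  model <- ltrModel(c(5, 5), 2, ctl)
  fit <- ltrFit(model, ds, cfg = ctl)
  expect_lt(sqrt(sum(fit$model@lambda^2)), sqrt(sum(model@lambda^2)))
})

test_that("explicit tensor obeys basis, zero and linearity properties", {
  # rank 1, p1 = e1, p2 = e2, lambda 1 -> single 1 at (1,2)
  m <- new("LTRModel",
           U = list(matrix(c(1, 0, 0), 3, 1), matrix(c(0, 1, 0), 3, 1)),
           scaleD = list(rep(1, 3), rep(1, 3)),
           V = list(matrix(1, 1, 1), matrix(1, 1, 1)),
           lambda = 1, Q = matrix(1, 1, 1),
           activationA = "identity", activationB = "identity")
  Tarr <- explicitWeightTensor(m)
  expect_equal(Tarr[1, 2], 1)
  expect_equal(sum(Tarr != 0), 1)
  expect_equal(polynomialCoefficient(m, c(1, 2)), 1)
  expect_equal(polynomialCoefficient(m, c(2, 2)), 0)
  mz <- m; mz@lambda <- 0
  expect_true(all(explicitWeightTensor(mz) == 0))

  cfg <- simControl(seed = 16, viewDims = c(4, 5), nT = 3)
  model <- plantModel(cfg, nY = 1)
  Tarr <- explicitWeightTensor(model)
  set.seed(17)
  for (k in 1:50) {
    idx <- c(sample(4, 1), sample(5, 1))
    expect_equal(polynomialCoefficient(model, idx), Tarr[idx[1], idx[2]],
                 tolerance = 1e-10)
  }
  m2 <- model; m2@lambda <- 2 * model@lambda
  expect_equal(explicitWeightTensor(m2), 2 * Tarr, tolerance = 1e-12)
  expect_error(polynomialCoefficient(model, c(9, 1)), "range")
  big <- ltrModel(c(101, 101, 101), 1, ltrControl(nT = 1))
  expect_error(explicitWeightTensor(big), "size guard")
  expect_error(explicitWeightTensor(plantModel(cfg, 1, "relu", "relu")),
               "identity")
})

test_that("mode-1 unfolding of a rank-2 plant has matrix rank <= 2", {
  cfg <- simControl(seed = 18, viewDims = c(5, 6), nT = 2)
  Tarr <- explicitWeightTensor(plantModel(cfg, nY = 1))
  expect_lte(qr(Tarr)$rank, 2)
})

test_that("ReLU view response is positively homogeneous", {
  cfg <- simControl(seed = 19, viewDims = c(4, 4), nT = 3)
  model <- plantModel(cfg, nY = 2, activationA = "relu",
                      activationB = "relu")
  set.seed(20)
  x <- list(rnorm(4), rnorm(4))
  base <- ltrForward(model, x)
  for (c1 in c(0.5, 2, 7)) {
    scaled <- ltrForward(model, list(c1 * x[[1]], x[[2]]))
    expect_equal(scaled, c1 * base, tolerance = 1e-10)
  }
})

test_that("model archives round-trip with their configuration", {
  cfg <- simControl(seed = 22, viewDims = c(3, 4), nT = 2)
  model <- plantModel(cfg, nY = 3)
  f <- tempfile(fileext = ".rds")
  ctl <- ltrControl(nT = 2, seed = 8)
  saveLTRModel(model, f, cfg = ctl)
  back <- loadLTRModel(f)
  expect_equal(back$model, model)
  expect_equal(back$cfg$seed, 8L)
  saveRDS(list(format = "other"), f)
  expect_error(loadLTRModel(f), "archive")
  unlink(f)
})
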