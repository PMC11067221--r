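# OBO parsing, annotation propagation, label-space selection, information
# content and hierarchical score propagation.

miniOBO <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: molecular_function",
    "",
    "[Term]", "id: GO:0000002", "name: a",
    "namespace: molecular_function", "is_a: GO:0000001 ! root",
    "alt_id: GO:0000099",
    "",
    "[Term]", "id: GO:0000003", "name: b",
    "namespace: molecular_function", "is_a: GO:0000002 ! a",
    "relationship: part_of GO:0000001",
    "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: molecular_function", "is_a: GO:0000001",
    "is_obsolete: true")
}

test_that("parseOBO retains is_a edges, drops obsolete terms, maps alt ids", {
  dag <- parseOBO(miniOBO())
  expect_setequal(goTerms(dag), c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(goRoots(dag), c(MFO = "GO:0000001"))
  expect_equal(goParents(dag)[["GO:0000003"]], "GO:0000002")
  # relationship: line ignored -> single parent
  expect_length(goParents(dag)[["GO:0000003"]], 1)
  expect_equal(unname(altIdMap(dag)["GO:0000099"]), "GO:0000002")
  expect_false("GO:0000004" %in% goTerms(dag))
})

test_that("parseOBO rejects structural defects with named errors", {
  expect_error(parseOBO(c("[Term]", "id: GO:1", "name: x",
                          "namespace: molecular_function",
                          "is_a: GO:9999")),
               "unknown term")
  cyc <- c("[Term]", "id: GO:1", "name: r",
           "namespace: molecular_function",
           "[Term]", "id: GO:2", "name: a",
           "namespace: molecular_function", "is_a: GO:3",
           "[Term]", "id: GO:3", "name: b",
           "namespace: molecular_function", "is_a: GO:2")
  expect_error(parseOBO(cyc), "cycle")
})

test_that("writeOBO / parseOBO round-trips edge sets and namespaces", {
  for (seed in 1:5) {
    cfg <- simControl(seed = seed, dagDepth = 3, dagBranching = 2, m = 10,
                      nClusters = 2)
    dag <- makeToyOntology(cfg)
    f <- tempfile(fileext = ".obo")
    writeOBO(dag, f)
    dag2 <- parseOBO(f)
    expect_setequal(goTerms(dag2), goTerms(dag))
    expect_equal(lapply(goParents(dag2), sort)[goTerms(dag)],
                 lapply(goParents(dag), sort)[goTerms(dag)],
                 ignore_attr = TRUE)
    expect_equal(goNamespace(dag2)[goTerms(dag)],
                 goNamespace(dag)[goTerms(dag)])
    unlink(f)
  }
})

test_that("filterEvidence keeps experimental codes and drops empty proteins", {
  rec <- data.frame(protein_id = c("p1", "p1", "p2"),
                    term_id = c("t1", "t2", "t3"),
                    evidence_code = c("EXP", "IEA", "IEA"))
  ann <- suppressMessages(filterEvidence(rec))
  expect_equal(annotations(ann), list(p1 = "t1"))
  allIEA <- data.frame(protein_id = "p", term_id = "t",
                       evidence_code = "IEA")
  expect_length(annotations(suppressMessages(filterEvidence(allIEA))), 0)
  expect_error(filterEvidence(rec, allowed = character(0)), "configuration")
})

test_that("filterEvidence kept count matches a direct count oracle", {
  set.seed(401)
  codes <- c(experimentalEvidenceCodes, "IEA", "ISS")
  rec <- data.frame(protein_id = sample(paste0("p", 1:20), 100, TRUE),
                    term_id = sample(paste0("t", 1:10), 100, TRUE),
                    evidence_code = sample(codes, 100, TRUE))
  ann <- suppressMessages(filterEvidence(rec))
  # oracle: count distinct (protein, term) pairs with allowed codes
  keep <- rec[rec$evidence_code %in% experimentalEvidenceCodes, ]
  oracle <- length(unique(paste(keep$protein_id, keep$term_id)))
  expect_equal(sum(lengths(annotations(ann))), oracle)
})

test_that("true-path propagation closes chains, is idempotent, matches BFS", {
  dag <- parseOBO(miniOBO())
  ann <- new("AnnotationSet", annotations = list(p1 = "GO:0000003"))
  prop <- propagateTruePath(ann, dag)
  expect_setequal(annotations(prop)$p1,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_true(isPropagated(prop))
  prop2 <- propagateTruePath(prop, dag)
  expect_identical(annotations(prop2), annotations(prop))
  expect_error(
    propagateTruePath(new("AnnotationSet",
                          annotations = list(p = "GO:404")), dag),
    "GO:404")

  # random DAG, random annotations vs BFS oracle
  study <- randomStudy(7, depth = 3, branching = 3)
  dag <- study$dag
  set.seed(77)
  ann <- lapply(1:15, function(i) sample(goTerms(dag), sample(1:4, 1)))
  names(ann) <- paste0("p", 1:15)
  prop <- propagateTruePath(new("AnnotationSet", annotations = ann), dag)
  for (p in names(ann)) {
    oracle <- sort(unique(c(ann[[p]], unlist(
      lapply(ann[[p]], function(t) oracleAncestors(goParents(dag), t))))))
    expect_equal(annotations(prop)[[p]], oracle)
  }
})

test_that("label-space selection thresholds counts and excludes the root", {
  dag <- parseOBO(miniOBO())
  # 50 proteins with B (hence A, root); 10 more with only A
  ann <- c(lapply(1:35, function(i) c("GO:0000001", "GO:0000002",
                                      "GO:0000003")),
           lapply(1:10, function(i) c("GO:0000001", "GO:0000002")))
  names(ann) <- paste0("p", seq_along(ann))
  annots <- new("AnnotationSet", annotations = ann, propagated = TRUE)
  space <- suppressMessages(selectLabelSpace(annots, dag, "MFO", 40))
  expect_equal(goTerms(space), "GO:0000002")  # root excluded, b below 40
  expect_error(suppressMessages(selectLabelSpace(annots, dag, "MFO", 1000)),
               "no labels survive")
})

test_that("label-space membership matches a brute-force counting oracle", {
  study <- randomStudy(13, m = 200, depth = 3, branching = 3, noise = 0,
                       nClusters = 10)
  Y <- labelMatrix(study$dataset)
  annots <- annotationSetFromLabels(Y, study$dag, study$space)
  space <- suppressMessages(
    selectLabelSpace(annots, study$dag, "MFO", 30))
  counts <- colSums(Y)
  oracle <- colnames(Y)[counts >= 30]
  expect_setequal(goTerms(space), oracle)
  # deterministic topological order: ancestors precede descendants
  idx <- termIndex(space)
  for (j in seq_along(goTerms(space))) {
    for (a in ancestorsInSpace(space)[[j]]) expect_lt(a, j)
  }
})

test_that("ancestorsInSpace equals brute-force path search", {
  study <- randomStudy(19, depth = 3, branching = 3)
  space <- study$space
  terms <- goTerms(space)
  for (j in seq_along(terms)) {
    oracle <- which(vapply(seq_along(terms), function(k) {
      k != j && oracleIsAncestor(goParents(study$dag), terms[j], terms[k])
    }, logical(1)))
    expect_setequal(ancestorsInSpace(space)[[j]], oracle)
  }
})

test_that("encodeLabels matches set membership and errors on missing ids", {
  dag <- parseOBO(miniOBO())
  annots <- new("AnnotationSet",
                annotations = list(p1 = c("GO:0000001", "GO:0000002"),
                                   p2 = "GO:0000001"),
                propagated = TRUE)
  space <- new("LabelSpace", namespace = "MFO", terms = "GO:0000002",
               ancestorsInSpace = list(integer(0)))
  Y <- encodeLabels(annots, space, c("p1", "p2"))
  expect_equal(unname(Y), matrix(c(1, 0), 2, 1))
  expect_error(encodeLabels(annots, space, c("p1", "p9")), "p9")

  study <- randomStudy(23)
  Ys <- labelMatrix(study$dataset)
  annots <- annotationSetFromLabels(Ys, study$dag, study$space)
  Y2 <- encodeLabels(annots, study$space, roster(study$dataset))
  expect_equal(Y2, Ys)
})

test_that("information content matches the definition and a counting oracle", {
  dag <- parseOBO(miniOBO())
  # 8 proteins have a; 4 of those also have b -> I(a)=0 needs all-root, I(b)=1
  ann <- c(lapply(1:4, function(i) c("GO:0000001", "GO:0000002",
                                     "GO:0000003")),
           lapply(1:4, function(i) c("GO:0000001", "GO:0000002")))
  names(ann) <- paste0("p", 1:8)
  annots <- new("AnnotationSet", annotations = ann, propagated = TRUE)
  space <- new("LabelSpace", namespace = "MFO",
               terms = c("GO:0000002", "GO:0000003"),
               ancestorsInSpace = list(integer(0), 1L))
  ic <- informationContent(annots, dag, space)
  expect_equal(unname(ic["GO:0000002"]), 0)  # co-extensive with root
  expect_equal(unname(ic["GO:0000003"]), 1)  # half of parent-annotated

  # multi-parent terms on a random fixture vs nested-loop oracle
  study <- randomStudy(29, m = 120)
  Y <- labelMatrix(study$dataset)
  annots <- annotationSetFromLabels(Y, study$dag, study$space)
  ic <- informationContent(annots, study$dag, study$space)
  ann <- annotations(annots)
  for (v in goTerms(study$space)) {
    ps <- goParents(study$dag)[[v]]
    nV <- 0L; nPa <- 0L
    for (p in names(ann)) {
      if (all(ps %in% ann[[p]])) nPa <- nPa + 1L
      if (v %in% ann[[p]]) nV <- nV + 1L
    }
    expect_equal(unname(ic[v]), max(-log2(nV / nPa), 0), tolerance = 1e-12)
  }
  # invariant to protein re-ordering
  annR <- new("AnnotationSet", annotations = rev(ann), propagated = TRUE)
  expect_equal(informationContent(annR, study$dag, study$space), ic)
})

test_that("max-score propagation enforces parent >= child and is idempotent", {
  # chain: term2 (parent) <- term3 (child)
  space <- new("LabelSpace", namespace = "MFO", terms = c("b", "c"),
               ancestorsInSpace = list(integer(0), 1L))
  S <- matrix(c(0.2, 0.9), 1, 2)
  out <- propagateScoresMax(S, space)
  expect_equal(out, matrix(c(0.9, 0.9), 1, 2))
  expect_equal(propagateScoresMax(out, space), out)

  study <- randomStudy(31, depth = 3, branching = 3)
  set.seed(123)
  S <- matrix(runif(20 * length(goTerms(study$space))), 20)
  out <- propagateScoresMax(S, study$space)
  expect_true(all(out >= S))
  oracle <- oracleDescendantMax(S, study$dag, goTerms(study$space))
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(propagateScoresMax(out, study$space), out)
})
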