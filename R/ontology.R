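## GO ontology handling: OBO parsing, true-path propagation, label-space
## selection, conditional information content, hierarchical score propagation.

#' Experimental-support evidence codes
#'
#' The default set of GO evidence codes counted as experimental support when
#' filtering annotation records: direct assays, physical interactions, mutant
#' phenotypes, genetic interactions, expression patterns, curator statements
#' and their high-throughput counterparts. Electronic annotations (IEA) and
#' sequence-similarity transfers (ISS) are excluded.
#'
#' @format character vector of 13 evidence codes.
#' @export
experimentalEvidenceCodes <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  "TAS", "IC", "HTP", "HDA", "HMP", "HGI", "HEP"
)

.NAMESPACE_MAP <- c(
  molecular_function = "MFO",
  cellular_component = "CCO",
  biological_process = "BPO",
  MFO = "MFO", CCO = "CCO", BPO = "BPO"
)

#' Parse a go-basic style OBO file
#'
#' Reads OBO 1.2 text and builds the is-a DAG. Only the tags \code{id},
#' \code{name}, \code{namespace}, \code{is_a}, \code{alt_id} and
#' \code{is_obsolete} are honored; \code{relationship:} lines (part_of,
#' regulates, ...) and \code{[Typedef]} stanzas are ignored, obsolete terms
#' are dropped, and alternate ids are mapped to their canonical term. The
#' unique parent-less term of each namespace becomes that namespace's root.
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @return an [OntologyDAG-class].
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: root",
#'          "namespace: molecular_function",
#'          "[Term]", "id: GO:2", "name: leaf",
#'          "namespace: molecular_function", "is_a: GO:1 ! root")
#' dag <- parseOBO(obo)
#' goRoots(dag)
#' @export
parseOBO <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  lines <- trimws(lines)

  # split into stanzas
  starts <- grep("^\\[", lines)
  stanzaType <- lines[starts]
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0); nm <- character(0); ns <- character(0)
  parents <- list(); altOf <- character(0)
  tagval <- function(block, tag) {
    hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
    sub("\\s*!.*$", "", sub(paste0("^", tag, ":\\s*"), "", hit))
  }
  for (s in seq_along(starts)) {
    if (stanzaType[s] != "[Term]") next
    block <- lines[(starts[s] + 1L):(bounds[s + 1L] - 1L)]
    id <- tagval(block, "id")
    if (length(id) != 1L) {
      stop("OBO structural error: [Term] stanza without a unique id",
           call. = FALSE)
    }
    obs <- tagval(block, "is_obsolete")
    if (length(obs) && any(obs == "true")) next
    namespace <- tagval(block, "namespace")
    nsShort <- if (length(namespace)) .NAMESPACE_MAP[[namespace[1]]] else NA_character_
    if (is.na(nsShort)) {
      stop("OBO structural error: term ", id, " has unknown namespace",
           call. = FALSE)
    }
    name <- tagval(block, "name")
    ids <- c(ids, id)
    nm[id] <- if (length(name)) name[1] else id
    ns[id] <- nsShort
    parents[[id]] <- unique(tagval(block, "is_a"))
    for (a in tagval(block, "alt_id")) altOf[a] <- id
  }
  if (!length(ids)) stop("OBO structural error: no usable [Term] stanzas",
                         call. = FALSE)

  refd <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(refd, ids)
  if (length(unknown)) {
    stop("OBO structural error: is_a reference to unknown term(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  # cycle check with a named offending edge
  edges <- data.frame(
    child = rep(ids, lengths(parents[ids])),
    parent = unlist(parents[ids], use.names = FALSE)
  )
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      bad <- names(comp$membership)[comp$membership ==
                                      which(comp$csize > 1)[1]]
      inCyc <- edges$child %in% bad & edges$parent %in% bad
      e <- edges[which(inCyc)[1], ]
      stop("OBO structural error: cycle through is_a edge ", e$child,
           " -> ", e$parent, call. = FALSE)
    }
  }

  roots <- character(0)
  for (space in unique(ns)) {
    cand <- ids[ns[ids] == space & lengths(parents[ids]) == 0L]
    if (length(cand) != 1L) {
      stop("OBO structural error: namespace ", space, " has ",
           length(cand), " parent-less terms (expected exactly 1)",
           call. = FALSE)
    }
    roots[space] <- cand
  }

  # parents must stay within the namespace
  for (id in ids) {
    p <- parents[[id]]
    if (length(p) && any(ns[p] != ns[[id]])) {
      stop("OBO structural error: term ", id, " has a parent in a ",
           "different namespace", call. = FALSE)
    }
  }

  new("OntologyDAG",
      terms = ids, termName = nm[ids], termNamespace = ns[ids],
      parents = parents[ids], roots = roots, altIds = altOf)
}

#' Ancestors of GO terms
#'
#' All is-a ancestors of the given terms (self excluded), up to and including
#' the namespace root.
#'
#' @param dag an [OntologyDAG-class].
#' @param ids character vector of term ids (alternate ids are mapped).
#' @return named list, id -> character vector of ancestor ids.
#' @export
goAncestors <- function(dag, ids) {
  anc <- .ancestorList(dag)
  ids2 <- .mapAltIds(dag, ids)
  setNames(anc[ids2], ids)
}

# full ancestor closure for every term, parents-first dynamic program
.ancestorList <- function(dag) {
  ord <- .topoOrder(dag)           # parents before children
  anc <- vector("list", length(ord))
  names(anc) <- ord
  for (t in ord) {
    ps <- dag@parents[[t]]
    anc[[t]] <- if (length(ps)) {
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    } else character(0)
  }
  anc[dag@terms]
}

# deterministic topological order, parents first, lexicographic tie-break
.topoOrder <- function(dag, terms = dag@terms) {
  parents <- lapply(dag@parents[terms], function(p) intersect(p, terms))
  names(parents) <- terms
  remainingDeg <- lengths(parents)
  names(remainingDeg) <- terms
  children <- list()
  for (t in terms) for (p in parents[[t]]) {
    children[[p]] <- c(children[[p]], t)
  }
  avail <- sort(terms[remainingDeg == 0L])
  out <- character(0)
  while (length(avail)) {
    t <- avail[1]
    avail <- avail[-1]
    out <- c(out, t)
    for (ch in children[[t]]) {
      remainingDeg[ch] <- remainingDeg[ch] - 1L
      if (remainingDeg[ch] == 0L) {
        avail <- sort(c(avail, ch))
      }
    }
  }
  if (length(out) != length(terms)) {
    stop("cycle detected during topological ordering", call. = FALSE)
  }
  out
}

.mapAltIds <- function(dag, ids) {
  hit <- ids %in% names(dag@altIds)
  if (any(hit)) ids[hit] <- dag@altIds[ids[hit]]
  ids
}

#' Filter annotation records by evidence code
#'
#' Keeps only records whose evidence code is in \code{allowed} (by default the
#' 13 experimental-support codes in [experimentalEvidenceCodes]); proteins
#' left with no surviving record are dropped. Duplicate (protein, term)
#' records collapse to one annotation.
#'
#' @param records data.frame with columns protein_id, term_id, evidence_code.
#' @param allowed character vector of evidence codes to keep.
#' @return an [AnnotationSet-class] (not yet propagated).
#' @export
filterEvidence <- function(records, allowed = experimentalEvidenceCodes) {
  if (!length(allowed)) {
    stop("configuration error: 'allowed' evidence-code set is empty",
         call. = FALSE)
  }
  stopifnot(all(c("protein_id", "term_id", "evidence_code") %in%
                  names(records)))
  keep <- records$evidence_code %in% allowed
  kept <- records[keep, , drop = FALSE]
  message("filterEvidence: kept ", nrow(kept), " of ", nrow(records),
          " records")
  annots <- if (nrow(kept)) {
    lapply(split(kept$term_id, kept$protein_id), function(x) unique(x))
  } else {
    structure(list(), names = character(0))
  }
  new("AnnotationSet",
      annotations = annots,
      evidence = data.frame(protein_id = kept$protein_id,
                            term_id = kept$term_id,
                            evidence_code = kept$evidence_code,
                            stringsAsFactors = FALSE),
      propagated = FALSE)
}

#' Read an annotation file
#'
#' Tab-separated columns \code{protein_id  term_id  evidence_code};
#' '#'-comment lines allowed.
#'
#' @param file path.
#' @return data.frame with the three columns.
#' @export
readAnnotations <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(protein_id = character(0), term_id = character(0),
                      evidence_code = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    bad <- which(lengths(parts) != 3L)[1]
    stop("parse error in annotation file line ", bad,
         ": expected 3 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(protein_id = m[, 1], term_id = m[, 2], evidence_code = m[, 3],
             stringsAsFactors = FALSE)
}

#' True-path propagation of annotations
#'
#' Replaces every protein's term set by its ancestor closure (self included,
#' up to and including the namespace root), so each set is a consistent
#' sub-graph of the DAG. Idempotent. Alternate ids are mapped to canonical
#' terms first; unknown terms are an error.
#'
#' @param annots an [AnnotationSet-class].
#' @param dag an [OntologyDAG-class].
#' @return a propagated [AnnotationSet-class].
#' @export
propagateTruePath <- function(annots, dag) {
  anc <- .ancestorList(dag)
  nAlt <- 0L
  out <- lapply(annotations(annots), function(terms) {
    mapped <- .mapAltIds(dag, terms)
    nAlt <<- nAlt + sum(mapped != terms)
    unknown <- setdiff(mapped, dag@terms)
    if (length(unknown)) {
      stop("lookup error: unknown term id(s): ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    sort(unique(c(mapped, unlist(anc[mapped], use.names = FALSE))))
  })
  if (nAlt > 0L) message("propagateTruePath: mapped ", nAlt,
                         " alternate-id annotations")
  new("AnnotationSet", annotations = out, propagated = TRUE)
}

#' Select the label space for one namespace
#'
#' Terms of the namespace annotated in at least \code{minCount} proteins
#' (counted on propagated annotations), excluding the namespace root. Terms
#' are ordered topologically (ancestors first) with lexicographic tie-break,
#' so label matrices are reproducible.
#'
#' @param annots propagated [AnnotationSet-class].
#' @param dag an [OntologyDAG-class].
#' @param namespace "MFO", "CCO" or "BPO".
#' @param minCount minimum number of annotated proteins per kept term
#'   (conventional thresholds: 30 for MFO and CCO, 60 for BPO).
#' @return a [LabelSpace-class].
#' @export
selectLabelSpace <- function(annots, dag, namespace, minCount) {
  stopifnot(minCount >= 1)
  if (!isPropagated(annots)) {
    stop("annotations must be true-path propagated before label selection",
         call. = FALSE)
  }
  if (!namespace %in% names(dag@roots)) {
    stop("namespace '", namespace, "' not present in the ontology",
         call. = FALSE)
  }
  counts <- table(unlist(annotations(annots), use.names = FALSE))
  nsTerms <- dag@terms[dag@termNamespace == namespace]
  root <- dag@roots[[namespace]]
  cnt <- as.numeric(counts[nsTerms])
  cnt[is.na(cnt)] <- 0
  keep <- setdiff(nsTerms[cnt >= minCount], root)
  if (!length(keep)) {
    stop("no labels survive threshold: namespace ", namespace,
         ", minCount ", minCount, call. = FALSE)
  }
  ord <- .topoOrder(dag, nsTerms)
  terms <- ord[ord %in% keep]
  anc <- .ancestorList(dag)
  idx <- setNames(seq_along(terms), terms)
  ancSpace <- lapply(terms, function(t) {
    unname(idx[intersect(anc[[t]], terms)])
  })
  message("selectLabelSpace: ", length(terms), " of ", length(nsTerms),
          " ", namespace, " terms kept at minCount ", minCount)
  new("LabelSpace", namespace = namespace, terms = terms,
      ancestorsInSpace = ancSpace, ic = numeric(0))
}

#' Encode annotations as a binary label matrix
#'
#' @param annots an [AnnotationSet-class] (propagated, so rows are
#'   ancestor-closed within the space).
#' @param space a [LabelSpace-class].
#' @param rosterIds ordered protein ids; must all be annotated.
#' @return binary matrix (length(rosterIds) x n_y) with dimnames.
#' @export
encodeLabels <- function(annots, space, rosterIds) {
  ann <- annotations(annots)
  missing <- setdiff(rosterIds, names(ann))
  if (length(missing)) {
    stop("lookup error: roster protein(s) missing from annotations: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  Y <- matrix(0, nrow = length(rosterIds), ncol = length(space@terms),
              dimnames = list(rosterIds, space@terms))
  for (i in seq_along(rosterIds)) {
    hit <- space@terms %in% ann[[rosterIds[i]]]
    Y[i, hit] <- 1
  }
  Y
}

#' Conditional information content of label-space terms
#'
#' For each in-space term v, I(v) = -log2( n(v) / n(Pa(v)) ) in bits, where
#' n(v) is the number of proteins annotated with v and n(Pa(v)) the number
#' annotated with \emph{all} parents of v jointly. On propagated annotations
#' v implies all its parents, so I(v) >= 0, and a term co-extensive with its
#' parents carries 0 bits.
#'
#' @param annots propagated [AnnotationSet-class].
#' @param dag an [OntologyDAG-class].
#' @param space a [LabelSpace-class].
#' @return named numeric vector of bits, one per in-space term.
#' @export
informationContent <- function(annots, dag, space) {
  if (!isPropagated(annots)) {
    stop("information content requires propagated annotations", call. = FALSE)
  }
  ann <- annotations(annots)
  ic <- setNames(numeric(length(space@terms)), space@terms)
  for (v in space@terms) {
    ps <- dag@parents[[v]]
    nV <- sum(vapply(ann, function(s) v %in% s, logical(1)))
    nPa <- sum(vapply(ann, function(s) all(ps %in% s), logical(1)))
    if (nPa == 0L) {
      stop("consistency error: term ", v, " has no parent-annotated ",
           "proteins; it should have been excluded by selectLabelSpace",
           call. = FALSE)
    }
    ic[v] <- -log2(nV / nPa)
  }
  pmax(ic, 0)  # guard tiny negative from floating log of ratio 1
}

#' Attach information content to a label space
#'
#' @param space a [LabelSpace-class].
#' @param ic numeric vector as returned by [informationContent()] (order must
#'   match the space's terms; a named vector is checked by name).
#' @return the [LabelSpace-class] with ic attached.
#' @export
attachIC <- function(space, ic) {
  if (!is.null(names(ic))) {
    stopifnot(setequal(names(ic), space@terms))
    ic <- ic[space@terms]
  }
  stopifnot(length(ic) == length(space@terms))
  space@ic <- unname(ic)
  validObject(space)
  space
}

#' Build a propagated annotation set from a binary label matrix
#'
#' Each protein is annotated with its positive in-space terms plus the
#' namespace root; rows must already be ancestor-closed within the space
#' (as [encodeLabels()] and the synthetic generator guarantee), so the
#' result is true-path consistent by construction.
#'
#' @param Y binary matrix with protein rownames and term colnames.
#' @param dag an [OntologyDAG-class].
#' @param space the [LabelSpace-class] the columns live in.
#' @return a propagated [AnnotationSet-class].
#' @export
annotationSetFromLabels <- function(Y, dag, space) {
  stopifnot(identical(colnames(Y), space@terms))
  root <- dag@roots[[space@namespace]]
  ann <- lapply(seq_len(nrow(Y)), function(i) {
    c(root, colnames(Y)[Y[i, ] == 1])
  })
  names(ann) <- rownames(Y)
  new("AnnotationSet", annotations = ann, propagated = TRUE)
}

#' Hierarchical max-score propagation
#'
#' Post-processes a score matrix so that every in-space ancestor carries at
#' least the score of each of its in-space descendants: each term's score
#' becomes the maximum over itself and all its in-space descendants. The
#' result satisfies score(parent) >= score(child) on every in-space is-a
#' edge, never decreases any entry, and is idempotent.
#'
#' @param scores numeric matrix (m x n_y), finite.
#' @param space a [LabelSpace-class].
#' @return matrix of the same shape.
#' @export
propagateScoresMax <- function(scores, space) {
  stopifnot(ncol(scores) == length(space@terms), all(is.finite(scores)))
  n <- length(space@terms)
  desc <- vector("list", n)
  for (i in seq_len(n)) {
    for (a in space@ancestorsInSpace[[i]]) {
      desc[[a]] <- c(desc[[a]], i)
    }
  }
  out <- scores
  for (j in seq_len(n)) {
    if (length(desc[[j]])) {
      block <- scores[, c(j, desc[[j]]), drop = FALSE]
      out[, j] <- do.call(pmax, lapply(seq_len(ncol(block)),
                                       function(k) block[, k]))
    }
  }
  out
}
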