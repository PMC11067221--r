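## Frequency and sequence-similarity baselines: pure scoring rules over
## training labels and precomputed alignment hit tables.

#' Naive frequency baseline
#'
#' Every test protein receives, for each term, the relative frequency of the
#' term among the training proteins. All test rows are identical.
#'
#' @param Ytrain binary training label matrix (rows = training proteins).
#' @param testIds protein ids for the output rows (or an integer count).
#' @return score matrix (n_test x n_y).
#' @export
naiveScores <- function(Ytrain, testIds) {
  stopifnot(nrow(Ytrain) > 0)
  if (is.numeric(testIds) && length(testIds) == 1L) {
    testIds <- paste0("test", seq_len(testIds))
  }
  freq <- colMeans(Ytrain)
  matrix(freq, nrow = length(testIds), ncol = ncol(Ytrain), byrow = TRUE,
         dimnames = list(testIds, colnames(Ytrain)))
}

#' Read a 12-column tabular alignment hit file
#'
#' The standard tabular alignment format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score). Rows with e-value above the cutoff are dropped.
#'
#' @param file path.
#' @param evalueMax e-value cutoff; hits above it are considered spurious
#'   (default 0.001).
#' @return data.frame with columns query, subject, pident, evalue, bitscore.
#' @export
readBlastTabular <- function(file, evalueMax = 0.001) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(query = character(0), subject = character(0),
                      pident = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 12L)) {
    stop("parse error line ", which(lengths(parts) != 12L)[1],
         ": expected 12 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("parse error line ", which(is.na(v))[1], ": non-numeric column ",
           j, call. = FALSE)
    }
    v
  }
  hits <- data.frame(query = m[, 1], subject = m[, 2], pident = num(3),
                     evalue = num(11), bitscore = num(12),
                     stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("parse error: percent identity outside [0,100]", call. = FALSE)
  }
  if (any(hits$evalue < 0)) {
    stop("parse error: negative e-value", call. = FALSE)
  }
  kept <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  message("readBlastTabular: kept ", nrow(kept), " of ", nrow(hits),
          " hits at e-value <= ", evalueMax)
  rownames(kept) <- NULL
  kept
}

# best hit per query: max bit score, ties by min e-value then subject id
.bestHits <- function(hits) {
  bySubj <- hits[order(hits$query, -hits$bitscore, hits$evalue,
                       hits$subject), ]
  bySubj[!duplicated(bySubj$query), , drop = FALSE]
}

#' Annotation transfer from the single best hit
#'
#' Each query inherits the full in-space label row of the training protein
#' with the highest scoring alignment (ties broken by lower e-value, then
#' lexicographic subject id). Queries without hits get zero rows, reducing
#' coverage.
#'
#' @param hits data.frame from [readBlastTabular()].
#' @param Ytrain binary training label matrix with protein rownames.
#' @param queryIds ordered query ids for the output rows.
#' @return binary prediction matrix (length(queryIds) x n_y).
#' @export
blastFull <- function(hits, Ytrain, queryIds) {
  stopifnot(!is.null(rownames(Ytrain)))
  unknown <- setdiff(unique(hits$subject), rownames(Ytrain))
  if (length(unknown)) {
    stop("hit subject(s) outside the training roster: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  best <- .bestHits(hits)
  out <- matrix(0, length(queryIds), ncol(Ytrain),
                dimnames = list(queryIds, colnames(Ytrain)))
  hit <- match(queryIds, best$query)
  for (i in which(!is.na(hit))) {
    out[i, ] <- Ytrain[best$subject[hit[i]], ]
  }
  out
}

#' Per-term maximum-identity transfer
#'
#' The score of query i for term j is the maximum percent identity (divided
#' by 100, sharing the [0,1] threshold grid with model scores) over the
#' query's hits to training proteins annotated with j; 0 when no annotated
#' subject is hit.
#'
#' @param hits data.frame from [readBlastTabular()].
#' @param Ytrain binary training label matrix with protein rownames.
#' @param queryIds ordered query ids for the output rows.
#' @return score matrix in [0,1].
#' @export
blastPartial <- function(hits, Ytrain, queryIds) {
  stopifnot(!is.null(rownames(Ytrain)))
  unknown <- setdiff(unique(hits$subject), rownames(Ytrain))
  if (length(unknown)) {
    stop("hit subject(s) outside the training roster: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, length(queryIds), ncol(Ytrain),
                dimnames = list(queryIds, colnames(Ytrain)))
  for (i in seq_along(queryIds)) {
    h <- hits[hits$query == queryIds[i], , drop = FALSE]
    if (!nrow(h)) next
    Ysub <- Ytrain[h$subject, , drop = FALSE]
    ident <- h$pident / 100
    # per term: max identity over hits whose subject carries the term
    out[i, ] <- apply(Ysub * ident, 2, max)
  }
  out
}
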