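## Protein-centric CAFA evaluation: precision-recall over a threshold grid,
## Fmax, IC-weighted Fmax, Smin, AUPRC, AUROC and coverage.

#' Evaluation configuration
#'
#' @param taus strictly increasing threshold grid in (0,1]; default the CAFA
#'   convention 0.01, 0.02, ..., 1.00.
#' @param ic optional per-term information content vector (bits), required by
#'   [weightedFmax()] and [sminDistance()].
#' @return list of settings.
#' @export
evalControl <- function(taus = seq(0.01, 1, by = 0.01), ic = NULL) {
  stopifnot(all(diff(taus) > 0), all(taus > 0), all(taus <= 1))
  list(taus = taus, ic = ic)
}

# per-threshold confusion summaries; the workhorse for all metrics.
# Returns a list of data per tau: prediction mask is S >= tau.
.checkYS <- function(Y, S) {
  stopifnot(is.matrix(Y), is.matrix(S), all(dim(Y) == dim(S)))
  if (!all(Y %in% c(0, 1))) stop("Y must be binary", call. = FALSE)
  if (!all(is.finite(S))) stop("scores must be finite", call. = FALSE)
}

#' Protein-centric precision-recall curve
#'
#' At each threshold tau, predictions are the terms with score >= tau.
#' Precision is averaged over the m(tau) proteins with at least one call;
#' recall is averaged over \emph{all} test proteins, with proteins whose true
#' set is empty contributing recall 1. Thresholds with m(tau) = 0 carry
#' pr = NA and are skipped by downstream metrics.
#'
#' @param Y binary truth matrix (m x n_y), root terms excluded.
#' @param S score matrix in [0,1], same shape.
#' @param cfg list from [evalControl()].
#' @return data.frame with columns tau, pr, rc, m.
#' @export
prCurve <- function(Y, S, cfg = evalControl()) {
  .checkYS(Y, S)
  nTrue <- rowSums(Y)
  out <- data.frame(tau = cfg$taus, pr = NA_real_, rc = NA_real_,
                    m = NA_integer_)
  for (i in seq_along(cfg$taus)) {
    P <- S >= cfg$taus[i]
    nPred <- rowSums(P)
    tp <- rowSums(P & Y == 1)
    called <- nPred > 0
    out$m[i] <- sum(called)
    out$pr[i] <- if (any(called)) mean(tp[called] / nPred[called]) else NA_real_
    rcI <- ifelse(nTrue > 0, tp / pmax(nTrue, 1), 1)
    out$rc[i] <- mean(rcI)
  }
  out
}

#' Maximum F1 over the threshold grid
#'
#' @param curve data.frame from [prCurve()].
#' @return list with \code{fmax} and \code{tau} (smallest argmax; NA when no
#'   threshold yields a valid point, in which case fmax = 0).
#' @export
fmaxScore <- function(curve) {
  valid <- !is.na(curve$pr) & curve$m > 0 & (curve$pr + curve$rc) > 0
  if (!any(valid)) return(list(fmax = 0, tau = NA_real_))
  f <- ifelse(valid, 2 * curve$pr * curve$rc / (curve$pr + curve$rc), -Inf)
  best <- which.max(f)
  list(fmax = f[best], tau = curve$tau[best])
}

# IC-weighted precision/recall at each threshold
.weightedCurve <- function(Y, S, ic, taus) {
  .checkYS(Y, S)
  if (length(ic) != ncol(Y)) stop("ic length mismatch", call. = FALSE)
  if (any(ic < 0)) stop("ic must be non-negative", call. = FALSE)
  icM <- matrix(ic, nrow(Y), ncol(Y), byrow = TRUE)
  trueMass <- rowSums(icM * (Y == 1))
  out <- data.frame(tau = taus, pr = NA_real_, rc = NA_real_, m = NA_integer_)
  for (i in seq_along(taus)) {
    P <- S >= taus[i]
    predMass <- rowSums(icM * P)
    tpMass <- rowSums(icM * (P & Y == 1))
    called <- predMass > 0
    out$m[i] <- sum(called)
    out$pr[i] <- if (any(called)) {
      mean(tpMass[called] / predMass[called])
    } else NA_real_
    rcI <- ifelse(trueMass > 0, tpMass / pmax(trueMass, 1e-300), 1)
    out$rc[i] <- mean(rcI)
  }
  out
}

#' IC-weighted maximum F1
#'
#' As [fmaxScore()] but with per-term counts replaced by information-content
#' weighted masses: weighted precision averages over proteins with positive
#' predicted IC mass, weighted recall over all proteins (empty-truth proteins
#' contribute 1). With uniform IC this reduces to the unweighted Fmax.
#'
#' @param Y,S as in [prCurve()].
#' @param ic per-term information content (bits).
#' @param cfg list from [evalControl()].
#' @return list with \code{wfmax} and \code{tau}.
#' @export
weightedFmax <- function(Y, S, ic, cfg = evalControl()) {
  curve <- .weightedCurve(Y, S, ic, cfg$taus)
  r <- fmaxScore(curve)
  list(wfmax = r$fmax, tau = r$tau)
}

#' Minimum semantic distance
#'
#' At each threshold, remaining uncertainty ru(tau) is the mean (over all
#' test proteins) total IC of true-but-not-predicted terms, and
#' misinformation mi(tau) the mean total IC of predicted-but-not-true terms;
#' Smin is the minimum over thresholds of sqrt(ru^2 + mi^2), in bits.
#'
#' @param Y,S as in [prCurve()].
#' @param ic per-term information content (bits).
#' @param cfg list from [evalControl()].
#' @return list with \code{smin} and \code{tau} (smallest argmin).
#' @export
sminDistance <- function(Y, S, ic, cfg = evalControl()) {
  .checkYS(Y, S)
  if (length(ic) != ncol(Y)) stop("ic length mismatch", call. = FALSE)
  icM <- matrix(ic, nrow(Y), ncol(Y), byrow = TRUE)
  s <- numeric(length(cfg$taus))
  for (i in seq_along(cfg$taus)) {
    P <- S >= cfg$taus[i]
    ru <- mean(rowSums(icM * (Y == 1 & !P)))
    mi <- mean(rowSums(icM * (P & Y == 0)))
    s[i] <- sqrt(ru^2 + mi^2)
  }
  best <- which.min(s)
  list(smin = s[best], tau = cfg$taus[best])
}

#' Area under the precision-recall curve
#'
#' Step sum pr(tau_i) * (rc(tau_i) - rc(tau_{i-1})) over valid thresholds,
#' taken in order of decreasing tau (recall increasing) and anchored at
#' recall 0; the absolute value is reported. Grid-resolution limited.
#'
#' @param curve data.frame from [prCurve()].
#' @return scalar in [0,1].
#' @export
auprcScore <- function(curve) {
  valid <- !is.na(curve$pr) & curve$m > 0
  if (!any(valid)) return(0)
  v <- curve[valid, ]
  v <- v[order(v$tau, decreasing = TRUE), ]
  rcPrev <- c(0, v$rc[-nrow(v)])
  abs(sum(v$pr * (v$rc - rcPrev)))
}

#' Micro-averaged AUROC
#'
#' All protein-term pairs are pooled; the statistic is the probability that a
#' uniformly drawn positive pair outscores a uniformly drawn negative pair,
#' counting ties as 1/2 (ties-averaged rank form).
#'
#' @param Y,S as in [prCurve()].
#' @return scalar in [0,1]; NA when there is no positive or no negative pair.
#' @export
aurocScore <- function(Y, S) {
  .checkYS(Y, S)
  pos <- S[Y == 1]
  neg <- S[Y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * as.numeric(length(neg)))
}

#' Prediction coverage
#'
#' Fraction of proteins with at least one strictly positive score.
#'
#' @param S score matrix.
#' @return scalar in [0,1].
#' @export
coverageScore <- function(S) {
  if (nrow(S) == 0) return(0)
  mean(rowSums(S > 0) > 0)
}

#' Evaluate a score matrix against a truth matrix
#'
#' Computes all protein-centric metrics in one pass and returns a
#' [MetricsReport-class]. IC-weighted metrics require \code{cfg$ic} (e.g.
#' from [informationContent()]).
#'
#' @param Y binary truth matrix.
#' @param S score matrix in [0,1], same shape.
#' @param cfg list from [evalControl()].
#' @return a [MetricsReport-class].
#' @export
evaluateScores <- function(Y, S, cfg = evalControl()) {
  curve <- prCurve(Y, S, cfg)
  f <- fmaxScore(curve)
  au <- auprcScore(curve)
  roc <- aurocScore(Y, S)
  cov <- coverageScore(S)
  if (!is.null(cfg$ic)) {
    wf <- weightedFmax(Y, S, cfg$ic, cfg)
    sm <- sminDistance(Y, S, cfg$ic, cfg)
  } else {
    wf <- list(wfmax = NA_real_, tau = NA_real_)
    sm <- list(smin = NA_real_, tau = NA_real_)
  }
  new("MetricsReport",
      fmax = f$fmax, tauFmax = f$tau,
      wfmax = wf$wfmax, tauWfmax = wf$tau,
      smin = sm$smin, tauSmin = sm$tau,
      auprc = au, auroc = roc, coverage = cov)
}
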