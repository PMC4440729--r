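#' Tolerant matching of detected groups against ground truth
#'
#' A ground-truth group `G` is considered correctly detected by a detected
#' group `D` when at least `ceiling(T * |G|)` of its members appear in `D`
#' and `D` carries at most `ceiling((1 - T) * |G|)` false subjects (members
#' outside `G`).  At `T = 1` this reduces to exact set equality.  Matching is
#' one-to-one and greedy by descending intersection size (ties broken by the
#' order of the truth groups, then of the detected groups).  Detected
#' singletons never participate: ground truth contains only groups of
#' cardinality >= 2.
#'
#' @param detected,truth [gcff_groups] objects sharing a person-id universe.
#' @param T tolerance threshold in \[1/2, 1\].
#' @return object of class `gcff_match`: list with `T`, `tp`, `fp`, `fn` and
#'   `matched_pairs` (list of `(truth_index, detected_index)` pairs).
#' @examples
#' truth <- gcff_groups(list(c("a", "b", "c")))
#' det   <- gcff_groups(list(c("a", "b", "d")), singletons = "c")
#' tolerant_match(det, truth, T = 2 / 3)$tp   # 1
#' tolerant_match(det, truth, T = 1)$tp       # 0
#' @export
tolerant_match <- function(detected, truth, T) {
  if (!is.numeric(T) || length(T) != 1L || T < 0.5 || T > 1) {
    stop("tolerance T must lie in [1/2, 1]", call. = FALSE)
  }
  detected <- as_gcff_groups(detected)
  truth <- as_gcff_groups(truth)
  tg <- truth$groups
  dg <- detected$groups
  nt <- length(tg); nd <- length(dg)
  matched_pairs <- list()
  if (nt > 0L && nd > 0L) {
    inter <- matrix(0L, nt, nd)
    ok <- matrix(FALSE, nt, nd)
    for (a in seq_len(nt)) {
      card <- length(tg[[a]])
      need <- ceil_tol(T * card)
      allow_false <- ceil_tol((1 - T) * card)
      for (b in seq_len(nd)) {
        found <- length(intersect(tg[[a]], dg[[b]]))
        inter[a, b] <- found
        ok[a, b] <- found >= need &&
          (length(dg[[b]]) - found) <= allow_false
      }
    }
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      sizes <- inter[ok]
      ord <- order(-sizes, cand[, 1L], cand[, 2L])
      used_t <- logical(nt); used_d <- logical(nd)
      for (r in ord) {
        a <- cand[r, 1L]; b <- cand[r, 2L]
        if (!used_t[a] && !used_d[b]) {
          used_t[a] <- TRUE; used_d[b] <- TRUE
          matched_pairs[[length(matched_pairs) + 1L]] <- c(truth = a,
                                                           detected = b)
        }
      }
    }
  }
  tp <- length(matched_pairs)
  structure(list(T = T, tp = tp, fp = nd - tp, fn = nt - tp,
                 matched_pairs = matched_pairs),
            class = "gcff_match")
}

# ceiling robust to the binary representation of T = 2/3 etc.
ceil_tol <- function(x) ceiling(x - 1e-9)

#' @export
print.gcff_match <- function(x, ...) {
  cat(sprintf("<gcff_match> T = %.4g: TP = %d, FP = %d, FN = %d\n",
              x$T, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean.
#' Empty denominators follow the vacuous convention: with no detected
#' groups precision is 1, with no truth groups recall is 1 (an empty frame
#' therefore scores a perfect 1/1/1); F1 is 0 when precision + recall = 0.
#'
#' @param m a `gcff_match`, or anything with `tp`, `fp`, `fn` fields.
#' @return named numeric vector `(precision, recall, f1)`, each in \[0, 1\].
#' @export
precision_recall_f1 <- function(m) {
  precision <- if (m$tp + m$fp == 0L) 1 else m$tp / (m$tp + m$fp)
  recall <- if (m$tp + m$fn == 0L) 1 else m$tp / (m$tp + m$fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Dataset-level evaluation over aligned frame lists
#'
#' Matches every frame at tolerance `T` and micro-averages: TP/FP/FN are
#' summed over frames before precision/recall/F1 are computed, so frames
#' with no groups at all are neutral.
#'
#' @param detected_frames,truth_frames aligned lists of [gcff_groups].
#' @param T tolerance in \[1/2, 1\].
#' @return named numeric vector `(precision, recall, f1, tp, fp, fn)`.
#' @export
evaluate_frames <- function(detected_frames, truth_frames, T) {
  stopifnot(length(detected_frames) == length(truth_frames))
  tp <- fp <- fn <- 0L
  for (i in seq_along(detected_frames)) {
    m <- tolerant_match(detected_frames[[i]], truth_frames[[i]], T)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  prf <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
  c(prf, tp = tp, fp = fp, fn = fn)
}

#' Global Tolerant Matching (GTM) score
#'
#' Area under the dataset-level F1-versus-tolerance curve, evaluated at
#' `T = 1/2, 2/3, 5/6, 1` (three equal steps of 1/6), integrated by the
#' trapezoidal rule over \[1/2, 1\] and normalised by the interval length
#' 1/2 — a detector with constant F1 = c scores GTM = c.
#'
#' @inheritParams evaluate_frames
#' @return scalar in \[0, 1\].
#' @export
gtm <- function(detected_frames, truth_frames) {
  grid <- c(1 / 2, 2 / 3, 5 / 6, 1)
  f1s <- vapply(grid, function(T) {
    evaluate_frames(detected_frames, truth_frames, T)[["f1"]]
  }, numeric(1L))
  auc <- sum(diff(grid) * (utils::head(f1s, -1L) + utils::tail(f1s, -1L)) / 2)
  auc / (1 / 2)
}

#' Cardinality-stratified F1
#'
#' Restricts the evaluation to groups of one cardinality `k`: truth groups
#' of size k count as TP when matched by the global (all-cardinality)
#' matching and FN otherwise, while FP counts detected groups of size k left
#' unmatched.  Useful to see which group sizes a detector handles well.
#'
#' @inheritParams evaluate_frames
#' @param k group cardinality, >= 2.
#' @return named numeric vector `(precision, recall, f1, tp, fp, fn)` for
#'   stratum `k`.
#' @export
cardinality_f1 <- function(detected_frames, truth_frames, k, T) {
  stopifnot(k >= 2)
  tp <- fp <- fn <- 0L
  for (i in seq_along(detected_frames)) {
    det <- as_gcff_groups(detected_frames[[i]])
    tru <- as_gcff_groups(truth_frames[[i]])
    m <- tolerant_match(det, tru, T)
    mt <- vapply(m$matched_pairs, `[`, 0, 1L)
    md <- vapply(m$matched_pairs, `[`, 0, 2L)
    tsize <- vapply(tru$groups, length, 1L)
    dsize <- vapply(det$groups, length, 1L)
    tp <- tp + sum(tsize[mt] == k)
    fn <- fn + sum(tsize == k) - sum(tsize[mt] == k)
    fp <- fp + sum(dsize == k) - sum(dsize[md] == k)
  }
  prf <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
  c(prf, tp = tp, fp = fp, fn = fn)
}

#' Mean and standard deviation of F1 across cardinalities
#'
#' Computes [cardinality_f1()] for every cardinality present among the truth
#' groups and summarises.
#'
#' @inheritParams cardinality_f1
#' @return list with `by_k` (data frame: k, precision, recall, f1) and
#'   `mean`, `sd` of the per-cardinality F1 scores.
#' @export
cardinality_f1_summary <- function(detected_frames, truth_frames, T) {
  ks <- sort(unique(unlist(lapply(truth_frames, function(g) {
    vapply(as_gcff_groups(g)$groups, length, 1L)
  }))))
  if (length(ks) == 0L) {
    return(list(by_k = data.frame(k = integer(), precision = numeric(),
                                  recall = numeric(), f1 = numeric()),
                mean = NA_real_, sd = NA_real_))
  }
  rows <- lapply(ks, function(k) {
    s <- cardinality_f1(detected_frames, truth_frames, k, T)
    data.frame(k = k, precision = s[["precision"]], recall = s[["recall"]],
               f1 = s[["f1"]])
  })
  by_k <- do.call(rbind, rows)
  list(by_k = by_k, mean = mean(by_k$f1), sd = stats::sd(by_k$f1))
}
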