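#' Match a reference detection through prior frames
#'
#' For each of the `N - 1` frames preceding the current one, finds the
#' detection whose box has the highest IoU with the reference box, provided
#' that IoU exceeds `vote_iou`; frames with no sufficiently overlapping
#' detection contribute no match. This builds the chain of boxes that vote on
#' the reference detection's action.
#'
#' @param reference a `det_frame` restricted to one detection, or a list with
#'   a 1-row `boxes` matrix.
#' @param prior_frames list of `det_frame`s, ordered by increasing frame
#'   index, strictly before the reference frame.
#' @param vote_iou minimum IoU to join the chain.
#' @return Integer vector, one entry per prior frame: the matched detection
#'   index in that frame, or `NA` if none qualifies.
#' @export
match_chain <- function(reference, prior_frames, vote_iou) {
  ref_box <- reference$boxes
  vapply(prior_frames, function(pf) {
    if (n_detections(pf) == 0L) return(NA_integer_)
    ious <- as.numeric(iou_matrix(ref_box, pf$boxes))
    best <- which.max(ious)
    if (ious[best] > vote_iou) best else NA_integer_
  }, integer(1))
}

#' Windowed vote scores for one detection
#'
#' The vote score of action `j` over an N-frame window is the mean over the
#' window of (class score of `j`) x (objectness), with absent frames
#' contributing zero — so a box that flickers in and out accumulates less
#' support than one detected stably. With `N = 1` the score reduces to the
#' detection's own class score times objectness.
#'
#' @param reference the current-frame detection (1-detection `det_frame`).
#' @param chain list of matched prior detections (1-detection `det_frame`s);
#'   absent frames are simply omitted.
#' @param N window length (the reference counts as one of the N frames).
#' @return Named numeric vector of vote scores over the full taxonomy, each
#'   in `[0, 1]`.
#' @export
vote_scores <- function(reference, chain, N) {
  if (N <= 0L) stop("N must be positive")
  acc <- reference$scores[1L, ] * reference$objectness[1L]
  for (d in chain) {
    acc <- acc + d$scores[1L, ] * d$objectness[1L]
  }
  acc / N
}

# tie-aware argmax over vote scores: prefer the reference's raw label when it
# is among the tied maxima, else the earliest tied class in taxonomy order
vote_argmax <- function(scores, raw_label) {
  mx <- max(scores)
  tied <- names(scores)[scores >= mx - 1e-12]
  if (raw_label %in% tied) raw_label else tied[1L]
}

#' Refine one frame's action labels by majority voting
#'
#' For each detection in the current frame, chains it back through the
#' `vote_N - 1` preceding frames ([match_chain()]), accumulates vote scores
#' ([vote_scores()]) and replaces the label with the winning action. Boxes,
#' scores, objectness and embeddings are untouched — only `label` changes.
#' Exact ties go to the detection's own argmax label when tied, else to
#' taxonomy order.
#'
#' @param current `det_frame` to refine.
#' @param prior_frames list of the `vote_N - 1` preceding `det_frame`s in
#'   frame order.
#' @param config a [pipeline_config()].
#' @return The refined `det_frame`.
#' @export
refine_frame <- function(current, prior_frames, config) {
  n <- n_detections(current)
  if (n == 0L) return(current)
  # vectorized equivalent of match_chain + vote_scores across all detections
  acc <- current$scores * current$objectness
  for (pf in prior_frames) {
    if (n_detections(pf) == 0L) next
    ious <- iou_matrix(current$boxes, pf$boxes)
    best <- max.col(ious, ties.method = "first")
    ok <- ious[cbind(seq_len(n), best)] > config$vote_iou
    if (any(ok)) {
      acc[ok, ] <- acc[ok, ] +
        pf$scores[best[ok], , drop = FALSE] * pf$objectness[best[ok]]
    }
  }
  S <- acc / config$vote_N
  label <- vapply(seq_len(n), function(i) {
    vote_argmax(S[i, ], current$raw_label[i])
  }, character(1))
  current$label <- label
  current
}

#' Refine a detection stream by sliding-window majority voting
#'
#' Applies [refine_frame()] from frame `vote_N` onward; the first
#' `vote_N - 1` frames pass through with their raw argmax labels (there is
#' not yet a full window to vote with). Detection counts, boxes and scores
#' are preserved everywhere; only labels change.
#'
#' @param frames list of `det_frame`s in frame order.
#' @param config a [pipeline_config()].
#' @return List of `det_frame`s with refined labels.
#' @export
refine_stream <- function(frames, config = pipeline_config()) {
  N <- config$vote_N
  if (length(frames) < N) return(frames)
  out <- frames
  for (t in N:length(frames)) {
    out[[t]] <- refine_frame(frames[[t]], frames[(t - N + 1L):(t - 1L)],
                             config)
  }
  out
}
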