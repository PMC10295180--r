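#' Appearance similarity and distances
#'
#' `cosine_similarity()` is the standard inner-product similarity
#' `A.B / (|A||B|)`. `appearance_distance()` compares a detection embedding
#' against a track's appearance gallery and returns the cosine distance to
#' the *closest* gallery member, `1 - max(similarity)`, clipped to `[0, 1]`:
#' a track is as close as its best remembered view.
#'
#' @param a,b numeric vectors of equal length (non-zero norm).
#' @return `cosine_similarity()`: a value in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @param gallery non-empty matrix of unit-norm embeddings, one per row.
#' @param e a unit-norm embedding vector.
#' @return `appearance_distance()`: cosine distance in `[0, 1]`.
#' @export
appearance_distance <- function(gallery, e) {
  if (is.null(dim(gallery))) gallery <- matrix(gallery, nrow = 1L)
  if (nrow(gallery) == 0L) stop("appearance gallery is empty")
  sims <- as.numeric(gallery %*% e)
  min(max(1 - max(sims), 0), 1)
}

# cosine-distance cost matrix: one row per gallery (track), one col per
# detection embedding
appearance_cost_matrix <- function(galleries, embeddings) {
  n <- length(galleries); m <- nrow(embeddings)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    sims <- galleries[[i]] %*% t(embeddings)     # g_i x m
    out[i, ] <- pmin(pmax(1 - apply(sims, 2L, max), 0), 1)
  }
  out
}

#' Combined motion/appearance association cost
#'
#' The association cost between a track and a detection is the convex
#' combination `D = lambda * Dm + (1 - lambda) * Dc` of the motion
#' (Mahalanobis) and appearance (cosine) distances. Because the raw squared
#' Mahalanobis distance is unbounded, it is first squashed to `[0, 1]` by
#' `min(d / mahalanobis_gate, 1)` before mixing, making the two terms
#' commensurable. The default `lambda = 0.1` weights appearance heavily.
#'
#' @param d_motion motion distances already scaled to `[0, 1]`.
#' @param d_appearance cosine distances in `[0, 1]`.
#' @param lambda motion weight in `[0, 1]`.
#' @return Combined costs, same shape as the inputs.
#' @export
combined_cost <- function(d_motion, d_appearance, lambda) {
  if (length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  stopifnot(all(d_motion >= 0 & d_motion <= 1),
            all(d_appearance >= 0 & d_appearance <= 1))
  lambda * d_motion + (1 - lambda) * d_appearance
}

scale_mahalanobis <- function(d, gate) pmin(d / gate, 1)

#' Gate an association cost matrix
#'
#' Marks track-detection pairs infeasible (`Inf`) when either the squared
#' Mahalanobis distance exceeds `mahalanobis_gate` or the cosine distance
#' exceeds `cosine_gate`; feasible entries pass through unchanged.
#'
#' @param costs combined cost matrix.
#' @param mahalanobis,cosine distance matrices of the same shape.
#' @param config a [pipeline_config()] supplying the two gates.
#' @return The gated cost matrix.
#' @export
gate_costs <- function(costs, mahalanobis, cosine, config) {
  if (!all(dim(costs) == dim(mahalanobis)) ||
      !all(dim(costs) == dim(cosine))) {
    stop("cost and distance matrices must share a shape")
  }
  costs[mahalanobis > config$mahalanobis_gate | cosine > config$cosine_gate] <- Inf
  costs
}

#' IoU association cost
#'
#' Cost matrix `1 - IoU` between track boxes and detection boxes, used by the
#' fallback association stage with `max_iou_distance` as the match ceiling.
#'
#' @param track_boxes,det_boxes center-form box matrices.
#' @return Cost matrix in `[0, 1]`.
#' @export
iou_cost <- function(track_boxes, det_boxes) {
  1 - iou_matrix(track_boxes, det_boxes)
}
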