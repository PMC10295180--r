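#' Per-frame detection sets
#'
#' A `det_frame` holds every detector candidate in one video frame: boxes in
#' center form, per-action class scores, objectness scores, and fixed-length
#' unit-norm appearance embeddings. `label` is the working action label,
#' initialized to the argmax of the class scores and later replaced by the
#' majority-voted label in [refine_stream()].
#'
#' @param frame 1-based frame index (integer).
#' @param boxes `n x 4` center-form box matrix (see [bbox()]).
#' @param scores `n x 11` matrix of class scores in `[0, 1]`, columns named
#'   after [action_taxonomy()] labels (any column order; missing actions are
#'   treated as score 0).
#' @param objectness length-`n` vector of objectness scores in `[0, 1]`.
#' @param embeddings `n x d` matrix of unit Euclidean-norm appearance
#'   embeddings.
#' @param label optional length-`n` character of action labels; default is
#'   the per-row argmax of `scores`.
#' @return An object of class `det_frame`: a list with elements `frame`,
#'   `boxes`, `scores`, `objectness`, `embeddings`, `label`, `raw_label`.
#' @export
det_frame <- function(frame, boxes, scores, objectness, embeddings,
                      label = NULL) {
  frame <- as.integer(frame)
  stopifnot(length(frame) == 1L, frame >= 1L)
  boxes <- as_box_matrix(boxes)
  n <- nrow(boxes)
  if (n > 0L) validate_bbox(boxes)

  tx <- action_taxonomy()$action
  full <- matrix(0, n, length(tx), dimnames = list(NULL, tx))
  if (n > 0L) {
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = n)
    if (is.null(colnames(scores))) {
      stop("score columns must be named with action labels")
    }
    unknown <- setdiff(colnames(scores), tx)
    if (length(unknown)) {
      stop("unknown action label(s) in scores: ",
           paste(unknown, collapse = ", "))
    }
    full[, colnames(scores)] <- scores
  }
  if (any(full < 0 | full > 1)) stop("class scores must lie in [0, 1]")

  objectness <- as.numeric(objectness)
  if (length(objectness) != n) stop("objectness length must match box count")
  if (n > 0L && any(objectness < 0 | objectness > 1)) {
    stop("objectness must lie in [0, 1]")
  }

  if (is.null(dim(embeddings))) {
    embeddings <- matrix(embeddings, nrow = n)
  }
  if (nrow(embeddings) != n) stop("embedding rows must match box count")
  if (n > 0L) {
    nrm <- sqrt(rowSums(embeddings^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("embeddings must be unit Euclidean norm (|norm - 1| < 1e-6)")
    }
  }

  raw <- if (n > 0L) tx[max.col(full, ties.method = "first")] else character(0)
  if (is.null(label)) label <- raw
  if (length(label) != n) stop("label length must match box count")
  if (n > 0L && !all(label %in% tx)) stop("labels must be taxonomy actions")

  structure(
    list(frame = frame, boxes = boxes, scores = full,
         objectness = objectness, embeddings = embeddings,
         label = as.character(label), raw_label = raw),
    class = "det_frame"
  )
}

#' @export
print.det_frame <- function(x, ...) {
  cat("<det_frame> frame", x$frame, "with", nrow(x$boxes), "detections\n")
  if (nrow(x$boxes)) {
    tab <- table(x$label)
    cat("  labels:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

n_detections <- function(df) nrow(df$boxes)

# subset a det_frame by detection index, preserving all parallel fields
det_subset <- function(df, idx) {
  structure(
    list(frame = df$frame,
         boxes = df$boxes[idx, , drop = FALSE],
         scores = df$scores[idx, , drop = FALSE],
         objectness = df$objectness[idx],
         embeddings = df$embeddings[idx, , drop = FALSE],
         label = df$label[idx],
         raw_label = df$raw_label[idx]),
    class = "det_frame"
  )
}

empty_det_frame <- function(frame, d = 128L) {
  det_frame(frame,
            boxes = matrix(numeric(0), 0, 4,
                           dimnames = list(NULL, c("u", "v", "a", "h"))),
            scores = matrix(numeric(0), 0, 11,
                            dimnames = list(NULL, action_taxonomy()$action)),
            objectness = numeric(0),
            embeddings = matrix(numeric(0), 0, d))
}

# detection confidence: objectness x best class score
det_confidence <- function(df) {
  if (n_detections(df) == 0L) return(numeric(0))
  df$objectness * apply(df$scores, 1L, max)
}
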