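#' Bounding boxes in center form
#'
#' Boxes are stored in center form `(u, v, a, h)`: `u, v` are the pixel
#' coordinates of the box center (origin top-left, y down), `h` the box height
#' in pixels and `a` the aspect ratio, defined throughout this package as
#' **width / height** (so width `= a * h`). The corner form used by MOT
#' Challenge files is `(left, top, width, height)`; the two forms round-trip
#' losslessly.
#'
#' @param u,v,a,h numeric vectors (recycled to common length): center
#'   coordinates, aspect ratio (width/height, > 0) and height (px, > 0).
#' @return `bbox()` returns an `n x 4` numeric matrix with columns
#'   `u, v, a, h`.
#' @examples
#' b <- bbox(u = 5, v = 5, a = 1, h = 10)
#' bbox_to_corner(b) # left 0, top 0, width 10, height 10
#' @export
bbox <- function(u, v, a, h) {
  m <- cbind(u = u, v = v, a = a, h = h)
  validate_bbox(m)
  m
}

validate_bbox <- function(m) {
  if (!is.matrix(m) || ncol(m) != 4L) {
    stop("boxes must be an n x 4 matrix with columns u, v, a, h")
  }
  if (!all(is.finite(m))) stop("boxes must have finite entries")
  if (any(m[, 3L] <= 0) || any(m[, 4L] <= 0)) {
    stop("boxes must have positive aspect ratio and height")
  }
  invisible(m)
}

#' @rdname bbox
#' @param box an `n x 4` center-form box matrix.
#' @return `bbox_to_corner()` returns an `n x 4` matrix with columns
#'   `left, top, width, height`.
#' @export
bbox_to_corner <- function(box) {
  box <- as_box_matrix(box)
  w <- box[, 3L] * box[, 4L]
  h <- box[, 4L]
  cbind(left = box[, 1L] - w / 2, top = box[, 2L] - h / 2,
        width = w, height = h)
}

#' @rdname bbox
#' @param corner an `n x 4` corner-form matrix `(left, top, width, height)`.
#' @return `bbox_from_corner()` returns the center-form matrix.
#' @export
bbox_from_corner <- function(corner) {
  corner <- as_box_matrix(corner)
  if (any(corner[, 3L] <= 0) || any(corner[, 4L] <= 0)) {
    stop("corner boxes must have positive width and height")
  }
  bbox(u = corner[, 1L] + corner[, 3L] / 2,
       v = corner[, 2L] + corner[, 4L] / 2,
       a = corner[, 3L] / corner[, 4L],
       h = corner[, 4L])
}

as_box_matrix <- function(box) {
  if (is.null(dim(box))) box <- matrix(box, nrow = 1L)
  storage.mode(box) <- "double"
  box
}

#' Intersection over union
#'
#' `bbox_iou()` computes the IoU of paired boxes; `iou_matrix()` computes the
#' full `n x m` IoU matrix between two box sets. Both take center-form boxes.
#'
#' @param box_a,box_b center-form box matrices (paired, recycled if one row).
#' @return IoU values in `[0, 1]`; 1 exactly for identical boxes, 0 for
#'   disjoint boxes.
#' @examples
#' a <- bbox(5, 5, 1, 10)
#' b <- bbox(10, 5, 1, 10)
#' bbox_iou(a, b) # 1/3
#' @export
bbox_iou <- function(box_a, box_b) {
  ca <- bbox_to_corner(box_a)
  cb <- bbox_to_corner(box_b)
  if (nrow(ca) == 1L && nrow(cb) > 1L) ca <- ca[rep(1L, nrow(cb)), , drop = FALSE]
  if (nrow(cb) == 1L && nrow(ca) > 1L) cb <- cb[rep(1L, nrow(ca)), , drop = FALSE]
  iou_corner(ca, cb)
}

iou_corner <- function(ca, cb) {
  ix <- pmax(0, pmin(ca[, 1L] + ca[, 3L], cb[, 1L] + cb[, 3L]) -
                pmax(ca[, 1L], cb[, 1L]))
  iy <- pmax(0, pmin(ca[, 2L] + ca[, 4L], cb[, 2L] + cb[, 4L]) -
                pmax(ca[, 2L], cb[, 2L]))
  inter <- ix * iy
  union <- ca[, 3L] * ca[, 4L] + cb[, 3L] * cb[, 4L] - inter
  inter / union
}

#' @rdname bbox_iou
#' @param boxes_a,boxes_b center-form box matrices with `n` and `m` rows.
#' @return `iou_matrix()` returns an `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  ca <- bbox_to_corner(boxes_a)
  cb <- bbox_to_corner(boxes_b)
  n <- nrow(ca); m <- nrow(cb)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  for (j in seq_len(m)) {
    out[, j] <- iou_corner(ca, cb[rep(j, n), , drop = FALSE])
  }
  out
}
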