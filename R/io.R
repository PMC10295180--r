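#' Read and write detection streams
#'
#' Detections travel as JSON: a top-level object with `embedding_dim` and
#' `frames`, each frame an object `{frame, detections: [{box: [u,v,a,h],
#' scores: {action: value, ...}, objectness, embedding: [...]}]}`. Boxes are
#' center form; embeddings must be unit norm. Malformed records are rejected
#' with an error naming the frame and detection index.
#'
#' @param frames list of [det_frame()]s.
#' @param path file path.
#' @return `read_detections()` returns the list of `det_frame`s.
#' @export
write_detections <- function(frames, path) {
  payload <- list(
    embedding_dim = if (length(frames)) ncol(frames[[1L]]$embeddings) else 0L,
    frames = lapply(frames, function(f) {
      list(frame = f$frame,
           detections = lapply(seq_len(n_detections(f)), function(i) {
             sc <- f$scores[i, ]
             list(box = unname(f$boxes[i, ]),
                  scores = as.list(sc[sc > 0]),
                  objectness = f$objectness[i],
                  embedding = unname(f$embeddings[i, ]))
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- payload$embedding_dim
  lapply(payload$frames, function(fr) {
    n <- length(fr$detections)
    if (n == 0L) return(empty_det_frame(fr$frame, max(d, 1L)))
    boxes <- matrix(NA_real_, n, 4L)
    obj <- numeric(n)
    emb <- matrix(NA_real_, n, d)
    sc <- matrix(0, n, 11L,
                 dimnames = list(NULL, action_taxonomy()$action))
    for (i in seq_len(n)) {
      det <- fr$detections[[i]]
      where <- sprintf("frame %s, detection %d", fr$frame, i)
      if (length(det$box) != 4L) stop("bad box at ", where)
      boxes[i, ] <- as.numeric(det$box)
      obj[i] <- as.numeric(det$objectness)
      e <- as.numeric(unlist(det$embedding))
      if (length(e) != d) stop("bad embedding length at ", where)
      if (abs(sqrt(sum(e^2)) - 1) > 1e-6) {
        stop("non-unit embedding at ", where)
      }
      emb[i, ] <- e
      for (a in names(det$scores)) {
        if (!a %in% colnames(sc)) stop("unknown action '", a, "' at ", where)
        sc[i, a] <- as.numeric(det$scores[[a]])
      }
    }
    det_frame(fr$frame, boxes, sc, obj, emb)
  })
}

#' Read and write MOT Challenge track files
#'
#' The MOT Challenge text dialect: one line per box,
#' `frame,id,bb_left,bb_top,width,height,conf,x,y,z`, comma-separated with
#' 1-based frames and corner-form boxes. Boxes are converted to center form
#' on read. Ground truth carries `conf = -1` by convention; predictions get
#' `conf = 1`.
#'
#' @param path file path.
#' @return `read_mot()` returns a [trackset()].
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(trackset(data.frame(frame = integer(0), id = integer(0),
                               u = numeric(0), v = numeric(0),
                               a = numeric(0), h = numeric(0))))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 6L)
  if (length(bad)) stop("line ", bad[1L], ": expected >= 6 comma-separated fields")
  num <- lapply(seq_along(parts), function(k) {
    v <- suppressWarnings(as.numeric(parts[[k]][1:6]))
    if (anyNA(v)) stop("line ", k, ": non-numeric field")
    v
  })
  m <- do.call(rbind, num)
  dup <- duplicated(m[, 1:2, drop = FALSE])
  if (any(dup)) {
    stop("line ", which(dup)[1L], ": duplicate (frame, id)")
  }
  ctr <- bbox_from_corner(m[, 3:6, drop = FALSE])
  ts <- data.frame(frame = as.integer(m[, 1L]), id = as.integer(m[, 2L]),
                   u = ctr[, 1L], v = ctr[, 2L], a = ctr[, 3L],
                   h = ctr[, 4L])
  trackset(ts[order(ts$frame, ts$id), ])
}

#' @rdname read_mot
#' @param ts a [trackset()] (or data frame `frame, id, u, v, a, h`).
#' @param conf confidence written to field 7 (`-1` for ground truth).
#' @export
write_mot <- function(ts, path, conf = 1) {
  if (!nrow(ts)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  corner <- bbox_to_corner(as.matrix(ts[, c("u", "v", "a", "h")]))
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                   as.integer(ts$frame), as.integer(ts$id),
                   format(corner[, 1L], trim = TRUE, digits = 15),
                   format(corner[, 2L], trim = TRUE, digits = 15),
                   format(corner[, 3L], trim = TRUE, digits = 15),
                   format(corner[, 4L], trim = TRUE, digits = 15),
                   format(conf, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced an output directory: the configuration snapshot,
#' MD5 digests of the input files, the seed, package version and a
#' timestamp. Deterministic stages rerun with an identical manifest produce
#' identical outputs.
#'
#' @param path output file (JSON).
#' @param config a configuration object (list-like).
#' @param inputs named character vector of input file paths.
#' @param seed integer seed used, if any.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, inputs = character(0), seed = NULL) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    tool = "herdtrack",
    version = as.character(utils::packageVersion("herdtrack")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = digests,
    config = unclass(config))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
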