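# Scene builders used across test files. Everything is generated in code at
# test time; no fixtures on disk.

# a 1-detection det_frame with a given box, label and score
one_det <- function(frame, u, v, a = 1.5, h = 60, label = "standing",
                    score = 0.9, objectness = 1, emb = NULL, d = 8L) {
  if (is.null(emb)) {
    emb <- rep(0, d); emb[1L] <- 1
  }
  sc <- matrix(0, 1, 1, dimnames = list(NULL, label))
  sc[1, 1] <- score
  det_frame(frame, bbox(u, v, a, h), sc, objectness, matrix(emb, 1))
}

# combine several single detections (same frame) into one det_frame
bind_dets <- function(...) {
  ds <- list(...)
  det_frame(ds[[1L]]$frame,
            do.call(rbind, lapply(ds, `[[`, "boxes")),
            do.call(rbind, lapply(ds, `[[`, "scores")),
            unlist(lapply(ds, `[[`, "objectness")),
            do.call(rbind, lapply(ds, `[[`, "embeddings")),
            label = unlist(lapply(ds, `[[`, "label")))
}

empty_frame <- function(t, d = 8L) herdtrack:::empty_det_frame(t, d)

# the predicted id most often matched (by IoU > 0.5) to a ground-truth agent
# over a frame window; NA if never matched
matched_pred_id <- function(scene, res, agent, frames) {
  ids <- integer(0)
  for (f in frames) {
    g <- scene$gt_tracks[scene$gt_tracks$frame == f &
                           scene$gt_tracks$id == agent, ]
    p <- res$tracks[res$tracks$frame == f, ]
    if (!nrow(p) || !nrow(g)) next
    io <- iou_matrix(as.matrix(g[, c("u", "v", "a", "h")]),
                     as.matrix(p[, c("u", "v", "a", "h")]))
    if (max(io) > 0.5) ids <- c(ids, p$id[which.max(io)])
  }
  if (!length(ids)) return(NA_integer_)
  as.integer(names(sort(table(ids), decreasing = TRUE))[1L])
}

# random ground truth + corrupted predictions for metric oracle comparisons
random_eval_scene <- function(n_ids = 3L, n_frames = 40L,
                              drop_rate = 0.1, jitter = 3,
                              switch_prob = 0.5, fp_rate = 0.1) {
  gt <- list(); pred <- list()
  next_pred_id <- n_ids + 1L
  for (i in seq_len(n_ids)) {
    s <- sample.int(max(1L, n_frames %/% 3L), 1L)
    e <- n_frames - sample.int(max(1L, n_frames %/% 3L), 1L) + 1L
    if (e < s) { s <- 1L; e <- n_frames }
    u <- cumsum(c(runif(1, 100, 900), rnorm(e - s, 0, 4)))
    v <- cumsum(c(runif(1, 100, 500), rnorm(e - s, 0, 4)))
    frames <- s:e
    gt[[i]] <- data.frame(frame = frames, id = i, u = u, v = v,
                          a = 1.5, h = 60)
    # predictions: same path jittered, occasional identity change mid-track
    pid <- i
    sw <- if (runif(1) < switch_prob && length(frames) > 4L) {
      sample(frames[-(1:2)], 1L)
    } else NA
    keep <- runif(length(frames)) > drop_rate
    if (any(keep)) {
      ids <- rep(pid, length(frames))
      if (!is.na(sw)) {
        ids[frames >= sw] <- next_pred_id
        next_pred_id <- next_pred_id + 1L
      }
      pred[[length(pred) + 1L]] <- data.frame(
        frame = frames[keep], id = ids[keep],
        u = u[keep] + rnorm(sum(keep), 0, jitter),
        v = v[keep] + rnorm(sum(keep), 0, jitter),
        a = 1.5, h = 60)
    }
  }
  n_fp <- rpois(1, fp_rate * n_frames)
  if (n_fp > 0L) {
    pred[[length(pred) + 1L]] <- data.frame(
      frame = sample.int(n_frames, n_fp, replace = TRUE),
      id = next_pred_id + seq_len(n_fp),
      u = runif(n_fp, 1500, 3000), v = runif(n_fp, 1200, 2000),
      a = 1.5, h = 60)
  }
  gt <- do.call(rbind, gt)
  pred <- do.call(rbind, pred)
  pred <- pred[!duplicated(pred[, c("frame", "id")]), ]
  list(gt = trackset(gt), pred = trackset(pred))
}

# noiseless straight-line detection stream for n agents, well separated
straight_line_stream <- function(n_agents, n_frames, d = 8L, speed = 2) {
  embs <- diag(d)[seq_len(n_agents), , drop = FALSE]
  lapply(seq_len(n_frames), function(t) {
    dets <- lapply(seq_len(n_agents), function(i) {
      one_det(t, u = 200 + 400 * i + speed * t, v = 500 + 10 * i,
              label = "standing", emb = embs[i, ], d = d)
    })
    do.call(bind_dets, dets)
  })
}
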