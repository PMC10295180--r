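#' Filter raw detections before tracking
#'
#' Applies the detector-side hygiene the tracker relies on: detections with
#' confidence (objectness x best class score) below `track_conf` are dropped;
#' non-maximum suppression removes boxes overlapping a higher-confidence box
#' at IoU above `match_iou`; group-action detections (fighting, social
#' licking, feeding) are split off as alerts and part-action detections
#' (moving head, ruminating, tail wagging) are split off for later
#' attribution — neither enters tracking; finally at most `max_targets`
#' individual-action detections are kept, by descending confidence.
#'
#' @param dets a `det_frame`.
#' @param config a [pipeline_config()].
#' @return List with `tracked`, `parts`, `alerts` — three `det_frame`s.
#' @export
filter_detections <- function(dets, config = pipeline_config()) {
  n <- n_detections(dets)
  if (n > 0L) {
    conf <- det_confidence(dets)
    dets <- det_subset(dets, which(conf >= config$track_conf))
  }
  n <- n_detections(dets)
  if (n > 1L) {
    conf <- det_confidence(dets)
    ord <- order(conf, decreasing = TRUE)
    keep <- logical(n)
    ious <- iou_matrix(dets$boxes, dets$boxes)
    for (i in ord) {
      if (!any(keep & ious[i, ] > config$match_iou)) keep[i] <- TRUE
    }
    dets <- det_subset(dets, which(keep))
  }
  cat_of <- action_category(dets$label)
  tracked <- det_subset(dets, which(cat_of == "individual"))
  if (n_detections(tracked) > config$max_targets) {
    conf <- det_confidence(tracked)
    tracked <- det_subset(tracked,
                          order(conf, decreasing = TRUE)[seq_len(config$max_targets)])
  }
  list(tracked = tracked,
       parts = det_subset(dets, which(cat_of == "part")),
       alerts = det_subset(dets, which(cat_of == "group")))
}

#' Create a tracker
#'
#' A tracker carries the active track set, the next unused identity and the
#' current frame index. Feed it one frame at a time with [tracker_step()] or
#' run a whole stream with [track_stream()].
#'
#' @param config a [pipeline_config()].
#' @return An object of class `herd_tracker`.
#' @export
tracker_init <- function(config = pipeline_config()) {
  structure(list(config = config, tracks = list(), next_id = 1L,
                 frame = 0L),
            class = "herd_tracker")
}

new_track <- function(id, dets, i, frame, config) {
  box <- dets$boxes[i, , drop = FALSE]
  list(id = id,
       state = kf_init(box, config),
       status = if (config$n_init <= 1L) "confirmed" else "tentative",
       hits = 1L,
       time_since_update = 0L,
       gallery = dets$embeddings[i, , drop = FALSE],
       trace = matrix(c(frame, box[1L, 1:2]), 1L, 3L,
                      dimnames = list(NULL, c("frame", "u", "v"))),
       label = dets$label[i],
       box = box)
}

track_mark_match <- function(tr, dets, i, frame, config, reinit = FALSE) {
  box <- dets$boxes[i, , drop = FALSE]
  if (reinit) {
    tr$state <- kf_init(box, config)   # long gap: velocity is meaningless
  } else {
    tr$state <- kf_update(tr$state, box, config)
  }
  tr$hits <- tr$hits + 1L
  tr$time_since_update <- 0L
  tr$gallery <- rbind(tr$gallery, dets$embeddings[i, , drop = FALSE])
  ng <- nrow(tr$gallery)
  if (ng > config$gallery_budget) {
    tr$gallery <- tr$gallery[(ng - config$gallery_budget + 1L):ng, ,
                             drop = FALSE]
  }
  tr$trace <- rbind(tr$trace, c(frame, box[1L, 1:2]))
  nt <- nrow(tr$trace)
  if (nt > config$trace_window) {
    tr$trace <- tr$trace[(nt - config$trace_window + 1L):nt, , drop = FALSE]
  }
  tr$label <- dets$label[i]
  tr$box <- box
  if (tr$status == "tentative" && tr$hits >= config$n_init) {
    tr$status <- "confirmed"
  }
  if (tr$status == "lost") tr$status <- "confirmed"
  tr
}

track_predicted_box <- function(tr) {
  m <- tr$state$mean
  bbox(u = m[1L], v = m[2L], a = max(m[3L], 1e-6), h = max(m[4L], 1e-6))
}

#' Advance the tracker by one frame
#'
#' The per-frame association protocol:
#' 1. Kalman-predict every live track.
#' 2. *Matching cascade*: confirmed tracks, in ascending order of frames
#'    since their last match, are matched to detections by the gated combined
#'    motion/appearance cost ([combined_cost()]).
#' 3. Remaining detections are matched by IoU cost (ceiling
#'    `max_iou_distance`) against tentative tracks and confirmed tracks that
#'    just went unmatched.
#' 4. Lost tracks (missed more than `unmatched_max` frames) are eligible only
#'    for appearance matching: cosine distance to their gallery within
#'    `cosine_gate`. On re-identification the motion state is re-initialized
#'    at the new box.
#' 5. Matched tracks are updated (filter, gallery, trace, action label);
#'    unmatched detections spawn new tentative tracks; lifecycle rules
#'    (tentative -> confirmed after `n_init` hits, tentative deleted on any
#'    miss, confirmed -> lost after `unmatched_max` misses, lost deleted
#'    after `max_age` frames without a match) are applied.
#'
#' @param tracker a `herd_tracker`.
#' @param dets the next frame's `det_frame` (already filtered and, if
#'   desired, vote-refined; [track_stream()] does both).
#' @return List with the advanced `tracker` and `result`, a data frame of
#'   one row per track matched this frame (`frame, id, u, v, a, h, action,
#'   status`). Boxes in the result are the associated detections' boxes.
#' @export
tracker_step <- function(tracker, dets) {
  config <- tracker$config
  frame <- tracker$frame + 1L
  if (dets$frame != frame) {
    stop(sprintf("out-of-order frame: expected %d, got %d", frame, dets$frame))
  }

  tracks <- tracker$tracks
  for (k in seq_along(tracks)) {
    tracks[[k]]$state <- kf_predict(tracks[[k]]$state, config)
    tracks[[k]]$time_since_update <- tracks[[k]]$time_since_update + 1L
  }

  nd <- n_detections(dets)
  det_left <- seq_len(nd)
  status <- vapply(tracks, `[[`, character(1), "status")
  tsu <- vapply(tracks, `[[`, integer(1), "time_since_update")
  matched <- integer(0)          # track index -> detection index pairs
  matched_det <- integer(0)
  matched_reinit <- logical(0)

  # --- stage 1: cascade over confirmed tracks by recency -------------------
  for (level in seq_len(config$unmatched_max)) {
    cand <- which(status == "confirmed" & tsu == level &
                    !(seq_along(tracks) %in% matched))
    if (!length(cand) || !length(det_left)) next
    sub <- det_subset(dets, det_left)
    maha <- t(vapply(cand, function(k) {
      kf_gating_distance(tracks[[k]]$state, sub$boxes, config)
    }, numeric(length(det_left))))
    maha <- matrix(maha, length(cand), length(det_left))
    cosd <- appearance_cost_matrix(lapply(tracks[cand], `[[`, "gallery"),
                                   sub$embeddings)
    cost <- combined_cost(scale_mahalanobis(maha, config$mahalanobis_gate),
                          cosd, config$lambda_motion)
    cost <- gate_costs(cost, maha, cosd, config)
    sol <- solve_assignment(cost, max_cost = 1)
    if (nrow(sol$matches)) {
      matched <- c(matched, cand[sol$matches[, 1L]])
      matched_det <- c(matched_det, det_left[sol$matches[, 2L]])
      matched_reinit <- c(matched_reinit, rep(FALSE, nrow(sol$matches)))
      det_left <- det_left[-sol$matches[, 2L]]
    }
  }

  # --- stage 2: IoU fallback for tentative + just-unmatched confirmed -----
  cand <- which((status == "tentative" |
                   (status == "confirmed" & tsu == 1L)) &
                  !(seq_along(tracks) %in% matched))
  if (length(cand) && length(det_left)) {
    sub <- det_subset(dets, det_left)
    tb <- do.call(rbind, lapply(tracks[cand], track_predicted_box))
    cost <- iou_cost(tb, sub$boxes)
    sol <- solve_assignment(cost, max_cost = config$max_iou_distance)
    if (nrow(sol$matches)) {
      matched <- c(matched, cand[sol$matches[, 1L]])
      matched_det <- c(matched_det, det_left[sol$matches[, 2L]])
      matched_reinit <- c(matched_reinit, rep(FALSE, nrow(sol$matches)))
      det_left <- det_left[-sol$matches[, 2L]]
    }
  }

  # --- stage 3: appearance-only re-identification of lost tracks ----------
  cand <- which(status == "lost" & !(seq_along(tracks) %in% matched))
  if (length(cand) && length(det_left)) {
    sub <- det_subset(dets, det_left)
    cosd <- appearance_cost_matrix(lapply(tracks[cand], `[[`, "gallery"),
                                   sub$embeddings)
    cost <- cosd
    cost[cosd > config$cosine_gate] <- Inf
    sol <- solve_assignment(cost, max_cost = config$cosine_gate)
    if (nrow(sol$matches)) {
      matched <- c(matched, cand[sol$matches[, 1L]])
      matched_det <- c(matched_det, det_left[sol$matches[, 2L]])
      matched_reinit <- c(matched_reinit, rep(TRUE, nrow(sol$matches)))
      det_left <- det_left[-sol$matches[, 2L]]
    }
  }

  # --- updates and lifecycle ----------------------------------------------
  for (j in seq_along(matched)) {
    k <- matched[j]
    tracks[[k]] <- track_mark_match(tracks[[k]], dets, matched_det[j],
                                    frame, config,
                                    reinit = matched_reinit[j])
  }
  drop <- logical(length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    if (tr$time_since_update == 0L) next
    if (tr$status == "tentative") {
      drop[k] <- TRUE
    } else if (tr$status == "confirmed" &&
               tr$time_since_update > config$unmatched_max) {
      tracks[[k]]$status <- "lost"
    } else if (tr$status == "lost" &&
               tr$time_since_update > config$max_age) {
      drop[k] <- TRUE
    }
  }
  tracks <- tracks[!drop]

  next_id <- tracker$next_id
  for (i in det_left) {
    tracks[[length(tracks) + 1L]] <- new_track(next_id, dets, i, frame, config)
    next_id <- next_id + 1L
  }

  emit <- which(vapply(tracks, `[[`, integer(1), "time_since_update") == 0L)
  result <- if (length(emit)) {
    boxes <- do.call(rbind, lapply(tracks[emit], `[[`, "box"))
    data.frame(frame = frame,
               id = vapply(tracks[emit], `[[`, integer(1), "id"),
               u = boxes[, 1L], v = boxes[, 2L],
               a = boxes[, 3L], h = boxes[, 4L],
               action = vapply(tracks[emit], `[[`, character(1), "label"),
               status = vapply(tracks[emit], `[[`, character(1), "status"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(frame = integer(0), id = integer(0), u = numeric(0),
               v = numeric(0), a = numeric(0), h = numeric(0),
               action = character(0), status = character(0))
  }

  tracker$tracks <- tracks
  tracker$next_id <- next_id
  tracker$frame <- frame
  list(tracker = tracker, result = result)
}

#' Track a full detection stream
#'
#' Runs the complete per-frame pipeline over an ordered detection stream:
#' optional action majority voting ([refine_stream()]), detection filtering
#' ([filter_detections()]) and tracking ([tracker_step()]). Deterministic:
#' identical inputs and configuration give identical output.
#'
#' @param frames list of `det_frame`s with consecutive frame indices
#'   starting at 1.
#' @param config a [pipeline_config()].
#' @return An object of class `herd_tracks`: list with
#'   \describe{
#'     \item{tracks}{data frame of all per-frame track emissions
#'       (`frame, id, u, v, a, h, action, status`).}
#'     \item{db}{the behavior database: `frame, id, action, u, v`, one row
#'       per tracked individual per frame (see [action_counts()]).}
#'     \item{alerts}{data frame `frame, action` of group-action detections.}
#'     \item{parts}{list of per-frame part-action `det_frame`s (see
#'       [attach_part_actions()]).}
#'     \item{n_ids}{total distinct track identities ever created.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' scene <- simulate_barn(sim_config(n_agents = 3, duration = 60, seed = 7))
#' res <- track_stream(scene$detections, pipeline_config())
#' summary(res)
#' @export
track_stream <- function(frames, config = pipeline_config()) {
  if (config$vote) frames <- refine_stream(frames, config)
  tracker <- tracker_init(config)
  results <- vector("list", length(frames))
  alerts <- vector("list", length(frames))
  parts <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    f <- filter_detections(frames[[t]], config)
    parts[[t]] <- f$parts
    alerts[[t]] <- if (n_detections(f$alerts)) {
      data.frame(frame = f$alerts$frame, action = f$alerts$label,
                 stringsAsFactors = FALSE)
    } else NULL
    stepped <- tracker_step(tracker, f$tracked)
    tracker <- stepped$tracker
    results[[t]] <- stepped$result
  }
  tracks <- do.call(rbind, results)
  if (is.null(tracks)) {
    tracks <- data.frame(frame = integer(0), id = integer(0), u = numeric(0),
                         v = numeric(0), a = numeric(0), h = numeric(0),
                         action = character(0), status = character(0))
  }
  db <- behavior_db(tracks[, c("frame", "id", "action", "u", "v")])
  structure(list(tracks = tracks, db = db,
                 alerts = if (length(alerts)) do.call(rbind, alerts) else NULL,
                 parts = parts,
                 n_ids = tracker$next_id - 1L,
                 config = config),
            class = "herd_tracks")
}

#' @export
print.herd_tracks <- function(x, ...) {
  cat("<herd_tracks>", x$n_ids, "identities over",
      if (nrow(x$tracks)) max(x$tracks$frame) else 0L, "frames;",
      nrow(x$db), "behavior records\n")
  invisible(x)
}

#' @export
summary.herd_tracks <- function(object, ...) {
  cat("Tracking run:", object$n_ids, "identities,",
      if (nrow(object$tracks)) max(object$tracks$frame) else 0L, "frames\n")
  if (nrow(object$db)) {
    cat("Behavior record counts by action:\n")
    print(sort(table(object$db$action), decreasing = TRUE))
  }
  n_alert <- if (is.null(object$alerts)) 0L else nrow(object$alerts)
  cat("Group-action alerts:", n_alert, "\n")
  invisible(object)
}

#' Extract predicted tracks as a track set
#'
#' Converts a tracking run to the `(frame, id, box)` track-set data frame
#' consumed by the evaluation functions and MOT writers.
#'
#' @param x a `herd_tracks` object.
#' @return A data frame `frame, id, u, v, a, h`.
#' @export
as_trackset <- function(x) {
  stopifnot(inherits(x, "herd_tracks"))
  x$tracks[, c("frame", "id", "u", "v", "a", "h")]
}
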