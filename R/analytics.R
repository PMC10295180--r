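#' The identity-action behavior database
#'
#' An append-only table of `(frame, id, action, u, v)` records — one row per
#' tracked individual per frame, carrying the voted action label and the box
#' center. All long-term statistics are derived from it. [track_stream()]
#' builds one automatically; this constructor validates a hand-built or
#' re-read table.
#'
#' @param records data frame with columns `frame`, `id`, `action`, `u`, `v`.
#' @return The validated data frame with class `behavior_db`.
#' @export
behavior_db <- function(records) {
  need <- c("frame", "id", "action", "u", "v")
  if (!all(need %in% names(records))) {
    stop("behavior_db needs columns: ", paste(need, collapse = ", "))
  }
  records <- records[, need]
  if (nrow(records)) {
    if (is.unsorted(records$frame)) stop("frames must be non-decreasing")
    if (!all(records$action %in% action_taxonomy()$action)) {
      stop("actions must be taxonomy labels")
    }
    if (anyDuplicated(records[, c("frame", "id", "action")])) {
      stop("duplicate (frame, id, action) record")
    }
  }
  class(records) <- c("behavior_db", "data.frame")
  records
}

#' Per-individual action counts
#'
#' Counts the frames an identity spent in each action inside a frame window.
#' The counts over individual actions sum to the number of frames the
#' identity was observed in the window (part actions, recorded alongside,
#' are extra rows).
#'
#' @param db a [behavior_db()].
#' @param id track identity.
#' @param window length-2 frame interval `c(from, to)`, inclusive; default
#'   the whole database.
#' @return Named integer vector of frame counts per action (empty for an
#'   unknown id or an empty window).
#' @export
action_counts <- function(db, id, window = NULL) {
  rows <- db[db$id == id, ]
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] <= window[2L])
    rows <- rows[rows$frame >= window[1L] & rows$frame <= window[2L], ]
  }
  if (!nrow(rows)) return(integer(0))
  tab <- table(rows$action)
  stats::setNames(as.integer(tab), names(tab))
}

#' Herd-level behavior time series
#'
#' Splits the timeline into bins of `bin_width` frames and, per bin and
#' individual action, reports how many distinct identities had that action
#' as their modal (most frequent) label in the bin — or the fraction of
#' observed identities, in percentage mode. Fractions within a bin sum to 1
#' whenever any identity was observed.
#'
#' @param db a [behavior_db()].
#' @param bin_width bin width in frames (>= 1), e.g. `fps * 60` for
#'   per-minute bins.
#' @param mode `"count"` or `"percentage"`.
#' @return Data frame `bin_start_frame, action, value` covering every
#'   individual action in every bin.
#' @export
herd_stats <- function(db, bin_width, mode = c("count", "percentage")) {
  mode <- match.arg(mode)
  stopifnot(bin_width >= 1)
  acts <- individual_actions()
  rows <- db[db$action %in% acts, ]
  if (!nrow(rows)) {
    return(data.frame(bin_start_frame = integer(0), action = character(0),
                      value = numeric(0)))
  }
  bin0 <- (rows$frame - 1L) %/% bin_width * bin_width + 1L
  out <- list()
  for (b in sort(unique(bin0))) {
    in_bin <- rows[bin0 == b, ]
    modal <- vapply(split(in_bin$action, in_bin$id), function(a) {
      tab <- table(a)
      # modal action; ties to the earliest taxonomy label
      cand <- names(tab)[tab == max(tab)]
      acts[min(match(cand, acts))]
    }, character(1))
    counts <- vapply(acts, function(a) sum(modal == a), numeric(1))
    value <- if (mode == "percentage") counts / length(modal) else counts
    out[[length(out) + 1L]] <- data.frame(bin_start_frame = b, action = acts,
                                          value = unname(value))
  }
  do.call(rbind, out)
}

#' Trajectories and travelled distance
#'
#' `trajectories()` extracts the per-identity box-center time series;
#' `path_length()` sums the Euclidean steps between consecutive observed
#' frames. Distances are in pixels; multiply by a metres-per-pixel scale to
#' convert where calibration is available.
#'
#' @param db a [behavior_db()].
#' @return `trajectories()`: named list (one element per id) of data frames
#'   `frame, u, v` ordered by frame; part-action rows are excluded so each
#'   frame appears once.
#' @export
trajectories <- function(db) {
  rows <- db[db$action %in% individual_actions(), ]
  lapply(split(rows[, c("frame", "u", "v")], rows$id), function(d) {
    d[order(d$frame), ]
  })
}

#' @rdname trajectories
#' @param traj one trajectory data frame (`frame, u, v`).
#' @return `path_length()`: total path length in pixels.
#' @export
path_length <- function(traj) {
  if (nrow(traj) < 2L) return(0)
  sum(sqrt(diff(traj$u)^2 + diff(traj$v)^2))
}

#' Attribute part actions to tracked individuals
#'
#' A part action (ruminating, tail wagging, moving head) is detected as its
#' own small box. It is assigned to the individual whose track box contains
#' the largest fraction of the part box (containment = intersection area /
#' part-box area), provided that fraction is at least `min_containment`;
#' otherwise it is dropped. Assigned part actions become additional behavior
#' records alongside — never instead of — the individual's concurrent
#' whole-body action.
#'
#' @param parts list of per-frame part-action `det_frame`s (e.g. the `parts`
#'   element of a [track_stream()] result).
#' @param tracks per-frame track emissions (`tracks` element, or any data
#'   frame `frame, id, u, v, a, h`).
#' @param min_containment assignment threshold in `[0, 1]`.
#' @return A data frame of `(frame, id, action, u, v)` part-action records.
#' @export
attach_part_actions <- function(parts, tracks, min_containment = 0.8) {
  out <- list()
  for (pf in parts) {
    if (is.null(pf) || n_detections(pf) == 0L) next
    tr <- tracks[tracks$frame == pf$frame, ]
    if (!nrow(tr)) next
    tboxes <- as.matrix(tr[, c("u", "v", "a", "h")])
    tc <- bbox_to_corner(tboxes)
    pc <- bbox_to_corner(pf$boxes)
    for (i in seq_len(nrow(pc))) {
      ix <- pmax(0, pmin(tc[, 1L] + tc[, 3L], pc[i, 1L] + pc[i, 3L]) -
                    pmax(tc[, 1L], pc[i, 1L]))
      iy <- pmax(0, pmin(tc[, 2L] + tc[, 4L], pc[i, 2L] + pc[i, 4L]) -
                    pmax(tc[, 2L], pc[i, 2L]))
      containment <- ix * iy / (pc[i, 3L] * pc[i, 4L])
      best <- which.max(containment)
      if (containment[best] >= min_containment) {
        out[[length(out) + 1L]] <- data.frame(
          frame = pf$frame, id = tr$id[best], action = pf$label[i],
          u = pf$boxes[i, 1L], v = pf$boxes[i, 2L])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), id = integer(0),
                      action = character(0), u = numeric(0), v = numeric(0)))
  }
  do.call(rbind, out)
}

#' Write behavior report files
#'
#' Emits the three standard reports: per-identity action counts
#' (`id, action, frames, seconds`), the herd time series
#' (`bin_start_frame, action, count, percentage`) and the trajectory table
#' (`id, frame, u, v`), as CSV files in `dir`.
#'
#' @param db a [behavior_db()].
#' @param dir output directory (created if missing).
#' @param fps frames per second, used to convert frame counts to seconds.
#' @param bin_width herd time-series bin width in frames.
#' @return Invisibly, the three file paths.
#' @export
write_behavior_reports <- function(db, dir, fps = 15, bin_width = fps * 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(db$id))
  per_id <- do.call(rbind, lapply(ids, function(i) {
    ct <- action_counts(db, i)
    data.frame(id = i, action = names(ct), frames = as.integer(ct),
               seconds = as.integer(ct) / fps)
  }))
  counts <- herd_stats(db, bin_width, "count")
  pct <- herd_stats(db, bin_width, "percentage")
  herd <- cbind(counts, percentage = pct$value)
  names(herd)[names(herd) == "value"] <- "count"
  trajs <- trajectories(db)
  traj_tab <- do.call(rbind, lapply(names(trajs), function(i) {
    cbind(id = as.integer(i), trajs[[i]])
  }))
  paths <- file.path(dir, c("action_counts.csv", "herd_timeseries.csv",
                            "trajectories.csv"))
  utils::write.csv(per_id, paths[1L], row.names = FALSE)
  utils::write.csv(herd, paths[2L], row.names = FALSE)
  utils::write.csv(traj_tab, paths[3L], row.names = FALSE)
  invisible(paths)
}
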