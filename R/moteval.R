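#' Track sets
#'
#' A track set is the evaluation-side view of tracking output or ground
#' truth: a data frame with one row per `(frame, id)` holding a center-form
#' box (`u, v, a, h`).
#'
#' @param records data frame with columns `frame, id, u, v, a, h`.
#' @return The validated data frame with class `trackset`.
#' @export
trackset <- function(records) {
  need <- c("frame", "id", "u", "v", "a", "h")
  if (!all(need %in% names(records))) {
    stop("trackset needs columns: ", paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[, need]
  if (anyDuplicated(records[, c("frame", "id")])) {
    stop("one box per (frame, id) allowed")
  }
  class(records) <- c("trackset", "data.frame")
  records
}

ts_frame <- function(ts, f) ts[ts$frame == f, , drop = FALSE]
ts_boxes <- function(rows) as.matrix(rows[, c("u", "v", "a", "h")])

#' Match one frame's boxes
#'
#' Maximum-cardinality, then maximum-overlap one-to-one matching between
#' ground-truth and predicted boxes, restricted to pairs with IoU at least
#' `alpha` (Hungarian assignment on `1 - IoU`).
#'
#' @param gt_boxes,pred_boxes center-form box matrices for one frame.
#' @param alpha IoU threshold for a feasible pair.
#' @return List with `pairs` (2-column matrix of gt, pred row indices),
#'   `fn` (unmatched gt indices), `fp` (unmatched pred indices), and `iou`
#'   (IoU per matched pair).
#' @export
frame_match <- function(gt_boxes, pred_boxes, alpha = 0.5) {
  n <- nrow(gt_boxes); m <- nrow(pred_boxes)
  if (n == 0L || m == 0L) {
    return(list(pairs = matrix(integer(0), 0, 2), fn = seq_len(n),
                fp = seq_len(m), iou = numeric(0)))
  }
  ious <- iou_matrix(gt_boxes, pred_boxes)
  cost <- 1 - ious
  cost[ious < alpha] <- Inf
  sol <- solve_assignment(cost, max_cost = 1)
  list(pairs = sol$matches,
       fn = sol$unmatched_rows, fp = sol$unmatched_cols,
       iou = ious[sol$matches])
}

#' CLEAR-MOT metrics
#'
#' Computes MOTA, MOTP and identity switches frame by frame. Matching uses
#' IoU threshold `alpha` with carryover: a ground-truth identity still
#' overlapping (IoU >= alpha) the predicted identity it was matched to in
#' the previous frame keeps that pairing before the remaining boxes are
#' matched by Hungarian assignment. An identity switch is counted when a
#' ground-truth identity's matched predicted id differs from the predicted
#' id it was last matched to. `MOTA = 100 (1 - (FN + FP + IDSW) / GT)` (can
#' be negative); `MOTP = 100 x mean IoU` over matched pairs.
#'
#' @param gt,pred [trackset()]s (plain data frames accepted).
#' @param alpha IoU matching threshold.
#' @return List with `mota`, `motp`, `id_switches`, and the tallies `tp`,
#'   `fn`, `fp`, `n_gt`.
#' @export
clear_mot <- function(gt, pred, alpha = 0.5) {
  n_gt <- nrow(gt)
  if (n_gt == 0L) stop("ground truth is empty")
  frames <- sort(unique(c(gt$frame, pred$frame)))
  last_pred_of <- integer(0)     # names: gt id; value: last matched pred id
  tp <- 0L; fn <- 0L; fp <- 0L; idsw <- 0L
  iou_sum <- 0

  for (f in frames) {
    g <- ts_frame(gt, f); p <- ts_frame(pred, f)
    gb <- ts_boxes(g); pb <- ts_boxes(p)
    g_left <- seq_len(nrow(g)); p_left <- seq_len(nrow(p))

    # carryover of the previous pairing where it still holds
    if (nrow(g) && nrow(p)) {
      ious <- iou_matrix(gb, pb)
      for (i in seq_len(nrow(g))) {
        prev <- last_pred_of[as.character(g$id[i])]
        if (!is.na(prev) && length(prev)) {
          j <- match(prev, p$id)
          if (!is.na(j) && j %in% p_left && ious[i, j] >= alpha) {
            tp <- tp + 1L
            iou_sum <- iou_sum + ious[i, j]
            g_left <- setdiff(g_left, i)
            p_left <- setdiff(p_left, j)
          }
        }
      }
    }
    fm <- frame_match(gb[g_left, , drop = FALSE], pb[p_left, , drop = FALSE],
                      alpha)
    if (nrow(fm$pairs)) {
      for (r in seq_len(nrow(fm$pairs))) {
        gi <- g_left[fm$pairs[r, 1L]]; pj <- p_left[fm$pairs[r, 2L]]
        tp <- tp + 1L
        iou_sum <- iou_sum + fm$iou[r]
        prev <- last_pred_of[as.character(g$id[gi])]
        if (!is.na(prev) && length(prev) && prev != p$id[pj]) {
          idsw <- idsw + 1L
        }
        last_pred_of[as.character(g$id[gi])] <- p$id[pj]
      }
    }
    fn <- fn + length(g_left[fm$fn])
    fp <- fp + length(p_left[fm$fp])
  }
  list(mota = 100 * (1 - (fn + fp + idsw) / n_gt),
       motp = if (tp > 0L) 100 * iou_sum / tp else NA_real_,
       id_switches = idsw, tp = tp, fn = fn, fp = fp, n_gt = n_gt)
}

#' IDF1 identity metric
#'
#' Finds the global one-to-one mapping between ground-truth and predicted
#' trajectories that maximizes identity true positives (frames where a
#' mapped pair co-occurs with IoU >= `alpha`), then reports
#' `IDF1 = 100 x 2 IDTP / (2 IDTP + IDFP + IDFN)`. Invariant under any
#' global relabelling of predicted ids.
#'
#' @inheritParams clear_mot
#' @return IDF1 percentage.
#' @export
idf1 <- function(gt, pred, alpha = 0.5) {
  if (nrow(gt) == 0L) stop("ground truth is empty")
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  overlap <- idf1_overlap_counts(gt, pred, alpha, gids, pids)
  idtp <- 0
  if (length(gids) && length(pids)) {
    sol <- solve_assignment(-overlap, max_cost = Inf)
    if (nrow(sol$matches)) {
      idtp <- sum(overlap[sol$matches])
    }
  }
  idfn <- nrow(gt) - idtp
  idfp <- nrow(pred) - idtp
  100 * 2 * idtp / (2 * idtp + idfp + idfn)
}

# frames in which each (gt id, pred id) pair co-occurs with IoU >= alpha
idf1_overlap_counts <- function(gt, pred, alpha, gids, pids) {
  counts <- matrix(0, length(gids), length(pids))
  for (f in sort(unique(gt$frame))) {
    g <- ts_frame(gt, f); p <- ts_frame(pred, f)
    if (!nrow(g) || !nrow(p)) next
    ious <- iou_matrix(ts_boxes(g), ts_boxes(p))
    hit <- which(ious >= alpha, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- match(g$id[hit[, 1L]], gids)
      pj <- match(p$id[hit[, 2L]], pids)
      for (r in seq_along(gi)) {
        counts[gi[r], pj[r]] <- counts[gi[r], pj[r]] + 1
      }
    }
  }
  counts
}

#' HOTA — higher-order tracking accuracy
#'
#' For each localization threshold `alpha` in 0.05, 0.10, ..., 0.95, boxes
#' are matched per frame ([frame_match()]); detection accuracy is
#' `DetA = TP / (TP + FN + FP)` and association accuracy `AssA` is the mean
#' over true positives of `TPA / (TPA + FNA + FPA)`, where for a TP with
#' ground-truth id g and predicted id p, TPA counts TPs pairing g with p,
#' FNA the other appearances of g and FPA the other appearances of p.
#' `HOTA(alpha) = sqrt(DetA x AssA)` and the reported HOTA is the mean over
#' the 19 thresholds, x100.
#'
#' @inheritParams clear_mot
#' @return HOTA percentage.
#' @export
hota <- function(gt, pred) {
  if (nrow(gt) == 0L) stop("ground truth is empty")
  alphas <- seq(0.05, 0.95, by = 0.05)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  per_frame <- lapply(frames, function(f) {
    g <- ts_frame(gt, f); p <- ts_frame(pred, f)
    list(g = g, p = p,
         ious = if (nrow(g) && nrow(p)) iou_matrix(ts_boxes(g), ts_boxes(p))
                else matrix(0, nrow(g), nrow(p)))
  })
  vals <- vapply(alphas, function(alpha) {
    hota_alpha(per_frame, alpha, n_gt = nrow(gt), n_pred = nrow(pred))
  }, numeric(1))
  100 * mean(vals)
}

hota_alpha <- function(per_frame, alpha, n_gt, n_pred) {
  gt_id <- integer(0); pr_id <- integer(0)     # matched pairs over all frames
  tp <- 0L
  for (pf in per_frame) {
    n <- nrow(pf$g); m <- nrow(pf$p)
    if (n == 0L || m == 0L) next
    cost <- 1 - pf$ious
    cost[pf$ious < alpha] <- Inf
    sol <- solve_assignment(cost, max_cost = 1)
    if (nrow(sol$matches)) {
      tp <- tp + nrow(sol$matches)
      gt_id <- c(gt_id, pf$g$id[sol$matches[, 1L]])
      pr_id <- c(pr_id, pf$p$id[sol$matches[, 2L]])
    }
  }
  if (tp == 0L) return(0)
  fn <- n_gt - tp
  fp <- n_pred - tp
  det_a <- tp / (tp + fn + fp)
  pair_key <- paste(gt_id, pr_id)
  pair_n <- table(pair_key)
  tpa <- as.numeric(pair_n[pair_key])
  # FNA includes g's matched frames with other ids plus g's unmatched frames;
  # equivalently gt_total(g) - TPA where gt_total counts every gt box of g
  gt_all <- tabulate_ids(per_frame, "g")
  pr_all <- tabulate_ids(per_frame, "p")
  fna <- as.numeric(gt_all[as.character(gt_id)]) - tpa
  fpa <- as.numeric(pr_all[as.character(pr_id)]) - tpa
  ass_a <- mean(tpa / (tpa + fna + fpa))
  sqrt(det_a * ass_a)
}

tabulate_ids <- function(per_frame, side) {
  ids <- unlist(lapply(per_frame, function(pf) pf[[side]]$id))
  table(ids)
}

#' Evaluate a tracking run
#'
#' Bundles [clear_mot()], [idf1()] and [hota()] into one report, plus the
#' number of distinct predicted identities (the "IDs" figure of tracker
#' comparisons: with a fixed herd, fewer spurious identities is better).
#'
#' @inheritParams clear_mot
#' @return An object of class `mot_eval`: list with `hota`, `mota`, `motp`,
#'   `idf1` (percentages), `id_switches`, `n_pred_ids` and the CLEAR
#'   tallies.
#' @examples
#' scene <- simulate_barn(sim_config(n_agents = 3, duration = 60, seed = 1,
#'                                   noise = "none"))
#' res <- track_stream(scene$detections)
#' evaluate_tracking(scene$gt_tracks, as_trackset(res))
#' @export
evaluate_tracking <- function(gt, pred, alpha = 0.5) {
  cm <- clear_mot(gt, pred, alpha)
  structure(list(hota = hota(gt, pred),
                 mota = cm$mota, motp = cm$motp,
                 idf1 = idf1(gt, pred, alpha),
                 id_switches = cm$id_switches,
                 n_pred_ids = length(unique(pred$id)),
                 tallies = cm[c("tp", "fn", "fp", "n_gt")]),
            class = "mot_eval")
}

#' @export
print.mot_eval <- function(x, ...) {
  cat(sprintf(
    "<mot_eval> HOTA %.2f  MOTA %.2f  MOTP %.2f  IDF1 %.2f  IDSW %d  IDs %d\n",
    x$hota, x$mota, x$motp, x$idf1, x$id_switches, x$n_pred_ids))
  invisible(x)
}
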