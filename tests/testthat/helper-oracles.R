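# Independent brute-force oracles. These deliberately avoid the package's
# Hungarian solver and metric code paths: assignment by permutation
# enumeration, trajectory mapping by exhaustive injection search. They are
# only feasible at the tiny sizes used in tests.

all_perms <- function(n) {
  if (n == 0L) return(matrix(integer(0), 1, 0))
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# minimum total cost of a complete assignment on a square finite matrix
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  pm <- all_perms(n)
  min(apply(pm, 1L, function(p) sum(cost[cbind(seq_len(n), p)])))
}

# max-cardinality then max-overlap one-frame matching by exhaustive search;
# returns list(pairs, iou_sum)
oracle_frame_match <- function(ious, alpha) {
  n <- nrow(ious); m <- ncol(ious)
  best <- list(k = -1L, iou_sum = -Inf, pairs = matrix(integer(0), 0, 2))
  rec <- function(i, used, pairs) {
    if (i > n) {
      k <- nrow(pairs)
      s <- if (k) sum(ious[pairs]) else 0
      if (k > best$k || (k == best$k && s > best$iou_sum)) {
        best <<- list(k = k, iou_sum = s, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1L, used, pairs)                     # leave gt i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && ious[i, j] >= alpha) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(pairs, c(i, j)))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), matrix(integer(0), 0, 2))
  best
}

frame_rows <- function(ts, f) ts[ts$frame == f, , drop = FALSE]
rows_boxes <- function(r) as.matrix(r[, c("u", "v", "a", "h")])

# CLEAR-MOT recomputed from scratch with the exhaustive matcher
oracle_clear_mot <- function(gt, pred, alpha = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  prev <- c()
  tp <- 0L; fn <- 0L; fp <- 0L; idsw <- 0L; iou_sum <- 0
  for (f in frames) {
    g <- frame_rows(gt, f); p <- frame_rows(pred, f)
    pairs <- matrix(integer(0), 0, 2)
    g_open <- seq_len(nrow(g)); p_open <- seq_len(nrow(p))
    if (nrow(g) && nrow(p)) {
      ious <- iou_matrix(rows_boxes(g), rows_boxes(p))
      for (i in seq_len(nrow(g))) {
        pv <- prev[as.character(g$id[i])]
        if (!is.null(pv) && !is.na(pv)) {
          j <- match(pv, p$id)
          if (!is.na(j) && j %in% p_open && ious[i, j] >= alpha) {
            pairs <- rbind(pairs, c(i, j))
            g_open <- setdiff(g_open, i); p_open <- setdiff(p_open, j)
          }
        }
      }
      if (length(g_open) && length(p_open)) {
        sub <- oracle_frame_match(ious[g_open, p_open, drop = FALSE], alpha)
        if (nrow(sub$pairs)) {
          pairs <- rbind(pairs, cbind(g_open[sub$pairs[, 1L]],
                                      p_open[sub$pairs[, 2L]]))
        }
      }
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        tp <- tp + 1L
        iou_sum <- iou_sum + ious[i, j]
        pv <- prev[as.character(g$id[i])]
        if (!is.null(pv) && !is.na(pv) && pv != p$id[j]) idsw <- idsw + 1L
        prev[as.character(g$id[i])] <- p$id[j]
      }
    }
    fn <- fn + nrow(g) - nrow(pairs)
    fp <- fp + nrow(p) - nrow(pairs)
  }
  list(mota = 100 * (1 - (fn + fp + idsw) / nrow(gt)),
       motp = if (tp) 100 * iou_sum / tp else NA_real_,
       id_switches = idsw, tp = tp, fn = fn, fp = fp)
}

# IDF1 by exhaustive search over injective gt-id -> pred-id mappings
oracle_idf1 <- function(gt, pred, alpha = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  co <- matrix(0, length(gids), length(pids))
  for (f in sort(unique(gt$frame))) {
    g <- frame_rows(gt, f); p <- frame_rows(pred, f)
    if (!nrow(g) || !nrow(p)) next
    ious <- iou_matrix(rows_boxes(g), rows_boxes(p))
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      if (ious[i, j] >= alpha) {
        co[match(g$id[i], gids), match(p$id[j], pids)] <-
          co[match(g$id[i], gids), match(p$id[j], pids)] + 1
      }
    }
  }
  ng <- length(gids); np <- length(pids)
  best <- 0
  if (ng && np) {
    # enumerate all injections of the smaller side into the larger
    small_n <- if (ng <= np) ng else np
    big_n <- max(ng, np)
    idx <- utils::combn(big_n, small_n, simplify = FALSE)
    pm <- all_perms(small_n)
    for (sel in idx) {
      for (r in seq_len(nrow(pm))) {
        tot <- 0
        for (s in seq_len(small_n)) {
          if (ng <= np) tot <- tot + co[s, sel[pm[r, s]]]
          else tot <- tot + co[sel[pm[r, s]], s]
        }
        if (tot > best) best <- tot
      }
    }
  }
  idtp <- best
  100 * 2 * idtp / (2 * idtp + (nrow(gt) - idtp) + (nrow(pred) - idtp))
}

# HOTA recomputed from scratch with the exhaustive matcher
oracle_hota <- function(gt, pred) {
  alphas <- seq(0.05, 0.95, by = 0.05)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_tot <- table(gt$id); pr_tot <- table(pred$id)
  vals <- vapply(alphas, function(alpha) {
    gi <- integer(0); pj <- integer(0)
    for (f in frames) {
      g <- frame_rows(gt, f); p <- frame_rows(pred, f)
      if (!nrow(g) || !nrow(p)) next
      ious <- iou_matrix(rows_boxes(g), rows_boxes(p))
      mm <- oracle_frame_match(ious, alpha)
      if (nrow(mm$pairs)) {
        gi <- c(gi, g$id[mm$pairs[, 1L]])
        pj <- c(pj, p$id[mm$pairs[, 2L]])
      }
    }
    tp <- length(gi)
    if (!tp) return(0)
    det_a <- tp / (tp + (nrow(gt) - tp) + (nrow(pred) - tp))
    ass <- vapply(seq_len(tp), function(c) {
      tpa <- sum(gi == gi[c] & pj == pj[c])
      fna <- as.numeric(gt_tot[as.character(gi[c])]) - tpa
      fpa <- as.numeric(pr_tot[as.character(pj[c])]) - tpa
      tpa / (tpa + fna + fpa)
    }, numeric(1))
    sqrt(det_a * mean(ass))
  }, numeric(1))
  100 * mean(vals)
}
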