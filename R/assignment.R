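#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular linear assignment problem by the Hungarian
#' algorithm (potentials / shortest augmenting path, O(n^3)). Entries marked
#' `Inf` are infeasible: they are never part of a returned match. Matches
#' whose cost exceeds `max_cost` are demoted to unmatched, so the returned
#' matches, unmatched rows and unmatched columns always partition both sides.
#'
#' @param cost numeric cost matrix (rows = tracks, columns = detections);
#'   `Inf` marks infeasible pairs.
#' @param max_cost matches costlier than this are discarded (default `Inf`).
#' @return List with `matches` (2-column matrix of row, col indices),
#'   `unmatched_rows`, `unmatched_cols`.
#' @examples
#' solve_assignment(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2))
#' @export
solve_assignment <- function(cost, max_cost = Inf) {
  n <- nrow(cost); m <- ncol(cost)
  empty <- list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m))
  if (n == 0L || m == 0L) return(empty)
  if (any(is.na(cost))) stop("cost matrix must not contain NA")

  BIG <- 1e9
  finite <- cost
  finite[!is.finite(finite)] <- BIG
  k <- max(n, m)
  sq <- matrix(0, k, k)                    # dummy rows/cols cost 0
  sq[seq_len(n), seq_len(m)] <- finite

  col_of_row <- hungarian_square(sq)       # length k: column given to each row

  rows <- seq_len(n)
  cols <- col_of_row[rows]
  real <- which(cols <= m)
  cval <- cost[cbind(rows[real], cols[real])]
  keep <- real[is.finite(cval) & cval <= max_cost]
  matches <- cbind(row = rows[keep], col = cols[keep])
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(n), matches[, 1L]),
       unmatched_cols = setdiff(seq_len(m), matches[, 2L]))
}

# Hungarian algorithm on a k x k matrix; returns the assigned column per row.
# Index 1 plays the role of the virtual source column; data live at 2..k+1.
hungarian_square <- function(a) {
  k <- nrow(a)
  u <- numeric(k + 1L); v <- numeric(k + 1L)
  p <- integer(k + 1L)                      # p[j]: row matched to column j-1
  way <- integer(k + 1L)
  for (i in seq_len(k)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2L:(k + 1L)) {
        if (!used[j]) {
          cur <- a[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(k + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  col_of_row <- integer(k)
  for (j in 2L:(k + 1L)) col_of_row[p[j]] <- j - 1L
  col_of_row
}
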