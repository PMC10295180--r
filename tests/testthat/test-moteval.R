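ts_df <- function(frame, id, u, v = 100, a = 1.5, h = 60) {
  data.frame(frame = frame, id = id, u = u, v = v, a = a, h = h)
}

test_that("frame matching is one-to-one above the IoU floor", {
  g <- as.matrix(ts_df(1, 1:2, u = c(100, 300))[, c("u", "v", "a", "h")])
  fm <- frame_match(g, g, 0.5)
  expect_identical(nrow(fm$pairs), 2L)
  expect_length(fm$fn, 0)
  expect_length(fm$fp, 0)

  fm2 <- frame_match(g, g[0, , drop = FALSE], 0.5)
  expect_identical(fm2$fn, 1:2)

  # crossed overlaps {0.9, 0.2; 0.3, 0.8}: straight matching wins
  b <- function(u) c(u = u, v = 100, a = 1.5, h = 60)
  gt2 <- rbind(b(100), b(200))
  shift <- function(u0, iou) {
    # horizontal shift of equal boxes giving the wanted IoU: d = w(1-i)/(1+i)
    u0 + 90 * (1 - iou) / (1 + iou)
  }
  pr2 <- rbind(b(shift(100, 0.9)), b(shift(200, 0.8)))
  ious <- iou_matrix(gt2, pr2)
  expect_equal(diag(ious), c(0.9, 0.8), tolerance = 1e-9)
  fm3 <- frame_match(gt2, pr2, 0.5)
  expect_equal(fm3$pairs[order(fm3$pairs[, 1]), "col"], 1:2,
               ignore_attr = TRUE)
})

test_that("perfect tracking scores 100 everywhere with zero switches", {
  gt <- trackset(ts_df(rep(1:20, each = 2), rep(1:2, 20),
                       u = rep(c(100, 400), 20) + rep(1:20, each = 2)))
  ev <- evaluate_tracking(gt, gt)
  expect_equal(ev$mota, 100)
  expect_equal(ev$motp, 100)
  expect_equal(ev$idf1, 100)
  expect_equal(ev$hota, 100)
  expect_identical(ev$id_switches, 0L)
})

test_that("MOTA follows the CLEAR error formula on a hand-built scenario", {
  # 2 gt tracks x 5 frames = 10 gt boxes; predictions drop one box (FN),
  # add one spurious box (FP) and change one id mid-track (1 IDSW)
  gt <- trackset(ts_df(rep(1:5, each = 2), rep(1:2, 5),
                       u = rep(c(100, 400), 5)))
  pred <- ts_df(rep(1:5, each = 2), rep(c(1L, 2L), 5),
                u = rep(c(100, 400), 5))
  pred$id[pred$frame >= 4 & pred$id == 2L] <- 9L   # IDSW at frame 4
  pred <- pred[-1, ]                               # FN at frame 1
  pred <- rbind(pred, ts_df(3, 50L, u = 2000))     # FP at frame 3
  cm <- clear_mot(gt, trackset(pred))
  expect_identical(cm$fn, 1L)
  expect_identical(cm$fp, 1L)
  expect_identical(cm$id_switches, 1L)
  expect_equal(cm$mota, 70)

  # every prediction far off: all FN + all FP gives MOTA = -100
  off <- trackset(ts_df(rep(1:5, each = 2), rep(1:2, 5), u = 3000))
  expect_equal(clear_mot(gt, off)$mota, -100)
  expect_error(clear_mot(gt[0, ], gt), "empty")
})

test_that("IDF1 matches closed forms for half-coverage and full swap", {
  # one gt track covered half by pred id A, half by id B
  gt <- trackset(ts_df(1:20, 1L, u = 100))
  pred <- trackset(ts_df(1:20, rep(c(1L, 2L), each = 10), u = 100))
  expect_equal(idf1(gt, pred), 50)

  # two-track full swap at mid-sequence
  gt2 <- trackset(ts_df(rep(1:20, each = 2), rep(1:2, 20),
                        u = rep(c(100, 400), 20)))
  pr2 <- gt2
  swap <- pr2$frame > 10
  pr2$id[swap] <- 3L - pr2$id[swap]
  expect_equal(idf1(gt2, trackset(pr2)), 50)
  # invariant under global relabelling of predicted ids
  rel <- pr2; rel$id <- rel$id + 100L
  expect_equal(idf1(gt2, trackset(rel)), idf1(gt2, trackset(pr2)))
})

test_that("HOTA is 100 for perfect input, 0 for empty predictions", {
  gt <- trackset(ts_df(rep(1:10, each = 2), rep(1:2, 10),
                       u = rep(c(100, 400), 10)))
  expect_equal(hota(gt, gt), 100)
  empty <- trackset(data.frame(frame = integer(0), id = integer(0),
                               u = numeric(0), v = numeric(0),
                               a = numeric(0), h = numeric(0)))
  expect_equal(hota(gt, empty), 0)
})

test_that("MOTP ignores id labels; metrics agree with brute-force oracles", {
  set.seed(31)
  for (k in 1:10) {
    sc <- random_eval_scene(n_ids = sample(2:4, 1),
                            n_frames = sample(20:40, 1))
    mine <- clear_mot(sc$gt, sc$pred)
    orac <- oracle_clear_mot(sc$gt, sc$pred)
    expect_equal(mine$mota, orac$mota, tolerance = 1e-9)
    expect_equal(mine$motp, orac$motp, tolerance = 1e-9)
    expect_identical(mine$id_switches, orac$id_switches)
    expect_equal(idf1(sc$gt, sc$pred), oracle_idf1(sc$gt, sc$pred),
                 tolerance = 1e-9)
    # MOTP must not change under relabelling
    rel <- sc$pred; rel$id <- rel$id * 7L + 1000L
    expect_equal(clear_mot(sc$gt, trackset(rel))$motp, mine$motp)
  }
})

test_that("the two-agent swap scenario scores the same HOTA as the oracle", {
  gt <- trackset(ts_df(rep(1:12, each = 2), rep(1:2, 12),
                       u = rep(c(100, 400), 12)))
  pr <- gt
  swap <- pr$frame > 6
  pr$id[swap] <- 3L - pr$id[swap]
  expect_equal(hota(gt, trackset(pr)), oracle_hota(gt, pr), tolerance = 0.1)
  set.seed(33)
  for (k in 1:5) {
    sc <- random_eval_scene(n_ids = 3, n_frames = 25)
    expect_equal(hota(sc$gt, sc$pred), oracle_hota(sc$gt, sc$pred),
                 tolerance = 0.1)
  }
})
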