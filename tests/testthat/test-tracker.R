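test_that("detection filtering applies confidence, NMS, routing and the cap", {
  cfg <- pipeline_config()
  # 25 confident individual detections in a row: only 21 survive the cap
  dets <- do.call(bind_dets, lapply(1:25, function(i) {
    one_det(1, u = 150 * i, v = 500, label = "standing", score = 0.95)
  }))
  f <- filter_detections(dets, cfg)
  expect_identical(n_detections(f$tracked), 21L)

  # confidence 0.5 < 0.6 is dropped
  weak <- one_det(1, 100, 100, score = 0.5, objectness = 1)
  expect_identical(n_detections(filter_detections(weak, cfg)$tracked), 0L)

  # overlapping boxes at IoU > match_iou: the higher-confidence one wins
  hi <- one_det(1, 100, 100, a = 1, h = 40, score = 0.9)
  lo <- one_det(1, 102, 100, a = 1, h = 40, score = 0.8)
  expect_gt(bbox_iou(hi$boxes, lo$boxes), cfg$match_iou)
  kept <- filter_detections(bind_dets(hi, lo), cfg)$tracked
  expect_identical(n_detections(kept), 1L)
  expect_equal(kept$boxes[1, "u"], 100, ignore_attr = TRUE)

  # group actions raise alerts and never enter tracking; parts split off
  mix <- bind_dets(one_det(1, 100, 100, label = "standing"),
                   one_det(1, 600, 100, label = "fighting"),
                   one_det(1, 1200, 100, label = "ruminating"))
  f2 <- filter_detections(mix, cfg)
  expect_identical(f2$tracked$label, "standing")
  expect_identical(f2$alerts$label, "fighting")
  expect_identical(f2$parts$label, "ruminating")
})

test_that("perfect separated detections yield one stable id per agent", {
  frames <- straight_line_stream(5, 120)
  res <- track_stream(frames, pipeline_config())
  expect_identical(res$n_ids, 5L)
  # no id appears twice within a frame
  expect_false(any(tapply(res$tracks$id, res$tracks$frame,
                          function(x) anyDuplicated(x) > 0)))
  # every agent keeps a single id across all frames
  per_frame <- split(res$tracks$id, res$tracks$frame)
  expect_true(all(vapply(per_frame, function(x) identical(sort(x), 1:5),
                         logical(1))))
})

test_that("out-of-order frames are rejected", {
  trk <- tracker_init(pipeline_config())
  expect_error(tracker_step(trk, one_det(5, 100, 100)), "out-of-order")
})

test_that("tentative tracks confirm after n_init hits and die on a miss", {
  cfg <- pipeline_config()
  trk <- tracker_init(cfg)
  for (t in 1:3) {
    st <- tracker_step(trk, one_det(t, 100, 100))
    trk <- st$tracker
  }
  expect_identical(st$result$status, "confirmed")
  expect_identical(trk$tracks[[1]]$hits, 3L)

  # a 1-frame-old tentative track vanishes on a missed frame
  trk2 <- tracker_init(cfg)
  trk2 <- tracker_step(trk2, one_det(1, 100, 100))$tracker
  expect_identical(trk2$tracks[[1]]$status, "tentative")
  trk2 <- tracker_step(trk2, empty_frame(2))$tracker
  expect_length(trk2$tracks, 0)
})

test_that("confirmed tracks become lost after unmatched_max misses and are
           re-identified by appearance across a gap shorter than max_age", {
  scene <- simulate_barn(sim_config(
    n_agents = 3, duration = 260, seed = 21,
    hide_rate = 0, fp_rate = 0, fn_rate = 0, part_rate = 0, p_occl = 0,
    forced_hide = list(id = 2, start = 80, duration = 100)))
  res <- track_stream(scene$detections)
  expect_identical(matched_pred_id(scene, res, 2, 70:79),
                   matched_pred_id(scene, res, 2, 195:215))
})

test_that("a gap longer than max_age forces a new identity", {
  cfg <- pipeline_config(max_age = 60L)
  scene <- simulate_barn(sim_config(
    n_agents = 3, duration = 260, seed = 22,
    hide_rate = 0, fp_rate = 0, fn_rate = 0, part_rate = 0, p_occl = 0,
    forced_hide = list(id = 2, start = 80, duration = 100)))
  res <- track_stream(scene$detections, cfg)
  before <- matched_pred_id(scene, res, 2, 70:79)
  after <- matched_pred_id(scene, res, 2, 195:215)
  expect_false(is.na(before) || is.na(after))
  expect_true(before != after)
  expect_gt(res$n_ids, 3L)
})

test_that("tracking is deterministic and emits at most one box per id-frame", {
  scene <- simulate_barn(sim_config(n_agents = 4, duration = 80, seed = 13))
  r1 <- track_stream(scene$detections)
  r2 <- track_stream(scene$detections)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$n_ids, r2$n_ids)
  expect_false(anyDuplicated(r1$tracks[, c("frame", "id")]) > 0)
})

test_that("an empty stream produces empty results", {
  res <- track_stream(list(), pipeline_config())
  expect_identical(nrow(res$tracks), 0L)
  expect_identical(nrow(res$db), 0L)
  expect_identical(res$n_ids, 0L)
})

test_that("with voting off and lambda 1 association is motion-only", {
  # two agents whose embeddings are swapped every frame: an appearance-heavy
  # tracker would be confused, a motion-only one must not switch ids
  d <- 8L
  e1 <- c(1, rep(0, d - 1)); e2 <- c(0, 1, rep(0, d - 2))
  frames <- lapply(1:60, function(t) {
    bind_dets(
      one_det(t, u = 300 + 2 * t, v = 300, emb = if (t %% 2) e1 else e2),
      one_det(t, u = 1500 - 2 * t, v = 800, emb = if (t %% 2) e2 else e1))
  })
  cfg <- pipeline_config(lambda_motion = 1, vote = FALSE, cosine_gate = 1)
  res <- track_stream(frames, cfg)
  expect_identical(res$n_ids, 2L)
  ids_at_u_small <- unique(res$tracks$id[res$tracks$u < 1000])
  expect_length(ids_at_u_small, 1L)
})

test_that("trace length never exceeds the trace window", {
  cfg <- pipeline_config()
  trk <- tracker_init(cfg)
  for (t in 1:40) trk <- tracker_step(trk, one_det(t, 100 + t, 100))$tracker
  expect_lte(nrow(trk$tracks[[1]]$trace), cfg$trace_window)
  expect_identical(trk$tracks[[1]]$time_since_update, 0L)
})
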