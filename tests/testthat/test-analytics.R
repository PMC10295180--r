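mk_db <- function(...) {
  behavior_db(data.frame(...))
}

test_that("action counts sum to observed frames per id and window", {
  db <- mk_db(frame = 1:900, id = 7L, action = "resting",
              u = 100, v = 100)
  expect_identical(action_counts(db, 7), c(resting = 900L))
  expect_identical(action_counts(db, 99), integer(0))

  db2 <- mk_db(frame = 1:900, id = 1L,
               action = rep(c("standing", "walking"), c(600, 300)),
               u = 0, v = 0)
  expect_identical(action_counts(db2, 1),
                   c(standing = 600L, walking = 300L))
  expect_identical(action_counts(db2, 1, window = c(550, 650)),
                   c(standing = 51L, walking = 50L))
  expect_identical(sum(action_counts(db2, 1)), 900L)
})

test_that("herd statistics report modal-action head counts and percentages", {
  frames <- rep(1:10, times = 10)
  ids <- rep(1:10, each = 10)
  db <- mk_db(frame = sort(frames), id = ids[order(frames)],
              action = "resting", u = 0, v = 0)
  hs <- herd_stats(db, 10, "count")
  expect_equal(hs$value[hs$action == "resting"], 10)
  hp <- herd_stats(db, 10, "percentage")
  expect_equal(hp$value[hp$action == "resting"], 1)
  expect_equal(sum(hp$value), 1)                     # fractions sum to 1

  # 4 standing + 4 resting + 2 walking -> 40 / 40 / 20 %
  acts <- rep(c("standing", "resting", "walking"), c(4, 4, 2))
  db2 <- mk_db(frame = rep(1L, 10), id = 1:10, action = acts, u = 0, v = 0)
  hp2 <- herd_stats(db2, 5, "percentage")
  expect_equal(hp2$value[hp2$action == "standing"], 0.4)
  expect_equal(hp2$value[hp2$action == "resting"], 0.4)
  expect_equal(hp2$value[hp2$action == "walking"], 0.2)

  # every observed id contributes to exactly one modal cell per bin
  set.seed(4)
  raw3 <- data.frame(frame = sort(sample(1:60, 200, TRUE)),
                     id = sample(1:6, 200, TRUE),
                     action = sample(individual_actions(), 200, TRUE),
                     u = 0, v = 0)
  db3 <- behavior_db(raw3[!duplicated(raw3[, c("frame", "id")]), ])
  hc <- herd_stats(db3, 20, "count")
  for (b in unique(hc$bin_start_frame)) {
    in_bin <- db3[db3$frame >= b & db3$frame < b + 20, ]
    expect_equal(sum(hc$value[hc$bin_start_frame == b]),
                 length(unique(in_bin$id)))
  }
  expect_identical(nrow(herd_stats(mk_db(frame = integer(0), id = integer(0),
                                         action = character(0), u = numeric(0),
                                         v = numeric(0)), 10)), 0L)
})

test_that("trajectories and path length follow the box centers", {
  db <- mk_db(frame = 1:50, id = 3L, action = "standing", u = 400, v = 250)
  tr <- trajectories(db)
  expect_named(tr, "3")
  expect_equal(path_length(tr[["3"]]), 0)

  db2 <- mk_db(frame = 1:101, id = 1L, action = "walking",
               u = seq(0, 200, by = 2), v = 0)
  expect_equal(path_length(trajectories(db2)[["1"]]), 200)

  # L-shaped path: 100 px right then 50 px down in unit steps
  db3 <- mk_db(frame = 1:151, id = 1L, action = "walking",
               u = c(0:100, rep(100, 50)), v = c(rep(0, 101), 1:50))
  expect_equal(path_length(trajectories(db3)[["1"]]), 150)
})

test_that("part actions are attributed by containment in the track box", {
  tracks <- data.frame(frame = 1L, id = c(10L, 20L),
                       u = c(100, 300), v = c(100, 100),
                       a = c(2, 2), h = c(50, 50))
  # part box fully inside track 10
  part_in <- one_det(1, 100, 100, a = 1, h = 20, label = "ruminating")
  rec <- attach_part_actions(list(part_in), tracks)
  expect_identical(rec$id, 10L)
  expect_identical(rec$action, "ruminating")

  # part box overlapping nothing at >= 0.8 containment is dropped
  part_out <- one_det(1, 700, 700, a = 1, h = 20, label = "tail wagging")
  expect_identical(nrow(attach_part_actions(list(part_out), tracks)), 0L)

  # 80% contained in A vs 20% in B: goes to A
  tracks2 <- data.frame(frame = 1L, id = c(1L, 2L),
                        u = c(0, 40), v = c(0, 0), a = c(1, 1),
                        h = c(40, 40))
  part <- one_det(1, u = 17, v = 0, a = 1, h = 10, label = "moving head")
  rec2 <- attach_part_actions(list(part), tracks2, min_containment = 0.5)
  expect_identical(rec2$id, 1L)
})

test_that("reports round-trip through CSV with identical statistics", {
  scene <- simulate_barn(sim_config(n_agents = 4, duration = 60, seed = 8,
                                    noise = "none", static_actions = TRUE))
  res <- track_stream(scene$detections)
  dir <- withr::local_tempdir()
  write_behavior_reports(res$db, dir, fps = 15, bin_width = 30)
  back <- utils::read.csv(file.path(dir, "action_counts.csv"))
  for (i in unique(res$db$id)) {
    ct <- action_counts(res$db, i)
    sub <- back[back$id == i, ]
    expect_identical(stats::setNames(sub$frames, sub$action), ct)
  }
  traj <- utils::read.csv(file.path(dir, "trajectories.csv"))
  expect_identical(nrow(traj), nrow(res$db))
})

test_that("behavior db validation catches malformed records", {
  expect_error(behavior_db(data.frame(frame = c(2, 1), id = 1,
                                      action = "standing", u = 0, v = 0)),
               "non-decreasing")
  expect_error(behavior_db(data.frame(frame = 1, id = 1,
                                      action = "grazing", u = 0, v = 0)),
               "taxonomy")
  expect_error(behavior_db(data.frame(frame = c(1, 1), id = c(1, 1),
                                      action = "standing", u = 0, v = 0)),
               "duplicate")
})
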