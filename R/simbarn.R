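#' Synthetic barn scene configuration
#'
#' Parameters of the synthetic scene generator. The defaults emulate the
#' study setting: a 30 x 12 m pen holding 21 animals (3 of them calves at
#' 0.6 scale) filmed by a fixed camera at 15 fps and 3840 x 2160 px.
#' Behavior follows a semi-Markov chain over the five individual actions
#' (geometric dwell times with configurable means; walking is the only
#' locomotive state); box height grows toward the bottom of the frame as a
#' perspective proxy, giving scale variation; occlusion arises both from
#' box overlap and from longer "hidden" episodes during which ground truth
#' continues but no detection is emitted. The detection stream corrupts
#' ground truth with box jitter, class confusion, missed detections,
#' uniform-clutter false positives (low objectness, so the confidence
#' filter removes most) and embedding noise.
#'
#' @param n_agents number of animals.
#' @param n_calves how many of them are calves (rendered at `calf_scale`);
#'   defaults to 3 at full herd size and scales down for small scenes.
#' @param calf_scale box-size scale factor for calves.
#' @param barn_m pen size `c(width, depth)` in metres.
#' @param frame_px image size `c(width, height)` in pixels.
#' @param fps frames per second.
#' @param duration scene length in frames.
#' @param embedding_dim appearance embedding dimension d.
#' @param seed integer seed; fixes the entire scene.
#' @param dwell_mean named mean dwell times (frames) per individual action.
#' @param transitions row-stochastic transition matrix between individual
#'   actions, applied when a dwell ends (rows must sum to 1).
#' @param speed_mps named movement speed per action in m/s (only walking
#'   moves by default).
#' @param static_actions if `TRUE`, every agent keeps its initial action for
#'   the whole scene (used by perfect-recovery checks, where label-smoothing
#'   lag at transitions would otherwise be conflated with tracking errors).
#' @param jitter_sigma box jitter standard deviation as a fraction of box
#'   height.
#' @param confusion_rate probability a detection's class scores favor a
#'   wrong action.
#' @param fn_rate probability a visible agent yields no detection in a frame.
#' @param fp_rate expected false-positive detections per frame (Poisson).
#' @param sigma_e embedding noise scale: the Gaussian perturbation added to
#'   the agent's mean embedding has expected norm `sigma_e` (per-component
#'   sd `sigma_e / sqrt(d)`).
#' @param occl_iou ground-truth box IoU above which the farther agent may be
#'   occluded.
#' @param p_occl per-frame drop probability when occluded by overlap.
#' @param hide_rate per-frame probability an agent starts a hidden episode.
#' @param hide_mean mean length (frames, geometric) of hidden episodes.
#' @param part_rate per-frame probability an agent also emits a part-action
#'   detection (head/mouth/tail box inside its body box).
#' @param min_sep_m minimum ground-plane separation enforced between agents.
#' @param forced_hide optional scripted occlusion: `list(id, start,
#'   duration)` hides that agent for exactly those frames.
#' @param noise `"default"` or `"none"`; `"none"` zeroes every noise source
#'   (jitter, confusion, misses, clutter, embedding noise, occlusion) and
#'   fixes objectness at 1, so detections reproduce ground truth exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 21L,
                       n_calves = min(3L, n_agents %/% 7L),
                       calf_scale = 0.6,
                       barn_m = c(30, 12),
                       frame_px = c(3840, 2160),
                       fps = 15,
                       duration = 900L,
                       embedding_dim = 128L,
                       seed = 1L,
                       dwell_mean = c("standing" = 150, "walking" = 90,
                                      "resting" = 600, "standing up" = 30,
                                      "self-grooming" = 75),
                       transitions = NULL,
                       speed_mps = c("standing" = 0, "walking" = 0.8,
                                     "resting" = 0, "standing up" = 0,
                                     "self-grooming" = 0),
                       static_actions = FALSE,
                       jitter_sigma = 0.02,
                       confusion_rate = 0.1,
                       fn_rate = 0.05,
                       fp_rate = 0.2,
                       sigma_e = 0.1,
                       occl_iou = 0.3,
                       p_occl = 0.5,
                       hide_rate = 5e-4,
                       hide_mean = 150,
                       part_rate = 0.05,
                       min_sep_m = 1.5,
                       forced_hide = NULL,
                       noise = c("default", "none")) {
  noise <- match.arg(noise)
  acts <- individual_actions()
  if (is.null(transitions)) {
    transitions <- matrix(0, 5, 5, dimnames = list(acts, acts))
    transitions["standing", c("walking", "resting", "self-grooming")] <-
      c(0.4, 0.4, 0.2)
    transitions["walking", "standing"] <- 1
    transitions["resting", "standing up"] <- 1
    transitions["standing up", "standing"] <- 1
    transitions["self-grooming", "standing"] <- 1
  }
  if (noise == "none") {
    jitter_sigma <- 0; confusion_rate <- 0; fn_rate <- 0; fp_rate <- 0
    sigma_e <- 0; p_occl <- 0; hide_rate <- 0; part_rate <- 0
  }
  cfg <- structure(
    list(n_agents = as.integer(n_agents), n_calves = as.integer(n_calves),
         calf_scale = calf_scale, barn_m = barn_m, frame_px = frame_px,
         fps = fps, duration = as.integer(duration),
         embedding_dim = as.integer(embedding_dim), seed = as.integer(seed),
         dwell_mean = dwell_mean, transitions = transitions,
         speed_mps = speed_mps, static_actions = isTRUE(static_actions),
         jitter_sigma = jitter_sigma, confusion_rate = confusion_rate,
         fn_rate = fn_rate, fp_rate = fp_rate, sigma_e = sigma_e,
         occl_iou = occl_iou, p_occl = p_occl, hide_rate = hide_rate,
         hide_mean = hide_mean, part_rate = part_rate,
         min_sep_m = min_sep_m, forced_hide = forced_hide, noise = noise),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  acts <- individual_actions()
  stopifnot(cfg$n_agents >= 1L, cfg$n_calves >= 0L,
            cfg$n_calves <= cfg$n_agents,
            length(cfg$barn_m) == 2L, all(cfg$barn_m > 0),
            length(cfg$frame_px) == 2L, all(cfg$frame_px > 0),
            cfg$duration >= 1L, cfg$embedding_dim >= 2L)
  rates <- c(cfg$confusion_rate, cfg$fn_rate, cfg$p_occl, cfg$hide_rate,
             cfg$part_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!all(acts %in% rownames(cfg$transitions))) {
    stop("transition matrix must cover all individual actions")
  }
  if (any(abs(rowSums(cfg$transitions) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  # a rough feasibility check: each agent needs ~min_sep_m^2 of floor
  if (cfg$n_agents * cfg$min_sep_m^2 > prod(cfg$barn_m)) {
    stop("too many agents for the pen at the requested separation")
  }
  invisible(cfg)
}

#' Simulate a barn scene
#'
#' Generates ground-truth trajectories and actions for every agent plus the
#' noise-corrupted per-frame detection stream derived from them (see
#' [sim_config()] for the scene model). Fully deterministic given the
#' config's seed; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return An object of class `barn_scene`: list with
#'   \describe{
#'     \item{gt_tracks}{[trackset()] of true boxes, complete for every agent
#'       and frame.}
#'     \item{gt_actions}{data frame `frame, id, action` of true actions.}
#'     \item{detections}{list of per-frame [det_frame()]s (body, part and
#'       false-positive detections mixed, as a detector would emit them).}
#'     \item{agent_embeddings}{`n_agents x d` matrix of true mean unit
#'       embeddings.}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' scene <- simulate_barn(sim_config(n_agents = 5, duration = 120, seed = 3))
#' scene
#' @export
simulate_barn <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)
  simulate_barn_impl(config)
}

simulate_barn_impl <- function(cfg) {
  n <- cfg$n_agents; T_ <- cfg$duration
  acts <- individual_actions()
  d <- cfg$embedding_dim
  px_per_m_x <- cfg$frame_px[1L] / cfg$barn_m[1L]
  px_per_m_y <- cfg$frame_px[2L] / cfg$barn_m[2L]

  # agent constants
  scale <- rep(1, n)
  if (cfg$n_calves > 0L) scale[seq_len(cfg$n_calves)] <- cfg$calf_scale
  aspect <- stats::runif(n, 1.6, 2.0)
  means <- matrix(stats::rnorm(n * d), n, d)
  means <- means / sqrt(rowSums(means^2))

  # initial placement on a jittered grid, honoring min separation
  ncol_grid <- ceiling(sqrt(n * cfg$barn_m[1L] / cfg$barn_m[2L]))
  nrow_grid <- ceiling(n / ncol_grid)
  gx <- ((seq_len(n) - 1L) %% ncol_grid + 0.5) / ncol_grid * (cfg$barn_m[1L] - 3) + 1.5
  gy <- ((seq_len(n) - 1L) %/% ncol_grid + 0.5) / nrow_grid * (cfg$barn_m[2L] - 1.6) + 0.8
  x <- gx + stats::runif(n, -0.3, 0.3)
  y <- gy + stats::runif(n, -0.3, 0.3)

  action <- sample(acts, n, replace = TRUE,
                   prob = c(0.35, 0.1, 0.45, 0.02, 0.08))
  dwell <- draw_dwell(cfg, action)
  heading <- stats::runif(n, 0, 2 * pi)
  hidden_left <- integer(n)

  gt <- vector("list", T_)
  gt_act <- vector("list", T_)
  dets <- vector("list", T_)
  visible_hist <- matrix(TRUE, T_, n)

  for (t in seq_len(T_)) {
    if (!cfg$static_actions) {
      dwell <- dwell - 1L
      done <- which(dwell <= 0L)
      for (i in done) {
        action[i] <- sample(acts, 1L, prob = cfg$transitions[action[i], ])
        if (action[i] == "walking") heading[i] <- stats::runif(1, 0, 2 * pi)
      }
      if (length(done)) dwell[done] <- draw_dwell(cfg, action[done])
    }

    # kinematics: walking agents move along their heading with slight wander
    sp <- cfg$speed_mps[action] / cfg$fps
    mv <- which(sp > 0)
    if (length(mv)) {
      heading[mv] <- heading[mv] + stats::rnorm(length(mv), 0, 0.05)
      x[mv] <- x[mv] + sp[mv] * cos(heading[mv])
      y[mv] <- y[mv] + sp[mv] * sin(heading[mv])
    }
    # reflect at walls
    for (i in seq_len(n)) {
      if (x[i] < 1.5 || x[i] > cfg$barn_m[1L] - 1.5) {
        x[i] <- min(max(x[i], 1.5), cfg$barn_m[1L] - 1.5)
        heading[i] <- pi - heading[i]
      }
      if (y[i] < 0.8 || y[i] > cfg$barn_m[2L] - 0.8) {
        y[i] <- min(max(y[i], 0.8), cfg$barn_m[2L] - 0.8)
        heading[i] <- -heading[i]
      }
    }
    # soft repulsion keeps agents min_sep_m apart in the ground plane
    if (n > 1L) {
      dd <- as.matrix(stats::dist(cbind(x, y)))
      close <- which(dd < cfg$min_sep_m & upper.tri(dd), arr.ind = TRUE)
      for (r in seq_len(nrow(close))) {
        i <- close[r, 1L]; j <- close[r, 2L]
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        nd <- sqrt(dx^2 + dy^2)
        if (nd < 1e-6) { dx <- 1; dy <- 0; nd <- 1 }
        push <- (cfg$min_sep_m - nd) / 2
        x[i] <- x[i] - push * dx / nd; y[i] <- y[i] - push * dy / nd
        x[j] <- x[j] + push * dx / nd; y[j] <- y[j] + push * dy / nd
      }
      x <- pmin(pmax(x, 1.5), cfg$barn_m[1L] - 1.5)
      y <- pmin(pmax(y, 0.8), cfg$barn_m[2L] - 0.8)
    }

    # project to image: height grows toward the bottom (near side) of frame
    u <- x * px_per_m_x
    v <- y * px_per_m_y
    h <- (0.55 + 0.55 * y / cfg$barn_m[2L]) * 200 * scale
    boxes <- bbox(u = u, v = v, a = aspect, h = h)
    gt[[t]] <- data.frame(frame = t, id = seq_len(n), u = u, v = v,
                          a = aspect, h = h)
    gt_act[[t]] <- data.frame(frame = t, id = seq_len(n), action = action,
                              stringsAsFactors = FALSE)

    # visibility: hidden episodes, scripted hides, overlap occlusion
    hidden_left <- pmax(hidden_left - 1L, 0L)
    if (cfg$hide_rate > 0) {
      start <- which(hidden_left == 0L &
                       stats::runif(n) < cfg$hide_rate)
      if (length(start)) {
        hidden_left[start] <- stats::rgeom(length(start),
                                           1 / cfg$hide_mean) + 1L
      }
    }
    visible <- hidden_left == 0L
    fh <- cfg$forced_hide
    if (!is.null(fh) && t >= fh$start && t < fh$start + fh$duration) {
      visible[fh$id] <- FALSE
    }
    if (cfg$p_occl > 0 && n > 1L) {
      ious <- iou_matrix(boxes, boxes)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (ious[i, j] > cfg$occl_iou) {
          behind <- if (v[i] < v[j]) i else j   # smaller v = farther away
          if (stats::runif(1) < cfg$p_occl) visible[behind] <- FALSE
        }
      }
    }
    visible_hist[t, ] <- visible

    dets[[t]] <- make_detections(cfg, t, boxes, action, means, visible)
  }

  structure(list(
    gt_tracks = trackset(do.call(rbind, gt)),
    gt_actions = do.call(rbind, gt_act),
    detections = dets,
    agent_embeddings = means,
    visible = visible_hist,
    config = cfg), class = "barn_scene")
}

draw_dwell <- function(cfg, action) {
  m <- cfg$dwell_mean[action]
  stats::rgeom(length(action), 1 / m) + 1L
}

noisy_embedding <- function(mean_vec, sigma_e) {
  d <- length(mean_vec)
  e <- mean_vec + stats::rnorm(d, 0, sigma_e / sqrt(d))
  e / sqrt(sum(e^2))
}

make_scores <- function(true_label, all_actions, confused) {
  s <- stats::setNames(numeric(length(all_actions)), all_actions)
  if (confused) {
    wrong <- sample(setdiff(individual_actions(), true_label), 1L)
    s[wrong] <- stats::runif(1, 0.6, 0.9)
    s[true_label] <- stats::runif(1, 0.2, 0.5)
  } else {
    s[true_label] <- stats::runif(1, 0.75, 0.95)
    others <- sample(setdiff(all_actions, true_label), 2L)
    s[others] <- stats::runif(2, 0, 0.15)
  }
  s
}

make_detections <- function(cfg, t, boxes, action, means, visible) {
  all_actions <- action_taxonomy()$action
  n <- nrow(boxes)
  rows <- list()
  for (i in seq_len(n)) {
    if (!visible[i]) next
    if (cfg$fn_rate > 0 && stats::runif(1) < cfg$fn_rate) next
    b <- boxes[i, ]
    if (cfg$jitter_sigma > 0) {
      jh <- cfg$jitter_sigma * b[4L]
      b[1L] <- b[1L] + stats::rnorm(1, 0, jh)
      b[2L] <- b[2L] + stats::rnorm(1, 0, jh)
      b[4L] <- max(b[4L] + stats::rnorm(1, 0, jh), 2)
      b[3L] <- max(b[3L] * exp(stats::rnorm(1, 0, cfg$jitter_sigma)), 0.1)
    }
    if (cfg$noise == "none") {
      scores <- stats::setNames(numeric(length(all_actions)), all_actions)
      scores[action[i]] <- 0.95
      obj <- 1
    } else {
      scores <- make_scores(action[i], all_actions,
                            confused = stats::runif(1) < cfg$confusion_rate)
      obj <- stats::runif(1, 0.75, 1)
    }
    emb <- if (cfg$sigma_e > 0) noisy_embedding(means[i, ], cfg$sigma_e)
           else means[i, ]
    rows[[length(rows) + 1L]] <- list(box = b, scores = scores,
                                      obj = obj, emb = emb)
    # optional part-action box nested inside the body box
    if (cfg$part_rate > 0 && stats::runif(1) < cfg$part_rate) {
      pa <- sample(part_actions(), 1L)
      pb <- c(b[1L] - 0.25 * b[3L] * b[4L], b[2L] - 0.25 * b[4L],
              b[3L], b[4L] * 0.3)
      ps <- stats::setNames(numeric(length(all_actions)), all_actions)
      ps[pa] <- stats::runif(1, 0.75, 0.95)
      rows[[length(rows) + 1L]] <- list(
        box = pb, scores = ps, obj = stats::runif(1, 0.75, 1),
        emb = noisy_embedding(means[i, ], max(cfg$sigma_e, 0.05)))
    }
  }
  if (cfg$fp_rate > 0) {
    for (k in seq_len(stats::rpois(1, cfg$fp_rate))) {
      hh <- stats::runif(1, 80, 300)
      fb <- c(stats::runif(1, 200, cfg$frame_px[1L] - 200),
              stats::runif(1, 150, cfg$frame_px[2L] - 150),
              stats::runif(1, 1, 2.5), hh)
      fs <- stats::setNames(numeric(length(all_actions)), all_actions)
      fs[sample(individual_actions(), 1L)] <- stats::runif(1, 0.4, 0.9)
      fe <- stats::rnorm(cfg$embedding_dim)
      rows[[length(rows) + 1L]] <- list(
        box = fb, scores = fs, obj = stats::runif(1, 0.2, 0.7),
        emb = fe / sqrt(sum(fe^2)))
    }
  }
  if (!length(rows)) return(empty_det_frame(t, cfg$embedding_dim))
  det_frame(
    frame = t,
    boxes = do.call(rbind, lapply(rows, `[[`, "box")),
    scores = do.call(rbind, lapply(rows, `[[`, "scores")),
    objectness = vapply(rows, `[[`, numeric(1), "obj"),
    embeddings = do.call(rbind, lapply(rows, `[[`, "emb")))
}

#' @export
print.barn_scene <- function(x, ...) {
  cat("<barn_scene>", x$config$n_agents, "agents,", x$config$duration,
      "frames,", sum(vapply(x$detections, n_detections, integer(1))),
      "detections\n")
  invisible(x)
}
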