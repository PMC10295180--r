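#' Tracking pipeline configuration
#'
#' Bundles every tunable of the voting + tracking pipeline. The defaults are
#' the operating point used throughout: 15 fps footage, a 4-frame voting
#' window, detection confidence threshold 0.6 with NMS at IoU 0.75, at most
#' 21 targets per frame (the herd size), track confirmation after 3
#' consecutive hits, loss of a confirmed track after 7 consecutive misses,
#' deletion of a lost track 5000 frames (about 5.5 min at 15 fps) after its
#' last match, a 15-frame trace window, and the combined association cost
#' `D = lambda * Dm + (1 - lambda) * Dc` with `lambda = 0.1` weighting the
#' (gate-normalized) Mahalanobis motion distance against the cosine
#' appearance distance.
#'
#' @param fps frames per second of the footage (reporting only).
#' @param vote_N voting window length N (frames); labels from frame N onward
#'   are decided by the window vote.
#' @param vote_iou minimum IoU for a prior-frame box to join a vote chain.
#' @param track_conf minimum detection confidence (objectness x best class
#'   score) for a detection to enter tracking.
#' @param match_iou NMS suppression threshold applied to incoming detections.
#' @param max_iou_distance maximum IoU cost (1 - IoU) for the fallback IoU
#'   association stage.
#' @param max_targets cap on detections kept per frame.
#' @param n_init consecutive hits before a tentative track is confirmed.
#' @param unmatched_max consecutive misses before a confirmed track becomes
#'   lost (appearance-only re-identification from then on).
#' @param max_age frames since last match after which a lost track is deleted.
#' @param trace_window number of recent centers kept per track for display.
#' @param lambda_motion weight of the motion term in the combined cost.
#' @param embedding_dim appearance embedding dimension d.
#' @param gallery_budget per-track appearance gallery size (ring buffer).
#' @param cosine_gate maximum cosine distance for a feasible appearance match.
#' @param mahalanobis_gate squared-Mahalanobis gate; default the 0.95
#'   chi-square quantile at 4 degrees of freedom (the measurement dimension).
#' @param sigma_p,sigma_v Kalman position / velocity noise scales, as
#'   fractions of box height per frame.
#' @param vote logical; apply action majority voting before tracking.
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$max_age
#' @export
pipeline_config <- function(fps = 15,
                            vote_N = 4L,
                            vote_iou = 0.5,
                            track_conf = 0.6,
                            match_iou = 0.75,
                            max_iou_distance = 0.7,
                            max_targets = 21L,
                            n_init = 3L,
                            unmatched_max = 7L,
                            max_age = 5000L,
                            trace_window = 15L,
                            lambda_motion = 0.1,
                            embedding_dim = 128L,
                            gallery_budget = 100L,
                            cosine_gate = 0.2,
                            mahalanobis_gate = stats::qchisq(0.95, df = 4),
                            sigma_p = 1 / 20,
                            sigma_v = 1 / 160,
                            vote = TRUE) {
  cfg <- list(fps = fps, vote_N = as.integer(vote_N), vote_iou = vote_iou,
              track_conf = track_conf, match_iou = match_iou,
              max_iou_distance = max_iou_distance,
              max_targets = as.integer(max_targets),
              n_init = as.integer(n_init),
              unmatched_max = as.integer(unmatched_max),
              max_age = as.integer(max_age),
              trace_window = as.integer(trace_window),
              lambda_motion = lambda_motion,
              embedding_dim = as.integer(embedding_dim),
              gallery_budget = as.integer(gallery_budget),
              cosine_gate = cosine_gate,
              mahalanobis_gate = mahalanobis_gate,
              sigma_p = sigma_p, sigma_v = sigma_v,
              vote = isTRUE(vote))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  unit <- c("vote_iou", "track_conf", "match_iou", "max_iou_distance",
            "lambda_motion", "cosine_gate")
  for (k in unit) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single number in [0, 1]", k))
    }
  }
  pos <- c("fps", "vote_N", "max_targets", "n_init", "unmatched_max",
           "max_age", "trace_window", "embedding_dim", "gallery_budget",
           "mahalanobis_gate", "sigma_p", "sigma_v")
  for (k in pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", k))
    }
  }
  if (!(cfg$n_init <= cfg$unmatched_max && cfg$unmatched_max <= cfg$max_age)) {
    stop("need n_init <= unmatched_max <= max_age")
  }
  if (cfg$max_targets < 1L) stop("max_targets must be >= 1")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  keys <- names(x)
  vals <- vapply(keys, function(k) format(x[[k]]), character(1))
  cat(paste0("  ", format(keys), " : ", vals, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a plain-text key-value (YAML) configuration and merges it over the
#' package defaults. Unknown keys are an error, so typos cannot silently fall
#' back to defaults. An empty file yields the full default configuration.
#'
#' @param path file path.
#' @param type `"pipeline"` for [pipeline_config()] or `"sim"` for
#'   [sim_config()].
#' @return A `pipeline_config` or `sim_config` object.
#' @export
load_config <- function(path, type = c("pipeline", "sim")) {
  type <- match.arg(type)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must be a key-value mapping")
  ctor <- if (type == "pipeline") pipeline_config else sim_config
  known <- names(formals(ctor))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(ctor, vals)
}
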