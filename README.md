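# herdtrack

Individual-animal behavior monitoring for barn-housed cattle from
fixed-camera detector output: action-label stabilization by sliding-window
majority voting, tracking-by-detection with motion + appearance association
and long-gap re-identification, per-identity and herd-level behavior
statistics, and CLEAR-MOT/IDF1/HOTA tracking evaluation — plus a seeded
synthetic barn-scene generator so the whole pipeline is testable without
video data or trained networks.

The package is aimed at precision-livestock-farming pipelines where an
object detector (e.g. a YOLO-family model) already emits per-frame boxes
with per-action class scores, objectness and an appearance embedding, and
what remains is turning those detections into stable identities and
behavior time series.

## Method in brief

**Action majority voting.** Each detection's label is decided over an
N-frame window (N = 4): the reference box is chained backwards by maximal
IoU (> 0.5) through the N−1 preceding frames, and the vote score of class
*j* is

    S_roi(j) = (1/N) * sum_n cls_n(j) * obj_n

with absent frames contributing zero; the refined label is argmax_j S_roi.

**Tracking.** Per identity, a constant-velocity Kalman filter over
(u, v, a, h) — box center, aspect ratio (width/height), height — and their
rates. Tracks and detections are matched by the gated combined cost

    D = λ·Dm + (1 − λ)·Dc,   λ = 0.1

with Dm the gate-normalized squared Mahalanobis distance and Dc the cosine
distance to the track's appearance gallery, solved by Hungarian assignment
in a recency-ordered cascade. Lifecycle: tracks confirm after 3 consecutive
hits, become *lost* after 7 consecutive misses (thereafter matchable by
appearance only), and are deleted 5000 frames (~5.5 min at 15 fps) after
their last match — so an animal occluded for minutes resumes its identity
when it reappears. Detections are pre-filtered at confidence 0.6, NMS IoU
0.75, at most 21 targets (the herd size); group-action detections
(fighting, social licking, feeding) raise alerts instead of being tracked.

**Analytics.** An append-only behavior database (frame, id, action, center)
feeds per-identity action counts, binned herd statistics (modal action per
identity per bin), trajectories and path lengths; part actions
(ruminating, tail wagging, moving head) are attributed to the individual
whose box contains ≥ 80% of the part box.

**Evaluation.** MOTA/MOTP (CLEAR, IoU 0.5 with carryover matching), IDF1
(optimal global trajectory mapping), HOTA (19-threshold average of
√(DetA·AssA)) and identity counts, against MOT Challenge text files.

## Worked example

```r
library(herdtrack)

scene <- simulate_barn(sim_config(n_agents = 8, duration = 300, seed = 42))
scene
#> <barn_scene> 8 agents, 300 frames, 2382 detections

res <- track_stream(scene$detections, pipeline_config())
summary(res)
#> Tracking run: 9 identities, 300 frames
#> Behavior record counts by action:
#>      standing       resting self-grooming       walking   standing up
#>          1298           474           224            63            30
#> Group-action alerts: 0

evaluate_tracking(scene$gt_tracks, as_trackset(res))
#> <mot_eval> HOTA 83.02  MOTA 87.00  MOTP 93.89  IDF1 92.98  IDSW 1  IDs 9

action_counts(res$db, 1)
#>       resting self-grooming      standing   standing up
#>             1            91           178             1

path_length(trajectories(res$db)[["1"]])
#> [1] 802.6
```

Reading the output: the noisy 300-frame scene of 8 animals is tracked with
9 identities ever created (one spurious tentative track) and a single
identity switch; HOTA/MOTA/IDF1 in the low-to-mid 80s/90s are typical for
the default noise level. Identity 1 spent 178 frames (11.9 s at 15 fps)
standing and 91 frames self-grooming, and travelled ~800 px. A zero-noise
scene (`sim_config(noise = "none")`) is recovered perfectly: all metrics
100, one identity per animal, behavior counts equal to ground truth.

The per-frame API (`tracker_init()` / `tracker_step()`), the report writers
(`write_behavior_reports()`), MOT file I/O (`read_mot()` / `write_mot()`)
and the detection JSON I/O are documented in the help pages. A thin command
line wrapper with `simulate` / `track` / `evaluate` / `report` subcommands
is installed at `inst/cli/herdtrack.R`.

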