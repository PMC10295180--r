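---
title: "Methods: action voting, tracking and evaluation in herdtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: action voting, tracking and evaluation in herdtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtrack)
```

## The problem

Continuous welfare monitoring of housed cattle needs three things from a
fixed overhead camera: *what* each animal is doing, *which* animal it is,
and how both change over hours and days. `herdtrack` implements the
post-detector half of such a system. It assumes an external object detector
has already produced, for every video frame, a set of candidate boxes with
per-action class scores, an objectness score and a fixed-length appearance
embedding. Everything downstream of the detector — label stabilization,
identity tracking, re-identification, behavior statistics and tracking
evaluation — is implemented here, together with a synthetic barn-scene
generator so the whole pipeline can be exercised and validated without any
video data or trained networks.

The action vocabulary is an eleven-label taxonomy in three categories:
five *individual* (whole-body) actions — standing, walking, resting,
standing up, self-grooming — that are the labels carried through tracking;
three *part* actions — moving head, ruminating, tail wagging — detected as
their own small boxes and attributed to an individual afterwards; and three
*group* actions — social licking, fighting, feeding — which are surfaced as
alerts only and never enter the tracker.

## Action majority voting

Per-frame action classification flickers: a resting cow is periodically
called standing for a frame or two. Before tracking, each detection's label
is therefore decided by a sliding window of $N$ frames (default $N = 4$).
The current detection is chained backwards: in each of the $N-1$ preceding
frames, the detection with maximal IoU to the reference box joins the chain
provided that IoU exceeds `vote_iou` (default 0.5, matching the usual
detector NMS threshold). The vote score of class $j$ is

$$S_{\mathrm{roi}}(j) = \frac{1}{N} \sum_{n=1}^{N} \mathrm{cls}_n(j)\,\mathrm{obj}_n,$$

the window mean of class score times objectness, with absent frames
contributing zero, and the refined label is $\arg\max_j S_{\mathrm{roi}}(j)$.
Design choices the formula leaves open, resolved here:

* **Score combination.** The per-frame contribution is the *product* of
  class score and objectness — the standard detector-confidence
  combination, consistent with using the same product as the tracking
  confidence threshold.
* **Absent frames.** The denominator stays $N$, so a box that flickers in
  and out accumulates less support than a stably detected one. This is
  deliberate: flicker is exactly the evidence of an unreliable label.
* **Ties.** Exact ties go to the current detection's own argmax when it is
  among the tied classes, else to taxonomy order. Ties have measure zero
  under continuous scores; the rule only matters for degenerate inputs.
* **Warm-up.** Frames $1..N-1$ pass through with raw argmax labels; labels
  are not revised retrospectively.

Voting trades a small label lag for stability: after an action transition
the window majority can keep the old label for up to $N-1$ frames. At 15
fps and $N = 4$ this is at most 200 ms, negligible for behavior budgets but
relevant when an exact frame-level comparison is wanted (see the validation
section).

## Motion model

Each identity carries a constant-velocity Kalman filter over the state
$(u, v, a, h, \dot u, \dot v, \dot a, \dot h)$: box center (px), aspect
ratio (width/height — the convention used throughout), height (px) and
their per-frame rates. Observation is linear, reading the first four
components. The time step is one frame; the frame rate only matters when
converting statistics to seconds.

Noise scales with box height so that near (large) animals tolerate
proportionally larger innovations: measurement standard deviations
$(\sigma_p h, \sigma_p h, 0.1, \sigma_p h)$ and process standard deviations
$(\sigma_p h, \sigma_p h, 10^{-2}, \sigma_p h, \sigma_v h, \sigma_v h,
10^{-5}, \sigma_v h)$ with defaults $\sigma_p = 1/20$, $\sigma_v = 1/160$,
both configurable. These are the conventional scales for height-normalized
box tracking; no claim is made that they match any particular tuned
deployment. The gating distance between a predicted state and a candidate
box is the squared Mahalanobis distance under the projected innovation
covariance, computed by Cholesky solves (no explicit inverse).

## Association

Tracks and detections are matched by the combined cost

$$D = \lambda D_m + (1 - \lambda) D_c, \qquad \lambda = 0.1,$$

where $D_c$ is the cosine distance between the detection embedding and the
*closest* member of the track's appearance gallery (a ring buffer of the
100 most recent embeddings), and $D_m$ is the squared Mahalanobis distance
squashed to $[0,1]$ by $d \mapsto \min(d / g, 1)$ with $g$ the 0.95
chi-square quantile at 4 degrees of freedom ($g = 9.4877$). The squashing
is needed because the two distances live on different scales; dividing by
the gate makes the mixture bounded and commensurable. Pairs are infeasible
when the Mahalanobis distance exceeds $g$ or the cosine distance exceeds
`cosine_gate` (default 0.2). Assignment is solved optimally by an in-package
Hungarian algorithm (shortest augmenting path, $O(n^3)$), not greedily; the
test suite checks it against exhaustive permutation enumeration.

## Track lifecycle

Per frame, the tracker:

1. Kalman-predicts every live track.
2. Runs a matching cascade over *confirmed* tracks in ascending
   time-since-update order, with the gated combined cost — so recently seen
   tracks get first claim on detections and long-occluded tracks cannot
   hijack them.
3. Matches the remaining detections by IoU cost (ceiling 0.7) against
   tentative tracks and confirmed tracks that just went unmatched.
4. Offers the still-unmatched detections to *lost* tracks on appearance
   alone (gallery cosine distance within the gate). On success the Kalman
   state is re-initialized at the new box: after a gap of hundreds of
   frames the extrapolated velocity is meaningless.
5. Updates matched tracks, spawns tentative tracks from unmatched
   detections, and applies the lifecycle rules: tentative tracks confirm
   after 3 consecutive hits and die on any miss; confirmed tracks become
   lost after 7 consecutive misses; lost tracks are deleted 5000 frames
   (about 5.5 minutes at 15 fps) after their last match.

The two patience constants deserve a comment, because they interact: 7 is
the *short* patience after which motion extrapolation is no longer trusted
and the track drops out of motion-based matching; 5000 is the *long*
patience governing how long an identity is kept alive for appearance-based
re-identification before being forgotten. Reading them as two stages of the
same lifecycle is the only interpretation under which both are meaningful,
and it is what makes minutes-long occlusions recoverable.

Incoming detections are first filtered: confidence (objectness × best
class score) at least 0.6, non-maximum suppression at IoU 0.75, at most 21
individual-action detections kept (the herd size — an upper bound on how
many targets can be real). Group-action detections become alerts; part
actions are set aside for attribution.

Frame results include tentative tracks, not only confirmed ones. This is a
deliberate departure from the usual convention of emitting confirmed tracks
only: with confirmation after 3 hits, the first two frames of every real
identity would otherwise be reported as missing, and behavior records would
systematically undercount by two frames per identity. The `status` column
lets callers filter to confirmed tracks if they prefer the conservative
view.

## Behavior analytics

All statistics derive from the behavior database: one record
`(frame, id, action, u, v)` per tracked individual per frame.
`action_counts()` gives per-identity frame counts (seconds = frames / fps);
`herd_stats()` bins the timeline and, per bin, assigns each observed
identity its *modal* label in the bin, reporting head counts or fractions
per action; `trajectories()` and `path_length()` work from the box centers.
Part actions are attributed to the track whose box contains at least 80% of
the part box's area, and are stored *alongside* the concurrent whole-body
action (a cow is resting *and* ruminating), never instead of it. Distances
are in pixels; with the pen being 30 × 12 m under a 3840 × 2160 view, a
uniform scale is roughly 8 mm/px, but no camera calibration is assumed, so
metric conversion is left to the caller.

## Evaluation metrics

`evaluate_tracking()` compares a predicted track set against ground truth
in MOT Challenge form:

* **CLEAR (MOTA/MOTP)** with IoU threshold 0.5 and carryover matching: a
  ground-truth identity that still overlaps its previous frame's predicted
  partner keeps it before the Hungarian step fills in the rest.
  $\mathrm{MOTA} = 100\,(1 - (\mathrm{FN}+\mathrm{FP}+\mathrm{IDSW})/\mathrm{GT})$;
  MOTP is reported as 100 × mean IoU over matches (higher is better).
* **IDF1** from the globally optimal one-to-one trajectory mapping
  maximizing identity true positives.
* **HOTA** as the mean over 19 localization thresholds
  $\alpha \in \{0.05, \dots, 0.95\}$ of
  $\sqrt{\mathrm{DetA}(\alpha)\cdot\mathrm{AssA}(\alpha)}$, with per-frame
  maximum-cardinality matching at each threshold; no localization-accuracy
  multiplier variant.
* **IDs**: the number of distinct predicted identities, reported alongside
  switch counts — with a fixed herd, identity churn is the most
  interpretable failure signal.

The test suite validates all three families against brute-force oracles
(exhaustive permutation assignment; exhaustive trajectory-mapping search)
on randomized small scenes.

## The synthetic barn scene

The generator emulates the statistical structure of fixed-camera barn
footage, not its appearance: around 21 agents (3 calves at 0.6 scale) in a
30 × 12 m pen viewed at 3840 × 2160 px and 15 fps. Behavior is a
semi-Markov chain over the five individual actions with geometric dwell
times (defaults: resting 40 s, standing 10 s, walking 6 s, standing up 2 s,
self-grooming 5 s at 15 fps) and a transition structure in which resting is
left via standing up and walking is entered from standing. True cattle
dwell distributions are not published for this setting; these defaults are
placeholders with the right orders of magnitude and are fully configurable.
Only walking moves (0.8 m/s); a soft repulsion keeps agents at least 1.5 m
apart in the ground plane, as real cows' bodies do. Box height grows toward
the near edge of the frame as a perspective proxy, producing the scale
variation a raised camera sees. A real camera model would add nothing to
what the tracker is exercised on.

Occlusion has two mechanisms: per-frame drops when two boxes overlap
(IoU > 0.3, drop probability 0.5 for the farther agent), producing short
flicker, and *hidden episodes* (geometric, mean 10 s) during which an agent
produces no detections at all while its ground truth continues — the
long-gap case that track age and appearance re-identification exist for.
Detection noise comprises box jitter (σ = 2% of height), class confusion
(10%), missed detections (5%), uniform clutter false positives (0.2 per
frame with low objectness, so the 0.6 confidence filter removes nearly
all — mirroring a detector's real precision behavior), and embedding noise.

Embedding noise is parameterized by the *expected norm* `sigma_e` of the
Gaussian perturbation added to the agent's mean unit vector (per-component
sd $\sigma_e/\sqrt{d}$). At $\sigma_e = 0.1$ the within-identity cosine
distance is about $\sigma_e^2/2 = 0.005$ while between-identity distances
are near 1, so identity information is cleanly present and tests isolate
tracker logic rather than fighting an impossible appearance space. A
per-component reading of the same number would put the perturbation norm
above 1 and within-identity distances at 0.3–0.5 — inconsistent with any
sensible appearance gate.

The generator is fully deterministic given its seed and restores the
caller's RNG state.

## What the validation does and does not show

The package's property checks are run at desk scale, with sizes chosen to
keep the full suite within a few minutes:

* Assignment vs exhaustive enumeration on 1000 random matrices up to 5×5;
  CLEAR/IDF1 vs brute-force re-computation on 50 random scenes and HOTA on
  10, each within 0.1 percentage points.
* Zero-noise recovery: a 5-agent, 500-frame noiseless scene is recovered
  perfectly — 5 identities, 0 switches, MOTA = MOTP = IDF1 = HOTA = 100,
  and behavior counts equal to ground truth frame-for-frame. Agents hold
  constant actions in this scene: under voting, an action transition
  carries an intrinsic ≤ N−1-frame label lag, so frame-exact label equality
  is only a meaningful target with transitions excluded; the lag itself is
  exercised by the voting tests.
* Re-identification: across a 100-frame occlusion gap (shorter than the
  track age) the same identity resumes in ≥ 95% of 100 seeded scenes; with
  the age set below the gap a fresh identity is issued in all of them.
* Parameter direction: on a 3-minute noisy benchmark scene, voting plus
  age 5000 creates strictly fewer identities than no voting plus age 100.
  The benchmark is 3 minutes long because that is the timescale the long
  age exists for; shorter scenes can contain no occlusion episode long
  enough for the compared ages to differ.
* Voting benefit: under 30% class confusion, windowed voting lifts label
  accuracy from ~71% (per-frame argmax) to ~99% over 1000+ windows.

Passing these says the machinery is correct and the parameter effects point
the right way *under the simulator's assumptions*. It does not certify
performance on real footage: real detectors have structured (not
independent) failures, real appearance embeddings drift with pose and
lighting, cows move in coordinated ways no semi-Markov chain captures, and
real occlusion correlates with crowding. Numbers from any real deployment
depend on the trained detector and embedding network, which are outside
this package.

## Numerical notes and degenerate inputs

Covariances are re-symmetrized after every filter step and factorized by
Cholesky; a singular innovation covariance is reported as an error rather
than patched. Infeasible assignment entries use a large finite surrogate
internally (1e9) so the Hungarian potentials stay finite; any forced
infeasible match is demoted to unmatched afterwards. Empty frames, empty
streams, empty galleries and zero-length track sets all have defined
behavior (tested); ground-truth-free evaluation is an error since every
metric divides by the ground-truth count. Aspect ratio and height are
clamped positive when a predicted state is used to build a box for IoU.
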