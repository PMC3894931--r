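---
title: "A hybrid force/agent-based model of consensus decision making in walking crowds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid force/agent-based model of consensus decision making in walking crowds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A group of people stands at the centre of a circular arena whose perimeter
carries sixteen numbered cards. A small minority is told "go to number X,
without leaving the group"; everyone else is told only "stay with the
group". Nobody may talk or gesture. Groups in this situation reliably reach
the periphery, and informed minorities steer them — but running such
experiments with, say, 200 people is logistically hard. `crowdconsensus`
simulates these experiments: small groups of ten with four informed-position
treatments, large groups of 200 with varying informed percentages, and
walking-speed sweeps that expose a speed–accuracy trade-off.

## The model

Agents live in continuous 2-D coordinates at a scale of 1 px = 0.05 m and
are updated synchronously at 60 frames per second. Every behaviour rule is a
parameterisation of one core kernel,

$$
\mathbf{B} \;=\; E_s\,F_a\,F_t\,F_d\;
R(\alpha)\,\widehat{(\mathbf{p}_t-\mathbf{p}_a)},
$$

a unit vector from the agent towards a (possibly virtual) target, rotated by
$\alpha$ and scaled. $E_s = s/(u\,r)$ converts the agent's walking speed $s$
(m/s) into pixels per frame given the unit scale $u$ (m/px) and frame rate
$r$; all the influence coefficients $F$ are 1 in these experiments, so every
single behaviour effect has magnitude $E_s$ — a full step. The effects an
agent selects in a frame are summed as Euclidean vectors and applied as its
displacement; its heading becomes the direction it actually moved.

The four rules:

* **Seek to** ($\alpha = 0$, $F_d = 1$): straight towards the assigned
  number card.
* **Wandering**: a full step along the agent's own direction, which turns by
  an angle drawn uniformly from $[-\theta, +\theta]$ with probability 5%
  per frame ($\theta = 0.5$ rad). Between turns the walker goes straight;
  each turn re-anchors to the direction the agent actually moved last frame
  (see *Design choices*).
* **Keep in group**: the sum of a unit cohesion vector (towards the mean
  position of the group members within the 5 m group range) and a unit
  alignment vector (the group's mean heading), re-normalised and scaled by
  $E_s$, so the magnitude law survives the combination.
* **Crowd repulsion** (passive, always on): for every other agent closer
  than 0.7 m (an arm's length, 14 px), a contribution $E_s\,g(d)$ pointing
  away, with the linear ramp $g(d) = (14-d)/14$ on $(0,14)$ and exactly 0 at
  or beyond the threshold.

Behaviour selection per agent and frame: an agent is *in the group* if it
belongs to the largest cluster formed by arm's-length contacts. Informed
and in the group: seek. Informed and out: keep-in-group (the instruction
subordinates the target to "without leaving the group"; a `"blend"` policy
that does both is available). Uninformed and in the group: wander.
Uninformed and out: keep-in-group. Uninformed selections never reference
any target — there is no information exchange.

A run terminates when the group centroid's radius reaches the outer circle;
the number reached is the card nearest the crossing point (exact ties break
to the lower index). Runs that have not arrived after 300 s of simulated
time are timeouts: they count as inaccurate and are excluded from time
statistics.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| base speed | 0.4 m/s | normal walking in a dense group; per-agent jitter ±10%, drawn once |
| unit scale | 0.05 m/px | 10 m arena = 200 px diameter |
| frame rate | 60 fps | update interval 1/60 s |
| arm's length | 0.7 m (14 px) | repulsion onset and group-membership contact distance |
| group range | 5 m (100 px) | neighbourhood of the keep-in-group rule |
| $\theta$, turn prob. | 0.5 rad, 5%/frame | wandering smoothness |
| arrival band | 1 m (20 px) | per-agent "arrived" flag at termination |
| max time | 300 s | timeout |

The arenas: the small arena is a 10 m circle with letters A–H equally
spaced on a 2 m inner circle and I, J at the centre (placed 0.7 m apart at
(±7, 0) px so two agents can share "the centre" at exactly arm's length).
The large arena fixes the 12 m inner circle in which all 200 agents start
and takes a configurable outer diameter, 30 m by default — the original
description does not state it, and results depend on it only through the
travel distance.

Treatments place the two small-group informed agents at J&E (core +
periphery), C&D (adjacent peripheral pair), B&F (opposite peripheral pair)
or I&J (two cores). Large-group treatments sample an informed subset at
2.5–15% and give every informed agent the same randomly drawn target.

## Design choices made where the design was open

**Wandering base direction.** "Turn by a random angle with 5% probability
per interval" leaves open what the turn applies to. We examined three
readings: (a) re-anchor to the realised heading every frame, (b) a fully
persistent wander heading, and (c) straight lines between turns with each
turn re-anchoring to the realised heading. Reading (a) couples wanderers so
tightly to the group that collective accuracy becomes independent of
walking speed; reading (b) makes the uninformed walk as independent random
walkers, and ten-agent groups then crawl with implausibly long arrival
tails. Reading (c) — the default — keeps the noise injection per unit time
(which produces the speed–accuracy trade-off) while letting the group's
motion entrain the wanderers at each turn, and is the reading most
consistent with "a virtual target in the front of the agent's current
direction". All three remain selectable (`default_params(wander_base=)`).

**Group membership.** "Stay within an arm's length of another individual"
could be judged against the nearest neighbour or against the group. The
nearest-neighbour reading lets two wanderers drift away together while each
satisfies the constraint through the other — the group can fission, which
the instruction plainly forbids. The default therefore tests membership of
the largest arm's-length-connected component; the nearest-neighbour reading
remains available (`group_status = "nearest"`).

**Termination.** "The group reached the periphery" is operationalised as
the centroid crossing the outer circle. An alternative `"number_capture"`
policy ends the run only when the centroid comes within 0.5 m of a card;
it sharpens small-arena scoring but behaves poorly in the large arena,
where cards sit 5.9 m apart and a 200-agent centroid can wander the rim
without committing, so the centroid policy is the default.

**Placement separation.** 200 agents cannot be placed in the 12 m inner
circle with a full arm's-length spacing (that packing is beyond the jamming
density of random sequential placement), so large-arena placement enforces
a 0.35 m (body-width) minimum separation and lets repulsion relax the pack
in the first frames.

**Degenerate directions.** Whenever a direction is undefined — an agent
exactly on its target, coincident agents, a cancelling
cohesion/alignment pair — the rule substitutes a uniformly random unit
vector from the run's seeded stream: symmetry is broken reproducibly and
no input can produce NaN.

## What the generator emulates, and what it does not

Initial conditions reproduce the experimental protocol: agents on the
lettered marks (small) or uniformly in the inner circle (large), each
facing a uniformly chosen number, each with a personal speed drawn once
from ±10% of the base speed. The simulation does not model the things the
original experimenters also could not control or chose to ignore: bodies
with extent and contact forces, visual occlusion, the time a human needs
to find and align with a number card, fatigue, or any communication.
Consequently, passing tests show that the *collective mechanisms* —
minority steering, cohesion-mediated consensus, noise-driven inaccuracy —
behave as in the field data; they do not certify agreement run-for-run
with human crowds.

Two known quantitative departures from the published field/simulation
values, visible in the acceptance checks: treatments with both informed
agents on the inner-circle rim (C&D adjacent vs B&F opposite) are
statistically tied here rather than clearly ordered, and large fast groups
lose less accuracy than reported — averaging over 200 agents suppresses
wander noise at the centroid more strongly than in the reference
implementation. Small-group runs also carry a few-percent tail of slow
(> 60 s) arrivals.

## Numerical choices

Synchronous (parallel) update; headings renormalised from realised
displacements each frame; distances compared against thresholds with
`<` for the repulsion support (where $g$ is 0 at the threshold anyway) and
`<=` for group contact, so I and J start exactly in contact. Termination
ties break deterministically to the lower card index. The batch engine is
compiled (Rcpp) and consumes R's RNG stream in a documented per-agent
order; `sim_step()` is a pure-R reference implementation, and a test pins
the two to identical trajectories under the same seed. Per-run seeds are
derived from the batch seed and the (treatment, target, replicate, speed)
labels with an integer hash below $2^{31}$, so any single run can be
reproduced in isolation.

## Problem sizes used by the tests and the acceptance script

The packaged checks run the full small-group design (100 replicates per
target, 1600 runs per treatment) for the ordering and coverage checks, a
25-replicate-per-target speed sweep over 0.3–1.25 m/s, a 3 × 3 large-group
grid (informed 5/10/15% × 0.4/0.8/1.2 m/s) at 30 replicates per cell, and
30 logged large-group runs for the leadership diagnostic; the acceptance
script uses 25 replicates per target (small) and 30 replicates (large).
These sizes put Monte-Carlo standard errors on accuracies at roughly 1–2.5
percentage points, adequate for the comparisons made.

## Limitations

The model inherits every ambiguity listed above; where a choice mattered we
exposed it as a parameter rather than hard-coding it. Accuracy magnitudes
are sensitive to the wandering reading and the termination policy at the
±10-percentage-point level. The large-arena outer diameter is a free
parameter of the reproduction, not of the original design. None of the
inferential statistics of the human experiments are reimplemented — the
package reports descriptive summaries only.
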