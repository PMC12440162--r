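---
title: "Methods: movement influence, trophallaxis and sociability in tracked bee colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement influence, trophallaxis and sociability in tracked bee colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflow)
```

## The problem

Automated tracking of barcoded honey bees produces per-frame positions and
orientations for every individual in an observation hive, recorded at 1
image per second. From these detections, together with a trophallaxis
(food-sharing) event detector, an entrance monitor, laboratory assays and
genotype data, one can ask how sociable an individual bee is, whether its
movement influences that of its nestmates, what behavioral task it
specializes in, and how these phenotypes relate to genetic variation.

`beeflow` implements that analysis chain as composable, tested stages:

1. **kinematics** — instantaneous linear and angular speeds with a
   stationarity filter;
2. **trophallaxis** — merging and duration-filtering of raw food-sharing
   detections into events, and per-bee event frequency (the sociability
   proxy);
3. **proximity** — extraction of proximal-interaction windows between bee
   pairs;
4. **influence** — directed movement-influence estimation via vector
   autoregressive (VAR) models and information partial directed coherence
   (iPDC), integrated into information flow in bits;
5. **behavior states** — rule-based classification into forager, guard,
   nurse, generalist, non-responder or baseline;
6. **association** — polygenic scores, hypergeometric gene-list overlap,
   and standard group statistics;
7. a **synthetic colony generator** that produces all of these inputs with
   known ground truth.

## Kinematics and the stationarity rule

For a bee detected at consecutive frames $t$ and $t+1$, linear speed is the
Euclidean displacement of the barcode center divided by the inter-frame
interval $1/f_s$, and angular speed is the unsigned angle between the two
orientation vectors, wrapped to $[0^\circ, 180^\circ]$, divided by the same
interval. ("Divided by the image rate" is implemented as division by the
interval, since a speed must carry units of distance per time; at
$f_s = 1$ the two readings coincide.) No measurement is produced for frame
$t+1$ if the bee was undetected at $t$, and a pair in which the bee moved
less than one honeycomb-cell width (4.9 mm) **and** turned less than the
angle between adjacent cell corners (60°) is marked unrecorded — such
sub-threshold jitter is what a stationary bee produces while grooming or
inspecting cells. When either threshold is exceeded, both speeds are
recorded, keeping the linear and angular sample sets aligned. Pairs
separated by a detection gap yield no record at all: gaps are never
interpolated.

Mean speeds average the recorded measurements inside an analysis window; a
bee with no recorded measurement gets an absent value, never zero.

## Trophallaxis events and sociability

Raw detector intervals for the same unordered pair are merged transitively
whenever the gap between them is under 60 s, then filtered to durations
between 3 s (shorter contacts may involve no liquid transfer) and 180 s
(longer detections are spurious). Durations use the inclusive frame span,
so a single-frame event at 1 frame/s lasts 1 s, and both bounds are
inclusive: an event of exactly 3 s is kept. The per-bee sociability score
is the number of filtered events credited to the bee (both partners count)
divided by the window length in days; events straddling the window edge
are assigned by their start frame, an unambiguous single-count rule. The
per-day normalization (rather than per detected time) is one reading of an
ambiguity in the source analysis; it is the one implemented here. The
identity $\sum_b \mathrm{freq}_b \times \mathrm{days} = 2\times$ (events
in window) is re-verified at run time by the pipeline.

## Proximal interactions

Movement influence is only meaningful when two bees are close enough to
perceive each other. A proximal interaction between a focal bee and a
neighbor is a maximal run of contiguous frames in which (i) both are
detected, (ii) their distance is at most $R_{max} = 20$ mm (about twice a
body length), (iii) neither bee is in a low-speed frame, and (iv) the pair
is not inside one of its own filtered trophallaxis events (third-party
trophallaxis does not exclude). Runs of at least $L_{min} = 30$ frames
qualify — enough samples to fit a VAR — and are kept whole rather than
truncated. Excluded frames break contiguity, because the VAR estimator
assumes uniformly sampled series without gaps. "Low speed" is
operationalized as a frame whose incoming kinematic pair was unrecorded
under the 4.9 mm / 60° rule, reusing the pipeline's own stationarity
definition instead of inventing a second threshold; the exclusion applies
when *either* bee is slow. Only the earliest qualifying interaction per
(focal, neighbor) pair is retained, so repeated encounters with the same
partner do not dominate a bee's average. Every bee serves as focal, so one
physical encounter contributes once to each partner's own average.

## VAR models, iPDC and information flow

Within an interaction, the focal and neighbor coordinates along one axis
form a bivariate series $y_t$. We fit
$y_t = \sum_{m=1}^{p} A_m y_{t-m} + w_t$ by conditional least squares on
the mean-removed series, with the innovation covariance $\Sigma_w$
estimated from residuals with denominator $n_{used} - kp$. The order is
selected by AIC over $p \in \{1, 2, 3\}$, all candidates scored on a
common effective sample; the cap of 3 keeps the parameter count (12) well
below a 30-sample window. Constant (zero-variance) series are rejected
with an error naming the offending interaction.

With $\bar A(f) = I - \sum_m A_m e^{-i 2\pi f m / f_s}$ and $\bar a_j$ its
$j$-th column, the squared information PDC for direction $j \to i$ is

$$\mathrm{iPDC}_{j\to i}(f) \;=\;
\frac{|\bar A_{ij}(f)|^2}
     {[\Sigma_w]_{ii} \; \bar a_j(f)^{\mathsf H} \Sigma_w^{-1} \bar a_j(f)}.$$

This is the information-PDC normalization of the mutual-information-rate
framework for frequency-domain connectivity: it reduces to the generalized
PDC when $\Sigma_w$ is diagonal (a property verified in the tests), and it
is bounded in $[0, 1]$ for any positive-definite $\Sigma_w$ by the
Cauchy–Schwarz inequality in the $\Sigma_w^{-1}$ inner product. An
alternative normalization that weights the numerator by
$[\Sigma_w^{-1}]_{ii}$ instead of $1/[\Sigma_w]_{ii}$ agrees on diagonal
covariances but can exceed 1 when innovations are strongly correlated,
which would make the information-flow integral undefined; it is therefore
not used. Classic PDC (column-norm normalization) and generalized PDC are
available behind a `variant` switch for comparison.

Information flow integrates the spectrum into a scalar in bits:

$$I_{flow} = -\frac{1}{f_s}\int_0^{f_s/2} \log_2\!\big(1 -
\mathrm{iPDC}(f)\big)\, df,$$

computed by the trapezoidal rule on a uniform 128-point grid over
$[0, f_s/2]$. Spectra from different interactions share the grid, so
pointwise averaging is well defined. Values are clipped to $1 - 10^{-12}$
before the logarithm as a floating-point guard; doubling the grid changes
the result by less than $10^{-3}$ bits (verified in the tests). Closed
forms anchor the integral: a constant spectrum of 0.5 at $f_s = 1$ gives
exactly 0.5 bits, and a zero spectrum gives exactly 0.

Per focal bee the estimator follows a fixed averaging order: fit a VAR and
compute both directional spectra per interaction and per axis; average
spectra pointwise across interactions within each axis; integrate the
averaged spectra; then average the X and Y results into a single
$I_{flow}$ per direction. Series are mean-centered but not differenced
(the analysis runs on raw coordinates); a differencing option exists for
stationarity-sensitive users.

## Behavioral states

A bee is a **forager** when its entrance-trip record shows at least 6
trips in total, at least 2 distinct days with 4 or more trips ("more than
three trips per day, for any 2 days"), and at least 25% of all its trips
starting during peak foraging hours (10:00–15:00). The 25% denominator is
the bee's full trip total, and the 2 days need not be consecutive.

Dish assays measure aggression (summed biting + stinging duration against
an intruder) and care (summed larval feeding + inspection duration). With
the qualifying threshold $T = 20$ s — the permissive end of the source
criterion's "20–30 s", exposed as a configuration value — the label rules
are, in order: **generalist** if two or more of {aggression ≥ T, care ≥ T,
forager} hold; otherwise the single qualifying behavior names the
specialist (**guard**, **nurse**, **forager**); a bee with zero response
to both stimuli, no other recorded behaviors and no foraging is a
**non-responder**; everything else — sub-threshold responsiveness or
fanning/wax-building/vibration only — is **baseline**. The six labels are
exhaustive and mutually exclusive, and adding a qualifying behavior can
only move a bee toward generalist, never between specialists.

## Association statistics

The polygenic score of a bee is the inner product of its
alternative-allele dosages (0/1/2) with per-SNP effect sizes; the
alternative allele is the effect allele because the low-sociability
genotype in the motivating analysis was homozygous-alternative. Gene-list
overlap uses the upper-tail hypergeometric probability $P(X \ge k)$
(observed overlap included) with fold enrichment $k/(|A||B|/N)$, and a
Bonferroni factor capped at 1. Group comparisons go through one-way ANOVA
with Tukey HSD, a rank-sum test for two groups, and Spearman rank
correlation — standard methods, called from base R rather than
reimplemented.

## The synthetic colony generator

The generator produces every input the pipeline consumes, with ground
truth, under the recording conditions the analysis assumes: 1 frame/s,
hundreds to thousands of frames, millimeter coordinates with the origin at
the hive's upper-left corner and y increasing downward.

**Movement.** Each bee follows a stable AR(1) process on per-frame
velocity (default persistence $\phi = 0.6$, innovation 4 mm/frame per
axis) with weak mean-reversion toward a per-bee anchor point (cohesion
0.02/frame, anchors spread 30 mm around the hive center) — bees aggregate
on the comb rather than diffuse. For a coupled ordered pair the follower's
velocity at $t$ adds $c$ times the leader's displacement at $t-1$, making
the pair's positions exactly a bivariate VAR, which is what renders the
influence estimand identifiable and the recovery experiments meaningful.
Positions reflect at the hive walls; windows used for estimation rarely
touch them. The AR(1)-velocity choice is a stand-in for unknown bee
locomotion dynamics, not a claim about it.

**Stationary bouts and trophallaxis.** Bees enter stationary bouts (mean
30 s) in which per-frame displacement and turn stay below the 4.9 mm /
60° thresholds. Injected trophallaxis episodes (a Poisson process over
bee-hours) hold both partners still and within 7.4 mm — the detector's
pairing distance — so the exclusion rules can be exercised.

**Paired encounters.** Two bees can only satisfy "within 20 mm for 30
consecutive frames while each displaces at least 4.9 mm per frame" if
their movements are correlated: independent walkers fast enough to pass
the stationarity filter cross a 20 mm neighborhood in a few seconds. The
generator therefore schedules explicit encounter bouts (default 3 per
bee-hour, 45–90 s long) during which two bees walk a tight orbit around a
common drifting center, each displacing 5.5–8 mm per frame — emulating
natural following and antennation bouts, which are exactly the periods the
proximity stage is designed to capture. Orbit phase and turning direction
are randomized per encounter, so displacement series of uncoupled pairs
remain uncorrelated on average; this is verified by a direct lag-1
cross-correlation test at 10,000 frames.

**Detection dropout** is independent per frame at 2% (a high-performing
barcode tracker); every generator is deterministic given its seed, with
the caller's RNG state restored afterwards.

**Behavioral inputs.** Trip logs give designated foragers patterns that
satisfy all three forager clauses, and give every other bee a pattern
violating exactly one clause, cycling through the four violation modes so
each clause is exercised. Assay tables satisfy each target label's rule by
construction, including boundary cases. Genotypes are Binomial(2, MAF)
dosages with MAF uniform on a configurable range; the ground-truth
polygenic score is computed by an explicit double loop, independent of the
package's matrix-product implementation.

**What the generator does not emulate:** barcode image decoding and its
structured error modes, body-outline geometry (distances are between
barcode centers), comb structure and task-dependent spatial zones,
diurnal rhythms, and any genotype–behavior coupling unless the caller
builds one in. Passing tests on synthetic colonies therefore validate the
*rules and estimators*, not claims about real colonies.

## Validation experiments and problem sizes

Three seeded experiments back the acceptance checks, sized to run on a
single CPU in well under the time a desk check should take:

- **Spectrum oracle equivalence** — 20 random stable bivariate VAR(2)
  models; a model fitted to 10,000 simulated samples must reproduce the
  spectrum of the true coefficients to within 0.05 everywhere.
- **Null symmetry** — 1,000 uncoupled pairs, 30-frame windows (the
  pipeline's minimum interaction length): the two directional flow means
  must agree within 0.005 bits. Each individual 30-sample estimate
  carries positive finite-sample bias, but the bias is symmetric; 1,000
  replicates put the Monte Carlo standard error of the measured
  difference (~0.0017 bits) well inside the bound.
- **Directional recovery** — couplings $c \in \{0, 0.2, 0.4, 0.6\}$, 100
  replicates each on 60-frame interactions (a typical encounter length):
  mean leader→follower flow must be non-decreasing in $c$, and must
  exceed the reverse direction in at least 80% of replicates at
  $c = 0.6$.

The packaged end-to-end fixture is a 20-bee, 2-simulated-hour colony with
three coupled pairs, run through every stage; reruns are byte-identical.

## Numerical choices and known limitations

- Ties in rank statistics use midranks (base R behavior).
- The VAR estimator requires $n_{used} > kp$ strictly and rejects
  constant channels rather than regularizing them.
- Automatic order selection compares candidates on a common sample (the
  last $n - p_{max}$ observations) and refits the winner on its full
  conditional sample.
- Interactions that fail to fit (for example, a bee pinned against a wall
  producing a degenerate axis) are skipped with a per-bee failure count;
  a bee whose interactions all fail gets an absent result and a warning,
  not a zero.
- Confidence intervals and significance tests for PDC, multichannel
  (>2) conditioning, and time-varying VAR are out of scope.
- On real data the absolute $I_{flow}$ scale depends on the VAR order
  policy and estimator settings; comparisons should hold those fixed, as
  the pipeline configuration does.
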