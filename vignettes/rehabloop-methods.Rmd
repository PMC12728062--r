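---
title: "Models and methods behind rehabloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rehabloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabloop)
```

`rehabloop` simulates and analyses sensor-driven assistance-as-needed (AAN)
hand rehabilitation. This vignette documents the models, the parameters
that matter, the numerical choices, and the design decisions the package
made where several defensible options existed. Everything quantitative
shown here is computed by the package's own functions and tests; the
vignette states no empirical result the test suite does not reproduce.

## The processing chain

A training session is a perception-assessment-assistance loop running on a
200 ms cycle:

1. **Sensing.** Surface EMG (nominally 1 kHz, up to 16 channels) and a
   wrist/hand IMU (100 Hz, 3-axis gyroscope in deg/s plus accelerometer in
   m/s^2) during reach-grasp-release trials logged by a VR task engine.
2. **Preprocessing.** EMG: 4th-order 20-450 Hz Butterworth bandpass, a
   2nd-order IIR notch at the mains frequency, rectification and a 2nd-order
   low-pass giving the activation envelope e(t). IMU: gyro integration (or
   extended Kalman filter fusion with the accelerometer gravity direction)
   to a joint angle; Hampel/MAD outlier cleaning; cross-correlation lag
   compensation; resampling to a common 100 Hz timeline; Teager-Kaiser
   onset detection; segmentation into trials tiled by 200 ms windows with
   50% overlap.
3. **Features.** Kinematic (ROM and ROM normalized by the individually
   calibrated baseline, velocity statistics, SPARC, log dimensionless jerk,
   4-12 Hz tremor power ratio, path efficiency), EMG time and frequency
   domain (RMS, MAV, WL, ZC, SSC, IEMG; Welch-based MNF/MDF and their
   temporal slope), cross-modal (co-contraction index, electromechanical
   delay, mutual information between envelope and speed) and task level
   (Fitts index of difficulty and throughput, success rate, completion-time
   dispersion).
4. **Scoring.** Per task label (FMA-UE proxy, ARAT proxy, ROMn, SPARC by
   default) a random forest and an RBF support vector regressor are fitted;
   a linear ridge meta-learner fuses their out-of-fold predictions with
   context. Standardized fused predictions map through a monotone
   linear-sigmoid into the composite score `S_t` in (0, 1), exponentially
   smoothed into `S~_t`; uncertainty combines between-tree variance with an
   EMA of recent residuals; a per-session bias term adapts online.
5. **Control.** The dual-channel AAN law steps assistance
   `u <- clip(u + k_u (S* - S~))` and difficulty
   `d <- clip(d + |k_d| (S~ - S*))`, each with a dead zone (0.05), a rate
   limit (0.02 per cycle), a hysteresis direction latch ([0.65, 0.85]) and
   the safety overrides (protection below 0.4, gain degradation above
   uncertainty 0.15, pause on sustained physiological disengagement).

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| EMG band | 20-450 | Hz | 4th-order Butterworth |
| Notch | 50, Q = 30 | Hz | 60 Hz selectable |
| Envelope low-pass | 5, order 2 | Hz | typical clinical range 3-10 |
| Window / overlap | 200 / 50% | ms | tiles each 5-30 s trial |
| Quality threshold tau | 0.9 | - | windows below get weight Q/tau |
| Target score S* | 0.75 | - | target band 0.7-0.8 |
| Gains k_u, k_d | 0.05, 0.08 | per cycle | |
| Rate limit r_max | 0.02 | per cycle | both channels |
| Dead zone | 0.05 | score units | |
| Hysteresis band | [0.65, 0.85] | score units | direction latch |
| theta_safe / sigma_thresh | 0.4 / 0.15 | - | safety overrides |
| RF | 200 trees, depth 8, leaf 5 | - | |
| SVR | RBF, gamma 0.01, C 10, eps 0.1 | - | |
| Ridge lambda | 0.5 | - | meta-learner |
| Huber delta | 1.0 | standardized residuals | |
| Smoothing lambda | 0.3 | - | |
| Bias learn rate eta | 0.1 | - | |

With the default constants the raw assistance step can never exceed the
rate limit while the score is above the protection floor:
`k_u * max|S* - S~| = 0.05 * 0.35 = 0.0175 < 0.02` — asserted as a
regression test on the constant set.

## The virtual patient

No public recordings accompany this problem, so the synthetic-data module
is a first-class, tested component. A `virtual_patient` has latent
capability `c` in [0, 1], an individual baseline range of motion, a 4-12 Hz
tremor amplitude, an antagonist co-contraction coupling, performance noise,
and a per-session learning rate.

* **Kinematics** are minimum-jerk point-to-point reach profiles (the
  standard model consistent with the smoothness metrics), with excursion
  `c x ROM_base`. The synthesized gyro channel is the trapezoid-consistent
  discrete derivative of the ground-truth angle, so cumulative trapezoidal
  integration recovers the angle to machine precision in the noise-free
  case — a deliberate construction that makes the integration contract
  exactly testable.
* **sEMG** is Gaussian noise band-limited to 20-450 Hz, amplitude-modulated
  by a raised-cosine activation envelope per trial; the antagonist channel
  receives the agonist envelope scaled by the co-contraction parameter;
  mains interference is optional.
* **Performance** follows
  `S = clip(sigmoid(b0 + b1 c + b2 u - b3 d) + eps, 0, 1)` with defaults
  `b = (-1.0, 2.0, 1.0, 1.2)` and `eps ~ N(0, noise_sd)`. The intercept was
  chosen so that a mid-to-high-capability patient has an *interior*
  assistance fixed point at the target score: with a more negative
  intercept the target is unreachable for almost all (c, u, d), the
  difficulty channel collapses, and between-session learning stalls — the
  closed loop then cannot exhibit the longitudinal pattern it exists to
  study. All four coefficients are arguments.
* **Trial success** is `S >= 0.5` for that trial; the success *rate* is
  then an emergent property of the loop rather than a dial.
* **Between-session learning** uses a zone-of-proximal-development kernel:
  `c' = clip(c + learn_rate * exp(-(d_bar - c)^2 / (2 w^2)) * (1 - u_bar/2))`
  — learning is fastest when mean session difficulty matches capability and
  is damped by heavy assistance. The kernel width defaults to `w = 0.35`;
  a markedly narrower kernel freezes learning whenever the controller
  parks difficulty far from capability (which the hysteresis latch makes
  common early in a course), a regime we verified by simulation before
  fixing the default.

**Reference study conditions.** Course-level analyses use
`improving_patient()` (capability 0.25, noise 0.15, learning rate 0.08 per
session) over 20 sessions of 300 cycles (one minute of 200 ms cycles; one
trial per 20 cycles, i.e. 15 trials/session), starting from assistance
0.62 and difficulty 0.35. These sizes keep a full 20-seed Monte-Carlo
course study under a minute of CPU while leaving every trend test
statistically comfortable; they are the package's chosen simulation scale,
not a claim about clinical session length.

What the generator does *not* emulate: motor-unit physiology, muscle
synergies, fatigue-dependent spectral compression, sensor dropout bursts,
or nonstationary tremor. Tests passing on this generator therefore
demonstrate the correctness and qualitative behaviour of the pipeline, not
clinical performance on real patients.

## Scoring model choices

* Base learners use their native criteria; the weighted Huber objective
  (delta = 1 on standardized residuals, task weights 0.4/0.3/0.2/0.1)
  is minimized by the ridge meta-learner via iteratively reweighted least
  squares, and serves as the model-selection objective. Stacking uses
  out-of-fold predictions from a grouped 5-fold split to avoid optimism;
  a leakage assertion fails loudly if any subject straddles a fold
  boundary.
* Isotonic calibration uses pool-adjacent-violators (`stats::isoreg`);
  Platt scaling fits the two-parameter sigmoid by least squares.
* The uncertainty rule `sigma_t = sqrt(0.5 Var_trees + 0.5 EMA(r^2))`
  works as an extrapolation flag when the regression surface is steep near
  the training boundary; it is *not* a general out-of-distribution
  detector (between-tree variance can shrink far outside the hull where
  every tree answers from the same edge leaf). The tests exercise the
  regime where the property holds and the limitation is stated here.
* Intent recognition is a linear SVM decision function `f(x) = w'x + b`
  with the boundary tie-break conservatively assigned to rest.

## Controller semantics

The mechanisms compose in a fixed order: dead zone, uncertainty gain
scaling, rate limit, bounds, hysteresis gate. The hysteresis latch stores
the last movement direction per channel; a reversal is only armed when the
smoothed score leaves the [0.65, 0.85] band on the appropriate side. In
protection mode assistance ramps to its maximum at the rate limit (an
instantaneous jump would violate the rate-limit invariant, which holds for
*every* reachable transition including mode switches) and difficulty is
frozen. Override precedence is protect > paused > degraded gain.

The difficulty channel implements the stated behaviour — difficulty rises
when performance exceeds the target — which corresponds to a positive
effective gain; the sign convention is exposed (`k_d_sign`) so the literal
inverse-gain form can be reproduced.

Difficulty is a scalar in [0, 1] mapped linearly onto the VR task
geometry: target diameter 15 to 5 cm, speed 0.1 to 0.5 m/s, reach distance
20 to 50 cm, so the Fitts index of difficulty is strictly increasing in d.

## Closed-loop simulation

`run_session()` supports two score sources. The *oracle* source draws S_t
directly from the virtual patient's response model; controller-dynamics
properties (settling into the target band within 200 cycles, trend
directions over a course, null behaviour at zero learning rate) use it,
because they test the controller and patient dynamics, not the
regressors. The *pipeline* source synthesizes raw signals per trial, runs
the full preprocessing/feature/scoring chain per 200 ms window, and is
exercised end to end in the suite with a fitted model bundle.

## Proxy labels and evaluation

Window-level clinical labels do not exist, so the package constructs
proxies: linear interpolation of the FMA-UE anchors across sessions (80%
of windows), biomechanical anchoring
`clip(FMA_s (1 + 0.05 z_bar), 0, 66)` from within-session feature
z-scores (15%), and simulated expert ordinal ratings on a 0-10 analog
scale with rater noise (5%) — the blend operates by data share, not value
averaging, because proportions of *data* are what the labelling protocol
fixes. The expert source is synthetic and labelled as such.

The statistics toolbox (paired t with the Hedges small-sample correction
computed from the pooled pre/post SD, ICC(2,1) from the two-way ANOVA
mean squares, quadratic weighted kappa, Bonferroni adjustment, grouped
k-fold and leave-one-subject-out harnesses) is hand-written against
brute-force oracles because no installed package provides these exact
estimators; standard primitives (t distribution quantiles, `isoreg`,
`prcomp`, `ccf`) come from base R.

## Numerical choices and degenerate inputs

* SPARC: spectrum zero-padded (pad level 4), normalized by its DC value,
  cutoff 20 Hz with adaptive 0.05 amplitude threshold. LDLJ uses the
  negative log of the duration- and amplitude-normalized squared-jerk
  integral so that *lower is worse*, consistent with SPARC and with the
  jitter-monotonicity property both metrics must satisfy.
* Welch PSD: 128-sample Hamming segments, 50% overlap.
* Mutual information: 16-bin equal-width plug-in histogram; constant
  inputs return 0 with a warning.
* All-zero spectral windows, zero-variance features and 0/0 co-contraction
  are masked (NA) rather than propagated; masks reduce fitting weights.
* Gaps above 10% of a segment flag it low-quality (Q below tau) but never
  drop it silently.
* Accelerometer-only position uses double integration with high-pass
  drift removal at each stage (a single integral of acceleration is a
  velocity, not a position).
* Determinism: every stochastic routine consumes the R RNG stream, so a
  fixed seed reproduces streams, courses, fitted bundles and closed-loop
  traces bit-identically.

## Known limitations

* The virtual patient is a behavioural, not physiological, model; effect
  magnitudes in simulated courses are patient-model-dependent and only
  trend *directions* are claimed.
* The EKF assumes the accelerometer measures gravity orientation plus
  noise; sustained linear acceleration biases the correction.
* The uncertainty estimate degrades to a constant far outside the training
  hull (see above).
* Online-mode filtering is causal and therefore phase-delayed; offline
  zero-phase filtering is the default everywhere latency is irrelevant.
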