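---
title: "The flexgait model: layered neuromuscular control of walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flexgait model: layered neuromuscular control of walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flexgait simulates human walking with a controller organized in layers:
spinal reflex circuits stabilize the stance leg, while the swing leg
executes voluntary, goal-directed movements planned at the task level and
transformed into descending motor commands by internal models.  This
vignette documents the model equations, the numerical choices, the free
parameters, and the design decisions taken where the architecture left
room, together with the limitations a user should know about.

## Body model

The skeleton is a seven-segment biped (trunk with lumped head and arms,
two thighs, shanks and feet) of 1.80 m and 80 kg with 14 generalized
coordinates: three trunk translations, yaw/pitch/roll of the trunk, and
per leg hip pitch, hip roll, knee and ankle.  The six trunk DoFs are
un-actuated.  The equation of motion

$$\tau = M(\theta)\,\ddot\theta + C(\theta, \dot\theta) + G(\theta) + T_{ext}$$

is evaluated by a recursive Newton-Euler sweep over the kinematic tree;
the mass matrix is assembled from unit-acceleration sweeps of the same
recursion, which makes forward and inverse dynamics consistent to machine
precision (the round-trip identity is a package test).  Segment masses
(53.5 / 8.5 / 3.5 / 1.25 kg) and lengths (0.46 m thigh and shank) follow
standard anthropometric tables for this stature; any table consistent
with the total mass and height would do.

Ground contact uses four points per foot — two at the heel 5 cm apart,
two at the forefoot 10 cm apart — with a compliant normal force
$f_z = k_n\,\delta\,(1 + c_n\,\dot\delta)$ and regularized Coulomb
friction bounded by $\mu f_z$.  The surface parameters
($k_n = 6\times10^4$ N/m per point, $c_n = 3$ s/m, $\mu = 0.9$,
regularization velocity 0.05 m/s) emulate a hard surface: static standing
penetrates about 1.6 mm, well below 5 mm.  They are chosen values, not
reproduced ones; nothing in the reference architecture prescribes them.
Soft spring-damper torques (300 N m/rad) engage beyond the joint range of
motion.

The integrator is fixed-step semi-implicit Euler at $dt = 10^{-4}$ s
(muscle-tendon dynamics are stiff), with the control layer running every
10 plant steps (1 kHz).  Fixed-step integration makes every simulation
bit-for-bit reproducible for identical inputs; the passive skeleton
conserves energy to better than 0.1% over 5 s at this step size.

## Muscle-tendon units

Each leg is actuated by eleven Hill-type MTUs: hip flexors (HFL), glutei
(GLU), hamstrings (HAM), rectus femoris (RF), vasti (VAS), biceps femoris
short head (BFSH), gastrocnemius (GAS), soleus (SOL) and tibialis
anterior (TA) on the pitch joints, and hip abductors (HAB) and adductors
(HAD) on the roll joint.  HAM, RF and GAS are biarticular.  The
contractile element produces

$$F_{ce} = A\,F_{max}\,f_l(l_{ce})\,f_v(v_{ce}),$$

with a bell-shaped force-length curve
$f_l = \exp(\ln 0.05\,|x|^3)$, $x = (l_{ce}-l_{opt})/(w\,l_{opt})$, a
Hill hyperbola for shortening and a saturating hyperbola
$f_v = N - (N-1)/(1 + 7.56\,K\,v/v_{max})$ for lengthening
($N = 1.5$, $K = 5$).  The eccentric branch was chosen pole-free and
monotone with the same endpoints and asymptote as the classic
formulation, so that the inverse relation needed by the controller is
single-valued everywhere.  Activation follows first-order dynamics
$\dot A = (S - A)/\tau_A$ with $\tau_A = 10$ ms.

The series elastic element (tendon) has quadratic force-strain with 4%
reference strain at $F_{max}$; the CE length is a state and its velocity
is found each step by inverting $f_v$ in the CE-SE force balance.  The
parallel element engages half a force-length width beyond the optimal
length and the buffer element below $l_{opt}(1-w)$, so both stay silent
over the normal operating range — a deliberate choice, because the
controller's inverse muscle model neglects them.

Moment arms are constant or cosine-saturating functions of the spanned
joint angle, and the MTU length is the exact integral of the arm, so the
virtual-work identity $\partial l_{mtu}/\partial\theta_j = -C_{jm}$ holds
analytically (checked numerically in the tests).  Muscle parameters
($F_{max}$, $l_{opt}$, slack lengths, arms) are adopted defaults in the
tradition of reflex-based walking models, scaled so each CE stays inside
its force-length operating range over the joint range of motion.  The
GAS knee arm is set to 1.5 cm (anatomically at the small end): larger
values couple knee motion into the ankle strongly enough to visibly
degrade ankle tracking.

## Spinal layer

During swing, every muscle is driven by a generic stretch reflex

$$S = \left[K_l(\hat l_{ce} + u) + K_v(\hat v_{ce} + \dot u) - h\right]^+ ,$$

clamped to $[S_{min}, 1]$ with a baseline tone $S_{min} = 0.01$ (the
rectification alone would allow exactly zero, which leaves tendons slack
and muscles unresponsive).  $\hat l_{ce}, \hat v_{ce}$ are spindle
signals with pathway-dependent transport delays: 10 ms for hip, 15 ms
for knee and 25 ms for ankle muscles; joint-state estimates use the same
segment-wise delays, and the balance pathway a 100 ms long-loop delay.
These delays are stated symbolically in the source architecture; the
values here are physiologically motivated choices and configurable.

During stance the stretch reflex is not used; the leg is controlled by
five functional modules: (1) positive force feedback on VAS, SOL and GAS
producing compliant, spring-like leg behavior (the loop force grows until
leg geometry saturates it), (2) knee-overextension prevention (VAS
suppression plus rate-gated BFSH recruitment), (3) a trunk-upright PD on
the delayed trunk pitch and roll, distributed over GLU/HAM/HFL
(sagittal) and HAB/HAD (frontal) and weighted by the leg's share of the
vertical ground reaction force, (4) compensation of the interaction
torque exerted by the contralateral swing leg's planned hip torque, and
(5) ankle dorsiflexion via TA length feedback suppressed by SOL force,
which yields ground clearance early in stance and allows push-off late.

## Behavioral organization

A finite state machine cycles each leg through stance, early swing and
late swing.  Early swing starts when ground contact of the contralateral
leg is detected; the early-to-late transition is a fixed 0.3 s timer;
late swing ends at ipsilateral contact.  Two implementation details
matter in practice.  First, a heel-strike must be a *fresh* contact: the
swing foot has to unload below the 50 N contact threshold before a new
touch-down counts, otherwise the trailing foot's residual load at the
early/late transition is mistaken for an instant heel-strike.  Second,
"detection of ground contact" of the contralateral leg is read as a
loading response: the trailing leg begins its swing only once the
freshly landed leg carries more than 250 N.  This produces the
double-support weight-transfer period that every walking gait has;
triggering on first touch makes the trailing leg flex against nearly
full body weight and stumble.

## Movement planning and balance

The swing-leg goal is a joint configuration with a target time.  For
each joint the plan is the unique minimum-jerk quintic satisfying
position/velocity/acceleration boundary conditions at both ends,
recomputed every control step from the current state estimate over the
remaining time; the commanded acceleration is the integrated jerk of
this replanned trajectory (equivalently the new plan evaluated one
control step ahead).  Below 0.03 s of remaining time the plan is frozen,
and past its end time the command holds the goal configuration rather
than extrapolating the polynomial — the quintic diverges cubically
outside its domain, so extrapolation while waiting for a delayed
heel-strike would corrupt the command chain.  Commanded accelerations
are capped at 400 rad/s² for the same reason: as the remaining time
shrinks, the quintic demands accelerations growing as $1/T^2$ for any
residual error, which no muscle could realize.  The boundary
acceleration of each replan is the previous commanded (capped)
acceleration; differentiating the delayed velocity estimates instead
injects filter lag into the loop and destabilizes it.

During walking the late-swing hip targets come from the foot-placement
balance law

$$\tilde\phi_{thigh} = \phi_0 + c_d\,\hat d + c_v\,\hat v, \qquad
  \tilde\theta_{hip} = \tilde\phi_{thigh} - \hat\phi_{trunk},$$

applied independently in the sagittal and frontal plane, with $\hat d$
the delayed horizontal displacement from the center of pressure to the
trunk center and $\hat v$ its filtered rate.  Early-swing targets are
volitional (part of the tuned parameter set) and are the hook for
obstacle avoidance, which retargets them linearly in the obstacle
extension, $\tilde\theta_i = \alpha_i h_o + c_i$, with hand-fitted
slopes and a 3 cm security margin.  Goals are clamped to the joint range
of motion.

## Descending motor commands

Executing the plan means realizing its joint accelerations.  The chain
is: (i) zero-pad the four swing accelerations into the 14-DoF vector and
evaluate inverse dynamics at the delayed state estimates — deliberately
without ground contact — and extract the swing-leg torque block;
(ii) distribute the torques over the eleven swing-leg muscles with the
Moore-Penrose pseudo-inverse of the moment-arm block, iterated seven
times: each pass discards the non-physical negative forces and
re-distributes the torque they would have produced, leaving a per-joint
residual below 3 N for stepping torques at a fraction of the cost of
exact non-negative least squares (which the tests keep as an oracle);
(iii) invert the contractile force law,
$\tilde S = \tilde F / (F_{max} f_l f_v)$, at the current estimates,
with the denominator floored at 0.05 so muscles near their force limits
do not request unbounded stimulation; and (iv) invert the stretch
reflex, $u = (\tilde S + h)/K_l - l_{ce}$, to obtain the threshold-shift
command.

The CE length in step (iv) is the *planned* CE length — the reference
point of the intended contracted state, computed from the desired-state
trajectory via the muscle geometry with the tendon at slack (consistent
with the inverse muscle model's neglect of the SE).  This is the one
place where the architecture genuinely underdetermines the
implementation, and the choice matters: if u is recomputed from the
*measured* CE length, the reflex length term cancels identically and the
loop has no postural stiffness — antagonist baseline tone then drags
the light foot segment away faster than the integrated-jerk correction
can recover.  Encoding the planned length makes the reflex a length
servo around the motor plan, which is the threshold-control reading of a
descending command that "shifts the reference point to the contracted
state".  The desired-state trajectory advances along its own
minimum-jerk plan toward the goal (never reset from measurements during
a movement) and is evaluated 40 ms ahead as a mild lead compensation for
the sensory delays; on-plan, command and measurement coincide and the
reflex reproduces $\tilde S$ exactly (a package test, to machine
precision).  The command rate $\dot u$ is a first-order-smoothed
difference across control steps (5 ms time constant); it carries the
planned CE velocity, so the $K_v$ term acts as relative damping around
the plan.

The reflex gains are parameterized per muscle group: $K_l$ as a
dimensionless scale on the inverse operating length ($K_l = k_l/(w\,
l_{opt})$) and $K_v$ as a damping time scale on $K_l$.  The shipped
values ($k_l = 0.8$ for most groups, 1.6 for TA; $k_v = 0.02$, with
0.04-0.05 for the knee-spanning and roll groups) are the stability
optimum under the stated delays: higher length gains oscillate against
the 15-25 ms distal delays, lower ones track poorly.

## Parameters and tuning

55 parameters are free: the six balance-law gains, seven swing-goal
angles and the two plan times, fifteen stance-module gains, and 27
reflex gains (K_l, K_v, h for nine muscle groups, legs symmetric).
They are tuned by a self-contained CMA-ES (rank-mu update, cumulative
step-size adaptation, box repair with quadratic penalty; validated on a
10-D sphere to 1e-8 within 5000 evaluations) minimizing the two-stage
walking cost

$$J = \begin{cases} 2c_0 - x_{fall} & \text{falling} \\
                    c_0 + d_{steady} & \text{otherwise}, \end{cases}
  \qquad c_0 = 10^3,$$

where $x_{fall}$ is the forward trunk position at fall detection (trunk
center below 60% of standing height) and the steadiness measure
$d_{steady}$ sums, over the last three left heel-strikes, the changes in
the Cartesian positions of the four limb points (knees and ankles)
relative to the trunk between successive heel-strikes.  The summands are
Euclidean norms per limb — a signed vector sum could cancel — and
$d_{steady}$ is capped at $c_0$ so falling candidates always score
strictly worse than walking ones.  Walks that end before three strides
count as maximally unsteady.  Cost evaluations use 9-12 s simulations;
the shipped parameter set is the best point of the package's own
optimization runs, verified over 30 s.

## Simulation experiments and their scales

The swing-leg experiments fix the trunk in space and run in seconds:
the center-out sequence (12 workspace targets with returns, 0.5 s per
segment, straight-line path lengths 0.2-0.55 m, targets defined as ankle
positions and converted to joint space by damped-least-squares inverse
kinematics), the 1 Hz four-joint oscillation for 10 s (implemented as
rest-to-rest half-cycle movements between two stepping-range
configurations, which is what "goal-directed movements between two
points" means operationally here), and randomized reaches over 15-85% of
each joint's range of motion (configurations that slacken any CE below
0.4 optimal lengths are redrawn) at movement times from 0.1 to 1 s.  The
reported NRMSE normalizes by each joint's range of motion; the Cartesian
ankle-path NRMSE normalizes by the diagonal of the planned path's
bounding box.  The full protocol of 1100 movements is supported but the
default replicate count is 10 per movement time, which reproduces the
same error-versus-time profile in about a minute of CPU time; the
methods and defaults were fixed at that scale.

Walking, perturbation staircases (force pulses at the trunk from 50 N in
50 N steps, refined in 5 N steps), obstacle runs and the trunk-lean
speed sweep use the full model; a 30 s walk takes on the order of a
minute of CPU time.

Muscles start tension-free (CE at the slack-adjusted length, activation
at tone level); the first movement of every swing experiment therefore
shows the largest transient, and each protocol begins with a short
settle hold.  Walking launches from quiet stance with a small forward
lean and push (0.06 rad, 0.35 m/s) and pre-activated muscles
(activation 0.3, decaying within tens of milliseconds) so the
force-feedback stance modules bootstrap before the first step.

## Known limitations

* Endpoint precision of the center-out reaches is limited to the
  centimeter scale by the finite reflex-servo stiffness against
  unmodeled antagonist tone; sub-millimeter terminal accuracy would
  require either integral action or much higher length gains than the
  delays allow.
* The ankle remains the hardest joint by a factor of 2-4 in every
  tracking experiment (small inertia, strong antagonist tone from the
  large plantarflexors, biarticular coupling) — the expected ordering
  for this architecture.
* The trunk has no internal rotation DoF at the hips; heading changes
  work only through stance-foot slip and are slow and imprecise by
  construction.
* Balance relies solely on foot placement; there is no push-off
  modulation or ankle-roll mechanism, so lateral robustness is bounded
  by what step placement can capture within one step.
* The Euler-angle trunk parameterization is singular at pitch 90
  degrees, far outside walking but reached in some falls; simulations
  stop at fall detection before this matters.
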