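# flexgait

Neuromuscular simulation of human walking that combines spinal reflex
control of the stance leg with voluntary, goal-directed movements of the
swing leg.

Most neuromechanical walking models generate their rhythmic pattern
entirely from low-level structures — reflex circuits or neural
oscillators — and therefore cannot *plan*: they cannot move the foot
along a specific path, step over an obstacle of a given height, or reach
with the leg to an arbitrary target. flexgait implements a layered
architecture that bridges this gap. A supraspinal layer represents
movement goals as swing-leg joint configurations, plans minimum-jerk
trajectories toward them, updates the plans in real time from sensory
feedback (for balance, via foot placement, and for tasks such as
obstacle avoidance), and transforms the planned accelerations into
descending motor commands using internal models of the biomechanics, the
muscles and the spinal stretch reflex. The spinal layer executes these
commands through a generic stretch reflex per muscle during swing and
controls the stance leg with five dedicated reflex modules. The plant is
a 14-DoF, seven-segment biped (1.80 m, 80 kg) actuated by 22 Hill-type
muscle-tendon units with physiological sensor delays and compliant
ground contact.

## The model in brief

* **Skeleton** — `tau = M(theta) theta_dd + C(theta, theta_d) + G(theta)
  + T_ext` over 14 generalized coordinates (6 free-body trunk DoFs + hip
  pitch/roll, knee, ankle per leg), recursive Newton-Euler dynamics,
  fixed-step integration at 0.1 ms.
* **Muscles** — `F_ce = A Fmax f_l(l_ce) f_v(v_ce)` with series,
  parallel and buffer elastic elements; activation is a 10 ms low-pass
  of the stimulation; joint torques via state-dependent moment arms,
  `tau = C F`.
* **Swing-leg reflex** — `S = [K_l(l_ce + u) + K_v(v_ce + u_dot) - h]+`;
  the descending command `u` shifts the reflex threshold to the planned
  contracted state.
* **Planning** — per-joint quintic (minimum-jerk) trajectories,
  replanned every millisecond from the current state estimate, frozen in
  the last 30 ms of a movement.
* **Descending transformation** — planned accelerations → inverse
  dynamics (zero-padded to the full model, contact-free) → non-negative
  muscle-force distribution by a 7-pass pseudo-inverse iteration →
  inverse muscle model `S = F/(Fmax f_l f_v)` → reflex inversion
  `u = (S + h)/K_l - l_ce`.
* **Balance** — foot placement from the delayed CoP-to-trunk
  displacement: `phi_thigh = phi0 + c_d d + c_v v`, per plane.
* **Stance leg** — five spinal modules: compliant-leg positive force
  feedback, knee-overextension prevention, load-weighted trunk-upright
  PD, swing-interaction compensation, and TA-driven ankle dorsiflexion.
* **Tuning** — 55 free controller parameters optimized by a built-in
  CMA-ES against the two-stage cost `J = 2000 - x_fall` (falling) /
  `J = 1000 + d_steady` (walking).

## Worked example

Trunk-fixed goal-directed reaching: swing the left leg from a hanging
posture to a flexed configuration and back, then inspect tracking.

```r
library(flexgait)
model <- fg_model()   # body + muscles + tuned controller parameters

goals <- rbind(c(0.6, 0.1, 1.0, 0.2, 0.5),   # hip, hip-roll, knee, ankle [rad], duration [s]
               c(0.3, 0.0, 0.3, 0.0, 0.5))
sw <- simulate_swing(model, goals, leg = "left",
                     q0_leg = c(0.3, 0, 0.3, 0), settle = 0.5)
sw
#> flexgait swing-leg simulation
#>   leg: left, 2 movement segment(s), 1.50 s simulated
#>   joint RMSE vs plan (rad): hip 0.0260, roll 0.0032, knee 0.0511, ankle 0.0751
```

The RMSE values compare the realized joint trajectories with the
minimum-jerk plans; dividing by each joint's range of motion gives the
normalized errors reported by the experiment runners. The full
experiment protocols are one call each:

```r
run_sinusoid(model)$nrmse        # 1 Hz four-joint tracking, 10 s
#>    hip   roll   knee  ankle
#> 0.0220 0.0222 0.0395 0.0530
run_center_out(model)$nrmse_ankle_path   # 12 center-out reaches + returns
#> [1] 0.0301
run_walk(model, duration = 30)$speed     # steady walking, m/s
```

The sinusoid errors are normalized to each joint's range of motion; the
ankle is the hardest joint, as expected for this architecture (small
inertia, strong plantarflexor tone, biarticular coupling). Walking,
perturbation staircases, obstacle avoidance, the trunk-lean speed sweep
and heading control are available through `run_walk()`,
`run_perturbations()`, `run_obstacle()`, `run_speed_sweep()` and
`run_direction()`; a command-line front end for all experiments is in
`inst/cli/flexgait.R`.

See `vignettes/flexgait-methods.Rmd` for the model equations, parameter
meanings, numerical choices and limitations.

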