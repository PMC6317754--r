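---
title: "An active-inference model of auditory hallucinations as false positive inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-inference model of auditory hallucinations as false positive inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avhsim)
```

## The model

`avhsim` simulates a synthetic subject holding a turn-taking conversation
with a scripted partner, formulated as a discrete-state partially observed
Markov decision process solved by active inference. The agent entertains two
binary hidden-state factors — *listening to a voice* (`voice` / `no_voice`)
and *speaking* (`speaking` / `not_speaking`) — observed through two
modalities: an auditory outcome (`sound` / `silence`) generated from the
listening factor, and a proprioceptive outcome (`speech_movement` / `none`)
generated from the speaking factor.

The generative model has the standard four components:

* **Likelihood `A`.** The proprioceptive mapping is the identity: the agent
  receives veridical evidence about whether it is moving its mouth. The
  auditory mapping is the column-normalized elementwise power
  $\bar{A} = \tfrac{1}{Z}(I_2 + \kappa)^{\zeta}$, where $\kappa$ is a small
  imprecision constant and $\zeta \ge 0$ the *likelihood precision*. Large
  $\zeta$ gives a near-identity (high-fidelity) mapping; $\zeta = 0$ gives a
  flat mapping in which outcomes carry no information about the listening
  state. While the agent is overtly speaking the auditory mapping is
  replaced by the uniform matrix — *sensory attenuation*, the down-weighting
  of self-generated sensation that protects the intention "I am speaking"
  from auditory counter-evidence.
* **Transitions `B`.** Actions are oppositional — one may listen or speak on
  each transition, not both. They are modelled as deterministic:
  choosing `speak` drives the speaking factor into `speaking` and (because
  taking one's turn silences the partner) the listening factor into
  `no_voice`; choosing `listen` drives the speaking factor into
  `not_speaking` and the listening factor into `voice`. The latter
  assignment is the crux of the model: *listening is the bundle of things
  one does when one expects to hear a voice*, so the agent's plan is itself
  a source of the empirical prior "a voice is there".
* **Preferences `C`.** Flat over outcomes (no outcome is rewarded), so
  policy value is purely epistemic.
* **Initial beliefs `D`.** Uniform over both factors.

Policies are fixed action sequences over the trial's `T - 1` transitions,
written compactly over `{L, S}` (e.g. `"SLSL"`). The policy being pursued is
itself a hidden variable to be inferred.

## Inference

Beliefs are updated by mean-field variational message passing. Under the
factorization $Q(\tilde{s}, \pi) = Q(\pi)\prod_\tau Q(s_\tau \mid \pi)$,
each per-policy, per-factor belief is the normalized exponential of the sum
of a likelihood message (observed steps only, attenuation-aware), a forward
transition message and a backward transition message; sweeps iterate to a
fixed point (cap 16 sweeps, tolerance $10^{-6}$ on the largest belief
change — ample for exact convergence in this four-state model; hitting the
cap logs a warning and returns the last iterate). Each policy is scored by

* its variational free energy
  $F(\pi) = E_Q[\ln Q(\tilde{s}\mid\pi) - \ln P(\tilde{o},\tilde{s}\mid\pi)]$
  over the observed steps (an upper bound on negative log evidence, tight at
  the exact posterior), and
* its expected free energy over future steps,
  $G(\pi) = \sum_\tau (\text{risk} + \text{ambiguity})$ per modality, with
  risk $o_{\pi\tau}\cdot(\ln o_{\pi\tau} - C)$ on predicted outcomes
  $o_{\pi\tau} = A s_{\pi\tau}$ and ambiguity $s_{\pi\tau} \cdot H$, $H_j$
  the entropy of likelihood column $j$.

The policy posterior is the precision-weighted softmax
$Q(\pi) = \sigma(-F(\pi) - \gamma\, G(\pi))$ with
$\gamma = e^{\texttt{gamma\_log}}$, restricted to policies consistent with
the actions already executed (inconsistent policies get exactly zero mass —
conditioning on behaviour). Marginal ("perceived") states are the Bayesian
model average $Q(s_\tau) = \sum_\pi Q(s_\tau\mid\pi) Q(\pi)$, and the next
action is the one carrying the larger posterior mass at the current
transition, with ties resolved deterministically in favour of `listen`.

Two published forms of the policy distribution differ on whether $\gamma$
multiplies $G$ inside the posterior; we adopt
$\sigma(-F - \gamma G)$ because only that form gives the policy-precision
parameter a pathway into state inference at all. Relatedly, the published
precision values $e^{\pm 64}$ swap the temperature/precision reading of
$\gamma$; the engine exposes `gamma_log` directly (presets `-4` / `+4` for
the low/high conditions, the extreme `±64` reachable via configuration).

## The environment

The generative process is deliberately separate from the generative model:
a script of alternating sounds and silences (default `"-x-x-"` over `T = 5`,
silences at steps 1, 3 and 5), plus the rule that speaking into a step
forces `sound` (one hears one's own voice) and a `speech_movement`
proprioceptive outcome, and triggers sensory attenuation for that step's
inference. The environment consults only executed actions, never beliefs.

A *hallucination* is scored at step $\tau$ when the marginal belief in
`voice` strictly exceeds a threshold while the true outcome is silence and
the agent did not speak into $\tau$; a *false negative* (speech-detection
error) is the mirror image at a true-sound step.

## Numerical choices

* **Floors.** Logarithms of exactly-zero entries (deterministic `B`, `D`,
  proprioceptive `A`) are floored at $e^{-16}$, the conventional choice for
  this family of models; the auditory likelihood is strictly positive for
  $\kappa > 0$ and its logs are computed analytically in log space, exact at
  any $\zeta$ (no underflow at $\zeta = 100$). Flooring the auditory
  likelihood itself would silently cap sensory log-evidence at 16 nats —
  exactly the strength of the floored transition prior — and erase the
  high-precision regime, which is why the floor is reserved for true zeros.
* **The imprecision constant $\kappa = e^{-30}$.** This default makes the
  three precision regimes work quantitatively. At a listened silent step the
  policy-derived prior carries $-\ln e^{-16} = 16$ nats of log-odds toward
  `voice`, while the silence observation carries
  $\zeta\ln\frac{1+\kappa}{\kappa} \approx 30\,\zeta$ nats toward
  `no_voice`. Hence $\zeta = 0.7$ (21 nats) → evidence wins, veridical
  perception; $\zeta = 0.525$ (15.75 nats) → near-balance, ambiguous
  beliefs; $\zeta = 0.3$ (9 nats) → the prior wins, a firm false percept.
  A larger constant (e.g. $e^{-3}$) caps evidence at $3\zeta \le 2.1$ nats
  and would make the agent hallucinate at *every* precision, so it is not
  the default, though it remains configurable.
* **Flag threshold 0.75.** The ambiguous regime produces beliefs around
  0.55–0.70 at silent steps — perceptual confusion, not frank
  hallucination, which lives near 1. A 0.5 threshold would conflate the
  two; 0.75 cleanly separates them and the flag is insensitive to the exact
  value between ~0.71 and ~0.99.
* **Determinism.** The pipeline contains no randomness; the only
  potentially arbitrary choice, an exact tie in action mass, resolves to
  `listen` by convention, so identical configurations always yield
  identical records.

## The experiments

`run_experiment()` reproduces three manipulations on the default
5-step script, with reconstructed policy catalogs (`policy_fixture()`;
the original catalogs are not published, so these are constrained
reconstructions):

1. `fig4_zeta_sweep` — fixture `F4` at $\zeta \in \{0.7, 0.525, 0.3\}$:
   the dose–response from veridical perception through perceptual confusion
   to firm hallucinations at the silent third and fifth steps.
2. `fig5_gamma` — fixture `F4` at $\zeta \in \{0.7, 0.525\}$ crossed with
   low/high policy precision.
3. `fig6_lesion` — the six-policy space `F6_full` versus `F6_lesioned`
   (the monologue-then-listen policy `SSLL` deleted) across the same
   $\zeta$ sweep.

```{r example}
ex <- run_experiment("fig4_zeta_sweep")
ex$summary[, c("condition", "hallucination_steps", "n_hallucinations")]
ex$records[["F4_zeta0.3_gamma0"]]
```

## Known limitations

The likelihood-precision mechanism reproduces in full. Two further effects
do **not** emerge under this reconstruction, and the package reports them
honestly rather than engineering them in:

* **Policy precision is inert.** With flat preferences and deterministic
  action-pinned transitions, every policy's predicted future states are
  one-hot, so each future step contributes
  $\log 2 - I(s;o)$ per modality with mutual information $I = 0$: the
  expected free energy is *identical across policies* up to floor-scale
  noise ($\sim 10^{-6}$ nats). $\gamma$ therefore cannot re-rank policies at
  any magnitude (verified up to $e^{\pm 64}$), and once behaviour masks the
  catalog down to a single consistent policy the marginal belief is
  $\gamma$-free altogether. The published $\gamma$-differential
  hallucination pattern must have relied on asymmetries (non-flat habits or
  preferences, or stochastic transitions) not recoverable from the
  published description.
* **The agent never speaks spontaneously.** For the same reason — no policy
  is epistemically better than another, and policies sharing the executed
  prefix carry identical evidence — action selection always falls to the
  listen-preferring tie-break. Effects that require self-generated speech
  (ceasing to hear one's own voice at low precision; the full-versus-
  lesioned policy-space contrast) are therefore out of reach of this
  reconstruction, and the corresponding acceptance checks are expected to
  fail.

The environment is a fixed script, not a second agent; there is no semantic
content, no learning of model parameters, and only two levels per factor.
Passing tests demonstrate the internal consistency of the inference scheme
(validated against exact enumeration on all horizons up to 3, where the
mean-field factorization is exact for this model class) and the precision
arithmetic above; they do not, of course, validate the model against human
perceptual data.

## Problem sizes

All simulations use the 5-step trial (4 transitions, at most 6 policies);
the oracle grid enumerates every state trajectory on horizons 2–3 across
$\zeta \in \{0, 0.3, 0.7, 5\}$ with attenuation on and off. The full test
suite and the acceptance script each run in a few seconds on one CPU.
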