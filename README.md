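# avhsim

Auditory verbal hallucinations — hearing a voice when none is there — can be
understood as *false positive inference*: prior beliefs dominating imprecise
sensory evidence. `avhsim` implements a discrete-state active-inference
(POMDP) agent engaged in a simulated turn-taking conversation and provides
the three computational manipulations under which such false percepts
emerge: reducing the sensory likelihood precision, raising the precision of
the prior over action policies, and lesioning the policy space. It is aimed
at computational-psychiatry researchers who want a small, fully inspectable
(and exhaustively validated) implementation of this class of model.

## The model in brief

The agent infers two binary hidden-state factors — *listening to a voice*
and *speaking* — from auditory and proprioceptive outcomes, under a
generative model with likelihood **A**, action-conditioned transitions
**B**, flat preferences **C** and uniform initial beliefs **D**. The
auditory likelihood is the column-normalized power
`(I + κ)^ζ`, with precision `ζ` controlling the fidelity of the
state→outcome mapping, and is replaced by a uniform matrix while the agent
speaks (sensory attenuation). Policies π (sequences of listen/speak
actions) are themselves inferred: per-policy beliefs are updated by
mean-field variational message passing; policies are scored by variational
free energy `F(π)` (evidence) and expected free energy `G(π)` (risk +
ambiguity); the policy posterior is `Q(π) = σ(−F − γG)` with policy
precision `γ`; and perceived states are the Bayesian model average
`Q(s_τ) = Σ_π Q(s_τ|π) Q(π)`. Because choosing to listen is, in this model,
the action of *expecting a voice*, beliefs about policies become empirical
priors over percepts — the seed of the hallucination when `ζ` is too low
for silence to correct them.

An exact-enumeration oracle (`exact_state_posterior()`,
`exact_policy_posterior()`) validates the variational engine on all small
horizons.

## Worked example

```r
library(avhsim)
ex <- run_experiment("fig4_zeta_sweep")
ex$summary[, c("condition", "hallucination_steps", "n_hallucinations")]
#>             condition hallucination_steps n_hallucinations
#> 1   F4_zeta0.7_gamma0                                    0
#> 2 F4_zeta0.525_gamma0                                    0
#> 3   F4_zeta0.3_gamma0                 3,5                2

ex$records[["F4_zeta0.3_gamma0"]]
#> <avh_trial> T = 5, zeta = 0.3, gamma_log = 0
#>   outcomes:   - x - x -
#>   actions:    L  L  L  L
#>   P(voice):   0.000 1.000 0.999 1.000 0.999
#>   hallucinations at: 3, 5
```

The partner alternates silence (`-`) and sound (`x`); the agent listens
throughout. At high precision (`ζ = 0.7`) its belief in a voice at the
silent third and fifth steps is ~0.007 — veridical perception. At
`ζ = 0.525` that belief rises to ~0.56: perceptual confusion, but no frank
hallucination. At `ζ = 0.3` the policy-derived prior ("I am listening, so a
voice is there") overwhelms the now-imprecise silence and the agent
believes, with probability 0.999, that it hears a voice at both silent
steps — the two flagged hallucinations. `run_trial()` runs single custom
conditions; `detect_hallucinations()` / `detect_false_negatives()` score
records; `plot_beliefs()` draws the belief raster (dark = confident).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/avhsim experiment fig4_zeta_sweep --outdir out
Rscript inst/cli/avhsim run --config my_config.yaml --outdir out --plot
Rscript inst/cli/avhsim validate
```

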