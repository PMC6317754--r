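Package: avhsim
Title: Active-Inference Simulation of Auditory Hallucinations as False
    Positive Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-state active-inference (Markov decision process)
    agent engaged in a simulated turn-taking conversation with a scripted
    partner. The agent infers two binary hidden-state factors (listening
    to a voice, speaking) from auditory and proprioceptive outcomes via
    variational message passing, selects listen/speak actions by expected
    free energy, and marginalizes state beliefs over policies by Bayesian
    model averaging. Tools to manipulate likelihood precision, policy
    precision and the policy space reproduce hallucination-like false
    positive inferences (confident belief in a voice during silence),
    with exact enumeration oracles for validating the variational scheme
    on small problems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
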