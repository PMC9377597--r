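# Shared fixtures built in code.

FB <- canonical_feedback_sequences()

# A deterministic reference run for fitting tests
ref_trajectory <- function(params = c(mu0 = 0.4, nu = 300, eta = 0.1, b = 1.2),
                           seed = 42L) {
  simulate_trajectory(3, params, FB$positive_first, seed = seed,
                      participant_id = "ref", feedback_order = "positive_first")
}

# A tiny hand-writable two-trial pseudo-run (bypasses the length-20 contract
# by building the pieces the likelihood needs directly)
toy_trajectory <- function(feedback = c(1L, 0L), reports = c(0.5, 0.6, 0.45)) {
  structure(list(participant_id = "toy", referent = "self",
                 framing = "top_half", feedback = feedback,
                 reports = reports, feedback_order = NA_character_),
            class = "belief_trajectory")
}
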