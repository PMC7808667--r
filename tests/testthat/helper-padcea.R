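# Shared fixtures, built in code.

# Two-state alive/dead chain with a constant per-cycle death probability.
two_state_matrix <- function(p_dead) {
  matrix(c(1 - p_dead, p_dead, 0, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("Alive", "Dead"), c("Alive", "Dead")))
}

# Identity transition over the full internal state space.
identity_matrix_8 <- function() {
  states <- pad_states()
  diag(8) |> `dimnames<-`(list(states, states))
}

# A deterministic calibrated parameter set (no jitter).
base_ps <- function(...) generate_calibrated_parameters(...)

# Minimal YAML configuration exercising the loader.
minimal_config_yaml <- function() {
  '
transitions:
  sc:
    matrix:
      Progressive: {Severe: 0.08, Dead: 0.01}
      Severe: {Dead_annual: 0.25, MinorAmputation: 0.05, MajorAmputation: 0.04}
      MinorAmputation: {RecoveredPostAmp: 0.15, Dead: 0.03}
      MajorAmputation: {RecoveredPostAmp: 0.10, Dead_annual: 0.35}
  flowox:
    relative_progression: 0.527
'
}
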