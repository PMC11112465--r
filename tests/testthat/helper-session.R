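# The reference synthetic session used by the closed-loop and significance
# checks: 40 pseudo-participants, 25 steps per foot and grade (50 per grade
# and participant with both feet), sensor noise 0.02 body weights, all nine
# grades. Built once per test run and shared between test files.

.session_cache <- new.env(parent = emptyenv())

reference_session <- function() {
  if (is.null(.session_cache$session)) {
    spec <- session_spec(steps_per_grade = 25, seed = 20240301)
    .session_cache$session <- generate_session(spec)
  }
  .session_cache$session
}

reference_parameters <- function() {
  if (is.null(.session_cache$params)) {
    .session_cache$params <- extract_parameters(reference_session())
  }
  .session_cache$params
}
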