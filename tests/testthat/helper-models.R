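# shared fixtures: all built in code, no stored data

default_sarc <- sarcomere_params()

# a model with a slightly coarser sampling grid for speed; physiology is
# the package default
test_model <- function(...) {
  rv_model(..., protocol = list(nsamp = 400, max_beats = 300))
}

# walls with prescribed sarcomere states, for direct geometry solves
walls_with_state <- function(model = test_model(),
                             Ls = c(2.2, 2.15, 2.18),
                             A = c(0.5, 0.5, 0.5),
                             xb = c(0.08, 0.08, 0.08)) {
  w <- model$walls
  for (i in 1:3) {
    nm <- c("L", "S", "R")[i]
    w[[nm]]$state <- sarcomere_state(Ls[i], A[i], xb[i])
  }
  w
}

# cache of the homeostasis-adjusted baseline, shared across test files
baseline_cache <- new.env()
get_baseline <- function() {
  if (is.null(baseline_cache$hs))
    baseline_cache$hs <- homeostasis_adjust(test_model())
  baseline_cache$hs
}
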