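# Shared fixtures: everything is built in code at test time.

pop <- population_model()
spec_correct <- model_spec("correct")
spec_mis <- model_spec("misspecified")
spec_null <- model_spec("null")

# one small multivariate normal sample reused by several correction tests
normal_sample <- function(N = 400, seed = 420) {
  generate_data(condition_spec("normal", 3, N = N, specification = "correct",
                               seed = seed), pop)$values
}

sample_kurtosis <- function(x) {
  xc <- x - mean(x)
  mean(xc^4) / mean(xc^2)^2
}

sample_skewness <- function(x) {
  xc <- x - mean(x)
  mean(xc^3) / mean(xc^2)^1.5
}
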