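# shared fixtures built in code

# equal-loading simple-structure loading matrix
equalLoadings <- function(lambda = 0.6) {
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- lambda
  L[5:8, 2] <- lambda
  L
}

# population model with equal loadings
popModel <- function(lambda = 0.6, phi12 = 0) {
  buildModel(equalLoadings(lambda), phi12)
}

# one simulated replication (measurement side only)
simReplication <- function(mu = 0.6, sigma = 0.03, phi12 = 0.3, n = 500,
                           seed = 42) {
  set.seed(seed)
  L <- drawLoadings(mu, sigma)
  model <- buildModel(L, phi12)
  samp <- simulateSample(model, n)
  list(model = model, samp = samp)
}
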