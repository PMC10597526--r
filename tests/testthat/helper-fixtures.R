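# Shared fixtures: tiny corpora and closed-form scorers built in code.

tiny_params <- function(n = 12L, seed = 101L, hard = FALSE)
  generatorParams(nPerClass = n, lengthRange = c(120L, 240L), seed = seed,
                  hard = hard)

tiny_corpus <- function(n = 12L, seed = 101L, hard = FALSE)
  generateDataset(tiny_params(n, seed, hard))

# deterministic linear scorer over dense L x 4 inputs: S(X) = sum(X * W0)
linear_scorer <- function(L, seed = 1L) {
  set.seed(seed)
  W0 <- matrix(rnorm(L * 4L), L, 4L)
  list(score = function(X) sum(X * W0), grad = function(X) W0,
       W0 = W0, id = "linear")
}

# smooth nonlinear scorer for IG convergence checks
tanh_scorer <- function(L, seed = 2L) {
  set.seed(seed)
  W1 <- matrix(rnorm(4L * 6L, sd = 0.8), 4L, 6L)
  w2 <- rnorm(6L)
  list(score = function(X) sum(tanh(X %*% W1) %*% w2),
       grad = function(X) {
         Z <- X %*% W1
         ((1 - tanh(Z)^2) * rep(w2, each = nrow(X))) %*% t(W1)
       },
       id = "tanh")
}

# a tiny random model for interface-level tests
tiny_model <- function(encoder = "lfnet", seed = 7L, task = "class", D = 16L)
  buildModel(modelConfig(encoder, nEncoderLayers = 2L, nDecoderLayers = 1L,
                         hiddenDim = D, nHeads = 4L, window = 12L,
                         task = task), seed = seed)
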