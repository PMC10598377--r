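# Internal helpers.

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-wise softmax of an n x B logit matrix (numerically stabilised).
softmaxCols <- function(m) {
  m <- m - rep(apply(m, 2, max), each = nrow(m))
  e <- exp(m)
  e / rep(colSums(e), each = nrow(e))
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Polynomial rolling hash of a character scalar, as 8 hex digits. Used to
# fingerprint encoder configs in checkpoints (no cryptographic intent).
strHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

configFingerprint <- function(cfg) {
  strHash(paste(cfg@stemChannels, paste(cfg@blockChannels, collapse = ","),
              paste(cfg@blocksPerStage, collapse = ","), cfg@embeddingDim,
              sep = "|"))
}

caseLabels <- function(cases) vapply(cases, caseLabel, integer(1))
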