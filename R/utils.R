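# Internal helpers shared across modules.

# Normalise an RNA/DNA string to the DNA alphabet (U -> T, uppercase).
normalizeTU <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# Deterministic sub-seed derived from a master seed and a stage label, kept
# within the 32-bit integer range.
subSeed <- function(seed, stage) {
  offsets <- c(kinetics = 11L, fractions = 23L, ribo = 37L, clip = 53L,
               metabolomics = 71L, controls = 89L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 101 + off) %% .Machine$integer.max)
}

# Negative-binomial draw parameterised by mean and dispersion
# (var = mu + disp * mu^2); dispersion 0 falls back to Poisson.
rnbinomMu <- function(n, mu, dispersion) {
  out <- numeric(n)
  pois <- dispersion <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / dispersion[!pois])
  }
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
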