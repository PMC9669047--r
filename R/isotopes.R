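#' Natural isotope abundance table
#'
#' Pinned terrestrial isotope frequencies (IUPAC representative values)
#' used to build natural-abundance correction matrices. Each element maps
#' to the probability distribution of the mass shift contributed by one
#' atom of that element: index 1 is shift 0 (lightest isotope), index 2 is
#' +1, and so on.
#'
#' @return Named list of per-atom mass-shift distributions for C, H, N, O,
#'   Si and S.
#' @examples
#' isotopeAbundances()$C   # (12C, 13C)
#' @export
isotopeAbundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

# Discrete convolution of two mass-shift distributions, truncated.
.convShift <- function(a, b, maxLen = Inf) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  if (length(out) > maxLen) out <- out[seq_len(maxLen)]
  out
}

# n-fold self-convolution of a per-atom distribution.
.convPower <- function(dist, n, maxLen = Inf) {
  out <- 1
  for (i in seq_len(n)) out <- .convShift(out, dist, maxLen)
  out
}
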