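## Matrix exponential by scaling-and-squaring with a [6/6] Pade approximant.
## The rate matrices here are tiny (k <= 4) and exponentiated once per branch
## inside likelihood loops, so a compact dense implementation is the right
## tool.  Accuracy contract: matches a truncated Taylor series to 1e-10 for
## ||Q t|| <= 10 (exercised in the test suite).

#' Matrix exponential
#'
#' Dense matrix exponential via scaling-and-squaring with a diagonal Pade
#' approximant, used to propagate Mk partial likelihoods along branches,
#' `exp(Q t)`.
#'
#' @param A a square numeric matrix.
#' @return `exp(A)` as a dense matrix.
#' @export
expm_pade <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(is.finite(A)))
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- 0L
  if (nrm > 0.5) s <- ceiling(log2(nrm / 0.5))
  if (s > 0L) A <- A / 2^s
  ## Pade [6/6] coefficients c_k = (12-k)! 6! / (12! k! (6-k)!)
  cf <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  P <- I
  N <- cf[1] * I
  D <- cf[1] * I
  sg <- 1
  for (k in 1:6) {
    P <- P %*% A
    sg <- -sg
    N <- N + cf[k + 1] * P
    D <- D + sg * cf[k + 1] * P
  }
  E <- solve(D, N)
  if (s > 0L) for (i in seq_len(s)) E <- E %*% E
  E
}
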