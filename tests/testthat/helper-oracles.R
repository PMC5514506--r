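# independent dense reference: loop-assembled 5-point operator with
# harmonic-mean face diffusivities, solved with base::solve
dense_steady_state <- function(D, k, src, bc, h) {
  n <- nrow(D)
  ni <- n - 2
  idx <- function(i, j) (j - 2) * ni + (i - 1)
  A <- matrix(0, ni * ni, ni * ni)
  b <- numeric(ni * ni)
  for (j in 2:(n - 1)) {
    for (i in 2:(n - 1)) {
      p <- idx(i, j)
      A[p, p] <- k[i, j]
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + s[1]; jj <- j + s[2]
        g <- 2 * D[i, j] * D[ii, jj] / (D[i, j] + D[ii, jj]) / h^2
        A[p, p] <- A[p, p] + g
        if (ii >= 2 && ii <= n - 1 && jj >= 2 && jj <= n - 1) {
          A[p, idx(ii, jj)] <- A[p, idx(ii, jj)] - g
        } else {
          b[p] <- b[p] + g * bc
        }
      }
      b[p] <- b[p] + src[i, j]
    }
  }
  out <- matrix(bc, n, n)
  out[2:(n - 1), 2:(n - 1)] <- solve(A, b)
  out
}
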