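# shared test utilities

# breadth-first search connectivity of a bead graph
graph_connected <- function(M, edges) {
  adj <- vector("list", M)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(M)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# a random rotation matrix in d dimensions (QR sign-fixed)
random_rotation <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# exact <1/r_j> for a freely jointed chain of j unit bonds:
# (2/pi) * Integral_0^inf (sin k / k)^j dk  -- independent oracle for the
# bead-spring model's short-range pair statistics
fjc_mean_rinv <- function(j) {
  if (j <= 2) return(1)
  f <- function(k) (sin(k) / k)^j
  2 / pi * (integrate(f, 0, 50, subdivisions = 2000L, rel.tol = 1e-10)$value +
              integrate(f, 50, Inf, subdivisions = 2000L,
                        rel.tol = 1e-8)$value)
}

# exact finite-M size ratio of a freely jointed chain with bond length b
fjc_chain_rho <- function(M, b2 = 1) {
  j <- seq_len(M - 1L)
  rinv <- vapply(j, fjc_mean_rinv, numeric(1)) / sqrt(b2)
  rhinv <- 2 / M^2 * sum((M - j) * rinv)
  sqrt((M^2 - 1) / (6 * M) * b2) * rhinv
}
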