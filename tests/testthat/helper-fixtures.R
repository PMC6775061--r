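# Shared generators for property-style tests.

# Random reversible chain with n states: symmetric positive weight matrix
# row-normalised; pi follows from the weights.
random_reversible_chain <- function(n, connectivity = 1) {
  S <- matrix(runif(n * n), n)
  S <- S * (matrix(runif(n * n), n) < connectivity)
  S <- S + t(S) + diag(runif(n) + 0.1)
  Tm <- S / rowSums(S)
  pi <- rowSums(S) / sum(S)
  list(T = Tm, pi = pi)
}

# Independent committor oracle: make A and B absorbing and read the
# absorption probabilities into B from the fundamental-matrix formula.
committor_oracle <- function(Tm, A, B) {
  n <- nrow(Tm)
  U <- setdiff(seq_len(n), c(A, B))
  q <- numeric(n)
  q[B] <- 1
  if (length(U) > 0) {
    Q <- Tm[U, U, drop = FALSE]
    R <- Tm[U, B, drop = FALSE]
    q[U] <- solve(diag(length(U)) - Q) %*% rowSums(R)
  }
  q
}

# Rigid-body transform of an atom table.
rotate_atoms <- function(atoms, angle = 0.7, axis = c(0, 0, 1),
                         shift = c(5, -3, 2)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
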