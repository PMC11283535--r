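# Independent oracles used to cross-check the package's geometry code.
# Deliberately implemented by a different route than the package itself:
# superposition via Horn's quaternion eigenvalue method rather than SVD.

# Horn (1987) closed-form absolute orientation: the optimal rotation is the
# largest eigenvector of the 4x4 key matrix built from the cross-covariance.
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  S <- crossprod(P, Q) # S[a, b] = sum p_a q_b
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  R <- quaternion_to_matrix(q)
  lambda <- e$values[1]
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  list(rotation = R,
       translation = ct - as.numeric(R %*% cm),
       rmsd = sqrt(max(msd, 0)))
}

quaternion_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# rotation angle via quaternion: angle = 2 acos(|w|)
quaternion_rotation_angle <- function(R) {
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  2 * acos(min(1, w)) * 180 / pi
}

# uniform random rotation from a normalised Gaussian quaternion
random_rotation <- function() {
  quaternion_to_matrix(rnorm(4))
}

random_points <- function(n, scale = 10) {
  matrix(runif(3 * n, -scale, scale), ncol = 3)
}

# small C-alpha-only model on a beta-PGM-like numbering, for I/O tests
toy_model <- function(resno = 1:30, chain = "A", resid = "ALA", id = "toy") {
  n <- length(resno)
  structure_model(data.frame(
    record = "ATOM", chain_id = chain, residue_number = resno,
    residue_name = resid, atom_name = "CA", element = "C", altloc = "",
    occupancy = 1,
    x = round(cos(seq_len(n)) * 8, 3),
    y = round(sin(seq_len(n)) * 8, 3),
    z = round(seq_len(n) * 1.4, 3),
    stringsAsFactors = FALSE), identifier = id)
}
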