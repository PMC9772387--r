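# Independent oracles: deliberately naive implementations used only to check
# the package's vectorized / closed-form code paths.

# exhaustive double loop over all atom pairs
brute_force_interface_distance <- function(structure, spec, chain, resno) {
  at <- structure$atoms
  res <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  opp_chains <- if (chain %in% spec$group_a) spec$group_b else spec$group_a
  opp <- at[at$chain %in% opp_chains, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(opp))) {
      d <- sqrt((res$x[i] - opp$x[j])^2 + (res$y[i] - opp$y[j])^2 +
                  (res$z[i] - opp$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# closed-form simple linear regression via the normal equations
ols_normal_equations <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# optimal superposition RMSD via the quaternion characteristic polynomial
# (largest eigenvalue of the 4x4 key matrix), independent of the SVD route
quaternion_rmsd <- function(ref, mobile) {
  q <- sweep(ref, 2, colMeans(ref))
  p <- sweep(mobile, 2, colMeans(mobile))
  m <- crossprod(p, q)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    nrow = 4, byrow = TRUE)
  lambda_max <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  e0 <- sum(q^2) + sum(p^2)
  sqrt(max(e0 - 2 * lambda_max, 0) / nrow(ref))
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_dec)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# random two-chain point-cloud structure for distance oracle checks
random_toy_structure <- function(n_atoms_per_chain = 10) {
  make_atoms <- function(chain, shift) {
    n <- n_atoms_per_chain
    data.frame(chain = chain,
               resno = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
               insert = "", resid = "ALA",
               elety = rep(c("CA", "CB"), length.out = n), element = "C",
               x = rnorm(n, shift[1], 4), y = rnorm(n, shift[2], 4),
               z = rnorm(n, shift[3], 4), stringsAsFactors = FALSE)
  }
  atoms <- rbind(make_atoms("A", c(0, 0, 0)), make_atoms("B", runif(3, 2, 9)))
  clrescore:::new_structure("random_toy", atoms)
}

# apply one rigid motion to every atom of a structure
transform_structure <- function(structure, rotation, translation) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% rotation
  at[, c("x", "y", "z")] <- sweep(xyz, 2, translation, "+")
  clrescore:::new_structure(structure$model_id, at)
}
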