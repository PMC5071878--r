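# Fixtures built in code and independent oracles the solver tests check
# against. The oracles deliberately avoid the code paths they verify.

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")

# Independent soft-thresholding oracle: reconstructs the shrunken matrix
# from eigen-decompositions of the Gram matrices rather than svd().
svt_oracle <- function(M, threshold) {
  n <- nrow(M); m <- ncol(M)
  if (n <= m) {
    eg <- eigen(M %*% t(M), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    U <- eg$vectors
    keep <- d > max(d) * 1e-12
    V <- t(M) %*% U[, keep, drop = FALSE] %*% diag(1 / d[keep], sum(keep))
    dk <- pmax(d[keep] - threshold, 0)
    U[, keep, drop = FALSE] %*% (dk * t(V))
  } else {
    t(svt_oracle(t(M), threshold))
  }
}

# Dense least-squares oracle for the X update: vectorize A and solve
# min || vec(A) - (Y2 kron Y1) vec(X) || with a QR factorization.
update_X_oracle <- function(A, Y1, Y2) {
  K <- kronecker(Y2, Y1)
  x <- qr.solve(K, as.vector(A))
  matrix(x, ncol(Y1), ncol(Y2))
}

# Eigen-based pseudo-inverse (independent of MASS::ginv) for the min-norm
# solutions of the possibly rank-deficient Y1/Y2 normal equations.
pinv_oracle <- function(G, tol = 1e-10) {
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values, 0)
  if (!any(pos)) return(matrix(0, nrow(G), ncol(G)))
  eg$vectors[, pos, drop = FALSE] %*%
    ((1 / eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE]))
}

# Min-norm least-squares oracle for the Y1 update with regressor B = X Y2':
# Y1 = A B' (B B')^+ . The regressor has rank min(k1, k2), so the plain
# normal equations are rank-deficient whenever k2 < k1.
update_Y1_oracle <- function(A, X, Y2) {
  B <- X %*% t(Y2)
  A %*% t(B) %*% pinv_oracle(B %*% t(B))
}

# C = Y1 X has full column rank whenever k2 <= k1 (the generic case), so
# the LS solution is unique and a backward-stable QR solve is the oracle;
# explicit normal equations would square the condition number.
update_Y2_oracle <- function(A, Y1, X) {
  C <- Y1 %*% X
  t(qr.solve(C, A))
}

# Random consistent mccf_state for oracle comparisons.
random_state <- function(n, m, k1, k2, seed) {
  set.seed(seed)
  mccf_state(
    A = matrix(rnorm(n * m), n, m),
    X = matrix(rnorm(k1 * k2), k1, k2),
    Y1 = matrix(rnorm(n * k1), n, k1),
    Y2 = matrix(rnorm(m * k2), m, k2)
  )
}

# Small genotype panel with a deterministic value pattern.
tiny_panel <- function(n = 4, m = 5, ploidy = "diploid_genotype", seed = 1) {
  set.seed(seed)
  hi <- if (ploidy == "haplotype") 1L else 2L
  genotype_panel(matrix(sample(0:hi, n * m, replace = TRUE), n, m), ploidy)
}

# Shared mosaic genotype fixture (the imputation study conditions):
# 4 founders, 400 haplotypes paired into 200 genotype samples, 1000 SNPs,
# switch and flip rates 0.01. Cached per session because generation and
# the solvers dominate test time.
mosaic_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- haplotypes_to_genotypes(
        simulate_mosaic_haplotypes(mosaic_params(seed = seed))
      )
    }
    cache[[key]]
  }
})

# Allelic error of a raw (unrounded) completion against hidden truth.
scored_error <- function(raw, masked, ploidy = "diploid_genotype") {
  allelic_error_rate(masked$truth, round_genotypes(raw, ploidy),
                     masked$hidden, ploidy)$error_rate
}

baseline_error <- function(masked, ploidy = "diploid_genotype") {
  allelic_error_rate(masked$truth, impute_baseline_majority(masked$panel),
                     masked$hidden, ploidy)$error_rate
}
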