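#' Parameters of the mosaic haplotype simulator
#'
#' Each simulated haplotype is a mosaic of a small set of founder
#' haplotypes: it copies one founder along the chromosome, switching to a
#' random founder with probability `switch_rate` between adjacent SNPs, and
#' finally flips each allele independently with probability `flip_rate`.
#' With few founders and rare switches the sample-by-SNP matrix is
#' approximately low rank -- the linkage-disequilibrium structure that both
#' completion models exploit. With `switch_rate = 0` and `flip_rate = 0`
#' the rank is exactly at most `n_founders`.
#'
#' @param n_founders number of founder haplotypes (controls the true rank).
#' @param n_haplotypes number of sample haplotypes to simulate.
#' @param n_snps number of SNPs (matrix columns).
#' @param switch_rate per-SNP probability of changing founder template.
#' @param flip_rate per-allele mutation/noise probability.
#' @param maf_range `(low, high)` range of founder minor-allele frequencies.
#' @param seed integer seed.
#' @return An object of class `mosaic_params`.
#' @export
mosaic_params <- function(n_founders = 4L, n_haplotypes = 400L, n_snps = 1000L,
                          switch_rate = 0.01, flip_rate = 0.01,
                          maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(
    n_founders >= 1L, n_haplotypes >= 1L, n_snps >= 1L,
    switch_rate >= 0, switch_rate <= 1, flip_rate >= 0, flip_rate <= 1,
    maf_range[1L] > 0, maf_range[1L] <= maf_range[2L], maf_range[2L] < 1
  )
  structure(
    list(n_founders = as.integer(n_founders),
         n_haplotypes = as.integer(n_haplotypes),
         n_snps = as.integer(n_snps),
         switch_rate = switch_rate, flip_rate = flip_rate,
         maf_range = maf_range, seed = as.integer(seed)),
    class = "mosaic_params"
  )
}

#' Simulate founder haplotypes
#'
#' Draws per-SNP minor-allele frequencies uniformly in `maf_range`, then
#' each founder's allele as Bernoulli of that frequency. Reproducible given
#' the seed.
#'
#' @param params a [mosaic_params()].
#' @return 0/1 integer matrix, `n_founders` x `n_snps`.
#' @export
simulate_founders <- function(params) {
  stopifnot(inherits(params, "mosaic_params"))
  with_seed(params$seed, {
    maf <- runif(params$n_snps, params$maf_range[1L], params$maf_range[2L])
    mat <- vapply(seq_len(params$n_snps), function(j) {
      rbinom(params$n_founders, 1L, maf[j])
    }, integer(params$n_founders))
    matrix(as.integer(mat), nrow = params$n_founders)
  })
}

#' Simulate a panel of mosaic haplotypes
#'
#' @inheritParams simulate_founders
#' @return A haplotype [genotype_panel()] (`n_haplotypes` x `n_snps`).
#'   The founder matrix and per-sample founder paths are attached as
#'   attributes `founders` and `paths` for ground-truth checks.
#' @export
simulate_mosaic_haplotypes <- function(params) {
  stopifnot(inherits(params, "mosaic_params"))
  founders <- simulate_founders(params)
  out <- with_seed(params$seed + 1L, {
    paths <- matrix(0L, params$n_haplotypes, params$n_snps)
    values <- matrix(0L, params$n_haplotypes, params$n_snps)
    for (i in seq_len(params$n_haplotypes)) {
      f <- sample.int(params$n_founders, 1L)
      for (j in seq_len(params$n_snps)) {
        if (j > 1L && runif(1L) < params$switch_rate) {
          f <- sample.int(params$n_founders, 1L)
        }
        paths[i, j] <- f
        values[i, j] <- founders[f, j]
      }
    }
    if (params$flip_rate > 0) {
      flips <- matrix(
        runif(length(values)) < params$flip_rate,
        nrow(values), ncol(values)
      )
      values[flips] <- 1L - values[flips]
    }
    list(values = values, paths = paths)
  })
  panel <- genotype_panel(out$values, "haplotype",
    sample_ids = paste0("h", seq_len(params$n_haplotypes))
  )
  attr(panel, "founders") <- founders
  attr(panel, "paths") <- out$paths
  panel
}

#' Pair phased haplotypes into diploid genotypes
#'
#' Genotype row `i` is the allele-count sum of haplotype rows `2i - 1` and
#' `2i`, giving codes in 0/1/2. Per-column allele counts are conserved
#' exactly.
#'
#' @param panel a haplotype [genotype_panel()] with an even number of rows.
#' @return a diploid [genotype_panel()] with half as many rows.
#' @export
haplotypes_to_genotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$ploidy != "haplotype") stop_ri("haplotypes_to_genotypes: panel must be haplotype-coded")
  n <- nrow(panel$values)
  if (n %% 2L != 0L) stop_ri("haplotypes_to_genotypes: odd number of haplotype rows")
  if (any(panel$values == panel$missing_sentinel)) {
    stop_ri("haplotypes_to_genotypes: haplotypes must be fully observed")
  }
  odd <- panel$values[seq(1L, n, by = 2L), , drop = FALSE]
  even <- panel$values[seq(2L, n, by = 2L), , drop = FALSE]
  genotype_panel(odd + even, "diploid_genotype",
    sample_ids = paste0("g", seq_len(n %/% 2L)),
    snp_ids = panel$snp_ids
  )
}

#' Systematic (chip-mismatch) masking
#'
#' Emulates a meta-analysis scenario where a study cohort was typed on a
#' chip missing many of the reference panel's SNPs: the first
#' `ceil(ref_fraction * n)` rows stay fully observed (the reference block),
#' and in the remaining study rows a seeded random `masked_snp_fraction` of
#' the columns is hidden *entirely* -- every study sample misses the same
#' SNPs, the signature of systematic missingness.
#'
#' @param panel a fully observed [genotype_panel()].
#' @param ref_fraction fraction of rows kept as the reference block, in (0, 1).
#' @param masked_snp_fraction fraction of SNP columns hidden in the study
#'   block, in \\[0, 1).
#' @param seed integer seed choosing which columns are hidden.
#' @return list with `panel` (masked), `hidden` (logical matrix), `truth`
#'   (original values) and `study_rows` (row indices of the study block).
#' @export
mask_systematic <- function(panel, ref_fraction = 0.5,
                            masked_snp_fraction = 0.853, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ref_fraction <= 0 || ref_fraction >= 1) stop_ri("mask_systematic: ref_fraction must be in (0, 1)")
  if (masked_snp_fraction < 0 || masked_snp_fraction >= 1) {
    stop_ri("mask_systematic: masked_snp_fraction must be in [0, 1)")
  }
  n <- nrow(panel$values)
  m <- ncol(panel$values)
  n_ref <- ceiling(ref_fraction * n)
  study_rows <- setdiff(seq_len(n), seq_len(n_ref))
  n_hide_cols <- round(masked_snp_fraction * m)
  hide_cols <- if (n_hide_cols > 0L) with_seed(seed, sample.int(m, n_hide_cols)) else integer(0)
  hidden <- matrix(FALSE, n, m)
  hidden[study_rows, hide_cols] <- TRUE
  values <- panel$values
  values[hidden] <- panel$missing_sentinel
  masked <- genotype_panel(values, panel$ploidy,
    sample_ids = panel$sample_ids, snp_ids = panel$snp_ids,
    missing_sentinel = panel$missing_sentinel
  )
  list(panel = masked, hidden = hidden, truth = panel$values,
       study_rows = study_rows)
}

#' Simulate a noisy low-rank matrix
#'
#' `U V' + noise` with seeded standard-normal factors; the factors are
#' returned for ground-truth comparisons in recovery experiments.
#'
#' @param n,m matrix dimensions.
#' @param rank true rank, `rank <= min(n, m)`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return list with `M` (n x m), `U` (n x rank), `V` (m x rank).
#' @export
simulate_lowrank <- function(n, m, rank, noise_sd = 0, seed = 1L) {
  stopifnot(rank >= 1L, rank <= min(n, m))
  with_seed(seed, {
    U <- matrix(rnorm(n * rank), n, rank)
    V <- matrix(rnorm(m * rank), m, rank)
    M <- U %*% t(V)
    if (noise_sd > 0) M <- M + matrix(rnorm(n * m, sd = noise_sd), n, m)
    list(M = M, U = U, V = V)
  })
}
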