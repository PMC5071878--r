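#' Hide observed entries uniformly at random
#'
#' Masks `round(rate * n_observed)` of the currently observed entries,
#' chosen uniformly without replacement under `seed`, and returns the hidden
#' truths for later scoring. Only originally observed entries can be hidden.
#' A row or column may lose all of its entries; that is permitted (markers
#' with all samples missing are still imputable from the rest of the
#' matrix) and logged as a warning.
#'
#' @param panel a [genotype_panel()].
#' @param rate masking fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with `panel` (the masked panel), `hidden` (logical matrix,
#'   `TRUE` at the newly hidden positions) and `truth` (integer matrix of
#'   the original values).
#' @export
mask_uniform <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (rate <= 0 || rate >= 1) stop_ri("mask_uniform: rate must be in (0, 1)")
  obs <- mask_from_panel(panel)
  idx <- which(obs)
  n_hide <- round(rate * length(idx))
  if (n_hide >= length(idx)) stop_ri("mask_uniform: masking would leave no observed entries")
  hide <- with_seed(seed, sample(idx, n_hide))
  hidden <- matrix(FALSE, nrow(panel$values), ncol(panel$values))
  hidden[hide] <- TRUE
  values <- panel$values
  values[hide] <- panel$missing_sentinel
  left <- obs & !hidden
  if (any(rowSums(left) == 0L) || any(colSums(left) == 0L)) {
    warning("mask_uniform: some rows or columns lost all observed entries")
  }
  masked <- genotype_panel(values, panel$ploidy,
    sample_ids = panel$sample_ids, snp_ids = panel$snp_ids,
    missing_sentinel = panel$missing_sentinel
  )
  list(panel = masked, hidden = hidden, truth = panel$values)
}

#' Round raw solver output to genotype codes
#'
#' The solvers return real numbers in (roughly) the 0-2 range; they are
#' converted to genotype codes by clamping to the valid range and rounding
#' half away from zero. Haplotype output clamps to \\[0, 1\\].
#'
#' @param raw real matrix.
#' @param ploidy `"diploid_genotype"` or `"haplotype"`.
#' @return integer matrix of valid codes.
#' @export
round_genotypes <- function(raw, ploidy = c("diploid_genotype", "haplotype")) {
  ploidy <- match.arg(ploidy)
  if (!all(is.finite(raw))) stop_ri("round_genotypes: non-finite entries")
  hi <- if (ploidy == "haplotype") 1 else 2
  x <- pmin(pmax(raw, 0), hi)
  # clamped values are nonnegative, so floor(x + 0.5) rounds half away from zero
  out <- floor(x + 0.5)
  storage.mode(out) <- "integer"
  matrix(out, nrow(raw), ncol(raw))
}

#' Allelic imputation error rate
#'
#' The proportion of masked alleles that are incorrectly imputed. A diploid
#' genotype entry carries two alleles, so truth `g` versus imputed `g_hat`
#' contributes `|g - g_hat|` allele errors out of 2; a haplotype entry
#' contributes 0 or 1 out of 1. `error_mode = "genotype"` instead counts
#' whole-entry mismatches out of the number of hidden entries.
#'
#' @param truth integer matrix of true codes.
#' @param imputed integer matrix of rounded imputed codes.
#' @param hidden logical matrix marking the scored (masked) entries.
#' @param ploidy `"diploid_genotype"` or `"haplotype"`.
#' @param method label recorded in the report.
#' @param error_mode `"allelic"` (default) or `"genotype"`.
#' @param objective_history optional solver trace echoed into the report.
#' @param elapsed optional wall-clock seconds, informational.
#' @return An object of class `imputation_report`.
#' @export
allelic_error_rate <- function(truth, imputed, hidden,
                               ploidy = c("diploid_genotype", "haplotype"),
                               method = "unknown",
                               error_mode = c("allelic", "genotype"),
                               objective_history = NULL, elapsed = NA_real_) {
  ploidy <- match.arg(ploidy)
  error_mode <- match.arg(error_mode)
  stopifnot(identical(dim(truth), dim(imputed)), identical(dim(truth), dim(hidden)))
  if (any(imputed[hidden] != round(imputed[hidden]))) {
    stop_ri("allelic_error_rate: imputed matrix must be rounded to integer codes")
  }
  n_masked <- sum(hidden)
  if (n_masked == 0L) stop_ri("allelic_error_rate: no hidden entries to score")
  diff <- abs(truth[hidden] - imputed[hidden])
  ploidy_factor <- if (ploidy == "haplotype") 1L else 2L
  if (error_mode == "allelic") {
    n_err <- sum(diff)
    rate <- n_err / (ploidy_factor * n_masked)
  } else {
    n_err <- sum(diff > 0)
    rate <- n_err / n_masked
  }
  structure(
    list(method = method, error_rate = rate, n_masked = n_masked,
         n_allele_errors = n_err, error_mode = error_mode, ploidy = ploidy,
         objective_history = objective_history, elapsed = elapsed),
    class = "imputation_report"
  )
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf(
    "imputation_report [%s]: %s error rate %.4f (%d errors over %d masked entries)\n",
    x$method, x$error_mode, x$error_rate, x$n_allele_errors, x$n_masked
  ))
  invisible(x)
}

#' Column-majority baseline imputer
#'
#' Fills every hidden entry with the most frequent observed code of its
#' column (ties to the smaller code; columns with no observed entries fall
#' back to the most frequent code overall). The floor any model-based
#' imputer must beat.
#'
#' @param panel a masked [genotype_panel()].
#' @return integer matrix with hidden entries filled.
#' @export
impute_baseline_majority <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  values <- panel$values
  obs <- values != panel$missing_sentinel
  codes <- valid_codes(panel$ploidy)
  majority <- function(v) {
    if (!length(v)) return(NA_integer_)
    tab <- tabulate(match(v, codes), nbins = length(codes))
    codes[which.max(tab)]
  }
  overall <- majority(values[obs])
  for (j in seq_len(ncol(values))) {
    mis <- !obs[, j]
    if (any(mis)) {
      fill <- majority(values[obs[, j], j])
      values[mis, j] <- if (is.na(fill)) overall else fill
    }
  }
  values
}

#' End-to-end imputation over stacked panels
#'
#' Stacks the given panels into one matrix (union of SNPs, missing where a
#' panel never typed a SNP), dispatches the chosen solver, rounds the raw
#' output to genotype codes, and returns the completed panel with
#' provenance of which input panel each row came from.
#'
#' @param panels a [genotype_panel()] or list of panels (reference panels
#'   first by convention; any order works).
#' @param method `"lrmc_s"`, `"bcu1"`, `"bcu2"`, `"bcu3"` or `"mbi_bl"`.
#' @param fpca a [fpca_config()] (used by `lrmc_s`).
#' @param window a [window_spec()] (used by `lrmc_s`).
#' @param mccf an [mccf_config()] (used by the factorization drivers).
#' @param rename_duplicates passed to [stack_panels()].
#' @return list with `panel` (completed, rounded `genotype_panel`), `raw`
#'   (pre-rounding real matrix), `uncertainty` (`|raw - rounded|`, a crude
#'   per-entry confidence proxy), `panel_rows` (row ranges per input
#'   panel), `method`, `objective_history` and `elapsed` (seconds).
#' @export
impute <- function(panels,
                   method = c("lrmc_s", "bcu1", "bcu2", "bcu3", "mbi_bl"),
                   fpca = fpca_config(), window = window_spec(),
                   mccf = mccf_config(), rename_duplicates = FALSE) {
  method <- match.arg(method)
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  stacked <- stack_panels(panels, rename_duplicates = rename_duplicates)
  mask <- mask_from_panel(stacked)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(method,
    lrmc_s = lrmc_s_complete(stacked, mask, cfg = fpca, window = window),
    bcu1 = run_bcu1(stacked, mask, cfg = mccf),
    bcu2 = run_bcu2(stacked, mask, cfg = mccf),
    bcu3 = run_bcu3(stacked, mask, cfg = mccf),
    mbi_bl = run_mbi_bl(stacked, mask, cfg = mccf)
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  raw <- if (inherits(res, "completion_result")) res$completed else res$A
  rounded <- round_genotypes(raw, stacked$ploidy)
  completed <- genotype_panel(rounded, stacked$ploidy,
    sample_ids = stacked$sample_ids, snp_ids = stacked$snp_ids,
    missing_sentinel = stacked$missing_sentinel
  )
  list(
    panel = completed, raw = raw, uncertainty = abs(raw - rounded),
    panel_rows = attr(stacked, "panel_rows"), method = method,
    objective_history = res$objective_history, elapsed = elapsed
  )
}

#' Validation-masking grid search over the column-factor dimension k2
#'
#' Runs the chosen factorization driver once per candidate `k2`, scores
#' each on a held-out validation mask, and returns the `k2` with the lowest
#' allelic error (ties go to the smaller `k2`). The validation mask must be
#' distinct from the entries one finally wants to impute.
#'
#' @param panel a [genotype_panel()] whose entries under `hidden` are held
#'   out; `truth` supplies their true codes.
#' @param hidden logical validation mask.
#' @param truth integer matrix of true codes (only positions under `hidden`
#'   are read).
#' @param k2_list integer candidates, e.g. `c(2, 3, 5, 10, 20)`.
#' @param cfg an [mccf_config()]; its `k2` is overridden per candidate.
#' @param method which driver to use.
#' @return list with `best_k2` and `table` (data.frame of k2, error_rate).
#' @export
k2_grid_search <- function(panel, hidden, truth,
                           k2_list = c(2L, 3L, 5L, 10L, 20L),
                           cfg = mccf_config(),
                           method = c("bcu2", "bcu1", "bcu3", "mbi_bl")) {
  method <- match.arg(method)
  if (!length(k2_list)) stop_ri("k2_grid_search: empty k2_list")
  driver <- switch(method, bcu1 = run_bcu1, bcu2 = run_bcu2,
                   bcu3 = run_bcu3, mbi_bl = run_mbi_bl)
  errs <- vapply(k2_list, function(k2) {
    cfg_k <- cfg
    cfg_k$k2 <- as.integer(k2)
    if (cfg_k$k2 > cfg_k$k1) cfg_k$k1 <- cfg_k$k2
    st <- driver(panel, cfg = cfg_k)
    rounded <- round_genotypes(st$A, panel$ploidy)
    allelic_error_rate(truth, rounded, hidden, panel$ploidy,
                       method = paste0(method, "_k2_", k2))$error_rate
  }, numeric(1L))
  ord <- order(errs, k2_list) # ties -> smaller k2
  list(best_k2 = as.integer(k2_list[ord[1L]]),
       table = data.frame(k2 = as.integer(k2_list), error_rate = errs))
}

#' Numeric encoding of nucleotide-letter matrices
#'
#' Substitutes each A/C/G/T letter by the number the mapping assigns, e.g.
#' `c(A = 0, T = 1, C = 0, G = 1)`. Missing tokens stay missing (`NA`).
#' Useful for inspecting how different encodings shape the singular-value
#' spectrum of a panel.
#'
#' @param letters character matrix over A, C, G, T and `missing_token`.
#' @param mapping named numeric vector with entries for A, C, G and T.
#' @param missing_token token preserved as `NA` (default `"?"`).
#' @return real matrix, `NA` where missing.
#' @export
encode_nucleotides <- function(letters, mapping, missing_token = "?") {
  stopifnot(is.matrix(letters))
  if (!all(c("A", "C", "G", "T") %in% names(mapping))) {
    stop_ri("encode_nucleotides: mapping must name all of A, C, G, T")
  }
  unknown <- !(letters %in% c(names(mapping), missing_token))
  if (any(unknown)) {
    stop_ri("encode_nucleotides: unknown letter '", letters[which(unknown)[1L]], "'")
  }
  out <- matrix(unname(mapping[letters]), nrow(letters), ncol(letters))
  out[letters == missing_token] <- NA_real_
  out
}

#' Leading singular values of a data matrix
#'
#' The decay of the spectrum is the empirical justification for low-rank
#' completion: genotype panels typically have a handful of dominant
#' singular values followed by a flat noise floor.
#'
#' @param M numeric matrix (or [genotype_panel()], whose observed values
#'   are used with missing entries as 0).
#' @param k how many leading singular values; `k <= min(dim(M))`.
#' @return numeric vector of length `k`, descending.
#' @export
leading_singular_values <- function(M, k) {
  if (inherits(M, "genotype_panel")) {
    v <- M$values * 1.0
    v[M$values == M$missing_sentinel] <- 0
    M <- v
  }
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop_ri("leading_singular_values: non-finite entries")
  if (k > min(dim(M))) stop_ri("leading_singular_values: k exceeds min(dim)")
  svd(M, nu = 0, nv = 0)$d[seq_len(k)]
}
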