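#' Singular-value soft-thresholding
#'
#' Proximal operator of the nuclear norm: with SVD `M = U diag(s) V'`,
#' returns `U diag(max(s - threshold, 0)) V'`, keeping at most `rank_cap`
#' singular triplets. Shrinking every singular value toward zero is the
#' exact minimizer of `threshold * ||X||_* + 0.5 ||X - M||_F^2`.
#'
#' @param M real matrix with finite entries.
#' @param threshold nonnegative shrinkage amount.
#' @param rank_cap maximum number of singular triplets retained.
#' @return real matrix of the same shape.
#' @export
svt <- function(M, threshold, rank_cap = 100L) {
  if (!all(is.finite(M))) stop_ri("svt: matrix has non-finite entries")
  if (threshold < 0) stop_ri("svt: threshold must be nonnegative")
  if (rank_cap < 1L) stop_ri("svt: rank_cap must be >= 1")
  sv <- svd(M)
  d <- pmax(sv$d - threshold, 0)
  keep <- which(d > 0)
  if (length(keep) > rank_cap) keep <- keep[seq_len(rank_cap)]
  if (length(keep) == 0L) {
    return(matrix(0, nrow(M), ncol(M)))
  }
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Solver configuration for fixed-point continuation
#'
#' The completion model `min mu ||X||_* + 0.5 ||P_Omega(X - M)||_F^2` is
#' solved by proximal-gradient iterations `X <- svt(X - tau * P_Omega(X - M),
#' tau * mu)` while `mu` decreases geometrically (continuation) from the
#' spectral norm of the masked data down to `mu_final_ratio` times it.
#'
#' @param mu_final_ratio target regularization as a fraction of the initial
#'   `mu0 = ||P_Omega(M)||_2`; small values push the solution toward exact
#'   agreement with the observed entries.
#' @param eta continuation decay factor in (0,1); each stage sets
#'   `mu <- max(eta * mu, mu_final)`.
#' @param tau gradient step size; the masked-residual gradient has unit
#'   Lipschitz constant, so `tau = 1` is safe.
#' @param max_outer cap on continuation stages.
#' @param max_inner cap on proximal-gradient iterations per stage.
#' @param rel_tol relative objective-change stopping rule within a stage.
#' @param svd_rank_cap maximum rank retained per thresholding step.
#' @param center `"auto"` (default), `TRUE` or `FALSE`. When centering is
#'   on, observed per-column means are removed before completion and
#'   restored afterwards: allele-frequency differences between SNPs
#'   otherwise dominate the spectrum as a rank-1 component that the nuclear
#'   norm pays for instead of modelling sample structure, and centering
#'   makes "predict the column mean" the zero-cost default. `"auto"`
#'   centers genotype/haplotype panels but leaves bare numeric matrices
#'   uncentered (generic low-rank matrices carry no allele-frequency
#'   offset, and estimating spurious means from few observations degrades
#'   exact recovery).
#' @return An object of class `fpca_config`.
#' @export
fpca_config <- function(mu_final_ratio = 1e-4,
                        eta = 0.25,
                        tau = 1,
                        max_outer = 50L,
                        max_inner = 200L,
                        rel_tol = 1e-5,
                        svd_rank_cap = 100L,
                        center = "auto") {
  stopifnot(eta > 0, eta < 1, tau > 0, rel_tol > 0, svd_rank_cap >= 1L,
            mu_final_ratio > 0,
            is.logical(center) || identical(center, "auto"))
  structure(
    list(
      mu_final_ratio = mu_final_ratio, eta = eta, tau = tau,
      max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
      rel_tol = rel_tol, svd_rank_cap = as.integer(svd_rank_cap),
      center = center
    ),
    class = "fpca_config"
  )
}

fpca_objective <- function(X, M, mask, mu) {
  r <- X[mask] - M[mask]
  0.5 * sum(r * r) + mu * sum(svd(X, nu = 0, nv = 0)$d)
}

#' Nuclear-norm matrix completion by fixed-point continuation
#'
#' Completes the missing entries of `M` with the matrix of least nuclear
#' norm that (approximately) agrees with the observed entries. `M` may be a
#' [genotype_panel()] (its sentinel entries become the missing set) or a
#' numeric matrix paired with a logical `mask`.
#'
#' @param M numeric matrix or `genotype_panel`.
#' @param mask logical matrix, `TRUE` = observed. Derived from the panel
#'   when `M` is a panel.
#' @param cfg an [fpca_config()].
#' @return An object of class `completion_result`: `completed` (real
#'   matrix), `objective_history`, `iterations`, `converged`, and for the
#'   windowed variant `per_window_ranks`.
#' @export
fpca_complete <- function(M, mask = NULL, cfg = fpca_config()) {
  if (inherits(M, "genotype_panel")) {
    mask <- mask %||% mask_from_panel(M)
    M <- M$values
    if (identical(cfg$center, "auto")) cfg$center <- TRUE
  }
  if (identical(cfg$center, "auto")) cfg$center <- FALSE
  M <- unname(as.matrix(M)) * 1.0
  if (is.null(mask)) mask <- matrix(TRUE, nrow(M), ncol(M))
  stopifnot(identical(dim(mask), dim(M)))
  if (!any(mask)) stop_ri("fpca_complete: no observed entries")
  if (!all(is.finite(M[mask]))) stop_ri("fpca_complete: non-finite observed entries")

  col_means <- rep(0, ncol(M))
  if (isTRUE(cfg$center)) {
    overall <- mean(M[mask])
    col_means <- vapply(seq_len(ncol(M)), function(j) {
      obs <- mask[, j]
      if (any(obs)) mean(M[obs, j]) else overall
    }, numeric(1L))
    M <- sweep(M, 2L, col_means)
  }

  PM <- matrix(0, nrow(M), ncol(M))
  PM[mask] <- M[mask]
  mu0 <- svd(PM, nu = 0, nv = 0)$d[1L]
  if (mu0 == 0) { # all (centered) observed entries are zero: constant fill
    return(structure(
      list(completed = sweep(PM, 2L, col_means, "+"), objective_history = 0,
           objective_stage = integer(0), iterations = 0L, converged = TRUE,
           per_window_ranks = NULL),
      class = "completion_result"
    ))
  }
  mu_final <- cfg$mu_final_ratio * mu0
  mu <- mu0
  X <- PM
  history <- numeric(0)
  stages <- integer(0) # continuation stage of each recorded objective
  iters <- 0L
  converged <- FALSE
  for (stage in seq_len(cfg$max_outer)) {
    mu <- max(cfg$eta * mu, mu_final)
    obj_prev <- fpca_objective(X, M, mask, mu)
    bad_steps <- 0L
    for (it in seq_len(cfg$max_inner)) {
      G <- matrix(0, nrow(M), ncol(M))
      G[mask] <- X[mask] - M[mask]
      X <- svt(X - cfg$tau * G, cfg$tau * mu, cfg$svd_rank_cap)
      obj <- fpca_objective(X, M, mask, mu)
      history <- c(history, obj)
      stages <- c(stages, stage)
      iters <- iters + 1L
      if (obj > obj_prev + 1e-10 * max(1, abs(obj_prev))) {
        bad_steps <- bad_steps + 1L
        if (bad_steps >= cfg$max_inner) {
          stop_ri("fpca_complete: divergent objective at continuation stage ", stage)
        }
      }
      if (abs(obj_prev - obj) < cfg$rel_tol * max(1, abs(obj_prev))) {
        break
      }
      obj_prev <- obj
    }
    if (mu <= mu_final) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(completed = sweep(X, 2L, col_means, "+"), objective_history = history,
         objective_stage = stages, iterations = iters, converged = converged,
         per_window_ranks = NULL),
    class = "completion_result"
  )
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf(
    "completion_result: %d x %d, %d iterations, converged: %s\n",
    nrow(x$completed), ncol(x$completed), x$iterations, x$converged
  ))
  invisible(x)
}

#' Sliding-window geometry for windowed completion
#'
#' @param width columns per window.
#' @param overlap shared columns between consecutive windows,
#'   `0 <= overlap < width`.
#' @param stitch `"average_overlap"` (overlapping columns are averaged over
#'   the windows covering them) or `"left_priority"` (the earlier window's
#'   estimate wins).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 500L, overlap = 100L,
                        stitch = c("average_overlap", "left_priority")) {
  stitch <- match.arg(stitch)
  width <- as.integer(width)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= width) stop_ri("window_spec: need 0 <= overlap < width")
  structure(list(width = width, overlap = overlap, stitch = stitch),
            class = "window_spec")
}

# Column index ranges of the sliding windows covering m columns.
window_starts <- function(m, width, overlap) {
  if (width >= m) return(list(seq_len(m)))
  stride <- width - overlap
  starts <- seq(1L, m, by = stride)
  wins <- lapply(starts, function(s) s:min(s + width - 1L, m))
  # drop trailing windows fully contained in their predecessor
  keep <- c(TRUE, vapply(seq_along(wins)[-1L], function(i) {
    utils::tail(wins[[i]], 1L) > utils::tail(wins[[i - 1L]], 1L)
  }, logical(1L)))
  wins[keep]
}

numeric_rank <- function(X, tol_ratio = 1e-8) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (!length(d) || d[1L] == 0) return(0L)
  sum(d > tol_ratio * d[1L])
}

#' Windowed nuclear-norm completion (sliding-window scheme)
#'
#' Splits the SNP columns into overlapping windows, runs [fpca_complete()]
#' per window, and stitches the overlapping columns per the stitch rule.
#' Linkage disequilibrium makes genotype matrices low-rank *locally*, so
#' per-window completion trades a little accuracy for much less work on long
#' panels. With a single full-width window the result equals
#' [fpca_complete()] exactly.
#'
#' @inheritParams fpca_complete
#' @param window a [window_spec()].
#' @return A `completion_result` with `per_window_ranks` filled in.
#' @export
lrmc_s_complete <- function(M, mask = NULL, cfg = fpca_config(),
                            window = window_spec()) {
  if (inherits(M, "genotype_panel")) {
    mask <- mask %||% mask_from_panel(M)
    M <- M$values
    if (identical(cfg$center, "auto")) cfg$center <- TRUE
  }
  if (identical(cfg$center, "auto")) cfg$center <- FALSE
  M <- unname(as.matrix(M)) * 1.0
  if (is.null(mask)) mask <- matrix(TRUE, nrow(M), ncol(M))
  stopifnot(inherits(window, "window_spec"), identical(dim(mask), dim(M)))
  wins <- window_starts(ncol(M), window$width, window$overlap)
  if (length(wins) == 1L) {
    res <- fpca_complete(M, mask, cfg)
    res$per_window_ranks <- numeric_rank(res$completed)
    return(res)
  }
  acc <- matrix(0, nrow(M), ncol(M))
  cover <- matrix(0L, nrow(M), ncol(M))
  done <- rep(FALSE, ncol(M)) # left_priority bookkeeping
  history <- numeric(0)
  iters <- 0L
  converged <- TRUE
  ranks <- integer(length(wins))
  for (w in seq_along(wins)) {
    cols <- wins[[w]]
    res <- tryCatch(
      fpca_complete(M[, cols, drop = FALSE], mask[, cols, drop = FALSE], cfg),
      error = function(e) stop_ri("window ", w, " (columns ", cols[1L], "-",
                                  utils::tail(cols, 1L), "): ", conditionMessage(e))
    )
    ranks[w] <- numeric_rank(res$completed)
    history <- c(history, res$objective_history)
    iters <- iters + res$iterations
    converged <- converged && res$converged
    if (window$stitch == "average_overlap") {
      acc[, cols] <- acc[, cols] + res$completed
      cover[, cols] <- cover[, cols] + 1L
    } else {
      new_cols <- cols[!done[cols]]
      acc[, new_cols] <- res$completed[, match(new_cols, cols), drop = FALSE]
      cover[, new_cols] <- 1L
      done[new_cols] <- TRUE
    }
  }
  structure(
    list(completed = acc / cover, objective_history = history,
         iterations = iters, converged = converged, per_window_ranks = ranks),
    class = "completion_result"
  )
}
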