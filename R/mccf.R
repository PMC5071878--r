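#' Configuration for the co-clustering factorization solvers
#'
#' The model completes a data matrix `A` (n x m) through the factorization
#' `A ~ Y1 X Y2'` with row factor `Y1` (n x k1), central-point matrix `X`
#' (k1 x k2) and column factor `Y2` (m x k2), minimizing
#' `f = ||A - Y1 X Y2'||_F^2` subject to `A` agreeing with the observed
#' data. `k1` and `k2` bound the number of sample and SNP clusters and so
#' the rank of the completed matrix.
#'
#' @param k1 row-factor dimension (default 100).
#' @param k2 column-factor dimension (default 20); `1 <= k2 <= k1`.
#' @param rel_tol relative objective-change stopping rule across sweeps.
#' @param inner_tol stopping rule for the paired-block alternations used by
#'   BCU-1 and the maximum-block-improvement driver.
#' @param inner_cap iteration cap for those alternations.
#' @param max_sweeps cap on outer sweeps.
#' @param seed integer seed for the factor initialization.
#' @param init `"svd_warm"` (default: factors from a truncated SVD of the
#'   mean-filled data, deterministic and close to the best low-rank fit) or
#'   `"random_normal"` (entries of `Y1`, `Y2` drawn N(0, 1/k)). Random
#'   starts tend to stall in poorer stationary points when whole columns of
#'   the study block are missing.
#' @return An object of class `mccf_config`.
#' @export
mccf_config <- function(k1 = 100L, k2 = 20L,
                        rel_tol = 1e-5, inner_tol = 1e-6, inner_cap = 50L,
                        max_sweeps = 500L, seed = 1L,
                        init = c("svd_warm", "random_normal")) {
  init <- match.arg(init)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k2 < 1L || k2 > k1) stop_ri("mccf_config: need 1 <= k2 <= k1")
  stopifnot(rel_tol > 0, inner_tol > 0, max_sweeps >= 0L)
  structure(
    list(k1 = k1, k2 = k2, rel_tol = rel_tol, inner_tol = inner_tol,
         inner_cap = as.integer(inner_cap), max_sweeps = as.integer(max_sweeps),
         seed = as.integer(seed), init = init),
    class = "mccf_config"
  )
}

#' Factorization state
#'
#' Bundles the four blocks and the objective trace. Users normally obtain a
#' state from one of the drivers ([run_bcu1()] and friends) rather than
#' constructing one directly.
#'
#' @param A n x m completed-data block.
#' @param X k1 x k2 central-point matrix.
#' @param Y1 n x k1 row factor.
#' @param Y2 m x k2 column factor.
#' @param objective_history numeric vector of objective values.
#' @param sweep_count sweeps performed so far.
#' @return An object of class `mccf_state`.
#' @export
mccf_state <- function(A, X, Y1, Y2, objective_history = numeric(0),
                       sweep_count = 0L) {
  A <- as.matrix(A); X <- as.matrix(X); Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (nrow(Y1) != nrow(A) || nrow(Y2) != ncol(A) ||
      nrow(X) != ncol(Y1) || ncol(X) != ncol(Y2)) {
    stop_ri("mccf_state: inconsistent block shapes")
  }
  structure(
    list(A = A, X = X, Y1 = Y1, Y2 = Y2,
         k1 = ncol(Y1), k2 = ncol(Y2),
         objective_history = objective_history,
         sweep_count = as.integer(sweep_count)),
    class = "mccf_state"
  )
}

#' @export
print.mccf_state <- function(x, ...) {
  cat(sprintf(
    "mccf_state: A %d x %d, k1 = %d, k2 = %d, %d sweeps, objective %.6g\n",
    nrow(x$A), ncol(x$A), x$k1, x$k2, x$sweep_count,
    if (length(x$objective_history)) utils::tail(x$objective_history, 1L) else NA_real_
  ))
  invisible(x)
}

#' Factorization objective
#'
#' `f = ||A - Y1 X Y2'||_F^2`.
#'
#' @param state an [mccf_state()].
#' @return nonnegative scalar.
#' @export
mccf_objective <- function(state) {
  R <- state$A - state$Y1 %*% state$X %*% t(state$Y2)
  sum(R * R)
}

check_finite_blocks <- function(state) {
  if (!all(is.finite(state$X)) || !all(is.finite(state$Y1)) ||
      !all(is.finite(state$Y2)) || !all(is.finite(state$A))) {
    stop_ri("mccf: non-finite block encountered")
  }
}

#' Single-block updates
#'
#' Each update minimizes `f` exactly over one block with the others fixed:
#'
#' * `update_A`: observed positions of `A` are pinned to the data `M`;
#'   missing positions take the model value `(Y1 X Y2')[i,j]`, which zeroes
#'   their residual.
#' * `update_X`: minimum-norm least-squares solution
#'   `X = pinv(Y1) A pinv(Y2')`.
#' * `update_Y1`: with regressor `B = X Y2'`, `Y1 = A pinv(B)`.
#' * `update_Y2`: with regressor `C = Y1 X`, `Y2' = pinv(C) A`.
#'
#' Rank-deficient systems take the pseudo-inverse (minimum-norm) solution,
#' so every update is an exact block minimizer and the objective can never
#' increase.
#'
#' @param state an [mccf_state()].
#' @param M numeric matrix of observed data.
#' @param mask logical matrix, `TRUE` = observed.
#' @return the updated `mccf_state`.
#' @export
update_A <- function(state, M, mask) {
  model <- state$Y1 %*% state$X %*% t(state$Y2)
  A <- model
  A[mask] <- M[mask]
  state$A <- A
  state
}

#' @rdname update_A
#' @export
update_X <- function(state) {
  check_finite_blocks(state)
  state$X <- pinv(state$Y1) %*% state$A %*% t(pinv(state$Y2))
  state
}

#' @rdname update_A
#' @export
update_Y1 <- function(state) {
  check_finite_blocks(state)
  B <- state$X %*% t(state$Y2) # k1 x m
  state$Y1 <- state$A %*% pinv(B)
  state
}

#' @rdname update_A
#' @export
update_Y2 <- function(state) {
  check_finite_blocks(state)
  C <- state$Y1 %*% state$X # n x k2
  state$Y2 <- t(pinv(C) %*% state$A)
  state
}

# Initial state: A = M with missing entries set to the column mean of the
# observed values (all-missing columns fall back to the overall mean); Y1,
# Y2 seeded N(0, 1/k); X from its closed-form update.
mccf_init <- function(M, mask, cfg) {
  n <- nrow(M); m <- ncol(M)
  if (!any(mask)) stop_ri("mccf: no observed entries")
  if (cfg$k1 > n) {
    warning("mccf: k1 = ", cfg$k1, " exceeds the number of samples ", n)
  }
  A <- M * 1.0
  overall <- mean(M[mask])
  for (j in seq_len(m)) {
    mis <- !mask[, j]
    if (any(mis)) {
      obs <- mask[, j]
      A[mis, j] <- if (any(obs)) mean(M[obs, j]) else overall
    }
  }
  st <- with_seed(cfg$seed, {
    if (cfg$init == "svd_warm") {
      r1 <- min(cfg$k1, n, m)
      r2 <- min(cfg$k2, n, m)
      sv <- svd(A, nu = r1, nv = r2)
      Y1 <- matrix(0, n, cfg$k1)
      Y1[, seq_len(r1)] <- sv$u
      Y2 <- matrix(0, m, cfg$k2)
      Y2[, seq_len(r2)] <- sv$v
    } else {
      Y1 <- matrix(rnorm(n * cfg$k1, sd = 1 / sqrt(cfg$k1)), n, cfg$k1)
      Y2 <- matrix(rnorm(m * cfg$k2, sd = 1 / sqrt(cfg$k2)), m, cfg$k2)
    }
    mccf_state(A, matrix(0, cfg$k1, cfg$k2), Y1, Y2)
  })
  st <- update_X(st)
  st$objective_history <- mccf_objective(st)
  st
}

record_obj <- function(state, slack = 1e-10) {
  obj <- mccf_objective(state)
  prev <- utils::tail(state$objective_history, 1L)
  if (length(prev) && obj > prev + slack * max(1, prev)) {
    stop_ri(sprintf(
      "mccf internal error: objective increased from %.12g to %.12g", prev, obj
    ))
  }
  state$objective_history <- c(state$objective_history, obj)
  state
}

# Alternate the two updates of a paired block until the objective stops
# moving (inner_tol) or inner_cap is reached. `funs` is a list of update
# closures taking and returning a state.
alternate_pair <- function(state, funs, cfg, record = TRUE) {
  prev <- mccf_objective(state)
  for (i in seq_len(cfg$inner_cap)) {
    for (f in funs) {
      state <- f(state)
      if (record) state <- record_obj(state)
    }
    obj <- mccf_objective(state)
    if (abs(prev - obj) < cfg$inner_tol * max(1, prev)) break
    prev <- obj
  }
  state
}

# Relative-change stopping rule on the per-sweep objective values v_k.
stop_sweeps <- function(v_prev, v_new, rel_tol) {
  abs(v_prev - v_new) < rel_tol * max(1, abs(v_prev))
}

mccf_prepare <- function(M, mask, cfg) {
  if (inherits(M, "genotype_panel")) {
    mask <- mask %||% mask_from_panel(M)
    M <- M$values
  }
  M <- unname(as.matrix(M)) * 1.0
  if (is.null(mask)) mask <- matrix(TRUE, nrow(M), ncol(M))
  stopifnot(identical(dim(mask), dim(M)))
  list(M = M, mask = mask)
}

#' Block-coordinate drivers for the co-clustering factorization
#'
#' All four drivers minimize `f = ||A - Y1 X Y2'||_F^2` with `A` pinned to
#' the observed data, and differ only in how the blocks are scheduled:
#'
#' * `run_bcu1`: paired blocks `(A-X) -> (Y1-X) -> (Y2-X)`, each pair
#'   alternated until its objective stalls.
#' * `run_bcu2`: single-block order `A -> X -> Y1 -> X -> Y2` (X twice per
#'   sweep).
#' * `run_bcu3`: order `A -> X -> Y1 -> X -> Y2 -> X` (X three times).
#' * `run_mbi_bl`: per sweep, the paired updates `(Y1-X)`, `(Y2-X)`,
#'   `(A-X)` and the lone `X` update are each attempted from the current
#'   state; only the candidate achieving the smallest objective is
#'   committed (maximum block improvement; ties go to the first candidate
#'   in that fixed order).
#'
#' Sweeps stop when the relative objective change drops below
#' `cfg$rel_tol` or `cfg$max_sweeps` is reached. Since every block update
#' is an exact minimizer, the recorded objective history is non-increasing;
#' an increase beyond numerical slack raises an internal error.
#'
#' @param M numeric matrix or [genotype_panel()]; its missing entries are
#'   the ones to complete.
#' @param mask logical matrix, `TRUE` = observed; derived from the panel
#'   when `M` is a panel.
#' @param cfg an [mccf_config()].
#' @return An [mccf_state()]; `state$A` is the completed matrix (exactly
#'   equal to the data on observed entries).
#' @export
run_bcu1 <- function(M, mask = NULL, cfg = mccf_config()) {
  d <- mccf_prepare(M, mask, cfg)
  state <- mccf_init(d$M, d$mask, cfg)
  upd_A <- function(s) update_A(s, d$M, d$mask)
  v_prev <- mccf_objective(state)
  for (sweep in seq_len(cfg$max_sweeps)) {
    state <- alternate_pair(state, list(upd_A, update_X), cfg)
    state <- alternate_pair(state, list(update_Y1, update_X), cfg)
    state <- alternate_pair(state, list(update_Y2, update_X), cfg)
    state$sweep_count <- sweep
    v_new <- mccf_objective(state)
    if (stop_sweeps(v_prev, v_new, cfg$rel_tol)) break
    v_prev <- v_new
  }
  state
}

#' @rdname run_bcu1
#' @export
run_bcu2 <- function(M, mask = NULL, cfg = mccf_config()) {
  d <- mccf_prepare(M, mask, cfg)
  state <- mccf_init(d$M, d$mask, cfg)
  v_prev <- mccf_objective(state)
  for (sweep in seq_len(cfg$max_sweeps)) {
    state <- record_obj(update_A(state, d$M, d$mask))
    state <- record_obj(update_X(state))
    state <- record_obj(update_Y1(state))
    state <- record_obj(update_X(state))
    state <- record_obj(update_Y2(state))
    state$sweep_count <- sweep
    v_new <- mccf_objective(state)
    if (stop_sweeps(v_prev, v_new, cfg$rel_tol)) break
    v_prev <- v_new
  }
  state
}

#' @rdname run_bcu1
#' @export
run_bcu3 <- function(M, mask = NULL, cfg = mccf_config()) {
  d <- mccf_prepare(M, mask, cfg)
  state <- mccf_init(d$M, d$mask, cfg)
  v_prev <- mccf_objective(state)
  for (sweep in seq_len(cfg$max_sweeps)) {
    state <- record_obj(update_A(state, d$M, d$mask))
    state <- record_obj(update_X(state))
    state <- record_obj(update_Y1(state))
    state <- record_obj(update_X(state))
    state <- record_obj(update_Y2(state))
    state <- record_obj(update_X(state))
    state$sweep_count <- sweep
    v_new <- mccf_objective(state)
    if (stop_sweeps(v_prev, v_new, cfg$rel_tol)) break
    v_prev <- v_new
  }
  state
}

#' @rdname run_bcu1
#' @export
run_mbi_bl <- function(M, mask = NULL, cfg = mccf_config()) {
  d <- mccf_prepare(M, mask, cfg)
  state <- mccf_init(d$M, d$mask, cfg)
  upd_A <- function(s) update_A(s, d$M, d$mask)
  v_prev <- mccf_objective(state)
  for (sweep in seq_len(cfg$max_sweeps)) {
    candidates <- mbi_candidates(state, upd_A, cfg)
    w <- vapply(candidates, mccf_objective, numeric(1L))
    best <- which.min(w) # ties: first candidate in the fixed order
    state <- candidates[[best]]
    state <- record_obj(state)
    state$sweep_count <- sweep
    if (stop_sweeps(v_prev, w[best], cfg$rel_tol)) break
    v_prev <- w[best]
  }
  state
}

# The four tentative block moves attempted per maximum-block-improvement
# sweep, in the fixed tie-break order (Y1-X), (Y2-X), (A-X), X alone.
mbi_candidates <- function(state, upd_A, cfg) {
  list(
    alternate_pair(state, list(update_Y1, update_X), cfg, record = FALSE),
    alternate_pair(state, list(update_Y2, update_X), cfg, record = FALSE),
    alternate_pair(state, list(upd_A, update_X), cfg, record = FALSE),
    update_X(state)
  )
}
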