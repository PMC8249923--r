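#' Log-transform a secretome matrix
#'
#' Entrywise `ln(max(value, detection_floor))`; the floor acts as a
#' pseudocount so zero concentrations are defined on the log scale. Missing
#' entries stay missing.
#'
#' @param x A [secretome_matrix()].
#' @return A plain numeric matrix of log concentrations (ln pg/mL), same
#'   dimnames, with the detection floor carried as an attribute.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "secretome_matrix"))
  floorv <- attr(x, "detection_floor")
  out <- log(pmax(unclass(x), floorv))
  attr(out, "detection_floor") <- floorv
  class(out) <- c("matrix", "array")
  out
}

#' Impute missing log concentrations by iterative truncated SVD
#'
#' Missing entries are initialized to their row means, then repeatedly
#' replaced by the rank-`rank` truncated-SVD reconstruction of the completed
#' matrix until the largest relative change of any imputed entry falls below
#' `tol` or `max_iter` is reached. Observed entries are never altered.
#'
#' @param lnX Numeric matrix (log scale) with `NA` for missing entries; every
#'   row and column must have at least one observed entry.
#' @param rank Truncation rank; default `min(5, min(dim) - 1)`.
#' @param tol Convergence tolerance on the relative change of imputed values.
#' @param max_iter Iteration cap; non-convergence sets the `converged`
#'   attribute to `FALSE` rather than raising an error.
#' @return The completed matrix with attributes `converged`, `iterations`,
#'   and `imputed` (logical mask of imputed cells).
#' @export
impute_missing_svd <- function(lnX, rank = NULL, tol = 1e-6, max_iter = 500L) {
  lnX <- as.matrix(lnX)
  if (is.null(rank)) rank <- max(1L, min(5L, min(dim(lnX)) - 1L))
  stopifnot(rank >= 1, rank <= min(dim(lnX)), tol > 0, max_iter >= 1)
  miss <- is.na(lnX)
  if (!any(miss)) {
    attr(lnX, "converged") <- TRUE
    attr(lnX, "iterations") <- 0L
    attr(lnX, "imputed") <- miss
    return(lnX)
  }
  bad_row <- rowSums(!miss) == 0L
  bad_col <- colSums(!miss) == 0L
  if (any(bad_row) || any(bad_col)) {
    stop(sprintf("all-missing %s: %s",
                 if (any(bad_row)) "row(s)" else "column(s)",
                 paste(if (any(bad_row)) rownames(lnX)[bad_row]
                       else colnames(lnX)[bad_col], collapse = ", ")),
         call. = FALSE)
  }
  cur <- lnX
  rmeans <- rowMeans(lnX, na.rm = TRUE)
  cur[miss] <- rmeans[row(lnX)[miss]]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    s <- svd(cur, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    newv <- recon[miss]
    delta <- max(abs(newv - cur[miss])) / max(max(abs(cur[miss])), 1e-12)
    cur[miss] <- newv
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(cur, "converged") <- converged
  attr(cur, "iterations") <- it
  attr(cur, "imputed") <- miss
  cur
}

#' Surprisal decomposition of a log-concentration matrix
#'
#' Computes the SVD of the completed log matrix and reads its components as
#' the surprisal decomposition: the leading component (alpha = 0) is the
#' steady-state term and each further component alpha >= 1 is an unbalanced
#' process with cytokine weights `G[, alpha]` (left singular vector) and
#' sample amplitudes `lambda[alpha, ]` (singular value times right singular
#' vector). Every component's sign is fixed so its largest-|weight| cytokine
#' has a positive weight; SVD signs are otherwise arbitrary.
#'
#' @param lnX Numeric matrix of log concentrations, no missing entries
#'   (run [impute_missing_svd()] first), at least 2 samples.
#' @return A `surprisal_decomposition` with fields `G` (cytokines x
#'   components), `lambda` (components x samples), `singular_values`,
#'   `steady_state_log`, `cytokine_ids`, `sample_ids`; `K_significant`,
#'   `noise_sd_est` and `null_q95` are `NA` until
#'   [count_significant_processes()] fills them. Component columns/rows are
#'   labeled `alpha0`, `alpha1`, ...
#' @export
surprisal_decompose <- function(lnX) {
  lnX <- as.matrix(lnX)
  if (anyNA(lnX)) {
    stop("lnX has missing entries; run impute_missing_svd() first",
         call. = FALSE)
  }
  if (ncol(lnX) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- svd(lnX)
  G <- s$u
  lambda <- s$d * t(s$v)
  for (a in seq_len(ncol(G))) {
    i <- which.max(abs(G[, a]))
    if (G[i, a] < 0) {
      G[, a] <- -G[, a]
      lambda[a, ] <- -lambda[a, ]
    }
  }
  comp <- paste0("alpha", seq_len(ncol(G)) - 1L)
  cyt <- rownames(lnX) %||% sprintf("CK%02d", seq_len(nrow(lnX)))
  smp <- colnames(lnX) %||% sprintf("S%02d", seq_len(ncol(lnX)))
  dimnames(G) <- list(cyt, comp)
  dimnames(lambda) <- list(comp, smp)
  structure(list(
    cytokine_ids = cyt, sample_ids = smp,
    G = G, lambda = lambda, singular_values = s$d,
    steady_state_log = outer(G[, 1L], lambda[1L, ]),
    K_significant = NA_integer_, noise_sd_est = NA_real_,
    null_q95 = NA_real_
  ), class = "surprisal_decomposition")
}

#' @export
print.surprisal_decomposition <- function(x, ...) {
  cat(sprintf("surprisal_decomposition: %d cytokines x %d samples, %d components\n",
              length(x$cytokine_ids), length(x$sample_ids),
              ncol(x$G)))
  if (!is.na(x$K_significant)) {
    cat(sprintf("  significant unbalanced processes: %d (null 95th pct %.4g, noise sd %.4g)\n",
                x$K_significant, x$null_q95, x$noise_sd_est))
  }
  invisible(x)
}

#' Pooled log-scale noise SD from replicate fragments
#'
#' Pools the per-cytokine, per-group (animal) sample variances of the log
#' concentrations: replicate explant fragments of one tumor differ only by
#' measurement/biological noise, so their pooled SD estimates the log-scale
#' noise floor.
#'
#' @param lnX Log-concentration matrix (may contain `NA`).
#' @param groups Factor/character of length `ncol(lnX)` grouping replicate
#'   samples (e.g. the metadata's `animal_id`).
#' @return Pooled SD (single number).
#' @export
estimate_noise_sd <- function(lnX, groups) {
  lnX <- as.matrix(lnX)
  stopifnot(length(groups) == ncol(lnX))
  groups <- as.character(groups)
  ss <- 0; df <- 0
  for (g in unique(groups)) {
    sub <- lnX[, groups == g, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    v <- apply(sub, 1L, stats::var, na.rm = TRUE)
    ok <- n_obs >= 2L & !is.na(v)
    ss <- ss + sum(v[ok] * (n_obs[ok] - 1L))
    df <- df + sum(n_obs[ok] - 1L)
  }
  if (df == 0) stop("no group has >= 2 observed replicates", call. = FALSE)
  sqrt(ss / df)
}

#' Count significant unbalanced processes by a Monte-Carlo noise null
#'
#' A process alpha >= 1 is called significant when its largest absolute
#' amplitude over samples, `max_k |lambda_alpha(k)|`, exceeds the 95th
#' percentile of the same statistic computed from `n_boot` pure-noise
#' matrices of the same shape (i.i.d. Gaussian on the log scale with the
#' given or estimated noise SD). The null statistic takes the max over all
#' noise components: the data's steady-state term absorbs none of the
#' noise, so the full noise spectrum — including its largest component —
#' leaks into the deviation components. With `noise_sd = 0` the null is the
#' numerical floor, so exactly the non-degenerate components are counted.
#'
#' @param result A [surprisal_decompose()] result.
#' @param noise_sd Log-scale noise SD; a number, or `"estimate"` to pool it
#'   from replicate `groups` via [estimate_noise_sd()].
#' @param groups Replicate grouping of samples, required when
#'   `noise_sd = "estimate"`.
#' @param n_boot Number of noise matrices (>= 10).
#' @param q Null quantile (default 0.95).
#' @param seed Seed for the noise draws.
#' @return The decomposition with `K_significant`, `noise_sd_est` and
#'   `null_q95` filled in.
#' @export
count_significant_processes <- function(result, noise_sd = "estimate",
                                        groups = NULL, n_boot = 200L,
                                        q = 0.95, seed = 1L) {
  stopifnot(inherits(result, "surprisal_decomposition"))
  if (n_boot < 10L) stop("n_boot must be >= 10", call. = FALSE)
  n <- length(result$cytokine_ids)
  m <- length(result$sample_ids)
  if (identical(noise_sd, "estimate")) {
    if (is.null(groups)) {
      stop("noise_sd = \"estimate\" needs replicate `groups`", call. = FALSE)
    }
    lnX <- result$G %*% result$lambda
    noise_sd <- estimate_noise_sd(lnX, groups)
  }
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  if (noise_sd > 0) {
    set.seed(seed)
    null_stat <- vapply(seq_len(n_boot), function(b) {
      N <- matrix(stats::rnorm(n * m, 0, noise_sd), n)
      s <- svd(N, nu = 0)
      max(abs(s$d * t(s$v)))
    }, numeric(1))
    thr <- stats::quantile(null_stat, q, names = FALSE)
  } else {
    thr <- 0
  }
  # numerical floor: components whose amplitude is only round-off never count
  thr <- max(thr, 1e-8 * result$singular_values[1L])
  dev <- result$lambda[-1L, , drop = FALSE]
  K <- if (nrow(dev)) sum(apply(abs(dev), 1L, max) > thr) else 0L
  result$K_significant <- as.integer(K)
  result$noise_sd_est <- noise_sd
  result$null_q95 <- thr
  result
}

#' Call the cytokine membership of one unbalanced process
#'
#' The participation baseline is the mean |G| of the `quantile` fraction of
#' cytokines with the smallest |G| in this process (at least one cytokine,
#' `floor()` count, ties broken by cytokine order); members are the
#' cytokines whose |G| is at least `fold` times that baseline. Member
#' weights keep their signs: opposite signs mean the process moves those
#' cytokines in opposite directions.
#'
#' @param result A [surprisal_decompose()] result.
#' @param alpha Process index >= 1 (0 is the steady state and has no
#'   membership).
#' @param fold Fold-over-baseline cutoff (default 20).
#' @param quantile Fraction of lowest-|G| cytokines forming the baseline
#'   (default 0.20).
#' @return An `unbalanced_process` with `member_ids` and `member_weights`
#'   filled.
#' @export
process_membership <- function(result, alpha, fold = 20, quantile = 0.20) {
  stopifnot(inherits(result, "surprisal_decomposition"))
  .check_alpha(result, alpha)
  stopifnot(fold > 0, quantile > 0, quantile <= 1)
  g <- result$G[, alpha + 1L]
  n_low <- max(1L, floor(quantile * length(g)))
  baseline <- mean(sort(abs(g), method = "radix")[seq_len(n_low)])
  members <- abs(g) >= fold * baseline
  structure(list(
    alpha = as.integer(alpha),
    member_ids = result$cytokine_ids[members],
    member_weights = g[members],
    fold = fold, quantile = quantile, baseline = baseline,
    activity_threshold = NULL, activity_calls = NULL,
    sample_ids = result$sample_ids,
    lambda = result$lambda[alpha + 1L, ]
  ), class = "unbalanced_process")
}

.check_alpha <- function(result, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha != round(alpha)) {
    stop("alpha must be a single integer", call. = FALSE)
  }
  if (alpha == 0) {
    stop("alpha = 0 is the steady state; it has no membership or activity",
         call. = FALSE)
  }
  if (alpha < 1 || alpha > ncol(result$G) - 1L) {
    stop(sprintf("alpha must be in 1..%d", ncol(result$G) - 1L),
         call. = FALSE)
  }
  invisible(alpha)
}

#' Call per-sample activity of one unbalanced process
#'
#' A sample is `active_positive` when its amplitude exceeds `threshold`,
#' `active_negative` below `-threshold`, otherwise `inactive`. Samples
#' active in the same direction are influenced by the process in the same
#' way. `threshold = "auto"` reuses the Monte-Carlo null 95th percentile
#' stored by [count_significant_processes()].
#'
#' @param result A [surprisal_decompose()] result.
#' @param alpha Process index >= 1.
#' @param threshold Positive amplitude threshold, or `"auto"`.
#' @param process Optionally an existing [process_membership()] result for
#'   the same alpha to fill the activity fields on.
#' @return An `unbalanced_process` with `activity_threshold` and
#'   `activity_calls` filled.
#' @export
process_activity <- function(result, alpha, threshold = "auto",
                             process = NULL) {
  stopifnot(inherits(result, "surprisal_decomposition"))
  .check_alpha(result, alpha)
  if (identical(threshold, "auto")) {
    if (is.na(result$null_q95)) {
      stop("threshold = \"auto\" needs count_significant_processes() first",
           call. = FALSE)
    }
    threshold <- result$null_q95
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  lam <- result$lambda[alpha + 1L, ]
  calls <- ifelse(lam > threshold, "active_positive",
                  ifelse(lam < -threshold, "active_negative", "inactive"))
  names(calls) <- result$sample_ids
  if (is.null(process)) {
    process <- structure(list(
      alpha = as.integer(alpha), member_ids = NULL, member_weights = NULL,
      fold = NULL, quantile = NULL, baseline = NULL,
      activity_threshold = NULL, activity_calls = NULL,
      sample_ids = result$sample_ids, lambda = lam
    ), class = "unbalanced_process")
  } else {
    stopifnot(inherits(process, "unbalanced_process"),
              process$alpha == alpha)
  }
  process$activity_threshold <- threshold
  process$activity_calls <- calls
  process
}

#' @export
print.unbalanced_process <- function(x, ...) {
  cat(sprintf("unbalanced process %d\n", x$alpha))
  if (!is.null(x$member_ids)) {
    cat(sprintf("  members (%d): %s\n", length(x$member_ids),
                paste(sprintf("%s(%+.3f)", x$member_ids, x$member_weights),
                      collapse = ", ")))
  }
  if (!is.null(x$activity_calls)) {
    tab <- table(factor(x$activity_calls,
                        c("active_positive", "active_negative", "inactive")))
    cat(sprintf("  activity at |lambda| > %.4g: %d +, %d -, %d inactive\n",
                x$activity_threshold, tab[1L], tab[2L], tab[3L]))
  }
  invisible(x)
}

#' Reconstruct log concentrations from the leading processes
#'
#' Steady state plus the first `n_processes` unbalanced processes;
#' `n_processes = 0` gives the steady-state-only (rank-1) matrix and keeping
#' all components reproduces the input exactly.
#'
#' @param result A [surprisal_decompose()] result.
#' @param n_processes Number of processes alpha >= 1 to include,
#'   `0 <= n_processes <= components - 1`.
#' @return Numeric matrix of reconstructed log concentrations.
#' @export
reconstruct <- function(result, n_processes) {
  stopifnot(inherits(result, "surprisal_decomposition"),
            n_processes >= 0, n_processes <= ncol(result$G) - 1L)
  idx <- seq_len(n_processes + 1L)
  result$G[, idx, drop = FALSE] %*% result$lambda[idx, , drop = FALSE]
}

#' Principal angles between two column spaces
#'
#' Utility for parameter-recovery checks: the principal angles between the
#' subspaces spanned by the columns of `A` and `B` (degrees). All angles
#' near 0 mean the spaces coincide; comparisons are sign- and
#' rotation-agnostic.
#'
#' @param A,B Matrices with the same number of rows.
#' @return Numeric vector of `min(ncol(A), ncol(B))` angles in degrees.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  cosv <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  theta <- acos(pmin(pmax(cosv, -1), 1))
  # acos loses resolution below ~sqrt(eps); recompute small angles from sines
  small <- cosv > 0.7
  if (any(small)) {
    sinv <- sort(svd(qb - qa %*% crossprod(qa, qb), nu = 0, nv = 0)$d)
    theta[small] <- asin(pmin(sinv[seq_len(sum(small))], 1))
  }
  theta * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
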