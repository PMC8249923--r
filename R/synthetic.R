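#' Define a planted-truth scenario for synthetic secretome data
#'
#' Builds the ground truth for a synthetic explant experiment that follows
#' the generative form of the surprisal decomposition: per-cytokine baseline
#' log concentrations, `k_true` mutually orthogonal planted weight columns
#' (cytokines x process) and orthogonal amplitude rows (process x sample),
#' plus log-normal measurement noise. Weight columns are drawn orthogonal to
#' the baseline direction and amplitude rows orthogonal to the constant
#' sample vector, so that with zero noise an SVD of the log matrix recovers
#' the planted structure exactly.
#'
#' The default scenario emulates a four-model explant study: 30 analytes
#' across 48 explants (4 tumor models x 3 animals x 4 treatment arms), four
#' planted processes, log-scale noise SD 0.1, and process amplitudes scaled
#' to 10x the noise (per-entry RMS), with a mild geometric decay across
#' processes so their singular values are distinct.
#'
#' @param n_cytokines,n_samples Matrix dimensions.
#' @param k_true Number of planted unbalanced processes (>= 0).
#' @param noise_sd Log-scale SD of i.i.d. Gaussian measurement noise (>= 0).
#' @param snr Amplitude scale: per-entry RMS of each process's contribution
#'   to the log matrix, in units of `noise_sd`.
#' @param missing_fraction Fraction of entries masked as missing, in [0, 1).
#' @param baseline_log_mean,baseline_log_sd Distribution of per-cytokine
#'   steady-state log concentrations (ln pg/mL).
#' @param infiltrate_link Named list mapping a planted process index
#'   (as character, e.g. `"1"`) to the population ids driven by it.
#' @param seed Integer seed; every draw derives from it.
#' @return A `synthetic_truth` list with fields `baseline_log_levels`,
#'   `planted_G`, `planted_lambda`, plus all scenario parameters.
#' @export
synthetic_truth <- function(n_cytokines = 30, n_samples = 48, k_true = 4,
                            noise_sd = 0.1, snr = 10, missing_fraction = 0,
                            baseline_log_mean = log(100), baseline_log_sd = 1,
                            infiltrate_link = list(), seed = 1L) {
  # weight columns must fit orthogonal to the baseline and constant
  # directions, amplitude rows orthogonal to the constant sample vector
  stopifnot(n_cytokines >= 2, n_samples >= 2, k_true >= 0,
            k_true <= n_cytokines - 2, k_true <= n_samples - 1,
            noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  if (length(infiltrate_link)) {
    idx <- as.integer(names(infiltrate_link))
    if (anyNA(idx) || any(idx < 1L | idx > k_true)) {
      stop("infiltrate_link names must be planted process indices in 1..k_true",
           call. = FALSE)
    }
  }
  set.seed(seed)
  b <- stats::rnorm(n_cytokines, baseline_log_mean, baseline_log_sd)
  if (k_true > 0) {
    # weight columns orthonormal and orthogonal to both the baseline
    # direction and the constant vector, so a global concentration rescale
    # (which shifts lnX along 1x1') cannot leak into the planted processes
    G <- qr.Q(qr(cbind(b, rep(1, n_cytokines),
                       matrix(stats::rnorm(n_cytokines * k_true),
                              n_cytokines))))[, -(1:2), drop = FALSE]
    # amplitude directions orthonormal and orthogonal to the constant vector
    V <- qr.Q(qr(cbind(rep(1, n_samples),
                       matrix(stats::rnorm(n_samples * k_true),
                              n_samples))))[, -1L, drop = FALSE]
    # per-entry RMS of process a's term is scale[a]/sqrt(n*m); decay keeps
    # singular values distinct so component order is stable
    decay <- if (k_true == 1) 1 else seq(1, 0.8, length.out = k_true)
    scale <- snr * max(noise_sd, 1e-3) *
      sqrt(n_cytokines * n_samples) * decay
    lambda <- t(V) * scale
  } else {
    G <- matrix(0, n_cytokines, 0)
    lambda <- matrix(0, 0, n_samples)
  }
  cyt <- sprintf("CK%02d", seq_len(n_cytokines))
  smp <- sprintf("S%02d", seq_len(n_samples))
  dimnames(G) <- list(cyt, if (k_true) paste0("process", seq_len(k_true)))
  dimnames(lambda) <- list(if (k_true) paste0("process", seq_len(k_true)), smp)
  names(b) <- cyt
  structure(list(
    n_cytokines = n_cytokines, n_samples = n_samples, k_true = k_true,
    baseline_log_levels = b, planted_G = G, planted_lambda = lambda,
    noise_sd = noise_sd, snr = snr, missing_fraction = missing_fraction,
    infiltrate_link = infiltrate_link, seed = as.integer(seed),
    cytokine_ids = cyt, sample_ids = smp
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d cytokines x %d samples, %d planted process(es), noise_sd %g, seed %d\n",
    x$n_cytokines, x$n_samples, x$k_true, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic secretome matrix from a planted truth
#'
#' Concentrations are `exp(baseline + planted_G %*% planted_lambda + noise)`
#' with i.i.d. Gaussian noise on the log scale (multiplicative log-normal on
#' concentrations, as in multiplex bead assays), after which
#' `missing_fraction` of the entries is masked at random. Fully reproducible
#' from the truth's seed; the noise/mask stream is offset from the stream
#' that drew the planted structure so the two are independent.
#'
#' @param truth A [synthetic_truth()].
#' @param detection_floor Detection floor recorded on the output matrix. The
#'   default sits below the generated dynamic range so that taking logs is
#'   exact and the planted model is recovered unclipped; real multiplex
#'   panels floor at ~1 pg/mL, which callers set when reading real data.
#' @return A list with `secretome` (a [secretome_matrix()]) and `truth`.
#' @export
gen_secretome <- function(truth, detection_floor = 1e-4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$n_cytokines; m <- truth$n_samples
  set.seed(truth$seed + 1L)
  lnX <- outer(truth$baseline_log_levels, rep(1, m))
  if (truth$k_true > 0) lnX <- lnX + truth$planted_G %*% truth$planted_lambda
  if (truth$noise_sd > 0) lnX <- lnX + matrix(stats::rnorm(n * m, 0, truth$noise_sd), n)
  X <- exp(lnX)
  if (truth$missing_fraction > 0) {
    n_mask <- floor(truth$missing_fraction * n * m)
    X[sample.int(n * m, n_mask)] <- NA_real_
  }
  dimnames(X) <- list(truth$cytokine_ids, truth$sample_ids)
  list(secretome = secretome_matrix(X, detection_floor = detection_floor),
       truth = truth)
}

#' Generate a synthetic infiltrate table linked to planted processes
#'
#' Populations named in `truth$infiltrate_link` are affine transforms of the
#' linked process's planted amplitude plus Gaussian noise, calibrated so the
#' expected Pearson correlation with that amplitude is `target_r`
#' (`sd(noise) = sd(amplitude) * sqrt(1/r^2 - 1)`). Unlinked populations are
#' independent log-normal draws. All values are clipped at 0.
#'
#' @param truth A [synthetic_truth()] (its `infiltrate_link` is used).
#' @param populations Population ids for the table rows.
#' @param target_r Target Pearson correlation in (-1, 1) for linked
#'   populations; `0` makes a nominally linked population behave unlinked.
#' @param abundance_mean,abundance_scale Location and scale of the affine
#'   transform to count-like abundances (also the log-normal location/spread
#'   for unlinked rows).
#' @param seed Seed for this draw; defaults to `truth$seed + 2`.
#' @return An [infiltrate_table()] with the truth's sample ids.
#' @export
gen_infiltrates <- function(truth,
                            populations = c("CD4", "CD8", "CD90.2", "TAM",
                                            "Monocyte", "Neutrophil",
                                            "DC1", "DC2", "Treg"),
                            target_r = 0.9,
                            abundance_mean = 500, abundance_scale = 100,
                            seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  m <- truth$n_samples
  link_of <- character(0)
  for (a in names(truth$infiltrate_link)) {
    for (p in truth$infiltrate_link[[a]]) link_of[p] <- a
  }
  set.seed(seed)
  vals <- matrix(NA_real_, length(populations), m,
                 dimnames = list(populations, truth$sample_ids))
  for (p in populations) {
    if (p %in% names(link_of) && target_r != 0) {
      a <- as.integer(link_of[[p]])
      lam <- truth$planted_lambda[a, ]
      z <- sign(target_r) * (lam - mean(lam)) / stats::sd(lam)
      tau <- sqrt(1 / target_r^2 - 1)
      y <- z + stats::rnorm(m, 0, tau)
      vals[p, ] <- abundance_mean + abundance_scale * y
    } else {
      vals[p, ] <- stats::rlnorm(m, log(abundance_mean), 0.5)
    }
  }
  vals[vals < 0] <- 0
  infiltrate_table(vals, unit = "count")
}

#' Generate metadata for the default explant design
#'
#' Lays the samples of a synthetic truth out as tumor models x animals x
#' treatment arms (consecutive samples of one animal are its replicate
#' fragments, one per arm block).
#'
#' @param truth A [synthetic_truth()].
#' @param models Tumor model labels.
#' @param arms Treatment arms (subset of [TREATMENTS]).
#' @return A validated metadata data.frame covering all samples.
#' @export
gen_metadata <- function(truth,
                         models = c("Moc1", "Moc2", "TC1", "SCC-VII"),
                         arms = c("untreated", "anti-PD1", "anti-CTLA4",
                                  "anti-OX40")) {
  m <- truth$n_samples
  n_animals <- max(1L, ceiling(m / length(arms) / length(models)))
  grid <- expand.grid(arm = arms,
                      animal = seq_len(n_animals),
                      model = models,
                      stringsAsFactors = FALSE)
  grid <- grid[seq_len(m), , drop = FALSE]
  sample_metadata(data.frame(
    sample_id = truth$sample_ids,
    tumor_model = grid$model,
    animal_id = paste0(grid$model, "_A", grid$animal),
    treatment = grid$arm,
    stringsAsFactors = FALSE
  ), treatments = TREATMENTS)
}
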