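#' Pairwise Pearson correlation between two feature tables
#'
#' Computes the product-moment correlation between every row of `x` and
#' every row of `y` over their shared samples, removing missing values
#' pairwise. Cells with fewer than 3 complete pairs, or involving a
#' zero-variance feature, are set to `NA` (flagged, not an error).
#'
#' @param x,y Numeric matrices, features x samples (a [secretome_matrix()],
#'   [infiltrate_table()], or plain matrix). `y` defaults to `x`.
#' @param samples Sample ids to use; default is the intersection of the two
#'   tables' column names.
#' @return A `correlation_report`: list with `row_ids`, `col_ids`,
#'   `r_values`, `n_pairs`, and (until [cluster_order()] fills them)
#'   `NULL` `row_order`/`col_order`/`linkage_params`.
#' @export
pearson_matrix <- function(x, y = x, samples = NULL) {
  x <- .as_feature_matrix(x)
  y <- .as_feature_matrix(y)
  if (is.null(samples)) samples <- intersect(colnames(x), colnames(y))
  if (length(samples) < 3L) stop("need >= 3 shared samples", call. = FALSE)
  xs <- x[, samples, drop = FALSE]
  ys <- y[, samples, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(xs), t(ys),
                                   use = "pairwise.complete.obs"))
  n_pairs <- (!is.na(xs)) %*% t(!is.na(ys))
  r[n_pairs < 3L] <- NA_real_
  structure(list(
    row_ids = rownames(xs), col_ids = rownames(ys),
    r_values = r, n_pairs = n_pairs,
    row_order = NULL, col_order = NULL, linkage_params = NULL
  ), class = "correlation_report")
}

.as_feature_matrix <- function(x) {
  m <- as.matrix(unclass(x))
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d x %d Pearson r (%d cells missing)\n",
              nrow(x$r_values), ncol(x$r_values), sum(is.na(x$r_values))))
  if (!is.null(x$linkage_params)) {
    cat(sprintf("  clustered: %s distance, %s linkage\n",
                x$linkage_params$distance, x$linkage_params$linkage))
  }
  invisible(x)
}

#' Order a correlation report by hierarchical clustering
#'
#' Clusters rows and columns of the r matrix agglomeratively — by default
#' with Chebyshev ("maximum") distance and average linkage — and records the
#' dendrogram leaf orders. Missing r cells are filled with 0 for distance
#' purposes only (flagged in the result).
#'
#' @param report A [pearson_matrix()] result.
#' @param distance `"maximum"` (Chebyshev), `"euclidean"`, or
#'   `"correlation"` (1 - r between profiles).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return The report with `row_order`, `col_order` (integer permutations),
#'   `linkage_params`, and `row_hclust`/`col_hclust` filled.
#' @export
cluster_order <- function(report, distance = c("maximum", "euclidean",
                                               "correlation"),
                          linkage = "average") {
  stopifnot(inherits(report, "correlation_report"))
  distance <- match.arg(distance)
  r <- report$r_values
  filled <- anyNA(r)
  r[is.na(r)] <- 0
  ord <- function(m) {
    if (nrow(m) < 2L) {
      return(list(order = seq_len(nrow(m)), hclust = NULL))
    }
    d <- if (distance == "correlation") {
      stats::as.dist(1 - suppressWarnings(stats::cor(t(m))))
    } else {
      stats::dist(m, method = distance)
    }
    d[is.na(d)] <- 1
    h <- stats::hclust(d, method = linkage)
    list(order = .canonical_leaf_order(h, rownames(m)), hclust = h)
  }
  ro <- ord(r)
  co <- ord(t(r))
  report$row_order <- ro$order
  report$col_order <- co$order
  report$row_hclust <- ro$hclust
  report$col_hclust <- co$hclust
  report$linkage_params <- list(distance = distance, linkage = linkage,
                                missing_filled = filled)
  report
}

# Deterministic dendrogram leaf order: at every merge the subtree whose
# lexicographically smallest label is smaller comes first, so the order
# depends only on the tree (hence on the dissimilarities), not on input
# row order.
.canonical_leaf_order <- function(h, labels) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    kids <- h$merge[node, ]
    l <- rec(kids[1L]); r <- rec(kids[2L])
    if (min(labels[l]) <= min(labels[r])) c(l, r) else c(r, l)
  }
  rec(nrow(h$merge))
}

#' Correlate process amplitudes with immune-infiltrate levels
#'
#' Builds the process-by-population Pearson matrix: rows are the significant
#' unbalanced processes' amplitudes, columns the infiltrate populations.
#' When an explant-to-tumor `alignment` is supplied, fragment amplitudes are
#' first aggregated per animal (mean or median) and paired with that
#' animal's infiltrate record; otherwise samples are matched by identical
#' ids.
#'
#' @param result A decomposition with `K_significant >= 1` (run
#'   [count_significant_processes()] first).
#' @param infiltrates An [infiltrate_table()].
#' @param alignment Optional result of [align_tables()].
#' @param aggregate Fragment aggregator when `alignment` is used.
#' @return A `correlation_report` with rows `process1..K`.
#' @export
amplitude_infiltrate_correlation <- function(result, infiltrates,
                                             alignment = NULL,
                                             aggregate = c("mean", "median")) {
  stopifnot(inherits(result, "surprisal_decomposition"))
  aggregate <- match.arg(aggregate)
  K <- result$K_significant
  if (is.na(K)) {
    stop("run count_significant_processes() before correlating amplitudes",
         call. = FALSE)
  }
  if (K < 1L) stop("no significant unbalanced processes", call. = FALSE)
  lam <- result$lambda[1L + seq_len(K), , drop = FALSE]
  rownames(lam) <- paste0("process", seq_len(K))
  if (!is.null(alignment)) {
    map <- alignment$mapping
    map <- map[map$sample_id %in% colnames(lam), , drop = FALSE]
    f <- if (aggregate == "mean") mean else stats::median
    animals <- unique(map$infiltrate_id)
    agg <- vapply(animals, function(a) {
      cols <- map$sample_id[map$infiltrate_id == a]
      apply(lam[, cols, drop = FALSE], 1L, f)
    }, numeric(nrow(lam)))
    lam <- matrix(agg, nrow = nrow(lam),
                  dimnames = list(rownames(lam), animals))
  }
  pearson_matrix(lam, infiltrates)
}

#' Principal component scores of sample profiles
#'
#' Projects samples onto the top principal components of the row-centered
#' (optionally row-scaled) feature table. Missing entries are first
#' completed with [impute_missing_svd()].
#'
#' @param x Numeric matrix, features x samples.
#' @param n_components Number of components to keep,
#'   `<= min(n_features, n_samples)`.
#' @param scale_rows Also scale each feature to unit variance (the treatment
#'   heatmap convention); default `FALSE` (centering only).
#' @param impute_rank Rank passed to the imputation step when `x` has
#'   missing entries.
#' @return A `pca_result` list: `scores` (samples x components),
#'   `explained_variance` (fractions, non-increasing, summing to <= 1 over
#'   the kept components), `rotation`, and `sdev`.
#' @export
pca_scores <- function(x, n_components = 2L, scale_rows = FALSE,
                       impute_rank = NULL) {
  x <- .as_feature_matrix(x)
  if (n_components > min(dim(x))) {
    stop(sprintf("n_components (%d) exceeds min(dim) = %d",
                 n_components, min(dim(x))), call. = FALSE)
  }
  if (anyNA(x)) x <- impute_missing_svd(x, rank = impute_rank)
  if (scale_rows) {
    sds <- apply(x, 1L, stats::sd)
    keep <- sds > 0
    x <- x[keep, , drop = FALSE]
  }
  p <- stats::prcomp(t(x), center = TRUE, scale. = scale_rows)
  evf <- p$sdev^2 / sum(p$sdev^2)
  idx <- seq_len(min(n_components, ncol(p$x)))
  structure(list(
    scores = p$x[, idx, drop = FALSE],
    explained_variance = evf[idx],
    rotation = p$rotation[, idx, drop = FALSE],
    sdev = p$sdev
  ), class = "pca_result")
}

#' Significance stars for the standard tiers
#'
#' @param p P-value(s) in [0, 1].
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `"NS"`.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "NS")))
}

#' Compare treated vs baseline secretion of one cytokine
#'
#' Equal-variance two-sample (unpaired, two-tailed) Student t-test between
#' the replicate fragments of the baseline arm and those of `arm`,
#' optionally restricted to one animal (the per-tumor comparison). The t
#' statistic is the first group (baseline) mean minus the second (treated),
#' over the pooled standard error, with `df = n1 + n2 - 2`.
#'
#' @param secretome A [secretome_matrix()].
#' @param metadata Validated metadata data.frame.
#' @param cytokine Cytokine id (row of `secretome`).
#' @param arm Treatment arm to compare against baseline.
#' @param animal Optional `animal_id` restricting both groups to one tumor.
#' @param baseline Baseline arm label (default `"untreated"`).
#' @return A one-row data.frame: `cytokine_id`, `arm`, `animal`,
#'   `baseline_mean`, `treated_mean`, `n_baseline`, `n_treated`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `stars`.
#' @export
compare_treatments <- function(secretome, metadata, cytokine, arm,
                               animal = NULL, baseline = "untreated") {
  stopifnot(inherits(secretome, "secretome_matrix"))
  if (!cytokine %in% cytokine_ids(secretome)) {
    stop(sprintf("unknown cytokine '%s'", cytokine), call. = FALSE)
  }
  md <- metadata[metadata$sample_id %in% sample_ids(secretome), , drop = FALSE]
  if (!is.null(animal)) md <- md[md$animal_id == animal, , drop = FALSE]
  vals <- unclass(secretome)[cytokine, ]
  grab <- function(lab) {
    v <- vals[md$sample_id[md$treatment == lab]]
    v[!is.na(v)]
  }
  b <- grab(baseline)
  t_ <- grab(arm)
  if (length(b) < 2L || length(t_) < 2L) {
    stop(sprintf("need >= 2 replicates per group (baseline %d, %s %d)",
                 length(b), arm, length(t_)), call. = FALSE)
  }
  tt <- stats::t.test(b, t_, var.equal = TRUE)
  data.frame(
    cytokine_id = cytokine, arm = arm,
    animal = if (is.null(animal)) NA_character_ else animal,
    baseline_mean = mean(b), treated_mean = mean(t_),
    n_baseline = length(b), n_treated = length(t_),
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = unname(tt$p.value),
    stars = signif_stars(unname(tt$p.value)),
    stringsAsFactors = FALSE
  )
}

#' Treatment comparisons across all cytokines and arms
#'
#' Runs [compare_treatments()] for every cytokine x non-baseline arm
#' combination with enough replicates (optionally per animal). Raw p-values
#' are starred exactly as reported per comparison; because many cytokines
#' are tested, a Benjamini-Hochberg adjusted column (`p_adj_bh`) is also
#' emitted, clearly labeled, for readers who want family-wise control.
#'
#' @inheritParams compare_treatments
#' @param arms Arms to test; default every non-baseline arm in the metadata.
#' @param per_animal Compare within each animal separately (default `FALSE`:
#'   all fragments pooled per arm).
#' @return A data.frame of comparison rows with an added `p_adj_bh` column;
#'   combinations lacking replicates are skipped.
#' @export
compare_all_treatments <- function(secretome, metadata, arms = NULL,
                                   per_animal = FALSE,
                                   baseline = "untreated") {
  md <- metadata[metadata$sample_id %in% sample_ids(secretome), , drop = FALSE]
  if (is.null(arms)) arms <- setdiff(unique(md$treatment), baseline)
  animals <- if (per_animal) unique(md$animal_id) else list(NULL)
  rows <- list()
  for (ck in cytokine_ids(secretome)) {
    for (arm in arms) {
      for (an in animals) {
        row <- tryCatch(
          compare_treatments(secretome, md, ck, arm, animal = an,
                             baseline = baseline),
          error = function(e) NULL)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) stop("no testable cytokine/arm combination", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
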