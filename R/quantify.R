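# Quantitative ladder, limit of quantification, depth analyses, feature
# counting, TMM / control-anchored RUVg normalisation and fold-change
# evaluation.

#' Count classified reads per adaptor
#'
#' @param classification a `captor_classification` (or its `reads` table).
#' @return named integer vector of counts per panel adaptor (zero for
#'   undetected adaptors); the number of unclassified reads is attached as
#'   attribute `n_unclassified`.
#' @export
captor_counts <- function(classification) {
  reads <- if (is.data.frame(classification)) classification
           else classification$reads
  ids <- if (is.data.frame(classification)) unique(reads$captor_id)
         else classification$panel$id
  ids <- setdiff(ids, UNCLASSIFIED)
  cls <- reads$captor_id[reads$captor_id != UNCLASSIFIED]
  if (!length(cls)) warnf("no classified reads; all counts zero")
  counts <- setNames(integer(length(ids)), ids)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "n_unclassified") <- sum(reads$captor_id == UNCLASSIFIED)
  counts
}

#' Fit the quantitative reference ladder
#'
#' Ordinary least squares of log2 observed count on log2 relative
#' concentration across the manifest's dilution series. Adaptors with zero
#' observed count are excluded from the fit (no pseudocount) and reported as
#' not detected.
#'
#' @param counts named counts from [captor_counts()].
#' @param manifest the `captor_manifest` used for the library.
#' @return a `captor_ladder_fit` list: `slope`, `intercept`, `r_squared`,
#'   `slope_ci_halfwidth` (95%), `n_points`, `not_detected`, and the fitted
#'   `points`.
#' @export
ladder_fit <- function(counts, manifest) {
  m <- manifest[match(names(counts), manifest$captor_id), ]
  ok <- !is.na(m$captor_id) & counts > 0
  if (sum(ok) < 3) {
    stopf("insufficient data: need >= 3 adaptors with positive counts, got %d",
          sum(ok))
  }
  pts <- data.frame(captor_id = names(counts)[ok],
                    x = log2(m$relative_concentration[ok]),
                    y = log2(as.numeric(counts[ok])),
                    stringsAsFactors = FALSE)
  fit <- lm(y ~ x, data = pts)
  se <- summary(fit)$coefficients["x", "Std. Error"]
  structure(list(
    slope = unname(coef(fit)["x"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = summary(fit)$r.squared,
    slope_ci_halfwidth = qt(0.975, df = fit$df.residual) * se,
    n_points = nrow(pts),
    not_detected = names(counts)[!is.na(m$captor_id) & counts == 0],
    points = pts), class = "captor_ladder_fit")
}

#' Segmental (two-segment) linear regression
#'
#' Continuous piecewise-linear least squares with the breakpoint chosen by
#' grid search over the midpoints between consecutive sorted x values
#' (restricted so each segment keeps at least two points). On ladder-like
#' data the breakpoint separates the noisy under-sampled regime from the
#' linear regime, and its observed-count ordinate `2^y(breakpoint)` is the
#' limit of quantification in reads. Perfectly collinear input is flagged
#' degenerate with the breakpoint reported at the lower boundary; a segment
#' whose observed values have zero variance (for example a fully
#' detection-censored low end where every count is 1) reports an `NA` R^2.
#'
#' @param points data.frame with `x` (log2 expected concentration) and `y`
#'   (log2 observed count), e.g. the `points` of a [ladder_fit()].
#' @return a `captor_segmental_fit` list: `breakpoint_x`, `loq_reads`,
#'   `left_slope`, `right_slope`, `left_r2`, `right_r2`, `sse`,
#'   `single_line_sse`, `degenerate`.
#' @export
segmental_fit <- function(points) {
  x <- points$x; y <- points$y
  if (length(x) < 6) {
    stopf("insufficient data: segmental regression needs >= 6 points, got %d",
          length(x))
  }
  ord <- order(x); x <- x[ord]; y <- y[ord]
  ux <- unique(x)
  r2_of <- function(res, yy) {
    tss <- sum((yy - mean(yy))^2)
    if (tss <= 0) return(NA_real_)  # zero-variance segment: R^2 undefined
    1 - sum(res^2) / tss
  }
  single <- lm(y ~ x)
  sse_single <- sum(residuals(single)^2)
  grid <- (ux[-length(ux)] + ux[-1]) / 2
  # each segment must hold at least two points at two distinct x values,
  # otherwise its slope (and R^2) is not identifiable
  keep <- vapply(grid, function(c0) {
    sum(x < c0) >= 2 && sum(x >= c0) >= 2 &&
      length(unique(x[x < c0])) >= 2 && length(unique(x[x >= c0])) >= 2
  }, logical(1))
  grid <- grid[keep]
  if (!length(grid)) stopf("too few distinct x values for a breakpoint grid")
  fits <- lapply(grid, function(c0) lm(y ~ x + pmax(x - c0, 0)))
  sses <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  best <- which.min(sses)
  scale <- max(sse_single, 1e-12)
  degenerate <- (sse_single - sses[best]) <= 1e-9 * scale
  if (degenerate) {
    b <- coef(single)
    bp <- min(x)
    yhat_bp <- unname(b[1] + b[2] * bp)
    r2s <- r2_of(residuals(single), y)
    out <- list(breakpoint_x = bp, loq_reads = 2^yhat_bp,
                left_slope = unname(b[2]), right_slope = unname(b[2]),
                left_r2 = r2s, right_r2 = r2s,
                sse = sse_single, single_line_sse = sse_single,
                degenerate = TRUE)
  } else {
    f <- fits[[best]]; c0 <- grid[best]; b <- coef(f)
    yhat_bp <- unname(b[1] + b[2] * c0)
    side_r2 <- function(keep) {
      if (sum(keep) < 2) return(NA_real_)
      r2_of(y[keep] - predict(f)[keep], y[keep])
    }
    out <- list(breakpoint_x = c0, loq_reads = 2^yhat_bp,
                left_slope = unname(b[2]),
                right_slope = unname(b[2] + b[3]),
                left_r2 = side_r2(x < c0), right_r2 = side_r2(x >= c0),
                sse = sses[best], single_line_sse = sse_single,
                degenerate = FALSE)
  }
  class(out) <- "captor_segmental_fit"
  out
}

#' Subsample reads
#'
#' Uniform sampling without replacement, deterministic for a fixed seed;
#' original read order is preserved.
#'
#' @param fastq reads data.frame (or FASTQ path).
#' @param n number of reads to keep (or use `fraction`).
#' @param fraction fraction of reads to keep.
#' @param rng_seed integer seed.
#' @export
subsample_reads <- function(fastq, n = NULL, fraction = NULL, rng_seed = 1L) {
  if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    fastq <- read_fastq(fastq)
  }
  total <- nrow(fastq)
  if (is.null(n)) {
    if (is.null(fraction)) stopf("give either n or fraction")
    n <- round(fraction * total)
  }
  if (n > total) stopf("cannot sample %d of %d reads", n, total)
  if (n == total) return(fastq)
  keep <- with_seed(rng_seed, sort(sample.int(total, n)))
  fastq[keep, , drop = FALSE]
}

#' Minimum depth for reliable quantification
#'
#' Subsamples a library to each candidate depth and reports the smallest one
#' at which every manifest adaptor is detected with at least
#' `min_count` reads and the ladder fit reaches `min_r2`. Reads are
#' classified once and subsampled at the classification level (equivalent to
#' subsampling the FASTQ, since classification is per-read).
#'
#' @param fastq reads (data.frame or FASTQ path).
#' @param panel,manifest panel and manifest of the library.
#' @param depths increasing vector of depths to test.
#' @param min_count,min_r2 reliability criterion.
#' @param rng_seed seed for the subsampling.
#' @param classification optional precomputed `captor_classification`.
#' @return list with `depth` (smallest passing depth, or `NA` when the
#'   criterion is never met) and `diagnostics` (per-depth table).
#' @export
min_reliable_depth <- function(fastq, panel, manifest, depths,
                               min_count = 5, min_r2 = 0.95, rng_seed = 1L,
                               classification = NULL) {
  if (is.unsorted(depths)) stopf("depths must be sorted ascending")
  if (is.null(classification)) {
    classification <- classify_reads(fastq, panel)
  }
  reads <- classification$reads
  diag <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    d <- depths[i]
    if (d > nrow(reads)) {
      diag[[i]] <- data.frame(depth = d, n_detected = NA, min_count = NA,
                              r_squared = NA, pass = NA)
      next
    }
    keep <- with_seed(rng_seed + i, sort(sample.int(nrow(reads), d)))
    sub <- reads[keep, ]
    counts <- captor_counts(sub)
    counts <- counts[intersect(names(counts), manifest$captor_id)]
    missing <- setdiff(manifest$captor_id, names(counts))
    full <- setNames(integer(nrow(manifest)), manifest$captor_id)
    full[names(counts)] <- counts
    r2 <- tryCatch(ladder_fit(full, manifest)$r_squared,
                   error = function(e) NA_real_)
    # manifests too small for a ladder fall back to the detection criterion
    r2_ok <- if (nrow(manifest) < 3) TRUE else !is.na(r2) && r2 >= min_r2
    pass <- all(full >= min_count) && r2_ok
    diag[[i]] <- data.frame(depth = d, n_detected = sum(full > 0),
                            min_count = min(full), r_squared = r2,
                            pass = pass)
  }
  diag <- do.call(rbind, diag)
  passing <- diag$depth[which(diag$pass)]
  list(depth = if (length(passing)) min(passing) else NA_integer_,
       diagnostics = diag)
}

#' Feature counts as mean aligned depth
#'
#' Per feature, the summed aligned insert bases divided by the feature
#' length ("mean read depth"), with the adaptor counts appended as control
#' rows.
#'
#' @param assignments insert assignments from [assign_inserts()].
#' @param feature_refs the feature sequences the assignment used.
#' @param classification the `captor_classification`, for the control rows;
#'   omit to return feature rows only.
#' @return data.frame with `feature`, `count`, `is_control`.
#' @export
feature_counts <- function(assignments, feature_refs, classification = NULL) {
  if (is.character(feature_refs) && length(feature_refs) == 1 &&
      file.exists(feature_refs)) {
    feature_refs <- read_fasta(feature_refs)
  }
  lens <- nchar(feature_refs)
  used <- assignments[assignments$feature_id != UNASSIGNED, ]
  depth <- setNames(numeric(length(feature_refs)), names(feature_refs))
  if (nrow(used)) {
    agg <- tapply(used$aligned_bases, used$feature_id, sum)
    depth[names(agg)] <- agg / lens[names(agg)]
  }
  out <- data.frame(feature = names(depth), count = unname(depth),
                    is_control = FALSE, stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    cc <- captor_counts(classification)
    out <- rbind(out, data.frame(feature = names(cc),
                                 count = as.numeric(cc),
                                 is_control = TRUE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Assemble a count matrix from per-sample count tables
#'
#' @param count_list named list of [feature_counts()] tables with identical
#'   feature sets.
#' @return list with `counts` (features x samples matrix) and `is_control`
#'   (logical vector over rows).
#' @export
build_count_matrix <- function(count_list) {
  feats <- count_list[[1]]$feature
  mat <- vapply(count_list, function(x) {
    x$count[match(feats, x$feature)]
  }, numeric(length(feats)))
  rownames(mat) <- feats
  list(counts = mat, is_control = count_list[[1]]$is_control)
}

#' TMM normalisation factors
#'
#' Trimmed-mean-of-M-values scaling factors between samples, computed with
#' the standard weighted, doubly-trimmed algorithm (edgeR's implementation;
#' the reference sample is the one whose upper quartile is closest to the
#' mean upper quartile). Factors are scaled to geometric mean 1.
#'
#' @param counts features x samples matrix (>= 2 samples).
#' @param trim_m log-ratio trim fraction.
#' @param trim_a absolute-intensity trim fraction.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stopf("sample '%s' has all-zero counts", colnames(counts)[which(zero)[1]])
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(as.numeric(f), colnames(counts))
}

#' RUVg normalisation with control features
#'
#' Removal of unwanted variation anchored on negative-control rows (the
#' CAPTOR adaptors, present in every library at the master-mix ratios):
#' log(count + 1) of the control rows is row-centred, the first `k`
#' sample-space singular vectors form the unwanted-variation factors W, and
#' W is regressed out of every (log-scale) row.
#'
#' @param counts features x samples matrix.
#' @param control_ids rownames of the negative-control features.
#' @param k number of unwanted-variation factors (1 to n_samples - 1).
#' @return list with `normalized` (corrected count matrix) and `W`
#'   (samples x k factor matrix).
#' @export
ruvg_normalize <- function(counts, control_ids, k = 1) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  if (k < 1 || k >= ns) stopf("k must satisfy 1 <= k < n_samples")
  if (k == ns - 1) warnf("k = n_samples - 1: likely over-correction")
  if (!all(control_ids %in% rownames(counts))) {
    stopf("control ids absent from count matrix")
  }
  Z <- log(counts + 1)
  Zc <- Z[control_ids, , drop = FALSE]
  Zc <- Zc - rowMeans(Zc)
  sv <- svd(Zc)
  W <- matrix(0, ns, k)
  use <- sv$d > 1e-10
  if (any(use[seq_len(k)])) {
    idx <- seq_len(k)[use[seq_len(k)]]
    W[, idx] <- sv$v[, idx, drop = FALSE]
  }
  corrected <- Z
  if (any(W != 0)) {
    X <- cbind(1, W)
    for (r in seq_len(nrow(Z))) {
      cf <- lm.fit(X, Z[r, ])$coefficients
      corrected[r, ] <- Z[r, ] - W %*% cf[-1]
    }
  }
  list(normalized = pmax(exp(corrected) - 1, 0), W = W)
}

#' Evaluate observed against expected fold changes
#'
#' Per feature, the observed mean log2 fold change between two replicated
#' conditions (difference of mean log2 counts with a 0.5 pseudocount);
#' summarised by the regression slope and R^2 of observed on expected, the
#' true-positive rate over features with `|expected| >= detect_threshold`
#' and the true-negative rate over features with expected 0 (detection:
#' `|observed| >= detect_threshold`), plus the RMSE of observed vs expected.
#'
#' @param mat_a,mat_b features x replicate-samples matrices (same rows).
#' @param expected_log2fc named numeric of expected log2 fold changes.
#' @param detect_threshold absolute log2 fold change counted as a detection.
#' @return a `captor_fc_eval` list: `per_feature`, `slope`, `r_squared`,
#'   `tpr`, `tnr`, `rmse`.
#' @export
fold_change_eval <- function(mat_a, mat_b, expected_log2fc,
                             detect_threshold = 1) {
  if (ncol(as.matrix(mat_a)) < 2 || ncol(as.matrix(mat_b)) < 2) {
    stopf("need >= 2 replicates per condition")
  }
  feats <- intersect(rownames(mat_a), names(expected_log2fc))
  a <- as.matrix(mat_a)[feats, , drop = FALSE]
  b <- as.matrix(mat_b)[feats, , drop = FALSE]
  obs <- rowMeans(log2(b + 0.5)) - rowMeans(log2(a + 0.5))
  exp_fc <- expected_log2fc[feats]
  per <- data.frame(feature = feats, expected = unname(exp_fc),
                    observed = unname(obs), stringsAsFactors = FALSE)
  changed <- abs(per$expected) >= detect_threshold
  null_f <- per$expected == 0
  fit <- if (length(unique(per$expected)) > 1) lm(observed ~ expected, data = per)
         else NULL
  structure(list(
    per_feature = per,
    slope = if (is.null(fit)) NA_real_ else unname(coef(fit)["expected"]),
    r_squared = if (is.null(fit)) NA_real_ else summary(fit)$r.squared,
    tpr = if (any(changed)) mean(abs(per$observed[changed]) >= detect_threshold)
          else NA_real_,
    tnr = if (any(null_f)) mean(abs(per$observed[null_f]) < detect_threshold)
          else NA_real_,
    rmse = sqrt(mean((per$observed - per$expected)^2))),
    class = "captor_fc_eval")
}

#' Flag features against the limit of quantification
#'
#' @param counts named numeric feature counts.
#' @param loq limit of quantification in reads (e.g. `loq_reads` from
#'   [segmental_fit()]).
#' @return list with `flags` (logical, above LOQ) and `fraction_above`.
#' @export
loq_flag <- function(counts, loq) {
  if (!length(counts)) {
    warnf("no features given; fraction above LOQ undefined")
    return(list(flags = logical(0), fraction_above = NA_real_))
  }
  flags <- counts > loq
  list(flags = flags, fraction_above = mean(flags))
}
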