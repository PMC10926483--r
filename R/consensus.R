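# Behavioral response typing by subsampled k-means consensus clustering with
# Monte-Carlo reference-based selection of the cluster count.
#
# Each consensus iteration clusters a random subsample of responses (rows)
# and features (columns); co-clustering tallies across iterations form a
# consensus matrix. Stability per k is scored by the proportion of ambiguous
# clustering (PAC); the real data's PAC is compared to PAC on structureless
# multivariate-normal reference data with matched covariance, giving the
# relative cluster stability index (RCSI) whose maximum selects k.

#' Z-score a feature table
#'
#' Columns are centered and scaled by the sample standard deviation, pooling
#' all responses across treatments. Rows containing any undefined feature are
#' excluded first (their count is reported via the `n_excluded` attribute).
#'
#' @param features data.frame or matrix of numeric feature columns, or the
#'   output of [extract_features()] (in which case the five response-feature
#'   columns are selected automatically).
#' @return numeric matrix of z-scores with attributes `center`, `scale`,
#'   `n_excluded` and `kept_rows` (row indices of the input that survived).
#' @export
zscore_features <- function(features) {
  feat_cols <- c("ymax", "rotation_asymmetry", "tortuosity", "walking_pace",
                 "abs_turning_velocity")
  if (is.data.frame(features) && all(feat_cols %in% names(features)))
    features <- features[, feat_cols]
  x <- as.matrix(features)
  if (!is.numeric(x)) stop_invalid("features must be numeric")
  if (nrow(x) < 2L) stop_invalid("need at least 2 rows to z-score")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) stop_invalid("fewer than 2 complete rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop_invalid("zero-variance column(s): ",
                 paste(colnames(x)[zero] %||% zero, collapse = ", "))
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdv
  attr(z, "n_excluded") <- sum(!keep)
  attr(z, "kept_rows") <- which(keep)
  z
}

#' Subsampled k-means consensus matrix
#'
#' Runs `reps` k-means clusterings, each on a random subsample of
#' `ceiling(item_frac * n)` rows and `ceiling(feature_frac * p)` columns drawn
#' without replacement, and tallies how often each pair of rows lands in the
#' same cluster relative to how often it was co-sampled.
#'
#' @param X numeric matrix (rows = responses, columns = features),
#'   typically from [zscore_features()].
#' @param k number of clusters (>= 2).
#' @param reps number of subsampled clustering iterations.
#' @param item_frac fraction of rows per subsample (default 0.9).
#' @param feature_frac fraction of columns per subsample (default 0.8;
#'   with 5 features this samples exactly 4 of 5).
#' @param seed integer seed; the run is fully reproducible given it.
#' @param nstart random restarts per k-means run.
#' @param iter_max maximum Lloyd/Hartigan-Wong iterations per run.
#' @return an n-by-n symmetric `consensus_matrix` with entries in \[0, 1\]
#'   (co-cluster count / co-sample count; 0 for pairs never co-sampled), unit
#'   diagonal, and attribute `k`.
#' @export
consensus_run <- function(X, k, reps = 2000, item_frac = 0.9,
                          feature_frac = 0.8, seed = NULL, nstart = 5,
                          iter_max = 20) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 2) stop_invalid("k must be >= 2")
  if (item_frac <= 0 || item_frac > 1 || feature_frac <= 0 || feature_frac > 1)
    stop_invalid("fractions must be in (0, 1]")
  if (reps < 1) stop_invalid("reps must be >= 1")
  n_sub <- ceiling(item_frac * n)
  p_sub <- ceiling(feature_frac * p)
  if (k > n_sub) stop_invalid("k exceeds the subsampled row count")
  # Membership indicators for all iterations are accumulated into two 0/1
  # matrices so the pairwise tallies reduce to two crossproducts:
  #   co_cluster = H H', H[i, (r-1)k + c] = 1 iff row i in cluster c at rep r
  #   co_sample  = S S', S[i, r] = 1 iff row i was subsampled at rep r
  H <- matrix(0, n, reps * k)
  S <- matrix(0, n, reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      ridx <- if (n_sub < n) sample.int(n, n_sub) else seq_len(n)
      cidx <- if (p_sub < p) sample.int(p, p_sub) else seq_len(p)
      km <- suppressWarnings(
        stats::kmeans(X[ridx, cidx, drop = FALSE], centers = k,
                      nstart = nstart, iter.max = iter_max))
      H[cbind(ridx, (r - 1L) * k + km$cluster)] <- 1
      S[ridx, r] <- 1
    }
  })
  co_cluster <- tcrossprod(H)
  co_sample <- tcrossprod(S)
  M <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(M) <- ifelse(diag(co_sample) > 0, 1, 0)
  structure(M, class = c("consensus_matrix", class(M)), k = k)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal consensus entries strictly inside the ambiguity
#' window `(lower, upper)`: entries near 0 or 1 indicate pairs stably split
#' or stably joined, while intermediate values indicate instability. Lower
#' PAC means a more stable clustering.
#'
#' @param M a consensus matrix.
#' @param lower,upper the ambiguity window (defaults 0.1 and 0.9).
#' @return PAC in \[0, 1\].
#' @export
pac <- function(M, lower = 0.1, upper = 0.9) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop_invalid("require 0 <= lower < upper <= 1")
  M <- unclass(M)
  off <- M[row(M) != col(M)]
  mean(off > lower & off < upper)
}

#' Structureless Monte-Carlo reference datasets
#'
#' Simulates `B` surrogate datasets of the same size as `X` from a zero-mean
#' multivariate normal whose covariance equals the empirical covariance of
#' `X`. This preserves the principal-component structure (feature
#' correlations and variances) while destroying any cluster structure, giving
#' the null reference against which real-data clustering stability is judged.
#'
#' @param X numeric matrix.
#' @param B number of surrogate datasets (>= 1).
#' @param seed integer seed.
#' @param ridge relative ridge added to a numerically singular covariance
#'   (a message reports when this happens).
#' @return list of `B` matrices, each `dim(X)`.
#' @export
monte_carlo_reference <- function(X, B, seed = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  if (B < 1) stop_invalid("B must be >= 1")
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge * max(ev)) {
    S <- S + diag(ridge * max(ev), ncol(S))
    message("monte_carlo_reference: ridge-regularized a degenerate covariance")
  }
  n <- nrow(X)
  with_seed(seed, lapply(seq_len(B), function(b)
    MASS::mvrnorm(n, mu = rep(0, ncol(X)), Sigma = S)))
}

#' Select the cluster count by Monte-Carlo consensus clustering
#'
#' For each candidate k, computes the real-data PAC from a subsampled k-means
#' consensus matrix and the distribution of PAC on `B` structureless
#' reference datasets. The relative cluster stability index
#' \deqn{RCSI(k) = \ln(\overline{PAC}_{null}(k) / PAC_{real}(k))}
#' (PAC values floored at `pac_floor` before the ratio) is largest where the
#' real data are most stable relative to chance; the selected k maximizes
#' RCSI. A one-sided p-value per k comes from a normal approximation to the
#' null PAC distribution.
#'
#' @param X z-scored feature matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param reps consensus iterations per k (default 2000).
#' @param B number of Monte-Carlo reference datasets (default 25).
#' @param item_frac,feature_frac subsampling fractions (defaults 0.9, 0.8).
#' @param seed integer root seed; real and null runs use streams derived
#'   from it.
#' @param pac_window lower/upper PAC ambiguity bounds.
#' @param pac_floor floor applied to PAC values before the log ratio.
#' @param nstart k-means restarts per subsample.
#' @return an object of class `k_selection`: list with `k_range`, `pac`
#'   (real PAC per k), `null_pac` (B-by-length(k_range) matrix), `rcsi`,
#'   `p_value`, and `chosen_k`.
#' @export
select_k <- function(X, k_range = 2:10, reps = 2000, B = 25,
                     item_frac = 0.9, feature_frac = 0.8, seed = NULL,
                     pac_window = c(0.1, 0.9), pac_floor = 1e-4, nstart = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop_invalid("k_range must lie within [2, n-1]")
  refs <- monte_carlo_reference(X, B, seed = derive_seed(seed %||% 0, 1L))
  pac_of <- function(M) pac(M, pac_window[1L], pac_window[2L])
  real_pac <- numeric(length(k_range))
  null_pac <- matrix(NA_real_, nrow = B, ncol = length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    real_pac[i] <- pac_of(consensus_run(
      X, k, reps = reps, item_frac = item_frac, feature_frac = feature_frac,
      seed = derive_seed(seed %||% 0, 100L + i), nstart = nstart))
    for (b in seq_len(B)) {
      null_pac[b, i] <- pac_of(consensus_run(
        refs[[b]], k, reps = reps, item_frac = item_frac,
        feature_frac = feature_frac,
        seed = derive_seed(seed %||% 0, 1000L + i * 101L + b), nstart = nstart))
    }
  }
  fl <- function(x) pmax(x, pac_floor)
  rcsi <- log(fl(colMeans(null_pac)) / fl(real_pac))
  mu <- colMeans(null_pac)
  sdv <- apply(null_pac, 2L, stats::sd)
  p_value <- ifelse(sdv > 0, stats::pnorm(real_pac, mean = mu, sd = sdv),
                    as.numeric(real_pac >= mu))
  chosen <- k_range[which.max(rcsi)]
  structure(list(k_range = k_range, pac = real_pac, null_pac = null_pac,
                 rcsi = rcsi, p_value = p_value, chosen_k = chosen),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> Monte-Carlo consensus clustering\n")
  print(data.frame(k = x$k_range, pac = round(x$pac, 4),
                   mean_null_pac = round(colMeans(x$null_pac), 4),
                   rcsi = round(x$rcsi, 3), p_value = signif(x$p_value, 3)))
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Assign cluster labels from a consensus matrix
#'
#' Hierarchical (average-linkage) clustering of the consensus dissimilarity
#' `1 - M`, cut at `k` clusters. Labels are renumbered by descending cluster
#' size so label 1 is always the largest cluster.
#'
#' @param M a consensus matrix from [consensus_run()].
#' @param k number of clusters.
#' @return integer vector of labels in `1..k`.
#' @export
assign_clusters <- function(M, k) {
  if (k < 2) stop_invalid("k must be >= 2")
  M <- unclass(M)
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  lab <- stats::cutree(hc, k = k)
  sizes <- table(lab)
  remap <- integer(length(sizes))
  remap[as.integer(names(sort(sizes, decreasing = TRUE)))] <- seq_along(sizes)
  unname(remap[lab])
}

#' Cluster proportions per treatment and stimulus
#'
#' @param labels integer cluster labels, one per response.
#' @param metadata data.frame with one row per response, containing
#'   `treatment` and `stimulus_label` columns.
#' @return data.frame with one row per (treatment, stimulus_label, cluster):
#'   `n` responses and `proportion` within the treatment-stimulus cell.
#' @export
cluster_proportions <- function(labels, metadata) {
  if (nrow(metadata) != length(labels))
    stop_invalid("metadata rows must match the number of labels")
  if (!all(c("treatment", "stimulus_label") %in% names(metadata)))
    stop_invalid("metadata needs 'treatment' and 'stimulus_label' columns")
  df <- data.frame(treatment = metadata$treatment,
                   stimulus_label = metadata$stimulus_label,
                   cluster = labels)
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = df[c("treatment", "stimulus_label", "cluster")],
                          FUN = sum)
  tot <- stats::aggregate(list(total = agg$n),
                          by = agg[c("treatment", "stimulus_label")], FUN = sum)
  out <- merge(agg, tot, by = c("treatment", "stimulus_label"))
  out$proportion <- out$n / out$total
  out$total <- NULL
  out[order(out$treatment, out$stimulus_label, out$cluster), ]
}
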