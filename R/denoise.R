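#' Embed one bin's power time series as a matrix for PCA
#'
#' PCA needs a multivariate view of each univariate bin series. Two layouts:
#'
#' * `"daily"` (default): a `[days x slots-per-day]` matrix — each row is one
#'   calendar day. Natural for scheduled monitoring (~50 recordings/day),
#'   where the dominant low-rank structure is the diurnal cycle. Missing
#'   slots (maintenance gaps, removed outliers, short trailing days) are
#'   imputed with the bin median and flagged so they can be restored after
#'   reconstruction.
#' * `"lag"`: an SSA-style delay embedding with window `width`
#'   (`n - width + 1` sliding windows).
#'
#' @param ensemble A [spectrum_ensemble].
#' @param bin Bin (column) index.
#' @param layout `"daily"` or `"lag"`.
#' @param width Window width in slots (lag layout only).
#' @return List with `matrix`, `imputed` (logical mask, same shape),
#'   `series_index` (row index into the ensemble per cell, `NA` for padding;
#'   daily layout), `layout`, and the original `series`.
#' @export
embed_bin_series <- function(ensemble, bin, layout = c("daily", "lag"),
                             width = NULL) {
  layout <- match.arg(layout)
  series <- ensemble$values[, bin]
  n <- length(series)
  med <- stats::median(series, na.rm = TRUE)
  if (is.na(med)) med <- 0

  if (layout == "lag") {
    stopifnot(!is.null(width), width >= 1)
    if (n - width + 1 < 2) {
      stop("need at least 2 lag windows (series length ", n, ", width ",
           width, ")", call. = FALSE)
    }
    filled <- ifelse(is.na(series), med, series)
    M <- stats::embed(filled, width)[, width:1, drop = FALSE]
    idx <- stats::embed(seq_len(n), width)[, width:1, drop = FALSE]
    imputed <- matrix(is.na(series)[idx], nrow = nrow(M))
    return(list(matrix = M, imputed = imputed, series_index = idx,
                layout = "lag", width = width, series = series))
  }

  dates <- as.Date(ensemble$timestamps)
  udates <- sort(unique(dates))
  if (length(udates) < 2) {
    stop("daily embedding needs at least 2 days of recordings", call. = FALSE)
  }
  slots <- max(table(dates))
  M <- matrix(med, nrow = length(udates), ncol = slots)
  idx <- matrix(NA_integer_, nrow = length(udates), ncol = slots)
  for (d in seq_along(udates)) {
    rows <- which(dates == udates[d])            # already time-sorted
    idx[d, seq_along(rows)] <- rows
    v <- series[rows]
    M[d, seq_along(rows)] <- ifelse(is.na(v), med, v)
  }
  imputed <- is.na(idx) | matrix(is.na(series[idx]), nrow = nrow(idx))
  list(matrix = M, imputed = imputed, series_index = idx, layout = "daily",
       dates = udates, series = series)
}

#' Truncated-PCA reconstruction of an embedded bin series
#'
#' Columns are centred, the covariance eigendecomposed, and the smallest
#' number `k` of leading components whose cumulative explained variance
#' reaches `var_threshold` is retained; the matrix is reconstructed from
#' those components and the column means re-added. The discarded tail
#' (at most `1 - var_threshold` of the variance) is treated as noise.
#'
#' @param embedding Numeric matrix (rows = observations).
#' @param var_threshold Fraction of variance to retain, in `(0, 1]`.
#' @param eigen_weighting If `TRUE`, additionally multiplies each retained
#'   component's contribution by its eigenvalue before summation (a literal
#'   reading of "weighted by its eigenvalue"). Nonstandard — it distorts
#'   amplitudes — and kept only for comparison; the default reconstruction
#'   already carries the eigenvalue scale in the scores.
#' @return List with `reconstruction` (matrix), `series` (row-major flatten),
#'   `k`, `explained` (cumulative fraction at `k`).
#' @export
pca_denoise_bin <- function(embedding, var_threshold = 0.95,
                            eigen_weighting = FALSE) {
  stopifnot(is.matrix(embedding), var_threshold > 0, var_threshold <= 1)
  mu <- colMeans(embedding)
  Xc <- sweep(embedding, 2, mu)
  total_var <- sum(Xc^2)
  if (total_var == 0) {
    return(list(reconstruction = embedding,
                series = as.numeric(t(embedding)), k = 0L, explained = 1))
  }
  pc <- stats::prcomp(embedding, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_threshold - 1e-12)[1]
  W <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  if (eigen_weighting) S <- sweep(S, 2, ev[seq_len(k)], "*")
  recon <- S %*% t(W)
  recon <- sweep(recon, 2, mu, "+")
  list(reconstruction = recon, series = as.numeric(t(recon)), k = k,
       explained = cum[k])
}

#' Denoise every bin of an ensemble by truncated PCA
#'
#' Applies [embed_bin_series()] + [pca_denoise_bin()] bin by bin and writes
#' the reconstructed values back in time order. Cells that were imputed for
#' the embedding (padding, pre-existing missing values) are restored to their
#' original values afterwards, so denoising never invents data. For the lag
#' layout, overlapping window reconstructions are combined by anti-diagonal
#' averaging.
#'
#' @param ensemble A [spectrum_ensemble].
#' @param var_threshold Fraction of variance to retain per bin.
#' @param layout,width See [embed_bin_series()].
#' @param eigen_weighting See [pca_denoise_bin()].
#' @return The denoised [spectrum_ensemble] with a `denoise_report`
#'   attribute: data frame of per-bin retained component count and explained
#'   fraction.
#' @export
denoise_ensemble <- function(ensemble, var_threshold = 0.95,
                             layout = c("daily", "lag"), width = NULL,
                             eigen_weighting = FALSE) {
  layout <- match.arg(layout)
  B <- ensemble$scheme$B
  out <- ensemble$values
  report <- data.frame(bin = seq_len(B), k = NA_integer_,
                       explained = NA_real_, n_imputed = NA_integer_)
  for (b in seq_len(B)) {
    emb <- embed_bin_series(ensemble, b, layout = layout, width = width)
    dn <- pca_denoise_bin(emb$matrix, var_threshold,
                          eigen_weighting = eigen_weighting)
    series <- emb$series
    if (layout == "daily") {
      keep <- !is.na(emb$series_index) & !emb$imputed
      series[emb$series_index[keep]] <- dn$reconstruction[keep]
    } else {
      acc <- cnt <- numeric(length(series))
      keep <- !emb$imputed
      i <- emb$series_index[keep]
      tab <- rowsum(dn$reconstruction[keep], i)
      acc[as.integer(rownames(tab))] <- tab
      cnt_tab <- rowsum(rep(1, sum(keep)), i)
      cnt[as.integer(rownames(cnt_tab))] <- cnt_tab
      series[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    }
    out[, b] <- series
    report$k[b] <- dn$k
    report$explained[b] <- dn$explained
    report$n_imputed[b] <- sum(emb$imputed)
  }
  res <- ensemble
  res$values <- out
  res$provenance <- c(ensemble$provenance, "pca_denoise")
  attr(res, "denoise_report") <- report
  res
}

#' Remove per-bin upper-quantile outliers
#'
#' Per frequency bin (and per site, since an ensemble is one site's data),
#' values strictly above the empirical `q`-quantile (type-7 interpolation of
#' order statistics) are set to missing. Rare, very loud events are thereby
#' excluded without touching the remaining distribution; a constant series
#' loses nothing, since no value is strictly above its own quantile.
#'
#' @param ensemble A [spectrum_ensemble].
#' @param q Quantile level in `(0, 1)`, conventionally `0.9995`.
#' @return The censored [spectrum_ensemble] with an `outlier_report`
#'   attribute: data frame of per-bin removal counts and the threshold used.
#' @export
remove_outliers <- function(ensemble, q = 0.9995) {
  stopifnot(q > 0, q < 1)
  out <- ensemble$values
  B <- ensemble$scheme$B
  report <- data.frame(bin = seq_len(B), threshold = NA_real_,
                       n_removed = 0L)
  for (b in seq_len(B)) {
    v <- out[, b]
    if (all(is.na(v))) next
    thr <- stats::quantile(v, q, na.rm = TRUE, names = FALSE, type = 7)
    drop <- !is.na(v) & v > thr
    out[drop, b] <- NA
    report$threshold[b] <- thr
    report$n_removed[b] <- sum(drop)
  }
  res <- ensemble
  res$values <- out
  res$provenance <- c(ensemble$provenance, "outlier_removal")
  attr(res, "outlier_report") <- list(q = q, quantile_type = 7,
                                      per_bin = report)
  res
}
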