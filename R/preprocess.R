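#' Loading normalization by median centering
#'
#' Within each batch, on log2 values: (1) center each antibody at its
#' cross-sample median; (2) per sample, take the median across antibodies of
#' the centered values as the loading correction factor (CF); (3) subtract
#' each sample's CF from its original log2 values. `CF_linear = 2^CF_log2`
#' is recorded and used by QC bounds. Samples with no observed values are
#' excluded with reason `"manual"`.
#'
#' @param data an [rppa_dataset()] on the log2 scale.
#' @param batch_scope if `TRUE` (default) the procedure runs within each
#'   batch independently.
#' @return list with elements `data` (normalized dataset) and `correction`
#'   (data.frame `sample`, `batch`, `cf_log2`, `cf_linear`).
#' @export
median_center_loading <- function(data, batch_scope = TRUE) {
  stopifnot(inherits(data, "rppa_dataset"))
  if (data$scale != "log2") {
    stop("loading normalization is defined on log2 values; ",
         "call to_log2() first", call. = FALSE)
  }
  all_missing <- rowSums(!is.na(data$values)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " sample(s) with no observed values excluded",
            call. = FALSE)
    data <- exclude_samples(data, which(all_missing), "manual")
  }
  groups <- if (batch_scope) data$meta$batch else rep("all", nrow(data$meta))
  cf <- numeric(nrow(data$values))
  out <- data$values
  for (b in unique(groups)) {
    rows <- which(groups == b)
    M <- data$values[rows, , drop = FALSE]
    ab_med <- apply(M, 2, stats::median, na.rm = TRUE)
    centered <- sweep(M, 2, ab_med)
    cf_b <- apply(centered, 1, stats::median, na.rm = TRUE)
    out[rows, ] <- M - cf_b
    cf[rows] <- cf_b
  }
  correction <- data.frame(sample = sample_key(data$meta),
                           batch = data$meta$batch,
                           cf_log2 = cf, cf_linear = 2^cf,
                           stringsAsFactors = FALSE)
  data$values <- out
  list(data = data, correction = correction)
}

#' Two-batch normalization against shared vehicle controls
#'
#' Both batches must already be loading-normalized log2 data. Antibodies not
#' present in both batches are removed. Per antibody, the mean and SD of the
#' control-regime (DMSO) samples are computed in each batch -- with the t = 0
#' replicates averaged into a single value beforehand, since they would
#' otherwise dominate -- giving `(mu1, s1)` and `(mu2, s2)`. Every individual
#' batch-2 value `x` is then mapped to `mu1 + s1 * (x - mu2) / s2`, so the
#' batch-2 controls agree with batch 1 in mean and SD. An antibody with
#' `s2 = 0` is centered only (`x - mu2 + mu1`) with a warning.
#'
#' @param batch1,batch2 [rppa_dataset()] objects (log2 scale).
#' @param control_regime regime id of the vehicle control.
#' @return the combined dataset; the per-antibody statistics are attached as
#'   attribute `"batch_stats"`.
#' @export
batch_normalize <- function(batch1, batch2, control_regime = "DMSO") {
  stopifnot(inherits(batch1, "rppa_dataset"),
            inherits(batch2, "rppa_dataset"),
            batch1$scale == "log2", batch2$scale == "log2")
  common <- intersect(colnames(batch1$values), colnames(batch2$values))
  if (length(common) == 0) stop("batches share no antibodies", call. = FALSE)
  b1 <- subset_rppa(batch1, antibodies = common)
  b2 <- subset_rppa(batch2, antibodies = common)

  ctrl_stats <- function(d) {
    ctrl <- d$meta$regime == control_regime
    if (!any(ctrl)) stop("batch has no '", control_regime, "' samples",
                         call. = FALSE)
    m <- d$meta[ctrl, , drop = FALSE]
    v <- d$values[ctrl, , drop = FALSE]
    # average replicates within each (cell line, stimulus, time) group first
    grp <- paste(m$cell_line, m$stimulus, m$time_min, sep = "|")
    avg <- rowsum(v, grp, na.rm = TRUE) /
      rowsum((!is.na(v)) * 1, grp)
    list(mu = apply(avg, 2, mean, na.rm = TRUE),
         sd = apply(avg, 2, stats::sd))
  }
  s1 <- ctrl_stats(b1)
  s2 <- ctrl_stats(b2)

  zero_sd <- which(!is.na(s2$sd) & s2$sd == 0)
  if (length(zero_sd) > 0) {
    warning("sd of batch-2 controls is 0 for antibod(ies) ",
            paste(common[zero_sd], collapse = ", "),
            "; centering only", call. = FALSE)
  }
  scale_fac <- ifelse(s2$sd > 0, s1$sd / s2$sd, 1)
  v2 <- sweep(b2$values, 2, s2$mu)        # x - mu2
  v2 <- sweep(v2, 2, scale_fac, `*`)      # * s1/s2
  v2 <- sweep(v2, 2, s1$mu, `+`)          # + mu1
  b2$values <- v2

  out <- bind_rppa(b1, b2)
  stats_tab <- data.frame(antibody = common,
                          mu1 = s1$mu, sd1 = s1$sd,
                          mu2 = s2$mu, sd2 = s2$sd,
                          center_only = seq_along(common) %in% zero_sd,
                          stringsAsFactors = FALSE)
  rownames(stats_tab) <- NULL
  attr(out, "batch_stats") <- stats_tab
  out
}

#' Replicate signal-to-noise ratios at t = 0
#'
#' For each (cell line, phospho antibody, regime) group, SNR = mean of the
#' t = 0 replicates divided by their standard deviation, computed on
#' linear-scale abundances. Groups whose replicates are identical get an
#' infinite-SNR flag; single-replicate groups are skipped with a warning.
#'
#' @param data an [rppa_dataset()]; converted to linear scale internally.
#' @param phospho_only restrict to phospho antibodies when annotation is
#'   available.
#' @param use_linear compute on linear-scale values (the default); set
#'   `FALSE` to use the values as stored.
#' @return data.frame (`cell_line`, `antibody`, `regime`, `n`, `snr`) with
#'   attribute `"grand"` = c(mean, sd) over the finite SNRs.
#' @export
compute_snr <- function(data, phospho_only = TRUE, use_linear = TRUE) {
  stopifnot(inherits(data, "rppa_dataset"))
  d <- if (use_linear) to_linear(data) else data
  abs_use <- colnames(d$values)
  if (phospho_only && any(d$antibodies$is_phospho)) {
    abs_use <- d$antibodies$name[d$antibodies$is_phospho]
  }
  t0 <- d$meta$time_min == 0
  m <- d$meta[t0, , drop = FALSE]
  v <- d$values[t0, abs_use, drop = FALSE]
  grp <- interaction(m$cell_line, m$regime, drop = TRUE)
  res <- list()
  skipped <- 0L
  for (g in levels(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 2) { skipped <- skipped + length(rows); next }
    mu <- colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
    sd_ <- apply(v[rows, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    snr <- ifelse(sd_ == 0, Inf, mu / sd_)
    res[[g]] <- data.frame(cell_line = m$cell_line[rows[1]],
                           antibody = abs_use,
                           regime = m$regime[rows[1]],
                           n = length(rows), snr = snr,
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(skipped, " single-replicate group(s) skipped in SNR computation",
            call. = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  finite <- out$snr[is.finite(out$snr)]
  attr(out, "grand") <- c(mean = mean(finite), sd = stats::sd(finite))
  out
}

#' Flag outlier samples and replicate groups for QC
#'
#' Applies the sample-exclusion criteria: loading correction factor
#' (linear scale) above `cf_bounds[2]` or below `cf_bounds[1]` (strict
#' inequalities); per-sample variance across all antibodies (log2 values)
#' above `var_threshold`; t = 0 replicate groups with SNR below
#' `snr_threshold` are flagged for review only (they mark replicate groups,
#' not automatic exclusions). A manual exclusion list is also supported.
#' Each excluded sample carries exactly one primary reason, with CF bounds
#' taking precedence over variance.
#'
#' @param data an [rppa_dataset()] (log2 scale).
#' @param cf the `correction` table from [median_center_loading()].
#' @param snr_table optional result of [compute_snr()].
#' @param cf_bounds lower/upper bounds on the linear-scale CF.
#' @param var_threshold per-sample variance threshold (log2 units squared).
#' @param snr_threshold SNR review threshold.
#' @param manual character vector of sample keys to exclude manually.
#' @return object of class `qc_report`: list with `samples` (per-sample
#'   flags), `snr_flags` (replicate groups under review) and `excluded`
#'   (sample key + primary reason).
#' @export
qc_flag_samples <- function(data, cf, snr_table = NULL,
                            cf_bounds = c(0.25, 2.5),
                            var_threshold = 40,
                            snr_threshold = 1,
                            manual = character()) {
  stopifnot(inherits(data, "rppa_dataset"))
  key <- sample_key(data$meta)
  cf_lin <- cf$cf_linear[match(key, cf$sample)]
  variance <- apply(data$values, 1, stats::var, na.rm = TRUE)
  cf_flag <- !is.na(cf_lin) &
    (cf_lin > cf_bounds[2] | cf_lin < cf_bounds[1])
  var_flag <- !is.na(variance) & variance > var_threshold
  manual_flag <- key %in% manual

  reason <- rep(NA_character_, length(key))
  reason[manual_flag] <- "manual"
  reason[var_flag] <- "variance"
  reason[cf_flag] <- "cf_bounds"   # primary reason precedence

  snr_flags <- NULL
  if (!is.null(snr_table)) {
    low <- !is.na(snr_table$snr) & snr_table$snr < snr_threshold
    snr_flags <- snr_table[low, c("cell_line", "antibody", "regime", "snr"),
                           drop = FALSE]
    rownames(snr_flags) <- NULL
  }
  excluded <- data.frame(sample = key[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  structure(list(samples = data.frame(sample = key, cf_linear = cf_lin,
                                      cf_flag = cf_flag,
                                      variance = variance,
                                      var_flag = var_flag,
                                      stringsAsFactors = FALSE),
                 snr_flags = snr_flags,
                 excluded = excluded,
                 thresholds = list(cf_bounds = cf_bounds,
                                   var_threshold = var_threshold,
                                   snr_threshold = snr_threshold)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$excluded), "sample(s) excluded (",
      paste(names(table(x$excluded$reason)),
            table(x$excluded$reason), collapse = ", "), ")\n")
  if (!is.null(x$snr_flags) && nrow(x$snr_flags) > 0) {
    cat("  ", nrow(x$snr_flags), "replicate group(s) under SNR review\n")
  }
  invisible(x)
}

#' Apply a QC report's exclusions to a dataset
#'
#' @param data an [rppa_dataset()].
#' @param report a [qc_flag_samples()] result.
#' @return the dataset with flagged samples removed and logged.
#' @export
apply_qc <- function(data, report) {
  stopifnot(inherits(report, "qc_report"))
  key <- sample_key(data$meta)
  for (r in unique(report$excluded$reason)) {
    drop <- which(key %in%
                    report$excluded$sample[report$excluded$reason == r])
    data <- exclude_samples(data, drop, r)
    key <- sample_key(data$meta)
  }
  data
}

#' Reduce to a deduplicated phosphoprotein panel
#'
#' Keeps phospho antibodies observed in every cell line, then removes
#' redundant antibodies: for each pair of antibodies against the same target
#' protein, the Pearson correlation is computed per cell line, and if it
#' exceeds `r_threshold` in *every* cell line one member of the pair is
#' dropped (the one later in the priority order; default lexicographic).
#'
#' @param data an [rppa_dataset()].
#' @param r_threshold correlation threshold (strict `>` in all cell lines).
#' @param priority optional character vector; antibodies earlier in this
#'   vector are preferred when a pair is collapsed.
#' @return list with `data` (reduced dataset) and `dropped`
#'   (data.frame `kept`, `dropped`, `min_r`).
#' @export
select_phospho_panel <- function(data, r_threshold = 0.9, priority = NULL) {
  stopifnot(inherits(data, "rppa_dataset"))
  ab <- data$antibodies
  keep <- if (any(ab$is_phospho)) ab$name[ab$is_phospho] else ab$name
  lines <- unique(data$meta$cell_line)
  observed_everywhere <- vapply(keep, function(a) {
    all(vapply(lines, function(cl) {
      any(!is.na(data$values[data$meta$cell_line == cl, a]))
    }, logical(1)))
  }, logical(1))
  keep <- keep[observed_everywhere]

  ab_keep <- ab[match(keep, ab$name), , drop = FALSE]
  dropped <- data.frame(kept = character(), dropped = character(),
                        min_r = numeric(), stringsAsFactors = FALSE)
  for (tg in unique(ab_keep$target_node)) {
    members <- ab_keep$name[ab_keep$target_node == tg]
    if (length(members) < 2) next
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (j <= i) next
      a <- members[i]; b <- members[j]
      if (!(a %in% keep) || !(b %in% keep)) next
      r_per_line <- vapply(lines, function(cl) {
        rows <- data$meta$cell_line == cl
        suppressWarnings(stats::cor(data$values[rows, a],
                                    data$values[rows, b],
                                    use = "complete.obs"))
      }, numeric(1))
      if (all(!is.na(r_per_line)) && all(r_per_line > r_threshold)) {
        ord <- if (!is.null(priority)) {
          match(c(a, b), priority, nomatch = .Machine$integer.max)
        } else rank(c(a, b))
        loser <- c(a, b)[which.max(ord)]
        winner <- setdiff(c(a, b), loser)
        keep <- setdiff(keep, loser)
        dropped <- rbind(dropped,
                         data.frame(kept = winner, dropped = loser,
                                    min_r = min(r_per_line),
                                    stringsAsFactors = FALSE))
      }
    }
  }
  list(data = subset_rppa(data, antibodies = keep), dropped = dropped)
}

#' Average replicates within (cell line, stimulus, regime, time) groups
#'
#' Averaging is done on the log2 scale. The number of replicate rows
#' contributing to each averaged sample is retained in the metadata column
#' `n_reps` for downstream variance pooling.
#'
#' @param data an [rppa_dataset()] (log2 scale).
#' @return the replicate-averaged dataset (one row per group).
#' @export
average_replicates <- function(data) {
  stopifnot(inherits(data, "rppa_dataset"))
  if (data$scale != "log2") {
    stop("replicate averaging is defined on log2 values", call. = FALSE)
  }
  m <- data$meta
  grp <- paste(m$cell_line, m$stimulus, m$regime, m$time_min, sep = "|")
  ugrp <- unique(grp)
  sums <- rowsum(ifelse(is.na(data$values), 0, data$values), grp)[ugrp, ,
                                                                  drop = FALSE]
  counts <- rowsum((!is.na(data$values)) * 1, grp)[ugrp, , drop = FALSE]
  avg <- sums / counts
  avg[counts == 0] <- NA_real_
  first <- match(ugrp, grp)
  meta <- m[first, , drop = FALSE]
  meta$replicate <- 1L
  meta$n_reps <- as.integer(table(grp)[ugrp])
  out <- rppa_dataset(avg, meta, data$antibodies, scale = "log2")
  out$excluded <- data$excluded
  out
}

#' Linear-interpolation imputation of a single time series
#'
#' Interior missing values are interpolated linearly in real time (minutes);
#' leading/trailing missing values take the nearest observed value.
#'
#' @param times numeric time points (minutes), sorted.
#' @param values numeric values with `NA` for missing.
#' @return list with `values` (completed) and `imputed` (logical flags).
#' @export
impute_series <- function(times, values) {
  obs <- !is.na(values)
  if (sum(obs) < 2) {
    stop("need at least 2 observed time points to impute", call. = FALSE)
  }
  if (all(obs)) return(list(values = values, imputed = !obs))
  filled <- stats::approx(times[obs], values[obs], xout = times,
                          method = "linear", rule = 2)$y
  list(values = filled, imputed = !obs)
}

#' Impute missing values across all time courses of a dataset
#'
#' Applies [impute_series()] per (cell line, stimulus, regime, antibody)
#' series. Series with fewer than 2 observed time points are left missing
#' with a warning. Imputed cells are flagged in the `"imputed"` attribute.
#'
#' @param data a replicate-averaged [rppa_dataset()].
#' @return the completed dataset.
#' @export
impute_time_course <- function(data) {
  stopifnot(inherits(data, "rppa_dataset"))
  m <- data$meta
  grp <- paste(m$cell_line, m$stimulus, m$regime, sep = "|")
  imputed <- matrix(FALSE, nrow(data$values), ncol(data$values),
                    dimnames = dimnames(data$values))
  n_bad <- 0L
  for (g in unique(grp)) {
    rows <- which(grp == g)
    ord <- rows[order(m$time_min[rows])]
    tt <- m$time_min[ord]
    for (j in seq_len(ncol(data$values))) {
      v <- data$values[ord, j]
      if (!anyNA(v)) next
      if (sum(!is.na(v)) < 2) { n_bad <- n_bad + 1L; next }
      res <- impute_series(tt, v)
      data$values[ord, j] <- res$values
      imputed[ord, j] <- res$imputed
    }
  }
  if (n_bad > 0) {
    warning(n_bad, " series with <2 observed points left unimputed",
            call. = FALSE)
  }
  attr(data, "imputed") <- imputed
  data
}

#' Run the full preprocessing chain
#'
#' Order of operations: loading normalization (within batch) -> optional
#' two-batch normalization -> QC exclusions -> replicate averaging ->
#' phospho panel selection -> time-course imputation. Input data on the
#' linear scale are log2-transformed first.
#'
#' @param data an [rppa_dataset()]; if `batch2` is supplied, `data` is
#'   batch 1.
#' @param batch2 optional second-batch dataset to merge via
#'   [batch_normalize()].
#' @param cf_bounds,var_threshold,snr_threshold QC thresholds, see
#'   [qc_flag_samples()].
#' @param r_threshold panel-collapse correlation threshold.
#' @param manual sample keys to exclude manually.
#' @param select_panel run [select_phospho_panel()] (default `TRUE`).
#' @return list with `data` (analysis-ready dataset), `qc` (the
#'   [qc_flag_samples()] report), `correction`, `snr`, `dropped_antibodies`.
#' @export
preprocess_rppa <- function(data, batch2 = NULL,
                            cf_bounds = c(0.25, 2.5),
                            var_threshold = 40,
                            snr_threshold = 1,
                            r_threshold = 0.9,
                            manual = character(),
                            select_panel = TRUE) {
  data <- to_log2(data)
  norm1 <- median_center_loading(data)
  data <- norm1$data
  correction <- norm1$correction
  if (!is.null(batch2)) {
    norm2 <- median_center_loading(to_log2(batch2))
    data <- batch_normalize(data, norm2$data)
    correction <- rbind(correction, norm2$correction)
  }
  snr <- compute_snr(data)
  qc <- qc_flag_samples(data, correction, snr,
                        cf_bounds = cf_bounds,
                        var_threshold = var_threshold,
                        snr_threshold = snr_threshold,
                        manual = manual)
  clean <- apply_qc(data, qc)
  panel <- if (select_panel) {
    select_phospho_panel(clean, r_threshold = r_threshold)
  } else list(data = clean, dropped = NULL)
  averaged <- impute_time_course(average_replicates(panel$data))
  list(data = averaged, unaveraged = panel$data, qc = qc,
       correction = correction, snr = snr,
       dropped_antibodies = panel$dropped)
}
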