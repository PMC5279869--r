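#' Paired t test on matched time-course means
#'
#' Tests whether the mean abundance over the time course differs between the
#' control and inhibitor arms, pairing by time point: with differences
#' `d_t = dmso_t - inhib_t`, `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom. The effect size is `mean(d)`, the mean log2 ratio
#' between control and inhibitor conditions (a positive effect means the
#' abundance decreased under inhibition).
#'
#' Degenerate series (zero variance of the differences) return `p = 0` when
#' the mean difference is nonzero and `p = 1` otherwise, with a flag.
#'
#' @param dmso,inhib numeric vectors of equal length (log2 scale), paired by
#'   time point.
#' @return list with `t`, `p`, `effect`, `df`, `degenerate`.
#' @export
paired_mean_test <- function(dmso, inhib) {
  stopifnot(length(dmso) == length(inhib), length(dmso) >= 2)
  d <- dmso - inhib
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m != 0) {
      return(list(t = Inf * sign(m), p = 0, effect = m, df = n - 1,
                  degenerate = TRUE))
    }
    return(list(t = 0, p = 1, effect = 0, df = n - 1, degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1),
       effect = m, df = n - 1, degenerate = FALSE)
}

#' Detect a stimulus-response peak window in a control time course
#'
#' A series is "peak"-shaped when its maximum occurs at an interior time
#' index and exceeds both the first and last values by more than
#' `k_peak * rep_sd`. The window is the maximal contiguous run of interior
#' indices, containing the maximum, whose values exceed the half-height
#' `(max + baseline) / 2` with `baseline = min(first, last)`. Windows
#' narrower than 2 points are discarded.
#'
#' @param dmso_series complete numeric series (post-imputation).
#' @param rep_sd replicate-variation scale used for the exceedance test.
#' @param k_peak exceedance multiplier.
#' @return integer vector of window indices, or `NULL` when the series is
#'   not peak-shaped.
#' @export
detect_peak_window <- function(dmso_series, rep_sd, k_peak = 1.0) {
  n <- length(dmso_series)
  if (n < 3 || anyNA(dmso_series)) return(NULL)
  imax <- which.max(dmso_series)
  if (imax == 1L || imax == n) return(NULL)
  mx <- dmso_series[imax]
  if (!(mx > dmso_series[1] + k_peak * rep_sd &&
        mx > dmso_series[n] + k_peak * rep_sd)) return(NULL)
  baseline <- min(dmso_series[1], dmso_series[n])
  half <- (mx + baseline) / 2
  interior <- 2:(n - 1)
  above <- dmso_series[interior] > half
  # maximal contiguous run of interior indices containing the maximum
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- which(interior == imax)
  run_id <- which(starts <= pos & ends >= pos)
  if (!runs$values[run_id]) return(NULL)
  window <- interior[starts[run_id]:ends[run_id]]
  if (length(window) < 2) return(NULL)
  window
}

#' Two-stage adaptive linear step-up FDR procedure
#'
#' Stage 1 runs the linear step-up procedure at level `q' = q / (1 + q)`,
#' giving `r1` rejections. If `r1 = 0` nothing is rejected; if `r1 = m`
#' everything is. Otherwise the number of true nulls is estimated as
#' `m0 = m - r1` and stage 2 reruns the linear step-up at level
#' `q' * m / m0`. Adjusted values are reported on a scale where rejection
#' corresponds to `q_fdr <= q`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target FDR level.
#' @param method `"two_stage"` (default) or plain one-stage `"bh"` for
#'   sensitivity analysis.
#' @return list with `reject` (logical), `q_fdr` (adjusted values), `r1`,
#'   `m0`.
#' @export
adaptive_fdr <- function(pvalues, q = 0.05,
                         method = c("two_stage", "bh")) {
  method <- match.arg(method)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  bh <- stats::p.adjust(pvalues, method = "BH")
  if (method == "bh") {
    return(list(reject = bh <= q, q_fdr = bh, r1 = sum(bh <= q), m0 = m))
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh <= q1)
  if (r1 == 0) {
    m0 <- m
    reject <- rep(FALSE, m)
  } else if (r1 == m) {
    m0 <- 1L
    reject <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    reject <- bh <= q1 * m / m0
  }
  q_fdr <- pmin(1, bh * (1 + q) * m0 / m)
  list(reject = reject, q_fdr = q_fdr, r1 = r1, m0 = m0)
}

#' Pooled replicate standard deviation across two arms
#'
#' At each time point the replicate variances of the control and inhibitor
#' arms are pooled with degree-of-freedom weights; the square roots are then
#' averaged over the time points that carry any replication.
#'
#' @param dmso_reps,inhib_reps lists (one element per time point) of numeric
#'   replicate vectors.
#' @return list with `sd` (the averaged pooled SD; `NA` with
#'   `fallback = TRUE` when no time point is replicated), `per_time`, and
#'   `fallback`.
#' @export
pooled_replicate_sd <- function(dmso_reps, inhib_reps) {
  stopifnot(length(dmso_reps) == length(inhib_reps))
  per_time <- rep(NA_real_, length(dmso_reps))
  for (t in seq_along(dmso_reps)) {
    ss <- 0
    df <- 0
    for (arm in list(dmso_reps[[t]], inhib_reps[[t]])) {
      arm <- arm[!is.na(arm)]
      if (length(arm) >= 2) {
        ss <- ss + (length(arm) - 1) * stats::var(arm)
        df <- df + length(arm) - 1
      }
    }
    if (df > 0) per_time[t] <- sqrt(ss / df)
  }
  ok <- !is.na(per_time)
  if (!any(ok)) {
    return(list(sd = NA_real_, per_time = per_time, fallback = TRUE))
  }
  list(sd = mean(per_time[ok]), per_time = per_time, fallback = FALSE)
}

#' Salient-change calls for one (context, regime) panel
#'
#' Core calling routine operating directly on matrices. For each protein:
#' a paired test over all time points gives `p_full`; when the control
#' series is peak-shaped ([detect_peak_window()]), the test is repeated
#' restricted to the window and the smaller p-value is retained (with the
#' effect size and replicate SD recomputed over the same window). The
#' retained p-values are corrected across the panel with [adaptive_fdr()],
#' and a protein is salient iff its FDR value is below `q` *and* its
#' absolute effect is at least `tau` times the (window-matched) pooled
#' replicate SD. The sign convention is `-sign(effect)`: `-1` marks a
#' decrease in abundance under inhibition, `+1` an increase.
#'
#' @param dmso_mat,inhib_mat numeric matrices, proteins x time points
#'   (log2, replicate-averaged, imputed).
#' @param rep_sd pooled replicate SD: either a vector (one per protein) or a
#'   proteins x time matrix of per-time pooled SDs (then averaged over the
#'   tested window).
#' @param q FDR level.
#' @param tau effect-size multiplier.
#' @param k_peak peak-detection exceedance multiplier.
#' @param peak_retest enable the peak-window retest.
#' @param fdr_method passed to [adaptive_fdr()].
#' @return data.frame with one row per protein: `protein`, `p_full`,
#'   `p_peak`, `p_final`, `q_fdr`, `effect`, `rep_sd`, `salient`, `sign`,
#'   `peak_used`.
#' @export
salient_change_panel <- function(dmso_mat, inhib_mat, rep_sd,
                                 q = 0.05, tau = 1.0, k_peak = 1.0,
                                 peak_retest = TRUE,
                                 fdr_method = "two_stage") {
  stopifnot(all(dim(dmso_mat) == dim(inhib_mat)))
  n_prot <- nrow(dmso_mat)
  n_time <- ncol(dmso_mat)
  sd_mat <- if (is.matrix(rep_sd)) rep_sd else
    matrix(rep_sd, n_prot, n_time)
  sd_all <- rowMeans(sd_mat, na.rm = TRUE)
  sd_all[is.nan(sd_all)] <- NA_real_
  med_sd <- stats::median(sd_all, na.rm = TRUE)
  sd_all[is.na(sd_all)] <- med_sd   # dataset-level fallback

  p_full <- p_peak <- p_final <- effect <- sd_used <- numeric(n_prot)
  peak_used <- logical(n_prot)
  for (i in seq_len(n_prot)) {
    full <- paired_mean_test(dmso_mat[i, ], inhib_mat[i, ])
    p_full[i] <- full$p
    effect[i] <- full$effect
    sd_used[i] <- sd_all[i]
    p_peak[i] <- NA_real_
    p_final[i] <- full$p
    if (peak_retest) {
      win <- detect_peak_window(dmso_mat[i, ], sd_all[i], k_peak = k_peak)
      if (!is.null(win)) {
        pk <- paired_mean_test(dmso_mat[i, win], inhib_mat[i, win])
        p_peak[i] <- pk$p
        if (pk$p < full$p) {
          peak_used[i] <- TRUE
          p_final[i] <- pk$p
          effect[i] <- pk$effect
          w_sd <- mean(sd_mat[i, win], na.rm = TRUE)
          sd_used[i] <- if (is.nan(w_sd)) sd_all[i] else w_sd
        }
      }
    }
  }
  fdr <- adaptive_fdr(p_final, q = q, method = fdr_method)
  salient <- fdr$reject & abs(effect) >= tau * sd_used
  proteins <- rownames(dmso_mat)
  if (is.null(proteins)) proteins <- paste0("P", seq_len(n_prot))
  data.frame(protein = proteins,
             p_full = p_full, p_peak = p_peak, p_final = p_final,
             q_fdr = fdr$q_fdr, effect = effect, rep_sd = sd_used,
             salient = salient,
             sign = ifelse(salient, -sign(effect), 0L),
             peak_used = peak_used,
             stringsAsFactors = FALSE)
}

#' Call salient changes under an inhibitor regime in one context
#'
#' Extracts the control and regime time courses for the given context from a
#' preprocessed (post-QC, log2) dataset with replicates, computes the pooled
#' replicate SD per protein and time point, replicate-averages, imputes, and
#' delegates to [salient_change_panel()].
#'
#' @param data post-QC [rppa_dataset()] (log2 scale, replicates retained).
#' @param regime an [inhibitor_regime()] or regime id to test.
#' @param context list/row with `cell_line` and `stimulus`.
#' @param control_regime the control regime id.
#' @param ... further arguments passed to [salient_change_panel()].
#' @return data.frame of calls augmented with `cell_line`, `stimulus`,
#'   `regime`, or `NULL` (with a warning) when an arm is missing.
#' @export
call_salient_changes <- function(data, regime, context,
                                 control_regime = "DMSO", ...) {
  stopifnot(inherits(data, "rppa_dataset"))
  regime_id <- if (inherits(regime, "inhibitor_regime")) regime$regime_id
  else as.character(regime)
  m <- data$meta
  in_ctx <- m$cell_line == context$cell_line &
    m$stimulus == context$stimulus
  dmso_rows <- which(in_ctx & m$regime == control_regime)
  inhib_rows <- which(in_ctx & m$regime == regime_id)
  if (length(dmso_rows) == 0 || length(inhib_rows) == 0) {
    warning("context ", context$cell_line, "/", context$stimulus,
            ": missing ", if (length(dmso_rows) == 0) control_regime else
              regime_id, " arm; skipped", call. = FALSE)
    return(NULL)
  }
  times <- sort(unique(m$time_min[c(dmso_rows, inhib_rows)]))
  n_prot <- ncol(data$values)

  series_mat <- function(rows) {
    out <- matrix(NA_real_, n_prot, length(times),
                  dimnames = list(colnames(data$values), times))
    for (ti in seq_along(times)) {
      rr <- rows[m$time_min[rows] == times[ti]]
      if (length(rr) > 0) {
        out[, ti] <- colMeans(data$values[rr, , drop = FALSE], na.rm = TRUE)
      }
    }
    # linear-interpolation imputation per protein
    for (i in seq_len(n_prot)) {
      if (anyNA(out[i, ]) && sum(!is.na(out[i, ])) >= 2) {
        out[i, ] <- impute_series(times, out[i, ])$values
      }
    }
    out
  }
  dmso_mat <- series_mat(dmso_rows)
  inhib_mat <- series_mat(inhib_rows)

  sd_mat <- matrix(NA_real_, n_prot, length(times))
  for (i in seq_len(n_prot)) {
    dr <- lapply(times, function(tt)
      data$values[dmso_rows[m$time_min[dmso_rows] == tt], i])
    ir <- lapply(times, function(tt)
      data$values[inhib_rows[m$time_min[inhib_rows] == tt], i])
    sd_mat[i, ] <- pooled_replicate_sd(dr, ir)$per_time
  }
  calls <- salient_change_panel(dmso_mat, inhib_mat, sd_mat, ...)
  calls$cell_line <- context$cell_line
  calls$stimulus <- context$stimulus
  calls$regime <- regime_id
  calls
}

#' Build a causal descendancy matrix from salient-change calls
#'
#' Rows are phosphoproteins, columns are contexts; entries are the call
#' signs (+1 increase under inhibition, -1 decrease, 0 no salient change).
#' Context cells with no call available are `NA`, not 0.
#'
#' @param calls data.frame of stacked [call_salient_changes()] results for
#'   one regime.
#' @param contexts optional context data.frame ([context_grid()]) fixing the
#'   column order.
#' @param proteins optional protein order for the rows.
#' @return integer matrix with attribute `"contexts"`.
#' @export
build_descendancy_matrix <- function(calls, contexts = NULL,
                                     proteins = NULL) {
  if (is.null(contexts)) {
    contexts <- unique(calls[, c("cell_line", "stimulus")])
    contexts$context <- paste(contexts$cell_line, contexts$stimulus,
                              sep = ".")
  }
  if (is.null(proteins)) proteins <- unique(calls$protein)
  M <- matrix(NA_integer_, length(proteins), nrow(contexts),
              dimnames = list(proteins, contexts$context))
  ctx_of <- paste(calls$cell_line, calls$stimulus, sep = ".")
  idx <- cbind(match(calls$protein, proteins),
               match(ctx_of, contexts$context))
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  M[idx[ok, , drop = FALSE]] <- as.integer(calls$sign[ok])
  attr(M, "contexts") <- contexts
  M
}

#' Context-difference statistics over descendancy matrices
#'
#' For each regime and unordered pair of contexts, counts the
#' phosphoproteins salient (nonzero) in exactly one of the two contexts
#' (presence/absence, ignoring sign; proteins missing in either context are
#' skipped). Returns the grand mean over all regimes and pairs, the mean
#' over pairs sharing a stimulus (cell-line comparisons), and the mean over
#' pairs sharing a cell line (stimulus comparisons).
#'
#' @param cdms named list of [build_descendancy_matrix()] results (one per
#'   regime), all carrying a `"contexts"` attribute.
#' @return list with `grand_mean`, `mean_same_stimulus`,
#'   `mean_same_cell_line` and the per-pair table `pairs`.
#' @export
context_difference_stats <- function(cdms) {
  if (!is.list(cdms)) cdms <- list(cdm = cdms)
  rows <- list()
  for (nm in names(cdms)) {
    M <- cdms[[nm]]
    ctx <- attr(M, "contexts")
    stopifnot(!is.null(ctx), ncol(M) >= 2)
    nz <- M != 0
    for (a in seq_len(ncol(M) - 1)) for (b in (a + 1):ncol(M)) {
      both <- !is.na(nz[, a]) & !is.na(nz[, b])
      count <- sum(xor(nz[both, a], nz[both, b]))
      rows[[length(rows) + 1L]] <-
        data.frame(regime = nm,
                   context_a = colnames(M)[a], context_b = colnames(M)[b],
                   same_stimulus = ctx$stimulus[a] == ctx$stimulus[b],
                   same_cell_line = ctx$cell_line[a] == ctx$cell_line[b],
                   n_different = count, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  list(grand_mean = mean(pairs$n_different),
       mean_same_stimulus =
         mean(pairs$n_different[pairs$same_stimulus &
                                  !pairs$same_cell_line]),
       mean_same_cell_line =
         mean(pairs$n_different[pairs$same_cell_line &
                                  !pairs$same_stimulus]),
       pairs = pairs)
}
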