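make_matrix_dataset <- function(values, batch = "b1", regime = "DMSO",
                                cell_line = "MCF7") {
  n <- nrow(values)
  meta <- data.frame(cell_line = cell_line, stimulus = "EGF",
                     regime = regime, time_min = 0,
                     replicate = seq_len(n), batch = batch,
                     stringsAsFactors = FALSE)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("AB", seq_len(ncol(values)))
  }
  rppa_dataset(values, meta, scale = "log2")
}

test_that("median centering reproduces the worked 3x3 example", {
  v <- rbind(c(0, 1, 2), c(1, 2, 3), c(2, 3, 4))
  d <- make_matrix_dataset(v)
  res <- median_center_loading(d)
  expect_equal(res$correction$cf_log2, c(-1, 0, 1))
  expect_equal(res$correction$cf_linear, c(0.5, 1, 2))
  for (i in 1:3) {
    expect_equal(unname(res$data$values[i, ]), c(1, 2, 3))
  }
  # all-zero matrix is a fixed point with CF_linear = 1
  d0 <- make_matrix_dataset(matrix(0, 3, 3))
  res0 <- median_center_loading(d0)
  expect_true(all(res0$data$values == 0))
  expect_true(all(res0$correction$cf_linear == 1))
})

test_that("a loading artifact moves the CF, not the normalized values", {
  set.seed(1)
  v <- matrix(rnorm(5 * 7, mean = 6), 5, 7)
  # keep the perturbed sample above every antibody median so the
  # perturbation cannot move the medians themselves
  v[3, ] <- apply(v, 2, max) + 0.1
  d <- make_matrix_dataset(v)
  base <- median_center_loading(d)
  # multiply one sample's linear values by 8 = +3 log2
  v2 <- v
  v2[3, ] <- v2[3, ] + 3
  pert <- median_center_loading(make_matrix_dataset(v2))
  expect_equal(pert$correction$cf_linear[3],
               8 * base$correction$cf_linear[3])
  expect_equal(pert$data$values[3, ], base$data$values[3, ])
  # oracle: recompute steps 1-3 by hand
  ab_med <- apply(v2, 2, median)
  centered <- sweep(v2, 2, ab_med)
  cf <- apply(centered, 1, median)
  expect_equal(unname(pert$correction$cf_log2), unname(cf))
  expect_equal(unname(pert$data$values), unname(v2 - cf))
})

test_that("median centering invariant holds on random matrices", {
  set.seed(42)
  for (i in 1:100) {
    v <- matrix(rnorm(6 * 9, sd = 2), 6, 9)
    res <- median_center_loading(make_matrix_dataset(v))
    ab_med <- apply(v, 2, median)
    resid <- sweep(res$data$values, 2, ab_med)
    expect_lt(max(abs(apply(resid, 1, median))), 1e-10)
  }
  # idempotence on additively structured data (sample + antibody effects):
  # renormalizing normalized data gives CF_log2 = 0 exactly
  a <- rnorm(6)
  b <- rnorm(9)
  v <- outer(a, rep(1, 9)) + outer(rep(1, 6), b)
  once <- median_center_loading(make_matrix_dataset(v))
  twice <- median_center_loading(once$data)
  expect_lt(max(abs(twice$correction$cf_log2)), 1e-12)
  expect_equal(twice$data$values, once$data$values, tolerance = 1e-12)
})

test_that("batch transform matches the printed formula and its fixed point", {
  # x = 5, mu1 = 0, s1 = 1, mu2 = 4, s2 = 2  ->  0.5
  expect_equal(0 + 1 * (5 - 4) / 2, 0.5)
  two_batch <- function(shift, scale) {
    set.seed(8)
    v1 <- matrix(rnorm(8 * 4, mean = 5), 8, 4,
                 dimnames = list(NULL, paste0("AB", 1:4)))
    meta1 <- data.frame(cell_line = "UACC812", stimulus = "EGF",
                        regime = rep(c("DMSO", "AZD8055"), each = 4),
                        time_min = rep(c(0, 0, 5, 15), 2),
                        replicate = c(1, 2, 1, 1, 1, 2, 1, 1),
                        batch = "b1", stringsAsFactors = FALSE)
    b1 <- rppa_dataset(v1, meta1, scale = "log2")
    v2 <- matrix(rnorm(8 * 4, mean = 5), 8, 4,
                 dimnames = list(NULL, paste0("AB", 1:4)))
    meta2 <- meta1
    meta2$batch <- "b2"
    meta2$regime <- rep(c("DMSO", "BEZ235"), each = 4)
    b2 <- rppa_dataset(v2 * scale + shift, meta2, scale = "log2")
    list(b1 = b1, b2 = b2)
  }
  ctrl_stats <- function(d, batch) {
    rows <- d$meta$batch == batch & d$meta$regime == "DMSO"
    m <- d$meta[rows, ]
    v <- d$values[rows, , drop = FALSE]
    grp <- paste(m$stimulus, m$time_min)
    avg <- rowsum(v, grp)
    avg <- avg / as.vector(table(grp)[rownames(avg)])
    list(mu = colMeans(avg), sd = apply(avg, 2, sd))
  }
  # identical control stats -> identity transform
  bb <- two_batch(shift = 0, scale = 1)
  b2_copy <- bb$b1
  b2_copy$meta$batch <- "b2"
  same <- batch_normalize(bb$b1, b2_copy)
  expect_equal(same$values[same$meta$batch == "b2", ],
               bb$b1$values, ignore_attr = TRUE)
  # planted affine batch effect is removed exactly
  bb <- two_batch(shift = 1.5, scale = 2)
  combined <- batch_normalize(bb$b1, bb$b2)
  s1 <- ctrl_stats(combined, "b1")
  s2 <- ctrl_stats(combined, "b2")
  expect_equal(s2$mu, s1$mu, tolerance = 1e-10)
  expect_equal(s2$sd, s1$sd, tolerance = 1e-10)
  # oracle: apply the printed formula independently per value
  st <- attr(combined, "batch_stats")
  raw2 <- bb$b2$values
  manual <- sweep(sweep(sweep(raw2, 2, st$mu2), 2, st$sd1 / st$sd2, `*`),
                  2, st$mu1, `+`)
  expect_equal(combined$values[combined$meta$batch == "b2", ], manual,
               ignore_attr = TRUE)
})

test_that("zero-variance controls fall back to centering with a warning", {
  v1 <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("A", "B")))
  meta <- data.frame(cell_line = "UACC812", stimulus = c("EGF", "HGF"),
                     regime = "DMSO", time_min = 0, replicate = 1,
                     batch = "b1", stringsAsFactors = FALSE)
  b1 <- rppa_dataset(v1, meta, scale = "log2")
  v2 <- matrix(c(5, 5, 1, 2), 2, 2, dimnames = list(NULL, c("A", "B")))
  meta2 <- meta
  meta2$batch <- "b2"
  b2 <- rppa_dataset(v2, meta2, scale = "log2")   # antibody A has sd 0
  expect_warning(out <- batch_normalize(b1, b2), "centering only")
  got <- out$values[out$meta$batch == "b2", "A"]
  expect_equal(unname(got), c(5, 5) - 5 + mean(c(1, 2)))
})

test_that("QC thresholds use strict inequalities and one primary reason", {
  v <- matrix(rnorm(4 * 6), 4, 6)
  d <- make_matrix_dataset(v)
  key <- with(d$meta, paste(cell_line, stimulus, regime, time_min,
                            replicate, batch, sep = "|"))
  cf <- data.frame(sample = key, batch = "b1",
                   cf_log2 = log2(c(2.5, 2.51, 0.25, 1)),
                   cf_linear = c(2.5, 2.51, 0.25, 1),
                   stringsAsFactors = FALSE)
  rep <- qc_flag_samples(d, cf)
  expect_equal(rep$samples$cf_flag, c(FALSE, TRUE, FALSE, FALSE))
  # variance > 40 flagged; CF takes precedence as primary reason
  v2 <- v
  v2[2, ] <- c(-10, 10, -10, 10, -10, 10)   # variance ~ 120 > 40
  d2 <- make_matrix_dataset(v2)
  rep2 <- qc_flag_samples(d2, cf)
  expect_true(rep2$samples$var_flag[2])
  expect_equal(rep2$excluded$reason[rep2$excluded$sample == key[2]],
               "cf_bounds")
  # variance exactly at the threshold is not flagged (strict >)
  vexact <- var(v2[2, ])
  expect_false(qc_flag_samples(d2, cf,
                               var_threshold = vexact)$samples$var_flag[2])
})

test_that("planted loading outliers are always caught (recall 1)", {
  set.seed(11)
  for (i in 1:20) {
    v <- matrix(rnorm(8 * 10, mean = 5, sd = 0.3), 8, 10)
    d <- make_matrix_dataset(v)
    bad <- sample(8, 2)
    d <- inject_batch_and_outliers(
      d, NULL, data.frame(sample = bad, multiplier = 8))
    res <- median_center_loading(d)
    rep <- qc_flag_samples(res$data, res$correction)
    flagged <- which(rep$samples$cf_flag)
    expect_true(all(bad %in% flagged))
  }
})

test_that("SNR follows mean/SD of t=0 replicates with degenerate flags", {
  v <- log2(rbind(c(2, 3), c(4, 3), c(3, 3)))
  colnames(v) <- c("A", "B")
  d <- make_matrix_dataset(v)
  d$antibodies$is_phospho <- TRUE
  snr <- compute_snr(d)
  # replicates {2,4}, {3} pattern: A has linear replicates 2,4,3
  a <- snr$snr[snr$antibody == "A"]
  expect_equal(a, mean(c(2, 4, 3)) / sd(c(2, 4, 3)))
  expect_true(is.infinite(snr$snr[snr$antibody == "B"]))
  # two-replicate toy: {2, 4} -> 3/sqrt(2)
  v2 <- log2(matrix(c(2, 4), 2, 1, dimnames = list(NULL, "A")))
  d2 <- make_matrix_dataset(v2)
  expect_equal(compute_snr(d2, phospho_only = FALSE)$snr, 3 / sqrt(2))
})

test_that("grand mean SNR tracks 1/CV for lognormal replicate noise", {
  set.seed(99)
  cv <- 0.1
  n_groups <- 500
  n_rep <- 4
  meta <- data.frame(cell_line = rep(sprintf("G%03d", seq_len(n_groups)),
                                     each = n_rep),
                     stimulus = "EGF", regime = "DMSO", time_min = 0,
                     replicate = rep(seq_len(n_rep), n_groups),
                     batch = "b1", stringsAsFactors = FALSE)
  v <- matrix(100 * exp(rnorm(n_groups * n_rep, sd = cv)), ncol = 1,
              dimnames = list(NULL, "A"))
  d <- rppa_dataset(v, meta, scale = "linear")
  snr <- compute_snr(d, phospho_only = FALSE)
  grand <- attr(snr, "grand")
  # Monte-Carlo oracle: independent draws of the same statistic
  oracle <- vapply(seq_len(2000), function(i) {
    x <- 100 * exp(rnorm(n_rep, sd = cv))
    mean(x) / sd(x)
  }, numeric(1))
  se <- sqrt(grand["sd"]^2 / n_groups + var(oracle) / length(oracle))
  expect_lt(abs(grand[["mean"]] - mean(oracle)), 3 * se)
  # and the small-sample mean SNR sits near the population 1/CV scale
  expect_gt(grand[["mean"]], 0.8 / cv)
  expect_lt(grand[["mean"]], 1.5 / cv)
})

test_that("redundant same-target phospho antibodies collapse correctly", {
  set.seed(5)
  n <- 40
  meta <- data.frame(cell_line = rep(c("MCF7", "BT20"), each = n / 2),
                     stimulus = "EGF", regime = "DMSO",
                     time_min = 0, replicate = rep(seq_len(n / 2), 2),
                     batch = "b1", stringsAsFactors = FALSE)
  x <- rnorm(n)
  v <- cbind(S6_a = x, S6_b = x, AKT_a = rnorm(n))
  ab <- antibody_table(colnames(v),
                       target_node = c("S6", "S6", "AKT"),
                       phospho_sites = c("S235", "S240", "T308"))
  d <- rppa_dataset(v, meta, ab, scale = "log2")
  res <- select_phospho_panel(d)
  expect_equal(res$dropped$dropped, "S6_b")  # lexicographic tie-break
  expect_setequal(colnames(res$data$values), c("S6_a", "AKT_a"))
  # high correlation in one cell line only -> kept
  v2 <- v
  v2[meta$cell_line == "BT20", "S6_b"] <- rnorm(n / 2)
  d2 <- rppa_dataset(v2, meta, ab, scale = "log2")
  res2 <- select_phospho_panel(d2)
  expect_equal(nrow(res2$dropped), 0)
  expect_equal(ncol(res2$data$values), 3)
})

test_that("independent random columns are essentially never collapsed", {
  set.seed(7)
  drops <- 0
  for (i in 1:100) {
    n <- 20
    meta <- data.frame(cell_line = rep(c("A", "B"), each = n / 2),
                       stimulus = "EGF", regime = "DMSO", time_min = 0,
                       replicate = rep(seq_len(n / 2), 2), batch = "b1",
                       stringsAsFactors = FALSE)
    v <- cbind(X1 = rnorm(n), X2 = rnorm(n))
    ab <- antibody_table(c("X1", "X2"), target_node = "X",
                         phospho_sites = c("S1", "S2"))
    d <- rppa_dataset(v, meta, ab, scale = "log2")
    drops <- drops + nrow(select_phospho_panel(d)$dropped)
  }
  expect_lte(drops, 1)
})

test_that("replicate averaging is the log2 arithmetic mean with counts", {
  meta <- data.frame(cell_line = "MCF7", stimulus = "EGF", regime = "DMSO",
                     time_min = c(0, 0, 5), replicate = c(1, 2, 1),
                     batch = "b1", stringsAsFactors = FALSE)
  v <- matrix(c(1, 3, 7, 2, 4, 8), 3, 2,
              dimnames = list(NULL, c("A", "B")))
  d <- rppa_dataset(v, meta, scale = "log2")
  avg <- average_replicates(d)
  expect_equal(nrow(avg$values), 2)
  expect_equal(unname(avg$values[avg$meta$time_min == 0, ]), c(2, 3))
  expect_equal(avg$meta$n_reps, c(2L, 1L))
  # missing values: mean of available, count still recorded
  v[2, 1] <- NA
  d2 <- rppa_dataset(v, meta, scale = "log2")
  avg2 <- average_replicates(d2)
  expect_equal(unname(avg2$values[avg2$meta$time_min == 0, 1]), 1)
})

test_that("imputation is linear in minutes with nearest-value boundaries", {
  # interior gap: times {0,5,15}, values {1, NA, 3} -> 1 + 2*(5/15)
  res <- impute_series(c(0, 5, 15), c(1, NA, 3))
  expect_equal(res$values[2], 1 + 2 * (5 / 15))
  expect_equal(res$imputed, c(FALSE, TRUE, FALSE))
  # boundary: missing t=0 takes the nearest observed value
  res2 <- impute_series(c(0, 5, 15), c(NA, 2, 3))
  expect_equal(res2$values[1], 2)
  # no missing data: identity
  res3 <- impute_series(c(0, 5), c(1, 2))
  expect_identical(res3$values, c(1, 2))
  expect_error(impute_series(c(0, 5, 15), c(NA, NA, 3)), "at least 2")
  # dataset-level application flags what it fills
  meta <- data.frame(cell_line = "MCF7", stimulus = "EGF", regime = "DMSO",
                     time_min = c(0, 5, 15), replicate = 1, batch = "b1",
                     stringsAsFactors = FALSE)
  v <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(NULL, c("A", "B")))
  d <- rppa_dataset(v, meta, scale = "log2")
  filled <- impute_time_course(d)
  expect_equal(unname(filled$values[2, "A"]), 1 + 2 * (5 / 15))
  expect_true(attr(filled, "imputed")[2, 1])
  expect_false(any(attr(filled, "imputed")[, 2]))
})
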