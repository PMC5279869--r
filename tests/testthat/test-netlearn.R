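# tiny replicate-free dataset with known lag-1 structure
make_design_dataset <- function(n_regimes = 1, seed = 1) {
  set.seed(seed)
  nodes <- c("A", "B", "C")
  times <- c(0, 5, 15, 30, 60, 120, 240)
  regimes <- c("DMSO", "Bi")[seq_len(n_regimes)]
  meta <- expand.grid(time_min = times, regime = regimes,
                      stringsAsFactors = FALSE)
  meta$cell_line <- "CL1"
  meta$stimulus <- "S1"
  meta$replicate <- 1L
  meta$batch <- "b1"
  v <- matrix(rnorm(nrow(meta) * 3, mean = 5), nrow(meta), 3,
              dimnames = list(NULL, nodes))
  rppa_dataset(v, meta, scale = "log2")
}

test_that("design assembly stacks lag-1 transitions with masking", {
  d <- make_design_dataset(1)
  ctx <- list(cell_line = "CL1", stimulus = "S1")
  regs <- list(inhibitor_regime("DMSO", is_control = TRUE))
  ds <- build_design(d, regs, ctx)
  expect_length(ds$blocks, 1)
  expect_equal(nrow(ds$blocks$DMSO$X), 6)   # 6 transitions per regime
  expect_equal(nrow(ds$blocks$DMSO$Y), 6)
  # predictors are exactly the lagged raw values when unmasked
  rows <- order(d$meta$time_min)[d$meta$regime[order(d$meta$time_min)] == "DMSO"]
  expect_equal(unname(ds$blocks$DMSO$X), unname(d$values[rows[1:6], ]))
  expect_equal(unname(ds$blocks$DMSO$Y), unname(d$values[rows[2:7], ]))

  d2 <- make_design_dataset(2)
  regs2 <- list(inhibitor_regime("DMSO", is_control = TRUE),
                inhibitor_regime("Bi", target_nodes = "B"))
  ds2 <- build_design(d2, regs2, ctx)
  expect_equal(sum(vapply(ds2$blocks, function(b) nrow(b$X), numeric(1))),
               12)
  # fix_baseline: the inhibited node's predictor column is clamped to the
  # control t = 0 value on the inhibitor block
  dmso_rows <- which(d2$meta$regime == "DMSO")
  t0 <- d2$values[dmso_rows[which.min(d2$meta$time_min[dmso_rows])], "B"]
  expect_true(all(ds2$blocks$Bi$X[, "B"] == t0))
  expect_false(all(ds2$blocks$DMSO$X[, "B"] == t0))
  # masking disabled: raw lagged values everywhere
  ds3 <- build_design(d2, regs2, ctx, mode = "none")
  b_rows <- which(d2$meta$regime == "Bi")
  b_ord <- b_rows[order(d2$meta$time_min[b_rows])]
  expect_equal(unname(ds3$blocks$Bi$X), unname(d2$values[b_ord[1:6], ]))
  # a regime targeting an off-panel node contributes data without masking
  regs4 <- list(inhibitor_regime("DMSO", is_control = TRUE),
                inhibitor_regime("Bi", target_nodes = "FGFR"))
  expect_warning(ds4 <- build_design(d2, regs4, ctx), "not in panel")
  expect_equal(unname(ds4$blocks$Bi$X), unname(d2$values[b_ord[1:6], ]))
})

test_that("g-prior marginal likelihood matches explicit matrix algebra", {
  set.seed(3)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  y <- 0.8 * X[, 1] + rnorm(n, sd = 0.4)
  g <- n
  for (cols in list(integer(0), 1, 2, c(1, 2))) {
    Xs <- X[, cols, drop = FALSE]
    # oracle: R^2 via the normal equations, formula transcribed literally
    k <- ncol(Xs)
    r2 <- if (k == 0) 0 else {
      Xc <- scale(Xs, center = TRUE, scale = FALSE)
      yc <- y - mean(y)
      beta <- solve(t(Xc) %*% Xc, t(Xc) %*% yc)
      1 - sum((yc - Xc %*% beta)^2) / sum(yc^2)
    }
    oracle <- 0.5 * (n - 1 - k) * log(1 + g) -
      0.5 * (n - 1) * log(1 + g * (1 - r2))
    expect_equal(as.numeric(log_marginal_likelihood(y, Xs, g = g)), oracle,
                 tolerance = 1e-10)
  }
  # a perfect predictor beats the empty model
  expect_gt(log_marginal_likelihood(X[, 1], X[, 1, drop = FALSE]),
            log_marginal_likelihood(X[, 1], X[, 0, drop = FALSE]))
  # a duplicated column cannot increase the score
  s1 <- log_marginal_likelihood(y, X[, 1, drop = FALSE])
  s2 <- log_marginal_likelihood(y, X[, c(1, 1)])
  expect_lte(as.numeric(s2), as.numeric(s1) + 1e-6)
  expect_true(isTRUE(attr(s2, "rank_deficient")))
})

test_that("parent-set enumeration is exact and guarded", {
  sets <- enumerate_parent_sets(c("a", "b"), 2)
  expect_equal(sets, list(character(0), "a", "b", c("a", "b")))
  expect_length(enumerate_parent_sets(letters[1:10], 0), 1)
  # binomial-sum oracle: 1 + 34 + C(34,2) + C(34,3) = 6580
  expect_length(enumerate_parent_sets(seq_len(34), 3), 6580)
  expect_error(enumerate_parent_sets(seq_len(40), 5), "reduce d_max")
})

test_that("uncoupled single-context learning is exact Bayesian model averaging", {
  set.seed(6)
  nodes <- c("A", "B", "C", "D")
  times <- c(0, 5, 15, 30, 60, 120, 240)
  meta <- expand.grid(time_min = times, regime = c("DMSO", "Di"),
                      stringsAsFactors = FALSE)
  meta$cell_line <- "CL1"
  meta$stimulus <- "S1"
  meta$replicate <- 1L
  meta$batch <- "b1"
  # B strongly driven by lagged A across both regimes (12 transitions)
  v <- matrix(rnorm(14 * 4, sd = 0.1), 14, 4, dimnames = list(NULL, nodes))
  v[, 1] <- c(0, 2, -1, 3, -2, 1, 0, 1, -3, 2, 0, -2, 3, -1)
  for (blk in list(1:7, 8:14)) {
    v[blk[2:7], 2] <- 0.9 * v[blk[1:6], 1] + rnorm(6, sd = 0.01)
  }
  d <- rppa_dataset(v, meta, scale = "log2")
  regs <- list(inhibitor_regime("DMSO", is_control = TRUE),
               inhibitor_regime("Di", target_nodes = "D"))
  cfg <- learning_config(lambda = 0, eta = 0, d_max = 2,
                         intervention_mode = "none")
  nets <- learn_networks(d, NULL, regs, config = cfg)
  prob <- nets[[1]]
  # oracle: enumerate parent sets for child B and average by hand
  X <- v[c(1:6, 8:13), ]
  y <- v[c(2:7, 9:14), "B"]
  cand <- c("A", "C", "D")
  sets <- enumerate_parent_sets(cand, 2)
  lml <- vapply(sets, function(s) {
    as.numeric(log_marginal_likelihood(y, X[, c("B", s), drop = FALSE]))
  }, numeric(1))
  w <- exp(lml - max(lml))
  w <- w / sum(w)
  for (p in cand) {
    expect_equal(prob[p, "B"],
                 sum(w[vapply(sets, function(s) p %in% s, logical(1))]),
                 tolerance = 1e-10)
  }
  # the true strong parent is found with high confidence
  expect_gt(prob["A", "B"], 0.9)
  # parent-set posteriors sum to one
  for (wts in attr(nets, "weights")[[1]]) expect_equal(sum(wts), 1)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_true(all(diag(prob) == 0))
})

test_that("large lambda forces inter-context agreement", {
  m <- strong_signal_model(seed = 21)
  d <- strong_signal_dataset(m, seed = 22)
  regs <- strong_signal_regimes()
  pair_l1 <- function(nets) {
    ctxs <- names(nets)
    out <- c()
    for (a in seq_along(ctxs)) for (b in seq_along(ctxs)) {
      if (b > a) out <- c(out, mean(abs(nets[[a]] - nets[[b]])))
    }
    mean(out)
  }
  cfg_big <- learning_config(lambda = 500, eta = 0, d_max = 2,
                             max_iter = 300)
  nets_big <- suppressWarnings(learn_networks(d, NULL, regs,
                                              config = cfg_big))
  ctxs <- names(nets_big)
  for (a in seq_along(ctxs)[-1]) {
    expect_lt(max(abs(nets_big[[a]] - nets_big[[1]])), 0.01)
  }
  # monotone coupling: mean pairwise L1 distance non-increasing in lambda
  dist <- vapply(c(0, 1, 3, 10), function(l) {
    cfg <- learning_config(lambda = l, eta = 0, d_max = 2, max_iter = 200)
    pair_l1(suppressWarnings(learn_networks(d, NULL, regs, config = cfg)))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-6))
})

test_that("large eta concentrates posteriors on the prior parent sets", {
  set.seed(30)
  nodes <- sprintf("N%d", 1:5)
  times <- c(0, 5, 15, 30, 60, 120, 240)
  meta <- data.frame(cell_line = "CL1", stimulus = "S1", regime = "DMSO",
                     time_min = times, replicate = 1L, batch = "b1",
                     stringsAsFactors = FALSE)
  v <- matrix(rnorm(7 * 5), 7, 5, dimnames = list(NULL, nodes))
  d <- rppa_dataset(v, meta, scale = "log2")
  prior <- prior_network(data.frame(parent = c("N1", "N2", "N1"),
                                    child = c("N2", "N3", "N3")))
  regs <- list(inhibitor_regime("DMSO", is_control = TRUE))
  cfg <- learning_config(lambda = 0, eta = 1000, d_max = 2)
  nets <- learn_networks(d, prior, regs, config = cfg)
  prob <- nets[[1]]
  # oracle: with eta dominating, each child's posterior mass sits on the
  # parent set minimizing |S delta prior parents| (enumerated directly)
  prior_parents <- list(N1 = character(0), N2 = "N1",
                        N3 = c("N1", "N2"), N4 = character(0),
                        N5 = character(0))
  for (j in nodes) {
    cand <- setdiff(nodes, j)
    sets <- enumerate_parent_sets(cand, 2)
    energy <- vapply(sets, function(s) {
      length(setdiff(s, prior_parents[[j]])) +
        length(setdiff(prior_parents[[j]], s))
    }, numeric(1))
    best <- sets[[which.min(energy)]]
    expect_setequal(rownames(prob)[prob[, j] > 0.5], best)
  }
  # prior pull is monotone in eta
  mean_prior_mass <- vapply(c(0, 5, 15, 50), function(e) {
    cfg <- learning_config(lambda = 0, eta = e, d_max = 2)
    pr <- learn_networks(d, prior, regs, config = cfg)[[1]]
    mean(pr[cbind(c("N1", "N2", "N1"), c("N2", "N3", "N3"))])
  }, numeric(1))
  expect_true(all(diff(mean_prior_mass) >= -1e-8))
})

test_that("cell-line summary averages stimulus networks above a strict threshold", {
  nodes <- c("A", "B", "C")
  base <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  nets <- lapply(1:8, function(i) { m <- base; m["A", "B"] <- 0.2; m })
  # identical networks: average equals each; 0.2 is excluded (strict >)
  s <- summarize_cell_line_network(nets, threshold = 0.2)
  expect_equal(s$average, nets[[1]])
  expect_equal(nrow(s$edges), 0)
  # {0.2 x7, 0.3} -> mean 0.2125 > 0.2 is included
  nets[[8]]["A", "B"] <- 0.3
  s2 <- summarize_cell_line_network(nets, threshold = 0.2)
  expect_equal(s2$edges$probability, 0.2125)
  expect_equal(s2$edges$parent, "A")
  # prior membership flag
  pn <- prior_network(data.frame(parent = "A", child = "B"))
  expect_true(summarize_cell_line_network(nets, 0.2, pn)$edges$in_prior)
})
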