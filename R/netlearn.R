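#' Configuration for joint interventional-DBN learning
#'
#' @param lambda inter-context agreement strength (the study used 3).
#' @param eta prior-network agreement strength (the study used 15).
#' @param d_max maximum parent-set size (exact enumeration up to this
#'   in-degree).
#' @param score `"g_prior"` (closed-form Gaussian marginal likelihood with a
#'   unit-information g-prior) or `"bic"`.
#' @param g g-prior scale; `NULL` means unit information (`g = n`).
#' @param intervention_mode `"fix_baseline"` (inhibited node's predictor
#'   clamped to its control t = 0 value), `"drop_edges"` (inhibited node
#'   removed from parent sets for the affected rows) or `"none"`.
#' @param kappa_eta,kappa_lambda scale constants multiplying the normalized
#'   prior and coupling strengths (default 1); they let users match an
#'   external parametrization of the same penalties.
#' @param tol convergence tolerance on the maximum edge-marginal change.
#' @param max_iter maximum mean-field sweeps.
#' @param seed integer seed (recorded; learning itself is deterministic).
#' @return a `learning_config` list.
#' @export
learning_config <- function(lambda = 3, eta = 15, d_max = 2,
                            score = c("g_prior", "bic"), g = NULL,
                            intervention_mode = c("fix_baseline",
                                                  "drop_edges", "none"),
                            kappa_eta = 1, kappa_lambda = 1,
                            tol = 1e-4, max_iter = 100, seed = 1L) {
  stopifnot(lambda >= 0, eta >= 0, d_max >= 1, tol > 0, max_iter >= 1)
  structure(list(lambda = lambda, eta = eta, d_max = as.integer(d_max),
                 score = match.arg(score), g = g,
                 intervention_mode = match.arg(intervention_mode),
                 kappa_eta = kappa_eta, kappa_lambda = kappa_lambda,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "learning_config")
}

#' Assemble the lag-1 regression design for one context
#'
#' Stacks the six lag-1 transitions of each regime's 7-point time course:
#' responses are node values at step t+1, predictors are all node values at
#' step t. Under `fix_baseline` masking, rows belonging to a regime that
#' inhibits node k have k's *predictor* values replaced by the context's
#' control t = 0 value (activity blocked from before stimulus); the node's
#' own response rows are retained. Under `drop_edges`, the inhibited node is
#' instead flagged for removal from parent sets on those rows. Regimes
#' targeting nodes absent from the panel contribute data without masking
#' (with a warning).
#'
#' @param data replicate-averaged, imputed [rppa_dataset()] (log2).
#' @param regimes list of [inhibitor_regime()] objects to include.
#' @param context list/row with `cell_line`, `stimulus`.
#' @param mode intervention mode, see [learning_config()].
#' @param control_regime control regime id.
#' @return object of class `design_set`: list of per-regime blocks, each
#'   with `X` (steps x nodes lagged predictors), `Y` (steps x nodes
#'   responses), `regime`, `masked` (nodes masked/dropped on this block).
#' @export
build_design <- function(data, regimes, context,
                         mode = c("fix_baseline", "drop_edges", "none"),
                         control_regime = "DMSO") {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "rppa_dataset"))
  nodes <- colnames(data$values)
  m <- data$meta
  in_ctx <- m$cell_line == context$cell_line &
    m$stimulus == context$stimulus
  times <- sort(unique(m$time_min[in_ctx]))
  if (length(times) < 2) {
    stop("context ", context$cell_line, "/", context$stimulus,
         " has fewer than 2 time points", call. = FALSE)
  }
  series_of <- function(regime_id) {
    rows <- which(in_ctx & m$regime == regime_id)
    if (length(rows) == 0) return(NULL)
    if (anyDuplicated(m$time_min[rows])) {
      stop("replicates present; average_replicates() must run first",
           call. = FALSE)
    }
    if (!all(times %in% m$time_min[rows])) return(NULL)
    data$values[rows[match(times, m$time_min[rows])], , drop = FALSE]
  }
  dmso <- series_of(control_regime)
  if (is.null(dmso)) {
    stop("context ", context$cell_line, "/", context$stimulus,
         " lacks a complete ", control_regime, " time course",
         call. = FALSE)
  }
  baseline_t0 <- dmso[1, ]

  blocks <- list()
  for (r in regimes) {
    S <- series_of(r$regime_id)
    if (is.null(S)) {
      warning("regime ", r$regime_id, " incomplete in context ",
              context$cell_line, "/", context$stimulus, "; skipped",
              call. = FALSE)
      next
    }
    K <- length(times) - 1L
    X <- S[seq_len(K), , drop = FALSE]
    Y <- S[seq_len(K) + 1L, , drop = FALSE]
    masked <- character()
    if (!r$is_control && length(r$target_nodes) > 0 && mode != "none") {
      present <- intersect(r$target_nodes, nodes)
      absent <- setdiff(r$target_nodes, nodes)
      if (length(absent) > 0) {
        warning("regime ", r$regime_id, " targets node(s) not in panel (",
                paste(absent, collapse = ", "), "); no masking applied",
                call. = FALSE)
      }
      if (length(present) > 0) {
        masked <- present
        if (mode == "fix_baseline") {
          for (k in present) X[, k] <- baseline_t0[[k]]
        }
      }
    }
    blocks[[r$regime_id]] <- list(X = X, Y = Y, regime = r$regime_id,
                                  masked = masked)
  }
  if (length(blocks) == 0) stop("no usable regimes in context", call. = FALSE)
  structure(list(blocks = blocks, nodes = nodes, mode = mode,
                 context = paste(context$cell_line, context$stimulus,
                                 sep = ".")),
            class = "design_set")
}

#' Closed-form Gaussian log marginal likelihood (g-prior)
#'
#' Linear model with an intercept (flat prior) and a Zellner g-prior on the
#' remaining coefficients; the noise variance carries the reference prior.
#' Up to a parent-set-independent constant, the log marginal likelihood is
#' `0.5 * (n - 1 - k) * log(1 + g) - 0.5 * (n - 1) * log(1 + g (1 - R^2))`
#' with `k` the column rank of the (centered) predictor block. Rank-deficient
#' predictor matrices are scored on their reduced column space with a flag.
#'
#' @param y response vector.
#' @param X predictor matrix (no intercept column; may have 0 columns).
#' @param g g-prior scale; default unit information, `g = n`.
#' @return the relative log marginal likelihood (attribute
#'   `"rank_deficient"` when columns were dropped).
#' @export
log_marginal_likelihood <- function(y, X, g = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n || ncol(X) == 0)
  if (is.null(g)) g <- n
  Xfull <- cbind(1, X)
  fit <- qr(Xfull)
  k <- fit$rank - 1L
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) {
    res <- qr.resid(fit, y)
    max(0, min(1, 1 - sum(res^2) / tss))
  } else 0
  out <- 0.5 * (n - 1 - k) * log(1 + g) -
    0.5 * (n - 1) * log(1 + g * (1 - r2))
  if (fit$rank < ncol(Xfull)) attr(out, "rank_deficient") <- TRUE
  out
}

# BIC-based alternative score (higher is better)
bic_score <- function(y, X) {
  n <- length(y)
  Xfull <- cbind(1, as.matrix(X))
  fit <- qr(Xfull)
  rss <- sum(qr.resid(fit, y)^2)
  rss <- max(rss, 1e-12)
  -0.5 * (n * log(rss / n) + fit$rank * log(n))
}

#' Enumerate candidate parent sets
#'
#' All subsets of the candidates of size 0..`d_max`, in deterministic order
#' (by size, then lexicographically by candidate position).
#'
#' @param candidates vector of candidate parents (names or indices).
#' @param d_max maximum subset size.
#' @return list of subsets (same type as `candidates`; first element is the
#'   empty set).
#' @export
enumerate_parent_sets <- function(candidates, d_max) {
  n <- length(candidates)
  d_max <- min(d_max, n)
  total <- sum(choose(n, 0:d_max))
  if (total > 2e5) {
    stop("parent-set enumeration too large (", total,
         " subsets); reduce d_max", call. = FALSE)
  }
  sets <- list(candidates[integer(0)])
  for (k in seq_len(d_max)) {
    idx <- utils::combn(n, k, simplify = FALSE)
    sets <- c(sets, lapply(idx, function(i) candidates[i]))
  }
  sets
}

# score all parent sets for one child in one design_set.
# returns list(candidates, sets, M, logml)
score_child <- function(design, child, config) {
  nodes <- design$nodes
  cand <- setdiff(nodes, child)
  sets <- enumerate_parent_sets(cand, config$d_max)
  M <- matrix(FALSE, length(sets), length(cand),
              dimnames = list(NULL, cand))
  for (s in seq_along(sets)) M[s, sets[[s]]] <- TRUE

  score_fun <- function(y, X) {
    if (config$score == "bic") bic_score(y, X)
    else log_marginal_likelihood(y, X, g = config$g)
  }
  drop_mode <- design$mode == "drop_edges"
  logml <- numeric(length(sets))
  if (!drop_mode) {
    X_all <- do.call(rbind, lapply(design$blocks, `[[`, "X"))
    y_all <- unlist(lapply(design$blocks, function(b) b$Y[, child]),
                    use.names = FALSE)
    for (s in seq_along(sets)) {
      cols <- c(child, sets[[s]])
      logml[s] <- score_fun(y_all, X_all[, cols, drop = FALSE])
    }
  } else {
    for (s in seq_along(sets)) {
      tot <- 0
      for (b in design$blocks) {
        cols <- c(child, setdiff(sets[[s]], b$masked))
        tot <- tot + score_fun(b$Y[, child], b$X[, cols, drop = FALSE])
      }
      logml[s] <- tot
    }
  }
  list(child = child, candidates = cand, sets = sets, M = M,
       logml = logml)
}

softmax <- function(lw) {
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Joint posterior edge probabilities across contexts
#'
#' Per child and context, the parent-set posterior is proportional to
#' `exp(logML - eta_n * |S delta prior parents| - lambda_n * D(S))`, where
#' `D(S)` is the expected edge disagreement with the other contexts under
#' their current marginals. `eta_n = eta * kappa_eta` and
#' `lambda_n = lambda / (C - 1) * kappa_lambda` (so the coupling pressure
#' per context does not grow with the number of contexts C). The coupled
#' posteriors are solved by mean-field iteration: initialize with
#' prior-only posteriors, then update contexts cyclically until the maximum
#' edge-marginal change drops below `tol`.
#'
#' @param scores list (one element per context) of per-child score lists as
#'   produced internally by [learn_networks()]; each child entry carries
#'   `candidates`, `M`, `logml`.
#' @param prior a [prior_network()] or `NULL`.
#' @param config a [learning_config()].
#' @param nodes node name order for the output matrices.
#' @return named list of edge-probability matrices (parent x child,
#'   diagonal 0, entries in `[0, 1]`), with attribute `"convergence"`
#'   (iterations, final delta, converged flag).
#' @export
joint_edge_posteriors <- function(scores, prior, config, nodes) {
  C <- length(scores)
  P <- length(nodes)
  eta_n <- config$eta * config$kappa_eta
  lambda_n <- if (C > 1) {
    config$lambda / (C - 1) * config$kappa_lambda
  } else 0
  prior_adj <- prior_adjacency(prior, nodes)

  # per-child prior field over candidates: -eta_n * (1 - 2 * in_prior)
  f_eta <- lapply(nodes, function(j) {
    function(cand) -eta_n * (1 - 2 * prior_adj[cand, j])
  })
  names(f_eta) <- nodes

  marg <- rep(list(matrix(0, P, P, dimnames = list(nodes, nodes))), C)
  names(marg) <- names(scores)
  weights <- vector("list", C)
  names(weights) <- names(scores)

  # initialization: prior-only posteriors, no coupling
  for (ci in seq_len(C)) {
    weights[[ci]] <- vector("list", P)
    names(weights[[ci]]) <- nodes
    for (j in nodes) {
      sc <- scores[[ci]][[j]]
      lw <- sc$logml + as.vector(sc$M %*% f_eta[[j]](sc$candidates))
      w <- softmax(lw)
      weights[[ci]][[j]] <- w
      marg[[ci]][sc$candidates, j] <- as.vector(crossprod(sc$M, w))
    }
  }

  iter <- 0L
  delta <- 0
  if (lambda_n > 0 && C > 1) {
    for (iter in seq_len(config$max_iter)) {
      delta <- 0
      for (ci in seq_len(C)) {
        others <- setdiff(seq_len(C), ci)
        m_sum <- Reduce(`+`, marg[others])
        for (j in nodes) {
          sc <- scores[[ci]][[j]]
          # expected disagreement field: for candidate i,
          # sum_{c'} [(1 - m_c'(i,j)) if i in S else m_c'(i,j)]
          f_c <- -lambda_n * (length(others) - 2 * m_sum[sc$candidates, j])
          lw <- sc$logml +
            as.vector(sc$M %*% (f_eta[[j]](sc$candidates) + f_c))
          w <- softmax(lw)
          new_m <- as.vector(crossprod(sc$M, w))
          delta <- max(delta, max(abs(new_m - marg[[ci]][sc$candidates, j])))
          weights[[ci]][[j]] <- w
          marg[[ci]][sc$candidates, j] <- new_m
        }
      }
      if (delta < config$tol) break
    }
    if (delta >= config$tol) {
      warning("mean-field iteration did not converge (final delta ",
              signif(delta, 3), ")", call. = FALSE)
    }
  }
  for (ci in seq_len(C)) diag(marg[[ci]]) <- 0
  attr(marg, "convergence") <- list(iterations = iter, delta = delta,
                                    converged = delta < config$tol)
  attr(marg, "weights") <- weights
  attr(marg, "scores") <- scores
  class(marg) <- "ctx_networks"
  marg
}

#' Learn context-specific networks by joint interventional-DBN inference
#'
#' Orchestrates [build_design()], exact scoring of all parent sets up to
#' `d_max` per child, and [joint_edge_posteriors()]. The self-lag
#' (autoregressive) term is always included in every model and never
#' reported as an edge. Replicated data are averaged and imputed first.
#'
#' @param data post-QC [rppa_dataset()] (log2).
#' @param prior a [prior_network()] or `NULL`.
#' @param regimes list of [inhibitor_regime()] objects to use as training
#'   data (a control regime must be included).
#' @param contexts context data.frame ([context_grid()]); defaults to all
#'   (cell line, stimulus) combinations present in the data.
#' @param config a [learning_config()].
#' @param control_regime control regime id.
#' @return a `ctx_networks` object: named list of parent x child
#'   edge-probability matrices, one per context.
#' @export
learn_networks <- function(data, prior = NULL, regimes,
                           contexts = NULL,
                           config = learning_config(),
                           control_regime = "DMSO") {
  stopifnot(inherits(data, "rppa_dataset"))
  m <- data$meta
  if (anyDuplicated(paste(m$cell_line, m$stimulus, m$regime, m$time_min))) {
    data <- impute_time_course(average_replicates(data))
  }
  if (is.null(contexts)) {
    cc <- unique(data$meta[, c("cell_line", "stimulus")])
    contexts <- data.frame(cell_line = cc$cell_line,
                           stimulus = cc$stimulus,
                           context = paste(cc$cell_line, cc$stimulus,
                                           sep = "."),
                           stringsAsFactors = FALSE)
  }
  nodes <- colnames(data$values)
  scores <- vector("list", nrow(contexts))
  names(scores) <- contexts$context
  for (ci in seq_len(nrow(contexts))) {
    design <- build_design(data, regimes, contexts[ci, ],
                           mode = config$intervention_mode,
                           control_regime = control_regime)
    scores[[ci]] <- lapply(stats::setNames(nodes, nodes), function(j) {
      score_child(design, j, config)
    })
  }
  joint_edge_posteriors(scores, prior, config, nodes)
}

#' @export
print.ctx_networks <- function(x, ...) {
  conv <- attr(x, "convergence")
  cat("ctx_networks:", length(x), "context network(s) over",
      nrow(x[[1]]), "nodes\n")
  if (!is.null(conv) && conv$iterations > 0) {
    cat("  mean-field:", conv$iterations, "sweep(s), delta",
        signif(conv$delta, 3),
        if (conv$converged) "(converged)" else "(NOT converged)", "\n")
  }
  invisible(x)
}

#' Summarize a cell line's networks across stimuli
#'
#' Element-wise mean of the stimulus-specific edge-probability matrices,
#' plus the edge list above a probability threshold (strictly greater
#' than), flagged for membership in the prior network.
#'
#' @param networks list of edge-probability matrices (shared node order),
#'   typically the 8 stimulus networks of one cell line.
#' @param threshold edge-probability threshold (default 0.2).
#' @param prior optional [prior_network()] for the membership flag.
#' @return list with `average` (matrix), `edges` (data.frame `parent`,
#'   `child`, `probability`, `in_prior`) and `n_networks`.
#' @export
summarize_cell_line_network <- function(networks, threshold = 0.2,
                                        prior = NULL) {
  networks <- Filter(Negate(is.null), networks)
  stopifnot(length(networks) >= 1)
  avg <- Reduce(`+`, networks) / length(networks)
  nodes <- rownames(avg)
  prior_adj <- prior_adjacency(prior, nodes)
  idx <- which(avg > threshold & row(avg) != col(avg), arr.ind = TRUE)
  edges <- data.frame(parent = nodes[idx[, 1]], child = nodes[idx[, 2]],
                      probability = avg[idx],
                      in_prior = prior_adj[idx] > 0,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$probability, edges$parent, edges$child), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(average = avg, edges = edges, n_networks = length(networks))
}
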