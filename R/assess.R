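#' Held-out-inhibitor train/test splits
#'
#' A regime is a valid test inhibitor when all of its target nodes are in
#' the network model and at least one other non-control regime targets only
#' disjoint nodes. The training set is always maximal: every non-control
#' regime whose targets are disjoint from the test targets.
#'
#' @param regimes list of [inhibitor_regime()] objects (controls are never
#'   test regimes; they are part of every training set implicitly).
#' @param network_nodes node names of the network model.
#' @return list of splits; each split is a list with `test`, `train`
#'   (list of regimes), `valid` and `reason`.
#' @export
make_train_test_splits <- function(regimes, network_nodes) {
  non_control <- Filter(function(r) !r$is_control, regimes)
  splits <- list()
  for (r in non_control) {
    targets_in <- all(r$target_nodes %in% network_nodes) &&
      length(r$target_nodes) > 0
    train <- Filter(function(s) {
      s$regime_id != r$regime_id &&
        length(intersect(s$target_nodes, r$target_nodes)) == 0
    }, non_control)
    valid <- targets_in && length(train) > 0
    reason <- if (!targets_in) {
      "test targets not in network model"
    } else if (length(train) == 0) {
      "no disjoint training regimes"
    } else ""
    splits[[r$regime_id]] <- list(test = r, train = train,
                                  valid = valid, reason = reason)
  }
  splits
}

# widest-path ("bottleneck") probability from targets to every node:
# b(v) = max over directed paths (>= 1 edge) from a target to v of the
# minimum edge probability along the path. A node is then a descendant at
# threshold t iff b(v) >= t, which reproduces breadth-first reachability on
# the thresholded graph for every threshold at once.
descendant_bottleneck <- function(prob, targets) {
  nodes <- rownames(prob)
  stopifnot(all(targets %in% nodes))
  W <- prob
  diag(W) <- 0
  b <- apply(W[targets, , drop = FALSE], 2, max)
  repeat {
    cap <- pmin(matrix(b, nrow(W), ncol(W)), W)   # min(b(u), prob(u->v))
    b_new <- pmax(b, apply(cap, 2, max))
    if (all(b_new == b)) break
    b <- b_new
  }
  names(b) <- nodes
  b
}

#' Predicted descendants of target nodes at an edge-probability threshold
#'
#' Keeps edges with probability at least `threshold` and returns every node
#' reachable from any target through at least one kept edge (a target is
#' included only if reachable from a target through a path of length >= 1).
#'
#' @param prob edge-probability matrix (parent x child).
#' @param targets character vector of target nodes.
#' @param threshold edge-keep threshold (keep rule is `>=`).
#' @return character vector of descendant node names.
#' @export
descendants_at_threshold <- function(prob, targets, threshold) {
  b <- descendant_bottleneck(prob, targets)
  names(b)[b >= threshold]
}

#' Descendant-set ROC curve and AUROC for one context
#'
#' Sweeps the threshold over the sorted unique edge probabilities (plus a
#' supra-maximal value). At each threshold the predicted descendant set of
#' the targets is compared against the gold-standard set: TPR over the
#' positives (gold) and FPR over the negatives (universe minus gold). The
#' points are completed with (0,0) and (1,1), sorted by FPR (ties keep the
#' maximal TPR), monotonized, and integrated by the trapezoid rule.
#'
#' By default the universe excludes the target nodes themselves: an
#' activity-state readout of the inhibited node trivially responds to its
#' own inhibitor.
#'
#' @param prob edge-probability matrix (parent x child).
#' @param targets target nodes of the (held-out) inhibitor.
#' @param gold character vector: the gold-standard descendant set.
#' @param universe node universe for scoring; default all nodes minus
#'   `targets`.
#' @param include_targets keep the targets in the universe.
#' @return list with `auroc`, `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`) and `flagged` (`TRUE` when positives or negatives are empty, in
#'   which case `auroc` is `NA`).
#' @export
descendant_roc_auroc <- function(prob, targets, gold, universe = NULL,
                                 include_targets = FALSE) {
  nodes <- rownames(prob)
  if (is.null(universe)) {
    universe <- if (include_targets) nodes else setdiff(nodes, targets)
  }
  gold <- intersect(gold, universe)
  negatives <- setdiff(universe, gold)
  if (length(gold) == 0 || length(negatives) == 0) {
    return(list(auroc = NA_real_, curve = NULL, flagged = TRUE))
  }
  b <- descendant_bottleneck(prob, targets)[universe]
  pos <- names(b) %in% gold
  thr <- sort(unique(as.vector(prob)), decreasing = TRUE)
  thr <- c(max(thr) + 1, thr)
  tpr <- vapply(thr, function(t) mean(b[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(b[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(NA, thr, NA),
                      fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  # sort by FPR, resolve ties by max TPR, monotonize the staircase
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  curve$tpr <- cummax(curve$tpr)
  auroc <- sum(diff(curve$fpr) *
                 (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(auroc = auroc, curve = curve, flagged = FALSE)
}

#' Empirical null distribution for a descendant AUROC
#'
#' Draws matrices of independent uniform(0, 1) edge probabilities over the
#' same node set, scores each against the same gold-standard set, and
#' returns the add-one empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_null)`.
#'
#' @param observed_auroc the observed AUROC.
#' @param targets,gold,universe as in [descendant_roc_auroc()].
#' @param nodes node names over which null matrices are drawn.
#' @param n_null number of null draws (>= 100).
#' @param seed integer RNG seed.
#' @return list with `p`, `null_aurocs`, `observed`.
#' @export
empirical_null_pvalue <- function(observed_auroc, targets, gold, nodes,
                                  universe = NULL, n_null = 1000,
                                  seed = 1L) {
  stopifnot(n_null >= 100)
  set.seed(as.integer(seed))
  P <- length(nodes)
  null_aurocs <- vapply(seq_len(n_null), function(i) {
    R <- matrix(stats::runif(P * P), P, P, dimnames = list(nodes, nodes))
    diag(R) <- 0
    descendant_roc_auroc(R, targets, gold, universe = universe)$auroc
  }, numeric(1))
  p <- (1 + sum(null_aurocs >= observed_auroc, na.rm = TRUE)) / (1 + n_null)
  list(p = p, null_aurocs = null_aurocs, observed = observed_auroc)
}

#' Full held-out-inhibitor assessment of causal network learning
#'
#' For every valid train/test split: gold-standard descendant sets are the
#' salient-change calls under the *test* regime (per context); networks are
#' re-learned from the *training* regimes only (plus the control); each
#' context's predicted descendants of the test targets are scored against
#' its gold set by threshold-sweep ROC, with an empirical null p-value.
#' Contexts whose gold set is empty (or full) are flagged and excluded from
#' summaries.
#'
#' @param data post-QC [rppa_dataset()] with replicates (log2 scale).
#' @param prior a [prior_network()] or `NULL`.
#' @param regimes list of [inhibitor_regime()] objects, control included.
#' @param contexts context data.frame; default all present in `data`.
#' @param config a [learning_config()].
#' @param q,tau salient-change parameters (see [salient_change_panel()]).
#' @param n_null empirical-null sample size.
#' @param seed integer RNG seed for the null draws.
#' @param control_regime control regime id.
#' @return data.frame with one row per (context, test regime): `context`,
#'   `test_regime`, `n_gold`, `auroc`, `p_empirical`, `flagged`.
#' @export
run_full_assessment <- function(data, prior = NULL, regimes,
                                contexts = NULL,
                                config = learning_config(),
                                q = 0.05, tau = 1.0,
                                n_null = 1000, seed = 1L,
                                control_regime = "DMSO") {
  stopifnot(inherits(data, "rppa_dataset"))
  nodes <- colnames(data$values)
  if (is.null(contexts)) {
    cc <- unique(data$meta[, c("cell_line", "stimulus")])
    contexts <- data.frame(cell_line = cc$cell_line, stimulus = cc$stimulus,
                           context = paste(cc$cell_line, cc$stimulus,
                                           sep = "."),
                           stringsAsFactors = FALSE)
  }
  splits <- make_train_test_splits(regimes, nodes)
  control <- Filter(function(r) r$is_control, regimes)
  out <- list()
  for (sp in splits) {
    if (!sp$valid) next
    test_id <- sp$test$regime_id
    # gold sets: salient changes under the test regime, per context
    gold_sets <- lapply(seq_len(nrow(contexts)), function(ci) {
      calls <- call_salient_changes(data, sp$test, contexts[ci, ],
                                    control_regime = control_regime,
                                    q = q, tau = tau)
      if (is.null(calls)) return(NULL)
      calls$protein[calls$salient]
    })
    # retrain on training regimes only (test regime data never enter)
    train_regimes <- c(control, sp$train)
    nets <- learn_networks(data, prior, train_regimes, contexts = contexts,
                           config = config,
                           control_regime = control_regime)
    for (ci in seq_len(nrow(contexts))) {
      gold <- gold_sets[[ci]]
      if (is.null(gold)) {
        out[[length(out) + 1L]] <-
          data.frame(context = contexts$context[ci], test_regime = test_id,
                     n_gold = NA_integer_, auroc = NA_real_,
                     p_empirical = NA_real_, flagged = TRUE,
                     stringsAsFactors = FALSE)
        next
      }
      roc <- descendant_roc_auroc(nets[[contexts$context[ci]]],
                                  sp$test$target_nodes, gold)
      p_emp <- NA_real_
      if (!roc$flagged) {
        p_emp <- empirical_null_pvalue(roc$auroc, sp$test$target_nodes,
                                       gold, nodes, n_null = n_null,
                                       seed = seed + ci)$p
      }
      out[[length(out) + 1L]] <-
        data.frame(context = contexts$context[ci], test_regime = test_id,
                   n_gold = length(gold), auroc = roc$auroc,
                   p_empirical = p_emp, flagged = roc$flagged,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
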