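# Shared fixtures and independent oracles for the test suite.

# small valid dataset built in code
make_toy_dataset <- function(n_ab = 3, scale = "log2") {
  meta <- data.frame(cell_line = c("MCF7", "MCF7"),
                     stimulus = c("EGF", "EGF"),
                     regime = c("DMSO", "DMSO"),
                     time_min = c(0, 5),
                     replicate = c(1L, 1L),
                     batch = "b1", stringsAsFactors = FALSE)
  v <- matrix(seq_len(2 * n_ab), 2, n_ab,
              dimnames = list(NULL, paste0("AB", seq_len(n_ab))))
  rppa_dataset(v, meta, scale = scale)
}

# canonical strong-signal simulation (the package's "recovery" benchmark
# scenario): 10 nodes, 4 contexts, three single-target inhibitor regimes
# plus vehicle, excitation dominated by process innovations
strong_signal_regimes <- function() {
  benchmark_scenario("recovery", seed = 1)$regimes
}

strong_signal_model <- function(seed) {
  benchmark_scenario("recovery", seed = seed)$model
}

strong_signal_dataset <- function(model, seed, n_rep_t0 = 4) {
  simulate_rppa_dataset(
    model,
    simulation_design(n_rep_t0 = n_rep_t0, n_rep_dmso = 2,
                      regimes = strong_signal_regimes()),
    seed = seed)
}

# directed-edge recovery AUROC of learned edge probabilities against the
# simulator's true edge sets (rank-based Mann-Whitney identity)
edge_recovery_auroc <- function(nets, model) {
  mean(vapply(names(nets), function(ctx) {
    W <- model$W[[ctx]]
    diag(W) <- 0
    off <- row(W) != col(W)
    truth <- (W != 0)[off]
    score <- nets[[ctx]][off]
    r <- rank(score)
    (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
  }, numeric(1)))
}

# independent reachability oracle: BFS on the thresholded graph via igraph,
# restricted to paths of length >= 1 from the targets
bfs_descendants <- function(prob, targets, threshold) {
  A <- prob >= threshold
  diag(A) <- FALSE
  nodes <- rownames(A)
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
  starts <- unique(unlist(lapply(targets, function(t) nodes[A[t, ]])))
  if (length(starts) == 0) return(character())
  sort(unique(unlist(lapply(starts, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  }))))
}
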