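#' Default (cell line, stimulus) context grid
#'
#' @param cell_lines character vector of cell line names.
#' @param stimuli character vector of stimulus names.
#' @return data.frame with columns `cell_line`, `stimulus` and a derived
#'   `context` label (`cell_line.stimulus`), one row per combination.
#' @export
context_grid <- function(cell_lines = c("CL1", "CL2"),
                         stimuli = c("STIM1", "STIM2")) {
  g <- expand.grid(stimulus = stimuli, cell_line = cell_lines,
                   stringsAsFactors = FALSE)[, c("cell_line", "stimulus")]
  g$context <- paste(g$cell_line, g$stimulus, sep = ".")
  rownames(g) <- NULL
  g
}

#' The full 32-context study grid
#'
#' Four breast cancer cell lines crossed with eight stimuli, the design under
#' which the real data were collected.
#' @return data.frame as in [context_grid()], 32 rows.
#' @export
study_contexts <- function() {
  context_grid(cell_lines = c("MCF7", "UACC812", "BT20", "BT549"),
               stimuli = c("PBS", "FBS", "EGF", "IGF1", "insulin",
                           "FGF1", "NRG1", "HGF"))
}

#' Draw ground-truth context-specific signed networks
#'
#' Draws a base directed network at the requested edge density with weights
#' of random sign and magnitude, then independently rewires a fraction of
#' base edges per context (delete + add elsewhere), giving related but
#' context-specific networks. Each weight matrix is rescaled, if necessary,
#' to the target spectral radius so the lag-1 dynamics are stable. The
#' diagonal holds a common self-persistence term and is never rewired.
#'
#' Weight matrices use the adjacency convention `W[parent, child]`.
#'
#' @param p_nodes number of nodes.
#' @param contexts data.frame from [context_grid()] (or an integer, expanded
#'   to that many single-stimulus contexts).
#' @param edge_density fraction of the `p_nodes * (p_nodes - 1)` possible
#'   directed edges present in the base network.
#' @param rewire_frac fraction of base edges rewired independently in each
#'   context.
#' @param seed integer RNG seed; the draw is reproducible.
#' @param w_range magnitude range for edge weights.
#' @param self_persistence shared diagonal (autoregressive) weight in
#'   `[0, 1)`.
#' @param spectral_target weight matrices with spectral radius above this
#'   value are rescaled onto it; smaller values give faster-mixing dynamics
#'   (responses that saturate within a few sampled time points).
#' @param baseline per-node resting level (log2 units); recycled.
#' @param stim_nodes integer: how many nodes receive stimulus input.
#' @param stim_gain stimulus input magnitude (log2 units) for stimulated
#'   nodes.
#' @param peak_frac fraction of stimulated nodes given a transient "peak"
#'   input shape (the rest get a sustained step).
#' @param noise_sd named vector `c(process = , measurement = )`, log2 units.
#' @param inhib_alpha default inhibition efficiency in `[0, 1]`
#'   (0 = complete blockade of the target's outgoing influence).
#' @param basal_drive constant basal input (log2 units) applied to the
#'   stimulated nodes in every regime, emulating resting-state signaling.
#'   Because cells are pre-treated with inhibitor before t = 0, blockade
#'   shifts the resting level of the target's descendants, so inhibitor
#'   effects are already visible at the first time point.
#' @return object of class `ground_truth_model`.
#' @export
sample_context_networks <- function(p_nodes, contexts = context_grid(),
                                    edge_density = 0.15,
                                    rewire_frac = 0.2,
                                    seed = 1L,
                                    w_range = c(0.4, 0.9),
                                    self_persistence = 0.3,
                                    spectral_target = 0.9,
                                    baseline = 8,
                                    stim_nodes = 2L,
                                    stim_gain = 2,
                                    peak_frac = 0.5,
                                    noise_sd = c(process = 0.05,
                                                 measurement = 0.05),
                                    inhib_alpha = 0,
                                    basal_drive = 0) {
  if (is.numeric(contexts) && length(contexts) == 1) {
    contexts <- context_grid("CL1", paste0("STIM", seq_len(contexts)))
  }
  stopifnot(rewire_frac >= 0, rewire_frac <= 1,
            self_persistence >= 0, self_persistence < 1,
            spectral_target > 0, spectral_target < 1)
  n_possible <- p_nodes * (p_nodes - 1)
  n_edges <- round(edge_density * n_possible)
  if (n_edges < 1) stop("edge_density too low: no edges", call. = FALSE)
  if (n_edges > n_possible) stop("edge_density exceeds 1", call. = FALSE)

  set.seed(as.integer(seed))
  nodes <- sprintf("N%02d", seq_len(p_nodes))
  offdiag <- which(diag(p_nodes) == 0)
  draw_w <- function(n) {
    sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, w_range[1], w_range[2])
  }
  base_idx <- sample(offdiag, n_edges)
  base_w <- draw_w(n_edges)

  W <- vector("list", nrow(contexts))
  names(W) <- contexts$context
  n_rewire <- floor(rewire_frac * n_edges)
  for (ci in seq_len(nrow(contexts))) {
    idx <- base_idx
    w <- base_w
    if (n_rewire > 0) {
      drop <- sample(seq_along(idx), n_rewire)
      free <- setdiff(offdiag, idx)
      add <- sample(free, n_rewire)
      idx <- c(idx[-drop], add)
      w <- c(w[-drop], draw_w(n_rewire))
    }
    Wc <- matrix(0, p_nodes, p_nodes, dimnames = list(nodes, nodes))
    Wc[idx] <- w
    diag(Wc) <- self_persistence
    rho <- max(Mod(eigen(Wc, only.values = TRUE)$values))
    if (rho > spectral_target) Wc <- Wc * (spectral_target / rho)
    W[[ci]] <- Wc
  }

  stim_nodes <- min(stim_nodes, p_nodes)
  stim_set <- nodes[seq_len(stim_nodes)]
  shapes <- rep("none", p_nodes)
  names(shapes) <- nodes
  n_peak <- round(peak_frac * stim_nodes)
  shapes[stim_set] <- c(rep("peak", n_peak),
                        rep("sustained", stim_nodes - n_peak))
  gain <- matrix(0, nrow(contexts), p_nodes,
                 dimnames = list(contexts$context, nodes))
  gain[, stim_set] <- stim_gain
  basal <- stats::setNames(rep(0, p_nodes), nodes)
  basal[stim_set] <- basal_drive

  base_W <- matrix(0, p_nodes, p_nodes, dimnames = list(nodes, nodes))
  base_W[base_idx] <- base_w
  diag(base_W) <- self_persistence
  structure(list(contexts = contexts, nodes = nodes, W = W,
                 base_W = base_W,
                 baseline = stats::setNames(rep_len(baseline, p_nodes),
                                            nodes),
                 stim_gain = gain, stim_shape = shapes,
                 noise_sd = noise_sd, inhib_alpha = inhib_alpha,
                 basal_drive = basal,
                 seed = as.integer(seed)),
            class = "ground_truth_model")
}

#' Construct a ground-truth model by hand
#'
#' Lower-level companion to [sample_context_networks()] for building small
#' models with fully specified dynamics (useful for worked examples and
#' oracle tests).
#'
#' @param W named list (one per context) of parent x child signed weight
#'   matrices with named dimnames; diagonals are self-persistence terms.
#' @param contexts context data.frame ([context_grid()]); names of `W` must
#'   match `contexts$context`.
#' @param baseline per-node resting level (log2), recycled.
#' @param stim_gain contexts x nodes matrix of stimulus magnitudes, or a
#'   single number applied to all stimulated nodes.
#' @param stim_shape per-node `"peak"`, `"sustained"` or `"none"`.
#' @param noise_sd named vector `c(process = , measurement = )`.
#' @param inhib_alpha inhibition efficiency in `[0, 1]`.
#' @param basal_drive per-node constant basal input (log2), recycled.
#' @param seed integer recorded with the model.
#' @return a `ground_truth_model`.
#' @export
ground_truth_model <- function(W, contexts, baseline = 0,
                               stim_gain = 0,
                               stim_shape = "none",
                               noise_sd = c(process = 0, measurement = 0),
                               inhib_alpha = 0, basal_drive = 0,
                               seed = 1L) {
  stopifnot(is.list(W), length(W) == nrow(contexts),
            !is.null(rownames(W[[1]])))
  nodes <- rownames(W[[1]])
  P <- length(nodes)
  names(W) <- contexts$context
  for (Wc in W) {
    stopifnot(identical(rownames(Wc), nodes), identical(colnames(Wc), nodes))
    if (any(diag(Wc) < 0 | diag(Wc) >= 1)) {
      stop("self-persistence (diagonal) must lie in [0, 1)", call. = FALSE)
    }
    if (max(Mod(eigen(Wc, only.values = TRUE)$values)) >= 1) {
      stop("weight matrix must have spectral radius < 1", call. = FALSE)
    }
  }
  if (!is.matrix(stim_gain)) {
    stim_gain <- matrix(stim_gain, nrow(contexts), P,
                        dimnames = list(contexts$context, nodes))
  }
  structure(list(contexts = contexts, nodes = nodes, W = W,
                 baseline = stats::setNames(rep_len(baseline, P), nodes),
                 stim_gain = stim_gain,
                 stim_shape = stats::setNames(rep_len(stim_shape, P), nodes),
                 noise_sd = noise_sd, inhib_alpha = inhib_alpha,
                 basal_drive = stats::setNames(rep_len(basal_drive, P),
                                               nodes),
                 seed = as.integer(seed)),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("ground_truth_model:", length(x$nodes), "nodes,",
      nrow(x$contexts), "contexts\n")
  ne <- vapply(x$W, function(w) sum(w != 0) - sum(diag(w) != 0), numeric(1))
  cat("  edges per context:", paste(ne, collapse = ", "), "\n")
  invisible(x)
}

#' Simulation design for synthetic RPPA time courses
#'
#' Defaults mirror the real study's replicate structure: seven observation
#' times, ~16 replicates at t = 0 and duplicates for vehicle-control samples
#' at t > 0, a single replicate elsewhere.
#'
#' @param time_points observation times in minutes.
#' @param n_rep_t0 replicates at t = 0 (measurement replicates of the
#'   pre-stimulus state).
#' @param n_rep_dmso replicate trajectories for the control regime at t > 0.
#' @param regimes list of [inhibitor_regime()] objects; must include one
#'   control.
#' @param batch_plan optional data.frame (`batch`, `antibody`, `shift`,
#'   `scale`; `antibody = "*"` applies to all) of log2-scale affine batch
#'   effects.
#' @param outlier_plan optional data.frame (`sample`, `multiplier`):
#'   linear-scale global multipliers applied to whole samples, keyed by row
#'   index into the simulated dataset.
#' @param batch_id batch label stamped on simulated samples.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(time_points = c(0, 5, 15, 30, 60, 120, 240),
                              n_rep_t0 = 16L,
                              n_rep_dmso = 2L,
                              regimes = list(inhibitor_regime("DMSO",
                                                              is_control = TRUE)),
                              batch_plan = NULL,
                              outlier_plan = NULL,
                              batch_id = "b1") {
  stopifnot(n_rep_t0 >= 2, n_rep_dmso >= 1, length(time_points) >= 2)
  if (!any(vapply(regimes, function(r) r$is_control, logical(1)))) {
    stop("design must include a control (DMSO) regime", call. = FALSE)
  }
  structure(list(time_points = sort(unique(time_points)),
                 n_rep_t0 = as.integer(n_rep_t0),
                 n_rep_dmso = as.integer(n_rep_dmso),
                 regimes = regimes, batch_plan = batch_plan,
                 outlier_plan = outlier_plan, batch_id = batch_id),
            class = "simulation_design")
}

# stimulus input over discrete steps 1..K (step 0 is pre-stimulus)
stim_input_shape <- function(shape, n_steps, rise = 0.8, decay = 2.5) {
  k <- seq_len(n_steps)
  switch(shape,
         none = rep(0, n_steps),
         sustained = rep(1, n_steps),
         peak = {
           s <- exp(-k / decay) - exp(-k / rise)
           s / max(s)
         },
         stop("unknown stimulus shape: ", shape, call. = FALSE))
}

#' Simulate an RPPA-like interventional time-course dataset
#'
#' For each (context, regime, replicate) the latent state follows the lag-1
#' linear-Gaussian recursion
#' `x(t+1) = baseline + W_eff' (x(t) - baseline) + u(t+1) + process noise`,
#' where `u` is the stimulus input (applied from the first post-stimulus
#' step, shaped per node) and `W_eff` equals the context weight matrix with
#' the inhibited node's outgoing row scaled by the regime's inhibition
#' efficiency `alpha` (blockade of activity, in force from t = 0 because
#' cells are pre-treated before stimulation). Measurement noise is added to
#' every observation; the dataset is emitted on the log2 scale. Batch and
#' outlier plans in the design are applied afterwards via
#' [inject_batch_and_outliers()].
#'
#' @param model a [sample_context_networks()] result.
#' @param design a [simulation_design()].
#' @param seed integer RNG seed.
#' @return an [rppa_dataset()] (log2 scale).
#' @export
simulate_rppa_dataset <- function(model, design = simulation_design(),
                                  seed = 1L) {
  stopifnot(inherits(model, "ground_truth_model"),
            inherits(design, "simulation_design"))
  nodes <- model$nodes
  P <- length(nodes)
  tp <- design$time_points
  K <- length(tp) - 1L
  for (r in design$regimes) {
    bad <- setdiff(r$target_nodes, nodes)
    if (length(bad) > 0) {
      stop("regime ", r$regime_id, " targets unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  proc_sd <- model$noise_sd[["process"]]
  meas_sd <- model$noise_sd[["measurement"]]

  shape_mat <- vapply(model$stim_shape,
                      function(s) if (s == "none") rep(0, K) else
                        stim_input_shape(s, K),
                      numeric(K))  # K x P

  rows <- list()
  m_cell <- m_stim <- m_reg <- character()
  m_time <- m_rep <- numeric()
  push <- function(env, x, ctx, regime, time, rep_i) {
    env$rows[[length(env$rows) + 1L]] <- x
    env$m_cell <- c(env$m_cell, ctx$cell_line)
    env$m_stim <- c(env$m_stim, ctx$stimulus)
    env$m_reg <- c(env$m_reg, regime)
    env$m_time <- c(env$m_time, time)
    env$m_rep <- c(env$m_rep, rep_i)
  }
  env <- environment()
  for (ci in seq_len(nrow(model$contexts))) {
    ctx <- model$contexts[ci, ]
    Wc <- model$W[[ci]]
    base <- model$baseline
    u_gain <- model$stim_gain[ci, ]
    for (r in design$regimes) {
      Weff <- Wc
      if (!r$is_control && length(r$target_nodes) > 0) {
        alpha <- model$inhib_alpha
        Weff[r$target_nodes, ] <- alpha * Weff[r$target_nodes, ]
        diag(Weff) <- diag(Wc)  # self-persistence is not an outgoing influence
      }
      # pre-stimulus resting state: the fixed point of the *effective*
      # dynamics under basal drive (inhibitor pre-treatment has already
      # equilibrated by t = 0)
      basal <- model$basal_drive
      rest <- base + solve(diag(P) - t(Weff), basal)
      for (rep_i in seq_len(design$n_rep_t0)) {
        push(env, rest + stats::rnorm(P, 0, meas_sd), ctx, r$regime_id,
             tp[1], rep_i)
      }
      n_traj <- if (r$is_control) design$n_rep_dmso else 1L
      for (rep_i in seq_len(n_traj)) {
        x <- rest
        for (k in seq_len(K)) {
          u <- u_gain * shape_mat[k, ]
          x <- base + as.vector(crossprod(Weff, x - base)) + basal + u +
            stats::rnorm(P, 0, proc_sd)
          push(env, x + stats::rnorm(P, 0, meas_sd), ctx, r$regime_id,
               tp[k + 1L], rep_i)
        }
      }
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- nodes
  meta <- data.frame(cell_line = m_cell, stimulus = m_stim, regime = m_reg,
                     time_min = m_time, replicate = m_rep,
                     batch = design$batch_id, stringsAsFactors = FALSE)
  data <- rppa_dataset(values, meta,
                       antibodies = antibody_table(nodes),
                       scale = "log2")
  if (!is.null(design$batch_plan) || !is.null(design$outlier_plan)) {
    data <- inject_batch_and_outliers(data, design$batch_plan,
                                      design$outlier_plan)
  }
  data
}

#' True descendant set of intervention targets in a ground-truth network
#'
#' A node is a descendant if it is reachable from any target by a directed
#' path of at least one nonzero-weight edge; a target counts as its own
#' descendant only if it lies on a cycle (or is reachable from a co-target).
#' Self-persistence diagonal terms are not edges.
#'
#' @param model a `ground_truth_model`.
#' @param context context label (or row index into `model$contexts`).
#' @param targets character vector of target nodes.
#' @return character vector of descendant node names.
#' @export
true_descendants <- function(model, context, targets) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (is.numeric(context)) context <- model$contexts$context[context]
  W <- model$W[[context]]
  if (is.null(W)) stop("unknown context: ", context, call. = FALSE)
  stopifnot(all(targets %in% model$nodes))
  A <- (W != 0)
  diag(A) <- FALSE
  reachable_from(A, targets)
}

# nodes reachable from `targets` through >= 1 edge in boolean adjacency
# A[parent, child]; uses igraph reachability from the targets' out-neighbors
reachable_from <- function(A, targets) {
  nodes <- rownames(A)
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
  starts <- unique(unlist(lapply(targets, function(t) {
    nodes[which(A[t, ])]
  })))
  if (length(starts) == 0) return(character())
  desc <- unique(unlist(lapply(starts, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
  sort(desc)
}

#' Time-shuffled negative control
#'
#' Permutes the time order independently within every
#' (cell line, stimulus, regime, replicate, antibody) series, destroying
#' both the lag-1 dependence and the cross-sectional alignment that network
#' learning exploits, while preserving each series' marginal distribution.
#' Used as a negative control: edge recovery on shuffled data should fall
#' to chance.
#'
#' @param data an [rppa_dataset()].
#' @param seed integer RNG seed.
#' @return the shuffled dataset.
#' @export
shuffle_time_courses <- function(data, seed = 1L) {
  stopifnot(inherits(data, "rppa_dataset"))
  set.seed(as.integer(seed))
  m <- data$meta
  grp <- paste(m$cell_line, m$stimulus, m$regime, m$replicate, sep = "|")
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 2) next
    for (j in seq_len(ncol(data$values))) {
      data$values[rows, j] <- data$values[sample(rows), j]
    }
  }
  data
}

#' Inject batch effects and outlier samples into a dataset
#'
#' Applies per-batch, per-antibody affine transforms `v -> shift + scale * v`
#' on the log2 scale, and per-sample global linear-scale multipliers
#' (`v -> v + log2(multiplier)` on log2 data), emulating the artifacts that
#' batch normalization and sample QC must repair. Perturbed samples are
#' recorded in the `perturbed` attribute.
#'
#' @param data an [rppa_dataset()] (log2 scale).
#' @param batch_plan data.frame (`batch`, `antibody`, `shift`, `scale`);
#'   `antibody = "*"` matches every antibody.
#' @param outlier_plan data.frame (`sample`, `multiplier`) with `sample` a
#'   row index into the dataset.
#' @return the perturbed dataset.
#' @export
inject_batch_and_outliers <- function(data, batch_plan = NULL,
                                      outlier_plan = NULL) {
  stopifnot(inherits(data, "rppa_dataset"), data$scale == "log2")
  perturbed <- integer()
  if (!is.null(batch_plan)) {
    bp <- as.data.frame(batch_plan, stringsAsFactors = FALSE)
    stopifnot(all(c("batch", "antibody", "shift", "scale") %in% names(bp)))
    for (i in seq_len(nrow(bp))) {
      rows <- which(data$meta$batch == bp$batch[i])
      cols <- if (bp$antibody[i] == "*") seq_len(ncol(data$values)) else {
        j <- match(bp$antibody[i], colnames(data$values))
        if (is.na(j)) stop("batch plan names unknown antibody: ",
                           bp$antibody[i], call. = FALSE)
        j
      }
      data$values[rows, cols] <- bp$shift[i] +
        bp$scale[i] * data$values[rows, cols]
      perturbed <- union(perturbed, rows)
    }
  }
  if (!is.null(outlier_plan)) {
    op <- as.data.frame(outlier_plan, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "multiplier") %in% names(op)))
    if (any(op$sample < 1 | op$sample > nrow(data$values))) {
      stop("outlier plan references nonexistent sample(s)", call. = FALSE)
    }
    for (i in seq_len(nrow(op))) {
      data$values[op$sample[i], ] <-
        data$values[op$sample[i], ] + log2(op$multiplier[i])
    }
    perturbed <- union(perturbed, op$sample)
  }
  attr(data, "perturbed") <- sort(perturbed)
  data
}
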