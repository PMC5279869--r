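#' RPPA dataset container
#'
#' An `rppa_dataset` bundles an abundance matrix (samples x antibodies) with
#' per-sample metadata and optional antibody annotation. Values may be on the
#' linear or log2 scale; the scale travels with the object so that
#' normalization steps can insist on the scale they are defined on.
#'
#' @param values numeric matrix, samples in rows, antibodies in columns.
#'   Column names are antibody names.
#' @param meta data.frame with one row per sample and columns
#'   `cell_line`, `stimulus`, `regime`, `time_min`, `replicate`, `batch`.
#' @param antibodies optional antibody annotation data.frame as produced by
#'   [antibody_table()]; if `NULL` a minimal table is derived from the
#'   column names of `values`.
#' @param scale `"linear"` or `"log2"`.
#'
#' @return An object of class `rppa_dataset`: a list with elements
#'   `values`, `meta`, `antibodies`, `scale` and `excluded` (a data.frame
#'   recording samples removed during QC together with a reason code).
#' @export
rppa_dataset <- function(values, meta,
                         antibodies = NULL,
                         scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)

  required <- c("cell_line", "stimulus", "regime", "time_min",
                "replicate", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop("'values' has ", nrow(values), " rows but 'meta' describes ",
         nrow(meta), " samples", call. = FALSE)
  }
  meta$time_min <- as.numeric(meta$time_min)
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$time_min) || any(meta$time_min < 0)) {
    stop("'time_min' must be non-negative numeric minutes", call. = FALSE)
  }
  if (anyNA(meta$replicate) || any(meta$replicate < 1)) {
    stop("'replicate' must be a positive integer", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale values must be non-negative", call. = FALSE)
  }

  key <- sample_key(meta)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate sample key: ", dup, call. = FALSE)
  }
  rownames(values) <- key
  rownames(meta) <- NULL

  if (is.null(colnames(values))) {
    colnames(values) <- paste0("ab", seq_len(ncol(values)))
  }
  if (is.null(antibodies)) {
    antibodies <- antibody_table(colnames(values))
  }
  if (!all(colnames(values) %in% antibodies$name)) {
    stop("antibody annotation does not cover all value columns",
         call. = FALSE)
  }
  antibodies <- antibodies[match(colnames(values), antibodies$name), ,
                           drop = FALSE]
  rownames(antibodies) <- NULL

  structure(
    list(values = values, meta = meta, antibodies = antibodies,
         scale = scale,
         excluded = data.frame(sample = character(), reason = character(),
                               stringsAsFactors = FALSE)),
    class = "rppa_dataset")
}

#' Build an antibody annotation table
#'
#' Antibody names map to network node names via the target protein plus the
#' phosphosites, joined in the field's usual style (`AKT` + `S473` gives
#' `AKT_pS473`; multiple sites chain as in `GSK3ab_pS21_pS9`).
#'
#' @param name character vector of antibody names.
#' @param target_node target protein per antibody (defaults to `name`).
#' @param phospho_sites character vector; comma-separated phosphosites per
#'   antibody, `""` for total-protein antibodies.
#' @param validation_label one of `"validated"`, `"use_with_caution"`,
#'   `"under_evaluation"` per antibody.
#' @return data.frame with columns `name`, `target_node`, `phospho_sites`,
#'   `is_phospho`, `validation_label` and derived `node`.
#' @export
antibody_table <- function(name, target_node = name,
                           phospho_sites = "",
                           validation_label = "validated") {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("antibody names must be unique", call. = FALSE)
  }
  tab <- data.frame(name = name,
                    target_node = rep_len(as.character(target_node),
                                          length(name)),
                    phospho_sites = rep_len(as.character(phospho_sites),
                                            length(name)),
                    validation_label = rep_len(as.character(validation_label),
                                               length(name)),
                    stringsAsFactors = FALSE)
  ok_labels <- c("validated", "use_with_caution", "under_evaluation")
  if (!all(tab$validation_label %in% ok_labels)) {
    stop("validation_label must be one of: ",
         paste(ok_labels, collapse = ", "), call. = FALSE)
  }
  tab$is_phospho <- nzchar(tab$phospho_sites)
  tab$node <- ifelse(
    tab$is_phospho,
    paste0(tab$target_node, vapply(strsplit(tab$phospho_sites, ","),
                                   function(s) paste0("_p", trimws(s),
                                                      collapse = ""),
                                   character(1))),
    tab$target_node)
  tab
}

#' Inhibitor regime descriptor
#'
#' @param regime_id short identifier (e.g. `"AZD8055"`, `"DMSO"`).
#' @param inhibitor_names compounds in the regime (a combination regime
#'   lists several).
#' @param target_nodes nodes whose activity the regime blocks; empty for the
#'   vehicle control.
#' @param is_control `TRUE` for the vehicle (DMSO) regime.
#' @return object of class `inhibitor_regime`.
#' @export
inhibitor_regime <- function(regime_id,
                             inhibitor_names = regime_id,
                             target_nodes = character(),
                             is_control = length(target_nodes) == 0) {
  if (is_control && length(target_nodes) > 0) {
    stop("a control regime cannot have target nodes", call. = FALSE)
  }
  structure(list(regime_id = as.character(regime_id),
                 inhibitor_names = as.character(inhibitor_names),
                 target_nodes = as.character(target_nodes),
                 is_control = isTRUE(is_control)),
            class = "inhibitor_regime")
}

sample_key <- function(meta) {
  paste(meta$cell_line, meta$stimulus, meta$regime, meta$time_min,
        meta$replicate, meta$batch, sep = "|")
}

#' @export
print.rppa_dataset <- function(x, ...) {
  cat("rppa_dataset:", nrow(x$values), "samples x", ncol(x$values),
      "antibodies [", x$scale, "scale ]\n")
  cat("  cell lines:", paste(unique(x$meta$cell_line), collapse = ", "), "\n")
  cat("  stimuli:   ", paste(unique(x$meta$stimulus), collapse = ", "), "\n")
  cat("  regimes:   ", paste(unique(x$meta$regime), collapse = ", "), "\n")
  cat("  times(min):", paste(sort(unique(x$meta$time_min)), collapse = ", "),
      "\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:  ", nrow(x$excluded), "samples\n")
  }
  invisible(x)
}

#' @export
dim.rppa_dataset <- function(x) dim(x$values)

#' Subset an RPPA dataset by samples and/or antibodies
#'
#' @param data an `rppa_dataset`.
#' @param samples logical or integer index over samples.
#' @param antibodies character, logical or integer index over antibodies.
#' @return the subset `rppa_dataset` (exclusion log carried over).
#' @export
subset_rppa <- function(data, samples = NULL, antibodies = NULL) {
  stopifnot(inherits(data, "rppa_dataset"))
  v <- data$values
  m <- data$meta
  ab <- data$antibodies
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(antibodies)) {
    if (is.character(antibodies)) {
      antibodies <- match(antibodies, colnames(v))
    }
    v <- v[, antibodies, drop = FALSE]
    ab <- ab[antibodies, , drop = FALSE]
  }
  out <- rppa_dataset(v, m, ab, scale = data$scale)
  out$excluded <- data$excluded
  out
}

#' Convert an RPPA dataset between linear and log2 scales
#'
#' @param data an `rppa_dataset`.
#' @return the dataset on the requested scale (a no-op if already there).
#' @export
to_log2 <- function(data) {
  stopifnot(inherits(data, "rppa_dataset"))
  if (data$scale == "log2") return(data)
  if (any(data$values <= 0, na.rm = TRUE)) {
    stop("cannot log2-transform non-positive values", call. = FALSE)
  }
  data$values <- log2(data$values)
  data$scale <- "log2"
  data
}

#' @rdname to_log2
#' @export
to_linear <- function(data) {
  stopifnot(inherits(data, "rppa_dataset"))
  if (data$scale == "linear") return(data)
  data$values <- 2^data$values
  data$scale <- "linear"
  data
}

#' Drop samples from a dataset, recording the reason
#'
#' Samples are never silently removed: every exclusion carries a reason code
#' in the dataset's `excluded` log.
#'
#' @param data an `rppa_dataset`.
#' @param idx integer or logical index of samples to drop.
#' @param reason single reason code recorded for all dropped samples.
#' @return the reduced dataset.
#' @export
exclude_samples <- function(data, idx, reason) {
  stopifnot(inherits(data, "rppa_dataset"))
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0) return(data)
  keys <- sample_key(data$meta)[idx]
  keep <- setdiff(seq_len(nrow(data$meta)), idx)
  out <- subset_rppa(data, samples = keep)
  out$excluded <- rbind(data$excluded,
                        data.frame(sample = keys,
                                   reason = rep_len(reason, length(keys)),
                                   stringsAsFactors = FALSE))
  out
}

# combine two datasets sample-wise (shared antibodies only)
bind_rppa <- function(a, b) {
  stopifnot(inherits(a, "rppa_dataset"), inherits(b, "rppa_dataset"),
            a$scale == b$scale)
  common <- intersect(colnames(a$values), colnames(b$values))
  v <- rbind(a$values[, common, drop = FALSE],
             b$values[, common, drop = FALSE])
  m <- rbind(a$meta, b$meta)
  ab <- a$antibodies[match(common, a$antibodies$name), , drop = FALSE]
  out <- rppa_dataset(v, m, ab, scale = a$scale)
  out$excluded <- rbind(a$excluded, b$excluded)
  out
}
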