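#' Read an RPPA abundance table
#'
#' The canonical on-disk layout is long format: one row per
#' (sample, antibody) with columns `cell_line, stimulus, inhibitor,
#' time_min, replicate, batch, antibody, value`. Wide format (one row per
#' sample, one column per antibody after the metadata columns) is accepted
#' for convenience. The delimiter is chosen from the file extension
#' (`.csv` comma, anything else tab). The measurement scale is read from a
#' `# scale=` comment on the first line when present; the `scale` argument
#' overrides it.
#'
#' Rows whose metadata cannot be parsed (non-numeric time or replicate) are
#' rejected with a warning naming the offending line numbers; duplicated
#' sample keys are an error.
#'
#' @param path file to read.
#' @param dialect `"long"` or `"wide"`.
#' @param scale optional `"linear"` or `"log2"`; overrides the file header.
#' @return an [rppa_dataset()].
#' @export
read_rppa_table <- function(path, dialect = c("long", "wide"),
                            scale = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  first <- readLines(path, n = 1L)
  header_scale <- NULL
  if (grepl("^#\\s*scale\\s*=", first)) {
    header_scale <- trimws(sub("^#\\s*scale\\s*=", "", first))
  }
  if (is.null(scale)) scale <- if (is.null(header_scale)) "log2" else header_scale

  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("cell_line", "stimulus", "inhibitor", "time_min",
                 "replicate", "batch")
  need <- if (dialect == "long") c(meta_cols, "antibody", "value") else meta_cols
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  tm <- suppressWarnings(as.numeric(df$time_min))
  rp <- suppressWarnings(as.integer(df$replicate))
  bad <- which(is.na(tm) | is.na(rp))
  if (length(bad) > 0) {
    warning("rejected ", length(bad), " row(s) with unparseable metadata ",
            "(data line(s) ", paste(bad, collapse = ", "),
            " after the header)", call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    tm <- tm[-bad]; rp <- rp[-bad]
  }
  df$time_min <- tm
  df$replicate <- rp

  if (dialect == "wide") {
    ab_names <- setdiff(names(df), meta_cols)
    if (length(ab_names) == 0) stop("wide file declares no antibody columns",
                                    call. = FALSE)
    values <- as.matrix(df[, ab_names, drop = FALSE])
    meta <- df[, meta_cols]
  } else {
    meta_all <- df[, meta_cols]
    key <- paste(meta_all$cell_line, meta_all$stimulus, meta_all$inhibitor,
                 meta_all$time_min, meta_all$replicate, meta_all$batch,
                 sep = "|")
    ukey <- unique(key)
    ab_names <- unique(df$antibody)
    if (anyDuplicated(paste(key, df$antibody, sep = "@"))) {
      stop("integrity error: duplicate (sample, antibody) record",
           call. = FALSE)
    }
    values <- matrix(NA_real_, nrow = length(ukey), ncol = length(ab_names),
                     dimnames = list(ukey, ab_names))
    values[cbind(match(key, ukey), match(df$antibody, ab_names))] <-
      as.numeric(df$value)
    meta <- df[match(ukey, key), meta_cols]
  }
  names(meta)[names(meta) == "inhibitor"] <- "regime"
  rppa_dataset(values, meta, scale = scale)
}

#' Write an RPPA dataset to disk
#'
#' Values are written with 17 significant digits so that
#' `read_rppa_table(write_rppa_table(d))` reproduces `d` to floating-point
#' round-trip accuracy. A `# scale=` header records the measurement scale.
#'
#' @param data an [rppa_dataset()].
#' @param path output file (`.csv` for comma-separated, else tab).
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_rppa_table <- function(data, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(data, "rppa_dataset"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- data$meta
  names(meta)[names(meta) == "regime"] <- "inhibitor"
  meta <- meta[, c("cell_line", "stimulus", "inhibitor", "time_min",
                   "replicate", "batch"), drop = FALSE]
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (dialect == "wide") {
    out <- cbind(meta, as.data.frame(apply(data$values, 2, fmt),
                                     stringsAsFactors = FALSE,
                                     check.names = FALSE))
  } else {
    n_ab <- ncol(data$values)
    idx <- rep(seq_len(nrow(meta)), each = n_ab)
    out <- meta[idx, , drop = FALSE]
    out$antibody <- rep(colnames(data$values), times = nrow(meta))
    out$value <- fmt(as.vector(t(data$values)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale=", data$scale), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a directed prior network from an edge list or SIF file
#'
#' Two whitespace/tab/comma-separated columns are read as (parent, child);
#' three columns are read as SIF (`parent relation child`). Self-loops are
#' dropped with a warning. The node set is the union of edge endpoints.
#'
#' @param path edge-list or SIF file.
#' @param nodes optional declared node names merged into the node set.
#' @return an object of class `prior_network`: list with `nodes` (character)
#'   and `edges` (data.frame `parent`, `child`).
#' @export
read_prior_network <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  edges <- matrix(character(), ncol = 2)
  parts <- strsplit(trimws(lines), "[\t, ]+")
  nf <- lengths(parts)
  if (any(nf == 1)) {
    stop("format error: single-column line at line ",
         which(nf == 1)[1], call. = FALSE)
  }
  parent <- vapply(parts, `[`, character(1), 1L)
  child <- ifelse(nf >= 3,
                  vapply(parts, function(p) p[3L], character(1)),
                  vapply(parts, `[`, character(1), 2L))
  self <- parent == child
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop(s)", call. = FALSE)
    parent <- parent[!self]; child <- child[!self]
  }
  edges <- unique(data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE))
  prior_network(edges, nodes = nodes)
}

#' Construct a prior network object
#'
#' @param edges data.frame with columns `parent` and `child`.
#' @param nodes optional additional node names.
#' @return a `prior_network`.
#' @export
prior_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  if (any(edges$parent == edges$child)) {
    stop("prior network cannot contain self-loops", call. = FALSE)
  }
  all_nodes <- sort(unique(c(edges$parent, edges$child,
                             as.character(nodes))))
  structure(list(nodes = all_nodes,
                 edges = edges[, c("parent", "child"), drop = FALSE]),
            class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat("prior_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# adjacency (parent x child) of a prior network over a given node order
prior_adjacency <- function(prior, nodes) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (is.null(prior)) return(A)
  keep <- prior$edges$parent %in% nodes & prior$edges$child %in% nodes
  e <- prior$edges[keep, , drop = FALSE]
  A[cbind(match(e$parent, nodes), match(e$child, nodes))] <- 1
  A
}

#' Write learned networks, descendancy matrices and a run manifest
#'
#' Writes (a) one Cytoscape-loadable edge table per context
#' (`parent, child, probability`, sorted by decreasing probability),
#' (b) one TSV per descendancy matrix with entries in \{-1, 0, +1\}, and
#' (c) a YAML manifest echoing all supplied configuration values.
#'
#' @param networks named list of edge-probability matrices
#'   (parent x child), e.g. the result of [learn_networks()].
#' @param cdms named list of descendancy matrices
#'   (see [build_descendancy_matrix()]); may be `NULL`.
#' @param path output directory (created if needed).
#' @param config named list echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_network_outputs <- function(networks, cdms = NULL, path,
                                  config = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(networks)) {
    prob <- networks[[nm]]
    if (is.list(prob) && !is.null(prob$prob)) prob <- prob$prob
    nodes <- rownames(prob)
    idx <- which(prob > 0 & row(prob) != col(prob), arr.ind = TRUE)
    tab <- data.frame(parent = nodes[idx[, 1]], child = nodes[idx[, 2]],
                      probability = prob[idx], stringsAsFactors = FALSE)
    tab <- tab[order(-tab$probability, tab$parent, tab$child), ,
               drop = FALSE]
    utils::write.csv(tab,
                     file.path(path, paste0("edges_", safe_name(nm), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  for (nm in names(cdms)) {
    utils::write.table(cdms[[nm]],
                       file.path(path, paste0("cdm_", safe_name(nm), ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  manifest <- list(package = "ctxcausal",
                   version = as.character(utils::packageVersion("ctxcausal")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config)
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
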