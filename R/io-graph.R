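# Graph persistence. JSON is the canonical, lossless round-trip format;
# bit patterns are stored as hex strings plus the catalog to keep files
# with thousands of nodes small. GraphML export (via igraph) carries the
# node attributes needed by external graph tooling. All writers use stable
# key order so repeated runs are byte-identical.

graph_to_list <- function(graph) {
  nodes <- graph$nodes
  has_layout <- !is.null(nodes$x)
  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    out <- list(id = nodes$node_id[i],
                hex = pattern_to_hex(nodes$pattern[i]),
                feature_count = nodes$feature_count[i],
                appearance_count = nodes$appearance_count[i],
                origin = nodes$origin[i],
                frames = nodes$frames[[i]],
                systems = I(nodes$systems[[i]]),
                system_counts = as.list(nodes$system_counts[[i]]))
    if (has_layout) {
      out$x <- nodes$x[i]; out$y <- nodes$y[i]; out$size <- nodes$size[i]
    }
    out
  })
  list(hgpm_graph = 1L,
       catalog = I(graph$catalog$entries),
       mode = graph$catalog$mode,
       metadata = graph$metadata,
       nodes = node_list,
       edges = lapply(seq_len(nrow(graph$edges)), function(i) {
         list(from = graph$edges$from[i], to = graph$edges$to[i])
       }))
}

#' Write a graph to disk
#'
#' @param graph An `hgpm_graph`.
#' @param path Output path.
#' @param format `"json"` (canonical round-trip) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(graph_to_list(graph), auto_unbox = TRUE,
                             digits = I(17), null = "null", pretty = FALSE)
    writeLines(as.character(json), path)
  } else {
    nodes <- graph$nodes
    g <- igraph::graph_from_data_frame(
      graph$edges, directed = TRUE,
      vertices = data.frame(
        name = nodes$node_id,
        origin = nodes$origin,
        count = nodes$appearance_count,
        column = nodes$feature_count,
        y = if (is.null(nodes$y)) rep(NA_real_, nrow(nodes)) else nodes$y,
        size = if (is.null(nodes$size)) rep(NA_real_, nrow(nodes)) else nodes$size,
        systems = vapply(nodes$systems, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph written by [write_graph()] (JSON format)
#'
#' @param path Path to a graph JSON file.
#' @return An `hgpm_graph`; `load(save(g))` reproduces `g` exactly.
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) hgpm_stop("hgpm_io_error", "file not found: %s", path)
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  if (is.null(x$hgpm_graph)) {
    hgpm_stop("hgpm_parse_error", "%s: not an hgpm graph file", path)
  }
  catalog <- structure(list(entries = as.character(unlist(x$catalog)),
                            mode = x$mode), class = "hgpm_catalog")
  nb <- length(catalog$entries)
  empty_frames <- data.frame(system_id = character(0), run_id = character(0),
                             frame_index = integer(0), stringsAsFactors = FALSE)
  nodes <- data.frame(
    node_id = vapply(x$nodes, `[[`, character(1), "id"),
    pattern = hex_to_pattern(vapply(x$nodes, `[[`, character(1), "hex"), nb),
    feature_count = vapply(x$nodes, function(n) as.integer(n$feature_count), integer(1)),
    appearance_count = vapply(x$nodes, function(n) as.integer(n$appearance_count), integer(1)),
    origin = vapply(x$nodes, `[[`, character(1), "origin"),
    stringsAsFactors = FALSE)
  nodes$frames <- lapply(x$nodes, function(n) {
    if (length(n$frames) == 0L) return(empty_frames)
    data.frame(system_id = vapply(n$frames, `[[`, character(1), "system_id"),
               run_id = vapply(n$frames, `[[`, character(1), "run_id"),
               frame_index = vapply(n$frames, function(f) as.integer(f$frame_index), integer(1)),
               stringsAsFactors = FALSE)
  })
  nodes$systems <- lapply(x$nodes, function(n) as.character(unlist(n$systems)))
  nodes$system_counts <- lapply(x$nodes, function(n) {
    sc <- n$system_counts
    out <- vapply(sc, function(v) as.integer(v), integer(1))
    if (length(out) == 0L) out <- integer(0)
    out
  })
  if (!is.null(x$nodes[[1L]]$x)) {
    nodes$x <- vapply(x$nodes, function(n) as.integer(n$x), integer(1))
    nodes$y <- vapply(x$nodes, function(n) as.numeric(n$y), numeric(1))
    nodes$size <- vapply(x$nodes, function(n) as.numeric(n$size), numeric(1))
  }
  edges <- data.frame(
    from = vapply(x$edges, `[[`, character(1), "from"),
    to = vapply(x$edges, `[[`, character(1), "to"),
    stringsAsFactors = FALSE)
  md <- x$metadata
  for (f in c("n_models", "n_observed", "n_reference", "n_artificial", "threshold",
              "n_frames")) {
    if (!is.null(md[[f]])) md[[f]] <- as.integer(md[[f]])
  }
  if (!is.null(md$systems)) md$systems <- as.character(unlist(md$systems))
  make_graph_object(nodes, edges, catalog, md)
}

#' Write a hit table or screening summary as CSV
#'
#' @param x Data frame (hit table or summary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a hit table CSV
#'
#' @param path CSV with columns `molecule_id`, `label`, `model_id`, `hit`,
#'   optionally `fit_score`.
#' @return Validated hit-table data frame.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) hgpm_stop("hgpm_io_error", "file not found: %s", path)
  check_hit_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
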