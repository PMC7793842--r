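# Hierarchy construction: intersection closure, cover edges, graph assembly.
#
# Nodes are unique feature vectors; the partial order is strict set
# inclusion of the underlying feature sets. Closing the observed family
# under pairwise non-empty intersection guarantees that any two nodes with
# common features have a unique "meet" node, which is what makes the graph
# independent of the order in which models are considered.

#' Close a family of feature sets under pairwise intersection
#'
#' Returns the smallest family that contains the input sets and is closed
#' under non-empty pairwise intersection. Sets added by the closure are
#' flagged artificial. Empty intersections are discarded (the graph has no
#' universal root). The incremental insertion used here — add each set
#' together with its intersections against everything already present —
#' yields the full fixpoint, because intersection is associative.
#'
#' @param patterns Character vector of bit patterns (equal length,
#'   duplicate-free, each with at least one set bit).
#' @return `data.frame` with columns `pattern` and `artificial`, sorted by
#'   pattern.
#' @export
intersection_closure <- function(patterns) {
  if (length(patterns) == 0L) {
    hgpm_stop("hgpm_parameter_error", "intersection_closure needs at least one set")
  }
  if (anyDuplicated(patterns)) {
    hgpm_stop("hgpm_parameter_error", "input sets must be duplicate-free")
  }
  nb <- nchar(patterns[[1L]])
  stopifnot(all(nchar(patterns) == nb))
  if (any(pat_popcount(patterns) == 0L)) {
    hgpm_stop("hgpm_parameter_error", "input sets must be non-empty")
  }

  cap <- max(64L, 4L * length(patterns))
  M <- matrix(FALSE, cap, nb)
  pats <- character(cap)
  n <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  grow <- function(need) {
    while (need > nrow(M)) {
      M <<- rbind(M, matrix(FALSE, nrow(M), nb))
      length(pats) <<- 2L * length(pats)
    }
  }
  add <- function(p) {
    if (!is.null(seen[[p]])) return(invisible())
    grow(n + 1L)
    n <<- n + 1L
    pats[n] <<- p
    M[n, ] <<- pat_bits(p)
    seen[[p]] <- TRUE
    invisible()
  }

  for (p in patterns) {
    new_pats <- character(0)
    if (n > 0L) {
      s <- pat_bits(p)
      inter <- M[seq_len(n), , drop = FALSE]
      inter[, !s] <- FALSE
      keep <- rowSums(inter) > 0L
      if (any(keep)) {
        new_pats <- unique(matrix_to_pats(inter[keep, , drop = FALSE]))
      }
    }
    add(p)
    for (q in new_pats) add(q)
  }

  out <- data.frame(pattern = sort_c(pats[seq_len(n)]), stringsAsFactors = FALSE)
  out$artificial <- !(out$pattern %in% patterns)
  out
}

#' Cover edges (Hasse diagram) of a family of feature sets
#'
#' Computes the transitive reduction of the strict-subset relation: an edge
#' u -> v is kept iff u's set is a strict subset of v's and no third set
#' lies strictly between them. The reduction of a partial order is unique.
#' Edges are directed subset -> superset.
#'
#' @param patterns Duplicate-free character vector of bit patterns.
#' @return `data.frame` with columns `from` and `to` (patterns), sorted.
#' @export
cover_edges <- function(patterns) {
  if (anyDuplicated(patterns)) {
    hgpm_stop("hgpm_parameter_error", "family must be duplicate-free")
  }
  n <- length(patterns)
  if (n < 2L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  M <- pats_to_matrix(patterns) * 1
  sz <- rowSums(M)
  inter <- tcrossprod(M)                    # |set_i  intersect  set_j|
  S <- (inter == sz) & outer(sz, sz, `<`)   # S[i,j]: set_i strictly subset of set_j
  storage.mode(S) <- "double"
  red <- S * (S %*% S == 0)                 # drop edges implied via a middle set
  idx <- which(red == 1, arr.ind = TRUE)
  out <- data.frame(from = patterns[idx[, 1L]], to = patterns[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

make_graph_object <- function(nodes, edges, catalog, metadata) {
  structure(list(nodes = nodes, edges = edges, catalog = catalog,
                 metadata = metadata), class = "hgpm_graph")
}

#' Build the hierarchical graph of pharmacophore models
#'
#' Assembles the full graph from counted unique vectors: closes the family
#' of observed (and reference) feature sets under intersection, marks the
#' added sets as artificial nodes with appearance count 0, and links the
#' family by its cover relation (subset -> superset, redundant transitive
#' paths removed). The result is a DAG whose node and edge sets do not
#' depend on the order of the input.
#'
#' @param counted Filtered output of [count_unique()] /
#'   [filter_by_count()].
#' @param catalog The `hgpm_catalog` the patterns are aligned to.
#' @param metadata Optional named list merged into the graph metadata
#'   (e.g. `threshold`, `n_frames`).
#' @return An object of class `hgpm_graph` with elements `nodes` (data frame:
#'   `node_id`, `pattern`, `feature_count`, `appearance_count`, `origin`,
#'   list-columns `frames`, `systems`, `system_counts`), `edges` (`from`,
#'   `to` node ids), `catalog`, `metadata`.
#' @export
build_graph <- function(counted, catalog, metadata = list()) {
  stopifnot(inherits(catalog, "hgpm_catalog"))
  nb <- length(catalog$entries)
  if (nrow(counted) == 0L) {
    hgpm_stop("hgpm_parameter_error", "no counted vectors to build a graph from")
  }
  if (any(nchar(counted$pattern) != nb)) {
    hgpm_stop("hgpm_catalog_error", "vector length does not match catalog size")
  }
  closure <- intersection_closure(counted$pattern)
  m <- match(closure$pattern, counted$pattern)

  frames <- vector("list", nrow(closure))
  counts <- integer(nrow(closure))
  origin <- character(nrow(closure))
  empty_frames <- data.frame(system_id = character(0), run_id = character(0),
                             frame_index = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(closure))) {
    if (is.na(m[i])) {
      origin[i] <- "artificial"
      frames[[i]] <- empty_frames
    } else {
      row <- counted[m[i], ]
      counts[i] <- row$appearance_count
      origin[i] <- if (row$reference) "reference" else "observed"
      frames[[i]] <- row$frames[[1L]]
    }
  }
  systems <- lapply(frames, function(f) sort_c(unique(f$system_id)))
  system_counts <- lapply(frames, function(f) {
    if (nrow(f) == 0L) return(integer(0))
    tab <- table(f$system_id)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[sort_c(names(out))]
  })

  nodes <- data.frame(node_id = node_id_for(closure$pattern),
                      pattern = closure$pattern,
                      feature_count = pat_popcount(closure$pattern),
                      appearance_count = counts,
                      origin = origin,
                      stringsAsFactors = FALSE)
  nodes$frames <- frames
  nodes$systems <- systems
  nodes$system_counts <- system_counts

  ed <- cover_edges(closure$pattern)
  edges <- data.frame(from = node_id_for(ed$from), to = node_id_for(ed$to),
                      stringsAsFactors = FALSE)

  md <- list(mode = catalog$mode,
             n_models = sum(counts),
             n_observed = sum(origin == "observed"),
             n_reference = sum(origin == "reference"),
             n_artificial = sum(origin == "artificial"),
             systems = sort_c(unique(unlist(systems))))
  md[names(metadata)] <- metadata
  make_graph_object(nodes, edges, catalog, md)
}

#' @export
print.hgpm_graph <- function(x, ...) {
  cat(sprintf(paste0("<hgpm graph: %d nodes (%d observed, %d artificial",
                     ", %d reference), %d edges, %d features, mode %s>\n"),
              nrow(x$nodes), sum(x$nodes$origin == "observed"),
              sum(x$nodes$origin == "artificial"),
              sum(x$nodes$origin == "reference"),
              nrow(x$edges), length(x$catalog$entries), x$catalog$mode))
  invisible(x)
}

node_lookup <- function(graph, node) {
  if (is.list(node) && !is.null(node$node_id)) node <- node$node_id
  i <- match(node, graph$nodes$node_id)
  if (is.na(i)) i <- match(node, graph$nodes$pattern)
  if (is.na(i)) hgpm_stop("hgpm_lookup_error", "node '%s' is not in the graph", node)
  i
}

#' Intersection (meet) node of two graph nodes
#'
#' Returns the node whose feature set is the intersection of the two query
#' nodes' sets, or `NULL` when the intersection is empty. By construction
#' the graph is closed under intersection, so a non-empty meet always has a
#' node.
#'
#' @param graph An `hgpm_graph`.
#' @param node_a,node_b Node ids, bit patterns, or rows of `graph$nodes`.
#' @return A one-row data frame (the meet node) or `NULL`.
#' @export
meet_node <- function(graph, node_a, node_b) {
  ia <- node_lookup(graph, node_a)
  ib <- node_lookup(graph, node_b)
  meet <- pat_and(graph$nodes$pattern[ia], graph$nodes$pattern[ib])
  if (pat_popcount(meet) == 0L) return(NULL)
  graph$nodes[match(meet, graph$nodes$pattern), , drop = FALSE]
}

#' Merge counted vectors from several systems into one projected graph
#'
#' Builds a single hierarchical graph over pharmacophore ensembles of
#' multiple protein-ligand systems. This is only meaningful for feature
#' serials projected onto the protein (ligand identities dropped); each
#' node records which systems contributed frames and the per-system
#' appearance counts, so nodes can later be coloured by origin.
#'
#' @param counted_by_system Named list of [count_unique()] /
#'   [filter_by_count()] outputs, all vectorized over the same shared
#'   projected catalog.
#' @param catalog The shared `hgpm_catalog`; must have mode `"projected"`.
#' @param metadata Optional metadata list, as in [build_graph()].
#' @return An `hgpm_graph`.
#' @export
merge_graphs <- function(counted_by_system, catalog, metadata = list()) {
  stopifnot(inherits(catalog, "hgpm_catalog"))
  if (catalog$mode != "projected") {
    hgpm_stop("hgpm_mode_error",
              "merging systems requires a projected catalog (mode is '%s')",
              catalog$mode)
  }
  if (length(counted_by_system) < 1L) {
    hgpm_stop("hgpm_parameter_error", "no systems supplied")
  }
  all_rows <- do.call(rbind, lapply(counted_by_system, function(cc) {
    cc[, c("pattern", "appearance_count", "observed", "reference")]
  }))
  all_frames <- unlist(lapply(counted_by_system, `[[`, "frames"), recursive = FALSE)
  groups <- split(seq_len(nrow(all_rows)), all_rows$pattern)
  pats <- sort_c(names(groups))
  merged <- data.frame(pattern = pats,
                       appearance_count = vapply(pats, function(p)
                         sum(all_rows$appearance_count[groups[[p]]]), integer(1),
                         USE.NAMES = FALSE),
                       observed = vapply(pats, function(p)
                         any(all_rows$observed[groups[[p]]]), logical(1),
                         USE.NAMES = FALSE),
                       reference = vapply(pats, function(p)
                         any(all_rows$reference[groups[[p]]]), logical(1),
                         USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  merged$frames <- lapply(pats, function(p) {
    f <- do.call(rbind, all_frames[groups[[p]]])
    f <- f[order(f$run_id, f$frame_index, method = "radix"), , drop = FALSE]
    rownames(f) <- NULL
    f
  })
  build_graph(merged, catalog, metadata)
}

#' Table-style summary statistics of a graph
#'
#' @param graph An `hgpm_graph`.
#' @return One-row `data.frame`: number of models, filtering threshold,
#'   unique features, observed / artificial / total node counts and the MDS
#'   variance of the projection when a layout has been assigned.
#' @export
graph_stats <- function(graph) {
  md <- graph$metadata
  data.frame(n_models = md$n_models,
             threshold = if (is.null(md$threshold)) NA_integer_ else md$threshold,
             n_unique_features = length(graph$catalog$entries),
             n_observed = sum(graph$nodes$origin %in% c("observed", "reference")),
             n_artificial = sum(graph$nodes$origin == "artificial"),
             n_total = nrow(graph$nodes),
             variance_percent = if (is.null(md$variance_percent)) NA_real_
                                else md$variance_percent)
}

#' Check the structural invariants of a graph
#'
#' Verifies that the graph is a DAG whose edges are exactly the cover
#' relation of strict subset inclusion, that the node family is closed
#' under pairwise non-empty intersection, and that bit patterns are unique
#' and non-empty. Intended for tests and post-load validation.
#'
#' @param graph An `hgpm_graph`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_graph <- function(graph) {
  nodes <- graph$nodes
  if (anyDuplicated(nodes$pattern)) stop("duplicate node bit patterns")
  if (any(pat_popcount(nodes$pattern) == 0L)) stop("empty feature set node")
  if (any(nodes$origin == "artificial" & nodes$appearance_count != 0L)) {
    stop("artificial node with non-zero appearance count")
  }
  ed <- cover_edges(nodes$pattern)
  want <- data.frame(from = node_id_for(ed$from), to = node_id_for(ed$to),
                     stringsAsFactors = FALSE)
  got <- graph$edges[order(graph$edges$from, graph$edges$to, method = "radix"), ,
                     drop = FALSE]
  rownames(got) <- NULL
  if (!identical(want, got)) stop("edges are not the cover relation")
  closure <- intersection_closure(
    nodes$pattern[nodes$origin != "artificial"])
  if (!setequal(closure$pattern, nodes$pattern)) {
    stop("node family is not the intersection closure of its observed sets")
  }
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = nodes$node_id)
  if (!igraph::is_dag(g)) stop("graph contains a cycle")
  invisible(TRUE)
}
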