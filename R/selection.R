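# Graph-driven model selection and consensus virtual-screening scoring.
#
# The selection strategies mirror how the graph is read in practice: look
# up the crystal-structure node, the highest-frequency node, or a node with
# designated common features, then optionally expand to all observed
# supersets and screen the representative model of every selected node.

#' Find the node matching a feature set
#'
#' Exact match: the query is serialized against the graph's catalog and the
#' node with precisely that bit pattern is returned, or `NULL` when no such
#' node exists. Features of the query that are not in the catalog make an
#' exact match impossible, so `NULL` is returned.
#'
#' @param graph An `hgpm_graph`.
#' @param query Character vector of feature serials, a list of
#'   `hgpm_feature_key` objects, an `hgpm_model`, or a bit-pattern string.
#' @return One-row data frame (the node) or `NULL`.
#' @export
find_node <- function(graph, query) {
  entries <- graph$catalog$entries
  if (inherits(query, "hgpm_model")) {
    if (query$mode != graph$catalog$mode) {
      hgpm_stop("hgpm_mode_error", "query mode '%s' does not match graph mode '%s'",
                query$mode, graph$catalog$mode)
    }
    query <- query$features
  }
  if (is.list(query)) {
    modes <- unique(vapply(query, `[[`, character(1), "mode"))
    if (!identical(modes, graph$catalog$mode)) {
      hgpm_stop("hgpm_mode_error", "query mode '%s' does not match graph mode '%s'",
                paste(modes, collapse = ","), graph$catalog$mode)
    }
    query <- vapply(query, `[[`, character(1), "serial")
  }
  if (length(query) == 1L && grepl("^[01]+$", query) &&
      nchar(query) == length(entries)) {
    pattern <- query
  } else {
    idx <- match(unique(query), entries)
    if (anyNA(idx)) return(NULL)
    bits <- rep(FALSE, length(entries))
    bits[idx] <- TRUE
    pattern <- bits_to_pat(bits)
  }
  i <- match(pattern, graph$nodes$pattern)
  if (is.na(i)) return(NULL)
  graph$nodes[i, , drop = FALSE]
}

#' Highest-frequency (HF) node
#'
#' The observed node with the largest appearance count. Ties are broken by
#' the larger feature count, then by lexicographic bit pattern, so the
#' result is deterministic.
#'
#' @param graph An `hgpm_graph` with at least one observed node.
#' @return One-row data frame.
#' @export
highest_frequency_node <- function(graph) {
  obs <- graph$nodes[graph$nodes$origin == "observed", , drop = FALSE]
  if (nrow(obs) == 0L) {
    hgpm_stop("hgpm_lookup_error", "graph has no observed nodes")
  }
  ord <- order(-obs$appearance_count, -obs$feature_count, obs$pattern,
               method = "radix")
  obs[ord[1L], , drop = FALSE]
}

#' Superset selection around an anchor node
#'
#' Returns every node whose feature set contains the anchor's set (the
#' anchor itself included when it qualifies). By default artificial nodes
#' are excluded, because no screening run exists for them — only observed
#' and reference nodes correspond to actual pharmacophore models.
#'
#' @param graph An `hgpm_graph`.
#' @param anchor Node id, bit pattern, or node row.
#' @param observed_only Drop artificial nodes (default `TRUE`).
#' @return Data frame of selected nodes, sorted by pattern.
#' @export
superset_selection <- function(graph, anchor, observed_only = TRUE) {
  ia <- node_lookup(graph, anchor)
  a <- graph$nodes$pattern[ia]
  keep <- vapply(graph$nodes$pattern, function(p) pat_is_subset(a, p),
                 logical(1), USE.NAMES = FALSE)
  if (observed_only) keep <- keep & graph$nodes$origin != "artificial"
  out <- graph$nodes[keep, , drop = FALSE]
  out <- out[order(out$pattern, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative model of each selected node
#'
#' For an observed node, the representative is the first pharmacophore
#' model seen with that exact feature vector: the provenance with the
#' smallest `(run_id, frame_index)` in lexicographic run order. Reference
#' nodes represent themselves (crystal-structure model). Artificial nodes
#' have no model and raise an error.
#'
#' @param graph An `hgpm_graph`.
#' @param nodes Data frame of nodes (e.g. from [superset_selection()]) or a
#'   vector of node ids.
#' @return Data frame with columns `node_id`, `system_id`, `run_id`,
#'   `frame_index`, `is_reference`.
#' @export
representative_models <- function(graph, nodes) {
  if (!is.data.frame(nodes)) {
    nodes <- graph$nodes[vapply(nodes, function(n) node_lookup(graph, n),
                                integer(1)), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    origin <- nodes$origin[i]
    if (origin == "artificial") {
      hgpm_stop("hgpm_no_representative",
                "artificial node %s has no associated pharmacophore model",
                nodes$node_id[i])
    }
    if (origin == "reference" && nrow(nodes$frames[[i]]) == 0L) {
      return(data.frame(node_id = nodes$node_id[i],
                        system_id = nodes$systems[[i]][1] %||% NA_character_,
                        run_id = NA_character_, frame_index = NA_integer_,
                        is_reference = TRUE, stringsAsFactors = FALSE))
    }
    f <- nodes$frames[[i]]
    f <- f[order(f$run_id, f$frame_index, method = "radix"), , drop = FALSE]
    data.frame(node_id = nodes$node_id[i], system_id = f$system_id[1L],
               run_id = f$run_id[1L], frame_index = f$frame_index[1L],
               is_reference = origin == "reference", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

check_hit_table <- function(hit_table) {
  needed <- c("molecule_id", "label", "model_id", "hit")
  if (!all(needed %in% names(hit_table))) {
    hgpm_stop("hgpm_parameter_error", "hit table needs columns: %s",
              paste(needed, collapse = ", "))
  }
  if (!all(hit_table$label %in% c("active", "decoy"))) {
    hgpm_stop("hgpm_parameter_error", "labels must be 'active' or 'decoy'")
  }
  invisible(hit_table)
}

#' Consensus score over a selection of models
#'
#' Common-hits scoring: the consensus score of a molecule is the number of
#' selected models that retrieved it. The hit list of the selection is the
#' set of molecules with score >= 1.
#'
#' @param hit_table Data frame with columns `molecule_id`, `label`
#'   (`"active"`/`"decoy"`), `model_id`, `hit` (0/1), optional `fit_score`.
#' @param selection Character vector of model ids to combine.
#' @return Named integer vector: consensus score per molecule (all
#'   molecules of the table, including score 0).
#' @export
consensus_score <- function(hit_table, selection) {
  check_hit_table(hit_table)
  if (length(selection) == 0L) {
    hgpm_stop("hgpm_parameter_error", "selection must contain at least one model")
  }
  missing <- setdiff(selection, unique(hit_table$model_id))
  if (length(missing) > 0L) {
    hgpm_stop("hgpm_lookup_error", "unknown model id(s): %s",
              paste(missing, collapse = ", "))
  }
  mols <- sort_c(unique(hit_table$molecule_id))
  sel <- hit_table[hit_table$model_id %in% selection & hit_table$hit > 0, ]
  counts <- table(factor(sel$molecule_id, levels = mols))
  out <- as.integer(counts)
  names(out) <- mols
  out
}

#' Labels of the molecules in a hit table
#'
#' @param hit_table A hit table (see [consensus_score()]).
#' @return Named character vector molecule_id -> `"active"`/`"decoy"`.
#' @export
molecule_labels <- function(hit_table) {
  check_hit_table(hit_table)
  first <- !duplicated(hit_table$molecule_id)
  out <- hit_table$label[first]
  names(out) <- hit_table$molecule_id[first]
  out[sort_c(names(out))]
}

#' Truncated ROC AUC at a database percentage
#'
#' Early-enrichment metric used to judge virtual-screening selections.
#' Molecules with a positive score are ranked by descending score and
#' traversed as a ROC curve; ties form straight segments (trapezoidal
#' traversal). Molecules with score 0 were not retrieved by any model and
#' are never screened, so the curve ends at the last retrieved molecule.
#' The curve is cut after `ceil(percent/100 * N)` screened molecules
#' (interpolating inside a tie block if needed) and the area under the
#' truncated curve is normalized by the false-positive rate reached at the
#' cutoff. Conventions: no actives retrieved within the cutoff gives 0.0;
#' a cutoff reached without screening any decoy gives 1.0.
#'
#' @param scores Named numeric vector: consensus (or other) score per
#'   molecule; 0 means not retrieved.
#' @param labels Named character vector (`"active"`/`"decoy"`) over the
#'   same molecules.
#' @param percent Percentage of the database in (0, 100].
#' @return AUC in `[0, 1]`.
#' @export
truncated_roc_auc <- function(scores, labels, percent = 100) {
  if (percent <= 0 || percent > 100) {
    hgpm_stop("hgpm_parameter_error", "percent must lie in (0, 100]")
  }
  labels <- labels[names(scores)]
  if (anyNA(labels)) {
    hgpm_stop("hgpm_parameter_error", "labels missing for some molecules")
  }
  A <- sum(labels == "active")
  Dn <- sum(labels == "decoy")
  if (A < 1L || Dn < 1L) {
    hgpm_stop("hgpm_undefined_metric",
              "AUC needs at least one active and one decoy (have %d/%d)", A, Dn)
  }
  N <- length(scores)
  n_p <- ceiling(percent / 100 * N)

  retrieved <- scores > 0
  if (!any(retrieved)) return(0)
  s <- scores[retrieved]
  l <- labels[retrieved]
  # tie blocks in descending score order
  lev <- sort(unique(s), decreasing = TRUE)
  blk_a <- vapply(lev, function(v) sum(l == "active" & s == v), numeric(1))
  blk_d <- vapply(lev, function(v) sum(l == "decoy" & s == v), numeric(1))
  blk_n <- blk_a + blk_d

  cum_n <- cumsum(blk_n)
  # walk blocks until the cutoff in screened molecules is reached
  tp <- 0; fp <- 0; area <- 0
  remaining <- min(n_p, sum(blk_n))
  for (j in seq_along(lev)) {
    take <- min(blk_n[j], remaining)
    if (take <= 0) break
    frac <- take / blk_n[j]
    dtp <- frac * blk_a[j]
    dfp <- frac * blk_d[j]
    # trapezoid in (FPR, TPR) space, unnormalized FPR axis for now
    area <- area + (dfp / Dn) * ((tp + tp + dtp) / (2 * A))
    tp <- tp + dtp
    fp <- fp + dfp
    remaining <- remaining - take
  }
  if (tp == 0) return(0)
  fpr_cut <- fp / Dn
  if (fpr_cut == 0) return(1)
  area / fpr_cut
}

#' Screening summary of a node selection
#'
#' Combines a selection's per-model hit lists into the consensus score and
#' reports, per requested database percentage, the truncated ROC AUC, plus
#' the size of the union hit list.
#'
#' @param hit_table Hit table (see [consensus_score()]).
#' @param selection Character vector of model ids.
#' @param percents Numeric vector of database percentages.
#' @param selection_id Label for the selection row.
#' @return One-row data frame: `selection_id`, `n_models`, `n_hits`, one
#'   `auc_at_<p>` column per percentage.
#' @export
screening_summary <- function(hit_table, selection, percents = c(1, 5, 10, 50, 100),
                              selection_id = "selection") {
  sc <- consensus_score(hit_table, selection)
  labs <- molecule_labels(hit_table)
  out <- data.frame(selection_id = selection_id,
                    n_models = length(unique(selection)),
                    n_hits = sum(sc > 0), stringsAsFactors = FALSE)
  for (p in percents) {
    out[[sprintf("auc_at_%g", p)]] <- truncated_roc_auc(sc, labs, p)
  }
  out
}

#' Node colours for a metric (e.g. per-node screening AUC)
#'
#' Maps a metric in `[0, 1]` onto a red-to-green ramp: 1 is full green, 0
#' full red. Artificial nodes are always gray (they have no screening
#' model), as are nodes missing from the metric. Values outside `[0, 1]`
#' are min-max normalized with a warning.
#'
#' @param graph An `hgpm_graph`.
#' @param metric Named numeric vector node_id -> value.
#' @param gray Colour for artificial / missing nodes.
#' @return Data frame `node_id`, `color` (hex strings).
#' @export
color_by_metric <- function(graph, metric, gray = "#808080") {
  vals <- metric
  if (length(vals) > 0 && (min(vals) < 0 || max(vals) > 1)) {
    warning("metric outside [0, 1]; min-max normalizing")
    rng <- range(vals)
    vals <- if (diff(rng) == 0) rep(0.5, length(vals)) else (vals - rng[1]) / diff(rng)
  }
  ramp <- grDevices::colorRamp(c("#FF0000", "#00FF00"))
  col <- vapply(seq_len(nrow(graph$nodes)), function(i) {
    id <- graph$nodes$node_id[i]
    if (graph$nodes$origin[i] == "artificial" || is.na(match(id, names(vals)))) {
      return(gray)
    }
    rgb <- ramp(vals[[id]])
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }, character(1))
  data.frame(node_id = graph$nodes$node_id, color = col, stringsAsFactors = FALSE)
}
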