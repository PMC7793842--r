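# Independent brute-force oracles used to validate the production
# implementations, plus small fixture builders. The oracles deliberately
# use naive algorithms (fixpoint loops, cubic reductions, explicit
# threshold sweeps) and plain set representation, not the package's
# bit-pattern machinery.

# fixpoint closure under pairwise non-empty intersection, on lists of
# character sets
oracle_closure <- function(sets) {
  fam <- unique(lapply(sets, sort))
  repeat {
    added <- FALSE
    n <- length(fam)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        inter <- sort(intersect(fam[[i]], fam[[j]]))
        if (length(inter) == 0) next
        if (!any(vapply(fam, identical, logical(1), y = inter))) {
          fam[[length(fam) + 1L]] <- inter
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  fam
}

# all strict-subset pairs, then cubic removal of transitively implied edges
oracle_cover_edges <- function(fam) {
  n <- length(fam)
  is_sub <- function(a, b) length(a) < length(b) && all(a %in% b)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !is_sub(fam[[i]], fam[[j]])) next
      redundant <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (is_sub(fam[[i]], fam[[k]]) && is_sub(fam[[k]], fam[[j]])) {
          redundant <- TRUE
          break
        }
      }
      if (!redundant) edges[[length(edges) + 1L]] <- list(from = fam[[i]], to = fam[[j]])
    }
  }
  edges
}

# The same two oracles on integer bitmasks (alphabet <= 30 features):
# a literal fixpoint sweep over all pairs, then an explicitly cubic
# reduction. Used where the list-based oracle above would be slow.
oracle_closure_masks <- function(masks) {
  fam <- unique(masks)
  repeat {
    inter <- unique(as.vector(outer(fam, fam, bitwAnd)))
    inter <- setdiff(inter[inter != 0L], fam)
    if (length(inter) == 0L) break
    fam <- c(fam, inter)
  }
  sort(fam)
}

oracle_cover_edges_masks <- function(fam) {
  n <- length(fam)
  sub <- outer(fam, fam, function(a, b) bitwAnd(a, b) == a & a != b)
  edges <- NULL
  for (i in seq_len(n)) {
    implied <- as.logical(sub[i, ] %*% sub)   # i subset k subset j for some k
    js <- which(sub[i, ] & !implied)
    if (length(js) > 0L) edges <- rbind(edges, cbind(i = i, j = js))
  }
  edges
}

sets_to_masks <- function(sets, alphabet) {
  vapply(sets, function(s) sum(bitwShiftL(1L, match(s, alphabet) - 1L)),
         integer(1))
}

mask_to_pattern <- function(mask, n_bits) {
  vapply(mask, function(m)
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, seq_len(n_bits) - 1L)) > 0L, "1", "0"),
          collapse = ""), character(1))
}

# set representation <-> bit patterns over an alphabet
sets_to_patterns <- function(sets, alphabet) {
  vapply(sets, function(s) {
    bits <- rep("0", length(alphabet))
    bits[match(s, alphabet)] <- "1"
    paste(bits, collapse = "")
  }, character(1))
}

patterns_to_sets <- function(patterns, alphabet) {
  lapply(patterns, function(p) alphabet[strsplit(p, "")[[1]] == "1"])
}

# explicit all-thresholds ROC sweep with geometric interpolation at the
# molecule cutoff; same conventions as the production code, independent path
oracle_truncated_auc <- function(scores, labels, percent) {
  A <- sum(labels == "active"); D <- sum(labels == "decoy")
  N <- length(scores)
  n_p <- ceiling(percent / 100 * N)
  keep <- scores > 0
  if (!any(keep)) return(0)
  s <- scores[keep]; l <- labels[keep]
  thresholds <- sort(unique(s), decreasing = TRUE)
  # curve points after screening everything with score >= t
  pts <- data.frame(n = 0, tp = 0, fp = 0)
  for (t in thresholds) {
    sel <- s >= t
    pts <- rbind(pts, data.frame(n = sum(sel), tp = sum(sel & l == "active"),
                                 fp = sum(sel & l == "decoy")))
  }
  # truncate at n_p screened molecules, interpolating inside a segment
  end <- min(n_p, max(pts$n))
  last <- max(which(pts$n <= end))
  tp <- pts$tp[last]; fp <- pts$fp[last]
  if (pts$n[last] < end) {
    f <- (end - pts$n[last]) / (pts$n[last + 1] - pts$n[last])
    tp <- tp + f * (pts$tp[last + 1] - pts$tp[last])
    fp <- fp + f * (pts$fp[last + 1] - pts$fp[last])
    pts <- rbind(pts[seq_len(last), ], data.frame(n = end, tp = tp, fp = fp))
  } else {
    pts <- pts[seq_len(last), ]
  }
  if (tp == 0) return(0)
  if (fp == 0) return(1)
  area <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    area <- area + (pts$fp[i + 1] - pts$fp[i]) / D *
      (pts$tp[i] + pts$tp[i + 1]) / (2 * A)
  }
  area / (fp / D)
}

# random family of distinct non-empty feature sets over an alphabet
random_sets <- function(n_sets, alphabet, p = 0.4) {
  out <- list()
  while (length(out) < n_sets) {
    s <- alphabet[stats::runif(length(alphabet)) < p]
    if (length(s) == 0) next
    if (!any(vapply(out, identical, logical(1), y = s))) out[[length(out) + 1L]] <- s
  }
  out
}

# tiny deterministic model ensemble over named feature sets
models_from_sets <- function(sets, run_id = "run1", system_id = "sys") {
  lapply(seq_along(sets), function(i) {
    pharmacophore_model(system_id, run_id, i - 1L, sets[[i]])
  })
}

# toy serials (valid vocabulary) used as an abstract alphabet; already in
# lexicographic order so bit positions match catalog order
toy_alphabet <- function(n) {
  stopifnot(n <= 99)
  sprintf("H|A%02d|RES%02d", seq_len(n), seq_len(n))
}

# counted-vector data frame straight from explicit sets and counts
counted_from_sets <- function(sets, counts, alphabet,
                              reference = rep(FALSE, length(sets))) {
  pats <- sets_to_patterns(sets, alphabet)
  frames <- lapply(seq_along(sets), function(i) {
    k <- counts[i]
    if (k == 0) {
      return(data.frame(system_id = character(0), run_id = character(0),
                        frame_index = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(system_id = "sys", run_id = "run1",
               frame_index = seq_len(k) - 1L, stringsAsFactors = FALSE)
  })
  out <- data.frame(pattern = pats, appearance_count = as.integer(counts),
                    observed = counts > 0, reference = reference,
                    stringsAsFactors = FALSE)
  out$frames <- frames
  ord <- order(out$pattern, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

node_id_for_test <- function(patterns) hgpm:::node_id_for(patterns)

toy_catalog <- function(alphabet, mode = "ligand_aware") {
  structure(list(entries = sort(alphabet, method = "radix"), mode = mode),
            class = "hgpm_catalog")
}
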