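# Deterministic 2-D layout: x is the feature-count column, y is a 1-D
# classical (Torgerson) MDS of the Manhattan distances between feature
# vectors. Classical scaling is seedless and has a natural "proportion of
# variance" diagnostic (leading eigenvalue over the sum of positive
# eigenvalues), which is reported with every layout.

#' Manhattan distance matrix between feature vectors
#'
#' For binary vectors the Manhattan (city-block) distance equals the
#' Hamming distance: the number of features present in exactly one of the
#' two models.
#'
#' @param patterns Character vector of equal-length bit patterns.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
manhattan_matrix <- function(patterns) {
  if (length(unique(nchar(patterns))) > 1L) {
    hgpm_stop("hgpm_parameter_error", "vectors must have equal length")
  }
  M <- pats_to_matrix(patterns) * 1
  as.matrix(stats::dist(M, method = "manhattan"))
}

#' One-dimensional classical multidimensional scaling
#'
#' Torgerson scaling to a single axis: the squared-distance matrix is
#' double-centered, and the coordinates are the leading eigenvector scaled
#' by the square root of the leading eigenvalue. Coordinates are centered
#' at zero. The sign is gauge-fixed so that the coordinate at `sign_index`
#' is `<= 0`, making the output fully deterministic. The proportion of
#' variance preserved by the projection is the leading eigenvalue divided
#' by the sum of the positive eigenvalues (Manhattan distances need not be
#' Euclidean-embeddable, so negative eigenvalues can occur; they are
#' excluded from the denominator).
#'
#' @param distances Symmetric non-negative matrix with zero diagonal.
#' @param sign_index Index of the element whose coordinate fixes the sign
#'   (the layout uses the node with the lexicographically smallest bit
#'   pattern).
#' @return List with `coordinates` (numeric, centered) and
#'   `variance_percent` in `[0, 100]`. A degenerate all-zero distance
#'   matrix yields all-zero coordinates and variance 100.
#' @export
mds_1d <- function(distances, sign_index = 1L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-12))) {
    hgpm_stop("hgpm_parameter_error", "distance matrix must be symmetric")
  }
  if (any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    hgpm_stop("hgpm_parameter_error",
              "distances must be non-negative with a zero diagonal")
  }
  if (n == 1L || all(D == 0)) {
    return(list(coordinates = rep(0, n), variance_percent = 100))
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1)
  pos <- eig$values > tol
  if (!any(pos)) {
    return(list(coordinates = rep(0, n), variance_percent = 100))
  }
  lambda1 <- eig$values[1L]
  y <- sqrt(lambda1) * eig$vectors[, 1L]
  y <- y - mean(y)
  if (y[sign_index] > 0) y <- -y
  list(coordinates = y,
       variance_percent = 100 * lambda1 / sum(eig$values[pos]))
}

#' Map appearance counts to node display sizes
#'
#' Affine map of the count range onto `[size_min, size_max]`; larger
#' appearance counts give larger nodes. Artificial nodes (count 0) always
#' receive `size_min`. When all counts are equal and positive, every node
#' receives `size_max`.
#'
#' @param counts Non-negative integer appearance counts.
#' @param size_min,size_max Display size bounds, `size_min < size_max`.
#' @return Numeric vector of sizes.
#' @export
node_sizes <- function(counts, size_min = 4, size_max = 20) {
  if (size_min >= size_max) {
    hgpm_stop("hgpm_parameter_error", "size_min must be < size_max")
  }
  if (length(counts) == 0L) return(numeric(0))
  cmin <- min(counts)
  cmax <- max(counts)
  if (cmax == cmin) {
    return(ifelse(counts == 0, size_min, size_max))
  }
  size_min + (counts - cmin) / (cmax - cmin) * (size_max - size_min)
}

#' Assign layout coordinates to a graph
#'
#' Sets, for every node (observed, reference and artificial alike), the x
#' column (= feature count), the y coordinate from [mds_1d()] of the
#' pairwise Manhattan distances, and the display size from [node_sizes()].
#' The variance of the projection is stored in
#' `graph$metadata$variance_percent`. The layout is fully deterministic;
#' an optional seeded jitter can be applied at render time for very dense
#' graphs.
#'
#' @param graph An `hgpm_graph`.
#' @param size_min,size_max Node display size bounds.
#' @return The graph with `x`, `y`, `size` columns added to `nodes`.
#' @export
assign_layout <- function(graph, size_min = 4, size_max = 20) {
  nodes <- graph$nodes
  D <- manhattan_matrix(nodes$pattern)
  sign_index <- order(nodes$pattern, method = "radix")[1L]
  mds <- mds_1d(D, sign_index = sign_index)
  nodes$x <- nodes$feature_count
  nodes$y <- mds$coordinates
  nodes$size <- node_sizes(nodes$appearance_count, size_min, size_max)
  graph$nodes <- nodes
  graph$metadata$variance_percent <- mds$variance_percent
  graph
}
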