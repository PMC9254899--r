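#' Ward agglomerative clustering of a distance matrix
#'
#' Implements Ward's minimum-variance criterion via the Lance-Williams
#' recurrence on squared distances, with merge heights reported on the
#' original distance scale (the convention in which two singletons
#' merge at exactly their input distance, matching
#' `stats::hclust(method = "ward.D2")`).  Ties are broken
#' deterministically by the lowest pair of cluster slot indices.
#'
#' @param dist Symmetric, non-negative matrix with zero diagonal (or a
#'   `dist` object).  Row/column names become the dendrogram labels.
#' @return Object of class `ward_dendrogram`: a list with hclust-style
#'   `merge` (n-1 x 2; negative entries are leaves, positive entries
#'   earlier merge nodes), `height`, and `labels`, plus slots for
#'   LCV/completeness annotations filled by [annotate_lcv()] and
#'   [annotate_completeness()].
#' @examples
#' D <- as.matrix(dist(c(0, 1, 10)))
#' ward_linkage(D)$height  # 1, sqrt(361/3)
#' @export
ward_linkage <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (ncol(D) != n || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(D < 0)) stop("distance matrix must be non-negative", call. = FALSE)
  if (any(diag(D) != 0))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  W <- D^2
  diag(W) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1, n)
  cid <- -seq_len(n)          # cluster id occupying each slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- min(W)
    hits <- which(W == m)
    j <- (hits[1] - 1L) %/% n + 1L
    i <- hits[1] - (j - 1L) * n
    if (length(hits) > 1L) {
      # deterministic tie-break: lexicographically lowest (i, j), i < j
      jj <- (hits - 1L) %/% n + 1L
      ii <- hits - (jj - 1L) * n
      lo <- pmin(ii, jj); hi <- pmax(ii, jj)
      o <- order(lo, hi)
      i <- lo[o[1]]; j <- hi[o[1]]
    } else if (i > j) {
      tmp <- i; i <- j; j <- tmp
    }
    height[step] <- sqrt(m)
    pair <- sort(c(cid[i], cid[j]))
    merge[step, ] <- if (pair[2] < 0) c(pair[2], pair[1]) else pair

    # Lance-Williams update (Ward) into slot i
    h <- which(active); h <- h[h != i & h != j]
    if (length(h)) {
      W[i, h] <- ((sizes[i] + sizes[h]) * W[i, h] +
                    (sizes[j] + sizes[h]) * W[j, h] -
                    sizes[h] * m) / (sizes[i] + sizes[j] + sizes[h])
      W[h, i] <- W[i, h]
    }
    W[i, i] <- Inf
    W[j, ] <- Inf
    W[, j] <- Inf
    active[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    cid[i] <- step
  }

  structure(list(merge = merge, height = height, labels = labels,
                 lcv_percent = NULL, alcv_angstrom = NULL,
                 completeness_nodes = NULL, completeness_leaves = NULL),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("Ward dendrogram: %d leaves, %d merge nodes, top height %.4g\n",
              length(x$labels), length(x$height), max(x$height)))
  if (!is.null(x$lcv_percent))
    cat(sprintf("  annotated with LCV (root %.2f%%)\n",
                x$lcv_percent[length(x$lcv_percent)]))
  if (!is.null(x$completeness_nodes))
    cat(sprintf("  annotated with completeness (root %.1f%%)\n",
                100 * x$completeness_nodes[length(x$completeness_nodes)]))
  invisible(x)
}

# list (length n-1) of leaf indices under each internal node
node_members <- function(d) {
  n1 <- length(d$height)
  out <- vector("list", n1)
  for (k in seq_len(n1)) {
    mem <- integer(0)
    for (child in d$merge[k, ])
      mem <- c(mem, if (child < 0) -child else out[[child]])
    out[[k]] <- mem
  }
  out
}

# leaf ordering for hclust conversion / plotting
leaf_order <- function(d) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(d$merge[node, 1]), rec(d$merge[node, 2]))
  }
  rec(length(d$height))
}

#' Convert a Ward dendrogram to a `stats::hclust` object
#' @param d A `ward_dendrogram`.
#' @return An `hclust` object (usable with [stats::cutree()], plotting,
#'   etc.).
#' @export
as_hclust <- function(d) {
  structure(list(merge = d$merge, height = d$height,
                 order = leaf_order(d), labels = d$labels,
                 method = "ward.D2", call = match.call(),
                 dist.method = NULL),
            class = "hclust")
}

#' Cut a dendrogram into flat clusters
#'
#' @param d A `ward_dendrogram`.
#' @param k Number of clusters, or
#' @param h Height to cut at (exactly one of `k`, `h`).
#' @return Named integer vector of cluster memberships (names are
#'   leaf labels).
#' @export
cut_dendrogram <- function(d, k = NULL, h = NULL) {
  stats::cutree(as_hclust(d), k = k, h = h)
}
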