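# longer parallelogram diagonal of the three independent cell faces:
# (b,c,alpha), (a,c,beta), (a,b,gamma); rows = cells, cols = faces
face_diagonals <- function(cells) {
  X <- do.call(rbind, lapply(cells, function(x) unclass(as_unit_cell(x))))
  dg <- function(x, y, th)
    sqrt(x^2 + y^2 + 2 * x * y * abs(cos(th * pi / 180)))
  cbind(dg(X[, 2], X[, 3], X[, 4]),
        dg(X[, 1], X[, 3], X[, 5]),
        dg(X[, 1], X[, 2], X[, 6]))
}

#' Linear cell variation of a group of cells
#'
#' LCV measures the maximum linear increase or decrease of the
#' diagonals on the three independent cell faces across a group of
#' cells, as a percentage of the smaller diagonal; values below 1%
#' generally indicate good isomorphism.  aLCV is the same maximum
#' spread in angstrom.  The convention used here takes the longer
#' parallelogram diagonal of each face.
#'
#' @param cells List of [unit_cell()] objects (length >= 1).
#' @return List with `lcv_percent` and `alcv_angstrom`.
#' @examples
#' lcv(list(unit_cell(10,10,10,90,90,90), unit_cell(10.1,10.1,10.1,90,90,90)))
#' @export
lcv <- function(cells) {
  Dg <- face_diagonals(cells)
  lo <- apply(Dg, 2, min); hi <- apply(Dg, 2, max)
  spread <- hi - lo
  pct <- 100 * spread / lo
  f <- which.max(pct)
  list(lcv_percent = pct[f], alcv_angstrom = spread[f])
}

#' Annotate a dendrogram with LCV / aLCV per node
#'
#' @param d A `ward_dendrogram`.
#' @param cells Named list of [unit_cell()] objects covering every
#'   leaf label.
#' @return The dendrogram with `lcv_percent` and `alcv_angstrom`
#'   vectors (one entry per internal node) filled in.
#' @export
annotate_lcv <- function(d, cells) {
  miss <- setdiff(d$labels, names(cells))
  if (length(miss))
    stop("no cell for leaf: ", paste(miss, collapse = ", "), call. = FALSE)
  Dg <- face_diagonals(cells[d$labels])
  n1 <- length(d$height)
  lo <- hi <- matrix(0, n1, 3)
  lcvp <- alcv <- numeric(n1)
  for (k in seq_len(n1)) {
    ch <- d$merge[k, ]
    lo1 <- if (ch[1] < 0) Dg[-ch[1], ] else lo[ch[1], ]
    hi1 <- if (ch[1] < 0) Dg[-ch[1], ] else hi[ch[1], ]
    lo2 <- if (ch[2] < 0) Dg[-ch[2], ] else lo[ch[2], ]
    hi2 <- if (ch[2] < 0) Dg[-ch[2], ] else hi[ch[2], ]
    lo[k, ] <- pmin(lo1, lo2); hi[k, ] <- pmax(hi1, hi2)
    spread <- hi[k, ] - lo[k, ]
    pct <- 100 * spread / lo[k, ]
    f <- which.max(pct)
    lcvp[k] <- pct[f]; alcv[k] <- spread[f]
  }
  d$lcv_percent <- lcvp
  d$alcv_angstrom <- alcv
  d
}

#' Annotate a dendrogram with completeness per node
#'
#' Completeness of an internal node is that of the union of its
#' members' observed symmetry-unique indices to `d_min`.  Numerator and
#' denominator are both evaluated against a single reference lattice
#' (by default the unweighted mean of all leaf cells) so that values
#' are comparable across the tree.
#'
#' @param d A `ward_dendrogram`.
#' @param sets Named list of [reflection_set()] objects covering every
#'   leaf label.
#' @param d_min Resolution limit in angstrom.
#' @param reference_cell Cell used for the ASU enumeration; default is
#'   the mean of the leaf cells.
#' @return The dendrogram with `completeness_nodes` (per internal
#'   node) and `completeness_leaves` (per leaf) filled in.
#' @export
annotate_completeness <- function(d, sets, d_min, reference_cell = NULL) {
  miss <- setdiff(d$labels, names(sets))
  if (length(miss))
    stop("no reflection set for leaf: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sets <- sets[d$labels]
  if (is.null(reference_cell)) {
    X <- do.call(rbind, lapply(sets, function(s) unclass(s$cell)))
    reference_cell <- as_unit_cell(colMeans(X))
  }
  group <- sets[[1]]$laue_group
  denom <- enumerate_asu_keys(reference_cell, group, d_min)
  nd <- length(denom)
  if (!nd) stop("no reflections in the ASU to d_min", call. = FALSE)
  leaf_keys <- lapply(sets, function(s)
    intersect(observed_asu_keys(s, d_min, cell = reference_cell), denom))
  n1 <- length(d$height)
  node_keys <- vector("list", n1)
  comp_nodes <- numeric(n1)
  for (k in seq_len(n1)) {
    ch <- d$merge[k, ]
    k1 <- if (ch[1] < 0) leaf_keys[[-ch[1]]] else node_keys[[ch[1]]]
    k2 <- if (ch[2] < 0) leaf_keys[[-ch[2]]] else node_keys[[ch[2]]]
    node_keys[[k]] <- unique(c(k1, k2))
    comp_nodes[k] <- length(node_keys[[k]]) / nd
  }
  d$completeness_nodes <- comp_nodes
  d$completeness_leaves <- vapply(leaf_keys, length, 0L) / nd
  d
}

#' Select non-overlapping clusters at a completeness threshold
#'
#' Returns the minimal (lowest) dendrogram nodes whose completeness
#' reaches `min_completeness`: a node is selected when it qualifies and
#' no node below it qualifies, so no selected node is an ancestor of
#' another and member sets are pairwise disjoint.  Leaves that already
#' meet the threshold are selected as singletons.  Leaves under no
#' qualifying node are reported as unassigned.
#'
#' @param d A completeness-annotated `ward_dendrogram`.
#' @param min_completeness Threshold in (0, 1\].
#' @return data.frame of class `cluster_selection` with columns
#'   `node_id` (positive = internal node index, negative = leaf index),
#'   `size` and `completeness`; attributes `members` (list of character
#'   vectors of dataset ids) and `unassigned` (character vector).
#' @export
select_nonoverlapping <- function(d, min_completeness) {
  if (is.null(d$completeness_nodes))
    stop("dendrogram is not annotated with completeness; run annotate_completeness first",
         call. = FALSE)
  n <- length(d$labels)
  n1 <- length(d$height)
  leaf_q <- d$completeness_leaves >= min_completeness
  node_q <- d$completeness_nodes >= min_completeness
  has_q_below <- logical(n1)   # any qualifying node/leaf strictly below k
  sel_nodes <- integer(0)
  sel_members <- list()
  sel_comp <- numeric(0)
  mem <- node_members(d)
  for (k in seq_len(n1)) {
    ch <- d$merge[k, ]
    below <- vapply(ch, function(c0)
      if (c0 < 0) leaf_q[-c0] else node_q[c0] || has_q_below[c0], NA)
    has_q_below[k] <- any(below)
    if (node_q[k] && !has_q_below[k]) {
      sel_nodes <- c(sel_nodes, k)
      sel_members <- c(sel_members, list(d$labels[mem[[k]]]))
      sel_comp <- c(sel_comp, d$completeness_nodes[k])
    }
  }
  for (i in which(leaf_q)) {
    sel_nodes <- c(sel_nodes, -i)
    sel_members <- c(sel_members, list(d$labels[i]))
    sel_comp <- c(sel_comp, d$completeness_leaves[i])
  }
  assigned <- unlist(sel_members)
  out <- data.frame(node_id = sel_nodes,
                    size = lengths(sel_members),
                    completeness = sel_comp)
  o <- order(-out$size, out$node_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- sel_members[o]
  attr(out, "unassigned") <- setdiff(d$labels, assigned)
  class(out) <- c("cluster_selection", "data.frame")
  out
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("%d non-overlapping clusters covering %d datasets (%d unassigned)\n",
              nrow(x), sum(x$size), length(attr(x, "unassigned"))))
  NextMethod()
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are parent height minus child height (leaves sit at
#' height zero).  If the dendrogram carries LCV annotations, internal
#' node labels show `LCV(aLCV)`.
#'
#' @param d A `ward_dendrogram`.
#' @return Single Newick string terminated by `;`.
#' @export
dendrogram_to_newick <- function(d) {
  n1 <- length(d$height)
  lab <- function(k) {
    if (is.null(d$lcv_percent)) return("")
    sprintf("%.2f(%.3f)", d$lcv_percent[k], d$alcv_angstrom[k])
  }
  build <- function(node, parent_h) {
    if (node < 0) {
      leafname <- gsub("[,;:()\\[\\] ]", "_", d$labels[-node])
      return(sprintf("%s:%.8g", leafname, parent_h))
    }
    h <- d$height[node]
    sprintf("(%s,%s)%s:%.8g",
            build(d$merge[node, 1], h), build(d$merge[node, 2], h),
            lab(node), parent_h - h)
  }
  root <- n1
  h <- d$height[root]
  paste0("(", build(d$merge[root, 1], h), ",",
         build(d$merge[root, 2], h), ")", lab(root), ";")
}

#' Serialize / restore a dendrogram as JSON
#'
#' The JSON form is lossless: `dendrogram_from_json()` returns an
#' identical object (including annotations).
#'
#' @param d A `ward_dendrogram`.
#' @return `dendrogram_to_json`: a JSON string.
#' @export
dendrogram_to_json <- function(d) {
  payload <- list(labels = d$labels,
                  merge1 = d$merge[, 1], merge2 = d$merge[, 2],
                  height = d$height,
                  lcv_percent = d$lcv_percent,
                  alcv_angstrom = d$alcv_angstrom,
                  completeness_nodes = d$completeness_nodes,
                  completeness_leaves = d$completeness_leaves)
  payload <- payload[!vapply(payload, is.null, NA)]
  jsonlite::toJSON(payload, digits = I(17), auto_unbox = FALSE)
}

#' @rdname dendrogram_to_json
#' @param txt JSON text produced by `dendrogram_to_json()`.
#' @return `dendrogram_from_json`: the restored `ward_dendrogram`.
#' @export
dendrogram_from_json <- function(txt) {
  p <- jsonlite::fromJSON(txt)
  structure(list(merge = cbind(as.integer(p$merge1), as.integer(p$merge2)),
                 height = as.numeric(p$height),
                 labels = as.character(p$labels),
                 lcv_percent = p$lcv_percent,
                 alcv_angstrom = p$alcv_angstrom,
                 completeness_nodes = p$completeness_nodes,
                 completeness_leaves = p$completeness_leaves),
            class = "ward_dendrogram")
}

#' Per-node cluster report of an annotated dendrogram
#'
#' @param d An annotated `ward_dendrogram`.
#' @return data.frame with one row per internal node: `node_id`,
#'   `size`, `completeness`, `lcv_percent`, `alcv_angstrom`,
#'   `members` (comma-joined dataset ids).  Writable as TSV.
#' @export
cluster_report <- function(d) {
  mem <- node_members(d)
  data.frame(node_id = seq_along(d$height),
             size = lengths(mem),
             height = d$height,
             completeness = if (is.null(d$completeness_nodes)) NA_real_
                            else d$completeness_nodes,
             lcv_percent = if (is.null(d$lcv_percent)) NA_real_
                           else d$lcv_percent,
             alcv_angstrom = if (is.null(d$alcv_angstrom)) NA_real_
                             else d$alcv_angstrom,
             members = vapply(mem, function(m)
               paste(d$labels[m], collapse = ","), ""))
}
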