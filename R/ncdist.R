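#' Niggli-cone boundary transform set
#'
#' The lattice distance in G6 is computed as a minimum over a set of
#' symmetry operators that map a Niggli-reduced cell onto equivalent
#' representations across reduced-cone boundaries: the 24 signed
#' permutations combining the 6 axis permutations (acting identically
#' on (g1,g2,g3) and (g4,g5,g6)) with the 4 even sign-flip patterns of
#' (g4,g5,g6) that arise from negating one basis vector.  The identity
#' is always a member.
#'
#' @return A list of 24 orthogonal 6x6 matrices acting on G6 vectors.
#' @export
g6_transform_set <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  out <- vector("list", 24L)
  k <- 0L
  for (p in perms) {
    P <- matrix(0, 6, 6)
    P[cbind(1:3, p)] <- 1
    P[cbind(4:6, p + 3L)] <- 1
    for (s in signs) {
      k <- k + 1L
      Ts <- P
      Ts[4, ] <- Ts[4, ] * s[1]
      Ts[5, ] <- Ts[5, ] * s[2]
      Ts[6, ] <- Ts[6, ] * s[3]
      out[[k]] <- Ts
    }
  }
  out
}

#' Niggli-cone distance between two lattices
#'
#' Both inputs are Niggli-reduced, then the distance is the minimum
#' Euclidean G6 distance over the configured boundary transform set
#' applied to either reduced vector.  This heals the discontinuities
#' that plain Euclidean distance on cell parameters suffers near
#' reduction boundaries (e.g. between type I and type II cells and for
#' near-cubic lattices).  The value is an upper bound on the exact
#' Niggli-cone geodesic; the identity transform guarantees it never
#' exceeds the plain Euclidean distance between the reduced vectors.
#'
#' @param g_a,g_b Cells or `g6` vectors.
#' @param transforms Transform set; defaults to [g6_transform_set()].
#' @param tol Reduction tolerance passed to [niggli_reduce()].
#' @return Distance in A^2 (non-negative, symmetric, zero iff the two
#'   inputs describe the same lattice).
#' @examples
#' ncdist(unit_cell(10, 10, 10, 90, 90, 90),
#'        unit_cell(10.1, 10.1, 10.1, 90, 90, 90))
#' @export
ncdist <- function(g_a, g_b, transforms = g6_transform_set(), tol = 1e-5) {
  ra <- unclass(niggli_reduce(as_g6(g_a), tol = tol)$reduced)
  rb <- unclass(niggli_reduce(as_g6(g_b), tol = tol)$reduced)
  best <- Inf
  for (Ts in transforms) {
    d <- sqrt(sum((ra - drop(Ts %*% rb))^2))
    if (d < best) best <- d
  }
  best
}

reduced_g6_rows <- function(cells, tol = 1e-5) {
  n <- length(cells)
  R <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    r <- tryCatch(niggli_reduce(as_g6(cells[[i]]), tol = tol),
                  serialmerge_reduction_failure = function(e) {
                    id <- names(cells)[i]
                    stop(sprintf("reduction failed for dataset %s: %s",
                                 if (is.null(id)) as.character(i) else id,
                                 conditionMessage(e)), call. = FALSE)
                  })
    R[i, ] <- unclass(r$reduced)
  }
  R
}

#' Pairwise Niggli-cone distance matrix
#'
#' @param cells List of [unit_cell()] objects (optionally named with
#'   dataset ids, used as dimnames).
#' @param transforms Transform set; defaults to [g6_transform_set()].
#' @param tol Reduction tolerance.
#' @return Symmetric matrix of distances in A^2 with zero diagonal.
#' @export
ncdist_matrix <- function(cells, transforms = g6_transform_set(), tol = 1e-5) {
  if (length(cells) < 2L)
    stop("need at least 2 cells", call. = FALSE)
  R <- reduced_g6_rows(cells, tol = tol)
  n <- nrow(R)
  na <- rowSums(R^2)
  D2 <- matrix(Inf, n, n)
  for (Ts in transforms) {
    Rt <- R %*% t(Ts)
    cross <- outer(na, rowSums(Rt^2), "+") - 2 * (R %*% t(Rt))
    D2 <- pmin(D2, cross)
  }
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D <- (D + t(D)) / 2  # symmetrize (min over T applied to either side)
  D <- pmin(D, t(D))
  diag(D) <- 0
  dimnames(D) <- list(names(cells), names(cells))
  D
}

#' Classic PCA/Euclidean cell distance matrix
#'
#' The original cell-based distance: treat each cell as the six-value
#' vector (a, b, c, alpha, beta, gamma), centre, run a principal
#' component analysis, drop components carrying less than
#' `variance_cutoff` of the variance, and return pairwise Euclidean
#' distances in the retained subspace.
#'
#' @param cells List of [unit_cell()] objects.
#' @param variance_cutoff Minimum explained-variance fraction for a
#'   component to be retained (default 0.01).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
blend_cell_distance_matrix <- function(cells, variance_cutoff = 0.01) {
  if (length(cells) < 2L)
    stop("need at least 2 cells", call. = FALSE)
  X <- do.call(rbind, lapply(cells, function(x) unclass(as_unit_cell(x))))
  tot_var <- sum(apply(X, 2, stats::var))
  n <- nrow(X)
  if (!is.finite(tot_var) || tot_var <= .Machine$double.eps) {
    D <- matrix(0, n, n)
    dimnames(D) <- list(names(cells), names(cells))
    return(D)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(frac >= variance_cutoff)
  if (!length(keep)) keep <- 1L
  S <- pc$x[, keep, drop = FALSE]
  D <- as.matrix(stats::dist(S))
  dimnames(D) <- list(names(cells), names(cells))
  D
}

#' Write a labelled distance matrix as TSV
#' @param D Symmetric matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(dataset_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
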