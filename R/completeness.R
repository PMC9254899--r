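#' Resolution (d-spacing) of reflection indices
#'
#' @param H n x 3 integer matrix of indices.
#' @param cell A [unit_cell()].
#' @return Numeric vector of d-spacings in angstrom, computed from the
#'   reciprocal metric of the cell.
#' @export
d_spacing <- function(H, cell) {
  H <- matrix(as.numeric(H), ncol = 3)
  Gstar <- solve(cell_metric(as_unit_cell(cell)))
  invd2 <- rowSums((H %*% Gstar) * H)
  1 / sqrt(invd2)
}

# All symmetry-unique (ASU) indices with d >= d_min for a given cell,
# as canonical integer keys.  The (0,0,0) index is excluded; Friedel
# inversion is part of every Laue group, so the enumeration is a
# half-sphere in effect.
enumerate_asu_keys <- function(cell, group, d_min) {
  cell <- as_unit_cell(cell)
  group <- as_laue_group(group)
  if (!is.finite(d_min) || d_min <= 0)
    stop("d_min must be positive", call. = FALSE)
  hmax <- floor(unclass(cell)[1:3] / d_min)
  rng <- lapply(hmax, function(m) seq.int(-m, m))
  H <- as.matrix(expand.grid(h = rng[[1]], k = rng[[2]], l = rng[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  keep <- !(H[, 1] == 0 & H[, 2] == 0 & H[, 3] == 0)
  H <- H[keep, , drop = FALSE]
  Gstar <- solve(cell_metric(cell))
  invd2 <- rowSums((H %*% Gstar) * H)
  H <- H[invd2 <= 1 / d_min^2 + 1e-12, , drop = FALSE]
  sort(unique(hkl_keys(asu_map_matrix(H, group))))
}

#' Enumerate the symmetry-unique reflections to a resolution limit
#'
#' @param cell A [unit_cell()].
#' @param group A [laue_group()] or symbol.
#' @param d_min Resolution limit in angstrom.
#' @return Integer matrix of canonical ASU indices (one row per
#'   symmetry-equivalence class) with d >= d_min.
#' @export
enumerate_asu <- function(cell, group, d_min) {
  keys_to_hkl(enumerate_asu_keys(cell, group, d_min))
}

# Unique observed ASU keys of a set, restricted to d >= d_min under
# the supplied cell (defaults to the set's own cell).
observed_asu_keys <- function(set, d_min, cell = set$cell) {
  obs <- set$observations
  if (!nrow(obs)) return(numeric(0))
  H <- as.matrix(obs[c("h", "k", "l")])
  d <- d_spacing(H, cell)
  H <- H[d >= d_min - 1e-9, , drop = FALSE]
  if (!nrow(H)) return(numeric(0))
  sort(unique(hkl_keys(asu_map_matrix(H, set$laue_group))))
}

#' Completeness of a reflection set
#'
#' Fraction of symmetry-unique reflections to the resolution limit that
#' the set has observed: distinct ASU-mapped indices present with
#' d >= d_min, divided by the full ASU enumeration from the set's own
#' cell (excluding (0,0,0)).
#'
#' @param set A [reflection_set()].
#' @param d_min Resolution limit in angstrom (> 0).
#' @return Fraction in \[0, 1\].
#' @export
completeness <- function(set, d_min) {
  if (!is.finite(d_min) || d_min <= 0)
    stop("d_min must be positive", call. = FALSE)
  denom <- enumerate_asu_keys(set$cell, set$laue_group, d_min)
  if (!length(denom)) return(0)
  num <- observed_asu_keys(set, d_min)
  length(intersect(num, denom)) / length(denom)
}
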