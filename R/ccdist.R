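cc_condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

intensity_vector <- function(tab, quantity) {
  if (quantity == "amplitude") sqrt(pmax(tab$intensity, 0))
  else tab$intensity
}

#' Pearson correlation between two merged reflection sets
#'
#' The correlation coefficient is the cosine of the angle between the
#' two intensity vectors over the common symmetry-unique indices after
#' subtracting each vector's mean and dividing by its norm; it is
#' therefore invariant to the (unknown) relative scale and offset of
#' the two datasets.
#'
#' @param a,b Merged [reflection_set()] objects with the same Laue
#'   group.
#' @param quantity `"intensity"` (default) or `"amplitude"` (compares
#'   sqrt(max(I, 0))).
#' @return List of class `cc_result`: `cc` in \[-1, 1\], `n_common`
#'   (count of common unique indices) and `f_unmatched` (fraction of
#'   the union of indices not in common).
#' @export
pearson_cc <- function(a, b, quantity = c("intensity", "amplitude")) {
  quantity <- match.arg(quantity)
  for (s in list(a, b))
    if (!s$merged)
      stop("pearson_cc expects merged sets; merge first", call. = FALSE)
  ta <- asu_table(a); tb <- asu_table(b)
  m <- match(ta$key, tb$key)
  ok <- !is.na(m)
  n_common <- sum(ok)
  n_union <- nrow(ta) + nrow(tb) - n_common
  if (n_common < 3L)
    stop(cc_condition("serialmerge_insufficient_overlap",
                      sprintf("only %d common unique indices (need >= 3)",
                              n_common)))
  x <- intensity_vector(ta[ok, ], quantity)
  y <- intensity_vector(tb[m[ok], ], quantity)
  x <- x - mean(x); y <- y - mean(y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop(cc_condition("serialmerge_undefined_cc",
                      "zero variance in common intensities"))
  cc <- sum(x * y) / (nx * ny)
  cc <- max(-1, min(1, cc))
  structure(list(cc = cc, n_common = n_common,
                 f_unmatched = 1 - n_common / n_union),
            class = "cc_result")
}

sfdist_from_cc <- function(cc, f_unmatched, penalty_weight, activation,
                           base) {
  d0 <- switch(base,
               chord = sqrt(2 * (1 - cc)),
               sine = sqrt(1 - cc^2),
               stop("unknown sfdist base form", call. = FALSE))
  if ((1 - f_unmatched) < activation)
    d0 <- d0 + penalty_weight * f_unmatched
  d0
}

#' Correlation-based distance between merged reflection sets (SFDist)
#'
#' Converts the Pearson correlation over common unique reflections to
#' a distance.  The default base form is the chord length between the
#' two mean-centred unit vectors whose angle-cosine is CC,
#' sqrt(2 (1 - CC)): zero at CC = 1, strictly decreasing in CC.  When
#' the common fraction of the index union falls below `activation`,
#' a penalty proportional to the unmatched fraction is added, so pairs
#' with little overlap are kept apart even if their few common
#' reflections happen to correlate.
#'
#' @inheritParams pearson_cc
#' @param penalty_weight Weight of the unmatched-reflection penalty
#'   (default 1).
#' @param activation Common-fraction threshold below which the penalty
#'   applies (default 0.90).
#' @param base `"chord"` (default) or `"sine"` (sqrt(1 - CC^2)).
#' @return Non-negative distance (symmetric in its arguments).
#' @export
sfdist <- function(a, b, penalty_weight = 1, activation = 0.90,
                   base = c("chord", "sine"),
                   quantity = c("intensity", "amplitude")) {
  base <- match.arg(base)
  r <- pearson_cc(a, b, quantity = match.arg(quantity))
  sfdist_from_cc(r$cc, r$f_unmatched, penalty_weight, activation, base)
}

#' Pairwise SFDist matrix
#'
#' Computes all pairwise correlation distances between merged sets.
#' Pairs with fewer than 3 common unique indices (or zero variance in
#' the common intensities) receive the `sentinel` distance and are
#' reported in the `failed_pairs` attribute.
#'
#' Internally uses a sufficient-statistics formulation (dense
#' set-by-reflection matrices) so the cost is a handful of matrix
#' products rather than one R call per pair.
#'
#' @param sets List of merged [reflection_set()] objects.
#' @inheritParams sfdist
#' @param sentinel Distance assigned to failing pairs (default 10).
#' @return Symmetric matrix with zero diagonal; attribute
#'   `failed_pairs` is a two-column matrix of indices that received the
#'   sentinel.
#' @export
sfdist_matrix <- function(sets, penalty_weight = 1, activation = 0.90,
                          base = c("chord", "sine"),
                          quantity = c("intensity", "amplitude"),
                          sentinel = 10) {
  base <- match.arg(base)
  quantity <- match.arg(quantity)
  if (length(sets) < 2L)
    stop("need at least 2 merged sets", call. = FALSE)
  for (s in sets)
    if (!s$merged)
      stop("sfdist_matrix expects merged sets", call. = FALSE)
  n <- length(sets)
  tabs <- lapply(sets, asu_table)
  all_keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  p <- length(all_keys)
  X <- matrix(0, n, p)  # intensities (0 where absent)
  Z <- matrix(0, n, p)  # presence indicators
  for (i in seq_len(n)) {
    idx <- match(tabs[[i]]$key, all_keys)
    Z[i, idx] <- 1
    X[i, idx] <- intensity_vector(tabs[[i]], quantity)
  }
  N  <- Z %*% t(Z)                  # common counts
  Sx <- X %*% t(Z)                  # sum of own intensities over common
  Sxx <- (X * X) %*% t(Z)
  Sxy <- X %*% t(X)
  counts <- rowSums(Z)
  union <- outer(counts, counts, "+") - N
  Nsafe <- pmax(N, 1)
  cov <- Sxy - Sx * t(Sx) / Nsafe
  vx <- Sxx - Sx^2 / Nsafe
  vy <- t(vx)
  denom <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  ok <- N >= 3 & denom > 0
  cc <- matrix(NA_real_, n, n)
  cc[ok] <- pmax(-1, pmin(1, cov[ok] / denom[ok]))
  f_un <- 1 - N / pmax(union, 1)
  D <- matrix(sentinel, n, n)
  d0 <- switch(base, chord = sqrt(pmax(2 * (1 - cc), 0)),
               sine = sqrt(pmax(1 - cc^2, 0)))
  pen <- ifelse((1 - f_un) < activation, penalty_weight * f_un, 0)
  D[ok] <- d0[ok] + pen[ok]
  diag(D) <- 0
  D <- (D + t(D)) / 2
  ids <- vapply(sets, function(s) s$dataset_id, "")
  dimnames(D) <- list(ids, ids)
  fp <- which(!ok & upper.tri(ok), arr.ind = TRUE)
  attr(D, "failed_pairs") <- fp
  D
}
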