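#' Laue group symmetry
#'
#' A Laue group is represented by its full set of 3x3 integer operator
#' matrices acting on reflection indices (h, k, l), closed under
#' composition and always containing the Friedel inversion -I.  It
#' defines which reflections are symmetry-equivalent, and therefore
#' what "common hkl indices" and completeness mean.
#'
#' Built-in symbols: `"-1"`, `"2/m"` (b-unique), `"mmm"`, `"4/m"`,
#' `"4/mmm"`.
#'
#' @param symbol One of the built-in symbols above.
#' @return Object of class `laue_group`: list with `symbol` and `ops`
#'   (list of 3x3 integer matrices).
#' @examples
#' length(laue_group("4/mmm")$ops)  # 16
#' @export
laue_group <- function(symbol) {
  gens <- switch(symbol,
    "-1"    = list(),
    "2/m"   = list(diag(c(-1, 1, -1))),
    "mmm"   = list(diag(c(-1, 1, -1)), diag(c(1, -1, -1))),
    "4/m"   = list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)),
    "4/mmm" = list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
                   diag(c(1, -1, -1))),
    stop(sprintf("unknown Laue group symbol '%s'", symbol), call. = FALSE))
  laue_group_from_ops(c(gens, list(-diag(3))), symbol = symbol)
}

#' Build a Laue group from operator matrices
#'
#' Computes the group closure of the supplied generators, adds the
#' Friedel inversion, and validates the result.
#'
#' @param ops List of 3x3 integer matrices (generators suffice).
#' @param symbol Label to attach.
#' @return A `laue_group`.
#' @export
laue_group_from_ops <- function(ops, symbol = "custom") {
  ops <- c(list(diag(3)), lapply(ops, function(m) {
    m <- round(as.matrix(m))
    if (!all(dim(m) == c(3, 3)) || abs(det(m)) != 1)
      stop("Laue operators must be 3x3 integer matrices with det +/-1",
           call. = FALSE)
    m
  }), list(-diag(3)))
  key <- function(m) paste(as.integer(m), collapse = ",")
  seen <- new.env(parent = emptyenv())
  queue <- ops
  members <- list()
  while (length(queue)) {
    m <- queue[[1]]
    queue <- queue[-1]
    k <- key(m)
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    members[[length(members) + 1L]] <- m
    for (g in ops) queue[[length(queue) + 1L]] <- m %*% g
    if (length(members) > 96L)
      stop("operator closure exceeds 96 elements; not a Laue group",
           call. = FALSE)
  }
  # full closure over the member set (generators may not be the whole set)
  repeat {
    added <- FALSE
    for (m1 in members) for (m2 in members) {
      k <- key(m1 %*% m2)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        members[[length(members) + 1L]] <- m1 %*% m2
        added <- TRUE
      }
    }
    if (!added) break
  }
  structure(list(symbol = symbol, ops = members), class = "laue_group")
}

#' Read Laue operators from a text file
#'
#' Format: one 3x3 integer matrix per block (three whitespace-separated
#' rows), blocks separated by blank lines.  The closure and Friedel
#' inversion are added automatically.
#'
#' @param path File path.
#' @param symbol Label for the resulting group.
#' @return A `laue_group`.
#' @export
laue_group_from_file <- function(path, symbol = basename(path)) {
  lines <- trimws(readLines(path))
  rows <- lapply(lines[nzchar(lines)], function(x)
    as.integer(strsplit(x, "\\s+")[[1]]))
  if (length(rows) %% 3L != 0L || any(lengths(rows) != 3L))
    stop("operator file must contain 3x3 integer matrices", call. = FALSE)
  ops <- lapply(seq_len(length(rows) / 3L), function(i)
    do.call(rbind, rows[(3 * i - 2):(3 * i)]))
  laue_group_from_ops(ops, symbol = symbol)
}

#' @export
print.laue_group <- function(x, ...) {
  cat(sprintf("Laue group %s (%d operators)\n", x$symbol, length(x$ops)))
  invisible(x)
}

as_laue_group <- function(x) {
  if (inherits(x, "laue_group")) return(x)
  laue_group(as.character(x))
}

# Canonical (ASU) image of each index row: the lexicographically
# greatest image of (h,k,l) under the group.  H is an n x 3 matrix.
asu_map_matrix <- function(H, group) {
  H <- matrix(as.numeric(H), ncol = 3)
  n <- nrow(H)
  if (!n) return(H)
  best <- H %*% t(group$ops[[1]])
  for (op in group$ops[-1]) {
    cand <- H %*% t(op)
    better <- (cand[, 1] > best[, 1]) |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] &
         cand[, 3] > best[, 3])
    if (any(better)) best[better, ] <- cand[better, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

#' Map reflection indices to their canonical ASU representative
#'
#' All symmetry-equivalent indices map to the same canonical index:
#' the lexicographically greatest image under the group operators.
#' Idempotent.
#'
#' @param h,k,l Integer vectors of Miller indices (recycled together).
#' @param group A [laue_group()].
#' @return Integer matrix with columns h, k, l of canonical indices.
#' @examples
#' map_to_asu(-1, -2, -3, laue_group("-1"))  # (1, 2, 3)
#' @export
map_to_asu <- function(h, k, l, group) {
  group <- as_laue_group(group)
  H <- cbind(h = as.integer(h), k = as.integer(k), l = as.integer(l))
  if (any(rowSums(H == 0L) == 3L))
    stop("(0,0,0) is not a valid reflection index", call. = FALSE)
  asu_map_matrix(H, group)
}

# Encode index rows as single integer keys (lexicographic-order
# preserving for fixed offset).  Used for fast set operations.
hkl_keys <- function(H, span = 512L) {
  H <- matrix(as.numeric(H), ncol = 3)
  if (any(abs(H) >= span))
    stop("reflection index exceeds supported range", call. = FALSE)
  b <- 2 * span + 1
  (H[, 1] + span) * b * b + (H[, 2] + span) * b + (H[, 3] + span)
}

keys_to_hkl <- function(keys, span = 512L) {
  b <- 2 * span + 1
  h <- keys %/% (b * b)
  rem <- keys %% (b * b)
  k <- rem %/% b
  l <- rem %% b
  cbind(h = as.integer(h - span), k = as.integer(k - span),
        l = as.integer(l - span))
}
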