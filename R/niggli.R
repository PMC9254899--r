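#' Niggli-reduce a G6 vector
#'
#' Canonicalizes a lattice basis to the Niggli reduced cell by the
#' classic Krivy-Gruber stepwise algorithm, operating on the G6
#' components (A, B, C, xi, eta, zeta) = (a^2, b^2, c^2, 2bc cos alpha,
#' 2ac cos beta, 2ab cos gamma).  Boundary comparisons use a relative
#' tolerance so that near-degenerate cells (type I vs type II, near
#' cubic) reduce stably.
#'
#' @param g A `g6` vector, [unit_cell()], or numeric of length 6.
#' @param tol Relative tolerance for boundary comparisons.
#' @param max_steps Step budget; exceeding it raises a
#'   `serialmerge_reduction_failure` error carrying the partial result.
#' @return A list of class `niggli_reduction` with elements
#'   `reduced` (the reduced `g6`), `transform` (3x3 integer matrix with
#'   det +/-1 mapping the input basis to the reduced basis, i.e.
#'   `M %*% G %*% t(M)` is the reduced metric), and `converged`.
#' @examples
#' niggli_reduce(unit_cell(5, 3, 4, 90, 90, 90))$reduced
#' @export
niggli_reduce <- function(g, tol = 1e-5, max_steps = 1000L) {
  g0 <- as_g6(g)
  G <- metric_from_g6(g0)
  M <- diag(3)
  eps <- tol * prod(diag(G))^(1 / 3)

  vals <- function(G) {
    list(A = G[1, 1], B = G[2, 2], C = G[3, 3],
         xi = 2 * G[2, 3], eta = 2 * G[1, 3], zeta = 2 * G[1, 2])
  }
  apply_E <- function(E) {
    M <<- E %*% M
    G <<- E %*% G %*% t(E)
  }

  steps <- 0L
  repeat {
    if (steps >= max_steps) {
      res <- structure(list(reduced = g6_from_metric(G),
                            transform = round(M), converged = FALSE),
                       class = "niggli_reduction")
      cond <- structure(
        class = c("serialmerge_reduction_failure", "error", "condition"),
        list(message = sprintf("Niggli reduction did not converge in %d steps",
                               max_steps),
             call = sys.call(-1), partial = res))
      stop(cond)
    }
    steps <- steps + 1L
    v <- vals(G)

    # step 1: order A <= B (tie broken on |xi| <= |eta|)
    if (v$A > v$B + eps ||
        (abs(v$A - v$B) <= eps && abs(v$xi) > abs(v$eta) + eps)) {
      apply_E(matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE))
      next
    }
    # step 2: order B <= C (tie broken on |eta| <= |zeta|)
    if (v$B > v$C + eps ||
        (abs(v$B - v$C) <= eps && abs(v$eta) > abs(v$zeta) + eps)) {
      apply_E(matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3, byrow = TRUE))
      next
    }
    sgn <- function(x) if (x > eps) 1L else if (x < -eps) -1L else 0L
    sx <- sgn(v$xi); se <- sgn(v$eta); sz <- sgn(v$zeta)
    if (sx * se * sz > 0) {
      # step 3: make all three angles acute (all components positive)
      r <- c(if (sx < 0) -1 else 1, if (se < 0) -1 else 1,
             if (sz < 0) -1 else 1)
      if (any(r < 0)) {
        apply_E(diag(c(1, r[3], r[2])))
        next
      }
    } else {
      # step 4: make all three angles obtuse (all components <= 0)
      r <- c(1, 1, 1); zslot <- 0L
      if (sx > 0) r[1] <- -1 else if (sx == 0L) zslot <- 1L
      if (se > 0) r[2] <- -1 else if (se == 0L) zslot <- 2L
      if (sz > 0) r[3] <- -1 else if (sz == 0L) zslot <- 3L
      if (prod(r) < 0) {
        if (zslot == 0L)
          stop("Niggli reduction: inconsistent sign state", call. = FALSE)
        r[zslot] <- -r[zslot]
      }
      if (any(r < 0)) {
        apply_E(diag(c(1, r[3], r[2])))
        next
      }
    }
    v <- vals(G)
    # step 5: reduce |xi| against B
    if (abs(v$xi) > v$B + eps ||
        (abs(v$xi - v$B) <= eps && 2 * v$eta < v$zeta - eps) ||
        (abs(v$xi + v$B) <= eps && v$zeta < -eps)) {
      s <- if (v$xi > 0) 1 else -1
      apply_E(matrix(c(1, 0, 0, 0, 1, 0, 0, -s, 1), 3, 3, byrow = TRUE))
      next
    }
    # step 6: reduce |eta| against A
    if (abs(v$eta) > v$A + eps ||
        (abs(v$eta - v$A) <= eps && 2 * v$xi < v$zeta - eps) ||
        (abs(v$eta + v$A) <= eps && v$zeta < -eps)) {
      s <- if (v$eta > 0) 1 else -1
      apply_E(matrix(c(1, 0, 0, 0, 1, 0, -s, 0, 1), 3, 3, byrow = TRUE))
      next
    }
    # step 7: reduce |zeta| against A
    if (abs(v$zeta) > v$A + eps ||
        (abs(v$zeta - v$A) <= eps && 2 * v$xi < v$eta - eps) ||
        (abs(v$zeta + v$A) <= eps && v$eta < -eps)) {
      s <- if (v$zeta > 0) 1 else -1
      apply_E(matrix(c(1, 0, 0, -s, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
      next
    }
    # step 8: body-diagonal condition
    tot <- v$xi + v$eta + v$zeta + v$A + v$B
    if (tot < -eps ||
        (abs(tot) <= eps && 2 * (v$A + v$eta) + v$zeta > eps)) {
      apply_E(matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3, 3, byrow = TRUE))
      next
    }
    break
  }

  structure(list(reduced = g6_from_metric(G), transform = round(M),
                 converged = TRUE),
            class = "niggli_reduction")
}

#' @export
print.niggli_reduction <- function(x, ...) {
  cat("Niggli reduction", if (x$converged) "(converged)" else "(PARTIAL)", "\n")
  print(x$reduced)
  invisible(x)
}
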