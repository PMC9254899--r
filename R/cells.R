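#' Construct a unit cell
#'
#' A unit cell is the atom of cell-based clustering: six numbers
#' (a, b, c in angstrom; alpha, beta, gamma in degrees) describing one
#' dataset's crystal lattice.
#'
#' @param a,b,c Cell edge lengths in angstrom (positive).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named numeric vector of
#'   length six.
#' @examples
#' unit_cell(79, 79, 38, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha, beta, gamma) {
  cell <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            gamma = as.numeric(gamma))
  class(cell) <- "unit_cell"
  validate_cell(cell)
  cell
}

validate_cell <- function(cell) {
  if (length(cell) != 6L || anyNA(cell))
    stop("invalid cell: expected six finite numbers", call. = FALSE)
  if (any(cell[1:3] <= 0))
    stop("invalid cell: edge lengths must be positive", call. = FALSE)
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees", call. = FALSE)
  if (cell_volume(cell) <= 0 || !is.finite(cell_volume(cell)))
    stop("invalid cell: metric tensor is not positive-definite",
         call. = FALSE)
  invisible(cell)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- as.numeric(x)
  unit_cell(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

#' Direct-space metric tensor of a cell
#'
#' @param cell A [unit_cell()].
#' @return 3x3 symmetric matrix G with G\[i,j\] the dot product of basis
#'   vectors i and j.
#' @export
cell_metric <- function(cell) {
  cell <- unclass(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

#' Cell volume in cubic angstrom
#' @param cell A [unit_cell()].
#' @return Volume in A^3.
#' @export
cell_volume <- function(cell) {
  cell <- unclass(cell)
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(NA_real_)
  unname(prod(cell[1:3]) * sqrt(arg))
}

#' Map a unit cell to its G6 vector
#'
#' The G6 embedding is the six-dimensional metric-tensor representation
#' \[a^2, b^2, c^2, 2bc cos(alpha), 2ac cos(beta), 2ab cos(gamma)\]
#' (all components in A^2) in which Niggli reduction and the
#' Niggli-cone lattice distance operate.
#'
#' @param cell A [unit_cell()].
#' @return Object of class `g6`: numeric vector g1..g6.
#' @examples
#' cell_to_g6(unit_cell(10, 10, 10, 90, 90, 90))
#' @export
cell_to_g6 <- function(cell) {
  cell <- as_unit_cell(cell)
  G <- cell_metric(cell)
  g6_from_metric(G)
}

g6_from_metric <- function(G) {
  g <- c(G[1, 1], G[2, 2], G[3, 3], 2 * G[2, 3], 2 * G[1, 3], 2 * G[1, 2])
  class(g) <- "g6"
  g
}

metric_from_g6 <- function(g) {
  g <- unclass(g)
  matrix(c(g[1],     g[6] / 2, g[5] / 2,
           g[6] / 2, g[2],     g[4] / 2,
           g[5] / 2, g[4] / 2, g[3]), 3, 3)
}

validate_g6 <- function(g) {
  g <- unclass(g)
  if (length(g) != 6L || anyNA(g) || any(!is.finite(g)))
    stop("invalid metric: expected six finite numbers", call. = FALSE)
  if (any(g[1:3] <= 0))
    stop("invalid metric: g1, g2, g3 must be positive", call. = FALSE)
  if (abs(g[4]) >= 2 * sqrt(g[2] * g[3]) ||
      abs(g[5]) >= 2 * sqrt(g[1] * g[3]) ||
      abs(g[6]) >= 2 * sqrt(g[1] * g[2]) ||
      det(metric_from_g6(g)) <= 0)
    stop("invalid metric: not positive-definite", call. = FALSE)
  invisible(g)
}

as_g6 <- function(x) {
  if (inherits(x, "g6")) return(x)
  if (inherits(x, "unit_cell")) return(cell_to_g6(x))
  x <- as.numeric(x)
  validate_g6(x)
  class(x) <- "g6"
  x
}

#' @export
print.g6 <- function(x, ...) {
  cat("G6:", paste(sprintf("%.4f", unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Map a G6 vector back to a unit cell
#'
#' Inverse of [cell_to_g6()].
#'
#' @param g A `g6` vector (or numeric of length 6).
#' @return A [unit_cell()].
#' @export
g6_to_cell <- function(g) {
  g <- unclass(g)
  validate_g6(g)
  a <- sqrt(g[1]); b <- sqrt(g[2]); cc <- sqrt(g[3])
  alpha <- acos(g[4] / (2 * b * cc)) * 180 / pi
  beta  <- acos(g[5] / (2 * a * cc)) * 180 / pi
  gamma <- acos(g[6] / (2 * a * b)) * 180 / pi
  unit_cell(a, b, cc, alpha, beta, gamma)
}

#' Read a table of per-dataset unit cells
#'
#' Expects a CSV with header
#' `dataset_id,a,b,c,alpha,beta,gamma,hkl_path` (angstrom / degrees).
#'
#' @param path CSV file path.
#' @return A data.frame with those columns; each row passes
#'   [unit_cell()] validation.
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "a", "b", "c", "alpha", "beta", "gamma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cells CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"hkl_path" %in% names(df)) df$hkl_path <- NA_character_
  df$dataset_id <- as.character(df$dataset_id)
  if (anyDuplicated(df$dataset_id))
    stop("cells CSV has duplicated dataset ids", call. = FALSE)
  for (i in seq_len(nrow(df)))
    unit_cell(df$a[i], df$b[i], df$c[i], df$alpha[i], df$beta[i], df$gamma[i])
  df[c(need, "hkl_path")]
}

#' Write a table of per-dataset unit cells
#' @param cells data.frame as returned by [read_cells_csv()].
#' @param path Output CSV path.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cells_from_df <- function(df) {
  cl <- lapply(seq_len(nrow(df)), function(i)
    unit_cell(df$a[i], df$b[i], df$c[i], df$alpha[i], df$beta[i], df$gamma[i]))
  names(cl) <- df$dataset_id
  cl
}
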