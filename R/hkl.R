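#' Construct a reflection set
#'
#' One dataset's (or one merged cluster's) indexed intensity
#' observations together with its unit cell and Laue-group context.
#'
#' @param dataset_id Character id.
#' @param cell A [unit_cell()].
#' @param laue_group A [laue_group()] or symbol.
#' @param observations data.frame with columns `h`, `k`, `l` (integer,
#'   never all zero), `intensity`, `sigma` (positive).
#' @param merged Logical; if `TRUE` every ASU-mapped index must appear
#'   at most once.
#' @return Object of class `reflection_set`.
#' @export
reflection_set <- function(dataset_id, cell, laue_group, observations,
                           merged = FALSE) {
  cell <- as_unit_cell(cell)
  laue_group <- as_laue_group(laue_group)
  obs <- as.data.frame(observations)
  need <- c("h", "k", "l", "intensity", "sigma")
  if (!all(need %in% names(obs)))
    stop("observations need columns h, k, l, intensity, sigma",
         call. = FALSE)
  obs <- obs[need]
  obs$h <- as.integer(obs$h); obs$k <- as.integer(obs$k)
  obs$l <- as.integer(obs$l)
  if (nrow(obs)) {
    if (any(obs$h == 0L & obs$k == 0L & obs$l == 0L))
      stop("reflection (0,0,0) is not allowed", call. = FALSE)
    if (any(!is.finite(obs$sigma)) || any(obs$sigma <= 0))
      stop("all sigmas must be positive", call. = FALSE)
    if (any(!is.finite(obs$intensity)))
      stop("all intensities must be finite", call. = FALSE)
  }
  x <- structure(list(dataset_id = as.character(dataset_id), cell = cell,
                      laue_group = laue_group, observations = obs,
                      merged = isTRUE(merged)),
                 class = "reflection_set")
  if (x$merged && nrow(obs)) {
    keys <- hkl_keys(asu_map_matrix(as.matrix(obs[c("h", "k", "l")]),
                                    laue_group))
    if (anyDuplicated(keys))
      stop("merged set contains duplicate symmetry-unique reflections",
           call. = FALSE)
  }
  x
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set '%s': %d observations, Laue %s%s\n",
              x$dataset_id, nrow(x$observations), x$laue_group$symbol,
              if (x$merged) ", merged" else ""))
  invisible(x)
}

# ASU-mapped unique keys + intensities for a merged set (row order by key)
asu_table <- function(set) {
  obs <- set$observations
  if (!nrow(obs))
    return(data.frame(key = numeric(0), intensity = numeric(0),
                      sigma = numeric(0)))
  keys <- hkl_keys(asu_map_matrix(as.matrix(obs[c("h", "k", "l")]),
                                  set$laue_group))
  o <- order(keys)
  data.frame(key = keys[o], intensity = obs$intensity[o],
             sigma = obs$sigma[o])
}

hkl4_format_line <- function(h, k, l, i, s) {
  fI <- sprintf("%8.2f", i)
  fS <- sprintf("%8.2f", s)
  fh <- sprintf("%4d", h); fk <- sprintf("%4d", k); fl <- sprintf("%4d", l)
  if (any(nchar(c(fh, fk, fl)) > 4L) || any(nchar(c(fI, fS)) > 8L))
    stop("value does not fit the HKL4 fixed-width format (3I4,2F8.2)",
         call. = FALSE)
  paste0(fh, fk, fl, fI, fS)
}

#' Read a SHELX HKL4 reflection file
#'
#' Fixed-width records (3I4,2F8.2): h, k, l, I, sigma(I).  The
#' all-zero index record terminates parsing and is not returned.
#'
#' @param path File path.
#' @param cell,laue_group Context attached to the returned set.
#' @param dataset_id Defaults to the file name without extension.
#' @param merged Mark the returned set as merged.
#' @return A [reflection_set()].
#' @export
read_hkl <- function(path, cell, laue_group, dataset_id = NULL,
                     merged = FALSE) {
  if (!file.exists(path))
    stop(sprintf("HKL file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (!length(lines))
    stop(sprintf("HKL file is empty: %s", path), call. = FALSE)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  n <- length(lines)
  h <- k <- l <- I <- S <- numeric(n)
  nrec <- 0L
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 28L)
      ln <- formatC(ln, width = -28)
    fields <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
                substr(ln, 13, 20), substr(ln, 21, 28))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("malformed HKL4 record at line %d of %s", i, path),
           call. = FALSE)
    if (all(vals[1:3] == 0)) break
    nrec <- nrec + 1L
    h[nrec] <- vals[1]; k[nrec] <- vals[2]; l[nrec] <- vals[3]
    I[nrec] <- vals[4]; S[nrec] <- vals[5]
  }
  idx <- seq_len(nrec)
  reflection_set(dataset_id, cell, laue_group,
                 data.frame(h = h[idx], k = k[idx], l = l[idx],
                            intensity = I[idx], sigma = S[idx]),
                 merged = merged)
}

#' Write a reflection set as SHELX HKL4
#'
#' Appends the conventional all-zero terminator record.  Values that do
#' not fit the fixed-width columns raise an overflow error.
#'
#' @param set A [reflection_set()].
#' @param path Output path.
#' @export
write_hkl <- function(set, path) {
  obs <- set$observations
  lines <- character(nrow(obs) + 1L)
  for (i in seq_len(nrow(obs)))
    lines[i] <- hkl4_format_line(obs$h[i], obs$k[i], obs$l[i],
                                 obs$intensity[i], obs$sigma[i])
  lines[length(lines)] <- hkl4_format_line(0L, 0L, 0L, 0, 0)
  writeLines(lines, path)
  invisible(path)
}
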