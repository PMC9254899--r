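# Inverse-variance-weighted merge of an observation table (key,
# intensity, sigma) to one row per unique key.
ivw_merge <- function(tab) {
  if (!nrow(tab)) return(tab)
  w <- 1 / tab$sigma^2
  f <- factor(tab$key)
  sw <- rowsum(w, f)[, 1]
  swi <- rowsum(w * tab$intensity, f)[, 1]
  data.frame(key = as.numeric(levels(f)), intensity = swi / sw,
             sigma = 1 / sqrt(sw))
}

#' Merge reflection sets into one
#'
#' Pools all observations after mapping indices to the asymmetric unit
#' and combines repeated observations of the same unique index by the
#' inverse-variance-weighted mean with propagated sigma.  With
#' `scale_mode = "linear"` each dataset after the first is first put on
#' a common scale by a linear factor fitted by least squares against
#' the running merged reference on their common indices.  The output
#' cell is the unweighted mean of the member cells.
#'
#' @param sets List of [reflection_set()] objects sharing a Laue group.
#' @param scale_mode `"none"` or `"linear"`.
#' @param dataset_id Id for the merged set; default joins member ids.
#' @param max_lcv Guard: maximum allowed linear cell variation (percent)
#'   among member cells (see [lcv()]); exceeding it is an error.
#' @return A merged [reflection_set()].
#' @examples
#' # two observations of one index: I = (10/1 + 20/4) / (1 + 1/4) = 12
#' @export
merge_sets <- function(sets, scale_mode = c("none", "linear"),
                       dataset_id = NULL, max_lcv = 2) {
  scale_mode <- match.arg(scale_mode)
  if (!length(sets)) stop("no sets to merge", call. = FALSE)
  symbols <- vapply(sets, function(s) s$laue_group$symbol, "")
  if (length(unique(symbols)) != 1L)
    stop("cannot merge sets with different Laue groups: ",
         paste(unique(symbols), collapse = ", "), call. = FALSE)
  cells <- lapply(sets, function(s) s$cell)
  if (length(sets) > 1L && is.finite(max_lcv)) {
    v <- lcv(cells)
    if (v$lcv_percent > max_lcv)
      stop(sprintf("member cells differ too much to merge (LCV %.2f%% > %.2f%%)",
                   v$lcv_percent, max_lcv), call. = FALSE)
  }
  ref <- ivw_merge(asu_table(sets[[1]]))
  for (s in sets[-1]) {
    tab <- asu_table(s)
    if (scale_mode == "linear" && nrow(tab) && nrow(ref)) {
      m <- match(tab$key, ref$key)
      ok <- !is.na(m)
      if (sum(ok) >= 3L && sum(tab$intensity[ok]^2) > 0) {
        k <- sum(tab$intensity[ok] * ref$intensity[m[ok]]) /
          sum(tab$intensity[ok]^2)
        if (is.finite(k) && k > 0) {
          tab$intensity <- tab$intensity * k
          tab$sigma <- tab$sigma * k
        }
      }
    }
    ref <- ivw_merge(rbind(ref, tab))
  }
  mean_cell <- as_unit_cell(colMeans(do.call(rbind, lapply(cells, unclass))))
  H <- keys_to_hkl(ref$key)
  if (is.null(dataset_id))
    dataset_id <- paste(vapply(sets, function(s) s$dataset_id, ""),
                        collapse = "+")
  reflection_set(dataset_id, mean_cell, sets[[1]]$laue_group,
                 data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                            intensity = ref$intensity, sigma = ref$sigma),
                 merged = TRUE)
}
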