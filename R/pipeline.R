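#' Default run configuration
#'
#' Returns the full set of tunable parameters for a two-stage run.
#' Stage 1 clusters on unit cells (`stage1_metric` `"ncdist"` or
#' `"blend_pca"`) until the completeness cutover; stage 2 merges the
#' selected clusters and re-clusters them on the correlation distance.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    stage1_metric = "ncdist",        # or "blend_pca"
    variance_cutoff = 0.01,          # PCA cutoff for blend_pca
    reduction_tol = 1e-5,            # Niggli boundary tolerance
    cutover_completeness = 0.10,     # stage-1 -> stage-2 switchover
    d_min = 2.5,                     # resolution limit (A)
    laue_group = "4/mmm",
    scale_mode = "none",             # merge scaling: none | linear
    max_lcv = 2,                     # merge guard (%)
    penalty_weight = 1,              # SFDist unmatched penalty
    activation = 0.90,               # penalty activation threshold
    sfdist_base = "chord",           # chord | sine
    quantity = "intensity",          # intensity | amplitude
    sentinel = 10,                   # distance for uncomparable pairs
    stage2_cut = list(rule = "adaptive", ratio = 1.25),
    # stage2_cut rules: adaptive | gap | count (k) | height (h)
    random_seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  stopifnot(cfg$cutover_completeness > 0, cfg$cutover_completeness <= 1,
            cfg$d_min > 0)
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Keys missing from the file take their [default_config()] values.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  do.call(default_config, ov)
}

#' @export
print.run_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Load an experiment directory
#'
#' Reads `cells.csv` (dataset_id, a, b, c, alpha, beta, gamma,
#' hkl_path), the per-dataset HKL4 files it points to (relative paths
#' are resolved against the CSV's directory), and `truth.csv` if
#' present.
#'
#' @param dir Directory containing `cells.csv`.
#' @param laue_group Laue symbol or [laue_group()] attached to each
#'   set.
#' @return List with `cells` (named list of [unit_cell()]), `sets`
#'   (named list of [reflection_set()]) and `truth` (named character
#'   or NULL).
#' @export
load_experiment_dir <- function(dir, laue_group) {
  df <- read_cells_csv(file.path(dir, "cells.csv"))
  cells <- cells_from_df(df)
  group <- as_laue_group(laue_group)
  sets <- list()
  for (i in seq_len(nrow(df))) {
    p <- df$hkl_path[i]
    if (!file.exists(p)) p <- file.path(dir, df$hkl_path[i])
    sets[[df$dataset_id[i]]] <- read_hkl(p, cells[[df$dataset_id[i]]],
                                         group,
                                         dataset_id = df$dataset_id[i])
  }
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    td <- utils::read.csv(tp, stringsAsFactors = FALSE)
    truth <- stats::setNames(as.character(td$form),
                             as.character(td$dataset_id))
  }
  list(cells = cells, sets = sets, truth = truth)
}

#' Stage 1: cell-based clustering to the completeness cutover
#'
#' Builds the configured cell distance matrix, Ward-clusters it,
#' annotates the dendrogram with LCV and completeness, and selects the
#' minimal non-overlapping clusters reaching
#' `config$cutover_completeness`.
#'
#' @param cells Named list of [unit_cell()] objects.
#' @param sets Named list of [reflection_set()] objects (same names).
#' @param config A [default_config()] list.
#' @return List with `dendrogram`, `selection`, `dist`, and a `log`
#'   list of input/selected/unassigned counts.
#' @export
run_stage1 <- function(cells, sets, config = default_config()) {
  ids <- names(cells)
  if (is.null(ids) || !setequal(ids, names(sets)))
    stop("cells and sets must be named consistently", call. = FALSE)
  sets <- sets[ids]
  D <- switch(config$stage1_metric,
              ncdist = ncdist_matrix(cells, tol = config$reduction_tol),
              blend_pca = blend_cell_distance_matrix(
                cells, variance_cutoff = config$variance_cutoff),
              stop("unknown stage1_metric: ", config$stage1_metric,
                   call. = FALSE))
  d <- ward_linkage(D)
  d <- annotate_lcv(d, cells)
  d <- annotate_completeness(d, sets, config$d_min)
  sel <- select_nonoverlapping(d, config$cutover_completeness)
  log <- list(n_input = length(ids), n_selected = nrow(sel),
              n_assigned = sum(sel$size),
              n_unassigned = length(attr(sel, "unassigned")))
  list(dendrogram = d, selection = sel, dist = D, log = log)
}

choose_k_gap <- function(heights) {
  m <- length(heights) + 1L       # number of items clustered
  if (m <= 2L) return(1L)
  h <- sort(heights)
  gaps <- diff(h)
  j <- which.max(gaps)
  m - j
}

# Adaptive cut: estimate the within-species distance scale from
# nearest-neighbour distances and the between-species scale from the
# median pairwise distance; if they are indistinguishable (ratio below
# `ratio`) the data are one homogeneous cluster, otherwise cut the
# tree midway between the two scales.  Favours small, pure clusters
# over large blended ones.
adaptive_cut_height <- function(D, ratio = 1.25) {
  n <- nrow(D)
  off <- D[upper.tri(D)]
  dnn <- apply(D + diag(Inf, n), 1, min)
  w <- stats::median(dnn)
  b <- stats::median(off)
  if (!is.finite(w) || !is.finite(b) || b < ratio * w) return(Inf)
  (w + b) / 2
}

#' Stage 2: merge selected clusters and re-cluster on reflections
#'
#' Merges each selected stage-1 cluster with [merge_sets()], computes
#' the pairwise correlation distance matrix, Ward-clusters the merged
#' sets, and cuts the tree per `config$stage2_cut`:
#' `rule = "adaptive"` (default) estimates the within-species distance
#' scale from nearest-neighbour distances and the between-species
#' scale from the median pairwise distance, returns a single cluster
#' when the two are indistinguishable (`ratio`, default 1.25), and
#' otherwise cuts midway between the scales — favouring small, pure
#' clusters; `rule = "gap"` cuts at the largest height gap;
#' `rule = "count"` with `k` and `rule = "height"` with `h` are fixed
#' cuts.
#'
#' @param selection A `cluster_selection` from [run_stage1()].
#' @param sets Named list of the original [reflection_set()] objects.
#' @param config A [default_config()] list.
#' @return List with `dendrogram` (over merged sets; NULL for a
#'   degenerate single-cluster run), `merged_sets`, `assignment`
#'   (data.frame dataset_id, stage1_node, stage2_cluster), `k`.
#' @export
run_stage2 <- function(selection, sets, config = default_config()) {
  members <- attr(selection, "members")
  n_sel <- nrow(selection)
  if (n_sel == 0L) stop("empty selection", call. = FALSE)
  merged <- vector("list", n_sel)
  mids <- sprintf("m%04d", seq_len(n_sel))
  for (i in seq_len(n_sel))
    merged[[i]] <- merge_sets(sets[members[[i]]],
                              scale_mode = config$scale_mode,
                              dataset_id = mids[i],
                              max_lcv = config$max_lcv)
  names(merged) <- mids
  set_assign <- function(cl) {
    do.call(rbind, lapply(seq_len(n_sel), function(i)
      data.frame(dataset_id = members[[i]],
                 stage1_node = selection$node_id[i],
                 stage2_cluster = cl[i])))
  }
  if (n_sel == 1L) {
    warning("single selected cluster; stage 2 is degenerate",
            call. = FALSE)
    return(list(dendrogram = NULL, merged_sets = merged,
                assignment = set_assign(1L), k = 1L))
  }
  D <- sfdist_matrix(merged, penalty_weight = config$penalty_weight,
                     activation = config$activation,
                     base = config$sfdist_base,
                     quantity = config$quantity,
                     sentinel = config$sentinel)
  d <- ward_linkage(D)
  cut <- config$stage2_cut
  cl <- switch(cut$rule,
               adaptive = {
                 h <- adaptive_cut_height(D, ratio = if (is.null(cut$ratio))
                   1.25 else cut$ratio)
                 if (is.infinite(h)) rep(1L, n_sel)
                 else cut_dendrogram(d, h = h)
               },
               gap = cut_dendrogram(d, k = choose_k_gap(d$height)),
               count = cut_dendrogram(d, k = min(cut$k, n_sel)),
               height = cut_dendrogram(d, h = cut$h),
               stop("unknown stage2_cut rule: ", cut$rule, call. = FALSE))
  list(dendrogram = d, merged_sets = merged,
       assignment = set_assign(unname(cl)), k = max(cl))
}

#' Run the full two-stage pipeline
#'
#' Cell-based Ward clustering to the completeness cutover, merge of
#' the selected clusters, then correlation-based Ward clustering of
#' the merged sets.  Deterministic given inputs and config.  If
#' `out_dir` is given, writes dendrograms (.nwk/.json), selection,
#' assignment and purity TSVs, a run log, and a MANIFEST; on error the
#' partial artifacts are flushed with the MANIFEST marking the run
#' incomplete.
#'
#' @param cells Named list of [unit_cell()] objects.
#' @param sets Named list of [reflection_set()] objects.
#' @param config A [default_config()] list.
#' @param truth Optional named ground-truth labels (enables the purity
#'   report).
#' @param out_dir Optional output directory.
#' @return List with `stage1`, `stage2`, `assignment`, `purity`
#'   (NULL without truth), `log`.
#' @export
run_two_stage <- function(cells, sets, config = default_config(),
                          truth = NULL, out_dir = NULL) {
  artifacts <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return()
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writer(file.path(out_dir, name))
    artifacts <<- c(artifacts, name)
  }
  finish <- function(complete) {
    if (is.null(out_dir)) return()
    writeLines(c(sprintf("complete: %s", tolower(complete)),
                 sprintf("artifact: %s", artifacts)),
               file.path(out_dir, "MANIFEST"))
  }
  result <- tryCatch({
    s1 <- tryCatch(run_stage1(cells, sets, config),
                   error = function(e)
                     stop("stage1: ", conditionMessage(e), call. = FALSE))
    emit("stage1_dendrogram.nwk", function(p)
      writeLines(dendrogram_to_newick(s1$dendrogram), p))
    emit("stage1_dendrogram.json", function(p)
      writeLines(dendrogram_to_json(s1$dendrogram), p))
    emit("selection.tsv", function(p) {
      sel <- s1$selection
      df <- data.frame(node_id = sel$node_id, size = sel$size,
                       completeness = sel$completeness,
                       members = vapply(attr(sel, "members"),
                                        paste, "", collapse = ","))
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    s2 <- tryCatch(run_stage2(s1$selection, sets, config),
                   error = function(e)
                     stop("stage2: ", conditionMessage(e), call. = FALSE))
    if (!is.null(s2$dendrogram)) {
      emit("stage2_dendrogram.nwk", function(p)
        writeLines(dendrogram_to_newick(s2$dendrogram), p))
      emit("stage2_dendrogram.json", function(p)
        writeLines(dendrogram_to_json(s2$dendrogram), p))
    }
    assignment <- s2$assignment
    emit("assignment.tsv", function(p)
      utils::write.table(assignment, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    purity <- NULL
    if (!is.null(truth)) {
      purity <- purity_report(assignment, truth)
      emit("purity.tsv", function(p)
        utils::write.table(purity$clusters, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
    log <- c(s1$log, list(n_merged = length(s2$merged_sets),
                          n_stage2_clusters = s2$k))
    emit("run_log.txt", function(p)
      writeLines(sprintf("%s: %s", names(log),
                         vapply(log, paste, "", collapse = ",")), p))
    list(stage1 = s1, stage2 = s2, assignment = assignment,
         purity = purity, log = log)
  }, error = function(e) {
    finish(FALSE)
    stop(e)
  })
  finish(TRUE)
  result
}

#' Score a cluster assignment against ground-truth form labels
#'
#' For every cluster: its size, composition over the true form labels,
#' and purity (the largest label fraction).  For every form: the size
#' of the largest cluster that is 100% that form.
#'
#' @param assignment data.frame with `dataset_id` and `stage2_cluster`
#'   columns (as produced by [run_stage2()]), or a named vector of
#'   cluster ids.
#' @param truth Named character vector of true form labels.
#' @return List of class `purity_report`: `clusters` (data.frame:
#'   cluster, size, purity, majority plus one count column per form),
#'   `forms` (data.frame: form, largest_pure_size), and `mean_purity`
#'   — the overall clustering purity, i.e. the fraction of datasets
#'   that belong to their cluster's majority form (equivalently the
#'   dataset-size-weighted mean of the per-cluster purities).
#' @export
purity_report <- function(assignment, truth) {
  if (is.data.frame(assignment)) {
    cl <- stats::setNames(assignment$stage2_cluster,
                          assignment$dataset_id)
  } else cl <- assignment
  miss <- setdiff(names(cl), names(truth))
  if (length(miss))
    stop("no truth label for dataset: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  lab <- truth[names(cl)]
  tab <- table(cluster = cl, form = lab)
  counts <- matrix(tab, nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  size <- rowSums(counts)
  purity <- apply(counts, 1, max) / size
  majority <- colnames(counts)[apply(counts, 1, which.max)]
  clusters <- data.frame(cluster = rownames(counts), size = size,
                         purity = as.numeric(purity), majority = majority,
                         counts, check.names = FALSE, row.names = NULL)
  forms <- vapply(colnames(counts), function(f) {
    pure <- counts[, f] == size
    if (any(pure)) max(size[pure]) else 0
  }, 0)
  structure(list(clusters = clusters,
                 forms = data.frame(form = names(forms),
                                    largest_pure_size = as.numeric(forms),
                                    row.names = NULL),
                 mean_purity = sum(size * purity) / sum(size)),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat(sprintf("purity report: %d clusters, mean purity %.3f\n",
              nrow(x$clusters), x$mean_purity))
  cat("largest 100%-pure cluster per form:\n")
  print(x$forms, row.names = FALSE)
  invisible(x)
}
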