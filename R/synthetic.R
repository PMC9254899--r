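# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(i)) %% 2147483629
}

#' Specification of one synthetic crystal form
#'
#' Describes how a crystal form differs from the shared reference:
#' its mean unit cell (and per-parameter Gaussian spread applied per
#' dataset) and a form-specific intensity perturbation applied to a
#' random subset of unique reflections.  This emulates a ligand soak:
#' a soak may shift the cell, change a subset of intensities, or both.
#'
#' @param label Form label (used as ground truth).
#' @param mean_cell A [unit_cell()].
#' @param cell_sigma Numeric of length 6: per-dataset Gaussian sd of
#'   (a, b, c, alpha, beta, gamma) in angstrom / degrees.
#' @param intensity_shift_fraction Fraction of unique indices whose
#'   intensity is perturbed (in \[0, 1\]).
#' @param intensity_shift_scale Multiplicative perturbation magnitude:
#'   affected intensities are multiplied by 1 + scale * u with
#'   u ~ U(0.5, 1).
#' @return A `form_spec` object.
#' @export
form_spec <- function(label, mean_cell, cell_sigma = rep(0, 6),
                      intensity_shift_fraction = 0,
                      intensity_shift_scale = 0) {
  stopifnot(length(cell_sigma) == 6, all(cell_sigma >= 0),
            intensity_shift_fraction >= 0, intensity_shift_fraction <= 1,
            intensity_shift_scale >= 0)
  structure(list(label = as.character(label),
                 mean_cell = as_unit_cell(mean_cell),
                 cell_sigma = as.numeric(cell_sigma),
                 intensity_shift_fraction = intensity_shift_fraction,
                 intensity_shift_scale = intensity_shift_scale),
            class = "form_spec")
}

#' Generate reference intensities for a full sphere of unique indices
#'
#' Every symmetry-unique index to `d_min` receives an intensity drawn
#' from an exponential (Wilson) distribution with mean
#' `mean_intensity`, with sigma set to 5% of the intensity.
#'
#' @param cell A [unit_cell()].
#' @param laue_group A [laue_group()] or symbol.
#' @param d_min Resolution limit in angstrom.
#' @param seed RNG seed; the output is deterministic per seed.
#' @param mean_intensity Mean of the Wilson prior (default 1).
#' @return A merged [reflection_set()] with completeness 1.
#' @export
generate_reference_intensities <- function(cell, laue_group, d_min, seed,
                                           mean_intensity = 1) {
  H <- enumerate_asu(cell, laue_group, d_min)
  I <- with_seed(seed, stats::rexp(nrow(H), rate = 1 / mean_intensity))
  reflection_set("reference", cell, laue_group,
                 data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                            intensity = I, sigma = 0.05 * I),
                 merged = TRUE)
}

#' Derive a crystal form from the reference intensities
#'
#' A random `intensity_shift_fraction` of the unique indices get their
#' intensity multiplied by 1 + scale * u (u uniform in \[0.5, 1\]);
#' the rest stay unchanged.  The form's cell is `spec$mean_cell`.
#' With fraction 0 the intensities are identical to the reference, so
#' forms can be built that differ in cell only, intensities only, or
#' both — the situations that make staged clustering necessary.
#'
#' @param reference Merged [reflection_set()] from
#'   [generate_reference_intensities()].
#' @param spec A [form_spec()].
#' @param seed RNG seed for the index subset and perturbation draws.
#' @return A merged [reflection_set()] labelled with the form label.
#' @export
derive_form <- function(reference, spec, seed) {
  obs <- reference$observations
  n <- nrow(obs)
  n_shift <- round(spec$intensity_shift_fraction * n)
  if (n_shift > 0) {
    pick_u <- with_seed(seed, list(pick = sample.int(n, n_shift),
                                   u = stats::runif(n_shift, 0.5, 1)))
    fac <- 1 + spec$intensity_shift_scale * pick_u$u
    obs$intensity[pick_u$pick] <- obs$intensity[pick_u$pick] * fac
    obs$sigma[pick_u$pick] <- obs$sigma[pick_u$pick] * fac
  }
  reflection_set(spec$label, spec$mean_cell, reference$laue_group, obs,
                 merged = TRUE)
}

#' Sample a partial wedge from a form's full reflection set
#'
#' Emulates a few degrees of rotation data from one microcrystal: a
#' random subset of the unique indices at the target completeness,
#' Gaussian relative measurement noise on the intensities, and a
#' per-dataset cell drawn around the form's mean cell.
#'
#' @param form_set Merged [reflection_set()] of the form (full sphere).
#' @param completeness_target Fraction of unique indices to keep,
#'   in (0, 1\].
#' @param noise_fraction Relative sd of multiplicative Gaussian noise.
#' @param seed RNG seed.
#' @param dataset_id Id for the wedge.
#' @param cell_sigma Numeric of length 6; per-parameter Gaussian sd
#'   added to the form's cell.
#' @return An unmerged [reflection_set()].
#' @export
sample_wedge <- function(form_set, completeness_target, noise_fraction,
                         seed, dataset_id = "wedge",
                         cell_sigma = rep(0, 6)) {
  stopifnot(completeness_target > 0, completeness_target <= 1)
  obs <- form_set$observations
  n <- nrow(obs)
  n_keep <- round(completeness_target * n)
  if (n_keep < 1L)
    stop("completeness target leaves no reflections", call. = FALSE)
  draw <- with_seed(seed, list(
    pick = sort(sample.int(n, n_keep)),
    eps = stats::rnorm(n_keep, 0, 1),
    cell_eps = stats::rnorm(6, 0, 1)))
  sub <- obs[draw$pick, , drop = FALSE]
  noisy <- sub$intensity * (1 + noise_fraction * draw$eps)
  sub$sigma <- sqrt(sub$sigma^2 + (noise_fraction * sub$intensity)^2)
  sub$intensity <- noisy
  cell <- unclass(form_set$cell) + as.numeric(cell_sigma) * draw$cell_eps
  reflection_set(dataset_id, as_unit_cell(cell), form_set$laue_group, sub,
                 merged = FALSE)
}

#' Generate a complete synthetic serial-crystallography experiment
#'
#' Builds a shared Wilson reference, derives each form per its
#' [form_spec()], and samples `n_per_form` partial wedges per form with
#' per-dataset cell noise and measurement noise.  Ground-truth form
#' labels are returned for every dataset, so clustering performance can
#' be scored.  Fully reproducible from the same arguments and seed.
#'
#' @param forms List of [form_spec()] objects.
#' @param n_per_form Wedges per form (scalar or vector per form).
#' @param laue_group Laue symbol or [laue_group()].
#' @param d_min Resolution limit in angstrom.
#' @param seed Master seed; all per-dataset seeds derive from it.
#' @param wedge_completeness Length-2 range; each wedge's completeness
#'   target is uniform in it.
#' @param noise_fraction Relative intensity noise per wedge.
#' @param mean_intensity Scale of the Wilson reference.  The default
#'   (1000) keeps intensities well inside the fixed-point HKL4 columns;
#'   correlation-based distances are scale-invariant, so the value has
#'   no effect on clustering.
#' @param out_dir If non-NULL, writes `cells.csv`, per-dataset `.hkl`
#'   files, `truth.csv` and `spec.yaml` there.
#' @return List of class `synthetic_experiment`: `sets` (named list of
#'   [reflection_set()]), `cells` (data.frame in cells-CSV layout),
#'   `truth` (named character vector), `forms`, `params`.
#' @export
generate_experiment <- function(forms, n_per_form, laue_group, d_min, seed,
                                wedge_completeness = c(0.03, 0.08),
                                noise_fraction = 0.05,
                                mean_intensity = 1000,
                                out_dir = NULL) {
  if (inherits(forms, "form_spec")) forms <- list(forms)
  n_per_form <- rep(as.integer(n_per_form), length.out = length(forms))
  labels <- vapply(forms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("form labels must be unique", call. = FALSE)

  ref_cell <- forms[[1]]$mean_cell
  reference <- generate_reference_intensities(ref_cell, laue_group, d_min,
                                              seed = derive_seed(seed, 0),
                                              mean_intensity = mean_intensity)
  form_sets <- lapply(seq_along(forms), function(i)
    derive_form(reference, forms[[i]], seed = derive_seed(seed, i)))

  sets <- list()
  truth <- character(0)
  rows <- list()
  idx <- 0L
  for (i in seq_along(forms)) {
    for (w in seq_len(n_per_form[i])) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", labels[i], w)
      sw <- derive_seed(seed, 1000 + idx)
      target <- with_seed(derive_seed(seed, 500000 + idx),
                          stats::runif(1, wedge_completeness[1],
                                       wedge_completeness[2]))
      sets[[id]] <- sample_wedge(form_sets[[i]], target, noise_fraction,
                                 seed = sw, dataset_id = id,
                                 cell_sigma = forms[[i]]$cell_sigma)
      truth[id] <- labels[i]
      cl <- unclass(sets[[id]]$cell)
      rows[[idx]] <- data.frame(dataset_id = id, a = cl[1], b = cl[2],
                                c = cl[3], alpha = cl[4], beta = cl[5],
                                gamma = cl[6],
                                hkl_path = paste0(id, ".hkl"))
    }
  }
  cells <- do.call(rbind, rows)
  params <- list(n_per_form = n_per_form,
                 laue_group = as_laue_group(laue_group)$symbol,
                 d_min = d_min, seed = seed,
                 wedge_completeness = wedge_completeness,
                 noise_fraction = noise_fraction,
                 mean_intensity = mean_intensity)
  exp <- structure(list(sets = sets, cells = cells, truth = truth,
                        forms = forms, params = params),
                   class = "synthetic_experiment")
  if (!is.null(out_dir)) write_experiment(exp, out_dir)
  exp
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic experiment: %d datasets, %d forms (%s), Laue %s, d_min %.2f A\n",
              length(x$sets), length(x$forms),
              paste(names(table(x$truth)), collapse = "/"),
              x$params$laue_group, x$params$d_min))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Writes `cells.csv`, one HKL4 file per dataset, `truth.csv`
#' (dataset_id, form) and `spec.yaml` (generator parameters).
#'
#' @param exp A `synthetic_experiment`.
#' @param out_dir Output directory (created if needed).
#' @export
write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cells_csv(exp$cells, file.path(out_dir, "cells.csv"))
  for (id in names(exp$sets))
    write_hkl(exp$sets[[id]], file.path(out_dir, paste0(id, ".hkl")))
  utils::write.csv(data.frame(dataset_id = names(exp$truth),
                              form = unname(exp$truth)),
                   file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  spec <- exp$params
  spec$forms <- lapply(exp$forms, function(f)
    list(label = f$label, mean_cell = as.numeric(unclass(f$mean_cell)),
         cell_sigma = f$cell_sigma,
         intensity_shift_fraction = f$intensity_shift_fraction,
         intensity_shift_scale = f$intensity_shift_scale))
  yaml::write_yaml(spec, file.path(out_dir, "spec.yaml"))
  invisible(out_dir)
}

#' The four-form benchmark preset
#'
#' Emulates the canonical mixed-soak lysozyme experiment: a tetragonal
#' base cell (79, 79, 38, 90, 90, 90) and four forms -
#' `N` (native: reference cell, reference intensities),
#' `G` (cell expanded 0.3% in a and b, plus an intensity signature —
#' recognizable from cell parameters alone),
#' `B` (reference cell but a distinct intensity signature —
#' cell-degenerate with `N`, so cell clustering cannot isolate it), and
#' `GB` (both the cell expansion and its own intensity signature).
#' Laue group 4/mmm, d_min 2.5 A, wedges of 3-8% completeness with 5%
#' relative intensity noise, cell noise 0.05 A / 0.02 deg.  Intensity
#' signatures perturb 30% of unique reflections with scale 2.
#'
#' @param seed Master seed (default 20220704).
#' @param n_per_form Wedges per form (default 250, i.e. 1000 total).
#' @param forms Which of the four forms to include (default all).
#' @param out_dir Optional output directory, see
#'   [generate_experiment()].
#' @return A `synthetic_experiment`.
#' @export
preset_lysozyme_soaks <- function(seed = 20220704, n_per_form = 250,
                              forms = c("N", "G", "B", "GB"),
                              out_dir = NULL) {
  base <- unit_cell(79, 79, 38, 90, 90, 90)
  shifted <- unit_cell(79 * 1.003, 79 * 1.003, 38, 90, 90, 90)
  sig <- c(0.05, 0.05, 0.05, 0.02, 0.02, 0.02)
  all_forms <- list(
    N  = form_spec("N", base, sig, 0, 0),
    G  = form_spec("G", shifted, sig, 0.3, 2),
    B  = form_spec("B", base, sig, 0.3, 2),
    GB = form_spec("GB", shifted, sig, 0.3, 2))
  unknown <- setdiff(forms, names(all_forms))
  if (length(unknown))
    stop("unknown preset forms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  generate_experiment(all_forms[forms], n_per_form = n_per_form,
                      laue_group = "4/mmm", d_min = 2.5, seed = seed,
                      wedge_completeness = c(0.03, 0.08),
                      noise_fraction = 0.05, out_dir = out_dir)
}
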