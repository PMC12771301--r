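#' Write a cohort to a directory of delimited files
#'
#' One CSV per subject (header = region names, rows = time points), a
#' \code{manifest.json} (subject id, group, file, seed) and, for synthetic
#' cohorts, a \code{ground_truth.json} with each group's h and J.
#'
#' @param cohort A [generate_cohort()] result (or a cohort read back with
#'   [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$subjects, function(s) {
    file <- paste0(s$id, ".csv")
    utils::write.csv(as.data.frame(s$ts), file.path(dir, file),
                     row.names = FALSE)
    list(id = s$id, group = s$group, file = file,
         seed = if (is.null(s$seed)) NA else s$seed)
  })
  manifest <- list(
    roi_names = cohort$spec$roi_names,
    t_max = cohort$spec$t_max,
    subjects = unname(entries)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cohort$spec$params_a)) {
    gt <- list(
      group_a = list(h = unname(cohort$spec$params_a$h),
                     J = unname(cohort$spec$params_a$J)),
      group_b = list(h = unname(cohort$spec$params_b$h),
                     J = unname(cohort$spec$params_b$J)),
      roi_names = cohort$spec$roi_names,
      sampler = cohort$spec$sampler,
      emission = cohort$spec$emission,
      seed = cohort$spec$seed
    )
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort from a directory
#'
#' Loads the manifest and every subject's CSV, validating shapes and
#' values: a missing or non-numeric entry raises an error naming the
#' subject and row, and a subject whose header lists the regions in a
#' different order is realigned by name with a warning.
#'
#' @param dir Directory containing \code{manifest.json} and the subject
#'   files written by [write_cohort()].
#' @return A \code{cohort} object (without ground truth).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  roi_names <- manifest$roi_names
  subjects <- list()
  for (r in seq_len(nrow(manifest$subjects))) {
    entry <- manifest$subjects[r, ]
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) {
      stop("missing subject file for ", entry$id, ": ", entry$file,
           call. = FALSE)
    }
    ts <- as.matrix(utils::read.csv(path, check.names = FALSE))
    if (!setequal(colnames(ts), roi_names)) {
      stop("subject ", entry$id, ": header does not match the manifest regions",
           call. = FALSE)
    }
    if (!identical(colnames(ts), roi_names)) {
      warning("subject ", entry$id,
              ": regions reordered to match the manifest", call. = FALSE)
      ts <- ts[, roi_names, drop = FALSE]
    }
    if (!is.numeric(ts) || anyNA(ts)) {
      bad <- which(is.na(ts) | !is.finite(ts), arr.ind = TRUE)
      stop("subject ", entry$id, ": missing/non-numeric value at row ",
           if (nrow(bad) > 0) bad[1L, 1L] else "?", call. = FALSE)
    }
    subjects[[entry$id]] <- list(id = entry$id, group = entry$group,
                                 seed = entry$seed, ts = ts)
  }
  groups <- unique(vapply(subjects, `[[`, character(1), "group"))
  if (length(groups) != 2L) {
    stop("cohort must contain exactly two groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  spec <- list(roi_names = roi_names, n_rois = length(roi_names),
               t_max = manifest$t_max)
  structure(list(subjects = subjects, spec = spec,
                 true_state_sequences = NULL),
            class = "cohort")
}

#' Run the full energy-landscape analysis pipeline
#'
#' Orchestrates the stages end to end: (optional) synthetic cohort
#' generation or cohort loading, per-region mean binarization, per-subject
#' maximum-entropy fits, group-level landscapes (fitted on each group's
#' concatenated binarized data), per-subject temporal dynamics with group
#' tables for the signature states, and the per-state group comparison.
#' Everything is deterministic given the input spec's seed.
#'
#' @param input A [cohort_spec()] (synthetic mode), a \code{cohort}, or a
#'   directory path for [read_cohort()].
#' @param out_dir Optional output directory; when given, all stage outputs
#'   are written as delimited text/JSON together with a run manifest
#'   containing per-file MD5 checksums.
#' @param roi_subset Optional region names or indices to restrict the
#'   analysis to (at most 15).
#' @param alpha Family-wise significance level for the Bonferroni rule.
#' @param tol,max_iter,method Fit options passed to [fit_mem()].
#' @param verbose Print stage progress.
#' @return An object of class \code{ela_run}: \code{cohort} (metadata
#'   only), \code{fits}, \code{group_landscapes}, \code{comparison},
#'   \code{signature_states}, \code{dynamics} (per-subject summaries),
#'   \code{dynamics_tables} (per-group aggregates over signature states),
#'   \code{energy_long} (box-plot-ready long table) and \code{manifest}.
#' @export
run_pipeline <- function(input, out_dir = NULL, roi_subset = NULL,
                         alpha = 0.05, tol = 1e-5, max_iter = 10000L,
                         method = "newton", verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  cohort <- if (inherits(input, "cohort_spec")) {
    say("simulate: generating synthetic cohort")
    generate_cohort(input)
  } else if (inherits(input, "cohort")) {
    input
  } else if (is.character(input) && length(input) == 1L) {
    say("load: reading cohort from ", input)
    read_cohort(input)
  } else {
    stop("input must be a cohort_spec, a cohort, or a directory path",
         call. = FALSE)
  }

  roi_names <- cohort$spec$roi_names
  if (!is.null(roi_subset)) {
    idx <- vapply(roi_subset, edge_to_index, integer(1), roi_names = roi_names)
    roi_names <- roi_names[idx]
    check_n_rois(length(roi_names))
    for (id in names(cohort$subjects)) {
      cohort$subjects[[id]]$ts <-
        cohort$subjects[[id]]$ts[, roi_names, drop = FALSE]
    }
  }
  n_rois <- length(roi_names)
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  group_levels <- sort(unique(groups))

  say("binarize: thresholding at per-region time means")
  binarized <- lapply(cohort$subjects, function(s) binarize(s$ts))
  sequences <- lapply(binarized, to_state_sequence)

  say("fit: per-subject maximum-entropy models")
  fits <- lapply(binarized, fit_mem, tol = tol, max_iter = max_iter,
                 method = method)

  say("landscape: group-level fits and topology")
  group_landscapes <- lapply(group_levels, function(g) {
    B <- do.call(rbind, lapply(binarized[groups == g], `[[`, "values"))
    fit <- fit_mem(B, tol = tol, max_iter = max_iter, method = method,
                   roi_names = roi_names)
    energy_landscape(fit)
  })
  names(group_landscapes) <- group_levels
  minima <- lapply(group_landscapes, function(l) l$minima$state)

  say("compare: per-state group tests")
  energies <- lapply(group_levels, function(g) {
    per_subject_energy_matrix(fits[groups == g])
  })
  names(energies) <- group_levels
  comparison <- compare_groups(energies[[1L]], energies[[2L]],
                               minima[[1L]], minima[[2L]],
                               alpha = alpha, n_rois = n_rois)
  signature <- select_signature_states(
    comparison$state[comparison$bonferroni_significant],
    minima[[1L]], minima[[2L]])

  say("dynamics: per-subject summaries and group tables")
  dynamics <- lapply(sequences, summarize_dynamics)
  dyn_states <- if (nrow(signature) > 0) signature$state else integer(0)
  dynamics_tables <- if (length(dyn_states) > 0) {
    lapply(stats::setNames(group_levels, group_levels), function(g) {
      aggregate_group_dynamics(dynamics[groups == g], dyn_states)
    })
  } else {
    list()
  }

  energy_long <- do.call(rbind, lapply(group_levels, function(g) {
    M <- energies[[g]]
    data.frame(subject = rep(rownames(M), times = ncol(M)),
               group = g,
               state = rep(seq_len(ncol(M)), each = nrow(M)),
               energy = as.vector(M))
  }))

  run <- structure(
    list(cohort = list(n_subjects = length(cohort$subjects),
                       groups = table(groups),
                       roi_names = roi_names,
                       t_max = cohort$spec$t_max),
         fits = fits,
         sequences = sequences,
         group_landscapes = group_landscapes,
         comparison = comparison,
         signature_states = signature,
         dynamics = dynamics,
         dynamics_tables = dynamics_tables,
         energy_long = energy_long,
         manifest = NULL),
    class = "ela_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, cohort, out_dir,
                              config = list(alpha = alpha, tol = tol,
                                            max_iter = max_iter,
                                            method = method,
                                            roi_subset = roi_subset))
  }
  run
}

#' @export
print.ela_run <- function(x, ...) {
  cat("Energy-landscape analysis run\n")
  cat("  subjects:", x$cohort$n_subjects, "(",
      paste(sprintf("%s=%d", names(x$cohort$groups), x$cohort$groups),
            collapse = ", "), ") | regions:", length(x$cohort$roi_names), "\n")
  conv <- vapply(x$fits, `[[`, logical(1), "converged")
  cat("  fits converged:", sum(conv), "/", length(conv), "\n")
  for (g in names(x$group_landscapes)) {
    cat("  group", g, "minima:",
        paste(x$group_landscapes[[g]]$minima$state, collapse = ", "), "\n")
  }
  cat("  Bonferroni-significant states:",
      sum(x$comparison$bonferroni_significant),
      "| signature states:", nrow(x$signature_states), "\n")
  if (nrow(x$signature_states) > 0) {
    print(x$signature_states, row.names = FALSE)
  }
  invisible(x)
}

# Serialise a pipeline run: per-subject parameter JSONs, energy tables,
# minima and trees, dynamics and comparison CSVs, plus a manifest with MD5
# checksums of every written file.
write_run <- function(run, cohort, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  fits_dir <- file.path(out_dir, "fits")
  dir.create(fits_dir, showWarnings = FALSE)
  for (id in names(run$fits)) {
    f <- run$fits[[id]]
    jsonlite::write_json(
      list(subject = id,
           roi_names = f$params$roi_names,
           h = unname(f$params$h),
           J = unname(f$params$J),
           converged = f$converged,
           iterations = f$iterations,
           max_moment_gap = f$max_moment_gap,
           log_likelihood = f$log_likelihood,
           fit_accuracy = f$fit_accuracy),
      add(file.path(fits_dir, paste0(id, "_params.json"))),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  for (g in names(run$group_landscapes)) {
    l <- run$group_landscapes[[g]]
    et <- l$energy_table
    utils::write.csv(
      data.frame(state = seq_along(et$energies),
                 pattern = state_pattern(seq_along(et$energies), et$n_rois),
                 energy = et$energies,
                 probability = et$probabilities),
      add(file.path(out_dir, paste0("energy_table_", g, ".csv"))),
      row.names = FALSE)
    utils::write.csv(
      l$minima,
      add(file.path(out_dir, paste0("minima_", g, ".csv"))),
      row.names = FALSE)
    writeLines(tree_to_newick(l$tree),
               add(file.path(out_dir, paste0("tree_", g, ".nwk"))))
    jsonlite::write_json(l$tree,
                         add(file.path(out_dir, paste0("tree_", g, ".json"))),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  utils::write.csv(as.data.frame(run$comparison),
                   add(file.path(out_dir, "comparison.csv")),
                   row.names = FALSE)
  utils::write.csv(run$energy_long,
                   add(file.path(out_dir, "energies_long.csv")),
                   row.names = FALSE)
  utils::write.csv(run$signature_states,
                   add(file.path(out_dir, "signature_states.csv")),
                   row.names = FALSE)
  for (g in names(run$dynamics_tables)) {
    utils::write.csv(run$dynamics_tables[[g]],
                     add(file.path(out_dir, paste0("dynamics_", g, ".csv"))),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("elascape")),
    config = config,
    seed = if (is.null(cohort$spec$seed)) NA else cohort$spec$seed,
    n_subjects = length(cohort$subjects),
    files = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
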