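# End-to-end orchestration: parsimony search -> strict consensus ->
# stratigraphic calibration -> diversity, disparity, trait models, body
# metrics. The pipeline is a pure function of (inputs, config, seed); rerun
# with the same configuration it produces an identical report.

#' Run the full macroevolutionary pipeline
#'
#' Executes the stages in dependency order and aggregates their outputs into
#' a single report. `config` is a named list:
#' \describe{
#'   \item{matrix}{a [char_matrix] or path to a NEXUS file}
#'   \item{ages}{taxon tibble or CSV path (`name`, `fad`, `lad`, optional
#'     measurements and `bin_label`)}
#'   \item{bins}{bin tibble or JSON path}
#'   \item{tree}{optional fixed tree (phylo or newick path); skips the
#'     search stage}
#'   \item{outgroup}{optional taxon used to root/orient output trees}
#'   \item{seed}{master seed, recorded in the report}
#'   \item{search}{list: `n_replicates`, `max_trees_held`}
#'   \item{calibration}{list: `method`, `min_duration`, `root_extension`}
#'   \item{disparity}{list: `n_resamples`, `sample_size`}
#'   \item{traits}{list: `measurement_sd`}
#'   \item{extra_taxa}{taxon tibble of range-only diversity additions}
#'   \item{out_dir}{optional directory for report.json and CSV outputs}
#' }
#' Stages whose inputs are absent (e.g. no trait measurements) are skipped
#' with a warning; a stage failure halts with an error naming the stage.
#'
#' @param config named list as above
#' @return a report list (invisibly also written to `out_dir` if given)
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  report <- list(schema_version = "1.0", seed = seed)

  mat <- stage("read_matrix", {
    if (inherits(config$matrix, "char_matrix")) config$matrix
    else read_character_matrix(config$matrix)
  })
  ages <- stage("read_ages", {
    if (is.data.frame(config$ages)) {
      a <- config$ages; a$name <- normalise_label(a$name); a
    } else read_taxon_table(config$ages)
  })
  bins <- stage("read_bins", {
    if (is.data.frame(config$bins)) config$bins else read_time_bins(config$bins)
  })

  if (!is.null(config$tree)) {
    trees <- stage("read_tree", {
      t <- if (inherits(config$tree, "phylo")) phy_norm(config$tree)
           else read_tree(config$tree)
      list(t)
    })
    best_length <- stage("score_tree", fitch_length(trees[[1]], mat))
  } else {
    srch <- stage("search", {
      s <- config$search %||% list()
      heuristic_search(mat, n_replicates = s$n_replicates %||% 10,
                       seed = seed, outgroup = config$outgroup,
                       max_trees_held = s$max_trees_held %||% Inf)
    })
    trees <- srch$trees
    best_length <- srch$length
  }
  report$n_trees <- length(trees)
  report$tree_stats <- stage("tree_stats",
                             as.list(ensemble_indices(trees[[1]], mat)))

  cons <- stage("consensus", {
    cns <- strict_consensus(trees)
    if (!is.null(config$outgroup)) cns <- root_safely(cns, config$outgroup)
    cns
  })
  report$consensus <- write_tree(cons)

  cal <- config$calibration %||% list()
  tt <- stage("calibrate", {
    calibrate(cons, ages, method = cal$method %||% "mbl",
              min_duration = cal$min_duration %||% 1,
              root_extension = cal$root_extension %||% 1)
  })
  report$timetree <- write_tree(tt$phy)
  report$root_age <- tt$phy$root.time

  curve <- stage("diversity", {
    phylogenetic_diversity(tt, bins, extra_taxa = config$extra_taxa)
  })
  report$diversity <- as.data.frame(curve)

  if (any(!is.na(ages$bin_label))) {
    dsp <- config$disparity %||% list()
    disp <- stage("disparity", {
      disparity_by_bin(mat, ages, n_resamples = dsp$n_resamples %||% 1000,
                       seed = seed, sample_size = dsp$sample_size)
    })
    report$disparity <- as.data.frame(disp)
    report$disparity_removed_taxa <- attr(disp, "removed")
  } else {
    warning("no bin assignments; disparity stage skipped")
    disp <- NULL
  }

  if (any(!is.na(ages$trunk_length))) {
    trc <- config$traits %||% list()
    fits <- stage("traits", {
      dat <- tibble::tibble(taxon = ages$name, value = ages$trunk_length)
      sd0 <- trc$measurement_sd %||% 0
      list(raw = fit_all(tt, dat, sd0, transform = "none"),
           ln = fit_all(tt, dat, sd0, transform = "ln"))
    })
    report$trait_models <- list(raw = as.data.frame(glance(fits$raw)),
                                ln = as.data.frame(glance(fits$ln)))
  } else {
    warning("no trunk measurements; trait-model stage skipped")
    fits <- NULL
  }

  if (any(!is.na(ages$trunk_length) & !is.na(ages$neck_length))) {
    bm <- stage("body_metrics", {
      props <- proportion_table(ages)
      sizes <- range_by_bin(
        tibble::tibble(value = ages$trunk_length, bin_label = ages$bin_label),
        bins)
      list(proportions = props, size_ranges = sizes)
    })
    report$body_metrics <- list(proportions = as.data.frame(bm$proportions),
                                size_ranges = as.data.frame(bm$size_ranges))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(vapply(trees, write_tree, ""),
               file.path(config$out_dir, "trees.nwk"))
    writeLines(report$timetree, file.path(config$out_dir, "timetree.nwk"))
    utils::write.csv(curve, file.path(config$out_dir, "curve.csv"),
                     row.names = FALSE)
    if (!is.null(disp))
      utils::write.csv(disp, file.path(config$out_dir, "disparity.csv"),
                       row.names = FALSE)
  }
  invisible(report)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
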