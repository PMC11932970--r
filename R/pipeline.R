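# Orchestration: simulate -> segment -> engulf -> aggregate -> stats, with a
# YAML/list config and a machine-readable run manifest. These functions are
# the batch interface; inst/cli/phagoquant.R wraps them for shell use.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

design_from_config <- function(cfg) {
  dn <- cfg$design
  if (is.null(dn)) dn <- list()
  args <- dn[intersect(names(dn),
                       names(formals(cohort_design)))]
  if (!is.null(cfg$seed) && is.null(args$seed)) args$seed <- cfg$seed
  do.call(cohort_design, args)
}

#' Simulate a cohort dataset to disk
#'
#' Renders every section of a [cohort_design()] and writes: one TIFF per
#' section plus its metadata sidecar, one ground-truth mask TIFF per section
#' (binary channels `iba1`, `cd68_in_iba1`, `marker`), a cohort manifest CSV,
#' the latent truth table CSV, and a JSON run manifest recording the full
#' configuration and seed. Idempotent given the seed.
#'
#' @param config A list or YAML path with a `design` section
#'   (arguments of [cohort_design()]) and optional top-level `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest data.frame and file paths.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  design <- design_from_config(cfg)
  dir.create(file.path(out_dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  write_section <- function(rec) {
    base <- sprintf("%s_s%02d", rec$animal_id, rec$section_index)
    stack_path <- file.path(out_dir, "stacks", paste0(base, ".tif"))
    truth_path <- file.path(out_dir, "stacks", paste0(base, "_truth.tif"))
    write_stack(rec$stack, stack_path)
    tm <- rec$truth$masks
    td <- array(0, c(3, dim(tm$cell$grid)))
    td[1, , , ] <- tm$cell$grid * 1
    td[2, , , ] <- tm$lysosome_in_cell$grid * 1
    td[3, , , ] <- tm$marker$grid * 1
    truth_stack <- channel_stack(td, rec$stack$voxel,
                                 c("iba1", "cd68_in_iba1", "marker"))
    write_stack(truth_stack, truth_path)
    data.frame(animal_id = rec$animal_id, section_index = rec$section_index,
               sex = rec$sex, neonatal_incision = rec$neonatal_incision,
               adult_incision = rec$adult_incision, age_class = rec$age_class,
               marker_kind = rec$marker_kind,
               file = file.path("stacks", paste0(base, ".tif")),
               truth_file = file.path("stacks", paste0(base, "_truth.tif")),
               true_engulfed_fraction = rec$truth$true_engulfed_fraction,
               seed = rec$seed, stringsAsFactors = FALSE)
  }
  cohort <- make_cohort(design, render = "full", section_fn = write_section)
  manifest <- do.call(rbind, lapply(cohort$sections, `[[`, "result"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth_table, file.path(out_dir, "truth_table.csv"),
                   row.names = FALSE)
  run <- list(stage = "simulate", package_version = as.character(utils::packageVersion("phagoquant")),
              seed = design$seed, config = cfg)
  jsonlite::write_json(run, file.path(out_dir, "run_simulate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(manifest = manifest, truth_table = cohort$truth_table,
                 dir = out_dir))
}

#' Analyse a simulated or acquired dataset
#'
#' For every section in the manifest: read the stack, apply the z-depth rule
#' by age class (adults: keep only the top `adult_depth_um` from the imaging
#' surface; neonates: full thickness), optionally crop to a fixed xy field of
#' view, binarise the three channels, and compute [engulfment_metrics()];
#' then aggregate per animal with [aggregate_cohort()]. With
#' `use_truth_masks = TRUE` segmentation is bypassed and the deposited
#' ground-truth masks are used (the oracle path). Every applied threshold is
#' logged in the run report.
#'
#' @param out_dir Dataset directory written by [run_simulate()] (or with the
#'   same layout).
#' @param use_truth_masks Bypass segmentation with the ground-truth masks.
#' @param threshold_method,min_voxels Passed to the segmentation stage
#'   (`min_voxels` is reserved for ROI exports; masks are used as-is for
#'   volume overlap).
#' @param crop_fov_um Optional xy field-of-view crop in micrometres
#'   (e.g. 192).
#' @param adult_depth_um Depth kept for adult sections (default 5; `NULL` or
#'   a depth beyond the stack disables the crop).
#' @param min_sections Per-animal section minimum for aggregation.
#' @return A list with `sections` (per-section results), `cohort`
#'   (per-animal `cohort_table`) and the run report; CSVs are written to
#'   `out_dir`.
#' @export
run_analyze <- function(out_dir, use_truth_masks = FALSE,
                        threshold_method = "otsu", min_voxels = 10,
                        crop_fov_um = NULL, adult_depth_um = 5,
                        min_sections = 6) {
  man_path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(man_path)) stop(sprintf("manifest not found: %s", man_path), call. = FALSE)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  thresholds <- list()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    path <- file.path(out_dir, if (use_truth_masks) m$truth_file else m$file)
    stack <- read_stack(path)
    if (identical(m$age_class, "adult") && !is.null(adult_depth_um) &&
        .px_ceil(adult_depth_um, stack$voxel$dz) < dim(stack$data)[2]) {
      stack <- crop_top_z(stack, adult_depth_um)
    }
    if (!is.null(crop_fov_um)) stack <- crop_xy(stack, crop_fov_um)
    if (use_truth_masks) {
      masks <- lapply(1:3, function(ch) {
        binary_mask(get_channel(stack, ch) > 0.5, stack$voxel,
                    stack$channel_names[ch])
      })
    } else {
      masks <- lapply(stack$channel_names, function(ch) {
        binarize(stack, channel = ch, method = threshold_method)
      })
      thresholds[[sprintf("%s_s%02d", m$animal_id, m$section_index)]] <<-
        lapply(masks, function(mm) mm$threshold)
    }
    engulfment_metrics(masks[[1]], masks[[2]], masks[[3]],
                       marker_kind = m$marker_kind,
                       animal_id = m$animal_id, section_id = m$section_index)
  })
  sections <- do.call(rbind, rows)
  cohort <- aggregate_cohort(sections, manifest, min_sections = min_sections)
  utils::write.csv(sections, file.path(out_dir, "sections.csv"), row.names = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  report <- list(stage = "analyze", use_truth_masks = use_truth_masks,
                 threshold_method = threshold_method,
                 crop_fov_um = crop_fov_um, adult_depth_um = adult_depth_um,
                 min_sections = min_sections, thresholds = thresholds)
  jsonlite::write_json(report, file.path(out_dir, "run_analyze.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(sections = sections, cohort = cohort, report = report))
}

#' Statistical report for a cohort table
#'
#' Runs, for each requested metric: the two-way factorial ANOVA over the
#' incision factors, the configured Sidak-adjusted pairwise comparisons, and
#' BCa bootstrap estimates of each pairwise mean difference. Sexes are pooled
#' for the estimation statistics while remaining available as an ANOVA
#' factor, and the report records alpha, the bootstrap size and the seed.
#'
#' @param cohort A `cohort_table` (or dataset directory containing
#'   `cohort.csv`).
#' @param metrics Metric columns to analyse.
#' @param factors Length-2 character vector of factor columns for the ANOVA.
#' @param comparisons List of group-label pairs for the post-hoc family;
#'   default: the four within-row/column comparisons of the 2x2 incision
#'   design.
#' @param alpha Significance level (default 0.05).
#' @param n_boot,level Bootstrap settings (defaults 5000 and 0.95).
#' @param seed Master seed for all bootstrap streams.
#' @param out_dir If given, writes `stats_report.json` there.
#' @return A list of class `stats_report`.
#' @export
run_stats <- function(cohort, metrics = "percent_engulfed",
                      factors = c("neonatal_incision", "adult_incision"),
                      comparisons = NULL, alpha = 0.05,
                      n_boot = 5000, level = 0.95, seed = 1,
                      out_dir = NULL) {
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- utils::read.csv(file.path(cohort, "cohort.csv"),
                              stringsAsFactors = FALSE)
  }
  cohort <- as.data.frame(cohort)
  for (f in factors) {
    if (!f %in% names(cohort)) {
      stop(sprintf("factor '%s' absent from cohort table", f), call. = FALSE)
    }
  }
  if (is.null(comparisons)) {
    gl <- unique(cohort$group)
    default <- list(c("IN(-,-)", "IN(+,-)"), c("IN(-,+)", "IN(+,+)"),
                    c("IN(-,-)", "IN(-,+)"), c("IN(+,-)", "IN(+,+)"))
    comparisons <- Filter(function(cp) all(cp %in% gl), default)
  }
  per_metric <- lapply(metrics, function(metric) {
    if (!metric %in% names(cohort)) {
      stop(sprintf("metric '%s' absent from cohort table", metric), call. = FALSE)
    }
    av <- two_way_anova(cohort[[metric]], cohort[[factors[1]]],
                        cohort[[factors[2]]], factor_names = factors)
    cmp <- if (length(comparisons)) {
      pairwise_comparisons(cohort, metric, comparisons,
                           n_boot = n_boot, level = level, seed = seed)
    } else NULL
    list(metric = metric, anova = av, comparisons = cmp)
  })
  names(per_metric) <- metrics
  report <- structure(
    list(metrics = per_metric, alpha = alpha, n_boot = n_boot,
         level = level, seed = seed, factors = factors,
         comparison_set = comparisons),
    class = "stats_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      lapply(per_metric, function(m) {
        list(metric = m$metric, anova = as.data.frame(m$anova),
             comparisons = m$comparisons)
      }),
      file.path(out_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE, dataframe = "rows")
  }
  report
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("stats report: alpha = %g, %d bootstrap resamples, seed %d\n",
              x$alpha, x$n_boot, x$seed))
  for (m in x$metrics) {
    cat("\n==", m$metric, "==\n")
    print(m$anova)
    if (!is.null(m$comparisons)) {
      cat("\npost-hoc (Sidak) + BCa estimates:\n")
      print.data.frame(m$comparisons, digits = 4, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Run the full pipeline
#'
#' [run_simulate()], then [run_analyze()], then [run_stats()], driven by one
#' config.
#'
#' @param config List or YAML path; sections `design`, `analyze`, `stats`.
#' @param out_dir Output directory.
#' @return The [run_stats()] report, invisibly.
#' @export
run_all <- function(config, out_dir) {
  cfg <- read_run_config(config)
  run_simulate(cfg, out_dir)
  an_args <- cfg$analyze
  res <- do.call(run_analyze, c(list(out_dir = out_dir), an_args))
  st_args <- cfg$stats
  rep <- do.call(run_stats, c(list(cohort = res$cohort, out_dir = out_dir), st_args))
  invisible(rep)
}
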