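# End-to-end orchestration: read (or simulate) -> align -> features ->
# consensus clustering -> group statistics -> plain-text reports. All
# randomness flows from one root seed, split per stage, so a rerun with the
# same config reproduces every output.

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain trajectories, either by reading every FicTrac log
#' listed in a metadata CSV under `input_dir`, or by simulating the supplied
#' cohort design; (2) extract per-response features; (3) z-score and run
#' Monte-Carlo consensus clustering to select k, assign clusters, and
#' tabulate cluster proportions per treatment and stimulus; (4) compare each
#' feature across treatments with Kruskal-Wallis tests and Bonferroni-adjusted
#' pairwise Mann-Whitney post hocs. Each stage logs row counts; any failure
#' aborts with a stage-named error, leaving earlier outputs in place.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `input_dir` (directory containing `metadata.csv`, `schedule.yaml` and
#'   per-animal `.dat` logs) or `design` (a [cohort_design()]; default
#'   [default_design()]); `output_dir` (required); `k_range`, `reps`, `B`,
#'   `item_frac`, `feature_frac` (clustering settings); `seed` (root seed);
#'   `control` (reference treatment for post hocs, default first level).
#' @param verbose print stage logs (default `TRUE`).
#' @return invisibly, a list with `features`, `k_selection`, `assignments`,
#'   `proportions`, `stats`, and the output file paths.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$output_dir %||% stop_invalid("config$output_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # stage 1+2: features
  features <- stage("features", {
    if (!is.null(config$input_dir)) {
      md_path <- file.path(config$input_dir, "metadata.csv")
      if (!file.exists(md_path))
        stop_invalid("metadata.csv not found in ", config$input_dir)
      metadata <- utils::read.csv(md_path, stringsAsFactors = FALSE)
      schedule <- read_schedule(file.path(config$input_dir, "schedule.yaml"))
      say("features: reading %d trajectories from %s", nrow(metadata),
          config$input_dir)
      rows <- lapply(seq_len(nrow(metadata)), function(i) {
        traj <- read_trackball_log(
          file.path(config$input_dir, basename(metadata$file[i])))
        ft <- extract_features(traj, schedule, t0 = metadata$t0[i],
                               animal_id = metadata$animal_id[i])
        ft$treatment <- metadata$treatment[i]
        ft
      })
      do.call(rbind, rows)
    } else {
      design <- config$design %||% default_design(seed = derive_seed(seed, 2L))
      say("features: simulating cohort (%d animals, %d stimuli)",
          sum(design$n_animals), length(design$schedule$stimuli))
      cohort_features(design)
    }
  })
  feat_path <- file.path(out_dir, "features.csv")
  utils::write.csv(features, feat_path, row.names = FALSE)
  say("features: %d responses written to %s", nrow(features), feat_path)

  # stage 3: clustering
  cluster_res <- stage("cluster", {
    Z <- zscore_features(features)
    say("cluster: %d responses enter clustering (%d excluded for undefined features)",
        nrow(Z), attr(Z, "n_excluded"))
    ks <- select_k(Z, k_range = config$k_range %||% 2:10,
                   reps = config$reps %||% 2000, B = config$B %||% 25,
                   item_frac = config$item_frac %||% 0.9,
                   feature_frac = config$feature_frac %||% 0.8,
                   seed = derive_seed(seed, 3L))
    say("cluster: chosen k = %d", ks$chosen_k)
    M <- consensus_run(Z, ks$chosen_k, reps = config$reps %||% 2000,
                       item_frac = config$item_frac %||% 0.9,
                       feature_frac = config$feature_frac %||% 0.8,
                       seed = derive_seed(seed, 4L))
    labels <- assign_clusters(M, ks$chosen_k)
    kept <- attr(Z, "kept_rows")
    assignments <- data.frame(features[kept, c("animal_id", "stimulus_label")],
                              cluster = labels)
    props <- cluster_proportions(labels, features[kept, ])
    list(k_selection = ks, consensus = M, assignments = assignments,
         proportions = props, kept = kept)
  })
  ks <- cluster_res$k_selection
  jsonlite::write_json(
    list(k_range = ks$k_range, pac = ks$pac,
         mean_null_pac = colMeans(ks$null_pac), rcsi = ks$rcsi,
         p_value = ks$p_value, chosen_k = ks$chosen_k, seed = seed),
    file.path(out_dir, "k_selection.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cluster_res$assignments,
                   file.path(out_dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(cluster_res$proportions,
                   file.path(out_dir, "proportions.csv"), row.names = FALSE)
  utils::write.table(unclass(cluster_res$consensus),
                     file.path(out_dir, "consensus_matrix.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)

  # stage 4: per-feature treatment comparisons
  stats_tab <- stage("stats", {
    feats <- c("ymax", "rotation_asymmetry", "tortuosity", "walking_pace",
               "abs_turning_velocity")
    control <- config$control %||% unique(features$treatment)[1L]
    rows <- lapply(feats, function(f) {
      ok <- is.finite(features[[f]])
      kw <- kruskal_wallis(features[[f]][ok], features$treatment[ok])
      ph <- pairwise_mann_whitney(features[[f]][ok], features$treatment[ok],
                                  ref = control)
      ph$feature <- f
      kw$feature <- f
      list(kw = kw, ph = ph)
    })
    list(kruskal = do.call(rbind, lapply(rows, `[[`, "kw")),
         posthoc = do.call(rbind, lapply(rows, `[[`, "ph")))
  })
  utils::write.csv(stats_tab$kruskal, file.path(out_dir, "kruskal_wallis.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tab$posthoc, file.path(out_dir, "posthoc.csv"),
                   row.names = FALSE)
  say("stats: %d Kruskal-Wallis tests, %d post hoc contrasts",
      nrow(stats_tab$kruskal), nrow(stats_tab$posthoc))

  invisible(list(features = features, k_selection = ks,
                 assignments = cluster_res$assignments,
                 proportions = cluster_res$proportions, stats = stats_tab,
                 output_dir = out_dir))
}
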