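#' Pipeline configuration with study defaults
#'
#' One flat list of every tunable threshold, each defaulting to the study
#' value: silence gate -20 dB over 50-ms frames; 2-s windows with 1-s step;
#' VAD threshold 0.7 on 20-ms frames; 250-ms minimum utterance; 75% window
#' coverage; RR retention band 350-1200 ms; 45-s minimum heart-rate
#' segment; exacerbation score threshold 6; VIF cutoff 20. The F0 search
#' range, voicing threshold, HNR cap and speed of sound are package
#' defaults (the corresponding choices are documented in the methods
#' vignette). The configuration round-trips losslessly through JSON.
#'
#' @param ... overrides of the defaults listed above.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    silence_db = -20, silence_frame_s = 0.050,
    window_s = 2.0, step_s = 1.0,
    vad_threshold = 0.7, vad_frame_s = 0.020,
    min_utterance_s = 0.250, coverage_fraction = 0.75,
    rr_min_ms = 350, rr_max_ms = 1200, min_segment_s = 45,
    exacerbation_threshold = 6, vif_cutoff = 20,
    f0_min = 60, f0_max = 400, voicing_threshold = 0.45,
    hnr_cap = 60, speed_of_sound = 35000,
    p_threshold = 0.05, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "run_config"))
}

#' @rdname run_config
#' @param config a `run_config` to validate.
#' @export
validate_config <- function(config) {
  with(config, {
    stopifnot(vad_threshold >= 0, vad_threshold <= 1,
              window_s > 0, step_s > 0, min_utterance_s >= 0,
              coverage_fraction >= 0, coverage_fraction <= 1,
              rr_min_ms < rr_max_ms, min_segment_s > 0,
              vif_cutoff > 1, f0_min < f0_max,
              p_threshold > 0, p_threshold < 1)
  })
  config
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

# defaults that restate a published study value, for the run manifest
study_defaults <- function(config) {
  data.frame(
    parameter = c("silence_db", "silence_frame_s", "window_s", "step_s",
                  "vad_threshold", "vad_frame_s", "min_utterance_s",
                  "coverage_fraction", "min_segment_s", "rr_min_ms",
                  "rr_max_ms", "exacerbation_threshold", "vif_cutoff"),
    value = unlist(config[c("silence_db", "silence_frame_s", "window_s",
                            "step_s", "vad_threshold", "vad_frame_s",
                            "min_utterance_s", "coverage_fraction",
                            "min_segment_s", "rr_min_ms", "rr_max_ms",
                            "exacerbation_threshold", "vif_cutoff")]),
    study_value = c(-20, 0.050, 2, 1, 0.7, 0.020, 0.250, 0.75, 45, 350,
                    1200, 6, 20),
    description = c(
      "silence gate intensity threshold (dB re full scale)",
      "silence gate sliding frame (s)",
      "analysis window length (s)",
      "window step, 50% overlap (s)",
      "speech-probability binarisation threshold",
      "voice activity detector frame (s)",
      "minimum utterance duration (s)",
      "window speech coverage criterion (fraction of window)",
      "minimum heart-rate segment (s)",
      "RR retention lower bound (ms)",
      "RR retention upper bound (ms)",
      "exacerbation daily-score threshold",
      "variance-inflation-factor cutoff"),
    row.names = NULL)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates a cohort from `spec` (all randomness flows from the spec's
#' seed), z-scores features and covariates, runs the univariate screen for
#' both outcomes, prunes the interaction design by VIF, fits the
#' multivariate interaction models, runs the moderation stratification for
#' each planted feature-moderator pair, and writes every table plus a run
#' manifest (config, seed, package versions, table hashes) into `out_dir`.
#' Identical config and seed produce byte-identical tables.
#'
#' @param config a [run_config()].
#' @param spec a [cohort_spec()]; defaults to `cohort_spec(seed =
#'   config$seed)`.
#' @param out_dir output directory, created if needed.
#' @return (invisibly) list with the analysis table, screen results,
#'   pruning log, multivariate results, moderation tables and file paths.
#' @export
run_pipeline <- function(config = run_config(), spec = NULL,
                         out_dir = tempfile("copdvoice_run_")) {
  if (is.null(spec)) spec <- cohort_spec(seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- gen_cohort(spec)
  zcols <- union(spec$features, spec$covariates)
  tab <- zscore(cohort, zcols)

  screen <- list()
  for (oc in c("score", "exacerbation")) {
    screen[[oc]] <- do.call(rbind, lapply(spec$features, function(f) {
      r <- fit_univariate(tab, f, oc)
      r$outcome <- oc
      r
    }))
  }
  sig_features <- lapply(screen, function(s) {
    s$term[!is.na(s$p_value) & s$p_value < config$p_threshold]
  })

  multi <- list(); prune_logs <- list(); moderation <- list()
  for (oc in c("score", "exacerbation")) {
    feats <- sig_features[[oc]]
    if (!length(feats)) next
    design <- build_interaction_design(feats, spec$covariates)
    pruned <- vif_prune(add_product_columns(tab, design), design,
                        cutoff = config$vif_cutoff)
    prune_logs[[oc]] <- pruned
    res <- fit_multivariate(tab, pruned$retained, oc)
    res$outcome <- oc
    multi[[oc]] <- res
    # moderation for significant feature x moderator two-way interactions
    two_way <- res[grepl(":", res$term) &
                     !grepl(":.*:", res$term) &
                     !is.na(res$p_value) & res$p_value < config$p_threshold, ]
    for (tm in two_way$term) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      f <- intersect(parts, spec$features)
      mzd <- intersect(parts, spec$covariates)
      if (length(f) == 1L && length(mzd) == 1L) {
        md <- moderation_stratify(tab, f, mzd, oc)
        md$outcome <- oc
        md$moderator <- mzd
        moderation[[paste(oc, tm, sep = "|")]] <- md
      }
    }
  }

  paths <- list(
    analysis_table = file.path(out_dir, "analysis_table.csv"),
    screen = file.path(out_dir, "univariate_screen.csv"),
    multivariate = file.path(out_dir, "multivariate_models.csv"),
    moderation = file.path(out_dir, "moderation_strata.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_table_csv(tab, paths$analysis_table)
  write_table_csv(render_reports(do.call(rbind, screen)), paths$screen)
  if (length(multi)) {
    write_table_csv(render_reports(do.call(rbind, multi)),
                    paths$multivariate)
  }
  if (length(moderation)) {
    mod_all <- do.call(rbind, moderation)
    rownames(mod_all) <- NULL
    write_table_csv(render_reports(mod_all), paths$moderation)
  }
  gt <- attr(cohort, "ground_truth")
  jsonlite::write_json(
    list(seed = spec$seed,
         spec = unclass(gt$spec),
         random_intercepts = as.list(gt$random_intercepts)),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    list(config = unclass(config),
         study_defaults = study_defaults(config),
         versions = list(copdvoice = as.character(
           utils::packageVersion("copdvoice")),
           R = paste(R.version$major, R.version$minor, sep = ".")),
         table_md5 = as.list(tools::md5sum(unlist(paths[c(
           "analysis_table", "screen")])))),
    paths$manifest, auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(table = tab, screen = screen, sig_features = sig_features,
                 prune_logs = prune_logs, multivariate = multi,
                 moderation = moderation, paths = paths, out_dir = out_dir))
}
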