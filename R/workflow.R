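# Workflow orchestration: one reproducible run from synthetic cohort
# generation (or a fingerprints CSV) through classification to a JSON
# report. Reports carry the config hash and contain no timestamps, so a
# rerun with the same config and seed is byte-identical.

#' Build a run configuration
#'
#' @param seed Master seed for every random stage.
#' @param positive_classes Cancer classes to classify against the negative
#'   class (each fitted separately).
#' @param negative_class Negative (control) class label.
#' @param n_donors Named donor counts per class (see
#'   [default_class_specs()]).
#' @param blind_validation_n Donors per class in the generated blind
#'   holdout (0 disables blind validation).
#' @param fingerprints_csv Optional path to a fingerprints CSV
#'   (`donor_id, class, starting_position_mm, levitating_area`); when given,
#'   generation is skipped and the CSV is analysed instead.
#' @param ellipse_level Confidence-ellipse coverage level.
#' @return List of class `maglev_run_config`.
#' @export
maglev_run_config <- function(seed = 1,
                              positive_classes = c("breast", "prostate",
                                                   "colorectal", "PDAC"),
                              negative_class = "NOP",
                              n_donors = c(NOP = 15, breast = 5,
                                           prostate = 5, colorectal = 5,
                                           PDAC = 15),
                              blind_validation_n = 5,
                              fingerprints_csv = NULL,
                              ellipse_level = 0.95) {
  structure(list(seed = seed, positive_classes = positive_classes,
                 negative_class = negative_class,
                 n_donors = as.list(n_donors),
                 blind_validation_n = blind_validation_n,
                 fingerprints_csv = fingerprints_csv,
                 ellipse_level = ellipse_level),
            class = "maglev_run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of [maglev_run_config()].
#' @return A `maglev_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("seed", "positive_classes", "negative_class", "n_donors")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  do.call(maglev_run_config, raw)
}

.config_hash <- function(config)
  fnv1a_hash(unlist(config[order(names(unlist(config)))], use.names = TRUE))

#' Run the full analysis workflow
#'
#' Generate (or load) a fingerprint cohort, fit one LDA per cancer class
#' against the negative class, compute confusion counts and metrics, the
#' pairwise p-value heatmap of starting positions, per-class confidence
#' ellipses, and optionally a blind validation on freshly generated holdout
#' donors. Writes `report.json` and `fingerprints.csv` to `output_dir` when
#' given.
#'
#' @param config A [maglev_run_config()].
#' @param output_dir Optional output directory.
#' @return Invisible list of artifacts: `cohort`, `models`, `results`,
#'   `pvalues`, `ellipses`, `blind`, `report`.
#' @export
run_full <- function(config = maglev_run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "maglev_run_config"))
  if (!is.null(config$fingerprints_csv)) {
    df <- utils::read.csv(config$fingerprints_csv)
    need <- c("donor_id", "class", "starting_position_mm", "levitating_area")
    if (!all(need %in% names(df)))
      stop("fingerprints CSV must have columns: ", paste(need, collapse = ", "))
    cohort <- maglev_cohort(df[, c("starting_position_mm", "levitating_area")],
                            df$class, df$donor_id)
  } else {
    specs <- default_class_specs(n_donors = unlist(config$n_donors))
    cohort <- generate_fingerprint_cohort(specs, seed = config$seed)$cohort
  }
  neg <- config$negative_class
  models <- list(); results <- list(); blind <- NULL
  for (pos in config$positive_classes) {
    m <- lda_fit(cohort, positive_class = pos, negative_class = neg)
    sub <- subset_cohort(cohort, c(neg, pos))
    cls <- lda_classify(m, sub$points, sub$labels)
    models[[pos]] <- m
    results[[pos]] <- list(confusion = cls$confusion,
                           metrics = classification_metrics(cls$confusion))
  }
  pvals <- pairwise_pvalue_matrix(cohort)
  classes <- unique(cohort$labels)
  ellipses <- lapply(stats::setNames(classes, classes), function(cl) {
    pts <- cohort$points[cohort$labels == cl, , drop = FALSE]
    if (nrow(pts) >= 3) confidence_ellipse(pts, config$ellipse_level) else NULL
  })
  if (is.null(config$fingerprints_csv) && config$blind_validation_n > 0 &&
      "PDAC" %in% config$positive_classes) {
    hspecs <- default_class_specs(
      n_donors = c(NOP = config$blind_validation_n, breast = 0,
                   prostate = 0, colorectal = 0,
                   PDAC = config$blind_validation_n))
    hspecs <- Filter(function(s) s$n_donors > 0, hspecs)
    hold <- generate_fingerprint_cohort(hspecs,
                                        seed = config$seed + 10000)$cohort
    hold$donor_ids <- paste0("holdout_", hold$donor_ids)
    blind <- blind_validation(models[["PDAC"]], hold)
  }
  artifacts <- list(cohort = cohort, models = models, results = results,
                    pvalues = pvals, ellipses = ellipses, blind = blind,
                    config = config)
  artifacts$report <- make_report(artifacts, output_dir)
  invisible(artifacts)
}

#' Assemble (and optionally write) the run report
#'
#' @param artifacts Output of [run_full()] (a list with `cohort`, `models`,
#'   `results`, `pvalues`, `ellipses`, `config`, optionally `blind`).
#' @param output_dir Directory for `report.json` and `fingerprints.csv`;
#'   `NULL` to skip writing.
#' @return The report list, invisibly when writing.
#' @export
make_report <- function(artifacts, output_dir = NULL) {
  need <- c("cohort", "models", "results", "pvalues", "config")
  missing <- setdiff(need, names(artifacts))
  if (length(missing))
    stop("artifacts missing: ", paste(missing, collapse = ", "))
  cfg <- artifacts$config
  report <- list(
    schema_version = "maglevneb-report-1",
    config = unclass(cfg),
    config_hash = .config_hash(cfg),
    n_donors = as.list(table(artifacts$cohort$labels)),
    classification = lapply(artifacts$models, function(m) NULL),
    pvalue_matrix = list(classes = rownames(artifacts$pvalues),
                         p = unname(apply(artifacts$pvalues, 1, as.list)))
  )
  for (pos in names(artifacts$models)) {
    m <- artifacts$models[[pos]]
    r <- artifacts$results[[pos]]
    report$classification[[pos]] <- list(
      weights = unname(m$weights), threshold = m$threshold,
      confusion = unclass(r$confusion),
      metrics = r$metrics[c("specificity", "sensitivity", "accuracy")])
  }
  report$ellipses <- lapply(artifacts$ellipses, function(e) {
    if (is.null(e)) return(NULL)
    list(center = unname(e$center), semi_axes = unname(e$semi_axes),
         orientation = e$orientation, level = e$level)
  })
  if (!is.null(artifacts$blind))
    report$blind_validation <- list(
      confusion = unclass(artifacts$blind$confusion),
      metrics = artifacts$blind$metrics[c("specificity", "sensitivity",
                                          "accuracy")],
      provenance = artifacts$blind$provenance)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    utils::write.csv(as.data.frame(artifacts$cohort),
                     file.path(output_dir, "fingerprints.csv"),
                     row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' One-command demo run
#'
#' Generates the default synthetic five-class cohort (15 controls, 5
#' breast, 5 prostate, 5 colorectal, 15 PDAC donors), classifies every
#' cancer class against the controls, and writes the report.
#'
#' @param seed Master seed.
#' @param output_dir Output directory (default: a fresh temp directory).
#' @return Invisible artifact list from [run_full()].
#' @export
maglev_demo <- function(seed = 1, output_dir = tempfile("maglev_demo_")) {
  run_full(maglev_run_config(seed = seed), output_dir = output_dir)
}
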