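#' Pipeline configuration
#'
#' @param kinetics A [kinetics_config()].
#' @param qc_window_s,qc_threshold_cm Movement-exclusion rule (default the
#'   protocol's > 1 cm within the initial 180 s).
#' @param run_qc Run the motion QC stage (default `TRUE`).
#' @param qc_frames `"window"` (default) estimates drift only for frames
#'   inside the decision window — the frames the rule consults —, `"all"`
#'   profiles every frame.
#' @param pixel_dispersion Attach per-pixel dispersion summaries to region
#'   parameters (slower; default `FALSE` at cohort scale).
#' @param stimulation_limbs Limb types paired for the stimulation response
#'   (default hands only).
#' @param stats_parameters Parameters compared across groups.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(kinetics = kinetics_config(),
                            qc_window_s = 180, qc_threshold_cm = 1.0,
                            run_qc = TRUE,
                            qc_frames = c("window", "all"),
                            pixel_dispersion = FALSE,
                            stimulation_limbs = "hand",
                            stats_parameters = c("bfi", "i_max", "mtt", "auc")) {
  qc_frames <- match.arg(qc_frames)
  structure(list(kinetics = kinetics, qc_window_s = qc_window_s,
                 qc_threshold_cm = qc_threshold_cm, run_qc = run_qc,
                 qc_frames = qc_frames, pixel_dispersion = pixel_dispersion,
                 stimulation_limbs = stimulation_limbs,
                 stats_parameters = stats_parameters),
            class = "pipeline_config")
}

#' Run the full analysis pipeline over a cohort
#'
#' Orchestrates the stages in acquisition order: motion QC (excluded limbs
#' are reported and dropped, never silently lost), digit/dorsum region
#' kinetics on every surviving stack, rest/post stimulation pairing, and
#' the group statistics. Works on an in-memory [generate_cohort()] object
#' (stacks regenerated per item from recorded seeds) or on a written
#' manifest (data frame with a `path` column of TIFF files plus key
#' columns).
#'
#' @param cohort An `icg_cohort`, or a manifest data frame with columns
#'   `item_id`, `subject`, `group`, `limb`, `side`, `condition`, `path`.
#' @param config A [pipeline_config()].
#' @param labels Optional label matrix for manifest input (defaults to the
#'   generator's layout matching the first stack's geometry).
#' @param progress Print a line per processed stack.
#' @return Object of class `icg_results`: `limb_params` (per item x region
#'   kinetic parameters), `responses` / `scatter` (stimulation, or NULL),
#'   `stats` (group comparison table, or NULL), `qc` (per-item decisions),
#'   `report` (counts, config echo, no-record-loss accounting).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), labels = NULL,
                         progress = FALSE) {
  in_memory <- inherits(cohort, "icg_cohort")
  manifest <- if (in_memory) cohort$manifest else cohort
  if (!in_memory) {
    need <- c("item_id", "subject", "group", "limb", "side", "condition", "path")
    miss <- setdiff(need, names(manifest))
    if (length(miss)) stop("manifest is missing columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  n_items <- nrow(manifest)
  qc_rows <- NULL
  limb_rows <- NULL
  failed <- character(0)

  for (i in seq_len(n_items)) {
    row <- manifest[i, ]
    res <- tryCatch({
      if (in_memory) {
        gs <- cohort_stack(cohort, i)
        stack <- gs$stack
        rset <- gs$regions
      } else {
        stack <- read_stack(row$path)
        lab <- if (is.null(labels)) limb_label_image(dim(stack$frames)[1],
                                                     dim(stack$frames)[2]) else labels
        rset <- region_set(lab, limb = row$limb, side = row$side)
      }

      decision <- "pass"; max_drift <- NA_real_
      if (config$run_qc) {
        frames <- if (config$qc_frames == "window") {
          which(stack$times <= config$qc_window_s)
        } else NULL
        prof <- estimate_displacement(stack, frames = frames)
        qc <- movement_exclusion(prof, config$qc_window_s,
                                 config$qc_threshold_cm)
        decision <- qc$decision
        max_drift <- qc$max_drift_cm
      }
      qrow <- data.frame(row[c("item_id", "subject", "group", "limb",
                               "side", "condition")],
                         decision = decision, max_drift_cm = max_drift,
                         stringsAsFactors = FALSE)

      lrows <- NULL
      if (decision == "pass") {
        for (rg in c("digit", "dorsum")) {
          mask <- if (rg == "digit") rset$digit_mask else rset$dorsum_mask
          rp <- region_params(stack, mask, config$kinetics,
                              pixel_dispersion = config$pixel_dispersion)
          pr <- as.data.frame(rp$params)
          lrows <- rbind(lrows, data.frame(
            row[c("item_id", "subject", "group", "limb", "side", "condition")],
            region = rg, pr, n_pixels = rp$n_pixels,
            flags = paste(rp$flags, collapse = ";"),
            stringsAsFactors = FALSE))
        }
      }
      list(qrow = qrow, lrows = lrows)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      failed <- c(failed, row$item_id)
      warning(sprintf("stack '%s' failed and was skipped: %s",
                      row$item_id, conditionMessage(res)), call. = FALSE)
      next
    }
    qc_rows <- rbind(qc_rows, res$qrow)
    limb_rows <- rbind(limb_rows, res$lrows)
    if (progress) cat(sprintf("[%d/%d] %s: %s\n", i, n_items, row$item_id,
                              res$qrow$decision))
  }

  responses <- NULL
  scatter <- NULL
  if (!is.null(limb_rows) &&
      any(limb_rows$limb %in% config$stimulation_limbs) &&
      all(c("rest", "post") %in% limb_rows$condition)) {
    sr <- pair_conditions(limb_rows, limbs = config$stimulation_limbs)
    responses <- sr$responses
    if (nrow(responses)) scatter <- response_scatter(sr)
  }

  stats <- NULL
  if (!is.null(limb_rows)) {
    rest <- limb_rows[limb_rows$condition == "rest" & limb_rows$valid, ]
    if (nrow(rest) && length(unique(rest$group)) >= 2) {
      stats <- group_stats_table(rest, parameters = config$stats_parameters)
    }
  }

  excluded <- if (is.null(qc_rows)) character(0) else
    qc_rows$item_id[qc_rows$decision == "exclude"]
  analyzed <- if (is.null(qc_rows)) character(0) else
    qc_rows$item_id[qc_rows$decision == "pass"]
  report <- list(n_items = n_items,
                 n_analyzed = length(analyzed),
                 n_excluded = length(excluded),
                 n_failed = length(failed),
                 excluded = excluded, failed = failed,
                 qc_rule = list(window_s = config$qc_window_s,
                                threshold_cm = config$qc_threshold_cm,
                                enabled = config$run_qc),
                 record_accounting = length(analyzed) + length(excluded) +
                   length(failed) == n_items)

  structure(list(limb_params = limb_rows, responses = responses,
                 scatter = scatter, stats = stats, qc = qc_rows,
                 report = report),
            class = "icg_results")
}

#' @export
print.icg_results <- function(x, ...) {
  r <- x$report
  cat(sprintf("<icg_results> %d items: %d analyzed, %d excluded, %d failed\n",
              r$n_items, r$n_analyzed, r$n_excluded, r$n_failed))
  if (!is.null(x$stats)) {
    sig <- vapply(x$stats$comparisons, function(cmp) cmp$p_value, 0)
    cat("  group comparisons (overall p): ",
        paste(sprintf("%s=%.2g", names(sig), sig), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' CSV tables (per-limb parameters, stimulation responses, scatter table,
#' group statistics), a QC JSON and a run-report JSON.
#'
#' @param results An `icg_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_results_bundle <- function(results, dir) {
  stopifnot(inherits(results, "icg_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(results$limb_params)) wcsv(results$limb_params, "limb_params.csv")
  if (!is.null(results$responses)) wcsv(results$responses, "responses.csv")
  if (!is.null(results$scatter)) wcsv(results$scatter, "scatter.csv")
  if (!is.null(results$stats)) wcsv(results$stats$table, "group_stats.csv")
  if (!is.null(results$qc)) {
    p <- file.path(dir, "qc.json")
    jsonlite::write_json(results$qc, p, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "run_report.json")
  jsonlite::write_json(results$report, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
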