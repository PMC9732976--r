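#' Configuration of a full surrogate Taguchi study
#'
#' Bundles every setting of the end-to-end study: the experiment design, the
#' replicate structure, the synthetic scene sets standing in for the
#' training and test images, the quality model and surrogate detector, and
#' the evaluation thresholds. Defaults give a desk-scale study (36 training
#' and 48 test scenes per replicate, re-drawn every replicate) that runs in
#' seconds; the test set gets the larger scene budget because the response
#' analysis consumes test-set SNR while training-set mAP is descriptive.
#'
#' @param space [factor_space()] of the tuned hyperparameters.
#' @param oa [orthogonal_array()] with one column per factor.
#' @param replicates independent replicates per run (>= 2; 3 matches the
#'   reference study).
#' @param m SNR target score (1 = perfect mAP).
#' @param analysis_set which dataset's SNR drives the response table and
#'   ANOVA: `"test"` (default) or `"training"`.
#' @param n_train,n_test scenes per replicate in each set.
#' @param scene a [scene_config()].
#' @param qm a [quality_model()].
#' @param surrogate a [surrogate_config()].
#' @param iou_threshold IoU matching threshold for evaluation.
#' @param confidence_threshold confidence cut for the counting report.
#' @param resample_scenes draw fresh scene sets every replicate (default)
#'   or reuse one fixed pair of sets across all runs and replicates.
#' @param seed master seed; all child seeds derive from it via
#'   [child_seed()].
#' @return A `study_config` list.
#' @export
study_config <- function(space = ssd_factor_space(), oa = l9_array(),
                         replicates = 3, m = 1, analysis_set = "test",
                         n_train = 36, n_test = 48,
                         scene = scene_config(),
                         qm = default_quality_model(),
                         surrogate = surrogate_config(),
                         iou_threshold = 0.5, confidence_threshold = 0.5,
                         resample_scenes = TRUE, seed = 1) {
  stopifnot(replicates >= 2, analysis_set %in% c("test", "training"),
            n_train >= 1, n_test >= 1)
  structure(list(
    space = space, oa = oa, replicates = replicates, m = m,
    analysis_set = analysis_set, n_train = n_train, n_test = n_test,
    scene = scene, qm = qm, surrogate = surrogate,
    iou_threshold = iou_threshold,
    confidence_threshold = confidence_threshold,
    resample_scenes = resample_scenes, seed = seed
  ), class = "study_config")
}

# one (run, replicate): quality draw, scene sets, surrogate detection,
# mAP on both sets. run_idx 0 is reserved for the validation stage.
run_replicate <- function(cfg, levels_vec, run_idx, rep_idx,
                          fixed_sets = NULL) {
  q <- quality_response(levels_vec, cfg$qm,
                        seed = child_seed(cfg$seed, run_idx, rep_idx, 1))
  sets <- if (is.null(fixed_sets)) {
    list(
      training = generate_scene_set(cfg$scene, cfg$n_train,
                                    seed = child_seed(cfg$seed, run_idx,
                                                      rep_idx, 2),
                                    prefix = "tr"),
      test = generate_scene_set(cfg$scene, cfg$n_test,
                                seed = child_seed(cfg$seed, run_idx,
                                                  rep_idx, 3),
                                prefix = "te")
    )
  } else fixed_sets
  out <- list(q = q)
  for (tag in c("training", "test")) {
    det <- surrogate_detect_set(
      sets[[tag]], q, cfg$surrogate,
      seed = child_seed(cfg$seed, run_idx, rep_idx,
                        if (tag == "training") 4 else 5),
      diameters = cfg$scene$diameters)
    ev <- evaluate_detections(det, sets[[tag]]$gt,
                              iou_threshold = cfg$iou_threshold)
    out[[tag]] <- list(map = ev$map, det = det, gt = sets[[tag]]$gt)
  }
  out
}

#' Run a complete surrogate Taguchi study
#'
#' Executes every stage of the tuning study: builds the experiment plan;
#' for each run and replicate draws per-class detector quality from the
#' quality model, generates training and test scene sets, runs the
#' surrogate detector and scores mAP; summarizes replicates (mean, sample
#' SD, SNR); builds the response table on the configured dataset; infers
#' the best factor-level combination; re-runs that combination as a
#' validation experiment; and decomposes the SNR variability with the
#' Taguchi ANOVA. Fully deterministic given the master seed.
#'
#' @param cfg a [study_config()].
#' @return A `study_report` list: `plan`, `scores` (long raw mAP table),
#'   `summary` (per-run mean/SD/eta for both sets), `response`, `best`,
#'   `validation` (replicate summary at the best combination),
#'   `predicted_eta` (the additive-model SNR prediction for that
#'   combination, to compare against the re-run validation), `anova`,
#'   `counts` (counting report on the final validation test set), `config`.
#' @examples
#' \donttest{
#' rep <- run_study(study_config(n_train = 4, n_test = 4, seed = 1))
#' rep$best
#' }
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  plan <- build_plan(cfg$oa, cfg$space)
  lev <- attr(plan, "levels")

  fixed_sets <- NULL
  if (!cfg$resample_scenes) {
    fixed_sets <- list(
      training = generate_scene_set(cfg$scene, cfg$n_train,
                                    seed = child_seed(cfg$seed, 0, 0, 2),
                                    prefix = "tr"),
      test = generate_scene_set(cfg$scene, cfg$n_test,
                                seed = child_seed(cfg$seed, 0, 0, 3),
                                prefix = "te")
    )
  }

  score_rows <- list()
  for (i in seq_len(nrow(cfg$oa))) {
    for (t in seq_len(cfg$replicates)) {
      res <- run_replicate(cfg, lev[i, ], i, t, fixed_sets)
      for (tag in c("training", "test")) {
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          run_id = i, dataset = tag, replicate = t,
          score = res[[tag]]$map, stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, score_rows)
  summary <- summarize_scores(scores, m = cfg$m)

  etas_df <- summary[summary$dataset == cfg$analysis_set, ]
  etas <- etas_df$eta[order(etas_df$run_id)]
  rt <- response_table(cfg$oa, etas, cfg$space)
  best <- best_combination(rt)
  av <- taguchi_anova(cfg$oa, etas, cfg$space)

  val_rows <- list()
  last <- NULL
  for (t in seq_len(cfg$replicates)) {
    last <- run_replicate(cfg, rt$best_level, 0L, t, fixed_sets)
    for (tag in c("training", "test")) {
      val_rows[[length(val_rows) + 1L]] <- data.frame(
        run_id = 0L, dataset = tag, replicate = t,
        score = last[[tag]]$map, stringsAsFactors = FALSE)
    }
  }
  val_scores <- do.call(rbind, val_rows)
  validation <- summarize_scores(val_scores, m = cfg$m)
  # additive-model prediction of the best combination's SNR, for comparison
  # with the re-run validation above (the report's headline number)
  predicted_eta <- av$grand_mean +
    sum(rt$maximum - av$grand_mean)
  counts <- count_cells(last$test$det, last$test$gt,
                        cfg$confidence_threshold)

  structure(list(
    plan = plan, scores = scores, summary = summary,
    response = rt, best = best,
    validation = validation, validation_scores = val_scores,
    predicted_eta = predicted_eta,
    anova = av, counts = counts,
    eta_capped = any(summary$eta_capped),
    config = cfg
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Surrogate Taguchi study report\n")
  cat(sprintf("  runs: %d, replicates: %d, analysis set: %s, seed: %s\n",
              nrow(x$config$oa), x$config$replicates,
              x$config$analysis_set, format(x$config$seed)))
  print(x$response)
  cat("\nValidation at the best combination:\n")
  val <- x$validation
  val$mean <- round(val$mean, 4); val$sd <- round(val$sd, 4)
  val$eta <- round(val$eta, 4)
  print(as.data.frame(val)[c("dataset", "n", "mean", "sd", "eta")],
        row.names = FALSE)
  cat(sprintf("Additive-model predicted eta (%s set): %.4f dB\n",
              x$config$analysis_set, x$predicted_eta))
  cat("\n")
  print(x$anova)
  if (x$eta_capped) {
    cat("Note: at least one run hit the SNR ceiling (mean score equal to",
        "the target); its eta is capped.\n")
  }
  invisible(x)
}

compare_cell <- function(table, cell, printed, recomputed, tol) {
  data.frame(table = table, cell = cell, printed = printed,
             recomputed = recomputed, diff = recomputed - printed,
             pass = is.finite(recomputed) &
               abs(recomputed - printed) <= tol,
             stringsAsFactors = FALSE)
}

#' Recompute and check every derived value of the reference study tables
#'
#' From the embedded raw replicate mAP scores alone, recomputes all derived
#' cells of the reference result tables — per-run means, sample SDs and SNR
#' values, the full response table (entries, effects, maxima, best levels
#' and values), the Taguchi ANOVA (sums of squares, variances, expected
#' sums of squares, percentage contributions, total), the validation and
#' comparison condition summaries, and the platelet counting accuracy — and
#' compares each against the printed value.
#'
#' @param fx fixture list from [ssd_study_tables()].
#' @param tol_value absolute tolerance for 4-decimal quantities.
#' @param tol_pct absolute tolerance for percentage contributions.
#' @return A `reference_reproduction` list: `comparisons` (data frame with
#'   one row per checked cell), `pass`, plus the recomputed `summary`,
#'   `response`, `anova` and condition summaries.
#' @examples
#' rr <- reproduce_reference_study()
#' rr$pass
#' @export
reproduce_reference_study <- function(fx = ssd_study_tables(),
                                      tol_value = 5e-4, tol_pct = 0.005) {
  space <- ssd_factor_space()
  oa <- l9_array()
  cmp <- list()
  add <- function(x) cmp[[length(cmp) + 1L]] <<- x

  # per-run summaries from raw replicates
  summary <- summarize_scores(fx$scores)
  for (i in seq_len(nrow(fx$summary))) {
    pr <- fx$summary[i, ]
    rc <- summary[summary$run_id == pr$run_id &
                  summary$dataset == pr$dataset, ]
    tag <- sprintf("run%d_%s", pr$run_id, pr$dataset)
    add(compare_cell("summary", paste0(tag, "_mean"), pr$mean, rc$mean,
                     tol_value))
    add(compare_cell("summary", paste0(tag, "_sd"), pr$sd, rc$sd,
                     tol_value))
    add(compare_cell("summary", paste0(tag, "_eta"), pr$eta, rc$eta,
                     tol_value))
  }

  # response table from the recomputed (unrounded) test-set etas
  test_sum <- summary[summary$dataset == "test", ]
  etas <- test_sum$eta[order(test_sum$run_id)]
  rt <- response_table(oa, etas, space)
  for (f in seq_len(nrow(rt$E))) {
    for (l in 1:3) {
      add(compare_cell("response", sprintf("E_%s_L%d", rownames(rt$E)[f], l),
                       fx$response$E[f, l], rt$E[f, l], tol_value))
    }
    add(compare_cell("response", paste0("effect_", rownames(rt$E)[f]),
                     fx$response$effect[f], rt$effect[[f]], tol_value))
    add(compare_cell("response", paste0("maximum_", rownames(rt$E)[f]),
                     fx$response$maximum[f], rt$maximum[[f]], tol_value))
    add(compare_cell("response", paste0("best_level_", rownames(rt$E)[f]),
                     fx$response$best_level[f], rt$best_level[[f]], 0))
  }
  best_value_ok <- identical(
    lapply(rt$best_value, as.character),
    lapply(fx$response$best_value, as.character))
  add(data.frame(table = "response", cell = "best_values",
                 printed = NA_real_, recomputed = NA_real_, diff = NA_real_,
                 pass = best_value_ok, stringsAsFactors = FALSE))

  # ANOVA from the same etas
  av <- taguchi_anova(oa, etas, space)
  fac <- rownames(fx$anova$table)
  for (f in fac) {
    add(compare_cell("anova", paste0("SS_", f), fx$anova$table[f, "SS"],
                     av$table[f, "SS"], tol_value))
    add(compare_cell("anova", paste0("V_", f), fx$anova$table[f, "V"],
                     av$table[f, "V"], tol_value))
    add(compare_cell("anova", paste0("expected_SS_", f),
                     fx$anova$table[f, "expected_SS"],
                     av$table[f, "expected_SS"], tol_value))
    add(compare_cell("anova", paste0("pct_", f), fx$anova$table[f, "pct"],
                     av$table[f, "pct"], tol_pct))
  }
  add(compare_cell("anova", "error_SS", fx$anova$error_SS,
                   av$table["Error", "SS"], tol_value))
  add(compare_cell("anova", "S_T", fx$anova$S_T,
                   av$table["Total", "SS"], tol_value))

  # validation / comparison conditions
  conditions <- list(validation = fx$validation, size300 = fx$size300,
                     matlab_default = fx$matlab_default)
  cond_sums <- list()
  for (nm in names(conditions)) {
    cs <- summarize_scores(conditions[[nm]]$scores)
    cond_sums[[nm]] <- cs
    for (tag in c("training", "test")) {
      pr <- conditions[[nm]]$summary
      pr <- pr[pr$dataset == tag, ]
      rc <- cs[cs$dataset == tag, ]
      add(compare_cell(nm, paste0(tag, "_mean"), pr$mean, rc$mean,
                       tol_value))
      add(compare_cell(nm, paste0(tag, "_sd"), pr$sd, rc$sd, tol_value))
      add(compare_cell(nm, paste0(tag, "_eta"), pr$eta, rc$eta, tol_value))
    }
  }

  # counting accuracy from the recorded counts (76% for platelets)
  acc <- 100 * fx$counts$n_detected / fx$counts$n_gt
  add(compare_cell("counts", "platelet_accuracy_pct", 76,
                   acc[fx$counts$class == "Platelets"], tol_pct))

  comparisons <- do.call(rbind, cmp)
  rownames(comparisons) <- NULL
  structure(list(
    comparisons = comparisons, pass = all(comparisons$pass),
    summary = summary, response = rt, anova = av,
    conditions = cond_sums
  ), class = "reference_reproduction")
}

#' @export
print.reference_reproduction <- function(x, ...) {
  cat(sprintf("Reference-table reproduction: %s (%d/%d cells)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$comparisons$pass), nrow(x$comparisons)))
  if (!x$pass) {
    bad <- x$comparisons[!x$comparisons$pass, ]
    cat("Mismatching cells:\n")
    print(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two experimental conditions side by side
#'
#' Lines up the per-dataset mean score, SD and SNR of two conditions (e.g.
#' 512 x 512 versus 300 x 300 inputs, or Taguchi-tuned versus toolbox
#' defaults) and reports their differences.
#'
#' @param a,b condition summaries: `replicate_summary` data frames (as
#'   returned by [summarize_scores()]), `study_report`s (their validation
#'   summaries are used), or fixture conditions with a `scores` element.
#' @param labels length-2 character vector naming the conditions.
#' @return A data frame with one row per dataset tag: means, SDs, etas for
#'   both conditions and `diff_mean` / `diff_eta` (`a - b`).
#' @examples
#' fx <- ssd_study_tables()
#' compare_conditions(fx$validation, fx$size300, c("512", "300"))
#' @export
compare_conditions <- function(a, b, labels = c("a", "b")) {
  as_summary <- function(x) {
    if (inherits(x, "study_report")) return(x$validation)
    if (is.list(x) && !is.data.frame(x) && !is.null(x$scores)) {
      return(summarize_scores(x$scores))
    }
    if (is.data.frame(x) && all(c("dataset", "mean", "eta") %in% names(x))) {
      return(x)
    }
    stop("cannot interpret a condition of class ",
         paste(class(x), collapse = "/"))
  }
  sa <- as_summary(a); sb <- as_summary(b)
  tags <- intersect(unique(sa$dataset), unique(sb$dataset))
  if (!length(tags)) stop("the two conditions share no dataset tag")
  rows <- lapply(tags, function(tag) {
    ra <- sa[sa$dataset == tag, ][1, ]
    rb <- sb[sb$dataset == tag, ][1, ]
    data.frame(dataset = tag,
               mean_a = ra$mean, mean_b = rb$mean,
               diff_mean = ra$mean - rb$mean,
               sd_a = ra$sd, sd_b = rb$sd,
               eta_a = ra$eta, eta_b = rb$eta,
               diff_eta = ra$eta - rb$eta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", labels[1]),
                    sub("_b$", paste0("_", labels[2]), names(out)))
  out
}

#' Write the aggregated study report as JSON plus delimited tables
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plan(report$plan, file.path(dir, "plan.tsv"))
  utils::write.table(report$scores, file.path(dir, "raw_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_report_table(report$summary, file.path(dir, "summary.tsv"))
  write_report_table(report$response, file.path(dir, "response_table.tsv"))
  write_report_table(report$anova, file.path(dir, "anova.tsv"))
  write_report_table(report$validation, file.path(dir, "validation.tsv"))
  utils::write.table(report$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  agg <- list(
    seed = report$config$seed,
    replicates = report$config$replicates,
    analysis_set = report$config$analysis_set,
    best = as.data.frame(report$best),
    validation = as.data.frame(report$validation),
    anova_pct = stats::setNames(
      report$anova$table$pct, rownames(report$anova$table)),
    eta_capped = report$eta_capped
  )
  jsonlite::write_json(agg, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
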