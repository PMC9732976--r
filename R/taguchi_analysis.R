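#' Deviation-from-target signal-to-noise ratio in decibels
#'
#' Computes the Taguchi SNR eta = -10 * log10((ybar - m)^2) where `ybar` is
#' the replicate mean and `m` the target score (1, i.e. a perfect mAP, by
#' default). Equivalently -20 * log10(|ybar - m|): eta grows as the mean
#' approaches the target, by 20 dB per decade of deviation.
#'
#' When the mean hits the target exactly the ratio is unbounded; the
#' configured ceiling (200 dB by default) is returned instead and flagged via
#' the `"capped"` attribute so it can never silently enter a response table.
#'
#' @param values numeric vector of replicate scores in `[0, 1]`.
#' @param m target score.
#' @param ceiling_db value returned when `mean(values) == m`.
#' @return eta in dB, with logical attribute `capped`.
#' @examples
#' snr_target(c(0.7179, 0.7113, 0.6713)) # 10.4624
#' snr_target(c(0.9, 0.9, 0.9))          # 20
#' @export
snr_target <- function(values, m = 1, ceiling_db = 200) {
  if (!length(values)) stop("`values` must be non-empty")
  if (anyNA(values)) stop("`values` contains NA")
  ybar <- mean(values)
  if (ybar == m) {
    return(structure(ceiling_db, capped = TRUE))
  }
  structure(-10 * log10((ybar - m)^2), capped = FALSE)
}

#' Summarize a replicate set: mean, sample SD and SNR
#'
#' @param values numeric vector of replicate scores (length >= 2, needed for
#'   the n-1 standard deviation).
#' @param m target score for [snr_target()].
#' @param run_id,dataset identifiers carried into the output row.
#' @param ceiling_db see [snr_target()].
#' @return A one-row `replicate_summary` data frame with columns `run_id`,
#'   `dataset`, `n`, `mean`, `sd`, `eta`, `eta_capped`. Values are exact;
#'   rounding happens only in print/format methods.
#' @examples
#' summarize_replicates(c(0.7179, 0.7113, 0.6713), run_id = 1)
#' @export
summarize_replicates <- function(values, m = 1, run_id = NA_integer_,
                                 dataset = "test", ceiling_db = 200) {
  if (length(values) < 2L) {
    stop("need at least 2 replicates for a sample standard deviation")
  }
  eta <- snr_target(values, m = m, ceiling_db = ceiling_db)
  out <- data.frame(
    run_id = run_id, dataset = dataset, n = length(values),
    mean = mean(values), sd = stats::sd(values),
    eta = as.numeric(eta), eta_capped = isTRUE(attr(eta, "capped")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' Summarize a long table of replicate scores into run-level rows
#'
#' Input mirrors how a study records its raw results: one row per
#' (run, dataset, replicate) with the score. Output has one row per
#' (run, dataset) in the shape of the study report tables: replicate scores,
#' mean, sample SD and eta.
#'
#' @param scores data frame with columns `run_id`, `dataset`, `replicate`,
#'   `score`.
#' @param m target score.
#' @return A `replicate_summary` data frame ordered by run and dataset.
#' @export
summarize_scores <- function(scores, m = 1) {
  need <- c("run_id", "dataset", "replicate", "score")
  if (!all(need %in% names(scores))) {
    stop("`scores` needs columns ", paste(need, collapse = ", "))
  }
  keys <- unique(scores[c("run_id", "dataset")])
  keys <- keys[order(keys$run_id, keys$dataset), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- scores[scores$run_id == keys$run_id[i] &
                  scores$dataset == keys$dataset[i], , drop = FALSE]
    sub <- sub[order(sub$replicate), , drop = FALSE]
    summarize_replicates(sub$score, m = m, run_id = keys$run_id[i],
                         dataset = keys$dataset[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Factor response table of mean SNR by level
#'
#' For each factor `f` and level `l`, the entry `E[f, l]` is the mean of eta
#' over exactly the runs where the array sets factor `f` to level `l` (three
#' runs each for the L9 design). The factor effect is the max - min spread of
#' its row, and the best level is the one attaining the row maximum (ties
#' broken toward the lowest level index and flagged).
#'
#' @param oa the [orthogonal_array()] that generated the runs.
#' @param etas numeric vector of per-run eta values, one per array row, in
#'   run order.
#' @param space optional [factor_space()]; when given, factor names and best
#'   level values are attached.
#' @return A `response_table` list with elements `E` (factor x level matrix),
#'   `effect`, `maximum`, `best_level`, `best_value`, `tie`.
#' @examples
#' rt <- response_table(l9_array(), c(10.4624, 12.7102, 10.0393, 1.8196,
#'   0.3302, 5.5501, 10.3131, 10.8666, 12.6219), ssd_factor_space())
#' rt$best_level # 3 3 2 2
#' @export
response_table <- function(oa, etas, space = NULL) {
  if (length(etas) != nrow(oa)) {
    stop("need one eta per run: got ", length(etas), " for ",
         nrow(oa), " runs")
  }
  if (anyNA(etas)) stop("`etas` contains NA")
  n_levels <- attr(oa, "n_levels") %||% 3L
  n_fac <- ncol(oa)
  fac_names <- colnames(oa) %||% paste0("F", seq_len(n_fac))
  if (!is.null(space)) {
    stopifnot(length(space$factors) == n_fac)
    fac_names <- names(space$factors)
  }
  E <- matrix(NA_real_, n_fac, n_levels,
              dimnames = list(fac_names, paste0("L", seq_len(n_levels))))
  for (f in seq_len(n_fac)) {
    for (l in seq_len(n_levels)) {
      E[f, l] <- mean(etas[oa[, f] == l])
    }
  }
  best <- apply(E, 1L, which.max) # which.max takes the lowest index on ties
  tie <- vapply(seq_len(n_fac), function(f) {
    sum(E[f, ] == max(E[f, ])) > 1L
  }, logical(1))
  best_value <- if (!is.null(space)) {
    stats::setNames(lapply(seq_len(n_fac), function(f) {
      space$factors[[f]]$levels[best[f]]
    }), fac_names)
  } else NULL
  structure(list(
    E = E,
    effect = apply(E, 1L, max) - apply(E, 1L, min),
    maximum = apply(E, 1L, max),
    best_level = stats::setNames(as.integer(best), fac_names),
    best_value = best_value,
    tie = stats::setNames(tie, fac_names)
  ), class = "response_table")
}

#' @export
print.response_table <- function(x, digits = 4, ...) {
  cat("Response table (mean eta, dB)\n")
  tab <- t(x$E)
  tab <- rbind(tab, Effect = x$effect, Maximum = x$maximum)
  print(round(tab, digits))
  cat("Best level:",
      paste(sprintf("%s=%d", names(x$best_level), x$best_level),
            collapse = ", "), "\n")
  if (!is.null(x$best_value)) {
    cat("Best value:",
        paste(sprintf("%s=%s", names(x$best_value),
                      vapply(x$best_value, format, "")), collapse = ", "),
        "\n")
  }
  if (any(x$tie)) {
    cat("Ties broken toward the lowest level for:",
        paste(names(x$tie)[x$tie], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Best factor-level combination from a response table
#'
#' @param rt a [response_table()].
#' @param space optional [factor_space()] used to attach level values when
#'   the response table was built without one.
#' @return A `best_combination` data frame with columns `factor`, `level`,
#'   `value`, `tie`, and attribute `provenance = "response_table"`.
#' @export
best_combination <- function(rt, space = NULL) {
  stopifnot(inherits(rt, "response_table"))
  values <- rt$best_value
  if (is.null(values) && !is.null(space)) {
    values <- stats::setNames(lapply(seq_along(space$factors), function(f) {
      space$factors[[f]]$levels[rt$best_level[f]]
    }), names(rt$best_level))
  }
  out <- data.frame(
    factor = names(rt$best_level),
    level = as.integer(rt$best_level),
    value = if (is.null(values)) NA_character_ else
      vapply(values, function(v) format(v, scientific = FALSE), ""),
    tie = as.logical(rt$tie),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- "response_table"
  class(out) <- c("best_combination", "data.frame")
  out
}

#' Taguchi analysis of variance on per-run SNR values
#'
#' Decomposes the total variability of eta across the design,
#' `S_T = sum((eta_i - mean(eta))^2)`, into per-factor sums of squares
#' `SS_f = r * sum_l (E_fl - mean(eta))^2` (with `r` runs per level) and an
#' error remainder `SS_e = S_T - sum(SS_f)`. Each factor carries
#' `levels - 1` degrees of freedom. For a saturated design (all df consumed,
#' as with four factors on L9) the error variance is defined as 0 and the
#' expected sum of squares equals the raw one; otherwise
#' `expected_SS_f = SS_f - df_f * V_e`. Percentage contributions are
#' `100 * expected_SS / S_T`, with the error row absorbing the remainder so
#' the column sums to 100.
#'
#' @param oa the [orthogonal_array()].
#' @param etas per-run eta vector.
#' @param space optional [factor_space()] for factor names.
#' @return A `taguchi_anova` list: `table` (data frame with rows per factor
#'   plus `Error` and `Total`), `grand_mean`, `degenerate` (TRUE when
#'   `S_T = 0`, in which case contributions are reported as 0).
#' @examples
#' av <- taguchi_anova(l9_array(), c(10.4624, 12.7102, 10.0393, 1.8196,
#'   0.3302, 5.5501, 10.3131, 10.8666, 12.6219))
#' av$table["A", "pct"] # 87.33
#' @export
taguchi_anova <- function(oa, etas, space = NULL) {
  if (length(etas) != nrow(oa)) stop("need one eta per run")
  if (anyNA(etas)) stop("`etas` contains NA")
  n_levels <- attr(oa, "n_levels") %||% 3L
  n_runs <- nrow(oa)
  n_fac <- ncol(oa)
  fac_names <- if (!is.null(space)) names(space$factors) else
    colnames(oa) %||% paste0("F", seq_len(n_fac))

  gbar <- mean(etas)
  S_T <- sum((etas - gbar)^2)
  df_T <- n_runs - 1L
  r <- n_runs / n_levels

  rt <- response_table(oa, etas)
  SS <- vapply(seq_len(n_fac), function(f) {
    r * sum((rt$E[f, ] - gbar)^2)
  }, numeric(1))
  df <- rep.int(n_levels - 1L, n_fac)
  if (sum(df) > df_T) {
    stop("over-saturated design: factor df (", sum(df),
         ") exceed total df (", df_T, ")")
  }
  SS_e <- S_T - sum(SS)
  df_e <- df_T - sum(df)
  V <- SS / df
  V_e <- if (df_e > 0L) SS_e / df_e else 0
  exp_SS <- SS - df * V_e
  degenerate <- S_T <= 0
  pct <- if (degenerate) rep(0, n_fac) else 100 * exp_SS / S_T
  pct_e <- if (degenerate) 0 else 100 - sum(pct)

  tab <- data.frame(
    SS = c(SS, SS_e, S_T),
    df = c(df, df_e, df_T),
    V = c(V, if (df_e > 0L) V_e else NA_real_, NA_real_),
    expected_SS = c(exp_SS, NA_real_, NA_real_),
    pct = c(pct, pct_e, if (degenerate) 0 else 100),
    row.names = c(fac_names, "Error", "Total")
  )
  structure(list(table = tab, grand_mean = gbar, degenerate = degenerate),
            class = "taguchi_anova")
}

#' @export
print.taguchi_anova <- function(x, ...) {
  cat("Taguchi ANOVA of per-run SNR (dB)\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 4)
  tab$V <- round(tab$V, 4)
  tab$expected_SS <- round(tab$expected_SS, 4)
  tab$pct <- round(tab$pct, 2)
  print(tab)
  if (x$degenerate) cat("Note: zero total variability; contributions undefined, reported as 0.\n")
  invisible(x)
}

#' Pool the smallest factors into the ANOVA error term
#'
#' Optional refinement for saturated designs: the `n_pool` factors with the
#' smallest sums of squares are merged into the error row and the expected
#' sums of squares and contributions of the remaining factors are
#' recomputed against the pooled error variance.
#'
#' @param av a [taguchi_anova()] result.
#' @param n_pool how many of the smallest-SS factors to pool.
#' @return A `taguchi_anova` with the pooled table; pooled factor rows keep
#'   their SS but are marked in `pooled`.
#' @export
pool_anova_error <- function(av, n_pool = 1L) {
  stopifnot(inherits(av, "taguchi_anova"), n_pool >= 1L)
  tab <- av$table
  fac <- setdiff(rownames(tab), c("Error", "Total"))
  if (n_pool >= length(fac)) stop("cannot pool all factors")
  ord <- fac[order(tab[fac, "SS"])]
  pooled <- ord[seq_len(n_pool)]
  keep <- setdiff(fac, pooled)
  S_T <- tab["Total", "SS"]
  df_T <- tab["Total", "df"]
  SS_e <- tab["Error", "SS"] + sum(tab[pooled, "SS"])
  df_e <- tab["Error", "df"] + sum(tab[pooled, "df"])
  V_e <- SS_e / df_e
  SS <- tab[keep, "SS"]; df <- tab[keep, "df"]
  exp_SS <- SS - df * V_e
  pct <- if (S_T > 0) 100 * exp_SS / S_T else rep(0, length(keep))
  out <- data.frame(
    SS = c(SS, SS_e, S_T),
    df = c(df, df_e, df_T),
    V = c(SS / df, V_e, NA_real_),
    expected_SS = c(exp_SS, NA_real_, NA_real_),
    pct = c(pct, if (S_T > 0) 100 - sum(pct) else 0, if (S_T > 0) 100 else 0),
    row.names = c(keep, "Error", "Total")
  )
  structure(list(table = out, grand_mean = av$grand_mean,
                 degenerate = av$degenerate, pooled = pooled),
            class = "taguchi_anova")
}

#' Write a replicate summary, response table or ANOVA as delimited text
#'
#' @param x a `replicate_summary`, [response_table()] or [taguchi_anova()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(x, path, sep = "\t") {
  df <- if (inherits(x, "response_table")) {
    cbind(data.frame(factor = rownames(x$E), stringsAsFactors = FALSE),
          as.data.frame(x$E),
          effect = x$effect, maximum = x$maximum,
          best_level = x$best_level)
  } else if (inherits(x, "taguchi_anova")) {
    cbind(data.frame(term = rownames(x$table), stringsAsFactors = FALSE),
          x$table)
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
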