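#' The L9(3^4) orthogonal array
#'
#' Returns the standard nine-run, four-column, three-level orthogonal array
#' used to plan fractional-factorial experiments over four three-level
#' factors. Nine runs replace the 81 runs of the full factorial while keeping
#' every pair of columns balanced: each ordered level pair occurs exactly
#' once per column pair.
#'
#' @return An `orthogonal_array`: an integer matrix with 9 rows and columns
#'   `A`..`D`, entries in 1..3, with attribute `n_levels = 3`.
#' @seealso [verify_orthogonality()], [build_plan()]
#' @examples
#' l9_array()
#' @export
l9_array <- function() {
  m <- matrix(c(
    1, 1, 1, 1,
    1, 2, 2, 2,
    1, 3, 3, 3,
    2, 1, 2, 3,
    2, 2, 3, 1,
    2, 3, 1, 2,
    3, 1, 3, 2,
    3, 2, 1, 3,
    3, 3, 2, 1
  ), nrow = 9, ncol = 4, byrow = TRUE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("A", "B", "C", "D"))
  orthogonal_array(m)
}

#' Construct an orthogonal-array object from a level-index matrix
#'
#' @param levels integer matrix of level indices (runs by columns).
#' @param n_levels number of levels per column (3 for the designs here).
#' @return An `orthogonal_array` object.
#' @export
orthogonal_array <- function(levels, n_levels = 3L) {
  if (!is.matrix(levels)) stop("`levels` must be a matrix of level indices")
  if (anyNA(levels)) stop("orthogonal array contains missing entries")
  if (!all(levels %in% seq_len(n_levels))) {
    stop("orthogonal array entries must be level indices in 1..", n_levels)
  }
  storage.mode(levels) <- "integer"
  structure(levels, n_levels = as.integer(n_levels),
            class = c("orthogonal_array", class(levels)))
}

#' Check the balance properties of an orthogonal array
#'
#' Verifies the two defining properties of a (strength-two) orthogonal
#' array: every column contains each level `n_runs / n_levels` times, and for
#' every pair of columns each of the `n_levels^2` ordered level pairs occurs
#' `n_runs / n_levels^2` times. A single-column array passes vacuously on the
#' pair condition.
#'
#' @param oa an [orthogonal_array()] (or plain integer matrix of level
#'   indices).
#' @param n_levels number of levels; taken from `oa` when available.
#' @return An `oa_check` list with elements `pass` (logical), `column_balance`
#'   (per-column logical), `pair_balance` (per column pair), and
#'   `pair_counts` (the ordered level-pair count tables).
#' @examples
#' verify_orthogonality(l9_array())$pass
#' @export
verify_orthogonality <- function(oa, n_levels = NULL) {
  n_levels <- n_levels %||% attr(oa, "n_levels") %||% 3L
  if (!is.matrix(oa)) stop("`oa` must be a matrix")
  if (anyNA(oa) || !all(oa %in% seq_len(n_levels))) {
    stop("array entries must be level indices in 1..", n_levels)
  }
  n_runs <- nrow(oa)
  n_cols <- ncol(oa)
  lev <- seq_len(n_levels)

  col_counts <- apply(oa, 2L, function(col) {
    tabulate(col, nbins = n_levels)
  })
  column_balance <- apply(col_counts == n_runs / n_levels, 2L, all)

  pair_counts <- list()
  pair_balance <- logical(0)
  if (n_cols >= 2L) {
    pairs <- utils::combn(n_cols, 2L)
    for (j in seq_len(ncol(pairs))) {
      c1 <- pairs[1L, j]; c2 <- pairs[2L, j]
      tab <- table(factor(oa[, c1], levels = lev),
                   factor(oa[, c2], levels = lev))
      nm <- paste0(c1, ":", c2)
      pair_counts[[nm]] <- tab
      pair_balance[nm] <- all(tab == n_runs / n_levels^2)
    }
  }
  structure(list(
    pass = all(column_balance) && all(pair_balance),
    column_balance = column_balance,
    pair_balance = pair_balance,
    pair_counts = pair_counts,
    n_runs = n_runs, n_levels = n_levels
  ), class = "oa_check")
}

#' @export
print.oa_check <- function(x, ...) {
  cat(sprintf("Orthogonal-array check: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  runs: %d, levels: %d\n", x$n_runs, x$n_levels))
  cat(sprintf("  columns balanced: %d/%d\n",
              sum(x$column_balance), length(x$column_balance)))
  if (length(x$pair_balance)) {
    cat(sprintf("  column pairs balanced: %d/%d\n",
                sum(x$pair_balance), length(x$pair_balance)))
    bad <- names(x$pair_balance)[!x$pair_balance]
    if (length(bad)) cat("  unbalanced pairs:", paste(bad, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Define a three-level experimental factor
#'
#' Level values may repeat (a factor can deliberately test the same setting
#' at two level slots); the analysis operates on level indices, never on the
#' values, so duplicate values are preserved verbatim.
#'
#' @param name short factor identifier, e.g. `"Optimizer"`.
#' @param levels vector of exactly 3 level values (numeric or character).
#' @return A `factor_spec` list.
#' @export
factor_spec <- function(name, levels) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(levels) != 3L) {
    stop("factor '", name, "' must have exactly 3 levels (got ",
         length(levels), ")")
  }
  structure(list(name = name, levels = levels), class = "factor_spec")
}

#' Assemble an ordered factor space
#'
#' Factor order is significant: it must match the column order of the
#' orthogonal array the space is combined with. `fixed_settings` records
#' non-varied configuration (carried as inert metadata in reports; it never
#' enters the analysis).
#'
#' @param ... [factor_spec()] objects, in array-column order.
#' @param fixed_settings named list of constant settings.
#' @return A `factor_space` list with elements `factors` and
#'   `fixed_settings`.
#' @export
factor_space <- function(..., fixed_settings = list()) {
  factors <- list(...)
  if (length(factors) == 1L && is.list(factors[[1L]]) &&
      !inherits(factors[[1L]], "factor_spec")) {
    factors <- factors[[1L]]
  }
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec"))) {
    stop("supply one or more factor_spec objects")
  }
  names(factors) <- vapply(factors, `[[`, "", "name")
  structure(list(factors = factors, fixed_settings = fixed_settings),
            class = "factor_space")
}

#' The ResNet50-SSD hyperparameter factor space
#'
#' The four training hyperparameters varied in the reference blood-cell
#' detection study, each at three levels: Optimizer (adam, sgdm, adam --
#' "adam" deliberately occupies both level 1 and level 3), MiniBatchSize
#' (14, 16, 18), InitialLearnRate (1e-3, 1e-4, 1e-5) and LearnRateDropPeriod
#' (30, 40, 50). Fixed settings (LearnRateDropFactor 0.8, MaxEpochs 200,
#' piecewise schedule) ride along as metadata.
#'
#' @return A [factor_space()].
#' @examples
#' build_plan(l9_array(), ssd_factor_space())
#' @export
ssd_factor_space <- function() {
  factor_space(
    factor_spec("Optimizer", c("adam", "sgdm", "adam")),
    factor_spec("MiniBatchSize", c(14, 16, 18)),
    factor_spec("InitialLearnRate", c(1e-3, 1e-4, 1e-5)),
    factor_spec("LearnRateDropPeriod", c(30, 40, 50)),
    fixed_settings = list(LearnRateDropFactor = 0.8, MaxEpochs = 200,
                          LearnRateSchedule = "piecewise")
  )
}

#' Map an orthogonal array onto concrete factor assignments
#'
#' Run `i` assigns factor `f` the value `space$factors[[f]]$levels[oa[i, f]]`.
#'
#' @param oa an [orthogonal_array()] whose column count equals the number of
#'   factors.
#' @param space a [factor_space()].
#' @return An `experiment_plan` data frame with `run_id` and one column per
#'   factor; the level-index matrix is kept in attribute `levels`.
#' @examples
#' plan <- build_plan(l9_array(), ssd_factor_space())
#' plan[4, ] # sgdm, 14, 1e-4, 50
#' @export
build_plan <- function(oa, space) {
  stopifnot(inherits(space, "factor_space"))
  if (ncol(oa) != length(space$factors)) {
    stop("array has ", ncol(oa), " columns but the space has ",
         length(space$factors), " factors")
  }
  cols <- lapply(seq_along(space$factors), function(f) {
    idx <- oa[, f]
    levs <- space$factors[[f]]$levels
    if (any(idx < 1L | idx > length(levs))) {
      stop("level index out of range for factor ",
           space$factors[[f]]$name)
    }
    levs[idx]
  })
  names(cols) <- names(space$factors)
  plan <- data.frame(run_id = seq_len(nrow(oa)), cols,
                     check.names = FALSE, stringsAsFactors = FALSE)
  structure(plan, levels = unclass(oa), space = space,
            class = c("experiment_plan", "data.frame"))
}

#' Write an experiment plan as a delimited table
#'
#' @param plan an [build_plan()] result.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path, sep = "\t") {
  utils::write.table(as.data.frame(plan), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment plan written by [write_plan()]
#'
#' @param path input file path.
#' @param sep field separator.
#' @return A data frame with `run_id` and one column per factor.
#' @export
read_plan <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
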