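#' Configuration for synthetic blood-smear scenes
#'
#' The generator emulates the statistical structure of the BCCD blood-cell
#' dataset: a 640 x 480 canvas holding, per image, roughly 11 red blood
#' cells (RBC), 1 white blood cell (WBC) and 1 platelet, with cell diameters
#' in the ratio platelet : RBC : WBC = 0.2 : 1 : 2. RBCs may overlap each
#' other up to a box-IoU cap, and platelets sit on top of an RBC with
#' configurable probability (mirroring how real platelets overlap RBCs
#' without visible borders). Per-image counts are drawn as RBC ~ Poisson(11)
#' (forced >= 1), WBC = 1 plus a rare second cell (probability 0.02), and
#' platelet ~ Poisson(1); these means match the dataset's printed label
#' totals (4155 RBC / 372 WBC / 361 platelet over 364 images).
#'
#' @param width,height canvas size in pixels.
#' @param rbc_diameter RBC diameter in pixels; platelet and WBC diameters
#'   follow from the 0.2 : 1 : 2 ratio.
#' @param rbc_mean Poisson mean for the RBC count (forced >= 1).
#' @param wbc_second_prob probability of a second WBC.
#' @param platelet_mean Poisson mean for the platelet count.
#' @param max_overlap_fraction maximum allowed box IoU between two RBCs.
#' @param platelet_on_rbc_prob probability a platelet is centered on an RBC.
#' @param jitter relative half-range of per-cell size jitter (box sides are
#'   `diameter * (1 + U(-jitter, jitter))`).
#' @param max_retries placement attempts per cell before it is skipped with
#'   a warning.
#' @param counts optional fixed counts, a named list/vector with entries
#'   `RBC`, `WBC`, `Platelets`, overriding the random count model.
#' @param seed default seed used when [generate_scene()] is called without
#'   one.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 640, height = 480, rbc_diameter = 60,
                         rbc_mean = 11, wbc_second_prob = 0.02,
                         platelet_mean = 1, max_overlap_fraction = 0.4,
                         platelet_on_rbc_prob = 0.5, jitter = 0.1,
                         max_retries = 100, counts = NULL, seed = 1) {
  diameters <- c(Platelets = 0.2, RBC = 1, WBC = 2) * rbc_diameter
  if (width < diameters[["WBC"]] || height < diameters[["WBC"]]) {
    stop("canvas too small to hold one WBC")
  }
  structure(list(
    width = width, height = height, diameters = diameters,
    rbc_mean = rbc_mean, wbc_second_prob = wbc_second_prob,
    platelet_mean = platelet_mean,
    max_overlap_fraction = max_overlap_fraction,
    platelet_on_rbc_prob = platelet_on_rbc_prob,
    jitter = jitter, max_retries = max_retries,
    counts = counts, seed = seed
  ), class = "scene_config")
}

#' Generate one synthetic smear scene
#'
#' Draws class counts, then places cells as axis-aligned square boxes fully
#' inside the canvas: WBC(s) first anywhere, then RBCs subject to the
#' pairwise RBC-RBC box-IoU cap, then platelets either centered on a random
#' RBC (with probability `platelet_on_rbc_prob`) or on background. Placement
#' that still violates the overlap cap after `max_retries` attempts skips
#' the cell with a warning. Deterministic given `(config, image_id, seed)`.
#'
#' @param config a [scene_config()].
#' @param image_id identifier stored with every ground-truth row.
#' @param seed RNG seed; defaults to `child_seed(config$seed, <image index
#'   parsed from image_id>)` when `NULL` a plain `config$seed` is used.
#' @return A `scene` list: `image_id`, `width`, `height`, `gt` (ground-truth
#'   box table in internal coordinates).
#' @examples
#' sc <- generate_scene(scene_config(), image_id = "im001", seed = 7)
#' table(sc$gt$class)
#' @export
generate_scene <- function(config, image_id = "im001", seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    n <- if (!is.null(config$counts)) {
      c(RBC = as.integer(config$counts[["RBC"]]),
        WBC = as.integer(config$counts[["WBC"]]),
        Platelets = as.integer(config$counts[["Platelets"]]))
    } else {
      c(RBC = max(1L, stats::rpois(1L, config$rbc_mean)),
        WBC = 1L + stats::rbinom(1L, 1L, config$wbc_second_prob),
        Platelets = stats::rpois(1L, config$platelet_mean))
    }
    jit <- function(d) d * (1 + stats::runif(1L, -config$jitter, config$jitter))
    # boxes accumulate in plain vectors; the data frame is built once
    cls <- character(0)
    x0 <- y0 <- x1 <- y1 <- numeric(0)
    add <- function(class, cx, cy, side) {
      cls[length(cls) + 1L] <<- class
      x0[length(x0) + 1L] <<- cx - side / 2
      y0[length(y0) + 1L] <<- cy - side / 2
      x1[length(x1) + 1L] <<- cx + side / 2
      y1[length(y1) + 1L] <<- cy + side / 2
    }
    rand_center <- function(side) {
      c(stats::runif(1L, side / 2, config$width - side / 2),
        stats::runif(1L, side / 2, config$height - side / 2))
    }

    for (i in seq_len(n[["WBC"]])) {
      side <- jit(config$diameters[["WBC"]])
      ctr <- rand_center(side)
      add("WBC", ctr[1], ctr[2], side)
    }

    # RBC placement with the pairwise overlap cap (vectors, no frames)
    rx0 <- ry0 <- rx1 <- ry1 <- numeric(0)
    for (i in seq_len(n[["RBC"]])) {
      placed <- FALSE
      for (try in seq_len(config$max_retries)) {
        side <- jit(config$diameters[["RBC"]])
        ctr <- rand_center(side)
        bx0 <- ctr[1] - side / 2; bx1 <- ctr[1] + side / 2
        by0 <- ctr[2] - side / 2; by1 <- ctr[2] + side / 2
        ok <- TRUE
        if (length(rx0)) {
          iw <- pmax(0, pmin(bx1, rx1) - pmax(bx0, rx0))
          ih <- pmax(0, pmin(by1, ry1) - pmax(by0, ry0))
          inter <- iw * ih
          un <- (bx1 - bx0) * (by1 - by0) +
            (rx1 - rx0) * (ry1 - ry0) - inter
          ok <- all(inter / un <= config$max_overlap_fraction)
        }
        if (ok) {
          rx0 <- c(rx0, bx0); ry0 <- c(ry0, by0)
          rx1 <- c(rx1, bx1); ry1 <- c(ry1, by1)
          add("RBC", ctr[1], ctr[2], side)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warning("scene ", image_id, ": RBC ", i, " skipped after ",
                config$max_retries, " placement attempts")
      }
    }

    for (i in seq_len(n[["Platelets"]])) {
      side <- jit(config$diameters[["Platelets"]])
      on_rbc <- length(rx0) > 0 &&
        stats::runif(1L) < config$platelet_on_rbc_prob
      if (on_rbc) {
        h <- sample.int(length(rx0), 1L)
        cx <- stats::runif(1L, rx0[h], rx1[h])
        cy <- stats::runif(1L, ry0[h], ry1[h])
        cx <- min(max(cx, side / 2), config$width - side / 2)
        cy <- min(max(cy, side / 2), config$height - side / 2)
        add("Platelets", cx, cy, side)
      } else {
        ctr <- rand_center(side)
        add("Platelets", ctr[1], ctr[2], side)
      }
    }

    gt <- data.frame(image_id = rep(image_id, length(cls)), class = cls,
                     xmin = x0, ymin = y0, xmax = x1, ymax = y1,
                     stringsAsFactors = FALSE)
    structure(list(image_id = image_id, width = config$width,
                   height = config$height, gt = gt),
              class = "scene")
  })
}

#' Generate a set of scenes and their pooled ground truth
#'
#' Scene `i` uses seed `child_seed(seed, i)`, so the set is reproducible and
#' individual scenes are independent.
#'
#' @param config a [scene_config()].
#' @param n number of scenes.
#' @param seed master seed for the set.
#' @param prefix image-id prefix (`"<prefix><i>"`).
#' @return A `scene_set` list: `scenes` (list of [generate_scene()]
#'   results) and `gt` (row-bound ground truth).
#' @export
generate_scene_set <- function(config, n, seed = config$seed,
                               prefix = "im") {
  scenes <- lapply(seq_len(n), function(i) {
    generate_scene(config, image_id = sprintf("%s%04d", prefix, i),
                   seed = child_seed(seed, i))
  })
  gt <- do.call(rbind, lapply(scenes, `[[`, "gt"))
  rownames(gt) <- NULL
  structure(list(scenes = scenes, gt = gt), class = "scene_set")
}

#' Render a scene as a grayscale raster
#'
#' Cosmetic companion to the box-level generator: cells are drawn as filled
#' discs inscribed in their boxes, on a light background, in the order RBC,
#' platelet, WBC so the rare large WBC stays visible on top. Returns a
#' `height x width` matrix of gray levels in `[0, 1]` (row 1 = top scan
#' line); [write_scene_png()] saves it with the `png` package.
#'
#' @param scene a [generate_scene()] result.
#' @param shades named gray levels for `background`, `RBC`, `Platelets`,
#'   `WBC`.
#' @return A numeric matrix.
#' @export
render_scene <- function(scene,
                         shades = c(background = 0.92, RBC = 0.62,
                                    Platelets = 0.30, WBC = 0.15)) {
  img <- matrix(shades[["background"]], nrow = scene$height,
                ncol = scene$width)
  # pixel (r, c) has center (c - 0.5, r - 0.5) in internal coordinates
  xc <- matrix(rep(seq_len(scene$width) - 0.5, each = scene$height),
               nrow = scene$height)
  yc <- matrix(rep(seq_len(scene$height) - 0.5, times = scene$width),
               nrow = scene$height)
  draw <- function(gt_rows, shade) {
    for (i in seq_len(nrow(gt_rows))) {
      b <- gt_rows[i, ]
      cx <- (b$xmin + b$xmax) / 2
      cy <- (b$ymin + b$ymax) / 2
      r <- min(b$xmax - b$xmin, b$ymax - b$ymin) / 2
      hit <- (xc - cx)^2 + (yc - cy)^2 <= r^2
      img[hit] <<- shade
    }
  }
  for (cl in c("RBC", "Platelets", "WBC")) {
    sel <- scene$gt[scene$gt$class == cl, , drop = FALSE]
    if (nrow(sel)) draw(sel, shades[[cl]])
  }
  img
}

#' @rdname render_scene
#' @param path output PNG path (requires the `png` package).
#' @export
write_scene_png <- function(scene, path,
                            shades = c(background = 0.92, RBC = 0.62,
                                       Platelets = 0.30, WBC = 0.15)) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is needed to write raster output")
  }
  png::writePNG(render_scene(scene, shades), path)
  invisible(path)
}

#' Per-class detector-quality model over the factor space
#'
#' A logistic response surface standing in for detector training: for class
#' `c` under factor-level assignment `a`, the quality is
#' `q_c = logistic(beta0_c + sum_f beta_c[f, a_f] + eps)` with
#' `eps ~ Normal(0, tau)` drawn independently per replicate. `q` feeds
#' [surrogate_detect()] as the detection probability (and controls jitter
#' and false-positive load), so factor effects propagate to mAP through a
#' known monotone channel — which is what makes parameter-recovery
#' experiments possible.
#'
#' @param beta0 named numeric vector of per-class intercepts (logit scale).
#' @param beta named list, one `n_factors x 3` matrix per class, of additive
#'   level effects (logit scale). A single matrix is recycled to all
#'   classes.
#' @param tau replicate noise SD (logit scale).
#' @return A `quality_model` list.
#' @export
quality_model <- function(beta0, beta, tau = 0) {
  stopifnot(is.numeric(beta0), !is.null(names(beta0)), tau >= 0)
  if (is.matrix(beta)) {
    beta <- stats::setNames(rep(list(beta), length(beta0)), names(beta0))
  }
  stopifnot(is.list(beta), all(names(beta0) %in% names(beta)))
  for (cl in names(beta0)) {
    if (!is.matrix(beta[[cl]]) || ncol(beta[[cl]]) != 3L) {
      stop("beta for class ", cl, " must be an n_factors x 3 matrix")
    }
  }
  structure(list(beta0 = beta0, beta = beta, tau = tau,
                 classes = names(beta0)),
            class = "quality_model")
}

#' Default quality model for surrogate studies
#'
#' Factor A dominates (level-effect spread 2.0 on the logit scale, versus
#' 0.3 for factors B-D), replicate noise `tau = 0.05`, and per-class
#' intercepts ordered WBC > RBC > Platelets — large, high-contrast WBCs are
#' the easiest class and small platelets the hardest, as in real smear
#' images. The designed argmax levels are (3, 3, 2, 2).
#'
#' For the minor factors the winning level carries the full 0.3 spread over
#' both others rather than an equal-spaced ladder: the study's job is to
#' identify the best level, and the winner-runner-up gap is what the
#' response table must resolve against replicate and scene-sampling noise,
#' so the designed optimum is kept identifiable at desk-scale scene counts.
#'
#' @param tau replicate noise SD.
#' @return A [quality_model()].
#' @export
default_quality_model <- function(tau = 0.05) {
  eff <- rbind(
    A = c(-1.0, -0.8, 1.0),
    B = c(-0.15, -0.15, 0.15),
    C = c(-0.15, 0.15, -0.15),
    D = c(-0.15, 0.15, -0.15)
  )
  quality_model(
    beta0 = c(WBC = 1.6, RBC = 0.6, Platelets = 0.0),
    beta = eff, tau = tau
  )
}

#' Per-class quality for one run and replicate
#'
#' @param levels_vec integer level indices, one per factor (a row of the
#'   orthogonal array).
#' @param qm a [quality_model()].
#' @param seed RNG seed for the replicate-noise draw.
#' @return Named numeric vector of qualities `q` in (0, 1), one per class.
#' @examples
#' quality_response(c(3, 3, 2, 2), default_quality_model(tau = 0), seed = 1)
#' @export
quality_response <- function(levels_vec, qm, seed = 1) {
  stopifnot(inherits(qm, "quality_model"))
  with_seed(seed, {
    out <- vapply(qm$classes, function(cl) {
      b <- qm$beta[[cl]]
      if (length(levels_vec) != nrow(b)) {
        stop("level vector has ", length(levels_vec), " entries but the ",
             "model has ", nrow(b), " factors")
      }
      if (any(levels_vec < 1L | levels_vec > ncol(b))) {
        stop("unknown level index in assignment")
      }
      x <- qm$beta0[[cl]] +
        sum(b[cbind(seq_len(nrow(b)), levels_vec)]) +
        stats::rnorm(1L, 0, qm$tau)
      stats::plogis(x)
    }, numeric(1))
    out
  })
}

#' Configuration of the surrogate detector
#'
#' The surrogate converts per-class quality `q` into detector behaviour:
#' each ground-truth box is found with probability `q` (recall is the
#' identity in `q`); found boxes are jittered in center and size by
#' `Normal(0, j0 * (1 - q) * side)`; each class sprinkles
#' `Poisson(lambda0 * (1 - q))` false positives per image with sizes within
#' +/-30% of the class diameter; true-positive confidences are
#' `min(1, 0.7 q + 0.3 U)` and false-positive confidences `U(0, 0.6)`. At
#' `q = 1` the detector is perfect: every box found, no jitter, no false
#' positives.
#'
#' @param j0 jitter scale coefficient.
#' @param lambda0 false-positive rate coefficient (per image per class).
#' @param fp_conf_max upper bound of the false-positive confidence range.
#' @return A `surrogate_config` list.
#' @export
surrogate_config <- function(j0 = 0.15, lambda0 = 2.0, fp_conf_max = 0.6) {
  stopifnot(j0 >= 0, lambda0 >= 0, fp_conf_max > 0, fp_conf_max <= 1)
  structure(list(j0 = j0, lambda0 = lambda0, fp_conf_max = fp_conf_max),
            class = "surrogate_config")
}

#' Run the surrogate detector on a scene
#'
#' @param scene a [generate_scene()] result.
#' @param q named per-class quality vector in (0, 1] (see
#'   [quality_response()]); classes missing from `q` are not detected.
#' @param sc a [surrogate_config()].
#' @param seed RNG seed.
#' @param diameters named per-class nominal diameters used to size false
#'   positives; defaults to the [scene_config()] defaults.
#' @return A detection table (`image_id`, `class`, box, `confidence`).
#' @examples
#' sc <- generate_scene(scene_config(), seed = 3)
#' det <- surrogate_detect(sc, c(WBC = 1, RBC = 1, Platelets = 1),
#'                         surrogate_config(), seed = 4)
#' evaluate_detections(det, sc$gt)$map # 1 at q = 1
#' @export
surrogate_detect <- function(scene, q, sc = surrogate_config(), seed = 1,
                             diameters = c(Platelets = 12, RBC = 60,
                                           WBC = 120)) {
  stopifnot(inherits(sc, "surrogate_config"))
  if (any(q <= 0) || any(q > 1)) stop("q must lie in (0, 1]")
  with_seed(seed, {
    cls <- character(0)
    ox0 <- oy0 <- ox1 <- oy1 <- oconf <- numeric(0)
    emit <- function(class, x0, y0, x1, y1, conf) {
      k <- length(x0)
      if (!k) return(invisible())
      cls <<- c(cls, rep(class, k))
      ox0 <<- c(ox0, x0); oy0 <<- c(oy0, y0)
      ox1 <<- c(ox1, x1); oy1 <<- c(oy1, y1)
      oconf <<- c(oconf, conf)
    }
    for (cl in intersect(unique(scene$gt$class), names(q))) {
      qc <- q[[cl]]
      sel <- scene$gt$class == cl
      gx0 <- scene$gt$xmin[sel]; gy0 <- scene$gt$ymin[sel]
      gx1 <- scene$gt$xmax[sel]; gy1 <- scene$gt$ymax[sel]
      found <- stats::runif(length(gx0)) < qc
      k <- sum(found)
      if (k) {
        hx0 <- gx0[found]; hy0 <- gy0[found]
        hx1 <- gx1[found]; hy1 <- gy1[found]
        side <- pmin(hx1 - hx0, hy1 - hy0)
        sg <- sc$j0 * (1 - qc) * side
        cx <- (hx0 + hx1) / 2 + stats::rnorm(k, 0, sg)
        cy <- (hy0 + hy1) / 2 + stats::rnorm(k, 0, sg)
        w <- pmax(2, (hx1 - hx0) + stats::rnorm(k, 0, sg))
        h <- pmax(2, (hy1 - hy0) + stats::rnorm(k, 0, sg))
        emit(cl,
             pmax(0, cx - w / 2), pmax(0, cy - h / 2),
             pmin(scene$width, cx + w / 2),
             pmin(scene$height, cy + h / 2),
             pmin(1, 0.7 * qc + 0.3 * stats::runif(k)))
      }
      n_fp <- stats::rpois(1L, sc$lambda0 * (1 - qc))
      if (n_fp > 0) {
        d0 <- diameters[[cl]] %||% 60
        side <- d0 * stats::runif(n_fp, 0.7, 1.3)
        side <- pmin(side, min(scene$width, scene$height))
        cx <- stats::runif(n_fp, side / 2, scene$width - side / 2)
        cy <- stats::runif(n_fp, side / 2, scene$height - side / 2)
        emit(cl, cx - side / 2, cy - side / 2, cx + side / 2,
             cy + side / 2, stats::runif(n_fp, 0, sc$fp_conf_max))
      }
    }
    data.frame(image_id = rep(scene$image_id, length(cls)), class = cls,
               xmin = ox0, ymin = oy0, xmax = ox1, ymax = oy1,
               confidence = oconf, stringsAsFactors = FALSE)
  })
}

#' Run the surrogate detector over a scene set
#'
#' Scene `i` uses seed `child_seed(seed, i)`.
#'
#' @param scene_set a [generate_scene_set()] result.
#' @param q named per-class quality vector.
#' @param sc a [surrogate_config()].
#' @param seed master seed.
#' @param diameters passed to [surrogate_detect()].
#' @return A pooled detection table over all scenes.
#' @export
surrogate_detect_set <- function(scene_set, q, sc = surrogate_config(),
                                 seed = 1,
                                 diameters = c(Platelets = 12, RBC = 60,
                                               WBC = 120)) {
  dets <- lapply(seq_along(scene_set$scenes), function(i) {
    surrogate_detect(scene_set$scenes[[i]], q, sc,
                     seed = child_seed(seed, i), diameters = diameters)
  })
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}
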