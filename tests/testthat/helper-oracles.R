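# Independent brute-force oracle for average precision: enumerate every
# confidence cut, take the enveloped precision at each achieved recall step
# directly from the definition (max precision over all cuts with recall at
# least r), and sum the rectangle areas. Shares no code with the package's
# cumulative-envelope implementation.
ap_bruteforce <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp) || !any(tp)) return(0)
  cuts <- seq_along(tp)
  prec <- cumsum(tp) / cuts
  rec <- cumsum(tp) / n_gt
  steps <- sort(unique(rec[tp]))
  ap <- 0
  prev <- 0
  for (r in steps) {
    ap <- ap + (r - prev) * max(prec[rec >= r])
    prev <- r
  }
  ap
}

# random single-image, single-class instance with <= 6 detections and
# <= 4 ground truths; boxes drawn so that overlaps of every degree occur
random_tiny_instance <- function(seed) {
  set.seed(seed)
  n_gt <- sample(0:4, 1)
  n_det <- sample(0:6, 1)
  rand_boxes <- function(n) {
    if (!n) {
      return(data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0)))
    }
    x <- runif(n, 0, 60); y <- runif(n, 0, 60)
    w <- runif(n, 5, 40); h <- runif(n, 5, 40)
    data.frame(xmin = x, ymin = y, xmax = x + w, ymax = y + h)
  }
  gt <- cbind(data.frame(image_id = rep("im1", n_gt),
                         class = rep("cell", n_gt),
                         stringsAsFactors = FALSE),
              rand_boxes(n_gt))
  det_boxes <- rand_boxes(n_det)
  # let some detections copy a ground-truth box so true positives happen
  if (n_det && n_gt) {
    copy <- runif(n_det) < 0.5
    src <- sample(n_gt, n_det, replace = TRUE)
    for (j in which(copy)) {
      shift <- runif(2, -3, 3)
      det_boxes[j, ] <- gt[src[j], c("xmin", "ymin", "xmax", "ymax")] +
        c(shift[1], shift[2], shift[1], shift[2])
    }
  }
  det <- cbind(data.frame(image_id = rep("im1", n_det),
                          class = rep("cell", n_det),
                          stringsAsFactors = FALSE),
               det_boxes,
               data.frame(confidence = if (n_det) runif(n_det) else numeric(0)))
  list(det = det, gt = gt)
}

# absolute-tolerance comparison against values printed to a fixed number
# of decimals (expect_equal's tolerance is relative)
expect_close <- function(object, expected, tol = 5e-4) {
  expect_lt(max(abs(object - expected)), tol)
}

# reference eta values of the nine test-set runs, recomputed from the
# embedded raw replicate scores
reference_test_etas <- function() {
  fx <- ssd_study_tables()
  sm <- summarize_scores(fx$scores)
  sm <- sm[sm$dataset == "test", ]
  sm$eta[order(sm$run_id)]
}
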