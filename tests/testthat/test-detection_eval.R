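box <- function(xmin, ymin, xmax, ymax, image_id = "im1", class = "RBC",
                confidence = NULL) {
  df <- data.frame(image_id = image_id, class = class, xmin = xmin,
                   ymin = ymin, xmax = xmax, ymax = ymax,
                   stringsAsFactors = FALSE)
  if (!is.null(confidence)) df$confidence <- confidence
  df
}

test_that("IoU covers identity, disjointness and partial overlap", {
  a <- box(0, 0, 10, 10)
  expect_equal(box_iou(a, a)[1, 1], 1)
  expect_equal(box_iou(a, box(20, 20, 30, 30))[1, 1], 0)
  expect_equal(box_iou(a, box(5, 5, 15, 15))[1, 1], 25 / 175)
  expect_error(box_iou(a, box(5, 5, 5, 15)), "degenerate")
})

test_that("greedy matching assigns each ground truth at most once", {
  gt <- box(0, 0, 10, 10)
  # perfect single match
  m <- match_detections(box(0, 0, 10, 10, confidence = 0.9), gt)
  expect_equal(sum(m$detections$tp), 1)
  expect_equal(sum(m$fn_by_image), 0)
  # two detections on one ground truth: the more confident one wins
  det2 <- rbind(box(0, 0, 10, 10, confidence = 0.6),
                box(1, 1, 11, 11, confidence = 0.9))
  m2 <- match_detections(det2, gt)
  expect_equal(m2$detections$confidence[m2$detections$tp], 0.9)
  expect_equal(sum(m2$detections$tp), 1)
  # just-above-threshold overlap still matches
  m3 <- match_detections(box(0, 0, 10, 5.5, confidence = 0.8), gt,
                         iou_threshold = 0.5) # IoU 55/100
  expect_equal(sum(m3$detections$tp), 1)
})

test_that("IoU below the threshold never matches", {
  gt <- box(0, 0, 10, 10)
  det <- box(0, 0, 10, 4, confidence = 0.9) # IoU = 40/100 = 0.4
  m <- match_detections(det, gt, iou_threshold = 0.5)
  expect_false(any(m$detections$tp))
  expect_equal(sum(m$fn_by_image), 1)
})

test_that("matching never crosses image boundaries", {
  gt <- box(0, 0, 10, 10, image_id = "imA")
  det <- box(0, 0, 10, 10, image_id = "imB", confidence = 1)
  m <- match_detections(det, gt)
  expect_false(any(m$detections$tp))
})

test_that("true positives plus unmatched ground truth conserve n_gt", {
  set.seed(99)
  for (k in 1:25) {
    inst <- random_tiny_instance(1000 + k)
    m <- match_detections(inst$det, inst$gt)
    expect_equal(sum(m$detections$tp) + sum(m$fn_by_image), m$n_gt)
  }
})

test_that("average precision handles the canonical hand cases", {
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 2), 0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_true(is.na(average_precision(logical(0), 0)))
})

test_that("pipeline AP equals the brute-force oracle on 200 tiny instances", {
  for (k in 1:200) {
    inst <- random_tiny_instance(k)
    m <- match_detections(inst$det, inst$gt)
    ap_pkg <- average_precision(m$detections$tp, m$n_gt)
    ap_ref <- ap_bruteforce(m$detections$tp, m$n_gt)
    expect_identical(is.na(ap_pkg), is.na(ap_ref))
    if (!is.na(ap_pkg)) expect_equal(ap_pkg, ap_ref, tolerance = 1e-12)
  }
})

test_that("AP depends only on the confidence ordering", {
  inst <- random_tiny_instance(7)
  m <- match_detections(inst$det, inst$gt)
  base <- average_precision(m$detections$tp, m$n_gt)
  inst$det$confidence <- plogis(5 * inst$det$confidence - 2) # monotone map
  m2 <- match_detections(inst$det, inst$gt)
  expect_equal(average_precision(m2$detections$tp, m2$n_gt), base)
})

test_that("appending lowest-confidence detections moves AP the right way", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    tp <- runif(n) < 0.6
    n_gt <- sum(tp) + sample(0:2, 1)
    if (n_gt == 0) next
    base <- average_precision(tp, n_gt)
    expect_lte(average_precision(c(tp, FALSE), n_gt), base + 1e-12)
    expect_gte(average_precision(c(tp, TRUE), n_gt), base - 1e-12)
  }
})

test_that("mAP is the unweighted mean over defined class APs", {
  expect_equal(mean_ap(c(WBC = 0.9766, RBC = 0.7627, Platelets = 0.5895)),
               0.7763, tolerance = 5e-5)
  expect_equal(mean_ap(0.42), 0.42)
  expect_equal(mean_ap(c(0, 1)), 0.5)
  expect_equal(mean_ap(c(0.5, NA, 0.7)), 0.6)
  expect_error(mean_ap(NA_real_), "no class")
})

test_that("classes without ground truth are excluded from mAP and flagged", {
  gt <- box(0, 0, 10, 10, class = "RBC")
  det <- rbind(box(0, 0, 10, 10, class = "RBC", confidence = 0.9),
               box(30, 30, 40, 40, class = "WBC", confidence = 0.8))
  ev <- evaluate_detections(det, gt)
  expect_equal(ev$undefined_classes, "WBC")
  expect_equal(ev$map, 1)
})

test_that("a perfect detector scores mAP 1 on a synthetic scene set", {
  set <- generate_scene_set(scene_config(), n = 3, seed = 21)
  det <- set$gt
  det$confidence <- 1
  ev <- evaluate_detections(det, set$gt)
  expect_equal(ev$map, 1)
  expect_true(all(ev$per_class$ap == 1))
})

test_that("counting accuracy follows the printed blood-cell arithmetic", {
  mk <- function(n, class, image = "im1", conf = 0.9) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      box(10 * i, 0, 10 * i + 5, 5, image_id = image, class = class,
          confidence = conf)
    }))
  }
  gt_cols <- c("image_id", "class", "xmin", "ymin", "xmax", "ymax")
  gt <- rbind(mk(75, "Platelets")[gt_cols], mk(10, "RBC")[gt_cols])
  det <- rbind(mk(57, "Platelets"), mk(23, "RBC"))
  rep <- count_cells(det, gt, confidence_threshold = 0.5)
  pl <- rep[rep$class == "Platelets", ]
  expect_equal(pl$accuracy, 76)
  expect_false(pl$over_count)
  rb <- rep[rep$class == "RBC", ]
  expect_equal(rb$accuracy, 230)
  expect_true(rb$over_count)
  # the reference study's RBC ratio: 1628 detected / 846 annotated
  expect_equal(100 * 1628 / 846, 192.4, tolerance = 0.05)
  # confidence threshold filters detections
  det$confidence <- 0.3
  rep2 <- count_cells(det, gt, confidence_threshold = 0.5)
  expect_true(all(rep2$n_detected == 0))
})

test_that("counting flags classes with no ground truth", {
  gt <- box(0, 0, 10, 10, class = "RBC")
  det <- box(0, 0, 10, 10, class = "WBC", confidence = 0.9)
  rep <- count_cells(det, gt, 0.5)
  w <- rep[rep$class == "WBC", ]
  expect_true(w$undefined)
  expect_true(is.na(w$accuracy))
})

test_that("detection tables round-trip through delimited files", {
  inst <- random_tiny_instance(12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_detections(inst$det, path)
  back <- read_detections(path)
  expect_equal(back$xmin, inst$det$xmin, tolerance = 1e-9)
  expect_equal(back$confidence, inst$det$confidence, tolerance = 1e-9)
  expect_equal(back$class, inst$det$class)
})
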