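test_that("fixed counts give exactly the requested boxes", {
  cfg <- scene_config(counts = list(RBC = 10, WBC = 1, Platelets = 1))
  sc <- generate_scene(cfg, "im001", seed = 4)
  expect_equal(nrow(sc$gt), 12)
  expect_equal(sum(sc$gt$class == "RBC"), 10)
  expect_equal(sum(sc$gt$class == "WBC"), 1)
  expect_equal(sum(sc$gt$class == "Platelets"), 1)
})

test_that("scene generation is deterministic given config, id and seed", {
  cfg <- scene_config()
  a <- generate_scene(cfg, "im007", seed = 33)
  b <- generate_scene(cfg, "im007", seed = 33)
  expect_identical(a$gt, b$gt)
  c <- generate_scene(cfg, "im007", seed = 34)
  expect_false(identical(a$gt, c$gt))
})

test_that("boxes respect the canvas and the 0.2 : 1 : 2 diameter ratio", {
  cfg <- scene_config(counts = list(RBC = 8, WBC = 1, Platelets = 2))
  for (seed in 1:10) {
    sc <- generate_scene(cfg, sprintf("im%03d", seed), seed = seed)
    gt <- sc$gt
    expect_true(all(gt$xmin >= 0 & gt$ymin >= 0 &
                    gt$xmax <= sc$width & gt$ymax <= sc$height))
    side <- function(cl) {
      g <- gt[gt$class == cl, ]
      (g$xmax - g$xmin)
    }
    # each side is its class diameter within the 10% jitter band
    expect_true(all(abs(side("RBC") / 60 - 1) <= 0.1 + 1e-9))
    expect_true(all(abs(side("WBC") / 120 - 1) <= 0.1 + 1e-9))
    expect_true(all(abs(side("Platelets") / 12 - 1) <= 0.1 + 1e-9))
    # hence WBC side is 10x the platelet side up to jitter
    ratio <- side("WBC")[1] / side("Platelets")
    expect_true(all(ratio >= 10 * 0.9 / 1.1 & ratio <= 10 * 1.1 / 0.9))
  }
})

test_that("RBC pairwise box overlap stays below the configured cap", {
  cfg <- scene_config(counts = list(RBC = 14, WBC = 1, Platelets = 1),
                      max_overlap_fraction = 0.3)
  for (seed in 1:5) {
    sc <- generate_scene(cfg, "im001", seed = seed)
    rbc <- sc$gt[sc$gt$class == "RBC", ]
    if (nrow(rbc) >= 2) {
      iou <- box_iou(rbc, rbc)
      diag(iou) <- 0
      expect_lte(max(iou), 0.3 + 1e-9)
    }
  }
})

test_that("per-image counts track the blood-cell count model", {
  cfg <- scene_config()
  counts <- t(vapply(1:300, function(i) {
    gt <- generate_scene(cfg, sprintf("im%04d", i), seed = i)$gt
    c(RBC = sum(gt$class == "RBC"), WBC = sum(gt$class == "WBC"),
      Platelets = sum(gt$class == "Platelets"))
  }, numeric(3)))
  expect_gt(mean(counts[, "RBC"]), 9.5)
  expect_lt(mean(counts[, "RBC"]), 12.5)
  expect_gte(min(counts[, "RBC"]), 1)
  expect_true(all(counts[, "WBC"] %in% c(1, 2)))
  expect_gt(mean(counts[, "Platelets"]), 0.7)
  expect_lt(mean(counts[, "Platelets"]), 1.3)
})

test_that("rendering draws discs where the ground truth says", {
  cfg <- scene_config(counts = list(RBC = 0, WBC = 0, Platelets = 0))
  empty <- generate_scene(cfg, "im000", seed = 1)
  img <- render_scene(empty)
  expect_true(all(img == img[1, 1])) # uniform background
  one <- empty
  one$gt <- data.frame(image_id = "im000", class = "RBC",
                       xmin = 290, ymin = 210, xmax = 350, ymax = 270,
                       stringsAsFactors = FALSE)
  img1 <- render_scene(one)
  hit <- which(img1 != img[1, 1], arr.ind = TRUE)
  # re-measured disc bounding box equals the ground-truth box within 1 px
  expect_lte(abs(min(hit[, "col"] - 1) - 290), 1)
  expect_lte(abs(max(hit[, "col"]) - 350), 1)
  expect_lte(abs(min(hit[, "row"] - 1) - 210), 1)
  expect_lte(abs(max(hit[, "row"]) - 270), 1)
})

test_that("the quality model is logistic and additive in its effects", {
  qm0 <- quality_model(beta0 = c(RBC = 0), beta = matrix(0, 4, 3), tau = 0)
  q <- quality_response(c(1, 1, 1, 1), qm0, seed = 1)
  expect_equal(unname(q), 0.5)
  # raising one cell's effect raises q only for assignments at that cell
  b <- matrix(0, 4, 3)
  b[2, 3] <- 1.5
  qm1 <- quality_model(beta0 = c(RBC = 0), beta = b, tau = 0)
  oa <- l9_array()
  for (i in 1:9) {
    q1 <- quality_response(oa[i, ], qm1, seed = 1)
    expect_equal(unname(q1),
                 if (oa[i, 2] == 3L) plogis(1.5) else 0.5)
  }
})

test_that("coordinate-wise argmax of an additive model is the global best", {
  qm <- default_quality_model(tau = 0)
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3))
  qs <- apply(grid, 1, function(lv) {
    quality_response(lv, qm, seed = 1)[["RBC"]]
  })
  designed <- c(3, 3, 2, 2)
  expect_equal(unname(grid[which.max(qs), ]), designed)
})

test_that("the surrogate detector is exact in the noiseless limit", {
  sc <- generate_scene(scene_config(), "im001", seed = 3)
  det <- surrogate_detect(sc, c(WBC = 1, RBC = 1, Platelets = 1),
                          surrogate_config(), seed = 5)
  expect_equal(nrow(det), nrow(sc$gt))
  ev <- evaluate_detections(det, sc$gt)
  expect_equal(ev$map, 1)
  # and nearly silent in the vanishing-quality limit
  det0 <- surrogate_detect(sc, c(WBC = 1e-6, RBC = 1e-6, Platelets = 1e-6),
                           surrogate_config(), seed = 5)
  ev0 <- evaluate_detections(det0, sc$gt)
  expect_lte(ev0$map, 0.2)
})

test_that("surrogate detection is deterministic given its seed", {
  sc <- generate_scene(scene_config(), "im001", seed = 3)
  q <- c(WBC = 0.8, RBC = 0.7, Platelets = 0.6)
  a <- surrogate_detect(sc, q, surrogate_config(), seed = 11)
  b <- surrogate_detect(sc, q, surrogate_config(), seed = 11)
  expect_identical(a, b)
})
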