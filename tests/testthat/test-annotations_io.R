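test_that("VOC records round-trip through XML files", {
  rec <- voc_record(
    filename = "im001.jpg", width = 640, height = 480, depth = 3,
    objects = data.frame(
      class = c("RBC", "WBC", "Platelets"),
      xmin = c(10, 100, 5), ymin = c(20, 150, 7),
      xmax = c(50, 220, 5), ymax = c(60, 270, 7),
      stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(rec, path)
  back <- read_voc_xml(path)
  expect_equal(back$filename, rec$filename)
  expect_equal(back$width, rec$width)
  expect_equal(back$height, rec$height)
  expect_equal(back$objects$class, rec$objects$class)
  expect_equal(back$objects$xmin, rec$objects$xmin)
  expect_equal(back$objects$ymax, rec$objects$ymax)
})

test_that("records with no objects are valid files", {
  rec <- voc_record("empty.jpg", 640, 480)
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(rec, path)
  back <- read_voc_xml(path)
  expect_equal(nrow(back$objects), 0)
})

test_that("invalid bounding boxes are rejected on construction and read", {
  expect_error(
    voc_record("x.jpg", 640, 480,
               objects = data.frame(class = "RBC", xmin = 50, ymin = 20,
                                    xmax = 10, ymax = 60)),
    "invalid bndbox")
  expect_error(voc_record("x.jpg", 640, 480, depth = 2), "depth")
  # a file with a missing coordinate names the object
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>x.jpg</filename>",
    "<size><width>640</width><height>480</height><depth>3</depth></size>",
    "<object><name>RBC</name><bndbox><xmin>1</xmin><ymin>2</ymin>",
    "<xmax>5</xmax></bndbox></object></annotation>"), path)
  expect_error(read_voc_xml(path), "object 1")
})

test_that("coordinate conversion is a width-preserving bijection", {
  voc <- data.frame(xmin = 1, ymin = 1, xmax = 10, ymax = 10)
  int <- voc_to_internal(voc)
  expect_equal(unlist(int), c(xmin = 0, ymin = 0, xmax = 10, ymax = 10))
  expect_equal(int$xmax - int$xmin, 10) # inclusive width 10 - 1 + 1
  expect_equal(internal_to_voc(int), voc)
  px <- voc_to_internal(data.frame(xmin = 5, ymin = 7, xmax = 5, ymax = 7))
  expect_equal(unlist(px), c(xmin = 4, ymin = 6, xmax = 5, ymax = 7))
  expect_equal((px$xmax - px$xmin) * (px$ymax - px$ymin), 1)
})

test_that("synthetic scenes survive VOC export and re-import", {
  sc <- generate_scene(scene_config(), "im042", seed = 9)
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(scene_to_voc(sc), path)
  gt2 <- voc_to_gt(read_voc_xml(path))
  expect_equal(gt2$class, sc$gt$class)
  expect_equal(gt2$xmin, sc$gt$xmin, tolerance = 1e-6)
  expect_equal(gt2$ymax, sc$gt$ymax, tolerance = 1e-6)
  expect_equal(unique(gt2$image_id), "im042")
})

test_that("the train/test split reproduces the 291/73 arithmetic", {
  ids <- sprintf("im%03d", 1:364)
  sp <- split_dataset(ids, 0.80, seed = 5)
  expect_length(sp$train, 291)
  expect_length(sp$test, 73)
  sp10 <- split_dataset(sprintf("x%02d", 1:10), 0.80, seed = 5)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  ids <- sprintf("im%03d", 1:50)
  a <- split_dataset(ids, 0.8, seed = 3)
  b <- split_dataset(ids, 0.8, seed = 3)
  c <- split_dataset(ids, 0.8, seed = 4)
  expect_identical(a$train, b$train)
  expect_false(identical(a$train, c$train))
  expect_length(intersect(a$train, a$test), 0)
  expect_setequal(c(a$train, a$test), ids)
  expect_error(split_dataset("one"), "at least 2")
  expect_error(split_dataset(ids, 1.2), "strictly between")
})

test_that("split specifications persist as JSON", {
  sp <- split_dataset(sprintf("im%03d", 1:20), 0.8, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  back <- read_split(path)
  expect_equal(back$train, sp$train)
  expect_equal(back$test, sp$test)
  expect_equal(back$seed, sp$seed)
})
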