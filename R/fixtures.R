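#' Reference result tables of the ResNet50-SSD blood-cell study
#'
#' The recorded results of the GPU-trained ResNet50-SSD Taguchi study on the
#' BCCD blood-cell dataset, embedded so that every derived quantity (means,
#' sample SDs, SNR values, response table, ANOVA, validation and comparison
#' statistics, counting accuracy) can be recomputed from the raw replicate
#' mAP scores and checked against the printed values without any network
#' access or trained weights. All numbers are stored exactly as printed, to
#' four decimals.
#'
#' @return A list with components:
#' \describe{
#'   \item{scores}{long data frame of the nine-run L9 study raw replicate
#'     mAPs: `run_id`, `dataset` ("training"/"test"), `replicate`, `score`.}
#'   \item{summary}{printed per-run mean / SD / eta for both datasets.}
#'   \item{response}{printed response table: `E` (4 x 3 matrix), `effect`,
#'     `maximum`, `best_level`, `best_value`.}
#'   \item{anova}{printed ANOVA table rows (SS, df, V, expected SS, pct) and
#'     `S_T`.}
#'   \item{validation}{raw replicates and printed summary for the best
#'     combination (adam, 18, 1e-4, 40) at 512 x 512 input.}
#'   \item{size300}{same detector at 300 x 300 input.}
#'   \item{matlab_default}{the toolbox-default combination
#'     (sgdm, 16, 1e-1, 30) at 512 x 512 input.}
#'   \item{headline_ap}{per-class APs of the best single test run and their
#'     mAP.}
#'   \item{counts}{test-set ground-truth label counts and detected counts
#'     per class.}
#' }
#' @examples
#' fx <- ssd_study_tables()
#' summarize_scores(fx$scores)[1:2, ]
#' @export
ssd_study_tables <- function() {
  reps <- function(dataset, run_scores) {
    do.call(rbind, lapply(seq_along(run_scores), function(i) {
      data.frame(run_id = i, dataset = dataset, replicate = 1:3,
                 score = run_scores[[i]], stringsAsFactors = FALSE)
    }))
  }
  train <- list(
    c(0.7322, 0.7194, 0.7111), c(0.7715, 0.7720, 0.7656),
    c(0.6245, 0.6242, 0.6247), c(0.1907, 0.1902, 0.1885),
    c(0.0332, 0.0332, 0.0332), c(0.4613, 0.4555, 0.4550),
    c(0.6348, 0.6332, 0.6338), c(0.7082, 0.7161, 0.7330),
    c(0.7767, 0.7797, 0.7821)
  )
  test <- list(
    c(0.7179, 0.7113, 0.6713), c(0.7705, 0.7679, 0.7672),
    c(0.6852, 0.6853, 0.6851), c(0.1900, 0.1896, 0.1874),
    c(0.0373, 0.0374, 0.0372), c(0.4729, 0.4720, 0.4716),
    c(0.6961, 0.6950, 0.6938), c(0.6913, 0.7190, 0.7311),
    c(0.7653, 0.7646, 0.7686)
  )
  scores <- rbind(reps("training", train), reps("test", test))

  summary <- rbind(
    data.frame(run_id = 1:9, dataset = "training",
               mean = c(0.7209, 0.7697, 0.6245, 0.1898, 0.0332, 0.4573,
                        0.6339, 0.7191, 0.7795),
               sd = c(0.0106, 0.0036, 0.0003, 0.0012, 0.0000, 0.0035,
                      0.0008, 0.0127, 0.0027),
               eta = c(11.0848, 12.7541, 8.5070, 1.8282, 0.2933, 5.3083,
                       8.7288, 11.0290, 13.1318)),
    data.frame(run_id = 1:9, dataset = "test",
               mean = c(0.7002, 0.7685, 0.6852, 0.1890, 0.0373, 0.4722,
                        0.6950, 0.7138, 0.7662),
               sd = c(0.0252, 0.0017, 0.0001, 0.0014, 0.0001, 0.0007,
                      0.0012, 0.0204, 0.0021),
               eta = c(10.4624, 12.7102, 10.0393, 1.8196, 0.3302, 5.5501,
                       10.3131, 10.8666, 12.6219))
  )

  E <- matrix(c(
    11.0706, 2.5666, 11.2672,
    7.5317, 7.9690, 9.4037,
    8.9597, 9.0506, 6.8942,
    7.8048, 9.5244, 7.5752
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("Optimizer", "MiniBatchSize", "InitialLearnRate",
                    "LearnRateDropPeriod"), c("L1", "L2", "L3")))
  response <- list(
    E = E,
    effect = c(8.7006, 1.8721, 2.1564, 1.9493),
    maximum = c(11.2672, 9.4037, 9.0506, 9.5244),
    best_level = c(3L, 3L, 2L, 2L),
    best_value = list(Optimizer = "adam", MiniBatchSize = 18,
                      InitialLearnRate = 1e-4, LearnRateDropPeriod = 40)
  )

  anova <- list(
    table = data.frame(
      SS = c(148.0572, 5.7544, 8.9246, 6.8096),
      df = c(2L, 2L, 2L, 2L),
      V = c(74.0286, 2.8772, 4.4623, 3.4048),
      expected_SS = c(148.0572, 5.7544, 8.9246, 6.8096),
      pct = c(87.33, 3.39, 5.26, 4.02),
      row.names = rownames(E)
    ),
    error_SS = 0, S_T = 169.5457
  )

  condition <- function(train_r, train_s, test_r, test_s) {
    list(
      scores = rbind(
        data.frame(run_id = 1L, dataset = "training", replicate = 1:3,
                   score = train_r, stringsAsFactors = FALSE),
        data.frame(run_id = 1L, dataset = "test", replicate = 1:3,
                   score = test_r, stringsAsFactors = FALSE)),
      summary = data.frame(
        dataset = c("training", "test"),
        mean = c(train_s[1], test_s[1]),
        sd = c(train_s[2], test_s[2]),
        eta = c(train_s[3], test_s[3]))
    )
  }

  list(
    scores = scores,
    summary = summary,
    response = response,
    anova = anova,
    validation = condition(
      c(0.7899, 0.7866, 0.7808), c(0.7858, 0.0046, 13.3823),
      c(0.7763, 0.7772, 0.7707), c(0.7747, 0.0035, 12.9461)),
    size300 = condition(
      c(0.7410, 0.7389, 0.7475), c(0.7425, 0.0045, 11.7833),
      c(0.7081, 0.7099, 0.7102), c(0.7094, 0.0011, 10.7341)),
    matlab_default = condition(
      c(0.7374, 0.7408, 0.7326), c(0.7369, 0.0041, 11.5987),
      c(0.7383, 0.7570, 0.7471), c(0.7475, 0.0094, 11.9536)),
    headline_ap = list(ap = c(WBC = 0.9766, RBC = 0.7627,
                              Platelets = 0.5895),
                       map = 0.7763),
    counts = data.frame(
      class = c("WBC", "RBC", "Platelets"),
      n_gt = c(73L, 846L, 75L),
      n_detected = c(75L, 1628L, 57L),
      stringsAsFactors = FALSE)
  )
}
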