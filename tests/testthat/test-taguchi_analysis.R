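tol4 <- 5e-4 # printed quantities carry four decimals

test_that("the deviation-from-target SNR matches its closed form", {
  expect_close(as.numeric(snr_target(c(0.7179, 0.7113, 0.6713))),
               10.4624, tol = tol4)
  expect_close(as.numeric(snr_target(c(0.7763, 0.7772, 0.7707))),
               12.9461, tol = tol4)
  expect_close(as.numeric(snr_target(c(0, 0, 0))), 0)
  expect_equal(as.numeric(snr_target(c(0.9, 0.9, 0.9))), 20)
  expect_equal(as.numeric(snr_target(0.5)), -20 * log10(0.5))
  expect_error(snr_target(numeric(0)), "non-empty")
})

test_that("an on-target mean hits the configured ceiling and is flagged", {
  eta <- snr_target(c(1, 1, 1))
  expect_equal(as.numeric(eta), 200)
  expect_true(attr(eta, "capped"))
  s <- summarize_replicates(c(1, 1, 1))
  expect_true(s$eta_capped)
  expect_equal(s$eta, 200)
})

test_that("SNR strictly increases as the replicate mean approaches target", {
  means <- seq(0.05, 0.95, by = 0.05)
  etas <- vapply(means, function(m) as.numeric(snr_target(m)), numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("replicate summaries use the n-1 standard deviation", {
  s <- summarize_replicates(c(0.7179, 0.7113, 0.6713), run_id = 1)
  expect_close(s$mean, 0.7002, tol = tol4)
  expect_close(s$sd, 0.0252, tol = tol4)
  expect_close(s$eta, 10.4624, tol = tol4)
  s2 <- summarize_replicates(c(0.7322, 0.7194, 0.7111), dataset = "training")
  expect_close(s2$mean, 0.7209, tol = tol4)
  expect_close(s2$sd, 0.0106, tol = tol4)
  expect_close(s2$eta, 11.0848, tol = tol4)
  s3 <- summarize_replicates(c(0.5, 0.5, 0.5))
  expect_close(s3$sd, 0)
  expect_close(s3$eta, 6.0206, tol = tol4)
  expect_error(summarize_replicates(0.5), "at least 2")
})

test_that("the response table averages eta over exactly the matching runs", {
  etas <- reference_test_etas()
  rt <- response_table(l9_array(), etas, ssd_factor_space())
  expect_close(unname(rt$E[, 1]),
               c(11.0706, 7.5317, 8.9597, 7.8048), tol = tol4)
  expect_close(unname(rt$effect),
               c(8.7006, 1.8721, 2.1564, 1.9493), tol = tol4)
  expect_close(unname(rt$best_level), c(3L, 3L, 2L, 2L))
  expect_equal(rt$best_value$Optimizer, "adam")
  expect_equal(rt$best_value$MiniBatchSize, 18)
  expect_equal(rt$best_value$InitialLearnRate, 1e-4)
  expect_equal(rt$best_value$LearnRateDropPeriod, 40)
  # each entry is the mean of three runs, directly
  expect_equal(rt$E["Optimizer", 1], mean(etas[1:3]))
  expect_equal(rt$E["MiniBatchSize", 2], mean(etas[c(2, 5, 8)]))
})

test_that("constant responses flatten the table and flag ties", {
  rt <- response_table(l9_array(), rep(7, 9), ssd_factor_space())
  expect_true(all(rt$E == 7))
  expect_true(all(rt$effect == 0))
  expect_true(all(rt$tie))
  expect_equal(unname(rt$best_level), rep(1L, 4)) # lowest index on ties
  bc <- best_combination(rt)
  expect_true(all(bc$tie))
  expect_equal(bc$level, rep(1L, 4))
})

test_that("a dominant level is selected per factor", {
  etas <- c(1, 1, 1, 1, 1, 1, 9, 9, 9) # runs 7-9 sit at optimizer level 3
  rt <- response_table(l9_array(), etas)
  expect_equal(unname(rt$best_level[1]), 3L)
  expect_false(rt$tie[[1]])
})

test_that("Taguchi ANOVA reproduces the reference decomposition", {
  etas <- reference_test_etas()
  av <- taguchi_anova(l9_array(), etas, ssd_factor_space())
  tab <- av$table
  expect_close(tab["Optimizer", "SS"], 148.0572, tol = tol4)
  expect_close(tab["Optimizer", "V"], 74.0286, tol = tol4)
  expect_close(tab["MiniBatchSize", "SS"], 5.7544, tol = tol4)
  expect_close(tab["InitialLearnRate", "SS"], 8.9246, tol = tol4)
  expect_close(tab["LearnRateDropPeriod", "SS"], 6.8096, tol = tol4)
  expect_close(tab$pct[1:4], c(87.33, 3.39, 5.26, 4.02), tol = 0.005)
  expect_equal(tab["Error", "SS"], 0, tolerance = 1e-9)
  expect_close(tab["Total", "SS"], 169.5457, tol = tol4)
  expect_close(tab["Total", "df"], 8)
  expect_equal(sum(tab$pct[1:5]), 100, tolerance = 1e-9)
})

test_that("the sums-of-squares decomposition is exact for random etas", {
  oa <- l9_array()
  set.seed(42)
  for (k in 1:100) {
    etas <- runif(9, 0, 20)
    av <- taguchi_anova(oa, etas)
    S_T_direct <- sum((etas - mean(etas))^2)
    ss_sum <- sum(av$table$SS[1:4]) + av$table["Error", "SS"]
    expect_equal(ss_sum, S_T_direct, tolerance = 1e-9)
    expect_equal(av$table["Total", "SS"], S_T_direct, tolerance = 1e-12)
  }
})

test_that("degenerate and over-saturated designs are handled explicitly", {
  av <- taguchi_anova(l9_array(), rep(3, 9))
  expect_true(av$degenerate)
  expect_true(all(av$table$SS == 0))
  expect_true(all(av$table$pct == 0))
  tiny <- orthogonal_array(matrix(c(1:3, 1:3), ncol = 2))
  expect_error(taguchi_anova(tiny, c(1, 2, 3)), "over-saturated")
})

test_that("pooling the smallest factor refreshes the error term", {
  etas <- reference_test_etas()
  av <- pool_anova_error(taguchi_anova(l9_array(), etas, ssd_factor_space()),
                         n_pool = 1)
  expect_equal(av$pooled, "MiniBatchSize") # smallest SS factor
  expect_false("MiniBatchSize" %in% setdiff(rownames(av$table),
                                            c("Error", "Total")))
  expect_close(av$table["Error", "SS"], 5.7544, tol = tol4)
  expect_equal(av$table["Error", "df"], 2)
  expect_equal(sum(av$table$pct[seq_len(nrow(av$table) - 1)]), 100,
               tolerance = 1e-9)
})

test_that("long score tables summarize one row per run and dataset", {
  fx <- ssd_study_tables()
  sm <- summarize_scores(fx$scores)
  expect_equal(nrow(sm), 18)
  expect_setequal(unique(sm$dataset), c("test", "training"))
  expect_equal(sm$n, rep(3L, 18))
})
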