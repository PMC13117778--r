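test_that("ensemble averaging is a per-key mean over aligned tables", {
  t1 <- random_prob_table(seed = 1)
  expect_equal(ensemble_average(replicate(5, t1, simplify = FALSE)), t1,
               tolerance = 1e-12)

  two <- t1[1, ]
  a <- two; a$p_benign <- 1; a$p_malignant <- 0
  b <- two; b$p_benign <- 0; b$p_malignant <- 1
  av <- ensemble_average(list(a, b))
  expect_equal(c(av$p_benign, av$p_malignant), c(0.5, 0.5))

  tabs <- lapply(1:5, function(s) {
    t <- random_prob_table(seed = s)
    t[sample(nrow(t)), ]          # key alignment must not depend on order
  })
  av5 <- ensemble_average(tabs)
  key <- function(t) paste(t$patient_id, t$image_id, t$patch_index)
  for (r in sample(nrow(av5), 10)) {
    k <- key(av5)[r]
    vals <- vapply(tabs, function(t) t$p_malignant[key(t) == k], numeric(1))
    expect_equal(av5$p_malignant[r], mean(vals), tolerance = 1e-12)
  }

  bad <- tabs[[1]]
  bad$patch_index <- bad$patch_index + 100L
  expect_error(ensemble_average(list(tabs[[1]], bad)), "different key set")
})

test_that("image aggregation averages exactly the image's patches", {
  t1 <- random_prob_table(n_patients = 2, n_images = 2, n_patches = 6,
                          seed = 2)
  im <- aggregate_image(t1)
  expect_equal(nrow(im), 4L)
  expect_equal(im$n_patches, rep(6L, 4))
  for (r in seq_len(nrow(im))) {
    rows <- t1[t1$image_id == im$image_id[r], ]
    expect_equal(im$p_malignant[r], mean(rows$p_malignant), tolerance = 1e-12)
  }

  one <- t1[1, ]
  im1 <- aggregate_image(one)
  expect_equal(im1$p_benign, one$p_benign)

  sym <- t1[1:3, ]
  sym$p_benign <- c(0.9, 0.5, 0.1); sym$p_malignant <- c(0.1, 0.5, 0.9)
  sym$image_id <- "same"; sym$patient_id <- "p"
  ims <- aggregate_image(sym)
  expect_equal(c(ims$p_benign, ims$p_malignant), c(0.5, 0.5))
  expect_equal(ims$label_pred, "malignant")  # argmax tie goes to malignant
})

test_that("patient aggregation averages images and thresholds at 0.5", {
  im <- data.frame(patient_id = "p1", image_id = c("a", "b", "c"),
                   p_malignant = c(0.9, 0.2, 0.4))
  im$p_benign <- 1 - im$p_malignant
  pa <- aggregate_patient(im)
  expect_equal(pa$p_malignant, 0.5)
  expect_equal(pa$label_pred, "malignant")     # boundary rule

  single <- data.frame(patient_id = "q", image_id = "a",
                       p_benign = 0.8, p_malignant = 0.2)
  ps <- aggregate_patient(single)
  expect_equal(ps$p_malignant, 0.2)
  expect_equal(ps$label_pred, "benign")

  t1 <- random_prob_table(seed = 4)
  pr <- aggregate_patient(aggregate_image(t1))
  for (r in seq_len(nrow(pr))) {
    imr <- aggregate_image(t1[t1$patient_id == pr$patient_id[r], ])
    expect_equal(pr$p_malignant[r], mean(imr$p_malignant), tolerance = 1e-12)
  }
})

test_that("aggregation obeys conservation, permutation and composition laws", {
  for (s in 1:5) {
    t1 <- random_prob_table(n_patients = 4, n_images = 3, n_patches = 5,
                            seed = s)
    im <- aggregate_image(t1)
    pa <- aggregate_patient(im)
    expect_true(all(abs(im$p_benign + im$p_malignant - 1) < 1e-9))
    expect_true(all(abs(pa$p_benign + pa$p_malignant - 1) < 1e-9))
    expect_true(all(im$p_malignant >= 0 & im$p_malignant <= 1))

    shuf <- t1[sample(nrow(t1)), ]
    expect_equal(aggregate_patient(aggregate_image(shuf)), pa,
                 tolerance = 1e-12)

    # patient mean = weighted mean of patches with weights 1/(M * N_i)
    for (pid in unique(t1$patient_id)) {
      rows <- t1[t1$patient_id == pid, ]
      m <- length(unique(rows$image_id))
      wts <- 1 / (m * ave(rows$patch_index, rows$image_id, FUN = length))
      expect_equal(pa$p_malignant[pa$patient_id == pid],
                   sum(rows$p_malignant * wts), tolerance = 1e-12)
    }
  }
})

test_that("confusion metrics reproduce the published worked examples", {
  m100 <- confusion_metrics(17, 1, 0, 7)
  expect_equal(m100$accuracy, 0.96)
  expect_equal(m100$precision, 17 / 18, tolerance = 1e-12)
  expect_equal(round(m100$precision, 4), 0.9444)
  expect_equal(m100$recall, 1)
  expect_equal(round(m100$f1, 4), 0.9714)

  m40 <- confusion_metrics(16, 1, 1, 7)
  expect_equal(m40$accuracy, 0.92)
  expect_equal(round(m40$f1, 4), 0.9412)
  expect_equal(round(m40$recall, 4), 0.9412)

  perf <- confusion_metrics(5, 0, 0, 5)
  expect_equal(c(perf$accuracy, perf$precision, perf$recall,
                 perf$specificity, perf$f1), rep(1, 5))
})

test_that("metrics are consistent with their own counts and flag undefined ones", {
  set.seed(31)
  for (r in 1:20) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) cts[1] <- 1
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$fp + m$fn + m$tn))
    if (!is.na(m$precision)) expect_equal(m$precision, m$tp / (m$tp + m$fp))
    if (!is.na(m$recall)) expect_equal(m$recall, m$tp / (m$tp + m$fn))
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)$precision))
  expect_true(is.na(confusion_metrics(0, 5, 0, 5)$recall))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("percentile bootstrap matches exact small-sample enumeration", {
  # all correct: degenerate interval at 1
  expect_equal(bootstrap_ci(rep(1, 10), seed = 1),
               c(low = 1, high = 1))

  # n = 3, (1, 1, 0): 27 equally likely resamples; exact inverse-CDF
  # quantiles of the resampling distribution are 0 and 1
  accs <- apply(expand.grid(1:3, 1:3, 1:3), 1,
                function(i) mean(c(1, 1, 0)[i]))
  exact <- unname(quantile(accs, c(0.025, 0.975), type = 1))
  ci <- bootstrap_ci(c(1, 1, 0), iterations = 4000, seed = 2)
  expect_equal(unname(ci), exact)

  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("bootstrap of 24-of-25 correct reproduces the 0.88 lower bound", {
  lows <- vapply(1:10, function(s)
    bootstrap_ci(c(rep(1, 24), 0), iterations = 1000, seed = s)[["low"]],
    numeric(1))
  modal <- as.numeric(names(sort(table(lows), decreasing = TRUE))[1])
  expect_equal(modal, 0.88)
  highs <- vapply(1:10, function(s)
    bootstrap_ci(c(rep(1, 24), 0), iterations = 1000, seed = s)[["high"]],
    numeric(1))
  expect_true(all(highs == 1))
})

test_that("paired fold comparison matches the closed form and flags ties", {
  base <- c(0.90, 0.92, 0.94, 0.91, 0.93)
  r <- paired_fold_test(base + c(1, 2, 3, 4, 5), base)
  d <- c(1, 2, 3, 4, 5)
  expect_false(r$degenerate)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)

  r2 <- paired_fold_test(base, base + d)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)

  same <- paired_fold_test(base, base)
  expect_true(same$degenerate)
  expect_true(is.na(same$t))

  expect_error(paired_fold_test(1:3, 1:4), "equal length")
})

test_that("patient evaluation builds counts, metrics and a CI together", {
  preds <- data.frame(patient_id = paste0("p", 1:6),
                      p_benign = c(0.9, 0.8, 0.2, 0.1, 0.3, 0.6),
                      p_malignant = c(0.1, 0.2, 0.8, 0.9, 0.7, 0.4))
  preds$label_pred <- ifelse(preds$p_malignant >= 0.5, "malignant", "benign")
  truth <- data.frame(patient_id = paste0("p", 1:6),
                      label = c("benign", "benign", "malignant", "malignant",
                                "benign", "malignant"))
  rep <- evaluate_patients(preds, truth, seed = 3)
  expect_equal(c(rep$tp, rep$fp, rep$fn, rep$tn), c(2, 1, 1, 2))
  expect_equal(rep$accuracy, 4 / 6)
  expect_lte(rep$ci_low, rep$accuracy)
  expect_gte(rep$ci_high, rep$accuracy)
})
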