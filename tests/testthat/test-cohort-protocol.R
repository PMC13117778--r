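test_that("patient split stratifies by class with round() test counts", {
  coh <- stub_cohort(24, 58)
  sp <- patient_split(coh, 0.30, seed = 42)
  lab <- function(ids) as.integer(table(sub("_.*", "", ids)))
  expect_equal(unname(lab(sp$test_patients)), c(7L, 17L))   # round(24*.3)=7
  expect_equal(unname(lab(sp$train_patients)), c(17L, 41L))
  expect_length(intersect(sp$train_patients, sp$test_patients), 0L)

  # published-split override: 16/41 train, 8/17 test
  sp2 <- patient_split(coh, seed = 42,
                       test_counts = c(benign = 8, malignant = 17))
  expect_equal(unname(lab(sp2$test_patients)), c(8L, 17L))
  expect_equal(unname(lab(sp2$train_patients)), c(16L, 41L))

  sp3 <- patient_split(stub_cohort(10, 10), 0.30, seed = 1)
  expect_equal(unname(lab(sp3$test_patients)), c(3L, 3L))
  expect_equal(unname(lab(sp3$train_patients)), c(7L, 7L))

  expect_identical(patient_split(coh, seed = 9), patient_split(coh, seed = 9))
  expect_error(patient_split(stub_cohort(1, 10)), "at least 2")
})

test_that("stratified k-fold partitions the training split evenly per class", {
  coh <- stub_cohort(21, 57)  # 15 + 40 in training after round() split
  sp <- patient_split(coh, 0.30, seed = 3)
  fp <- stratified_kfold(sp, coh, k = 5, seed = 3)
  lab <- function(ids) c(ben = sum(grepl("^ben", ids)),
                         mal = sum(grepl("^mal", ids)))
  per <- sapply(fp$folds, lab)
  expect_equal(unname(per["ben", ]), rep(3L, 5))
  expect_equal(unname(per["mal", ]), rep(8L, 5))
  expect_setequal(unlist(fp$folds), sp$train_patients)

  expect_error(stratified_kfold(patient_split(stub_cohort(5, 20), seed = 1),
                                stub_cohort(5, 20), k = 5),
               "at least k")
})

test_that("fold class ratios stay within one patient of balance across cohorts", {
  set.seed(99)
  for (rep in 1:100) {
    nb <- sample(6:20, 1); nm <- sample(6:30, 1)
    coh <- stub_cohort(nb, nm)
    sp <- patient_split(coh, 0.30, seed = rep)
    fp <- stratified_kfold(sp, coh, k = 3, seed = rep)
    for (cls in c("ben", "mal")) {
      sizes <- vapply(fp$folds, function(f) sum(grepl(paste0("^", cls), f)),
                      integer(1))
      expect_lte(max(sizes) - min(sizes), 1L)
    }
    expect_setequal(unlist(fp$folds), sp$train_patients)
  }
})

test_that("leakage audit passes clean plans and flags planted violations", {
  coh <- stub_cohort(8, 10)
  sp <- patient_split(coh, 0.30, seed = 5)
  fp <- stratified_kfold(sp, coh, k = 5, seed = 5)

  a1 <- leakage_audit(list(train = sp$train_patients,
                           test = sp$test_patients))
  expect_true(a1$pass)
  expect_length(a1$violations, 0L)

  # every training patient in exactly one of the 5 folds
  a2 <- leakage_audit(fp$folds)
  expect_true(a2$pass)
  expect_setequal(unlist(fp$folds), sp$train_patients)

  # planted violation: one patient's patches recorded in train and test
  man <- data.frame(
    patient_id = c("ben_01", "ben_01", "mal_02"),
    subset = c("train", "test", "train"))
  a3 <- leakage_audit(list(train = sp$train_patients,
                           test = sp$test_patients), man)
  expect_false(a3$pass)
  expect_equal(a3$violations, "ben_01")

  a4 <- leakage_audit(list(train = c("p1", "p2"), test = c("p2", "p3")))
  expect_false(a4$pass)
  expect_equal(a4$violations, "p2")
})

test_that("plans are pure functions of cohort and seed", {
  coh <- stub_cohort(9, 13)
  expect_identical(patient_split(coh, seed = 4), patient_split(coh, seed = 4))
  sp <- patient_split(coh, seed = 4)
  expect_identical(stratified_kfold(sp, coh, k = 4, seed = 8),
                   stratified_kfold(sp, coh, k = 4, seed = 8))
})

test_that("cohort index validation catches structural problems", {
  expect_error(cohort_index(data.frame(patient_id = "p")), "missing columns")
  bad <- data.frame(patient_id = c("p1", "p1"), image_id = c("a", "b"),
                    magnification = "40X", label = c("benign", "malignant"))
  expect_error(cohort_index(bad), "conflicting labels")
})
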