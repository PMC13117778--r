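# Patient-level cohort handling: leakage-free 70/30 split, stratified
# patient-wise k-fold cross-validation, and the leakage audit.

#' Build a cohort index
#'
#' Validates and tags a per-image table as a cohort index. Labels are
#' provided at the patient level: every patient must carry exactly one
#' label and at least one image.
#'
#' @param images Data frame with columns `patient_id`, `image_id`,
#'   `magnification`, `label` (`"benign"`/`"malignant"`) and optionally
#'   `path`.
#' @return The validated data frame with class `cohort_index`.
#' @export
cohort_index <- function(images) {
  req <- c("patient_id", "image_id", "magnification", "label")
  miss <- setdiff(req, names(images))
  if (length(miss))
    stop("cohort index missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(images) == 0L) stop("empty cohort", call. = FALSE)
  if (!all(images$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  nlab <- tapply(images$label, images$patient_id,
                 function(l) length(unique(l)))
  if (any(nlab > 1L))
    stop("patients with conflicting labels: ",
         paste(names(nlab)[nlab > 1L], collapse = ", "), call. = FALSE)
  class(images) <- unique(c("cohort_index", class(images)))
  images
}

.patient_table <- function(cohort) {
  unique(as.data.frame(cohort)[, c("patient_id", "label")])
}

#' Patient-level train/test split
#'
#' Splits the cohort's patients into training and test sets, stratified by
#' class: per class the test count is `round(n_class * test_fraction)` (at
#' least 1, at most `n_class - 1`), with assignment by seeded shuffle within
#' the class. All images and patches of a patient follow the patient, so no
#' leakage is possible by construction.
#'
#' @param cohort A [cohort_index()].
#' @param test_fraction Fraction of patients per class held out (default
#'   0.30).
#' @param seed Integer seed for the shuffles.
#' @param test_counts Optional named vector `c(benign =, malignant =)`
#'   overriding the per-class test counts (e.g. to reproduce a published
#'   split whose rounding rule is not recoverable).
#' @return An object of class `split_plan`: list with `train_patients`,
#'   `test_patients`, `seed`, `test_fraction`.
#' @export
patient_split <- function(cohort, test_fraction = 0.30, seed = 1L,
                          test_counts = NULL) {
  pts <- .patient_table(cohort)
  train <- character(0); test <- character(0)
  set.seed(seed)
  for (cls in c("benign", "malignant")) {
    ids <- pts$patient_id[pts$label == cls]
    n <- length(ids)
    if (n < 2L)
      stop("class '", cls, "' has ", n,
           " patient(s); at least 2 are required to split", call. = FALSE)
    nt <- if (!is.null(test_counts)) as.integer(test_counts[[cls]])
          else round(n * test_fraction)
    nt <- min(max(nt, 1L), n - 1L)
    ids <- ids[sample.int(n)]
    test <- c(test, ids[seq_len(nt)])
    train <- c(train, ids[-seq_len(nt)])
  }
  structure(list(train_patients = sort(train), test_patients = sort(test),
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "split_plan")
}

#' Stratified patient-wise k-fold plan
#'
#' Partitions the training patients into `k` folds, stratified by class:
#' within each class, patients are shuffled (seeded) and dealt round-robin,
#' so fold sizes differ by at most one patient per class and every patient
#' appears in exactly one fold.
#'
#' @param plan A [patient_split()] plan.
#' @param cohort The [cohort_index()] the plan was drawn from.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffles.
#' @return An object of class `fold_plan`: list with `folds` (list of `k`
#'   patient-id vectors), `k`, `seed`.
#' @export
stratified_kfold <- function(plan, cohort, k = 5L, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  pts <- .patient_table(cohort)
  pts <- pts[pts$patient_id %in% plan$train_patients, ]
  folds <- replicate(k, character(0), simplify = FALSE)
  set.seed(seed)
  for (cls in c("benign", "malignant")) {
    ids <- pts$patient_id[pts$label == cls]
    if (length(ids) < k)
      stop("class '", cls, "' has ", length(ids),
           " training patient(s); need at least k = ", k, call. = FALSE)
    ids <- ids[sample.int(length(ids))]
    for (i in seq_along(ids)) {
      f <- (i - 1L) %% k + 1L
      folds[[f]] <- c(folds[[f]], ids[i])
    }
  }
  structure(list(folds = lapply(folds, sort), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Audit subsets for patient leakage
#'
#' Checks that no patient contributes data to more than one subset, both at
#' the plan level (overlapping patient-id sets) and, when a patch manifest
#' is given, at the manifest level (a patient's patches recorded under more
#' than one subset). The audit always returns; a non-empty violation list
#' means the plan must not be used for training.
#'
#' @param subsets Named list of patient-id vectors (e.g.
#'   `list(train = ..., test = ...)` or the `folds` of a [stratified_kfold()]
#'   plan).
#' @param manifest Optional data frame with columns `patient_id` and
#'   `subset`.
#' @return List with `violations` (character vector of offending patient
#'   ids) and `pass` (logical).
#' @export
leakage_audit <- function(subsets, manifest = NULL) {
  stopifnot(is.list(subsets))
  ids <- unlist(subsets, use.names = FALSE)
  viol <- unique(ids[duplicated(ids)])
  if (!is.null(manifest)) {
    stopifnot(all(c("patient_id", "subset") %in% names(manifest)))
    nsub <- tapply(manifest$subset, manifest$patient_id,
                   function(s) length(unique(s)))
    viol <- union(viol, names(nsub)[nsub > 1L])
  }
  list(violations = sort(viol), pass = length(viol) == 0L)
}
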