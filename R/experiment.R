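# End-to-end study driver: split -> folds -> patches -> training ->
# ensemble -> hierarchical aggregation -> metrics.

.load_image <- function(row, images = NULL) {
  if (!is.null(images) && !is.null(images[[row$image_id]]))
    return(images[[row$image_id]])
  if (is.na(row$path)) stop("image ", row$image_id,
                            " has no path and no in-memory copy", call. = FALSE)
  img <- png::readPNG(row$path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  img[, , 1:3, drop = FALSE]
}

#' Extract the patch set of a group of patients
#'
#' Runs the tiling plan over every image of the given patients — strictly
#' after the patient-level split, never before — and returns patch records
#' resized to the model input size.
#'
#' @param cohort A [cohort_index()].
#' @param patients Character vector of patient ids to include.
#' @param images Optional named list of in-memory images (values in
#'   `[0, 1]`), keyed by `image_id`; otherwise images are read from the
#'   index's `path` column.
#' @param input_size Side length patches are resized to (`NULL` keeps the
#'   native patch size).
#' @param patch_size,overlap Tiling parameters (defaults 224, 0.20).
#' @return List of patch records (see [extract_patches()]).
#' @export
cohort_patches <- function(cohort, patients, images = NULL,
                           input_size = NULL, patch_size = 224L,
                           overlap = 0.20) {
  df <- as.data.frame(cohort)
  df <- df[df$patient_id %in% patients, ]
  if (nrow(df) == 0L) stop("no images for the requested patients",
                           call. = FALSE)
  recs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    img <- .load_image(row, images)
    grid <- plan_grid(dim(img)[1], dim(img)[2], patch_size, overlap)
    pr <- extract_patches(img, grid, patient_id = row$patient_id,
                          image_id = row$image_id,
                          magnification = row$magnification,
                          label = row$label)
    if (!is.null(input_size)) {
      pr <- lapply(pr, function(r) {
        r$pixels <- resize_bilinear(r$pixels, input_size, input_size)
        r
      })
    }
    recs <- c(recs, pr)
  }
  recs
}

#' Train and evaluate one model on a patient-level split
#'
#' The compact single-split protocol: 70/30 patient split, balanced
#' training patches, one model, hierarchical aggregation of the test
#' predictions to patient level.
#'
#' @param cohort A [cohort_index()].
#' @param images Optional in-memory image list (see [cohort_patches()]).
#' @param seed Integer seed driving the split, balancing, initialization
#'   and shuffling.
#' @param mswa `NULL` for the plain backbone or a [wavelet_spec()]/per-stage
#'   list (see [model_config()]).
#' @param epochs,learning_rate,batch_size Training settings.
#' @param width_multiplier,input_size Desk-scale reductions (see
#'   [model_config()]).
#' @param test_fraction Held-out patient fraction.
#' @return List with `patient_acc`, `patch_acc`, `metrics`
#'   (a `metrics_report` with bootstrap CI), `patient_preds`, `model`,
#'   `split`.
#' @export
run_patient_eval <- function(cohort, images = NULL, seed = 1L, mswa = NULL,
                             epochs = 5L, learning_rate = 3e-4,
                             batch_size = 32L, width_multiplier = 0.25,
                             input_size = 56L, test_fraction = 0.30) {
  split <- patient_split(cohort, test_fraction, seed = seed)
  train_recs <- cohort_patches(cohort, split$train_patients, images,
                               input_size = input_size)
  train_recs <- balance_training_set(train_recs, seed = seed)
  train_set <- records_to_patchset(train_recs)
  test_set <- records_to_patchset(
    cohort_patches(cohort, split$test_patients, images,
                   input_size = input_size))
  cfg <- model_config(num_classes = 2L, mswa = mswa,
                      width_multiplier = width_multiplier,
                      input_size = input_size)
  model <- build_model(cfg, seed = seed)
  tcfg <- train_config(learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs, seed = seed)
  model <- train_fold(model, train_set, tcfg)
  probs <- predict_probs(model, test_set)
  patch_acc <- mean(
    ifelse(probs$p_malignant >= probs$p_benign, "malignant", "benign") ==
      test_set$meta$label)
  pats <- aggregate_patient(aggregate_image(probs))
  metrics <- evaluate_patients(pats, test_set$meta, seed = seed)
  list(patient_acc = metrics$accuracy, patch_acc = patch_acc,
       metrics = metrics, patient_preds = pats, model = model,
       split = split)
}

#' Run the full cross-validated study protocol
#'
#' The reference protocol end to end: stratified patient-level 70/30 split,
#' stratified patient-wise k-fold cross-validation on the training split
#' (with a leakage audit that refuses to continue on any violation), one
#' model per fold selected by validation patient-level accuracy, ensemble
#' averaging of the fold models' test-patch probabilities (or a single
#' refit on the whole training split), hierarchical aggregation and
#' patient-level metrics with a bootstrap confidence interval.
#'
#' @inheritParams run_patient_eval
#' @param k Number of cross-validation folds (default 5).
#' @param ensemble `"folds"` (average the k fold models, default) or
#'   `"refit"` (retrain once on the whole training split).
#' @return List with `metrics`, `patient_preds`, `image_preds`,
#'   `prob_table`, `fold_val_acc`, `split`, `folds`.
#' @export
run_study <- function(cohort, images = NULL, seed = 1L, mswa = NULL, k = 5L,
                      ensemble = c("folds", "refit"), epochs = 5L,
                      learning_rate = 3e-4, batch_size = 32L,
                      width_multiplier = 0.25, input_size = 56L,
                      test_fraction = 0.30) {
  ensemble <- match.arg(ensemble)
  split <- patient_split(cohort, test_fraction, seed = seed)
  folds <- stratified_kfold(split, cohort, k = k, seed = seed)
  audit <- leakage_audit(c(list(test = split$test_patients), folds$folds))
  if (!audit$pass)
    stop("leakage audit failed for patients: ",
         paste(audit$violations, collapse = ", "), call. = FALSE)
  cfg <- model_config(num_classes = 2L, mswa = mswa,
                      width_multiplier = width_multiplier,
                      input_size = input_size)
  test_set <- records_to_patchset(
    cohort_patches(cohort, split$test_patients, images,
                   input_size = input_size))
  fold_tables <- list()
  fold_val_acc <- numeric(0)
  if (ensemble == "folds") {
    for (f in seq_len(folds$k)) {
      tr_pat <- setdiff(split$train_patients, folds$folds[[f]])
      tr <- balance_training_set(
        cohort_patches(cohort, tr_pat, images, input_size = input_size),
        seed = seed + f)
      tr_set <- records_to_patchset(tr)
      va_set <- records_to_patchset(
        cohort_patches(cohort, folds$folds[[f]], images,
                       input_size = input_size))
      model <- build_model(cfg, seed = seed + f)
      tcfg <- train_config(learning_rate = learning_rate,
                           batch_size = batch_size, epochs = epochs,
                           seed = seed + f)
      model <- train_fold(model, tr_set, tcfg, val_patches = va_set)
      fold_val_acc <- c(fold_val_acc, max(model$history$val_acc, na.rm = TRUE))
      fold_tables[[f]] <- predict_probs(model, test_set)
    }
    probs <- ensemble_average(fold_tables)
  } else {
    tr <- balance_training_set(
      cohort_patches(cohort, split$train_patients, images,
                     input_size = input_size), seed = seed)
    model <- build_model(cfg, seed = seed)
    tcfg <- train_config(learning_rate = learning_rate,
                         batch_size = batch_size, epochs = epochs,
                         seed = seed)
    model <- train_fold(model, records_to_patchset(tr), tcfg)
    probs <- predict_probs(model, test_set)
  }
  image_preds <- aggregate_image(probs)
  patient_preds <- aggregate_patient(image_preds)
  metrics <- evaluate_patients(patient_preds, test_set$meta, seed = seed)
  list(metrics = metrics, patient_preds = patient_preds,
       image_preds = image_preds, prob_table = probs,
       fold_val_acc = fold_val_acc, split = split, folds = folds)
}
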