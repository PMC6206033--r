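# Subclassifier training: C-classification SVM with a Gaussian RBF kernel
# on log-transformed, standardized peptide amplitudes. Hyperparameters are
# chosen by stratified cross-validated AUC over a small grid; panels are
# pruned by take-one-out backward elimination against the same objective.

# Feature transform: log(amplitude + 1), then per-peptide standardization
# with constants learned on training data (zero-sd features get sd 1 so
# they stay constant instead of producing NaN).
feature_transform_fit <- function(amp_panel) {
  lx <- log1p(amp_panel)
  mu <- colMeans(lx)
  s <- apply(lx, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, sd = s)
}

feature_transform_apply <- function(amp_panel, transform) {
  lx <- log1p(amp_panel)
  sweep(sweep(lx, 2, transform$mu), 2, transform$sd, "/")
}

# Extract panel amplitudes for samples; peptides missing from the matrix
# are imputed as non-detected (0) and counted.
panel_amplitudes <- function(amp, panel_ids) {
  present <- intersect(panel_ids, colnames(amp))
  out <- matrix(0, nrow(amp), length(panel_ids),
                dimnames = list(rownames(amp), panel_ids))
  out[, present] <- amp[, present]
  attr(out, "n_missing") <- length(panel_ids) - length(present)
  out
}

#' Default hyperparameter grid for subclassifier training
#'
#' Regularization cost in \{0.1, 1, 10, 100\} and RBF kernel width gamma in
#' \{0.1, 1, 10\} / d where d is the panel size (features are standardized,
#' so 1/d is the usual variance-scaled width).
#'
#' @param d panel size
#' @return data.frame with columns cost, gamma
#' @export
default_svm_grid <- function(d) {
  expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(0.1, 1, 10) / max(d, 1))
}

fit_rbf_svm <- function(x, y, cost, gamma) {
  wts <- length(y) / (2 * table(y))  # inverse class-frequency weights
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             class.weights = wts, fitted = FALSE)
}

decision_values <- function(fit, x) {
  as.numeric(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
}

# Cross-validated AUC of an RBF SVM at fixed hyperparameters.
cv_auc <- function(x, y, cost, gamma, folds) {
  k <- max(folds)
  aucs <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    fit <- fit_rbf_svm(x[tr, , drop = FALSE], y[tr], cost, gamma)
    # orient on the training fold: higher decision value = more case-like
    dv_tr <- decision_values(fit, x[tr, , drop = FALSE])
    flip <- mean(dv_tr[y[tr] == "case"]) < mean(dv_tr[y[tr] == "control"])
    dv <- decision_values(fit, x[te, , drop = FALSE])
    if (flip) dv <- -dv
    aucs <- c(aucs, auc_rank(dv, y[te] == "case"))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

# Grid search over hyperparameters by CV AUC; deterministic tie-break
# (smaller cost, then smaller gamma).
select_hyperparameters <- function(x, y, grid, folds) {
  objs <- vapply(seq_len(nrow(grid)), function(i) {
    cv_auc(x, y, grid$cost[i], grid$gamma[i], folds)
  }, numeric(1))
  ord <- order(-objs, grid$cost, grid$gamma)
  best <- ord[1]
  list(cost = grid$cost[best], gamma = grid$gamma[best], cv_auc = objs[best])
}

#' Train a peptide-panel SVM subclassifier
#'
#' Features are log(amplitude + 1) standardized by training statistics.
#' An RBF-kernel C-classification SVM with inverse-class-frequency weights
#' is tuned by maximizing stratified cross-validated AUC over the
#' hyperparameter grid, then refit on all training samples. The fitted
#' model is stored as explicit support vectors and coefficients so that
#' scoring is self-contained and models serialize to plain JSON.
#'
#' @param matrix a normalized [peptide_matrix()]
#' @param labels data.frame with `patient_id` and `label`; only rows labeled
#'   "rapid" (cases) or "stable" (controls) are used
#' @param panel a `peptide_panel` or character vector of peptide ids
#' @param grid hyperparameter data.frame (cost, gamma); default
#'   [default_svm_grid()]
#' @param cv_folds stratified CV folds (default 5)
#' @param seed controls fold assignment
#' @param stratum optional stratum id recorded in metadata
#' @return object of class `ckd_classifier`
#' @export
train_svm <- function(matrix, labels, panel, grid = NULL, cv_folds = 5,
                      seed = 1, stratum = NA) {
  panel_ids <- if (is.data.frame(panel)) panel$peptide_id else as.character(panel)
  if (!length(panel_ids)) stopf("empty panel")
  use <- labels[labels$label %in% c("rapid", "stable"), ]
  use <- use[use$patient_id %in% rownames(matrix$amplitudes), ]
  use <- use[order(use$patient_id), ]  # canonical order: sample-order invariance
  y <- factor(ifelse(use$label == "rapid", "case", "control"),
              levels = c("case", "control"))
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stopf("training needs at least 2 samples per class")
  }
  amp <- panel_amplitudes(matrix$amplitudes[use$patient_id, , drop = FALSE],
                          panel_ids)
  transform <- feature_transform_fit(amp)
  x <- feature_transform_apply(amp, transform)
  if (is.null(grid)) grid <- default_svm_grid(ncol(x))
  folds <- stratified_folds(y, cv_folds, seed)
  hp <- select_hyperparameters(x, y, grid, folds)
  fit <- fit_rbf_svm(x, y, hp$cost, hp$gamma)

  model <- structure(list(
    schema_version = 1L,
    panel = panel_ids,
    provenance = if (is.data.frame(panel)) panel$provenance else rep(NA_character_, length(panel_ids)),
    transform = transform,
    cost = hp$cost, gamma = hp$gamma,
    sv = unname(as.matrix(fit$SV)),
    sv_coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    orientation = 1,
    metadata = list(stratum = stratum, seed = seed, cv_folds = cv_folds,
                    cv_auc = hp$cv_auc, n_cases = sum(y == "case"),
                    n_controls = sum(y == "control"))
  ), class = "ckd_classifier")

  # orient the decision score so higher = more case-like
  tr_scores <- score(model, matrix, sample_ids = use$patient_id)
  if (mean(tr_scores[y == "case"]) < mean(tr_scores[y == "control"])) {
    model$orientation <- -1
  }
  model
}

#' @export
print.ckd_classifier <- function(x, ...) {
  cat(sprintf(
    "ckd_classifier: %d peptides, cost %.3g, gamma %.4g, CV AUC %.3f (stratum %s)\n",
    length(x$panel), x$cost, x$gamma, x$metadata$cv_auc %||% NA,
    as.character(x$metadata$stratum)
  ))
  invisible(x)
}

#' Score samples with a trained subclassifier
#'
#' Computes the signed SVM decision value (higher = more case-like) from the
#' stored support vectors: f(x) = sum_i alpha_i exp(-gamma ||sv_i - x||^2)
#' - rho, after applying the model's feature transform. Peptides missing
#' from the input are treated as non-detected (amplitude 0); their count is
#' attached as the `n_missing_peptides` attribute. The score does not depend
#' on the column order of the input.
#'
#' @param model a `ckd_classifier`
#' @param matrix a [peptide_matrix()], a numeric matrix with peptide
#'   colnames, or a single named profile vector
#' @param sample_ids optional subset of samples to score
#' @return named numeric vector of scores
#' @export
score <- function(model, matrix, sample_ids = NULL) {
  amp <- if (inherits(matrix, "peptide_matrix")) {
    matrix$amplitudes
  } else if (is.matrix(matrix)) {
    matrix
  } else {
    t(as.matrix(matrix))
  }
  if (!is.null(sample_ids)) amp <- amp[sample_ids, , drop = FALSE]
  px <- panel_amplitudes(amp, model$panel)
  x <- feature_transform_apply(px, model$transform)
  sv <- model$sv
  # RBF kernel matrix between support vectors and samples
  d2 <- outer(rowSums(sv^2), rowSums(x^2), "+") - 2 * tcrossprod(sv, x)
  k <- exp(-model$gamma * pmax(d2, 0))
  out <- model$orientation * (colSums(model$sv_coefs * k) - model$rho)
  names(out) <- rownames(amp)
  attr(out, "n_missing_peptides") <- attr(px, "n_missing")
  out
}

#' Take-one-out backward panel reduction
#'
#' Greedy backward elimination against cross-validated AUC: each round
#' evaluates removing every remaining peptide (with hyperparameters
#' re-selected per candidate unless `refit_hyperparameters = FALSE`, which
#' freezes them at the initial grid choice) and accepts the single removal
#' with the best CV objective, provided it does not fall more than
#' `tolerance` below the current objective — so removals that least degrade
#' performance are accepted too, favouring smaller panels. Elimination
#' stops when no removal is acceptable, the panel reaches `min_panel`, or
#' the incumbent best objective has not improved for `patience` accepted
#' rounds. The returned model is the best seen (highest CV objective;
#' at equal objective the smaller panel wins), refit on all training data.
#'
#' The `trace` element records, per accepted round, the removed peptide,
#' the accepted CV objective (which may dip within tolerance) and
#' `best_objective`, the running incumbent maximum, which is non-decreasing
#' by construction.
#'
#' @param matrix a normalized [peptide_matrix()]
#' @param labels labeling data.frame (see [train_svm()])
#' @param initial_panel `peptide_panel` or character vector
#' @param cv_folds CV folds (default 5)
#' @param seed fold-assignment seed
#' @param min_panel minimum panel size (default 5)
#' @param patience accepted rounds without incumbent improvement before
#'   stopping (default Inf)
#' @param tolerance acceptable CV-AUC drop per removal (default 0.002)
#' @param refit_hyperparameters re-tune cost/gamma for every candidate
#'   removal (default FALSE: tune once on the initial panel)
#' @param grid hyperparameter grid (default [default_svm_grid()])
#' @param stratum recorded in metadata
#' @return a `ckd_classifier` with a `trace` element
#' @export
take_one_out_reduce <- function(matrix, labels, initial_panel, cv_folds = 5,
                                seed = 1, min_panel = 5, patience = Inf,
                                tolerance = 0.002,
                                refit_hyperparameters = FALSE,
                                grid = NULL, stratum = NA) {
  panel_ids <- if (is.data.frame(initial_panel)) initial_panel$peptide_id else as.character(initial_panel)
  if (!length(panel_ids)) stopf("empty initial panel")
  if (min_panel > length(panel_ids)) {
    stopf("min_panel (%d) exceeds panel size (%d)", min_panel, length(panel_ids))
  }
  use <- labels[labels$label %in% c("rapid", "stable"), ]
  use <- use[use$patient_id %in% rownames(matrix$amplitudes), ]
  use <- use[order(use$patient_id), ]
  y <- factor(ifelse(use$label == "rapid", "case", "control"),
              levels = c("case", "control"))
  amp_all <- matrix$amplitudes[use$patient_id, , drop = FALSE]
  folds <- stratified_folds(y, cv_folds, seed)

  eval_panel <- function(ids, hp = NULL) {
    px <- panel_amplitudes(amp_all, ids)
    x <- feature_transform_apply(px, feature_transform_fit(px))
    g <- if (is.null(grid)) default_svm_grid(ncol(x)) else grid
    if (is.null(hp)) {
      select_hyperparameters(x, y, g, folds)
    } else {
      list(cost = hp$cost, gamma = hp$gamma,
           cv_auc = cv_auc(x, y, hp$cost, hp$gamma, folds))
    }
  }

  current <- panel_ids
  hp0 <- eval_panel(current)
  frozen <- if (refit_hyperparameters) NULL else hp0
  cur_obj <- hp0$cv_auc
  best_obj <- cur_obj
  best_panel <- current
  stale <- 0
  trace <- data.frame(round = 0L, removed = NA_character_,
                      panel_size = length(current), objective = cur_obj,
                      best_objective = best_obj, stringsAsFactors = FALSE)

  round_i <- 0L
  while (length(current) > min_panel) {
    round_i <- round_i + 1L
    cand <- lapply(seq_along(current), function(j) {
      eval_panel(current[-j], frozen)
    })
    objs <- vapply(cand, `[[`, numeric(1), "cv_auc")
    j_best <- order(-objs, current)[1]
    if (!is.finite(objs[j_best]) || objs[j_best] < cur_obj - tolerance) break
    removed <- current[j_best]
    current <- current[-j_best]
    cur_obj <- objs[j_best]
    improved <- cur_obj > best_obj
    if (improved || (cur_obj == best_obj && length(current) < length(best_panel))) {
      best_panel <- current
      if (improved) best_obj <- cur_obj
    }
    stale <- if (improved) 0 else stale + 1
    trace <- rbind(trace, data.frame(
      round = round_i, removed = removed, panel_size = length(current),
      objective = cur_obj, best_objective = best_obj,
      stringsAsFactors = FALSE
    ))
    if (stale >= patience) break
  }

  prov <- if (is.data.frame(initial_panel)) {
    initial_panel$provenance[match(best_panel, initial_panel$peptide_id)]
  } else {
    NULL
  }
  final_panel <- if (is.null(prov)) {
    best_panel
  } else {
    structure(data.frame(peptide_id = best_panel, provenance = prov,
                         stringsAsFactors = FALSE),
              class = c("peptide_panel", "data.frame"))
  }
  model <- train_svm(matrix, labels, final_panel,
                     grid = if (!refit_hyperparameters) data.frame(cost = frozen$cost, gamma = frozen$gamma) else grid,
                     cv_folds = cv_folds, seed = seed, stratum = stratum)
  model$trace <- trace
  model$metadata$initial_panel_size <- length(panel_ids)
  model
}

#' Serialize a subclassifier to JSON
#'
#' All numeric fields are written at full precision (17 significant digits),
#' so a load-save-load cycle reproduces scores to machine precision.
#'
#' @param model a `ckd_classifier`
#' @param path output file
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$trace <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = TRUE)
  invisible(path)
}

#' Load a subclassifier saved by [save_model()]
#'
#' @param path JSON file path
#' @return a `ckd_classifier`
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stopf("unsupported model schema version: %s",
          as.character(obj$schema_version %||% "missing"))
  }
  obj$sv <- as.matrix(obj$sv)
  obj$transform$mu <- setNames(as.numeric(obj$transform$mu), obj$panel)
  obj$transform$sd <- setNames(as.numeric(obj$transform$sd), obj$panel)
  structure(obj, class = "ckd_classifier")
}
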