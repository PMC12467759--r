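#' Area under the ROC curve (Mann–Whitney form)
#'
#' AUC = P(score_MUT > score_WT) + 0.5 * P(equal), computed from ranks so ties
#' are handled exactly.
#'
#' @param scores numeric prediction scores (higher = more MUT-like).
#' @param labels factor/character with values `WT`/`MUT` (both present).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "MUT"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (!n1 || !n0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: each class is dealt round-robin after shuffling
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' L1-penalised logistic feature selection
#'
#' Fits a LASSO logistic regression of mutation status on the candidate genes
#' with stratified cross-validation (AUC loss), picks the penalty minimising
#' the cross-validated loss ("minimal lambda" rule), and returns the genes
#' with non-zero coefficients there.
#'
#' @param ds an `ExpressionDataset`.
#' @param candidate_genes genes to offer the model (subset of `ds$genes`).
#' @param n_folds number of CV folds (default 10).
#' @param seed seed for fold assignment.
#' @return list: `selected` (gene symbols), `cv_auc` (mean cross-validated AUC
#'   at the chosen penalty), `lambda`.
#' @export
l1_select <- function(ds, candidate_genes = ds$genes, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing <- setdiff(candidate_genes, ds$genes)
  if (length(missing)) stop("candidate genes absent from dataset")
  if (nlevels(droplevels(ds$labels)) < 2) stop("both classes required")
  X <- t(ds$values[candidate_genes, , drop = FALSE])
  y <- as.integer(ds$labels == "MUT")
  foldid <- stratified_folds(as.character(ds$labels), n_folds, seed)
  fit <- suppressWarnings(
    glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "auc",
                      foldid = foldid, keep = TRUE)
  )
  i <- which(fit$lambda == fit$lambda.min)
  beta <- stats::coef(fit, s = "lambda.min")
  nz <- rownames(beta)[as.numeric(beta) != 0]
  # cross-validated AUC from the prevalidated (held-out) linear predictors,
  # so it is an AUC regardless of the loss glmnet used internally
  cv_auc <- auc(fit$fit.preval[, i], as.character(ds$labels))
  list(selected = setdiff(nz, "(Intercept)"),
       cv_auc = cv_auc,
       lambda = fit$lambda.min)
}

#' Cross-platform evaluation of a selected gene signature
#'
#' Implements the two-cohort validation protocol: genes selected on the source
#' platform are mapped onto the target platform (missing genes dropped, with a
#' message), and a plain logistic regression is fitted. Under the default
#' `"refit"` protocol the model is fitted on the target dataset itself and its
#' in-sample AUC reported — the published protocol; `"transfer"` fits on the
#' source and scores the target, the stricter variant. Aliased coefficients
#' are zeroed and iterations are capped, which guards against separation (AUC
#' only needs the score ordering).
#'
#' @param selected character vector of selected gene symbols.
#' @param source_ds source `ExpressionDataset` (used by `"transfer"`).
#' @param target_ds target `ExpressionDataset`.
#' @param protocol `"refit"` (default) or `"transfer"`.
#' @return list of class `ClassifierReport`: `selected`, `mapped`, `scores`
#'   (per target sample), `auc`, `protocol`.
#' @export
cross_platform_eval <- function(selected, source_ds, target_ds,
                                protocol = c("refit", "transfer")) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(target_ds, "ExpressionDataset"))
  mapped <- intersect(selected, target_ds$genes)
  if (!length(mapped)) stop("no selected gene is present on the target platform")
  if (length(mapped) < length(selected)) {
    message(length(selected) - length(mapped),
            " selected gene(s) absent from the target platform dropped")
  }
  fit_ds <- if (protocol == "refit") target_ds else source_ds
  if (protocol == "transfer") {
    stopifnot(inherits(source_ds, "ExpressionDataset"))
    mapped <- intersect(mapped, source_ds$genes)
    if (!length(mapped)) stop("no mapped gene present on the source platform")
  }
  X <- cbind(`(Intercept)` = 1, t(fit_ds$values[mapped, , drop = FALSE]))
  y <- as.integer(fit_ds$labels == "MUT")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 50))
  )
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  Xt <- cbind(1, t(target_ds$values[mapped, , drop = FALSE]))
  scores <- drop(Xt %*% beta)
  structure(
    list(selected = selected, mapped = mapped,
         scores = stats::setNames(scores, target_ds$samples),
         auc = auc(scores, target_ds$labels),
         protocol = protocol),
    class = "ClassifierReport"
  )
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf(
    "ClassifierReport (%s): %d selected, %d mapped on target, AUC = %.3f\n",
    x$protocol, length(x$selected), length(x$mapped), x$auc
  ))
  invisible(x)
}
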