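#' Configuration for repeated double cross-validation
#'
#' @param n_outer_folds outer (performance-estimation) folds.
#' @param n_inner_folds inner (complexity-selection) folds.
#' @param n_repetitions number of repeated random splits.
#' @param max_components largest PLS component count tried.
#' @param n_permutations label permutations for [permutation_test()].
#' @param perm_repetitions repetitions used inside the permutation test
#'   (both for the observed statistic and each permuted one, keeping the
#'   comparison exchangeable).
#' @param alpha significance level for variable selection.
#' @param ridge relative ridge on the within-class scatter in the LDA
#'   step.
#' @param seed master seed; all folds and permutations derive from it.
#' @return A list of class `rdcv_config`.
#' @export
rdcv_config <- function(n_outer_folds = 7, n_inner_folds = 6,
                        n_repetitions = 50, max_components = 10,
                        n_permutations = 1000, perm_repetitions = 5,
                        alpha = 0.05, ridge = 1e-8, seed = NULL) {
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2, n_repetitions >= 1,
            max_components >= 1, alpha > 0, alpha < 1)
  structure(list(n_outer_folds = n_outer_folds,
                 n_inner_folds = n_inner_folds,
                 n_repetitions = n_repetitions,
                 max_components = max_components,
                 n_permutations = n_permutations,
                 perm_repetitions = perm_repetitions,
                 alpha = alpha, ridge = ridge, seed = seed),
            class = "rdcv_config")
}

# Stratified fold assignment: within each class, fold labels 1..k are
# recycled and shuffled.
stratified_folds <- function(y01, k) {
  f <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    if (length(idx) < k) stopf("class smaller than the number of folds")
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

# Build the full fold layout consumed by the compiled engine:
# outer (n x reps) and inner (n x kout x reps, 0 for held-out samples).
build_folds <- function(y01, kout, kin, reps) {
  n <- length(y01)
  outer <- matrix(0L, n, reps)
  inner <- array(0L, dim = c(n, kout, reps))
  for (r in seq_len(reps)) {
    outer[, r] <- stratified_folds(y01, kout)
    for (k in seq_len(kout)) {
      tr <- which(outer[, r] != k)
      inner[tr, k, r] <- stratified_folds(y01[tr], kin)
    }
  }
  list(outer = outer, inner = inner)
}

prepare_xy <- function(x, y) {
  if (inherits(x, "binned_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stopf("y must have exactly two classes")
  list(X = x, y = y, y01 = as.integer(y == levels(y)[1]))
}

#' Repeated double cross-validation of a PLS-LDA model
#'
#' Nested cross-validation repeated over random stratified splits. Per
#' repetition, the outer loop holds out each fold once; for each outer
#' fold the inner loop selects the PLS component count minimizing inner
#' misclassification (1-SE parsimony tie-break toward fewer components),
#' the model is refit on the full outer-training set, and the held-out
#' predictions are recorded. Reported per repetition: sensitivity
#' (correct rate in the positive class, the first factor level),
#' specificity (second level), balanced accuracy and the raw correct
#' classification rate, all in percent. Variable weights along the first
#' canonical variate are recorded for every submodel fit during
#' validation.
#'
#' @param x predictor matrix (samples x variables) or a
#'   [binned_matrix] (its `labels` element supplies `y`).
#' @param y two-level factor; first level = positive class.
#' @param config an [rdcv_config()].
#' @return An object of class `rdcv_result`; see
#'   [select_variables()], [sample_stability()], [permutation_test()].
#' @export
rdcv <- function(x, y = NULL, config = rdcv_config()) {
  d <- prepare_xy(x, y)
  cfg <- config
  n <- nrow(d$X)
  if (min(table(d$y01)) < cfg$n_outer_folds) {
    stopf("class sizes must be >= n_outer_folds")
  }
  folds <- with_seed(cfg$seed, {
    build_folds(d$y01, cfg$n_outer_folds, cfg$n_inner_folds,
                cfg$n_repetitions)
  })
  eng <- rdcv_engine_cpp(d$X, d$y01, folds$outer, folds$inner,
                         cfg$max_components, cfg$ridge)
  metrics <- rdcv_metrics(eng$pred, d$y01)
  vars <- colnames(d$X) %||% sprintf("V%d", seq_len(ncol(d$X)))
  colnames(eng$weights_rep) <- colnames(eng$weights_fold) <- vars
  structure(list(metrics = metrics,
                 summary = data.frame(
                   metric = names(metrics),
                   mean = vapply(metrics, mean, 0),
                   sd = vapply(metrics, sd, 0),
                   row.names = NULL),
                 predictions = eng$pred,
                 chosen_components = eng$chosen_A,
                 weights_rep = eng$weights_rep,
                 weights_fold = eng$weights_fold,
                 sign_pos = drop(eng$sign_pos),
                 sign_neg = drop(eng$sign_neg),
                 y = d$y, y01 = d$y01, variables = vars,
                 config = cfg),
            class = "rdcv_result")
}

# Per-repetition metric table (percent) from the engine's prediction
# record (columns = repetitions; 1 = positive class).
rdcv_metrics <- function(pred, y01) {
  pos <- y01 == 1
  sens <- 100 * colMeans(pred[pos, , drop = FALSE] == 1)
  spec <- 100 * colMeans(pred[!pos, , drop = FALSE] == 0)
  ccr <- 100 * colMeans(pred == matrix(y01, nrow(pred), ncol(pred)))
  data.frame(accuracy = (sens + spec) / 2, sensitivity = sens,
             specificity = spec, ccr = ccr)
}

#' @exportS3Method base::print
print.rdcv_result <- function(x, ...) {
  cat(sprintf("<rdcv_result> %d repetitions, %d x %d folds\n",
              x$config$n_repetitions, x$config$n_outer_folds,
              x$config$n_inner_folds))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %5.1f +/- %4.1f %%\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Permutation test of rdCV classification metrics
#'
#' Re-runs a reduced-repetition rdCV under `n_permutations` random label
#' shuffles and compares each observed metric with its null
#' distribution; the observed statistic is computed with the same
#' reduced configuration so observed and null values are exchangeable
#' under the null hypothesis. P-values use the add-one estimator
#' `(1 + #{null >= observed}) / (1 + n_permutations)`.
#'
#' @inheritParams rdcv
#' @return List with `observed` (named means), `p_values` (named),
#'   `null` (matrix permutations x metrics) and `n_permutations`.
#' @export
permutation_test <- function(x, y = NULL, config = rdcv_config()) {
  d <- prepare_xy(x, y)
  cfg <- config
  pcfg <- cfg
  pcfg$n_repetitions <- cfg$perm_repetitions
  with_seed(cfg$seed, {
    pcfg$seed <- NULL
    obs <- rdcv(d$X, d$y, pcfg)
    obs_mean <- vapply(obs$metrics, mean, 0)
    null <- matrix(NA_real_, cfg$n_permutations, length(obs_mean),
                   dimnames = list(NULL, names(obs_mean)))
    for (b in seq_len(cfg$n_permutations)) {
      yb <- sample(d$y)
      rb <- rdcv(d$X, yb, pcfg)
      null[b, ] <- vapply(rb$metrics, mean, 0)
    }
    p <- (1 + colSums(sweep(null, 2, obs_mean, `>=`))) /
      (1 + cfg$n_permutations)
    list(observed = obs_mean, p_values = p, null = null,
         n_permutations = cfg$n_permutations)
  })
}

#' Sign-stable selection of discriminant variables
#'
#' A variable is significant when (i) its first-canonical-variate weight
#' kept the same sign in every submodel fit during the validation
#' procedure, and (ii) the 95% percentile interval of its weight across
#' the recorded weight draws excludes zero. Positive mean weight
#' associates the variable with the positive class (first factor
#' level), negative with the second.
#'
#' @param result an `rdcv_result`.
#' @param alpha CI level is `1 - alpha`; defaults to the config value.
#' @param weights which weight records define the CI and the stability
#'   check: `"submodels"` (default) pools every outer-training refit
#'   across repetitions; `"repetitions"` uses the repetition-averaged
#'   weights; `"all_models"` pools the outer refits for the CI but
#'   additionally requires the sign to hold in every inner-loop
#'   submodel (the strictest reading, with the lowest false-positive
#'   rate and the lowest sensitivity to weakly weighted variables).
#' @return Data.frame of class `variable_selection`: per variable the
#'   mean weight, CI bounds, `sign_stable`, `significant` and
#'   `group` (factor level name or `NA`).
#' @export
select_variables <- function(result, alpha = NULL,
                             weights = c("submodels", "repetitions",
                                         "all_models")) {
  stopifnot(inherits(result, "rdcv_result"))
  weights <- match.arg(weights)
  alpha <- alpha %||% result$config$alpha
  if (nrow(result$weights_rep) < 2) stopf("need >= 2 repetitions")
  W <- if (weights == "repetitions") result$weights_rep else
    result$weights_fold
  keep <- rowSums(W != 0) > 0   # skip folds that produced no model
  W <- W[keep, , drop = FALSE]
  mw <- colMeans(W)
  ci <- apply(W, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  stable <- apply(W, 2, function(w) all(w > 0) || all(w < 0))
  if (weights == "all_models") {
    stable <- stable & (result$sign_pos == 0 | result$sign_neg == 0) &
      (result$sign_pos + result$sign_neg > 0)
  }
  sig <- stable & (ci[1, ] > 0 | ci[2, ] < 0)
  lv <- levels(result$y)
  out <- data.frame(variable = result$variables,
                    mean_weight = mw,
                    ci_lo = ci[1, ], ci_hi = ci[2, ],
                    sign_stable = stable,
                    significant = sig,
                    group = ifelse(sig, ifelse(mw > 0, lv[1], lv[2]), NA),
                    row.names = NULL)
  class(out) <- c("variable_selection", class(out))
  out
}

#' Per-sample classification stability
#'
#' Categorizes every sample by its outer-loop prediction record across
#' repetitions: `always_correct`, `always_wrong`, or `unstable`.
#'
#' @param result an `rdcv_result`.
#' @return Factor of length n with the three categories.
#' @export
sample_stability <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  pred <- result$predictions
  truth <- matrix(result$y01, nrow(pred), ncol(pred))
  correct <- pred == truth
  cat_of <- function(row) {
    if (all(row)) "always_correct" else if (!any(row)) "always_wrong"
    else "unstable"
  }
  factor(apply(correct, 1, cat_of),
         levels = c("always_correct", "unstable", "always_wrong"))
}
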