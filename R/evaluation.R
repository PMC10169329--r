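# Cross-validation harness. A "sample" is a positive edge: the observed
# interactions are split into folds, masked from the training adjacency,
# and scored by the model fitted on what remains. Negatives are every pair
# never observed as interacting; they are scored by each fold's model and
# pooled, so one AUC summarizes each CV repeat.

#' Split positive edges into k cross-validation folds
#'
#' Indices `1..n_positives` are shuffled and cut into `k` folds whose sizes
#' differ by at most one. Splitting the 5118 observed interactions of a
#' typical curated network into 5 folds gives a smallest test fold of 1023
#' with a 4095-edge training complement.
#'
#' @param n_positives number of positive edges.
#' @param k number of folds, `2 <= k <= n_positives`.
#' @return List of `k` disjoint integer vectors partitioning
#'   `1..n_positives`. Uses the current RNG state; seed with [set.seed()].
#' @export
make_folds <- function(n_positives, k) {
  if (k < 2L || k > n_positives) {
    gk_data_error("k must be between 2 and the number of positives")
  }
  idx <- sample.int(n_positives)
  sizes <- rep(n_positives %/% k, k)
  extra <- n_positives %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(k), times = sizes))
}

#' Midrank (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, with ties counted one half — the area under the ROC
#' curve.
#'
#' @param positive_scores,negative_scores non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.3), c(0.8, 0.1)) # 0.75
#' @export
auc_score <- function(positive_scores, negative_scores) {
  np <- length(positive_scores); nn <- length(negative_scores)
  if (np == 0L || nn == 0L) gk_data_error("auc needs non-empty score lists")
  r <- rank(c(positive_scores, negative_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Standard threshold sweep over the pooled scores, tied scores collapsed
#' into a single operating point. The trapezoidal area under the returned
#' curve equals [auc_score()] exactly.
#'
#' @inheritParams auc_score
#' @return data.frame with columns `fpr`, `tpr`, both non-decreasing from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(positive_scores, negative_scores) {
  np <- length(positive_scores); nn <- length(negative_scores)
  if (np == 0L || nn == 0L) gk_data_error("roc needs non-empty score lists")
  sc <- c(positive_scores, negative_scores)
  lab <- rep(c(1L, 0L), c(np, nn))
  th <- sort(unique(sc), decreasing = TRUE)
  tp <- cumsum(vapply(th, function(t) sum(lab == 1L & sc == t), 0L))
  fp <- cumsum(vapply(th, function(t) sum(lab == 0L & sc == t), 0L))
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

mask_positives <- function(dataset, test_idx, pos_idx) {
  adj <- dataset$adj
  adj[pos_idx[test_idx, , drop = FALSE]] <- 0
  new_dataset(dataset$mirna_ids, dataset$lncrna_ids, adj)
}

#' Repeated k-fold cross-validation of link prediction
#'
#' For each repeat the positive edges are split into `k` folds. Each fold is
#' masked (set to 0) in the training adjacency, the model is refitted on the
#' masked network — with the interaction-profile similarities recomputed
#' from the masked adjacency when `profile = "network"`, so held-out edges
#' cannot leak into training — and the held-out positives are scored by
#' their fold's model. Negatives (all never-positive pairs) are scored by
#' every fold's model and pooled alongside the pooled held-out positive
#' scores, giving one AUC per repeat; the result reports their mean and
#' sample standard deviation.
#'
#' @param dataset a `gklink_dataset`.
#' @param k number of folds (default 5).
#' @param repeats number of CV repetitions (default 100); repeat `r` uses
#'   seed `seed + r - 1`, so results are reproducible.
#' @param seed base integer seed.
#' @param profile,alpha,sequences,expression,annotations,params passed to
#'   [gklink()].
#' @return An object of class `gklink_cv`: list with `per_run_aucs`,
#'   `mean_auc`, `sd_auc`, and the echoed `k`, `repeats`, `alpha`,
#'   `profile`.
#' @export
run_kfold_cv <- function(dataset, k = 5L, repeats = 100L, seed = 1L,
                         profile = "network", alpha = 0.007,
                         sequences = NULL, expression = NULL,
                         annotations = NULL, params = alignment_params()) {
  stopifnot(repeats >= 1L)
  pos_idx <- which(dataset$adj == 1, arr.ind = TRUE)
  n_pos <- nrow(pos_idx)
  neg_mask <- dataset$adj == 0
  aucs <- vapply(seq_len(repeats), function(r) {
    set.seed(seed + r - 1L)
    folds <- make_folds(n_pos, k)
    pos_scores <- numeric(0)
    neg_scores <- numeric(0)
    for (fold in folds) {
      train <- mask_positives(dataset, fold, pos_idx)
      if (sum(train$adj) == 0) gk_data_error("a training fold has zero positives")
      fit <- gklink(train, profile = profile, alpha = alpha,
                    sequences = sequences, expression = expression,
                    annotations = annotations, params = params)
      pos_scores <- c(pos_scores, fit$scores[pos_idx[fold, , drop = FALSE]])
      neg_scores <- c(neg_scores, fit$scores[neg_mask])
    }
    auc_score(pos_scores, neg_scores)
  }, 0)
  structure(list(per_run_aucs = aucs, mean_auc = mean(aucs),
                 sd_auc = if (repeats > 1L) stats::sd(aucs) else NA_real_,
                 k = k, repeats = repeats, alpha = alpha, profile = profile),
            class = "gklink_cv")
}

#' @export
print.gklink_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV, %d repeat(s), profile %s, alpha %g\n",
              x$k, x$repeats, x$profile, x$alpha))
  if (is.na(x$sd_auc)) {
    cat(sprintf("  AUC %.4f\n", x$mean_auc))
  } else {
    cat(sprintf("  AUC %.4f +/- %.4f\n", x$mean_auc, x$sd_auc))
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Each positive edge is masked in turn and scored by the model trained on
#' all remaining positives (similarities recomputed from the masked network
#' when `profile = "network"`). Negative pairs are scored once, by the model
#' trained on the full network: refitting per negative would add hundreds of
#' thousands of solves for no change in ranking behaviour. A single AUC
#' compares the held-out positive scores with the negative scores.
#' Deterministic — no sampling is involved.
#'
#' @inheritParams run_kfold_cv
#' @return Scalar AUC.
#' @export
run_loo_cv <- function(dataset, profile = "network", alpha = 0.007,
                       sequences = NULL, expression = NULL,
                       annotations = NULL, params = alignment_params()) {
  pos_idx <- which(dataset$adj == 1, arr.ind = TRUE)
  n_pos <- nrow(pos_idx)
  if (n_pos < 2L) gk_data_error("leave-one-out needs at least 2 positives")
  pos_scores <- vapply(seq_len(n_pos), function(i) {
    train <- mask_positives(dataset, i, pos_idx)
    fit <- gklink(train, profile = profile, alpha = alpha,
                  sequences = sequences, expression = expression,
                  annotations = annotations, params = params)
    fit$scores[pos_idx[i, 1L], pos_idx[i, 2L]]
  }, 0)
  full <- gklink(dataset, profile = profile, alpha = alpha,
                 sequences = sequences, expression = expression,
                 annotations = annotations, params = params)
  auc_score(pos_scores, full$scores[dataset$adj == 0])
}

#' Sensitivity sweep over the reconstruction weight alpha
#'
#' Runs repeated k-fold CV at each grid value with a shared seed schedule
#' (identical folds across alphas, so differences are attributable to alpha
#' alone). The default grid spans 0.001 to 0.019 in steps of 0.0015 — 13
#' values bracketing the default alpha = 0.007.
#'
#' @inheritParams run_kfold_cv
#' @param grid positive alpha values to evaluate, in order.
#' @return data.frame with columns `alpha`, `mean_auc`, `sd_auc` in grid
#'   order.
#' @export
alpha_sweep <- function(dataset, grid = default_alpha_grid(), k = 5L,
                        repeats = 10L, seed = 1L, profile = "network",
                        sequences = NULL, expression = NULL,
                        annotations = NULL) {
  if (length(grid) == 0L || any(grid <= 0)) {
    gk_data_error("alpha grid must be non-empty and positive")
  }
  rows <- lapply(grid, function(a) {
    cv <- run_kfold_cv(dataset, k = k, repeats = repeats, seed = seed,
                       profile = profile, alpha = a, sequences = sequences,
                       expression = expression, annotations = annotations)
    data.frame(alpha = a, mean_auc = cv$mean_auc, sd_auc = cv$sd_auc)
  })
  do.call(rbind, rows)
}

#' Default alpha grid: 0.001 to 0.019 in steps of 0.0015 (13 values)
#' @export
default_alpha_grid <- function() 0.001 + 0.0015 * (0:12)

#' Serialize a CV result as TSV
#'
#' One summary line (`k`, `repeats`, `alpha`, `profile`, `mean_auc`,
#' `sd_auc`); per-run AUCs appended as comment lines for provenance.
#'
#' @param cv a `gklink_cv` object. @param sink path or connection.
#' @export
write_cv_result <- function(cv, sink) {
  con <- if (is.character(sink)) file(sink, "w") else sink
  if (is.character(sink)) on.exit(close(con))
  writeLines("k\trepeats\talpha\tprofile\tmean_auc\tsd_auc", con)
  writeLines(sprintf("%d\t%d\t%.10g\t%s\t%.10g\t%.10g", cv$k, cv$repeats,
                     cv$alpha, cv$profile, cv$mean_auc, cv$sd_auc), con)
  writeLines(paste0("# per_run_aucs\t",
                    paste(sprintf("%.10g", cv$per_run_aucs), collapse = "\t")),
             con)
  invisible(cv)
}
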