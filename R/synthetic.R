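# Seeded generator of synthetic classifier score banks. Emulates M CNNs'
# softmax outputs on an imbalanced classification task with controllable
# per-model accuracy, confidence sharpness, class imbalance and error
# correlation, so fusion, baselines and evaluation are testable without any
# trained model or dataset download.

#' Configuration for the synthetic score-bank generator
#'
#' Defaults mirror a three-class chest-CT classification setting: class
#' proportions from supports 120/561/416 (benign/malignant/normal) and
#' three base models with accuracies 0.9902/0.9726/0.9945.
#'
#' @param n_samples Number of samples to generate.
#' @param class_proportions C nonnegative reals summing to 1 (within 1e-9).
#' @param n_models Number of base classifiers M.
#' @param model_accuracies M per-model accuracies, each in (1/C, 1].
#' @param concentration Positive Dirichlet boost on the target class;
#'   larger values sharpen rows toward one-hot vectors. Default 10 makes
#'   the argmax recover the target class ~99.9% of the time at C = 3, so
#'   empirical accuracy tracks the nominal accuracy.
#' @param error_correlation Probability in \[0, 1\] that a sample draws one
#'   common wrong target class shared by all erring models (correlated
#'   failures); 0 means independent errors.
#' @param class_labels Optional class names (default `class1..classC`).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 1097,
                             class_proportions = c(120, 561, 416) / 1097,
                             n_models = 3,
                             model_accuracies = c(0.9902, 0.9726, 0.9945),
                             concentration = 10,
                             error_correlation = 0,
                             class_labels = NULL,
                             seed = 1) {
  C <- length(class_proportions)
  if (C < 2) stop("need at least two classes", call. = FALSE)
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be nonnegative and sum to 1", call. = FALSE)
  if (n_samples < 1 || n_samples != round(n_samples))
    stop("n_samples must be a positive integer", call. = FALSE)
  if (n_models < 1 || length(model_accuracies) != n_models)
    stop("model_accuracies must have length n_models >= 1", call. = FALSE)
  if (any(model_accuracies <= 1 / C) || any(model_accuracies > 1))
    stop(sprintf("model accuracies must lie in (1/C, 1] = (%.3f, 1]", 1 / C),
         call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  if (error_correlation < 0 || error_correlation > 1)
    stop("error_correlation must lie in [0, 1]", call. = FALSE)
  class_labels <- class_labels %||% paste0("class", seq_len(C))
  stopifnot(length(class_labels) == C)
  structure(list(n_samples = as.integer(n_samples),
                 class_proportions = class_proportions,
                 n_models = as.integer(n_models),
                 model_accuracies = model_accuracies,
                 concentration = concentration,
                 error_correlation = error_correlation,
                 class_labels = as.character(class_labels),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# one Dirichlet draw per row: symmetric base alpha = 1, target class gets
# alpha = 1 + concentration
rdirichlet_target <- function(n, C, target, concentration) {
  g <- matrix(stats::rgamma(n * C, shape = 1), n, C)
  boost <- stats::rgamma(n, shape = 1 + concentration)
  g[cbind(seq_len(n), target)] <- boost
  g / rowSums(g)
}

#' Simulate an ensemble score bank
#'
#' Truth labels are drawn from `class_proportions`. For each sample and
#' model, the model is correct with probability equal to its nominal
#' accuracy; its confidence row is a symmetric Dirichlet draw with the
#' concentration boost placed on the true class when correct, otherwise on
#' a wrong class. With `error_correlation > 0`, a sample flagged (with that
#' probability) as a shared-failure case pre-draws one common wrong target
#' that every erring model aims at, emulating correlated failures of CNNs
#' on genuinely confusing images. Every row sums to 1 and the output is a
#' deterministic function of the seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `scores` (a strict-valid [score_set()]) and `truth`
#'   (character vector of true class labels).
#' @examples
#' bank <- simulate_bank(synthetic_config(n_samples = 20, seed = 7))
#' bank$scores
#' @export
simulate_bank <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_samples; C <- length(cfg$class_labels); M <- cfg$n_models
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  truth_idx <- sample.int(C, n, replace = TRUE, prob = cfg$class_proportions)
  shared <- stats::runif(n) < cfg$error_correlation
  # common wrong target for shared-failure samples (uniform over wrong classes)
  common_wrong <- (truth_idx + sample.int(C - 1, n, replace = TRUE) - 1) %% C + 1

  matrices <- vector("list", M)
  for (i in seq_len(M)) {
    correct <- stats::runif(n) < cfg$model_accuracies[i]
    own_wrong <- (truth_idx + sample.int(C - 1, n, replace = TRUE) - 1) %% C + 1
    target <- ifelse(correct, truth_idx,
                     ifelse(shared, common_wrong, own_wrong))
    m <- rdirichlet_target(n, C, target, cfg$concentration)
    dimnames(m) <- list(paste0("s", seq_len(n)), cfg$class_labels)
    matrices[[i]] <- m
  }
  names(matrices) <- paste0("model", seq_len(M))
  list(scores = score_set(matrices),
       truth = cfg$class_labels[truth_idx])
}

#' Ensemble-vs-base accuracy check on independent errors
#'
#' Simulates a bank with independent, equally accurate base models, fuses
#' it with the fuzzy-rank rule and all classical baselines, and reports
#' each method's accuracy together with how often the fusion rescues a
#' sample on which exactly one, or exactly two, base models erred — the
#' jury-theorem regime where decision fusion should beat every individual
#' model.
#'
#' @param cfg A [synthetic_config()] with `error_correlation = 0` and equal
#'   `model_accuracies`.
#' @param k Top-k cut passed to [fuse()] (default 2).
#' @return List with `accuracy` (named vector: each base model, `fused`,
#'   and the baselines), `rescued_one_wrong` and `rescued_two_wrong`
#'   (counts of samples fused correctly while 1 or 2 base models were
#'   wrong), and `n`.
#' @export
condorcet_check <- function(cfg, k = 2) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$error_correlation != 0)
    stop("condorcet_check requires error_correlation = 0", call. = FALSE)
  if (length(unique(cfg$model_accuracies)) != 1)
    stop("condorcet_check requires equal model accuracies", call. = FALSE)
  bank <- simulate_bank(cfg)
  truth <- bank$truth
  base_pred <- lapply(bank$scores$matrices, function(m)
    colnames(m)[apply(m, 1, which.max)])
  base_acc <- vapply(base_pred, function(p) mean(p == truth), numeric(1))

  fused <- fuse(bank$scores, k = k)$fused_label
  acc <- c(base_acc, fused = mean(fused == truth))
  w <- accuracy_weights(base_acc)
  for (m in BASELINE_METHODS) {
    p <- baseline_fuse(bank$scores, m,
                       weights = if (m == "weighted_average") w)$label
    acc[[m]] <- mean(p == truth)
  }
  n_wrong <- Reduce(`+`, lapply(base_pred, function(p) as.integer(p != truth)))
  list(accuracy = acc,
       rescued_one_wrong = sum(fused == truth & n_wrong == 1),
       rescued_two_wrong = sum(fused == truth & n_wrong == 2),
       n = cfg$n_samples)
}
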