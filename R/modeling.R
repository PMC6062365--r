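#' Random forest parameters
#'
#' The study-fixed learner settings: 500 trees, and \code{mtry} equal to
#' the (floored) square root of the post-preprocessing descriptor count,
#' recomputed in every fold from the trained matrix width.
#'
#' @param n_trees number of trees (default 500).
#' @return Object of class \code{rf_params}.
#' @export
rf_params <- function(n_trees = 500L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees)), class = "rf_params")
}

all_combos <- function() {
  list("chemical",
       "target",
       "cytotox",
       c("chemical", "target"),
       c("chemical", "cytotox"),
       c("target", "cytotox"),
       c("chemical", "target", "cytotox"))
}

combo_name <- function(combo) paste(combo, collapse = "+")

# deterministic per-(repeat, fold, combo, scramble) child seed below 2^31
child_seed <- function(master, rep_i, fold_i, combo_i, scramble_i = 0L) {
  x <- (as.double(master) * 2654435.0 + rep_i * 97911.0 + fold_i * 7907.0 +
          combo_i * 733.0 + scramble_i * 57.0)
  as.integer(x %% 2147483629)
}

#' Build a shared class-stratified cross-validation split plan
#'
#' For each of \code{n_repeats} repeats, compounds are partitioned into
#' \code{n_folds} folds by shuffling within each class and dealing fold
#' labels round-robin, so every fold's class counts are within one
#' compound of perfect stratification.  The identical plan is reused for
#' every descriptor-domain combination so that paired comparisons remove
#' split-to-split variability.
#'
#' @param labels named factor/character vector of toxic/nontoxic labels.
#' @param n_repeats number of CV repeats (default 20).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the plan is deterministic given it.
#' @return Object of class \code{split_plan}: an integer matrix
#'   (compounds x repeats) of fold labels, plus \code{n_repeats},
#'   \code{n_folds} and \code{seed}.
#' @export
make_split_plan <- function(labels, n_repeats = 20L, n_folds = 5L, seed) {
  stopifnot(!is.null(names(labels)))
  cls <- as.character(labels)
  counts <- table(cls)
  if (any(counts < n_folds))
    stop("make_split_plan: class '", names(counts)[which.min(counts)],
         "' has fewer members (", min(counts), ") than n_folds (",
         n_folds, ")", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(labels)
  assignment <- matrix(NA_integer_, n, n_repeats,
                       dimnames = list(names(labels), NULL))
  for (r in seq_len(n_repeats)) {
    for (cl in names(counts)) {
      idx <- which(cls == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx, r] <- rep(seq_len(n_folds),
                                length.out = length(idx))
    }
  }
  structure(list(assignment = assignment,
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d repeats x %d class-stratified folds over %d compounds (seed %d)\n",
              x$n_repeats, x$n_folds, nrow(x$assignment), x$seed))
  invisible(x)
}

# vote fraction -> class; ties go to toxic (false negatives cost more)
vote_to_class <- function(p_toxic) {
  factor(ifelse(p_toxic >= 0.5, "toxic", "nontoxic"),
         levels = c("nontoxic", "toxic"))
}

# train one fold's pipeline and predict its external set
fit_fold <- function(table, labels, plan, rep_i, fold_i, cutoffs, rf,
                     control, seed, scramble_modeling_labels = FALSE,
                     chem_table = NULL) {
  fold_of <- plan$assignment[rownames(table), rep_i]
  ext <- fold_of == fold_i
  mod <- !ext
  mod_table <- table[mod, , drop = FALSE]
  attr(mod_table, "domain") <- domains(table)
  mod_labels <- labels[rownames(mod_table)]
  mod_chem <- if (!is.null(chem_table))
    chem_table[rownames(mod_table), , drop = FALSE]

  set.seed(seed)
  if (scramble_modeling_labels)
    mod_labels[] <- mod_labels[sample.int(length(mod_labels))]

  state <- fit_preprocess(mod_table, mod_labels, cutoffs, control,
                          dist_table = mod_chem)
  x_mod <- apply_preprocess(state, mod_table)[state$kept_ids, ,
                                              drop = FALSE]
  y_mod <- factor(as.character(mod_labels[state$kept_ids]),
                  levels = c("nontoxic", "toxic"))
  ext_table <- table[ext, , drop = FALSE]
  attr(ext_table, "domain") <- domains(table)
  x_ext <- apply_preprocess(state, ext_table)

  mtry <- max(1L, floor(sqrt(ncol(x_mod))))
  fit <- randomForest::randomForest(x = x_mod, y = y_mod,
                                    ntree = rf$n_trees, mtry = mtry,
                                    importance = FALSE)
  votes <- stats::predict(fit, x_ext, type = "vote")   # normalized votes
  p_toxic <- votes[, "toxic"]
  list(predictions = data.frame(compound_id = rownames(x_ext),
                                truth = as.character(
                                  labels[rownames(x_ext)]),
                                prediction = as.character(
                                  vote_to_class(p_toxic)),
                                p_toxic = as.numeric(p_toxic),
                                stringsAsFactors = FALSE),
       state = state,
       importance = fit$importance[, "MeanDecreaseGini"],
       mtry = mtry)
}

#' Run repeated cross-validation for one descriptor-domain combination
#'
#' For every (repeat, fold) cell of the shared plan: holds out the fold,
#' fits the four preprocessing steps on the remaining four fifths, applies
#' them to both sets, trains a random forest (majority vote over trees,
#' \code{p_toxic} = fraction of trees voting toxic, ties classified toxic),
#' and records the external predictions, the fitted preprocessing state
#' and the raw variable importances (mean decrease in Gini impurity).
#' A fold whose preprocessing fails is recorded as a failure and the run
#' continues.
#'
#' @param table full domain-tagged descriptor matrix.
#' @param labels named toxic/nontoxic labels.
#' @param combo non-empty subset of c("chemical", "target", "cytotox").
#' @param plan a [make_split_plan()] shared across combinations.
#' @param rf an [rf_params()].
#' @param cutoffs a [calibrate_cutoffs()] result; if NULL, calibrated on
#'   the full table (and recalibrated per fold only when
#'   \code{control$recalibrate_per_fold}).
#' @param control a [preprocess_config()].
#' @param master_seed integer; every fold derives its own child seed.
#' @return Object of class \code{combo_result}: \code{combo},
#'   \code{cells} (one list per (repeat, fold) with repeat, fold,
#'   predictions, state, importance, seed), \code{failures}, and the plan.
#' @export
run_combination <- function(table, labels, combo, plan, rf = rf_params(),
                            cutoffs = NULL, control = preprocess_config(),
                            master_seed = 1L) {
  stopifnot(inherits(plan, "split_plan"), length(combo) >= 1L)
  sub <- select_domains(table, combo)
  # downsampling distances always use the chemical block when one exists
  chem_table <- if (!("chemical" %in% combo) &&
                    "chemical" %in% domains(table))
    select_domains(table, "chemical")
  if (is.null(cutoffs)) {
    calib_on <- if (is.null(chem_table)) sub else table
    cutoffs <- calibrate_cutoffs(calib_on,
                                 target_size = control$target_size,
                                 freq_ratio = control$nzv_freq_ratio,
                                 unique_cut = control$nzv_unique_cut)
  }
  combo_i <- match(combo_name(combo),
                   vapply(all_combos(), combo_name, ""))
  if (is.na(combo_i)) combo_i <- 0L
  cells <- list()
  failures <- list()
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      seed <- child_seed(master_seed, r, f, combo_i)
      fold_cutoffs <- cutoffs
      res <- tryCatch({
        if (control$recalibrate_per_fold) {
          src <- if (is.null(chem_table)) sub else table
          mod_ids <- rownames(src)[plan$assignment[rownames(src), r] != f]
          ms <- src[mod_ids, , drop = FALSE]
          attr(ms, "domain") <- domains(src)
          fold_cutoffs <- calibrate_cutoffs(
            ms, target_size = control$target_size,
            freq_ratio = control$nzv_freq_ratio,
            unique_cut = control$nzv_unique_cut)
        }
        fit_fold(sub, labels, plan, r, f, fold_cutoffs, rf, control, seed,
                 chem_table = chem_table)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(repeat_ = r, fold = f, message = conditionMessage(res))
      } else {
        cells[[length(cells) + 1L]] <-
          c(list(repeat_ = r, fold = f, seed = seed), res)
      }
    }
  }
  structure(list(combo = combo,
                 cells = cells,
                 failures = failures,
                 plan = plan,
                 cutoffs = cutoffs,
                 rf = rf,
                 master_seed = as.integer(master_seed)),
            class = "combo_result")
}

#' @export
print.combo_result <- function(x, ...) {
  cat(sprintf("Combination '%s': %d fold models (%d failures)\n",
              combo_name(x$combo), length(x$cells), length(x$failures)))
  if (length(x$cells)) {
    ccr <- vapply(x$cells, function(cl)
      confusion_metrics(cl$predictions$truth,
                        cl$predictions$prediction)[["ccr"]], 0)
    cat(sprintf("  CCR %.3f +/- %.3f over %d cells\n",
                mean(ccr), stats::sd(ccr), length(ccr)))
  }
  invisible(x)
}

#' Cross-validated multi-domain toxicity classification study
#'
#' The package's main fitting function.  Runs the full 20x5 (configurable)
#' repeated class-stratified cross-validation of random-forest classifiers
#' for every requested descriptor-domain combination, re-using one shared
#' split plan, with all preprocessing fitted inside each fold.
#' Per-domain correlation cutoffs are calibrated once on the full table
#' (held fixed across folds) unless \code{control$recalibrate_per_fold}.
#'
#' @param table domain-tagged descriptor matrix from [assemble_table()] /
#'   [featurize_cohort()].
#' @param labels named factor of toxic/nontoxic labels.
#' @param combos list of domain subsets (default: all 7 combinations).
#' @param n_repeats,n_folds cross-validation design (defaults 20 and 5).
#' @param rf an [rf_params()].
#' @param control a [preprocess_config()].
#' @param seed master seed driving the split plan and every fold.
#' @param plan optionally, a pre-built [make_split_plan()] to share with
#'   other studies.
#' @return Object of class \code{toxcv}: \code{results} (named list of
#'   \code{combo_result}), \code{plan}, \code{cutoffs}, \code{labels} and
#'   the call parameters.  See [summary.toxcv()], [paired_improvement()],
#'   [ad_profile()], [aggregate_importance()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synth_config(n_compounds = 80, n_toxic = 20,
#'   n_chem_descriptors = 15, n_fingerprint_bits = 128, n_targets = 12,
#'   n_cell_lines = 3, n_bioactivity_compounds = 100, seed = 3))
#' feats <- featurize_cohort(cohort, min_records = 20)
#' fit <- toxcv(feats$table, feats$labels, n_repeats = 1,
#'              rf = rf_params(100), seed = 3)
#' summary(fit)
#' }
#' @export
toxcv <- function(table, labels, combos = all_combos(), n_repeats = 20L,
                  n_folds = 5L, rf = rf_params(),
                  control = preprocess_config(), seed = 1L, plan = NULL) {
  stopifnot(is.matrix(table), !is.null(rownames(table)),
            identical(sort(rownames(table)), sort(names(labels))))
  if (is.null(plan))
    plan <- make_split_plan(labels, n_repeats, n_folds, seed = seed)
  cutoffs <- calibrate_cutoffs(table, target_size = control$target_size,
                               freq_ratio = control$nzv_freq_ratio,
                               unique_cut = control$nzv_unique_cut)
  results <- list()
  for (combo in combos) {
    nm <- combo_name(combo)
    results[[nm]] <- run_combination(table, labels, combo, plan, rf,
                                     cutoffs = cutoffs, control = control,
                                     master_seed = seed)
  }
  structure(list(results = results,
                 plan = plan,
                 cutoffs = cutoffs,
                 labels = labels,
                 rf = rf,
                 control = control,
                 seed = as.integer(seed)),
            class = "toxcv")
}

#' @export
print.toxcv <- function(x, ...) {
  cat(sprintf("Repeated-CV toxicity study: %d combination(s), %d repeats x %d folds\n",
              length(x$results), x$plan$n_repeats, x$plan$n_folds))
  print(summary(x))
  invisible(x)
}

#' y-randomization robustness assessment of one fold model
#'
#' Retrains the complete fold pipeline (preprocessing included)
#' \code{n_scrambles} times with the modelling-set labels permuted
#' uniformly at random, leaving the external fold and its true labels
#' untouched, and tests whether the real model's external CCR could have
#' arisen from the scrambled-label distribution.  The one-tailed p-value
#' uses the prediction-interval form
#' \deqn{t = (CCR_{real} - \bar{CCR}_{scr}) / (s_{scr}\sqrt{1 + 1/n}),}
#' compared against a t distribution with \code{n_scrambles - 1} degrees
#' of freedom, which is calibrated under exchangeability of the real and
#' scrambled models.  If the scrambled CCRs have zero variance the
#' degenerate rule applies: p = 0 when the real CCR exceeds the common
#' value, else 1.  A model passes when p < 0.05.
#'
#' @inheritParams run_combination
#' @param rep_i,fold_i the (repeat, fold) cell to assess.
#' @param n_scrambles number of scrambled retrainings (default 10; at
#'   least 2 are required for the t-test).
#' @param real_ccr optionally, the cell's real external CCR (recomputed if
#'   missing).
#' @return List with \code{p}, \code{real_ccr}, \code{scrambled_ccr} and
#'   \code{pass}.
#' @export
y_scramble_assess <- function(table, labels, combo, plan, rep_i, fold_i,
                              rf = rf_params(), cutoffs = NULL,
                              control = preprocess_config(),
                              n_scrambles = 10L, master_seed = 1L,
                              real_ccr = NULL) {
  if (n_scrambles < 2L)
    stop("y_scramble_assess: insufficient scrambles for t-test ",
         "(n_scrambles must be >= 2)", call. = FALSE)
  sub <- select_domains(table, combo)
  chem_table <- if (!("chemical" %in% combo) &&
                    "chemical" %in% domains(table))
    select_domains(table, "chemical")
  if (is.null(cutoffs)) {
    calib_on <- if (is.null(chem_table)) sub else table
    cutoffs <- calibrate_cutoffs(calib_on,
                                 target_size = control$target_size,
                                 freq_ratio = control$nzv_freq_ratio,
                                 unique_cut = control$nzv_unique_cut)
  }
  combo_i <- match(combo_name(combo), vapply(all_combos(), combo_name, ""))
  if (is.na(combo_i)) combo_i <- 0L
  if (is.null(real_ccr)) {
    real <- fit_fold(sub, labels, plan, rep_i, fold_i, cutoffs, rf, control,
                     child_seed(master_seed, rep_i, fold_i, combo_i),
                     chem_table = chem_table)
    real_ccr <- confusion_metrics(real$predictions$truth,
                                  real$predictions$prediction)[["ccr"]]
  }
  scr <- vapply(seq_len(n_scrambles), function(s) {
    res <- fit_fold(sub, labels, plan, rep_i, fold_i, cutoffs, rf, control,
                    child_seed(master_seed, rep_i, fold_i, combo_i, s),
                    scramble_modeling_labels = TRUE,
                    chem_table = chem_table)
    confusion_metrics(res$predictions$truth,
                      res$predictions$prediction)[["ccr"]]
  }, 0)
  s_sd <- stats::sd(scr)
  if (s_sd == 0) {
    p <- if (real_ccr > scr[1]) 0 else 1
  } else {
    t_stat <- (real_ccr - mean(scr)) / (s_sd * sqrt(1 + 1 / n_scrambles))
    p <- stats::pt(t_stat, df = n_scrambles - 1, lower.tail = FALSE)
  }
  list(p = p, real_ccr = real_ccr, scrambled_ccr = scr, pass = p < 0.05)
}
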