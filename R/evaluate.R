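#' Sensitivity, selectivity and correct classification rate
#'
#' Sensitivity is the fraction of toxic compounds correctly identified,
#' selectivity the fraction of nontoxic compounds correctly identified,
#' and CCR their arithmetic mean (balanced accuracy).
#'
#' @param truth,predictions vectors of "toxic"/"nontoxic" labels; the
#'   truth must contain both classes.
#' @return Named numeric vector: sensitivity, selectivity, ccr.
#' @examples
#' confusion_metrics(c("toxic", "toxic", "nontoxic", "nontoxic"),
#'                   c("toxic", "nontoxic", "nontoxic", "nontoxic"))
#' @export
confusion_metrics <- function(truth, predictions) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  stopifnot(length(truth) == length(predictions))
  if (!all(c("toxic", "nontoxic") %in% truth))
    stop("confusion_metrics: truth must contain both classes", call. = FALSE)
  sens <- mean(predictions[truth == "toxic"] == "toxic")
  sel <- mean(predictions[truth == "nontoxic"] == "nontoxic")
  c(sensitivity = sens, selectivity = sel, ccr = (sens + sel) / 2)
}

# per-cell metric table for a combo_result
cell_metrics <- function(result) {
  stopifnot(inherits(result, "combo_result"))
  rows <- lapply(result$cells, function(cl) {
    m <- confusion_metrics(cl$predictions$truth, cl$predictions$prediction)
    data.frame(repeat_ = cl$repeat_, fold = cl$fold,
               sensitivity = m[["sensitivity"]],
               selectivity = m[["selectivity"]], ccr = m[["ccr"]])
  })
  cbind(combo = combo_name(result$combo), do.call(rbind, rows))
}

#' Summarize per-combination performance distributions
#'
#' Mean and standard deviation of sensitivity, selectivity and CCR over
#' all (repeat, fold) cells, one row per descriptor-domain combination.
#'
#' @param object a \code{toxcv} fit (or a single \code{combo_result}).
#' @param ... unused.
#' @return data.frame with columns combo, n_cells, ccr, ccr_sd,
#'   sensitivity, sensitivity_sd, selectivity, selectivity_sd.
#' @export
summary.toxcv <- function(object, ...) {
  do.call(rbind, lapply(object$results, performance_summary))
}

#' @rdname summary.toxcv
#' @param result a \code{combo_result}.
#' @export
performance_summary <- function(result) {
  cm <- cell_metrics(result)
  out <- data.frame(combo = combo_name(result$combo),
                    n_cells = nrow(cm),
                    ccr = mean(cm$ccr), ccr_sd = stats::sd(cm$ccr),
                    sensitivity = mean(cm$sensitivity),
                    sensitivity_sd = stats::sd(cm$sensitivity),
                    selectivity = mean(cm$selectivity),
                    selectivity_sd = stats::sd(cm$selectivity),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired performance comparison of two domain combinations
#'
#' Per-cell CCR differences (A minus B) over the shared (repeat, fold)
#' splits, with mean, standard error and a two-tailed paired t-test of no
#' difference.  Pairing requires both results to have been produced under
#' an identical split plan.  If every per-cell difference is identical the
#' degenerate rule applies: p = 1 when the common difference is 0,
#' otherwise p = 0.
#'
#' @param a,b \code{combo_result} objects sharing one split plan.
#' @return Object of class \code{improvement_record}: combo names, the
#'   per-cell deltas, mean, se and p_value.
#' @export
paired_improvement <- function(a, b) {
  stopifnot(inherits(a, "combo_result"), inherits(b, "combo_result"))
  if (!identical(a$plan$assignment, b$plan$assignment))
    stop("paired_improvement: results were not produced under the same ",
         "split plan", call. = FALSE)
  ma <- cell_metrics(a)
  mb <- cell_metrics(b)
  key_a <- paste(ma$repeat_, ma$fold)
  key_b <- paste(mb$repeat_, mb$fold)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 2L)
    stop("paired_improvement: fewer than 2 shared cells", call. = FALSE)
  delta <- ma$ccr[match(shared, key_a)] - mb$ccr[match(shared, key_b)]
  n <- length(delta)
  se <- stats::sd(delta) / sqrt(n)
  if (stats::sd(delta) == 0) {
    p <- if (mean(delta) == 0) 1 else 0
  } else {
    p <- stats::t.test(delta, mu = 0,
                       alternative = "two.sided")$p.value
  }
  structure(list(combo_a = combo_name(a$combo),
                 combo_b = combo_name(b$combo),
                 delta = delta, n = n, mean = mean(delta), se = se,
                 p_value = p),
            class = "improvement_record")
}

#' @export
print.improvement_record <- function(x, ...) {
  cat(sprintf("CCR improvement '%s' vs '%s': %+0.4f +/- %0.4f (SE), p = %.3g over %d paired cells\n",
              x$combo_a, x$combo_b, x$mean, x$se, x$p_value, x$n))
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random toxic compound
#' receives a higher toxic-class score than a random nontoxic compound,
#' with ties counted half.  Invariant under strictly monotone score
#' transformations.
#'
#' @param truth "toxic"/"nontoxic" labels.
#' @param p_toxic numeric toxic-class scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(truth, p_toxic) {
  truth <- as.character(truth)
  stopifnot(length(truth) == length(p_toxic))
  if (!all(c("toxic", "nontoxic") %in% truth))
    stop("roc_auc: truth must contain both classes", call. = FALSE)
  r <- rank(p_toxic, ties.method = "average")
  n1 <- sum(truth == "toxic")
  n0 <- sum(truth == "nontoxic")
  (sum(r[truth == "toxic"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Applicability-domain performance profile
#'
#' For every external prediction of every cell, computes the Euclidean
#' distance from the predicted compound to its nearest neighbour in that
#' fold's modelling set, measured in a chemical descriptor space
#' preprocessed once on the whole dataset.  Distances are pooled to form
#' shared quantile bin edges, and a per-bin CCR is reported for each
#' requested combination, so the decay of accuracy with chemical novelty
#' is directly comparable across combinations.
#'
#' With \code{reference = "membership"} (the default) distances are taken
#' to the full four-fifths modelling membership; \code{"trained"} uses
#' only the compounds retained after downsampling (the set the forest
#' actually saw).  The default measures chemical novelty; the trained
#' variant instead measures distance to the class-boundary region that
#' downsampling concentrates the training set on.
#'
#' @param fit a \code{toxcv} object.
#' @param space numeric matrix of preprocessed chemical descriptors for
#'   all compounds (see [descriptor_space()]).
#' @param combos character vector of combination names (default: all in
#'   \code{fit}).
#' @param bins number of quantile bins (default 5).
#' @param reference "membership" (full 4/5 modelling membership) or
#'   "trained" (post-downsampling training compounds).
#' @return Object of class \code{ad_profile}: \code{edges}, and
#'   \code{profile}, a data.frame of combo, bin, n, ccr (ccr is NA for a
#'   bin with no predictions or a single class).
#' @export
ad_profile <- function(fit, space, combos = names(fit$results), bins = 5L,
                       reference = c("membership", "trained")) {
  stopifnot(inherits(fit, "toxcv"), is.matrix(space))
  reference <- match.arg(reference)
  plan <- fit$plan
  ids <- rownames(plan$assignment)
  stopifnot(all(ids %in% rownames(space)))
  sp <- space[ids, , drop = FALSE]
  kept <- vector("list", plan$n_repeats * plan$n_folds)
  if (reference == "trained") {
    for (cl in fit$results[[1]]$cells)
      if (!is.null(cl$state))
        kept[[(cl$repeat_ - 1L) * plan$n_folds + cl$fold]] <-
          cl$state$kept_ids
  }
  dist_cell <- matrix(NA_real_, length(ids), plan$n_repeats,
                      dimnames = list(ids, NULL))
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      ext <- plan$assignment[, r] == f
      train_ids <- kept[[(r - 1L) * plan$n_folds + f]]
      if (is.null(train_ids)) train_ids <- ids[!ext]
      dist_cell[ext, r] <- nearest_distance(sp[ext, , drop = FALSE],
                                            sp[train_ids, , drop = FALSE])
    }
  }
  pooled <- as.vector(dist_cell)
  edges <- stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1),
                           names = FALSE)
  edges[1] <- -Inf; edges[length(edges)] <- Inf

  rows <- list()
  for (cb in combos) {
    result <- fit$results[[cb]]
    pred_all <- do.call(rbind, lapply(result$cells, function(cl) {
      df <- cl$predictions
      df$dist <- dist_cell[df$compound_id, cl$repeat_]
      df
    }))
    bin <- cut(pred_all$dist, edges, labels = FALSE)
    for (b in seq_len(bins)) {
      sel <- bin == b
      ccr <- NA_real_
      if (any(sel)) {
        tr <- pred_all$truth[sel]
        if (all(c("toxic", "nontoxic") %in% tr))
          ccr <- confusion_metrics(tr, pred_all$prediction[sel])[["ccr"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(combo = cb, bin = b,
                                              n = sum(sel), ccr = ccr)
    }
  }
  structure(list(edges = stats::quantile(
                   pooled, probs = seq(0, 1, length.out = bins + 1),
                   names = FALSE),
                 profile = do.call(rbind, rows)),
            class = "ad_profile")
}

#' @export
print.ad_profile <- function(x, ...) {
  cat("Applicability-domain profile (per-bin CCR, nearest to farthest)\n")
  print(stats::reshape(x$profile[, c("combo", "bin", "ccr")],
                       direction = "wide", idvar = "combo",
                       timevar = "bin"), row.names = FALSE)
  invisible(x)
}

#' Whole-dataset preprocessed descriptor space for one domain
#'
#' Applies near-zero-variance filtering, the domain's correlation cutoff
#' and range scaling over the full dataset -- the space used for
#' descriptor-space figures, applicability-domain distances, Mantel tests
#' and neighbour contrasts.
#'
#' @param table domain-tagged descriptor matrix.
#' @param domain one of "chemical", "target", "cytotox".
#' @param cutoffs a \code{domain_cutoffs}; if NULL, calibrated on
#'   \code{table}.
#' @param control a [preprocess_config()].
#' @return Scaled matrix for the domain.
#' @export
descriptor_space <- function(table, domain, cutoffs = NULL,
                             control = preprocess_config()) {
  if (is.null(cutoffs))
    cutoffs <- calibrate_cutoffs(table, target_size = control$target_size,
                                 freq_ratio = control$nzv_freq_ratio,
                                 unique_cut = control$nzv_unique_cut)
  blk <- select_domains(table, domain)
  blk <- drop_near_zero_variance(blk, control$nzv_freq_ratio,
                                 control$nzv_unique_cut)
  blk <- apply_correlation_filter(blk, unname(cutoffs[[domain]]))
  apply_range_scaler(fit_range_scaler(blk), blk)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal triangles, with
#' significance from joint row/column permutations:
#' p = (1 + #\{permuted r >= observed r\}) / (1 + n_perm).
#'
#' @param a,b symmetric zero-diagonal distance matrices over the same
#'   compounds in the same order.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return Object of class \code{mantel_result}: r, p, n_perm.
#' @export
mantel_test <- function(a, b, n_perm = 9999L, seed = 1L) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (!isSymmetric(unname(a)) || !isSymmetric(unname(b)))
    stop("mantel_test: distance matrices must be symmetric", call. = FALSE)
  if (any(diag(a) != 0) || any(diag(b) != 0))
    stop("mantel_test: distance matrices must have zero diagonals",
         call. = FALSE)
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], b[ut])
  set.seed(as.integer(seed))
  n <- nrow(a)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    pm <- sample.int(n)
    r_p <- stats::cor(a[ut], b[pm, pm][ut])
    if (r_p >= r_obs) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (1 + n_perm),
                 n_perm = as.integer(n_perm)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Aggregate variable importances over tripartite models
#'
#' Within each fold model, raw importances (mean decrease in Gini
#' impurity) are range-scaled to [0, 100]; each descriptor's scaled
#' importance is then averaged over the models in which it survived
#' preprocessing (models where it was filtered out are excluded from its
#' average rather than imputed as zero, and the contributing-model count
#' is reported).
#'
#' @param result a \code{combo_result} (canonically the tripartite one).
#' @param table the descriptor table, used for domain tags.
#' @param top_n rows kept per domain in the printed summary (default 10).
#' @return Object of class \code{importance_table}: data.frame with
#'   descriptor, domain, avg_importance, n_models, and rank within
#'   domain, sorted by domain then rank; descriptors surviving zero
#'   models are listed in the \code{omitted} attribute.
#' @export
aggregate_importance <- function(result, table, top_n = 10L) {
  stopifnot(inherits(result, "combo_result"), length(result$cells) >= 1L)
  dom <- stats::setNames(domains(table), colnames(table))
  acc_sum <- numeric(0)
  acc_n <- integer(0)
  for (cl in result$cells) {
    imp <- cl$importance
    rng <- range(imp)
    scaled <- if (rng[2] > rng[1])
      (imp - rng[1]) / (rng[2] - rng[1]) * 100
    else stats::setNames(rep(0, length(imp)), names(imp))
    new <- setdiff(names(scaled), names(acc_sum))
    acc_sum[new] <- 0; acc_n[new] <- 0L
    acc_sum[names(scaled)] <- acc_sum[names(scaled)] + scaled
    acc_n[names(scaled)] <- acc_n[names(scaled)] + 1L
  }
  avg <- acc_sum / acc_n
  out <- data.frame(descriptor = names(avg),
                    domain = unname(dom[names(avg)]),
                    avg_importance = unname(avg),
                    n_models = unname(acc_n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$domain, -out$avg_importance, out$descriptor), ]
  out$rank <- stats::ave(-out$avg_importance, out$domain,
                         FUN = function(z) rank(z, ties.method = "first"))
  rownames(out) <- NULL
  omitted <- setdiff(names(dom)[dom %in% unique(out$domain)],
                     out$descriptor)
  structure(out, omitted = omitted, top_n = as.integer(top_n),
            class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, ...) {
  top_n <- attr(x, "top_n")
  cat(sprintf("Top %d descriptors per domain by average scaled importance\n",
              top_n))
  df <- as.data.frame(x)
  print(df[df$rank <= top_n, ], row.names = FALSE)
  invisible(x)
}

#' Nearest-neighbour target-score contrast for a toxic compound
#'
#' Finds the query's k nearest nontoxic neighbours in chemical space
#' (optionally within \code{max_distance}) and, for each neighbour, the m
#' target descriptors with the largest numerical increase going from the
#' nontoxic neighbour to the toxic query -- the targets implicated as more
#' likely to interact with the toxic compound.  Targets recurring in at
#' least 3 of the k per-neighbour lists are flagged.
#'
#' @param query_id id of the toxic query compound.
#' @param chem_space preprocessed chemical-space matrix (rownames = ids).
#' @param target_block matrix of target-score descriptors (rownames = ids).
#' @param labels named toxic/nontoxic labels.
#' @param k number of nontoxic neighbours (default 5).
#' @param m number of targets listed per neighbour (default 5).
#' @param max_distance optional Euclidean radius for eligible neighbours.
#' @return Object of class \code{neighbor_contrast}: query, neighbours
#'   (data.frame id, distance), per-neighbour top-m target lists, and
#'   \code{flagged} (targets appearing in >= 3 lists).
#' @export
neighbor_contrast <- function(query_id, chem_space, target_block, labels,
                              k = 5L, m = 5L, max_distance = NULL) {
  stopifnot(query_id %in% rownames(chem_space),
            query_id %in% rownames(target_block))
  nontox <- names(labels)[as.character(labels) == "nontoxic"]
  nontox <- setdiff(intersect(nontox, rownames(chem_space)), query_id)
  d <- sqrt(colSums((t(chem_space[nontox, , drop = FALSE]) -
                       chem_space[query_id, ])^2))
  if (!is.null(max_distance)) {
    nontox <- nontox[d <= max_distance]
    d <- d[d <= max_distance]
  }
  if (length(nontox) == 0L)
    stop("neighbor_contrast: no eligible nontoxic neighbours", call. = FALSE)
  if (length(nontox) < k)
    warning("neighbor_contrast: only ", length(nontox),
            " eligible neighbours (k = ", k, ")", call. = FALSE)
  ord <- order(d, nontox)[seq_len(min(k, length(nontox)))]
  nbrs <- nontox[ord]
  q_scores <- target_block[query_id, ]
  # ties in the score difference are broken by target id
  lists <- lapply(nbrs, function(nb) {
    diff <- q_scores - target_block[nb, ]
    ord2 <- order(-diff, names(diff))
    names(diff)[ord2][seq_len(min(m, length(diff)))]
  })
  counts <- table(unlist(lists))
  structure(list(query = query_id,
                 neighbors = data.frame(compound_id = nbrs,
                                        distance = d[ord],
                                        stringsAsFactors = FALSE),
                 lists = stats::setNames(lists, nbrs),
                 flagged = sort(names(counts)[counts >= 3])),
            class = "neighbor_contrast")
}

#' @export
print.neighbor_contrast <- function(x, ...) {
  cat(sprintf("Target-score contrast for toxic compound %s\n", x$query))
  for (i in seq_len(nrow(x$neighbors))) {
    cat(sprintf("  neighbour %s (d = %.3f): %s\n",
                x$neighbors$compound_id[i], x$neighbors$distance[i],
                paste(x$lists[[i]], collapse = ", ")))
  }
  cat("  flagged (>= 3 lists):",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
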