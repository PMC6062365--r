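#' Laplacian-modified naive Bayes multi-target scorer
#'
#' Trains the multi-target interaction-likelihood model used to generate
#' protein-target descriptors.  For each retained target \eqn{t} the model
#' stores Laplace-corrected feature counts over the active training
#' compounds; a compound with binary feature set \eqn{x} is then scored as
#' \deqn{score(t, x) = \sum_{f \in x} \ln\frac{A_{t,f} + 1}{N_f P_t + 1}}
#' where \eqn{A_{t,f}} is the number of active compounds for \eqn{t}
#' containing feature \eqn{f}, \eqn{N_f} the number of training compounds
#' containing \eqn{f}, and \eqn{P_t = n_{active,t} / n_{records,t}} the
#' target's base rate.  Features unseen in training contribute
#' \eqn{\ln(1/1) = 0}, the Laplacian-neutral element.  Scores are relative
#' interaction likelihoods, not affinities, and are used directly as
#' numeric descriptors.
#'
#' Targets with fewer than \code{min_records} bioactivity records, or with
#' a degenerate base rate (all active or all inactive), are dropped and
#' listed in the \code{dropped} element of the fit.
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{target_id} and \code{active} (0/1 or logical).
#' @param fingerprints named list mapping each training \code{compound_id}
#'   to its non-empty set of binary feature ids (integer or character).
#' @param min_records minimum records per retained target (default 50).
#' @return An object of class \code{lmnb} with elements \code{targets},
#'   \code{weights} (targets x features matrix of per-feature log ratios),
#'   \code{priors}, \code{n_records}, \code{n_active}, \code{feature_ids},
#'   \code{feature_count} (\eqn{N_f}), \code{n_train} and \code{dropped}.
#' @examples
#' recs <- data.frame(compound_id = c("c1", "c2", "c3", "c4"),
#'                    target_id = "t", active = c(1, 1, 0, 0))
#' fps <- list(c1 = 1L, c2 = 1L, c3 = 1L, c4 = 2L)
#' fit <- lmnb(recs, fps, min_records = 1)
#' predict(fit, list(q = 1L))      # log((2 + 1) / (3 * 0.5 + 1)) = log(1.2)
#' @export
lmnb <- function(records, fingerprints, min_records = 50L) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "target_id", "active") %in% names(records)))
  if (nrow(records) == 0L)
    stop("lmnb: no bioactivity records supplied", call. = FALSE)
  records$compound_id <- as.character(records$compound_id)
  records$target_id <- as.character(records$target_id)
  records$active <- as.integer(records$active)
  missing_fp <- setdiff(unique(records$compound_id), names(fingerprints))
  if (length(missing_fp))
    stop("lmnb: no fingerprint for compound(s): ",
         paste(utils::head(missing_fp, 5), collapse = ", "), call. = FALSE)
  if (any(lengths(fingerprints[unique(records$compound_id)]) == 0L))
    stop("lmnb: fingerprints must be non-empty", call. = FALSE)

  train_ids <- unique(records$compound_id)
  n_train <- length(train_ids)
  feature_ids <- sort(unique(unlist(fingerprints[train_ids])))
  fidx <- stats::setNames(seq_along(feature_ids), as.character(feature_ids))
  # N_f: number of distinct training compounds containing feature f
  Nf <- integer(length(feature_ids))
  cpd_feat <- lapply(fingerprints[train_ids],
                     function(b) unname(fidx[as.character(unique(b))]))
  for (b in cpd_feat) Nf[b] <- Nf[b] + 1L

  tgt_split <- split(seq_len(nrow(records)), records$target_id)
  targets <- names(tgt_split)
  n_records <- vapply(tgt_split, length, 0L)
  n_active <- vapply(tgt_split, function(i) sum(records$active[i]), 0L)

  too_few <- n_records < min_records
  degenerate <- !too_few & (n_active == 0L | n_active == n_records)
  reason <- rep(NA_character_, length(targets))
  reason[too_few] <- "fewer records than min_records"
  reason[degenerate] <- "degenerate base rate (all active or all inactive)"
  dropped <- data.frame(target_id = targets[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- is.na(reason)
  if (!any(keep))
    stop("lmnb: no target has at least ", min_records,
         " records with a non-degenerate base rate", call. = FALSE)

  targets_k <- targets[keep]
  A <- matrix(0L, length(targets_k), length(feature_ids),
              dimnames = list(targets_k, as.character(feature_ids)))
  for (j in seq_along(targets_k)) {
    rows <- tgt_split[[targets_k[j]]]
    act_cpds <- unique(records$compound_id[rows][records$active[rows] == 1L])
    for (cp in act_cpds) {
      b <- cpd_feat[[cp]]
      A[j, b] <- A[j, b] + 1L
    }
  }
  priors <- n_active[keep] / n_records[keep]
  # per-feature log ratios; unseen features implicitly contribute 0
  W <- log((A + 1) / (outer(unname(priors), Nf) + 1))

  structure(list(targets = targets_k,
                 weights = W,
                 priors = priors,
                 n_records = n_records[keep],
                 n_active = n_active[keep],
                 feature_ids = feature_ids,
                 feature_count = stats::setNames(Nf,
                                                 as.character(feature_ids)),
                 n_train = n_train,
                 min_records = as.integer(min_records),
                 dropped = dropped),
            class = "lmnb")
}

#' @export
print.lmnb <- function(x, ...) {
  cat("Laplacian-modified naive Bayes target scorer\n")
  cat(sprintf("  %d retained targets (min %d records each), %d dropped\n",
              length(x$targets), x$min_records, nrow(x$dropped)))
  cat(sprintf("  %d training compounds, %d binary features\n",
              x$n_train, length(x$feature_ids)))
  invisible(x)
}

#' Score compounds against every retained target
#'
#' Computes the summed per-feature log likelihood ratio for each compound
#' and target.  Duplicated feature ids within a fingerprint are ignored
#' (set semantics) and features absent from the training data contribute
#' zero.  An empty fingerprint yields an all-zero row with a warning.
#'
#' @param object a fitted [lmnb()] model.
#' @param fingerprints a single feature-id vector, or a (preferably named)
#'   list of them.
#' @param ... unused.
#' @return A numeric matrix, compounds x retained targets.
#' @export
predict.lmnb <- function(object, fingerprints, ...) {
  if (!is.list(fingerprints)) fingerprints <- list(fingerprints)
  n <- length(fingerprints)
  scores <- matrix(0, n, length(object$targets),
                   dimnames = list(names(fingerprints), object$targets))
  if (n == 0L) return(scores)
  known <- as.character(object$feature_ids)
  for (i in seq_len(n)) {
    feats <- unique(as.character(fingerprints[[i]]))
    if (length(feats) == 0L) {
      warning("predict.lmnb: empty fingerprint at position ", i,
              "; returning zero scores", call. = FALSE)
      next
    }
    feats <- feats[feats %in% known]
    if (length(feats))
      scores[i, ] <- rowSums(object$weights[, feats, drop = FALSE])
  }
  scores
}

#' Build a target-score descriptor matrix
#'
#' Batch interface over [predict.lmnb()]: row \code{i} of the result equals
#' the score vector of fingerprint \code{i}.
#'
#' @inheritParams predict.lmnb
#' @param model a fitted [lmnb()] model.
#' @return compounds x targets score matrix with target ids as column names.
#' @export
score_matrix <- function(model, fingerprints) {
  stopifnot(inherits(model, "lmnb"))
  predict(model, fingerprints)
}
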