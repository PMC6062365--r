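#' Preprocessing configuration
#'
#' Parameters for the four-step fold-internal preprocessing routine:
#' (1) drop zero/near-zero-variance descriptors, (2) apply the per-domain
#' correlation cutoffs, (3) range-scale to [0, 1], (4) downsample distant
#' nontoxic compounds to balance the classes.  The step order is fixed;
#' supplying any other order is rejected by [fit_preprocess()].
#'
#' @param nzv_freq_ratio near-zero-variance frequency-ratio threshold
#'   (most common value count / second most common; default 19).
#' @param nzv_unique_cut near-zero-variance distinct-value percentage
#'   threshold (default 10).
#' @param target_size target per-domain descriptor count for cutoff
#'   calibration; NULL (default) uses the smallest post-NZV domain width.
#' @param downsample_ratio nontoxic:toxic ratio kept after downsampling
#'   (default 1, i.e. approximately class-balanced).
#' @param recalibrate_per_fold if TRUE, correlation cutoffs are recalibrated
#'   inside every fold instead of once on the full dataset.
#' @param steps the preprocessing step order; must be the canonical one.
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(nzv_freq_ratio = 19,
                              nzv_unique_cut = 10,
                              target_size = NULL,
                              downsample_ratio = 1.0,
                              recalibrate_per_fold = FALSE,
                              steps = c("nzv", "correlation", "scale",
                                        "downsample")) {
  structure(list(nzv_freq_ratio = nzv_freq_ratio,
                 nzv_unique_cut = nzv_unique_cut,
                 target_size = target_size,
                 downsample_ratio = downsample_ratio,
                 recalibrate_per_fold = isTRUE(recalibrate_per_fold),
                 steps = steps),
            class = "preprocess_config")
}

canonical_steps <- c("nzv", "correlation", "scale", "downsample")

#' Drop zero- and near-zero-variance descriptors
#'
#' A column is dropped when its variance is zero, or when its
#' most-common-to-second-most-common value frequency ratio exceeds
#' \code{freq_ratio} \emph{and} its distinct-value percentage is below
#' \code{unique_cut}.
#'
#' @param x numeric matrix (compounds x descriptors).
#' @param freq_ratio,unique_cut thresholds, see [preprocess_config()].
#' @return The reduced matrix with a \code{dropped} attribute naming the
#'   removed columns.  Errors if every column would be dropped.
#' @export
drop_near_zero_variance <- function(x, freq_ratio = 19, unique_cut = 10) {
  stopifnot(is.matrix(x), ncol(x) >= 1L, nrow(x) >= 1L)
  drop <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (length(v) > 1L && !anyDuplicated(v)) next   # all-distinct: kept
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) {            # constant: zero variance
      drop[j] <- TRUE
      next
    }
    ratio <- tab[1] / tab[2]
    distinct_pct <- 100 * length(tab) / length(v)
    drop[j] <- ratio > freq_ratio && distinct_pct < unique_cut
  }
  if (all(drop))
    stop("drop_near_zero_variance: all descriptors are (near-)zero ",
         "variance", call. = FALSE)
  out <- x[, !drop, drop = FALSE]
  d <- attr(x, "domain")
  if (!is.null(d)) attr(out, "domain") <- d[!drop]
  attr(out, "dropped") <- colnames(x)[drop]
  out
}

# Sorted list of column pairs by descending absolute correlation, with the
# static mean-absolute-correlation ranking used for removal decisions.
correlation_pairs <- function(x) {
  p <- ncol(x)
  cn <- colnames(x)
  if (p < 2L)
    return(list(i = integer(0), j = integer(0), r = numeric(0),
                mc = numeric(0), names = cn))
  cm <- abs(suppressWarnings(stats::cor(x)))
  cm[!is.finite(cm)] <- 0
  mc <- (colSums(cm) - 1) / (p - 1)     # mean |r| to all other columns
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  ord <- order(-r, cn[ut[, 1]], cn[ut[, 2]])
  list(i = ut[ord, 1], j = ut[ord, 2], r = r[ord], mc = mc, names = cn)
}

# Greedy sweep: visit pairs in descending |r|; whenever both members of a
# pair exceeding the cutoff are still alive, remove the member with the
# larger mean absolute correlation (ties: the lexicographically later name).
greedy_survivors <- function(pairs, cutoff) {
  alive <- rep(TRUE, length(pairs$names))
  ii <- pairs$i; jj <- pairs$j; rr <- pairs$r
  mc <- pairs$mc; nm <- pairs$names
  for (k in seq_along(rr)) {
    if (rr[k] <= cutoff) break
    a <- ii[k]; b <- jj[k]
    if (alive[a] && alive[b]) {
      rm <- if (mc[a] > mc[b]) a
            else if (mc[b] > mc[a]) b
            else if (nm[a] > nm[b]) a else b
      alive[rm] <- FALSE
    }
  }
  alive
}

#' Greedy pairwise-correlation filter
#'
#' Repeatedly removes one member of the most-correlated remaining column
#' pair until no pair's absolute Pearson correlation exceeds
#' \code{cutoff}.  Within a pair, the column with the larger mean absolute
#' correlation to all other columns is removed; exact ties are broken
#' deterministically by column name.
#'
#' @param x numeric matrix.
#' @param cutoff maximum permitted absolute pairwise correlation, in (0, 1].
#' @return The reduced matrix (domain tags preserved) with a
#'   \code{dropped} attribute.
#' @export
apply_correlation_filter <- function(x, cutoff) {
  stopifnot(is.matrix(x), cutoff > 0, cutoff <= 1)
  alive <- greedy_survivors(correlation_pairs(x), cutoff)
  out <- x[, alive, drop = FALSE]
  d <- attr(x, "domain")
  if (!is.null(d)) attr(out, "domain") <- d[alive]
  attr(out, "dropped") <- colnames(x)[!alive]
  out
}

#' Calibrate per-domain correlation cutoffs
#'
#' The three descriptor domains have very different raw widths; to stop
#' any one domain dominating the random forest's feature sampling, each
#' domain's correlation cutoff is chosen (by bisection) so that greedy
#' filtering leaves roughly \code{target_size} columns.  Domains already
#' at or below the target keep cutoff 1 (no-op).  If even the most
#' aggressive cutoff cannot reach within 10% of the target (mutually
#' uncorrelated columns), the closest achievable cutoff is used with a
#' warning.
#'
#' Near-zero-variance columns are excluded before calibration so the
#' calibrated widths refer to the columns that survive step 1.
#'
#' @param table domain-tagged descriptor matrix (see [assemble_table()]).
#' @param target_size desired per-domain width; NULL = smallest post-NZV
#'   domain width.
#' @param freq_ratio,unique_cut passed to [drop_near_zero_variance()].
#' @return Object of class \code{domain_cutoffs}: named numeric vector of
#'   cutoffs with a \code{widths} attribute (achieved widths).
#' @export
calibrate_cutoffs <- function(table, target_size = NULL, freq_ratio = 19,
                              unique_cut = 10) {
  d <- domains(table)
  doms <- unique(d)
  blocks <- lapply(doms, function(dd) {
    drop_near_zero_variance(table[, d == dd, drop = FALSE],
                            freq_ratio, unique_cut)
  })
  names(blocks) <- doms
  widths <- vapply(blocks, ncol, 0L)
  if (is.null(target_size)) target_size <- min(widths)
  lo_band <- 0.9 * target_size
  hi_band <- 1.1 * target_size

  cutoffs <- stats::setNames(rep(1.0, length(doms)), doms)
  achieved <- widths
  for (dd in doms) {
    if (widths[[dd]] <= target_size) next
    pairs <- correlation_pairs(blocks[[dd]])
    n_at <- function(cut) sum(greedy_survivors(pairs, cut))
    if (n_at(0) > hi_band) {
      warning("calibrate_cutoffs: domain '", dd, "' cannot reach ",
              target_size, " +/- 10% columns; using most aggressive cutoff",
              call. = FALSE)
      cutoffs[[dd]] <- 1e-6
      achieved[[dd]] <- n_at(1e-6)
      next
    }
    lo <- 0; hi <- 1
    best_cut <- 1; best_n <- widths[[dd]]
    for (it in seq_len(40L)) {
      mid <- (lo + hi) / 2
      n <- n_at(mid)
      if (abs(n - target_size) < abs(best_n - target_size) ||
          (abs(n - target_size) == abs(best_n - target_size) &&
           mid > best_cut)) {
        best_cut <- mid; best_n <- n
      }
      if (n >= lo_band && n <= hi_band) break
      if (n > target_size) hi <- mid else lo <- mid
    }
    if (best_n < lo_band || best_n > hi_band)
      warning("calibrate_cutoffs: domain '", dd, "' calibrated to width ",
              best_n, ", outside ", target_size, " +/- 10%", call. = FALSE)
    cutoffs[[dd]] <- best_cut
    achieved[[dd]] <- best_n
  }
  structure(cutoffs, widths = achieved, target_size = target_size,
            class = "domain_cutoffs")
}

#' Fit a range scaler on the modelling set
#'
#' Records each column's modelling-set minimum and maximum for the linear
#' map \code{(x - min) / (max - min)}.
#'
#' @param x numeric matrix (modelling set only).
#' @return List with \code{min} and \code{max} named vectors.
#' @export
fit_range_scaler <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' Apply a fitted range scaler
#'
#' Uses the modelling-set bounds; values of an external set may fall
#' outside [0, 1] and are deliberately not clipped.  Columns constant in
#' the modelling set (max = min) map to 0.
#'
#' @param scaler from [fit_range_scaler()].
#' @param x matrix with the scaler's columns.
#' @return The scaled matrix (domain tags preserved).
#' @export
apply_range_scaler <- function(scaler, x) {
  stopifnot(is.matrix(x), all(names(scaler$min) %in% colnames(x)))
  x2 <- x[, names(scaler$min), drop = FALSE]
  span <- scaler$max - scaler$min
  out <- sweep(x2, 2, scaler$min, "-")
  pos <- span > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, span[pos], "/")
  out[, !pos] <- 0
  d <- attr(x, "domain")
  if (!is.null(d)) attr(out, "domain") <- d[match(colnames(out),
                                                  colnames(x))]
  out
}

# squared-Euclidean nearest-neighbour distance from each row of a to rows of b
nearest_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Downsample distant nontoxic compounds
#'
#' Computes each nontoxic compound's Euclidean distance (in the supplied
#' chemical-descriptor space) to its nearest toxic compound and keeps the
#' \code{ceiling(ratio * n_toxic)} nontoxic compounds with the smallest
#' distances (distance ties broken by compound id).  All toxic compounds
#' are kept.  Applied to the modelling set only; external compounds are
#' never removed.
#'
#' @param chem numeric matrix of (preprocessed) chemical descriptors with
#'   compound ids as rownames.
#' @param labels factor/character vector (toxic/nontoxic) aligned to rows.
#' @param ratio nontoxic:toxic ratio to keep (default 1).
#' @return Character vector of kept compound ids, in input row order.
#' @export
downsample_modeling_set <- function(chem, labels, ratio = 1.0) {
  stopifnot(is.matrix(chem), nrow(chem) == length(labels))
  ids <- rownames(chem)
  if (is.null(ids)) stop("downsample_modeling_set: rownames required",
                         call. = FALSE)
  is_tox <- as.character(labels) == "toxic"
  if (!any(is_tox))
    stop("downsample_modeling_set: no toxic compounds in modelling set",
         call. = FALSE)
  if (!any(!is_tox)) return(ids)
  n_keep <- ceiling(ratio * sum(is_tox))
  if (n_keep >= sum(!is_tox)) return(ids)
  nt_ids <- ids[!is_tox]
  d <- nearest_distance(chem[!is_tox, , drop = FALSE],
                        chem[is_tox, , drop = FALSE])
  keep_nt <- nt_ids[order(d, nt_ids)][seq_len(n_keep)]
  ids[is_tox | ids %in% keep_nt]
}

#' Fit the four-step preprocessing on a modelling set
#'
#' Runs, strictly in order and on the modelling set only: near-zero
#' variance filtering (per domain), the per-domain correlation cutoffs,
#' range scaling, and nontoxic downsampling by nearest-toxic distance in
#' the (post-scaling) chemical block.  The downsampling distance space is
#' always chemical: when the modelled combination excludes the chemical
#' block, the chemical descriptors of the same modelling compounds are
#' supplied via \code{dist_table} and preprocessed identically (on the
#' modelling set only) for the distance computation.  Only if no chemical
#' block exists anywhere does downsampling fall back to the modelled
#' descriptor space.  The returned state is all that is needed to
#' transform any other table identically; no external-set value can
#' influence it.
#'
#' @param table domain-tagged modelling-set descriptor matrix.
#' @param labels toxic/nontoxic labels aligned to its rows.
#' @param cutoffs a \code{domain_cutoffs} object (or named vector) giving
#'   the correlation cutoff per domain (including \code{chemical} when
#'   \code{dist_table} is supplied).
#' @param control a [preprocess_config()].
#' @param dist_table optional chemical-block matrix (same modelling rows)
#'   used for downsampling distances when \code{table} has no chemical
#'   columns.
#' @return Object of class \code{preprocess_state}: kept columns (with
#'   domain tags), the fitted range scaler, kept compound ids after
#'   downsampling, the cutoffs used, and a fingerprint of the modelling
#'   set it was fitted on.
#' @export
fit_preprocess <- function(table, labels, cutoffs,
                           control = preprocess_config(),
                           dist_table = NULL) {
  stopifnot(is.matrix(table), nrow(table) == length(labels))
  if (!identical(control$steps, canonical_steps))
    stop("fit_preprocess: preprocessing steps must run in the order ",
         paste(canonical_steps, collapse = " -> "), call. = FALSE)
  d <- domains(table)
  doms <- unique(d)
  missing_cut <- setdiff(doms, names(cutoffs))
  if (length(missing_cut))
    stop("fit_preprocess: no correlation cutoff for domain(s): ",
         paste(missing_cut, collapse = ", "), call. = FALSE)

  prep_block <- function(blk, dd) {
    attr(blk, "domain") <- rep(dd, ncol(blk))
    blk <- drop_near_zero_variance(blk, control$nzv_freq_ratio,
                                   control$nzv_unique_cut)
    apply_correlation_filter(blk, unname(cutoffs[[dd]]))
  }
  pieces <- lapply(doms, function(dd)
    prep_block(table[, d == dd, drop = FALSE], dd))
  reduced <- do.call(cbind, pieces)
  attr(reduced, "domain") <- unlist(lapply(pieces, domains),
                                    use.names = FALSE)
  scaler <- fit_range_scaler(reduced)
  scaled <- apply_range_scaler(scaler, reduced)

  if ("chemical" %in% domains(scaled)) {
    dist_space <- select_domains(scaled, "chemical")
  } else if (!is.null(dist_table)) {
    stopifnot(is.matrix(dist_table),
              identical(rownames(dist_table), rownames(table)),
              "chemical" %in% names(cutoffs))
    blk <- prep_block(dist_table, "chemical")
    dist_space <- apply_range_scaler(fit_range_scaler(blk), blk)
  } else {
    dist_space <- scaled
  }
  kept_ids <- downsample_modeling_set(dist_space, labels,
                                      control$downsample_ratio)

  structure(list(kept_cols = colnames(reduced),
                 col_domains = domains(reduced),
                 scaler = scaler,
                 kept_ids = kept_ids,
                 cutoffs = cutoffs[doms],
                 control = control,
                 fitted_on = sort(rownames(table))),
            class = "preprocess_state")
}

#' Apply a fitted preprocessing state to any table
#'
#' Column selection and range scaling only; row downsampling is part of
#' the modelling set and is applied by the caller via
#' \code{state$kept_ids}.
#'
#' @param state a \code{preprocess_state} from [fit_preprocess()].
#' @param table descriptor matrix containing the state's columns.
#' @return Scaled matrix restricted to the kept columns, domain-tagged.
#' @export
apply_preprocess <- function(state, table) {
  stopifnot(inherits(state, "preprocess_state"), is.matrix(table))
  missing_cols <- setdiff(state$kept_cols, colnames(table))
  if (length(missing_cols))
    stop("apply_preprocess: table lacks column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         call. = FALSE)
  out <- table[, state$kept_cols, drop = FALSE]
  attr(out, "domain") <- state$col_domains
  apply_range_scaler(state$scaler, out)
}

#' Serialize a preprocessing state to JSON
#'
#' Audit sidecar recording every fitted parameter: kept columns and their
#' domains, the range-scaling bounds, the downsampled compound list and
#' the cutoffs used.
#'
#' @param state a \code{preprocess_state}.
#' @param path file to write; NULL returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_preprocess_state <- function(state, path = NULL) {
  stopifnot(inherits(state, "preprocess_state"))
  obj <- list(kept_cols = state$kept_cols,
              col_domains = state$col_domains,
              scaler = list(min = as.list(state$scaler$min),
                            max = as.list(state$scaler$max)),
              kept_ids = state$kept_ids,
              cutoffs = as.list(unclass(state$cutoffs)),
              fitted_on = state$fitted_on)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
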