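# Shared fixtures, built once per test run and cached in-process.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# small cohort for fast unit tests
small_cfg <- function(seed = 1, ...) {
  synth_config(n_compounds = 100, n_toxic = 25, n_chem_descriptors = 20,
               n_fingerprint_bits = 256, n_targets = 16, n_cell_lines = 4,
               n_bioactivity_compounds = 120, seed = seed, ...)
}

small_cohort <- function(seed = 1) {
  cached(paste0("cohort_", seed), function() generate_cohort(small_cfg(seed)))
}

small_features <- function(seed = 1) {
  cached(paste0("feat_", seed),
         function() featurize_cohort(small_cohort(seed)))
}

# one cheap cross-validated fit reused by structural tests
small_fit <- function(seed = 1) {
  cached(paste0("fit_", seed), function() {
    f <- small_features(seed)
    toxcv(f$table, f$labels,
          combos = list("chemical", c("chemical", "target", "cytotox")),
          n_repeats = 1, rf = rf_params(100), seed = seed)
  })
}

# study-scale fixture shared by the acceptance tests: default cohort,
# 5 CV repeats, the three single domains plus the tripartite combination
study_combos <- list("chemical", "target", "cytotox",
                     c("chemical", "target", "cytotox"))

acceptance_study <- function(seed) {
  cached(paste0("study_", seed), function() {
    cohort <- generate_cohort(synth_config(seed = seed))
    feats <- featurize_cohort(cohort)
    fit <- toxcv(feats$table, feats$labels, combos = study_combos,
                 n_repeats = 5, seed = seed)
    list(cohort = cohort, feats = feats, fit = fit)
  })
}

# independent brute-force tally oracle for the Laplacian-modified
# naive Bayes score: nested loops, no shared code with lmnb()
lmnb_oracle <- function(records, fingerprints, min_records, query_fps) {
  records$compound_id <- as.character(records$compound_id)
  records$target_id <- as.character(records$target_id)
  train_ids <- unique(records$compound_id)
  feats <- sort(unique(unlist(fingerprints[train_ids])))
  Nf <- sapply(feats, function(f)
    sum(sapply(train_ids, function(cp) f %in% fingerprints[[cp]])))
  names(Nf) <- as.character(feats)
  targets <- sort(unique(records$target_id))
  keep <- character(0)
  for (t in targets) {
    sub <- records[records$target_id == t, ]
    if (nrow(sub) >= min_records &&
        sum(sub$active) > 0 && sum(sub$active) < nrow(sub))
      keep <- c(keep, t)
  }
  out <- matrix(0, length(query_fps), length(keep),
                dimnames = list(names(query_fps), keep))
  for (t in keep) {
    sub <- records[records$target_id == t, ]
    Pt <- sum(sub$active) / nrow(sub)
    act_cpds <- unique(sub$compound_id[sub$active == 1])
    for (qi in seq_along(query_fps)) {
      s <- 0
      for (f in unique(query_fps[[qi]])) {
        if (!(as.character(f) %in% names(Nf))) next
        Atf <- sum(sapply(act_cpds, function(cp)
          f %in% fingerprints[[cp]]))
        s <- s + log((Atf + 1) / (Nf[[as.character(f)]] * Pt + 1))
      }
      out[qi, t] <- s
    }
  }
  out
}

# random toy bioactivity instance for oracle-equivalence testing
random_lmnb_instance <- function() {
  n_cpd <- sample(4:10, 1)
  n_feat <- sample(3:8, 1)
  n_tgt <- sample(1:3, 1)
  cpds <- paste0("c", seq_len(n_cpd))
  fps <- lapply(cpds, function(cp)
    sort(sample.int(n_feat, sample(seq_len(n_feat), 1))))
  names(fps) <- cpds
  rec <- do.call(rbind, lapply(seq_len(n_tgt), function(t) {
    sel <- sample(cpds, sample(2:n_cpd, 1))
    data.frame(compound_id = sel, target_id = paste0("t", t),
               active = sample(0:1, length(sel), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  q <- lapply(1:3, function(i) sort(sample.int(n_feat + 2, sample(1:4, 1))))
  names(q) <- paste0("q", 1:3)
  list(records = rec, fingerprints = fps, queries = q)
}

# fabricate a combo_result whose cells have prescribed CCR values,
# for testing the evaluation statistics in isolation
fake_result <- function(ccrs, combo = "chemical", plan = NULL,
                        n_folds = 5) {
  n_repeats <- ceiling(length(ccrs) / n_folds)
  if (is.null(plan)) {
    labels <- factor(rep(c("nontoxic", "toxic"), each = 10 * n_folds),
                     levels = c("nontoxic", "toxic"))
    names(labels) <- sprintf("CPD%03d", seq_along(labels))
    plan <- make_split_plan(labels, n_repeats = n_repeats,
                            n_folds = n_folds, seed = 99)
  }
  cells <- lapply(seq_along(ccrs), function(i) {
    r <- (i - 1) %/% n_folds + 1
    f <- (i - 1) %% n_folds + 1
    # 10 toxic + 10 nontoxic externals; realise CCR via sensitivity,
    # keeping selectivity = 1: ccr = (sens + 1) / 2
    sens <- 2 * ccrs[i] - 1
    stopifnot(sens >= 0, sens <= 1, abs(sens * 10 - round(sens * 10)) < 1e-9)
    n_tp <- round(sens * 10)
    truth <- rep(c("toxic", "nontoxic"), each = 10)
    pred <- c(rep("toxic", n_tp), rep("nontoxic", 10 - n_tp),
              rep("nontoxic", 10))
    list(repeat_ = r, fold = f, seed = i,
         predictions = data.frame(
           compound_id = sprintf("X%03d", seq_len(20)),
           truth = truth, prediction = pred,
           p_toxic = ifelse(pred == "toxic", 0.9, 0.1),
           stringsAsFactors = FALSE),
         importance = NULL, state = NULL)
  })
  structure(list(combo = combo, cells = cells, failures = list(),
                 plan = plan, cutoffs = NULL, rf = rf_params(1),
                 master_seed = 99L),
            class = "combo_result")
}
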