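study_labels <- function() {
  n <- 367
  ids <- sprintf("c%03d", seq_len(n))
  labels <- setNames(rep("nontoxic", n), ids)
  labels[seq_len(92)] <- "toxic"
  factor(labels, levels = c("nontoxic", "toxic"))
}

test_that("split plans stratify folds to within one compound per class", {
  labels <- study_labels()
  plan <- make_split_plan(labels, n_repeats = 3, n_folds = 5, seed = 7)
  for (r in 1:3) {
    sizes <- table(plan$assignment[, r])
    expect_setequal(as.integer(sizes), c(73L, 73L, 73L, 74L, 74L))
    tox_per_fold <- table(plan$assignment[as.character(labels) == "toxic",
                                          r])
    expect_true(all(tox_per_fold %in% c(18L, 19L)))
    # folds partition the compounds
    expect_equal(sum(sizes), 367L)
  }
  # repeats differ from each other
  expect_false(identical(plan$assignment[, 1], plan$assignment[, 2]))
})

test_that("split plans are deterministic and validate class sizes", {
  labels <- study_labels()
  p1 <- make_split_plan(labels, 2, 5, seed = 3)
  p2 <- make_split_plan(labels, 2, 5, seed = 3)
  expect_identical(p1, p2)
  tiny <- factor(setNames(c("toxic", "toxic", rep("nontoxic", 10)),
                          sprintf("x%02d", 1:12)),
                 levels = c("nontoxic", "toxic"))
  expect_error(make_split_plan(tiny, 1, 5, seed = 1), "fewer members")
})

test_that("each fold model predicts exactly its held-out fold", {
  fit <- small_fit(1)
  res <- fit$results[["chemical"]]
  expect_length(res$cells, 5L)
  for (cl in res$cells) {
    fold_ids <- rownames(fit$plan$assignment)[
      fit$plan$assignment[, cl$repeat_] == cl$fold]
    expect_setequal(cl$predictions$compound_id, fold_ids)
    # predictions carry the vote fraction and the tie-to-toxic rule
    expect_true(all(cl$predictions$p_toxic >= 0 &
                      cl$predictions$p_toxic <= 1))
    expect_equal(cl$predictions$prediction,
                 ifelse(cl$predictions$p_toxic >= 0.5, "toxic",
                        "nontoxic"))
  }
})

test_that("identical seeds reproduce identical fold models", {
  f <- small_features(1)
  plan <- make_split_plan(f$labels, 1, 5, seed = 5)
  a <- run_combination(f$table, f$labels, "chemical", plan,
                       rf = rf_params(50), master_seed = 5)
  b <- run_combination(f$table, f$labels, "chemical", plan,
                       rf = rf_params(50), master_seed = 5)
  expect_equal(a$cells[[1]]$predictions, b$cells[[1]]$predictions)
  expect_equal(a$cells[[3]]$importance, b$cells[[3]]$importance)
})

test_that("the split plan is shared bit-identically across combinations", {
  fit <- small_fit(1)
  plans <- lapply(fit$results, function(r) r$plan$assignment)
  expect_identical(plans[[1]], plans[[2]])
  # and the per-cell external membership matches
  for (i in seq_along(fit$results[[1]]$cells)) {
    expect_identical(sort(fit$results[[1]]$cells[[i]]$predictions$compound_id),
                     sort(fit$results[[2]]$cells[[i]]$predictions$compound_id))
  }
})

test_that("mtry follows the square root of the post-preprocessing width", {
  fit <- small_fit(1)
  for (cl in fit$results[["chemical"]]$cells) {
    p <- length(cl$state$kept_cols)
    expect_equal(cl$mtry, max(1L, floor(sqrt(p))))
  }
})

test_that("a degenerate descriptor block fails per fold with diagnostics", {
  f <- small_features(1)
  tab <- f$table
  tab[, domains(tab) == "chemical"] <- 1   # constant chemical block
  attr(tab, "domain") <- domains(f$table)
  plan <- make_split_plan(f$labels, 1, 5, seed = 2)
  res <- suppressWarnings(
    run_combination(tab, f$labels, "chemical", plan, rf = rf_params(20),
                    cutoffs = c(chemical = 1), master_seed = 2))
  expect_length(res$cells, 0L)
  expect_length(res$failures, 5L)
  expect_match(res$failures[[1]]$message, "variance")
})

test_that("ties in the tree vote classify as toxic", {
  expect_equal(as.character(toxtriad:::vote_to_class(c(0.5, 0.49, 0.51))),
               c("toxic", "nontoxic", "toxic"))
})

test_that("a single-tree forest yields all-or-nothing vote fractions", {
  f <- small_features(1)
  plan <- make_split_plan(f$labels, 1, 5, seed = 4)
  res <- run_combination(f$table, f$labels, "chemical", plan,
                         rf = rf_params(1), master_seed = 4)
  p <- res$cells[[1]]$predictions$p_toxic
  expect_true(all(p %in% c(0, 1)))
})

test_that("perturbing external-fold rows leaves the trained model unchanged", {
  f <- small_features(1)
  plan <- make_split_plan(f$labels, 1, 5, seed = 6)
  cuts <- calibrate_cutoffs(f$table)
  a <- run_combination(f$table, f$labels, "chemical", plan,
                       rf = rf_params(50), cutoffs = cuts,
                       master_seed = 6)
  ext_ids <- rownames(plan$assignment)[plan$assignment[, 1] == 1]
  tampered <- f$table
  tampered[ext_ids, ] <- tampered[ext_ids, ] + 100
  attr(tampered, "domain") <- domains(f$table)
  b <- run_combination(tampered, f$labels, "chemical", plan,
                       rf = rf_params(50), cutoffs = cuts,
                       master_seed = 6)
  cell_a <- a$cells[[1]]; cell_b <- b$cells[[1]]
  expect_identical(cell_a$state, cell_b$state)
  expect_equal(cell_a$importance, cell_b$importance)
})

test_that("y-scrambling arithmetic, degenerate rules and guards", {
  expect_error(
    y_scramble_assess(small_features(1)$table, small_features(1)$labels,
                      "chemical", make_split_plan(small_features(1)$labels,
                                                  1, 5, seed = 1),
                      1, 1, n_scrambles = 1),
    "insufficient scrambles")
  f <- small_features(1)
  plan <- make_split_plan(f$labels, 1, 5, seed = 1)
  ys <- y_scramble_assess(f$table, f$labels,
                          c("chemical", "target", "cytotox"), plan, 1, 1,
                          rf = rf_params(60), n_scrambles = 4,
                          master_seed = 1)
  # recompute the prediction-interval t-test from the returned pieces
  n <- length(ys$scrambled_ccr)
  t_stat <- (ys$real_ccr - mean(ys$scrambled_ccr)) /
    (sd(ys$scrambled_ccr) * sqrt(1 + 1 / n))
  expect_equal(ys$p, pt(t_stat, df = n - 1, lower.tail = FALSE))
  expect_identical(ys$pass, ys$p < 0.05)
})
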