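test_that("confusion metrics count the 2x2 table correctly", {
  m <- confusion_metrics(c("toxic", "toxic", "nontoxic", "nontoxic"),
                         c("toxic", "nontoxic", "nontoxic", "nontoxic"))
  expect_equal(unname(m), c(0.5, 1.0, 0.75))
  expect_equal(unname(confusion_metrics(rep(c("toxic", "nontoxic"), 3),
                                        rep(c("toxic", "nontoxic"), 3))),
               c(1, 1, 1))
  expect_error(confusion_metrics(rep("toxic", 4), rep("toxic", 4)),
               "both classes")
})

test_that("CCR equals the mean of sensitivity and selectivity exactly", {
  set.seed(12)
  for (i in 1:20) {
    truth <- sample(c("toxic", "nontoxic"), 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("toxic", "nontoxic"), 30, replace = TRUE)
    m <- confusion_metrics(truth, pred)
    expect_identical(m[["ccr"]],
                     (m[["sensitivity"]] + m[["selectivity"]]) / 2)
  }
})

test_that("performance summaries aggregate cells correctly", {
  res <- fake_result(rep(0.8, 10))
  s <- performance_summary(res)
  expect_equal(s$ccr, 0.8)
  expect_equal(s$ccr_sd, 0)
  res2 <- fake_result(c(0.6, 0.7, 0.8, 0.9, 1.0))
  s2 <- performance_summary(res2)
  expect_equal(s2$ccr, mean(c(0.6, 0.7, 0.8, 0.9, 1.0)))
  expect_equal(s2$ccr_sd, sd(c(0.6, 0.7, 0.8, 0.9, 1.0)))
  expect_equal(s2$n_cells, 5L)
})

test_that("paired improvement of a result against itself is identically zero", {
  a <- fake_result(c(0.7, 0.8, 0.9, 0.6, 1.0))
  rec <- paired_improvement(a, a)
  expect_equal(rec$mean, 0)
  expect_equal(rec$se, 0)
  expect_equal(rec$p_value, 1)
})

test_that("a single-cell spike gives the closed-form mean and SE", {
  ccrs <- rep(0.8, 100)
  a <- fake_result(ccrs, n_folds = 5)
  b_ccrs <- ccrs; b_ccrs[1] <- 0.7
  b <- fake_result(b_ccrs, plan = a$plan, n_folds = 5)
  rec <- paired_improvement(a, b)
  expect_equal(rec$mean, 0.001)
  expect_equal(rec$se, 0.001)
  expect_lt(rec$p_value, 1)
})

test_that("paired improvement refuses mismatched split plans", {
  a <- fake_result(rep(0.8, 5))
  labels <- factor(setNames(rep(c("nontoxic", "toxic"), each = 50),
                            sprintf("CPD%03d", 1:100)),
                   levels = c("nontoxic", "toxic"))
  other_plan <- make_split_plan(labels, 1, 5, seed = 123)
  b <- fake_result(rep(0.8, 5), plan = other_plan)
  expect_error(paired_improvement(a, b), "same\\s+split plan")
})

test_that("rank-based AUC equals the concordant-pair fraction", {
  expect_equal(roc_auc(c("toxic", "toxic", "nontoxic"), c(0.9, 0.8, 0.1)),
               1)
  # 4-point toy, exhaustive pair count: pairs (toxic, nontoxic)
  truth <- c("toxic", "nontoxic", "toxic", "nontoxic")
  score <- c(0.9, 0.7, 0.4, 0.2)
  # toxic scores {0.9, 0.4} vs nontoxic {0.7, 0.2}:
  # concordant: (0.9>0.7), (0.9>0.2), (0.4>0.2) = 3 of 4
  expect_equal(roc_auc(truth, score), 3 / 4)
  # ties count half
  expect_equal(roc_auc(c("toxic", "nontoxic"), c(0.5, 0.5)), 0.5)
  # invariance under strictly monotone transformation
  set.seed(3)
  tr <- sample(c("toxic", "nontoxic"), 40, replace = TRUE)
  tr[1:2] <- c("toxic", "nontoxic")
  sc <- rnorm(40)
  expect_equal(roc_auc(tr, sc), roc_auc(tr, exp(3 * sc)))
})

test_that("random scores give chance-level AUC on average", {
  set.seed(7)
  aucs <- replicate(200, {
    tr <- c("toxic", "nontoxic", sample(c("toxic", "nontoxic"), 18,
                                        replace = TRUE))
    roc_auc(tr, runif(20))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("Mantel r and p match an exhaustive-permutation oracle on 5 objects", {
  set.seed(21)
  pts_a <- matrix(rnorm(10), 5, 2)
  a <- as.matrix(dist(pts_a))
  b <- as.matrix(dist(pts_a + matrix(rnorm(10, 0, 0.4), 5, 2)))
  ut <- upper.tri(a)
  r_direct <- cor(a[ut], b[ut])
  mt <- mantel_test(a, b, n_perm = 2000, seed = 1)
  expect_equal(mt$r, r_direct)
  # exhaustive oracle over all 120 permutations
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ,
                 drop = FALSE]
  r_all <- apply(perms, 1, function(p) cor(a[ut], b[p, p][ut]))
  exact_frac <- mean(r_all >= r_direct)
  expect_lt(abs(mt$p - exact_frac), 0.05)
  # symmetry in the arguments
  mt_rev <- mantel_test(b, a, n_perm = 2000, seed = 1)
  expect_equal(mt_rev$r, mt$r)
})

test_that("Mantel test agrees with the vegan reference implementation", {
  set.seed(22)
  a <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  b <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  mt <- mantel_test(a, b, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(mt$r, unname(ref$statistic))
  expect_lt(abs(mt$p - ref$signif), 0.1)
  expect_error(mantel_test(a[, c(2, 1, 3:20)], b), "symmetric")
})

test_that("identical and independent matrices give the expected Mantel extremes", {
  set.seed(23)
  a <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  expect_equal(mantel_test(a, a, n_perm = 99, seed = 1)$r, 1)
  b <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  mt <- mantel_test(a, b, n_perm = 999, seed = 1)
  expect_lt(abs(mt$r), 0.35)
  expect_gt(mt$p, 0.05)
})

test_that("importance scaling and cross-model averaging follow the rules", {
  mk_cell <- function(imp) list(repeat_ = 1, fold = 1, seed = 1,
                                predictions = NULL, importance = imp,
                                state = NULL)
  tab <- matrix(0, 1, 3, dimnames = list("c", c("x", "y", "z")))
  attr(tab, "domain") <- rep("chemical", 3)
  one <- structure(list(combo = "chemical",
                        cells = list(mk_cell(c(x = 2, y = 4, z = 6))),
                        failures = list(), plan = NULL),
                   class = "combo_result")
  it <- aggregate_importance(one, tab)
  expect_equal(it$avg_importance[match(c("x", "y", "z"), it$descriptor)],
               c(0, 50, 100))
  # two models with opposite scaled importances average to 50;
  # a descriptor absent from one model averages over the other only
  two <- structure(list(combo = "chemical",
                        cells = list(mk_cell(c(x = 0, y = 100)),
                                     mk_cell(c(x = 100, y = 0, z = 30))),
                        failures = list(), plan = NULL),
                   class = "combo_result")
  it2 <- aggregate_importance(two, tab)
  expect_equal(it2$avg_importance[it2$descriptor == "x"], 50)
  expect_equal(it2$avg_importance[it2$descriptor == "y"], 50)
  expect_equal(it2$avg_importance[it2$descriptor == "z"], 30)
  expect_equal(it2$n_models[it2$descriptor == "z"], 1L)
})

test_that("neighbour contrasts find perturbed targets and flag recurrences", {
  ids <- c("q", paste0("n", 1:6))
  chem <- matrix(c(0, 1:6), 7, 1, dimnames = list(ids, "x"))
  tgt <- matrix(0.5, 7, 4, dimnames = list(ids, paste0("T", 1:4)))
  labels <- setNames(c("toxic", rep("nontoxic", 6)), ids)
  # all-zero differences: ties broken by target id
  nc <- neighbor_contrast("q", chem, tgt, labels, k = 3, m = 2)
  expect_equal(nc$neighbors$compound_id, c("n1", "n2", "n3"))
  expect_equal(nc$lists[["n1"]], c("T1", "T2"))
  expect_equal(nc$flagged, c("T1", "T2"))   # same list for all 3 neighbours
  # lowering one target's neighbour score tops its list
  tgt2 <- tgt
  tgt2["n1", "T3"] <- 0.1
  nc2 <- neighbor_contrast("q", chem, tgt2, labels, k = 3, m = 2)
  expect_equal(nc2$lists[["n1"]][1], "T3")
  # fewer eligible neighbours than k warns and returns what exists
  expect_warning(nc3 <- neighbor_contrast("q", chem, tgt, labels, k = 5,
                                          max_distance = 2.5),
                 "eligible")
  expect_equal(nrow(nc3$neighbors), 2L)
})

test_that("AD profiles bin by pooled distance quantiles with shared edges", {
  # hand-built fit: 10 compounds, 1 repeat, 2 folds, one combo
  ids <- sprintf("c%02d", 1:10)
  labels <- factor(setNames(rep(c("nontoxic", "toxic"), 5), ids),
                   levels = c("nontoxic", "toxic"))
  assignment <- matrix(rep(c(1L, 2L), 5), 10, 1,
                       dimnames = list(ids, NULL))
  plan <- structure(list(assignment = assignment, n_repeats = 1L,
                         n_folds = 2L, seed = 1L), class = "split_plan")
  cells <- lapply(1:2, function(f) {
    ext <- ids[assignment[, 1] == f]
    list(repeat_ = 1L, fold = f, seed = f,
         predictions = data.frame(compound_id = ext,
                                  truth = as.character(labels[ext]),
                                  prediction = as.character(labels[ext]),
                                  p_toxic = 0.5,
                                  stringsAsFactors = FALSE))
  })
  fit <- structure(list(results = list(chemical = structure(
    list(combo = "chemical", cells = cells, failures = list(),
         plan = plan), class = "combo_result")),
    plan = plan, labels = labels), class = "toxcv")
  # space where c01 coincides with c02 (a modelling compound of fold 1)
  space <- matrix(seq(0, 90, by = 10), 10, 1, dimnames = list(ids, "x"))
  space["c01", ] <- space["c02", ]
  ad <- ad_profile(fit, space, bins = 2)
  expect_equal(sum(ad$profile$n), 10L)
  d01 <- 0   # identical to a modelling-set compound
  expect_equal(min(ad$edges), d01)
  # perfect predictions give CCR 1 in every populated mixed-class bin
  expect_true(all(ad$profile$ccr[!is.na(ad$profile$ccr)] == 1))
})
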