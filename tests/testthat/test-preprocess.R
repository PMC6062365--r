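test_that("near-zero-variance filtering applies the ratio and uniqueness rules", {
  n <- 367
  x <- cbind(const = rep(1, n),
             cont = rnorm(n),
             rare = c(rep(0, 360), rep(1, 7)),     # ratio 51.4, 2 levels
             common = c(rep(0, 300), rep(1, 67)))  # ratio 4.5 -> kept
  out <- drop_near_zero_variance(x, freq_ratio = 19, unique_cut = 10)
  expect_equal(colnames(out), c("cont", "common"))
  expect_equal(attr(out, "dropped"), c("const", "rare"))
  expect_error(drop_near_zero_variance(cbind(a = rep(1, 5))), "variance")
})

test_that("the correlation filter removes exactly the offending columns", {
  set.seed(4)
  z <- rnorm(50)
  x <- cbind(a = z, b = z, c = rnorm(50))
  out <- apply_correlation_filter(x, 0.9)
  expect_equal(sort(colnames(out)), c("a", "c"))   # |r(a,b)| = 1, b removed
  y <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, letters[1:4]))
  expect_equal(apply_correlation_filter(y, 0.99), y,
               ignore_attr = "dropped")
})

test_that("greedy filtering matches the exhaustive max-subset oracle on a toy", {
  set.seed(9)
  z <- rnorm(40)
  x <- cbind(c1 = z, c2 = z, c3 = z, d = rnorm(40), e = rnorm(40))
  cutoff <- 0.9
  # oracle: largest subset with all pairwise |r| <= cutoff, ties broken
  # lexicographically by the sorted column-name set
  cols <- colnames(x)
  best <- NULL
  for (size in length(cols):1) {
    combos <- utils::combn(cols, size, simplify = FALSE)
    ok <- Filter(function(s) {
      cm <- abs(cor(x[, s, drop = FALSE]))
      all(cm[upper.tri(cm)] <= cutoff)
    }, combos)
    if (length(ok)) {
      keys <- vapply(ok, function(s) paste(sort(s), collapse = ","), "")
      best <- ok[[order(keys)[1]]]
      break
    }
  }
  got <- colnames(apply_correlation_filter(x, cutoff))
  expect_equal(sort(got), sort(best))
  expect_equal(sort(got), c("c1", "d", "e"))
})

test_that("filtered tables satisfy the pairwise correlation bound", {
  set.seed(5)
  for (i in 1:5) {
    base <- matrix(rnorm(60 * 4), 60, 4)
    x <- base[, sample(4, 12, replace = TRUE)] +
      matrix(rnorm(60 * 12, 0, 0.3), 60, 12)
    colnames(x) <- sprintf("v%02d", 1:12)
    cutoff <- runif(1, 0.5, 0.95)
    out <- apply_correlation_filter(x, cutoff)
    if (ncol(out) > 1) {
      cm <- abs(cor(out))
      expect_lte(max(cm[upper.tri(cm)]), cutoff)
    }
  }
})

test_that("cutoff calibration reaches the target width per domain", {
  # a domain already at or below target keeps cutoff 1
  set.seed(6)
  x <- matrix(rnorm(300), 50, 6,
              dimnames = list(NULL, sprintf("a%d", 1:6)))
  attr(x, "domain") <- rep("chemical", 6)
  cuts <- calibrate_cutoffs(x, target_size = 10)
  expect_equal(unname(cuts[["chemical"]]), 1.0)

  # ten duplicated columns collapse to one for any cutoff below 1
  z <- rnorm(50)
  dup <- matrix(rep(z, 10), 50, 10,
                dimnames = list(NULL, sprintf("d%02d", 1:10)))
  two <- cbind(dup, s = rnorm(50))
  attr(two, "domain") <- c(rep("chemical", 10), "target")
  cuts2 <- calibrate_cutoffs(two, target_size = 1)
  expect_equal(unname(attr(cuts2, "widths")[["chemical"]]), 1)
  expect_lt(unname(cuts2[["chemical"]]), 1)

  # unreachable target (exactly orthogonal columns) warns and falls back
  # to the most aggressive cutoff
  ind <- cbind(u1 = c(1, -1, 1, -1), u2 = c(1, 1, -1, -1),
               u3 = c(1, -1, -1, 1))
  attr(ind, "domain") <- rep("chemical", 3)
  expect_warning(cuts3 <- calibrate_cutoffs(ind, target_size = 1),
                 "cannot reach")
  expect_equal(unname(attr(cuts3, "widths")[["chemical"]]), 3)
})

test_that("default cohort domains calibrate to a common width within 10%", {
  feats <- acceptance_study(1)$feats
  cuts <- calibrate_cutoffs(feats$table)
  widths <- attr(cuts, "widths")
  target <- attr(cuts, "target_size")
  expect_equal(length(widths), 3L)
  for (w in widths) {
    expect_gte(w, 0.9 * target)
    expect_lte(w, 1.1 * target)
  }
})

test_that("range scaling uses modelling-set bounds without clipping", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  sc <- fit_range_scaler(x)
  out <- apply_range_scaler(sc, x)
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE)   # constant -> 0
  ext <- cbind(a = 8, b = 5)
  expect_equal(unname(apply_range_scaler(sc, ext)[1, "a"]), 1.5) # unclipped
})

test_that("downsampling keeps the nearest nontoxic compounds only", {
  # hand-checkable 1-D coordinates: toxic at 0, 1, 2
  ids <- c(paste0("n", 1:6), paste0("t", 1:3))
  chem <- matrix(c(0.4, 0.9, 5, 6, 7, 8, 0, 1, 2), ncol = 1,
                 dimnames = list(ids, "x"))
  labels <- setNames(c(rep("nontoxic", 6), rep("toxic", 3)), ids)
  kept <- downsample_modeling_set(chem, labels, ratio = 1)
  # nearest-toxic distances: n1 = 0.4, n2 = 0.1, n3 = 3, n4 = 4, n5 = 5, n6 = 6
  expect_setequal(kept, c("n1", "n2", "n3", "t1", "t2", "t3"))
  # generous ratio keeps everyone
  expect_equal(downsample_modeling_set(chem, labels, ratio = 10), ids)
  expect_error(downsample_modeling_set(chem[1:6, , drop = FALSE],
                                       labels[1:6]), "toxic")
})

test_that("a 275:92 cohort downsamples to a balanced 92:92 modelling set", {
  set.seed(8)
  n <- 367
  ids <- sprintf("c%03d", seq_len(n))
  labels <- setNames(rep("nontoxic", n), ids)
  labels[sample(n, 92)] <- "toxic"
  chem <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(ids, paste0("x", 1:5)))
  kept <- downsample_modeling_set(chem, labels, ratio = 1)
  expect_equal(sum(labels[kept] == "toxic"), 92L)
  expect_equal(sum(labels[kept] == "nontoxic"), 92L)
})

test_that("preprocessing refuses a shuffled step order", {
  f <- small_features(1)
  bad <- preprocess_config()
  bad$steps <- c("scale", "nzv", "correlation", "downsample")
  cuts <- calibrate_cutoffs(f$table)
  expect_error(fit_preprocess(f$table, f$labels, cuts, bad), "order")
})

test_that("no external-set value influences the fitted state", {
  f <- small_features(1)
  cuts <- calibrate_cutoffs(f$table)
  ids <- rownames(f$table)
  mod_ids <- ids[1:70]
  ext_ids <- ids[71:length(ids)]
  mod <- f$table[mod_ids, , drop = FALSE]
  attr(mod, "domain") <- domains(f$table)
  s1 <- fit_preprocess(mod, f$labels[mod_ids], cuts)
  # perturb the external rows arbitrarily; the state must be identical
  perturbed <- f$table
  perturbed[ext_ids, ] <- perturbed[ext_ids, ] * 3 + 17
  mod2 <- perturbed[mod_ids, , drop = FALSE]
  attr(mod2, "domain") <- domains(f$table)
  s2 <- fit_preprocess(mod2, f$labels[mod_ids], cuts)
  expect_identical(s1, s2)
  # and external rows transform through the fitted state, unclipped
  ext <- apply_preprocess(s1, f$table[ext_ids, , drop = FALSE])
  expect_equal(colnames(ext), s1$kept_cols)
})

test_that("the fitted state serializes to a JSON audit sidecar", {
  f <- small_features(1)
  cuts <- calibrate_cutoffs(f$table)
  state <- fit_preprocess(f$table, f$labels, cuts)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_state(state, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$kept_cols, state$kept_cols)
  expect_equal(js$kept_ids, state$kept_ids)
  expect_equal(unlist(js$scaler$min), unlist(state$scaler$min))
})

test_that("near-zero-variance agreement with the caret reference on random data", {
  set.seed(10)
  x <- cbind(matrix(rnorm(200 * 5), 200, 5),
             rep(0, 200),
             c(rep(1, 195), rep(2, 5)),
             sample(1:3, 200, replace = TRUE))
  colnames(x) <- sprintf("v%d", 1:8)
  ours <- drop_near_zero_variance(x)
  ref_drop <- caret::nearZeroVar(as.data.frame(x), freqCut = 19,
                                 uniqueCut = 10)
  expect_equal(attr(ours, "dropped"), colnames(x)[ref_drop])
})
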