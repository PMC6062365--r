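toy_records <- function() {
  # 4 compounds, one target; c1, c2 active; feature 1 in c1, c2, c3
  list(records = data.frame(compound_id = c("c1", "c2", "c3", "c4"),
                            target_id = "t", active = c(1, 1, 0, 0),
                            stringsAsFactors = FALSE),
       fps = list(c1 = c(1L, 2L), c2 = 1L, c3 = c(1L, 3L), c4 = 2L))
}

test_that("the toy score equals the closed-form count arithmetic", {
  toy <- toy_records()
  fit <- lmnb(toy$records, toy$fps, min_records = 1)
  # A_t,f = 2, N_f = 3, P_t = 0.5: score({f}) = ln(3 / 2.5)
  expect_equal(unname(predict(fit, list(q = 1L))[1, "t"]), log(1.2))
  # feature 2: A = 1 (only c1 active has it), N = 2 -> ln(2 / 2)
  expect_equal(unname(predict(fit, list(q = 2L))[1, "t"]), 0)
  # two features sum their contributions
  expect_equal(unname(predict(fit, list(q = c(1L, 2L)))[1, "t"]),
               log(1.2))
})

test_that("targets below the record threshold are dropped and reported", {
  set.seed(7)
  cpds <- paste0("c", 1:80)
  fps <- lapply(cpds, function(i) sort(sample.int(20, 5)))
  names(fps) <- cpds
  rec <- rbind(data.frame(compound_id = sample(cpds, 60, replace = TRUE),
                          target_id = "X", active = rbinom(60, 1, 0.5)),
               data.frame(compound_id = sample(cpds, 40, replace = TRUE),
                          target_id = "Y", active = rbinom(40, 1, 0.5)))
  fit <- lmnb(rec, fps, min_records = 50)
  expect_identical(fit$targets, "X")
  expect_true("Y" %in% fit$dropped$target_id)
  expect_match(fit$dropped$reason[fit$dropped$target_id == "Y"],
               "min_records")
})

test_that("a target with a degenerate base rate is dropped with a reason", {
  toy <- toy_records()
  rec <- rbind(toy$records,
               data.frame(compound_id = c("c1", "c2", "c3"),
                          target_id = "dead", active = c(0, 0, 0)))
  fit <- lmnb(rec, toy$fps, min_records = 1)
  expect_false("dead" %in% fit$targets)
  expect_match(fit$dropped$reason[fit$dropped$target_id == "dead"],
               "base rate")
  # nothing retained -> explicit failure
  expect_error(lmnb(rec[rec$target_id == "dead", ], toy$fps,
                    min_records = 1), "no target")
})

test_that("counts on a hand-tallied 5-compound set are exact", {
  fps <- list(a = c(1L, 2L), b = c(2L, 3L), c = c(1L, 3L), d = 3L,
              e = c(1L, 2L, 3L))
  rec <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                    target_id = "t", active = c(1, 0, 1, 0, 1),
                    stringsAsFactors = FALSE)
  fit <- lmnb(rec, fps, min_records = 1)
  # hand tally: N = (f1: a,c,e = 3), (f2: a,b,e = 3), (f3: b,c,d,e = 4)
  expect_equal(unname(fit$feature_count), c(3L, 3L, 4L))
  expect_equal(unname(fit$priors), 3 / 5)
  # actives {a, c, e}: A = (f1: 3), (f2: 2), (f3: 2)
  expect_equal(unname(fit$weights["t", ]),
               log(c((3 + 1) / (3 * 0.6 + 1), (2 + 1) / (3 * 0.6 + 1),
                     (2 + 1) / (4 * 0.6 + 1))))
})

test_that("unseen and duplicated features behave as set semantics", {
  toy <- toy_records()
  fit <- lmnb(toy$records, toy$fps, min_records = 1)
  expect_equal(unname(predict(fit, list(q = c(99L, 100L)))[1, ]), 0)
  expect_equal(predict(fit, list(q = c(1L, 1L, 1L))),
               predict(fit, list(q = 1L)))
  expect_warning(s <- predict(fit, list(q = integer(0))), "empty")
  expect_equal(unname(s[1, ]), 0)
})

test_that("scores are additive over disjoint fingerprints", {
  set.seed(3)
  inst <- random_lmnb_instance()
  fit <- tryCatch(lmnb(inst$records, inst$fingerprints, min_records = 2),
                  error = function(e) NULL)
  if (is.null(fit)) succeed() else {
    a <- c(1L, 3L); b <- c(2L, 4L)
    expect_equal(predict(fit, list(x = a)) + predict(fit, list(x = b)),
                 predict(fit, list(x = c(a, b))))
  }
})

test_that("adding a feature above the Laplacian-neutral ratio raises the score", {
  toy <- toy_records()
  fit <- lmnb(toy$records, toy$fps, min_records = 1)
  # feature 1 has (A+1)/(N*P+1) = 1.2 > 1
  base <- predict(fit, list(x = 2L))[1, "t"]
  more <- predict(fit, list(x = c(1L, 2L)))[1, "t"]
  expect_gt(more, base)
})

test_that("score_matrix batches predict row by row with permutation equivariance", {
  toy <- toy_records()
  fit <- lmnb(toy$records, toy$fps, min_records = 1)
  fps <- list(p = 1L, q = c(1L, 2L), r = 3L)
  m <- score_matrix(fit, fps)
  expect_equal(nrow(m), 3L)
  for (i in 1:3)
    expect_equal(m[i, , drop = FALSE],
                 predict(fit, fps[i]))
  perm <- c(3, 1, 2)
  expect_equal(score_matrix(fit, fps[perm]), m[perm, , drop = FALSE])
  empty <- score_matrix(fit, list())
  expect_equal(dim(empty), c(0L, 1L))
  expect_equal(colnames(empty), "t")
})

test_that("scores match the brute-force tally oracle on random toys", {
  set.seed(2024)
  n_ok <- 0
  for (i in 1:100) {
    inst <- random_lmnb_instance()
    fit <- tryCatch(lmnb(inst$records, inst$fingerprints, min_records = 2),
                    error = function(e) NULL)
    oracle <- lmnb_oracle(inst$records, inst$fingerprints, 2, inst$queries)
    if (is.null(fit)) {
      expect_equal(ncol(oracle), 0L)
      next
    }
    got <- predict(fit, inst$queries)
    got <- got[, sort(colnames(got)), drop = FALSE]
    expect_equal(got, oracle[, sort(colnames(oracle)), drop = FALSE],
                 tolerance = 1e-12)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 50)
})

test_that("cohort target scores recover mechanism-matched targets", {
  hits <- 0L
  for (seed in 1:5) {
    co <- generate_cohort(small_cfg(seed = seed))
    scorer <- lmnb(co$bioactivity, co$bio_fingerprints)
    sc <- predict(scorer, co$fingerprints)
    link <- co$truth$target_mech[colnames(sc)]
    facing <- co$truth$facing
    cors <- vapply(which(facing == "target"), function(k) {
      linked_cols <- which(!is.na(link) & link == k)
      cor(co$truth$mechanisms[, k], rowMeans(sc[, linked_cols,
                                                drop = FALSE]))
    }, 0)
    decoy_cor <- vapply(which(facing == "target"), function(k) {
      decoys <- which(is.na(link))
      abs(cor(co$truth$mechanisms[, k], rowMeans(sc[, decoys,
                                                    drop = FALSE])))
    }, 0)
    if (mean(cors) > mean(decoy_cor)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
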