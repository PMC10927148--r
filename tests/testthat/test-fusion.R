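test_that("validate_scores enforces the simplex contract", {
  mk <- function(v) matrix(v, 1, dimnames = list("s1", c("a", "b", "c")))
  ok <- score_set(list(mk(c(0.2, 0.3, 0.5))))
  expect_equal(validate_scores(ok, policy = "strict")$matrices[[1]][1, ],
               c(a = 0.2, b = 0.3, c = 0.5))

  raw <- score_set(list(mk(c(2, 3, 5))))
  expect_warning(v <- validate_scores(raw, policy = "renormalize"),
                 "renormalized")
  expect_equal(unname(v$matrices[[1]][1, ]), c(0.2, 0.3, 0.5))
  expect_error(validate_scores(raw, policy = "strict"), "deviates")

  expect_error(validate_scores(score_set(list(mk(c(0, 0, 0))))), "zero-sum")
  expect_error(validate_scores(score_set(list(mk(c(-0.2, 0.6, 0.6))))),
               "negative")
})

test_that("score_set rejects misaligned inputs", {
  m1 <- matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  m2 <- matrix(0.5, 2, 2, dimnames = list(c("s2", "s1"), c("a", "b")))
  m3 <- matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), c("b", "a")))
  expect_error(score_set(list(m1, m2)), "sample ids")
  expect_error(score_set(list(m1, m3)), "class labels")
  expect_error(score_set(list(matrix(1, 2, 1))), "two classes")
})

test_that("ordinal ranks sort ascending with stable class-order ties", {
  m <- matrix(c(0.37, 0.85, 0.93,
                0.93, 0.26, 0.93,
                0.74, 0.74, 0.74), 3, 3, byrow = TRUE)
  expect_equal(unname(ordinal_ranks(m)),
               matrix(c(1, 2, 3,
                        2, 1, 3,
                        1, 2, 3), 3, 3, byrow = TRUE))
})

test_that("select_topk membership has exactly k classes and validates k", {
  ords <- ordinal_ranks(matrix(runif(20), 4, 5))
  for (k in 1:5)
    expect_equal(unname(rowSums(select_topk(ords, k))), rep(k, 4))
  expect_error(select_topk(ords, 0), "k must be")
  expect_error(select_topk(ords, 6), "k must be")
  expect_error(select_topk(ords, 2.5), "k must be")
})

test_that("FRS, CCFS and FDS match hand-computed scalar values", {
  # class included in all 3 top-k sets
  ranks <- list(matrix(0.3755, 1, 1), matrix(0.4843, 1, 1),
                matrix(0.9282, 1, 1))
  member <- list(matrix(TRUE, 1, 1), matrix(TRUE, 1, 1), matrix(TRUE, 1, 1))
  expect_equal(fuzzy_rank_sum(ranks, member)[1, 1], 1.788, tolerance = 1e-12)

  # class in no top-k set: FRS = M * P_R
  none <- list(matrix(FALSE, 1, 1), matrix(FALSE, 1, 1), matrix(FALSE, 1, 1))
  expect_identical(fuzzy_rank_sum(ranks, none)[1, 1], 3)

  # M = 1, included: FRS is just the rank
  expect_equal(fuzzy_rank_sum(ranks[1], member[1])[1, 1], 0.3755)

  mk <- function(v) matrix(v, 1, dimnames = list("s1", c("a", "b")))
  ss <- score_set(list(mk(c(0.7, 0.3)), mk(c(0.6, 0.4)), mk(c(0.1, 0.9))))
  all_in <- replicate(3, matrix(TRUE, 1, 2), simplify = FALSE)
  ccfs <- complement_confidence_sum(ss, all_in, "complement")
  expect_equal(unname(ccfs[1, "a"]), 1 - (0.7 + 0.6 + 0.1) / 3,
               tolerance = 1e-12)
  lit <- complement_confidence_sum(ss, all_in, "literal")
  expect_equal(unname(lit[1, "a"]), (0.7 + 0.6 + 0.1) / 3, tolerance = 1e-12)
  none2 <- replicate(3, matrix(FALSE, 1, 2), simplify = FALSE)
  expect_equal(unname(complement_confidence_sum(ss, none2)[1, ]), c(1, 1))

  expect_equal(final_decision_score(matrix(1.788), matrix(1 - 1.4 / 3))[1, 1],
               1.788 * (1 - 1.4 / 3), tolerance = 1e-12)
  expect_identical(final_decision_score(matrix(0), matrix(0.7))[1, 1], 0)
})

test_that("decide takes the argmin with first-class tie-break", {
  fds <- matrix(c(0.9536, 1.0648, 3), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(decide(fds), "a")
  expect_identical(decide(matrix(2, 1, 3, dimnames = list(NULL, c("x", "y", "z")))),
                   "x")
})

test_that("fuse reproduces the worked one-sample bank end to end", {
  res <- fuse(worked_bank(), k = 2)
  # frozen from the scalar oracle transcription
  expect_equal(unname(res$frs[1, ]),
               c(1.7880051782408379, 1.8790561050658006, 3), tolerance = 1e-12)
  expect_equal(unname(res$ccfs[1, ]),
               c(1 - 1.4 / 3, 1 - 1.3 / 3, 1), tolerance = 1e-12)
  expect_equal(unname(res$fds[1, ]),
               c(0.95360276172844705, 1.06479845953728702, 3),
               tolerance = 1e-12)
  expect_identical(res$fused_label, "c1")
  expect_true(res$fds[1, "c1"] < res$fds[1, "c2"] &&
              res$fds[1, "c2"] < res$fds[1, "c3"])
  expect_identical(res$penalties, c(P_R = 1, P_CoF = 0))
})

test_that("vectorized fuse matches the scalar oracle on random banks", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(1:50, 1); C <- sample(2:5, 1); M <- sample(1:4, 1)
    k <- sample(seq_len(C), 1)
    variant <- sample(c("complement", "literal"), 1)
    bank <- random_bank(n, C, M, seed = 1000 + rep)
    res <- fuse(bank, k = k, variant = variant)
    orc <- oracle_fuse(bank$matrices, k = k, variant = variant)
    expect_lt(max(abs(res$fds - orc$fds)), 1e-12)
    expect_identical(res$fused_label, bank$class_labels[orc$label])
  }
})

test_that("fusion is invariant to classifier order", {
  bank <- random_bank(30, 4, 3, seed = 5)
  res <- fuse(bank, k = 2)
  perm <- score_set(bank$matrices[c(3, 1, 2)])
  res_p <- fuse(perm, k = 2)
  expect_equal(res$fds, res_p$fds, tolerance = 1e-14)
  expect_identical(res$fused_label, res_p$fused_label)
})

test_that("fusion is equivariant under class relabeling", {
  bank <- random_bank(40, 4, 3, seed = 6)
  res <- fuse(bank, k = 2)
  p <- c(3, 1, 4, 2)
  permuted <- score_set(lapply(bank$matrices, function(m) {
    m2 <- m[, p]
    colnames(m2) <- colnames(m)  # same label set, permuted contents
    m2
  }))
  res_p <- fuse(permuted, k = 2)
  expect_equal(unname(res_p$fds), unname(res$fds[, p]), tolerance = 1e-14)
  # map labels through the permutation (random banks: ties have measure zero)
  relabel <- stats::setNames(bank$class_labels[order(p)], bank$class_labels)
  expect_identical(res_p$fused_label, unname(relabel[res$fused_label]))
})

test_that("bounds hold and fully penalized classes attain FDS = M exactly", {
  for (seed in 1:5) {
    bank <- random_bank(25, 4, 3, seed = seed)
    res <- fuse(bank, k = 1)
    M <- 3
    expect_true(all(res$frs >= 0 & res$frs <= M))
    expect_true(all(res$ccfs >= 0 & res$ccfs <= 1))
    expect_true(all(res$fds >= 0 & res$fds <= M))
    ranks <- lapply(bank$matrices, rank_transform)
    out_everywhere <- Reduce(`&`, lapply(select_topk(ordinal_ranks(ranks), 1), `!`))
    if (any(out_everywhere))
      expect_identical(unique(res$fds[out_everywhere]), 3)
  }
})

test_that("k = C disables penalties entirely", {
  bank <- random_bank(20, 3, 3, seed = 12)
  res <- fuse(bank, k = 3)
  ranks <- lapply(bank$matrices, rank_transform)
  expect_equal(res$frs, Reduce(`+`, ranks), tolerance = 1e-14)
})

test_that("unanimous top choice is always recovered", {
  # 1000 random samples where every classifier shares the same argmax class
  set.seed(77)
  total <- 0
  for (b in 1:20) {
    n <- 50; C <- sample(3:5, 1); M <- sample(2:4, 1)
    target <- sample.int(C, n, replace = TRUE)
    mats <- lapply(seq_len(M), function(i) {
      m <- matrix(stats::rexp(n * C), n, C)
      m[cbind(seq_len(n), target)] <- apply(m, 1, max) + stats::rexp(n) + 0.05
      m <- m / rowSums(m)
      colnames(m) <- paste0("class", seq_len(C))
      m
    })
    bank <- score_set(mats)
    res <- fuse(bank, k = 2)
    expect_identical(res$fused_label, paste0("class", target))
    total <- total + n
  }
  expect_gte(total, 1000)
})

test_that("single model with k = C reduces to that model's argmax", {
  bank <- random_bank(40, 4, 1, seed = 21)
  res <- fuse(bank, k = 4)
  argmax <- bank$class_labels[apply(bank$matrices[[1]], 1, which.max)]
  expect_identical(res$fused_label, argmax)
})

test_that("literal CCFS variant lets improbable classes win (the audit case)", {
  # with M = 1 and k = C the literal FDS = R(x) * x is minimized away from
  # the argmax; the complement variant picks the argmax. This asymmetry is
  # why complement is the default.
  mk <- matrix(c(0.05, 0.60, 0.35), 1, dimnames = list("s1", c("a", "b", "c")))
  bank <- score_set(list(mk))
  expect_identical(fuse(bank, k = 3, variant = "complement")$fused_label, "b")
  expect_identical(fuse(bank, k = 3, variant = "literal")$fused_label, "a")
})
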