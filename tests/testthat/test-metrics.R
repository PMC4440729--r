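test_that("tolerant match handles the canonical 3-member cases", {
  truth <- gcff_groups(list(c("a", "b", "c")))
  det <- gcff_groups(list(c("a", "b", "d")), singletons = "c")
  # T = 2/3: two of three members found, one false subject allowed
  m <- tolerant_match(det, truth, T = 2 / 3)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  # T = 1: all and only the members must be detected
  m1 <- tolerant_match(det, truth, T = 1)
  expect_equal(m1$tp, 0L)
  expect_equal(m1$fp, 1L)
  expect_equal(m1$fn, 1L)
})

test_that("perfect detection matches every truth group at any tolerance", {
  g <- gcff_groups(list(c("a", "b"), c("c", "d", "e")), singletons = "f")
  for (T in c(1 / 2, 2 / 3, 5 / 6, 1)) {
    m <- tolerant_match(g, g, T)
    expect_equal(m$tp, 2L)
    expect_equal(m$fp, 0L)
    expect_equal(m$fn, 0L)
  }
})

test_that("tolerance is validated and T = 1 means exact set equality", {
  g <- gcff_groups(list(c("a", "b")))
  expect_error(tolerant_match(g, g, T = 0.4), "1/2")
  expect_error(tolerant_match(g, g, T = 1.01), "1/2")
  truth <- gcff_groups(list(c("a", "b", "c", "d")))
  almost <- gcff_groups(list(c("a", "b", "c")), singletons = "d")
  expect_equal(tolerant_match(almost, truth, 1)$tp, 0L)
  expect_equal(tolerant_match(truth, truth, 1)$tp, 1L)
})

test_that("matching counts satisfy the partition identities", {
  set.seed(14)
  params <- gcff_params(stride_D = 30, sigma = 80)
  batch <- generate_batch(reps = 2, seed = 5)
  for (sc in batch[1:6]) {
    noisy <- add_noise(sc, noise_spec(4, seed = 99))
    det <- gcff_detect(noisy, params)$groups
    tru <- scene_truth(sc)
    for (T in c(1 / 2, 2 / 3, 1)) {
      m <- tolerant_match(det, tru, T)
      expect_equal(m$tp + m$fn, length(tru$groups))
      expect_equal(m$tp + m$fp, length(det$groups))
      # one-to-one: no truth or detected group used twice
      mt <- vapply(m$matched_pairs, `[`, 0, 1L)
      md <- vapply(m$matched_pairs, `[`, 0, 2L)
      expect_false(anyDuplicated(mt) > 0)
      expect_false(anyDuplicated(md) > 0)
    }
  }
})

test_that("a looser tolerance never destroys a match (monotonicity in T)", {
  set.seed(15)
  params <- gcff_params(stride_D = 30, sigma = 80)
  batch <- generate_batch(reps = 2, seed = 8)
  grid <- c(1 / 2, 2 / 3, 5 / 6, 1)
  for (sc in batch[seq(1, 20, by = 3)]) {
    noisy <- add_noise(sc, noise_spec(3, seed = 7))
    det <- gcff_detect(noisy, params)$groups
    tru <- scene_truth(sc)
    tps <- vapply(grid, function(T) tolerant_match(det, tru, T)$tp, 1L)
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("precision/recall/F1 follow the stated conventions", {
  expect_equal(unname(precision_recall_f1(list(tp = 1, fp = 0, fn = 0))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(list(tp = 1, fp = 1, fn = 0))),
               c(0.5, 1, 2 / 3))
  # vacuous empty frame scores perfect
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 0, fn = 0))),
               c(1, 1, 1))
  # total failure scores zero F1
  expect_equal(precision_recall_f1(list(tp = 0, fp = 2, fn = 3))[["f1"]], 0)
  # all scores within [0, 1] on random counts
  set.seed(3)
  for (rep in 1:20) {
    cnt <- as.list(stats::setNames(sample(0:5, 3, TRUE),
                                   c("tp", "fp", "fn")))
    prf <- precision_recall_f1(cnt)
    expect_true(all(prf >= 0 & prf <= 1))
  }
})

test_that("swapping detected and truth swaps FP and FN at equal cardinality", {
  a <- gcff_groups(list(c("a", "b"), c("c", "d")))
  b <- gcff_groups(list(c("a", "b"), c("e", "f")))
  m_ab <- tolerant_match(a, b, 1)
  m_ba <- tolerant_match(b, a, 1)
  expect_equal(m_ab$fp, m_ba$fn)
  expect_equal(m_ab$fn, m_ba$fp)
  expect_equal(m_ab$tp, m_ba$tp)
})

test_that("GTM is the normalised AUC of F1 over the tolerance grid", {
  g <- list(gcff_groups(list(c("a", "b"), c("c", "d", "e"))))
  # identical detected/truth: F1 constant at 1 -> GTM = 1
  expect_equal(gtm(g, g), 1)
  # nothing detected: F1 constant at 0 -> GTM = 0
  none <- list(gcff_groups(singletons = c("a", "b", "c", "d", "e")))
  expect_equal(gtm(none, g), 0)
  # hand trapezoid: F1 = (1, 1, 0, 0) over the grid gives 0.5
  f1s <- c(1, 1, 0, 0)
  grid <- c(1 / 2, 2 / 3, 5 / 6, 1)
  auc <- sum(diff(grid) * (head(f1s, -1) + tail(f1s, -1)) / 2) / 0.5
  expect_equal(auc, 0.5)
  # a detection that is tolerant-correct but not exact reproduces that
  # profile: 2 of 3 members found, membership correct only for T <= 2/3
  truth <- list(gcff_groups(list(c("a", "b", "c"))))
  approx <- list(gcff_groups(list(c("a", "b", "d")), singletons = "c"))
  expect_equal(gtm(approx, truth), 0.5)
})

test_that("cardinality-stratified F1 recounts the global matching per size", {
  truth <- list(gcff_groups(list(c("a", "b", "c"), c("d", "e"))))
  det <- list(gcff_groups(list(c("a", "b", "c")),
                          singletons = c("d", "e")))
  expect_equal(cardinality_f1(det, truth, k = 3, T = 1)[["f1"]], 1)
  expect_equal(cardinality_f1(det, truth, k = 2, T = 1)[["f1"]], 0)
  s <- cardinality_f1_summary(det, truth, T = 1)
  expect_equal(s$by_k$k, c(2L, 3L))
  expect_equal(s$mean, 0.5)

  # independent per-stratum recount on a mixed synthetic batch
  set.seed(6)
  params <- gcff_params(stride_D = 30, sigma = 80)
  batch <- generate_batch(reps = 1, seed = 44)
  detected <- lapply(batch, function(sc) {
    gcff_detect(add_noise(sc, noise_spec(3, seed = 5)), params)$groups
  })
  truths <- lapply(batch, scene_truth)
  for (k in c(2, 3)) {
    direct <- cardinality_f1(detected, truths, k, T = 2 / 3)
    # recount: per frame, matched pairs restricted to truth size k
    tp <- fn <- fp <- 0
    for (i in seq_along(batch)) {
      m <- tolerant_match(detected[[i]], truths[[i]], 2 / 3)
      tsz <- vapply(truths[[i]]$groups, length, 1L)
      dsz <- vapply(detected[[i]]$groups, length, 1L)
      mt <- vapply(m$matched_pairs, `[`, 0, 1L)
      md <- vapply(m$matched_pairs, `[`, 0, 2L)
      tp <- tp + sum(tsz[mt] == k)
      fn <- fn + sum(tsz == k) - sum(tsz[mt] == k)
      fp <- fp + sum(dsz == k) - sum(dsz[md] == k)
    }
    manual <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
    expect_equal(direct[["f1"]], manual[["f1"]])
  }
})

test_that("micro-averaged evaluation sums counts across frames", {
  f1 <- gcff_groups(list(c("a", "b")))
  f2 <- gcff_groups(list(c("c", "d")), singletons = "e")
  empty <- gcff_groups(singletons = c("x", "y"))
  res <- evaluate_frames(list(f1, empty), list(f1, empty), T = 1)
  expect_equal(unname(res[c("precision", "recall", "f1")]), c(1, 1, 1))
  miss <- evaluate_frames(list(f1, gcff_groups(singletons = c("c", "d", "e"))),
                          list(f1, f2), T = 1)
  expect_equal(miss[["tp"]], 1)
  expect_equal(miss[["fn"]], 1)
  expect_equal(miss[["recall"]], 0.5)
})
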