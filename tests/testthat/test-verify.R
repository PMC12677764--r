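test_that("identical results score zero and match", {
  m <- matrix(runif(303), ncol = 3)
  p <- compare_results(fake_run("a", m), fake_run("b", m))
  expect_identical(p$status, "compared")
  expect_identical(p$score, 0)
  expect_true(p$matched)
})

test_that("a uniform 2e-4 relative offset scores about 2 when range-atol vanishes", {
  set.seed(1)
  a <- matrix(runif(202, 1, 10), ncol = 2)
  b <- a * (1 + 2e-4)
  cfg <- comparison_config(rtol = 1e-4, range_atol_scale = 1e-12)
  p <- compare_results(fake_run("a", a), fake_run("b", b), cfg)
  # hand-derivation: r = 2e-4 |a| / (1e-4 |a| (1 + 2e-4)) ~ 2
  expect_equal(p$score, 2 / (1 + 2e-4), tolerance = 1e-6)
  expect_false(p$matched)
})

test_that("shape or label mismatches and failures make pairs incomparable", {
  a <- fake_run("a", matrix(1:202, ncol = 2))
  b51 <- fake_run("b", matrix(1:102, ncol = 2))
  expect_identical(compare_results(a, b51)$status, "incomparable")
  relabeled <- fake_run("b", matrix(1:202, ncol = 2), labels = c("u", "v"))
  expect_identical(compare_results(a, relabeled)$status, "incomparable")
  failed <- fake_run("b", matrix(1:202, ncol = 2), status = "failed_numeric")
  expect_identical(compare_results(a, failed)$status, "incomparable")
  naval <- matrix(1:202, ncol = 2); naval[5, 1] <- NaN
  expect_identical(compare_results(a, fake_run("b", naval))$status,
                   "incomparable")
  expect_false(compare_results(a, failed)$matched)
})

test_that("the comparison is symmetric and scale-covariant", {
  set.seed(7)
  for (i in 1:50) {
    a <- matrix(rnorm(60, sd = 10^runif(1, -3, 3)), ncol = 3)
    b <- a + matrix(rnorm(60, sd = 10^runif(1, -6, 0)), ncol = 3)
    p1 <- compare_results(fake_run("a", a), fake_run("b", b))
    p2 <- compare_results(fake_run("b", b), fake_run("a", a))
    expect_identical(p1$score, p2$score)
    expect_identical(p1$matched, p2$matched)
    c <- 10^runif(1, -4, 4)
    p3 <- compare_results(fake_run("a", c * a), fake_run("b", c * b))
    expect_equal(p3$score, p1$score, tolerance = 1e-6)
  }
})

test_that("growing the element-wise deviation never decreases the score", {
  set.seed(11)
  a <- matrix(runif(50, 1, 5), ncol = 1)
  d <- abs(rnorm(50, sd = 0.01))
  prev <- -Inf
  for (scale in c(0.5, 1, 2, 5)) {
    p <- compare_results(fake_run("a", a), fake_run("b", a + scale * d))
    expect_gte(p$score, prev)
    prev <- p$score
  }
})

test_that("agreement size equals brute-force maximum clique on random graphs", {
  brute_clique <- function(n, edges) {
    best <- if (n >= 1) 1L else 0L
    for (size in 2:max(2, n)) {
      if (size > n) break
      for (cs in utils::combn(n, size, simplify = FALSE)) {
        prs <- utils::combn(cs, 2, simplify = FALSE)
        if (all(vapply(prs, function(p)
          any(vapply(edges, function(e) setequal(e, p), TRUE)), TRUE)))
          best <- max(best, size)
      }
    }
    best
  }
  set.seed(5)
  for (trial in 1:30) {
    n <- sample(2:6, 1)
    all_pairs <- utils::combn(n, 2, simplify = FALSE)
    edges <- all_pairs[runif(length(all_pairs)) < 0.5]
    engines <- paste0("e", seq_len(n))
    got <- sedverify:::max_agreement(
      engines, lapply(edges, function(e) engines[e]))
    expect_identical(got, brute_clique(n, edges))
  }
})

test_that("aggregation counts pairs, matches and agreement per the pairwise law", {
  m <- matrix(runif(101), ncol = 1)
  runs5 <- lapply(paste0("e", 1:5), fake_run, values = m)
  v <- aggregate_runs("m1", "template", runs5)
  expect_length(v$pairs, 10L)          # C(5,2)
  expect_identical(v$n_matched, 10L)
  expect_identical(v$agreement_size, 5L)
  expect_true(v$verified)
  expect_identical(v$level, "functional")

  v1 <- aggregate_runs("m2", "template", list(fake_run("e1", m)))
  expect_length(v1$pairs, 0L)
  expect_false(v1$verified)
  expect_identical(v1$level, "unverified")

  # matches exactly {(A,B),(B,C)} among three succeeded -> agreement 2
  base <- matrix(rep(100, 101), ncol = 1)
  rA <- fake_run("A", base)
  rB <- fake_run("B", base + 0.007)
  rC <- fake_run("C", base + 0.014)
  v3 <- aggregate_runs("m3", "curation", list(rA, rB, rC))
  matched_pairs <- vapply(Filter(function(p) p$matched, v3$pairs),
                          function(p) paste(sort(c(p$engine_a, p$engine_b)),
                                            collapse = "-"), "")
  expect_setequal(matched_pairs, c("A-B", "B-C"))
  expect_identical(v3$agreement_size, 2L)
  expect_identical(v3$level, "end_to_end")

  expect_error(aggregate_runs("m", "template",
                              list(fake_run("e1", m), fake_run("e1", m))),
               "duplicate engine")
})

test_that("classification distinguishes functional from end-to-end reproducibility", {
  mk <- function(prov, verified)
    structure(list(provenance = prov, verified = verified),
              class = "model_verification")
  expect_identical(classify_level(mk("template", TRUE)), "functional")
  expect_identical(classify_level(mk("curation", TRUE)), "end_to_end")
  expect_identical(classify_level(mk("unknown", TRUE)), "functional")
  expect_identical(classify_level(mk("curation", FALSE)), "unverified")
})

test_that("corpus summaries tally histograms and totals consistently", {
  empty <- summarize_corpus(list())
  expect_identical(empty$n_models, 0L)
  expect_identical(sum(empty$histogram), 0L)

  m <- matrix(runif(11), ncol = 1)
  v_full <- aggregate_runs("a", "template", lapply(paste0("e", 1:5),
                                                   fake_run, values = m))
  v_one <- aggregate_runs("b", "template", list(fake_run("e1", m)))
  v_none <- aggregate_runs("c", "template",
                           list(fake_run("e1", m, status = "failed_numeric")))
  s <- summarize_corpus(list(v_full, v_one, v_none))
  expect_identical(s$histogram["5", "5"], 1L)
  expect_identical(s$histogram["1", "1"], 1L)
  expect_identical(s$histogram["0", "0"], 1L)
  expect_identical(sum(s$histogram), 3L)
  expect_identical(s$totals$pairs_compared, 10L)
  expect_identical(s$per_level[["functional"]], 1L)
  expect_identical(s$per_level[["unverified"]], 2L)
  # pairs compared = sum of C(S_i, 2)
  expect_identical(s$totals$pairs_compared,
                   as.integer(sum(choose(c(5, 1, 0), 2))))
})
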