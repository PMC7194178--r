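# Overlap analysis: intersections, analytic hypergeometric tail, bootstrap.

test_that("intersection counts cover every combination with inclusive semantics", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  ci <- compute_intersections(sets)
  expect_equal(ci$combos$observed, 1L)
  four <- list(A = "g1", B = "g2", C = "g3", D = "g4")
  expect_equal(nrow(compute_intersections(four)$combos), 11L)  # 6 + 4 + 1
  expect_true(all(compute_intersections(four)$combos$observed == 0L))
})

test_that("intersection counts are symmetric under permutation of the sets", {
  set.seed(4)
  sets <- lapply(setNames(1:3, c("A", "B", "C")), function(i)
    sample(sprintf("g%02d", 1:30), 15))
  a <- compute_intersections(sets)$combos
  b <- compute_intersections(rev(sets))$combos
  for (i in seq_len(nrow(a))) {
    m <- sort(parse_combo(a$combination[i]))
    j <- which(vapply(b$combination, function(x)
      identical(sort(parse_combo(x)), m), logical(1L)))
    expect_equal(a$observed[i], b$observed[j])
  }
})

test_that("inclusive and exclusive conventions differ as expected", {
  sets <- list(A = c("g1", "g2"), B = c("g1", "g2", "g3"),
               C = c("g1", "g4"))
  incl <- compute_intersections(sets)$combos
  excl <- compute_intersections(sets, exclusive = TRUE)$combos
  expect_equal(incl[combination == "A:B", observed], 2L)
  expect_equal(excl[combination == "A:B", observed], 1L)  # g1 is in C too
  expect_equal(excl[combination == "A:B:C", observed], 1L)
})

test_that("analytic hypergeometric tail matches closed forms", {
  expect_equal(hypergeom_overlap_p(2, 2, 4, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(5, 5, 10, 5), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(7, 9, 50, 0), 1)
  expect_error(hypergeom_overlap_p(2, 2, 4, 3), "impossible")
  expect_error(hypergeom_overlap_p(8, 2, 4, 1), "exceed")
})

test_that("the tail probability grows as the background shrinks", {
  # same sizes and observed overlap, denser nulls in a smaller background
  p_small <- hypergeom_overlap_p(10, 10, 50, 4)
  p_big <- hypergeom_overlap_p(10, 10, 500, 4)
  expect_gt(p_small, p_big)
  for (N in c(60, 120, 240, 480)) {
    expect_gte(hypergeom_overlap_p(10, 10, N, 3),
               hypergeom_overlap_p(10, 10, N * 2, 3))
  }
})

test_that("bootstrap overlap is seeded, bounded and uses the add-one estimator", {
  bg <- sprintf("g%02d", 1:20)
  r1 <- bootstrap_overlap(c(A = 5L, B = 5L), bg, observed = 2L,
                          n_boot = 500L, seed = 3)
  r2 <- bootstrap_overlap(c(A = 5L, B = 5L), bg, observed = 2L,
                          n_boot = 500L, seed = 3)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_length(r1$null_counts, 500L)
  expect_equal(r1$empirical_p,
               (1 + sum(r1$null_counts >= 2L)) / 501)
  # observed 0 can never beat the null
  r0 <- bootstrap_overlap(c(A = 5L, B = 5L), bg, observed = 0L,
                          n_boot = 100L, seed = 3)
  expect_equal(r0$empirical_p, 1)
  expect_error(bootstrap_overlap(c(A = 30L, B = 5L), bg, 1L, 10L, 1),
               "exceeds background")
  # stream is derived from the combination label: order does not matter
  r3 <- bootstrap_overlap(c(B = 5L, A = 5L), bg, observed = 2L,
                          n_boot = 500L, seed = 3)
  expect_identical(sort(r1$null_counts), sort(r3$null_counts))
})

test_that("pairwise bootstrap agrees with the analytic tail", {
  set.seed(21)
  for (i in 1:6) {
    N <- sample(20:80, 1L)
    n1 <- sample.int(N %/% 2L, 1L); n2 <- sample.int(N %/% 2L, 1L)
    obs <- stats::rhyper(1L, n1, N - n1, n2)
    p <- hypergeom_overlap_p(n1, n2, N, obs)
    r <- bootstrap_overlap(c(A = n1, B = n2), sprintf("g%03d", 1:N),
                           obs, n_boot = 4000L, seed = i)
    tol <- 3 * sqrt(p * (1 - p) / 4000) + 1 / 4001
    expect_lt(abs(r$empirical_p - p), tol + 1e-12)
  }
})

test_that("planted enrichment is detected at the prescribed strength", {
  # observed overlap three times the hypergeometric expectation
  N <- 500L; bg <- sprintf("g%03d", seq_len(N))
  sizes <- c(A = 60L, B = 60L)
  expectation <- 60 * 60 / 500   # 7.2
  observed <- 22L                # >= 3x expectation
  r <- bootstrap_overlap(sizes, bg, observed, n_boot = 10000L, seed = 5)
  expect_lt(r$empirical_p, 0.01)
})

test_that("dual-background evaluation flags verdict changes and checks subsets", {
  set.seed(8)
  bg_big <- sprintf("g%03d", 1:400)
  bg_small <- sprintf("g%03d", 1:120)
  shared <- sample(bg_small, 12)
  sets <- list(A = unique(c(shared, sample(bg_small, 40))),
               B = unique(c(shared, sample(bg_small, 40))),
               C = sample(bg_small, 30),
               D = sample(bg_small, 25))
  res <- run_both_backgrounds(sets,
                              list(all = bg_big, spatial = bg_small),
                              n_boot = 400L, seed = 9)
  expect_equal(nrow(res$table), 22L)   # 11 combinations x 2 backgrounds
  expect_true(all(res$table$empirical_p > 0 & res$table$empirical_p <= 1))
  # analytic p present exactly for pairwise rows
  expect_true(all(is.na(res$table[k > 2, analytic_p])))
  expect_true(all(!is.na(res$table[k == 2, analytic_p])))
  # identical backgrounds give identical results under the same seed
  res2 <- run_both_backgrounds(sets, list(x = bg_small, y = bg_small),
                               n_boot = 200L, seed = 4)
  expect_equal(res2$table[background == "x", empirical_p],
               res2$table[background == "y", empirical_p])
  # sets must be subsets of every background
  sets_bad <- sets; sets_bad$A <- c(sets_bad$A, "not_a_gene")
  expect_error(run_both_backgrounds(sets_bad, list(b = bg_big), 10L, 1),
               "missing from background")
})
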