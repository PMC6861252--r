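test_that("complete deletion keeps exactly the gap-free columns", {
  M <- rbind(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  expect_identical(complete_deletion(M), rep(TRUE, 4))
  M[1, 2] <- "-"
  expect_identical(complete_deletion(M), c(TRUE, FALSE, TRUE, TRUE))
  M[1, ] <- "N"
  expect_warning(mask <- complete_deletion(M[1, , drop = FALSE]), "every column")
  expect_false(any(mask))
  expect_error(complete_deletion(matrix(character(0), 0, 0)), "empty")
})

test_that("polymorphism summaries match hand-computed toys", {
  a <- make_aln(c(s1 = strrep("A", 100), s2 = strrep("A", 100)), c("X", "X"))
  s <- summarize_polymorphism(a)
  expect_identical(s$S, 0L)
  expect_equal(s$pi, 0)
  expect_identical(s$h, 1L)

  b <- make_aln(c(s1 = paste0(strrep("A", 99), "C"), s2 = strrep("A", 100)), c("X", "X"))
  s <- summarize_polymorphism(b)
  expect_equal(s$pi, 0.01)
  expect_identical(s$S, 1L)
  expect_identical(s$singletons, 1L)   # one singleton site, counting convention
  expect_identical(s$h, 2L)

  expect_error(summarize_polymorphism(a, group = "s1"), "at least two")
})

test_that("summary statistics match brute-force oracles on random alignments", {
  set.seed(202)
  for (rep in 1:5) {
    M <- random_alignment(5, 200)
    aln <- make_aln(setNames(apply(M, 1, paste, collapse = ""), rownames(M)),
                    rep("X", 5))
    s <- summarize_polymorphism(aln)
    o <- oracle_site_table(M)
    expect_equal(s$pi, oracle_pi(M))
    expect_identical(s$S, o$S)
    expect_identical(s$singletons, o$singletons)
    expect_identical(s$multihit, o$multihit)
    expect_identical(s$h, oracle_h(M))
  }
})

test_that("statistics are invariant to sequence order", {
  set.seed(7)
  M <- random_alignment(6, 150)
  strings <- setNames(apply(M, 1, paste, collapse = ""), rownames(M))
  a1 <- make_aln(strings, rep("X", 6))
  perm <- sample(names(strings))
  a2 <- make_aln(strings[perm], rep("X", 6))
  s1 <- summarize_polymorphism(a1); s2 <- summarize_polymorphism(a2)
  expect_equal(s1$pi, s2$pi)
  expect_identical(s1[c("S", "singletons", "multihit", "h")],
                   s2[c("S", "singletons", "multihit", "h")])
})

test_that("divergence uses outgroup-aware deletion and the exact correction", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.09), 0.09587503, tolerance = 1e-7)
  expect_error(jc_correct(0.75), "saturates")
  expect_error(jc_correct(-0.1), "non-negative")

  aln <- make_aln(
    c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", og = "AAAAAAAATT"),
    c("X", "X", NA), outgroup = c(FALSE, FALSE, TRUE))
  s <- summarize_polymorphism(aln)
  expect_equal(s$K, jc_correct(0.2))
  # gaps in the outgroup shrink only the divergence site set
  aln2 <- make_aln(
    c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", og = "-AAAAAAATT"),
    c("X", "X", NA), outgroup = c(FALSE, FALSE, TRUE))
  s2 <- summarize_polymorphism(aln2)
  expect_identical(s2$sites_used, 10L)
  expect_identical(s2$sites_K, 9L)
  expect_equal(s2$K, jc_correct(2 / 9))
})

test_that("Hudson F_ST matches brute force and handles degenerate groups", {
  toy <- make_aln(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAT",
                    b1 = "CCCCCAAAAA", b2 = "CCCCCAAAAT"),
                  c("X", "X", "Y", "Y"))
  expect_equal(fst_hudson(toy, "X", "Y"), 1 - 0.1 / 0.55)
  expect_equal(fst_hudson(toy, c("a1", "a2"), c("b1", "b2")), 0.81818, tolerance = 1e-4)

  # fixed difference, no within-group variation
  fix <- make_aln(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT", b2 = "TTTT"),
                  c("X", "X", "Y", "Y"))
  expect_equal(fst_hudson(fix, "X", "Y"), 1)

  # identical pools carry no variation to apportion
  same <- make_aln(c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA"),
                   c("X", "X", "Y", "Y"))
  expect_error(fst_hudson(same, "X", "Y"), "undefined")
  expect_error(fst_hudson(toy, c("a1"), c("b1", "b2")), "at least two")

  set.seed(31)
  M <- random_alignment(8, 120)
  aln <- make_aln(setNames(apply(M, 1, paste, collapse = ""), rownames(M)),
                  rep(c("P", "Q"), each = 4))
  expect_equal(fst_hudson(aln, "P", "Q"), oracle_fst(M, 1:4, 5:8))
})

test_that("the permutation test matches exhaustive enumeration and detects strong structure", {
  toy <- make_aln(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAT",
                    b1 = "CCCCCAAAAA", b2 = "CCCCCAAAAT"),
                  c("X", "X", "Y", "Y"))
  # with 2+2 sequences a random relabelling recreates the observed partition
  # with probability 1/3, which is the exhaustive p-value
  res <- fst_permutation_p(toy, "X", "Y", n_perm = 3000, seed = 1)
  expect_equal(res$p_value, 1 / 3, tolerance = 0.035)
  expect_equal(res$fst, 1 - 0.1 / 0.55)

  # larger strongly differentiated groups: recurrence is negligible
  big <- make_aln(setNames(c(replicate(6, paste0(strrep("A", 40),
                                                 paste(sample(c("A", "C"), 10, TRUE), collapse = ""))),
                             replicate(6, paste0(strrep("T", 40),
                                                 paste(sample(c("T", "G"), 10, TRUE), collapse = "")))),
                           paste0("s", 1:12)),
                  rep(c("X", "Y"), each = 6))
  res2 <- fst_permutation_p(big, "X", "Y", n_perm = 2000, seed = 2)
  expect_lt(res2$p_value, 0.01)

  expect_error(fst_permutation_p(toy, "X", "Y", n_perm = 0), "positive")
  # reproducible given the seed
  r1 <- fst_permutation_p(toy, "X", "Y", n_perm = 500, seed = 9)
  r2 <- fst_permutation_p(toy, "X", "Y", n_perm = 500, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("the F_ST matrix is symmetric and consistent with pairwise recomputation", {
  set.seed(12)
  ds <- simulate_alignment(sim_params(
    seq_length = 250, sample_sizes = c(AB = 4, AG = 3, GAL = 3, AK = 3, AH2 = 3),
    seed = 12))
  fm <- fst_matrix(ds$alignment, n_perm = 50, seed = 5)
  expect_true(isSymmetric(fm$fst))
  expect_true(all(is.na(diag(fm$fst))))
  expect_equal(fm$fst["AB", "AG"], fst_hudson(ds$alignment, "AB", "AG"))
  expect_equal(fm$fst["AK", "AH2"], fst_hudson(ds$alignment, "AK", "AH2"))
  expect_true(all(fm$p >= 0 & fm$p <= 1, na.rm = TRUE))

  two <- make_aln(c(a1 = "AAAT", a2 = "AAAA", b1 = "TTTA", b2 = "TTTT"),
                  c("X", "X", "Y", "Y"))
  fm2 <- fst_matrix(two, n_perm = 20, seed = 1)
  expect_identical(dim(fm2$fst), c(2L, 2L))
  one <- make_aln(c(a1 = "AAAT", a2 = "AAAA"), c("X", "X"))
  expect_error(fst_matrix(one, n_perm = 10), "two region groups")
})

test_that("pairwise deletion recovers per-pair comparable sites", {
  aln <- make_aln(c(s1 = "AA-A", s2 = "AATA", s3 = "CCTA"), c("X", "X", "X"))
  s <- summarize_polymorphism(aln, deletion = "pairwise")
  # complete deletion would use 3 sites; pairwise compares s1/s2 over 3
  sc <- summarize_polymorphism(aln)
  expect_identical(sc$sites_used, 3L)
  expect_equal(s$pi, mean(c(0 / 3, 2 / 3, 2 / 4)), tolerance = 1e-9)
})
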