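test_that("NG86 hand-counted example and degenerate cases", {
  # identical sequences: zero distances, omega undefined
  same <- ng86("TTTGGGAAA", "TTTGGGAAA")
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_false(same$valid)
  expect_true(is.na(same$omega))

  # Phe TTT -> TTC is a single synonymous pathway
  est <- ng86("TTTGGGAAA", "TTCGGGAAA")
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$dN, 0)
  expect_gt(est$dS, 0)
  expect_equal(est$omega, 0)

  expect_error(ng86("TAAGGG", "TACGGG"), "stop")
  expect_error(ng86("---", "---"), "comparable")
})

test_that("NG86 is symmetric and conserves sites", {
  fam <- simulate_family(sim_config(2, 2, 150, seed = 19))
  a <- fam$aln$seq[1]
  b <- fam$aln$seq[2]
  expect_equal(ng86(a, b), ng86(b, a))
  est <- ng86(a, b)
  expect_equal(est$S + est$N, 3 * nchar(a) / 3)
})

test_that("pair sampling is exhaustive when small, distinct and seeded", {
  fam <- simulate_family(sim_config(3, 3, 60, n_old_dups_grass = 0, seed = 29))
  aln <- fam$aln
  two <- aln$gene_id[1:2]
  s2 <- sample_pair_omegas(aln, two, n_pairs = 50, seed = 1)
  expect_equal(nrow(s2), 1)

  six <- aln$gene_id[1:6]
  s6a <- sample_pair_omegas(aln, six, n_pairs = 10, seed = 4)
  s6b <- sample_pair_omegas(aln, six, n_pairs = 10, seed = 4)
  expect_identical(s6a, s6b)
  expect_equal(nrow(s6a), 10)
  keys <- paste(s6a$gene_a, s6a$gene_b)
  expect_equal(anyDuplicated(keys), 0L)
  all15 <- apply(t(combn(sort(six), 2)), 1, paste, collapse = " ")
  expect_true(all(keys %in% all15))

  expect_error(sample_pair_omegas(aln, aln$gene_id[1], 5), "at least 2")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  expect_error(compare_clades(1, 1), "at least 2")

  same <- compare_clades(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_false(same$significant)
  expect_equal(same$mean_difference, 0)

  shifted <- compare_clades(c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.3))
  expect_true(shifted$degenerate)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 1e-300)

  set.seed(7)
  d <- stats::rnorm(20, 0.05, 0.01)
  g <- stats::runif(20, 0.2, 0.4)
  cmp <- compare_clades(g, g - d)
  t_expected <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(cmp$t, t_expected, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_expected), 19), tolerance = 1e-12)
  # cross-check against the stock implementation
  ref <- stats::t.test(g, g - d, paired = TRUE)
  expect_equal(cmp$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("subfamily omega comparison flags a real clade rate difference", {
  fam <- simulate_family(sim_config(4, 4, 300,
    omega_grass = 0.05, omega_eudicot = 0.9,
    branch_length_range = c(0.1, 0.2), seed = 53
  ))
  prot <- translate_alignment(fam$aln)
  tr <- nj_tree(p_distance_matrix(prot))
  sf <- partition_subfamilies(tr, fam$clade_map, min_support = 0)
  cmp <- compare_subfamily_omegas(fam$aln, sf, n_pairs = 6, seed = 2)
  expect_equal(nrow(cmp), 1)
  expect_lt(cmp$mean_grass, cmp$mean_eudicot)
  expect_true(cmp$significant)
})
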