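test_that("GY94 rate matrix is a reversible, correctly scaled generator", {
  pi <- uniform_codon_freqs()
  Q <- gy94_rate_matrix(kappa = 2.5, omega = 0.3, pi = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji
  flux <- pi * Q
  expect_lt(max(abs(flux - t(flux))), 1e-15)
  # kappa = omega = 1, uniform pi: all single-change rates equal
  Q1 <- gy94_rate_matrix(1, 1, pi)
  off <- Q1[row(Q1) != col(Q1)]
  expect_equal(length(unique(round(off[off > 0], 12))), 1L)
  expect_error(gy94_rate_matrix(2, 0.5, rep(1, 61)), "pi")
})

test_that("F3x4 frequencies follow the position-product construction", {
  # arbitrary fixture: normalization to 1 within 1e-12
  codons <- sense_codons()
  aln <- tibble::tibble(gene_id = "all61", seq = paste(codons, collapse = ""))
  p_uni <- f3x4_frequencies(aln)
  expect_equal(sum(p_uni), 1, tolerance = 1e-12)
  # single observed codon: point mass
  aln_aaa <- tibble::tibble(gene_id = c("a", "b"), seq = c("AAAAAA", "AAAAAA"))
  p_aaa <- f3x4_frequencies(aln_aaa)
  expect_equal(unname(p_aaa["AAA"]), 1)
  expect_equal(sum(p_aaa), 1)
  # gap-only position errors
  expect_error(
    f3x4_frequencies(tibble::tibble(gene_id = "a", seq = "---")),
    "no observed"
  )
})

test_that("uniform base frequencies give every sense codon 1/61 via F3x4", {
  pos <- matrix(0.25, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
  p <- cladeshift:::pi_f3x4(pos)
  expect_equal(unname(p), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("pruning log-likelihood matches limit case and exhaustive sum", {
  pi <- uniform_codon_freqs()
  # identical sequences joined by zero-length branches: lnL = sum log pi
  aln <- tibble::tibble(gene_id = c("a", "b"), seq = c("ATGAAACCC", "ATGAAACCC"))
  tr <- ape::read.tree(text = "(a:0,b:0);")
  ll <- codon_loglik(aln, tr, kappa = 2, omega = 0.5, pi = pi)
  expect_equal(as.numeric(ll), 3 * log(1 / 61), tolerance = 1e-9)

  # 3-taxon exhaustive oracle
  fam <- simulate_family(sim_config(2, 2, 4, seed = 3))
  aln3 <- fam$aln[1:3, ]
  tr3 <- ape::read.tree(text = sprintf(
    "(%s:0.1,(%s:0.2,%s:0.3):0.15);",
    aln3$gene_id[1], aln3$gene_id[2], aln3$gene_id[3]
  ))
  ll3 <- codon_loglik(aln3, tr3, kappa = 2, omega = 0.4, pi = pi)
  bf3 <- brute_force_loglik(aln3, tr3, kappa = 2, omega = 0.4, pi = pi)
  expect_equal(as.numeric(ll3), bf3, tolerance = 1e-8)
})

test_that("likelihood is invariant to rerooting (pulley principle)", {
  fam <- simulate_family(sim_config(2, 2, 30, seed = 8))
  aln <- fam$aln
  tr <- fam$gene_tree
  ll1 <- codon_loglik(aln, tr, kappa = 2, omega = 0.3)
  tr2 <- phytools::reroot(ape::unroot(tr), ape::Ntip(tr) - 1, position = 0.02)
  ll2 <- codon_loglik(aln, tr2, kappa = 2, omega = 0.3)
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-8)
})

test_that("likelihood errors on leaf/alignment mismatch", {
  aln <- tibble::tibble(gene_id = c("a", "b"), seq = c("AAA", "AAA"))
  tr <- ape::read.tree(text = "(a:0.1,c:0.1);")
  expect_error(codon_loglik(aln, tr, 2, 0.5), "match")
})
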