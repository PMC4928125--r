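test_that("species trees split clades at the root with lengths in range", {
  # degenerate range forces every branch length
  tr <- simulate_species_tree(2, 2, c(0.1, 0.1), seed = 1)
  expect_equal(sort(tr$tip.label), c("e1", "e2", "g1", "g2"))
  expect_true(all(abs(tr$edge.length - 0.1) < 1e-12))
  kids <- tr$edge[tr$edge[, 1] == 5, 2]
  sides <- lapply(kids, function(k) {
    ape::extract.clade(tr, k)$tip.label
  })
  clades <- lapply(sides, function(s) unique(substr(s, 1, 1)))
  expect_setequal(unlist(clades), c("g", "e"))
  expect_true(all(lengths(clades) == 1))

  # seeded determinism
  t1 <- ape::write.tree(simulate_species_tree(4, 3, c(0.05, 0.3), seed = 9))
  t2 <- ape::write.tree(simulate_species_tree(4, 3, c(0.05, 0.3), seed = 9))
  expect_identical(t1, t2)

  # all drawn lengths inside the configured range
  tr2 <- simulate_species_tree(5, 7, c(0.05, 0.3), seed = 7)
  expect_equal(ape::Ntip(tr2), 12)
  expect_true(all(tr2$edge.length >= 0.05 & tr2$edge.length <= 0.3))

  expect_error(simulate_species_tree(1, 5), "at least 2")
})

test_that("single-branch evolution matches the substitution process", {
  s <- paste(rep("ATGAAACCCGGG", 5), collapse = "")
  expect_identical(evolve_codon_sequence(s, 0, 2, 0.5), s)
  a1 <- evolve_codon_sequence(s, 0.4, 2, 0.5, seed = 11)
  a2 <- evolve_codon_sequence(s, 0.4, 2, 0.5, seed = 11)
  expect_identical(a1, a2)
  expect_error(evolve_codon_sequence("TAAATG", 0.1, 2, 0.5), "stop")

  # proportion of changed codon sites vs matrix-exponential expectation
  pi <- uniform_codon_freqs()
  n <- 10000
  set.seed(5)
  codons <- sense_codons()
  root_idx <- sample.int(61, n, replace = TRUE)
  root <- paste0(codons[root_idx], collapse = "")
  child <- evolve_codon_sequence(root, 0.5, 1, 1, pi = pi, seed = 6)
  child_cod <- substring(child, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
  p_changed <- mean(child_cod != codons[root_idx])
  P <- as.matrix(Matrix::expm(gy94_rate_matrix(1, 1, pi) * 0.5))
  expected <- 1 - sum(pi * diag(P))
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p_changed - expected), 3 * mc_se)
})

test_that("long-branch simulation stays at the stationary distribution", {
  pi <- uniform_codon_freqs()
  n <- 6000
  codons <- sense_codons()
  set.seed(2)
  root <- paste0(codons[sample.int(61, n, TRUE, prob = pi)], collapse = "")
  child <- evolve_codon_sequence(root, 3, 2, 0.5, pi = pi, seed = 3)
  freq <- table(factor(
    substring(child, seq(1, 3 * n, 3), seq(3, 3 * n, 3)),
    levels = codons
  )) / n
  # each frequency within 4 binomial SEs of its stationary value
  se <- sqrt(pi * (1 - pi) / n)
  expect_true(all(abs(as.numeric(freq) - pi) < 4 * se + 1e-9))
})

test_that("simulated families honour the event bookkeeping contract", {
  fam <- simulate_family(sim_config(3, 3, 60, n_recent_dups = 1, seed = 4))
  expect_equal(fam$truth$events$kind, "recent_dup")

  fam2 <- simulate_family(sim_config(3, 3, 60, n_old_dups_grass = 1, seed = 5))
  sf <- fam2$subfamilies |>
    dplyr::left_join(fam2$clade_map, by = "gene_id") |>
    dplyr::filter(.data$clade == "grass")
  sets <- split(sf$species, sf$subfamily)
  expect_length(sets, 2)
  for (s in sets) expect_setequal(s, c("g1", "g2", "g3"))

  expect_error(
    sim_config(2, 2, 60, n_recent_losses = 10),
    "losses"
  )
  expect_error(sim_config(2, 2, 60, omega_grass = -1), "omega")
})

test_that("truth-log closure holds: copies = 1 + dups - losses per species", {
  for (seed in 1:5) {
    cfg <- sim_config(4, 3, 30,
      n_old_dups_grass = seed %% 3, n_old_dups_eudicot = seed %% 2,
      n_recent_dups = seed %% 4, n_recent_losses = seed %% 2, seed = seed
    )
    fam <- simulate_family(cfg)
    ev <- fam$truth$events
    for (sp in unique(fam$clade_map$species)) {
      clade <- fam$clade_map$clade[match(sp, fam$clade_map$species)]
      expected <- 1 +
        sum(ev$kind == "old_dup" & ev$clade == clade) +
        sum(ev$kind == "recent_dup" & ev$species == sp, na.rm = TRUE) -
        sum(ev$kind == "recent_loss" & ev$species == sp, na.rm = TRUE)
      got <- sum(fam$clade_map$species == sp)
      expect_equal(got, expected, info = paste("seed", seed, "species", sp))
    }
  }
})

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(3, 3, 40, n_recent_dups = 1, seed = 77)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_sim_family(simulate_family(cfg), d1)
  write_sim_family(simulate_family(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
})
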