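test_that("p-distances use pairwise deletion and flag undefined pairs", {
  aln <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    seq = c("AAAA", "AAAT", "AA-A", "AATA")
  )
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["c", "d"], 0) # gapped column dropped pairwise
  expect_equal(d, t(d))
  # no comparable columns -> NA
  d2 <- p_distance_matrix(tibble::tibble(
    gene_id = c("a", "b"), seq = c("A---", "-AAA")
  ))
  expect_true(is.na(d2["a", "b"]))
  expect_error(
    p_distance_matrix(tibble::tibble(gene_id = c("a", "b"), seq = c("AA", "AAA"))),
    "equal"
  )
})

test_that("neighbor joining recovers closed forms and additive trees", {
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.05, 0.15, 0.25))

  # additive distances from a known 4-taxon tree are reproduced exactly
  true_tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.07);")
  d4 <- cophenetic(true_tr)[letters[1:4], letters[1:4]]
  nj4 <- nj_tree(d4)
  expect_equal(max(abs(cophenetic(nj4)[letters[1:4], letters[1:4]] - d4)), 0,
    tolerance = 1e-10
  )
  expect_equal(ape::dist.topo(ape::unroot(true_tr), nj4), setNames(0, "PH85"),
    ignore_attr = TRUE
  )

  # equal distances: tie-break joins the lowest index pair, stably
  de <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  t1 <- ape::write.tree(nj_tree(de))
  t2 <- ape::write.tree(nj_tree(de))
  expect_identical(t1, t2)

  dna <- d
  dna[1, 2] <- dna[2, 1] <- NA
  expect_error(nj_tree(dna), "a and b")
})

test_that("neighbor joining agrees with the reference implementation", {
  set.seed(42)
  for (n in c(5, 7)) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    d <- cophenetic(tr)
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(mine, ref), setNames(0, "PH85"),
      ignore_attr = TRUE
    )
  }
})

test_that("bootstrap support separates clear clusters and is seeded", {
  fam <- simulate_family(sim_config(3, 3, 120,
    branch_length_range = c(0.05, 0.1), seed = 31
  ))
  prot <- translate_alignment(fam$aln)
  tr1 <- bootstrap_support(prot, n_reps = 100, seed = 5)
  tr2 <- bootstrap_support(prot, n_reps = 100, seed = 5)
  expect_identical(
    attr(tr1, "split_support"),
    attr(tr2, "split_support")
  )
  # the grass/eudicot split (long stem) gets high support
  cm <- fam$clade_map
  grass <- sort(cm$gene_id[cm$clade == "grass"])
  key_of <- function(tr, side) {
    other <- sort(setdiff(tr$tip.label, side))
    a <- paste(sort(side), collapse = ",")
    b <- paste(other, collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }
  supp <- attr(tr1, "split_support")
  expect_gte(supp[[key_of(tr1, grass)]], 95)

  # identical sequences: unresolved, all supports zero
  same <- tibble::tibble(gene_id = letters[1:4], seq = rep("AAAAAAA", 4))
  tr0 <- bootstrap_support(same, n_reps = 10, seed = 1)
  expect_true(isTRUE(attr(tr0, "unresolved")))
  expect_true(all(as.numeric(tr0$node.label) == 0))
  expect_error(bootstrap_support(prot, n_reps = 0), "n_reps")
})

test_that("bootstrap supports are invariant to leaf order", {
  fam <- simulate_family(sim_config(2, 3, 80, seed = 17))
  prot <- translate_alignment(fam$aln)
  s1 <- attr(bootstrap_support(prot, n_reps = 50, seed = 3), "split_support")
  s2 <- attr(
    bootstrap_support(prot[rev(seq_len(nrow(prot))), ], n_reps = 50, seed = 3),
    "split_support"
  )
  expect_setequal(names(s1), names(s2))
  # same columns are resampled given the seed, so supports agree exactly
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("subfamily partition matches the documented examples", {
  # g1..g4 are two gene copies in each of two grass species (a stem
  # duplication), e1/e2 single copies in two eudicot species
  cm <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "e1", "e2"),
    species = c("s1", "s2", "s1", "s2", "t1", "t2"),
    clade = c(rep("grass", 4), rep("eudicot", 2))
  )
  tr <- ape::read.tree(text = "((g1:0.1,g2:0.1):0.2,(e1:0.1,e2:0.1):0.2);")
  sf <- partition_subfamilies(tr, cm[c(1, 2, 5, 6), ], min_support = 50)
  expect_equal(length(unique(sf$subfamily_id)), 2)
  wide <- sf |> dplyr::distinct(.data$subfamily_id, .data$clade, .data$partners)
  expect_equal(
    wide$partners[wide$clade == "grass"],
    wide$subfamily_id[wide$clade == "eudicot"]
  )

  # two grass subfamilies both pair with the single eudicot subfamily
  tr2 <- ape::read.tree(
    text = "(((g1:0.1,g2:0.1):0.3,(g3:0.1,g4:0.1):0.3):0.2,(e1:0.1,e2:0.1):0.4);"
  )
  sf2 <- partition_subfamilies(tr2, cm, min_support = 50)
  counts <- sf2 |>
    dplyr::distinct(.data$subfamily_id, .data$clade) |>
    dplyr::count(.data$clade)
  expect_equal(counts$n[counts$clade == "grass"], 2)
  expect_equal(counts$n[counts$clade == "eudicot"], 1)
  e_id <- unique(sf2$subfamily_id[sf2$clade == "eudicot"])
  for (p in sf2$partners[sf2$clade == "grass"]) expect_equal(p, e_id)

  # every leaf lands in exactly one subfamily
  expect_setequal(sf2$gene_id, cm$gene_id)
  expect_equal(anyDuplicated(sf2$gene_id), 0L)

  expect_error(
    partition_subfamilies(tr2, cm[1:3, ]),
    "missing from clade map"
  )
})

test_that("an injected stem duplication yields two grass subfamilies", {
  fam <- simulate_family(sim_config(4, 4, 150,
    n_old_dups_grass = 1,
    seed = 23
  ))
  prot <- translate_alignment(fam$aln)
  tr <- nj_tree(p_distance_matrix(prot))
  sf <- partition_subfamilies(tr, fam$clade_map, min_support = 0)
  n_grass <- sf |>
    dplyr::filter(.data$clade == "grass") |>
    dplyr::distinct(.data$subfamily_id) |>
    nrow()
  expect_equal(n_grass, 2)
})
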