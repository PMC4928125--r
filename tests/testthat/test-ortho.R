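hit_row <- function(q, s, score, evalue = 1e-50, len = 100) {
  tibble::tibble(
    query_gene = q, subject_gene = s, pident = 90, length = len,
    mismatch = 5, gapopen = 0, qstart = 1, qend = len, sstart = 1,
    send = len, evalue = evalue, bitscore = score
  )
}

toy_map <- function(genes, species) {
  tibble::tibble(
    gene_id = genes, species = species,
    clade = ifelse(grepl("^s[12]", species), "grass", "eudicot")
  )
}

test_that("best hits pick maximal bitscore with documented tie-breaks", {
  cm <- toy_map(c("g1", "x1", "x2"), c("s1", "s2", "s2"))
  hits <- dplyr::bind_rows(
    hit_row("g1", "x1", 100),
    hit_row("g1", "x2", 90)
  )
  bets <- compute_bets(hits, cm)
  expect_equal(bets$best_hit[bets$query_gene == "g1"], "x1")

  # equal scores: smaller evalue wins
  hits2 <- dplyr::bind_rows(
    hit_row("g1", "x1", 100, evalue = 1e-50),
    hit_row("g1", "x2", 100, evalue = 1e-40)
  )
  expect_equal(compute_bets(hits2, cm)$best_hit, "x1")

  # no hits into a species: no entry
  cm3 <- toy_map(c("g1", "x1", "y1"), c("s1", "s2", "s3"))
  bets3 <- compute_bets(dplyr::bind_rows(hit_row("g1", "x1", 80)), cm3)
  expect_false("s3" %in% bets3$target_species)

  expect_error(
    compute_bets(dplyr::bind_rows(hit_row("g1", "zz", 50)), cm),
    "unknown species"
  )
})

test_that("symmetric BeTs require reciprocity", {
  cm <- toy_map(c("a", "b", "b2"), c("s1", "s2", "s2"))
  bets_sym <- dplyr::bind_rows(
    hit_row("a", "b", 100), hit_row("b", "a", 100)
  )
  edges <- symmetric_bets(compute_bets(bets_sym, cm), cm)
  expect_equal(nrow(edges), 1)
  expect_equal(c(edges$gene_a, edges$gene_b), c("a", "b"))

  # asymmetry: a's best is b, but b's best is elsewhere
  cm2 <- toy_map(c("a", "a2", "b"), c("s1", "s1", "s2"))
  asym <- dplyr::bind_rows(
    hit_row("a", "b", 100), hit_row("b", "a2", 100), hit_row("b", "a", 90)
  )
  expect_equal(nrow(symmetric_bets(compute_bets(asym, cm2), cm2)), 0)
})

test_that("COGs are triangle-seeded and merged by shared edges", {
  cm <- toy_map(
    c("a", "b", "c", "d"),
    c("s1", "s2", "s3", "s4")
  )
  tri <- tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    species_a = c("s1", "s1", "s2"), species_b = c("s2", "s3", "s3")
  )
  cogs <- build_cogs(tri, cm)
  expect_equal(sort(cogs$gene_id), c("a", "b", "c"))
  expect_equal(length(unique(cogs$cog_id)), 1)

  # two triangles sharing edge b-c merge into one COG
  tri2 <- dplyr::bind_rows(
    tri,
    tibble::tibble(
      gene_a = c("b", "c"), gene_b = c("d", "d"),
      species_a = c("s2", "s3"), species_b = c("s4", "s4")
    )
  )
  cogs2 <- build_cogs(tri2, cm)
  expect_equal(sort(cogs2$gene_id), c("a", "b", "c", "d"))
  expect_equal(length(unique(cogs2$cog_id)), 1)

  # a lone edge seeds nothing
  lone <- tibble::tibble(
    gene_a = "a", gene_b = "b", species_a = "s1", species_b = "s2"
  )
  expect_equal(nrow(build_cogs(lone, cm)), 0)
})

test_that("COG construction is invariant to hit-table row order", {
  fam <- simulate_family(sim_config(3, 3, 60, seed = 13))
  hits <- make_hits_from_family(fam)
  cm <- fam$clade_map
  c1 <- cogs_from_hits(hits, cm)
  set.seed(1)
  c2 <- cogs_from_hits(hits[sample(nrow(hits)), ], cm)
  expect_identical(c1, c2)
  # single-copy family across >= 3 species: exactly one COG with all genes
  expect_equal(length(unique(c1$cog_id)), 1)
  expect_setequal(c1$gene_id, fam$clade_map$gene_id)
})

test_that("paralog collapse applies the in-paralog score rule transitively", {
  cm <- tibble::tibble(
    gene_id = c("p1", "p2", "p3", "q1"),
    species = c("s1", "s1", "s1", "s2"),
    clade = c("grass", "grass", "grass", "eudicot")
  )
  base <- dplyr::bind_rows(
    hit_row("p1", "p1", 500, len = 120), hit_row("p2", "p2", 500, len = 100),
    hit_row("p3", "p3", 500, len = 90), hit_row("q1", "q1", 500, len = 100),
    hit_row("p1", "q1", 150), hit_row("p2", "q1", 150), hit_row("p3", "q1", 150)
  )
  # chain p1~p2, p2~p3 above the inter-species score: one cluster, rep =
  # longest member (p1, self-hit length 120)
  chain <- dplyr::bind_rows(
    base,
    hit_row("p1", "p2", 300), hit_row("p2", "p1", 300),
    hit_row("p2", "p3", 280), hit_row("p3", "p2", 280)
  )
  cp <- collapse_paralogs(chain, cm)
  reps <- setNames(cp$representative, cp$gene_id)
  expect_equal(unname(reps[c("p1", "p2", "p3")]), rep("p1", 3))
  expect_equal(unname(reps["q1"]), "q1")

  # below the inter-species score: not collapsed
  weak <- dplyr::bind_rows(base, hit_row("p1", "p2", 100), hit_row("p2", "p1", 100))
  cp2 <- collapse_paralogs(weak, cm)
  expect_equal(cp2$representative, cp2$gene_id)
})
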