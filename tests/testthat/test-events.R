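toy_subfamilies <- function(...) {
  dplyr::bind_rows(...)
}

sf_row <- function(id, clade, genes, species, partners = "", unplaced = FALSE) {
  tibble::tibble(
    subfamily_id = id, clade = clade, gene_id = genes, species = species,
    support = 99, unplaced = unplaced, partners = partners
  )
}

test_that("duplication rules count old and recent events", {
  roster <- list(grass = c("s1", "s2"), eudicot = c("t1", "t2"))
  # a eudicot subfamily with two genes of one species -> one recent_dup
  sf <- toy_subfamilies(
    sf_row("GSF1", "grass", c("a", "b"), c("s1", "s2"), "ESF1"),
    sf_row("ESF1", "eudicot", c("x", "y", "z"), c("t1", "t1", "t2"), "GSF1")
  )
  ev <- classify_duplications(sf, NULL, roster)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "recent_dup")
  expect_equal(ev$species, "t1")

  # 2 grass subfamilies, 1 eudicot subfamily -> 1 old_dup (grass)
  sf2 <- toy_subfamilies(
    sf_row("GSF1", "grass", c("a", "b"), c("s1", "s2"), "ESF1"),
    sf_row("GSF2", "grass", c("c", "d"), c("s1", "s2"), "ESF1"),
    sf_row("ESF1", "eudicot", c("x", "y"), c("t1", "t2"), "GSF1,GSF2")
  )
  ev2 <- classify_duplications(sf2, NULL, roster)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "old_dup")
  expect_equal(ev2$clade, "grass")

  expect_error(classify_duplications(sf2[0, ], NULL, roster), "empty")
})

test_that("loss rules cover recent roster gaps and orphaned subfamilies", {
  roster <- list(
    grass = paste0("s", 1:5),
    eudicot = c("t1", "t2")
  )
  # grass subfamily missing 1 of 5 roster species -> 1 recent_loss
  sf <- toy_subfamilies(
    sf_row("GSF1", "grass", paste0("a", 1:4), paste0("s", 1:4), "ESF1"),
    sf_row("ESF1", "eudicot", c("x", "y"), c("t1", "t2"), "GSF1")
  )
  ev <- classify_losses(sf, NULL, roster)
  rec <- ev[ev$kind == "recent_loss", ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$species, "s5")

  # full roster everywhere -> zero losses
  sf_full <- toy_subfamilies(
    sf_row("GSF1", "grass", paste0("a", 1:5), paste0("s", 1:5), "ESF1"),
    sf_row("ESF1", "eudicot", c("x", "y"), c("t1", "t2"), "GSF1")
  )
  expect_equal(nrow(classify_losses(sf_full, NULL, roster)), 0)

  # a eudicot subfamily whose pairing is non-mutual marks an old grass loss
  sf_orphan <- toy_subfamilies(
    sf_row("ESF1", "eudicot", c("u", "v"), c("t1", "t2"), "GSF1"),
    sf_row("ESF2", "eudicot", c("x", "y"), c("t1", "t2"), "GSF1"),
    sf_row("GSF1", "grass", paste0("a", 1:5), paste0("s", 1:5), "ESF2")
  )
  old <- classify_losses(sf_orphan, NULL, roster)
  old <- old[old$kind == "old_loss", ]
  expect_equal(nrow(old), 1)
  expect_equal(old$clade, "grass")
  expect_equal(old$subfamily, "ESF1")
})

test_that("event counting aggregates deterministically", {
  ev <- tibble::tibble(
    kind = c(rep("recent_dup", 3), "old_dup"),
    clade = c(rep("eudicot", 3), "grass"),
    species = c("t1", "t1", "t2", NA), subfamily = NA_character_
  )
  counts <- count_events(ev)
  expect_equal(
    counts$n[counts$clade == "eudicot" & counts$kind == "recent_dup"], 3
  )
  expect_equal(counts$n[counts$clade == "grass" & counts$kind == "old_dup"], 1)
  empty <- count_events(ev[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("adding a complete single-copy species changes no event calls", {
  roster <- list(grass = c("s1", "s2", "s3"), eudicot = c("t1", "t2"))
  sf <- toy_subfamilies(
    sf_row("GSF1", "grass", c("a1", "a2", "a3", "a3b"),
      c("s1", "s2", "s3", "s3"), "ESF1"
    ),
    sf_row("GSF2", "grass", c("b1", "b2"), c("s1", "s2"), "ESF1"),
    sf_row("ESF1", "eudicot", c("x", "y"), c("t1", "t2"), "GSF1,GSF2")
  )
  before <- dplyr::bind_rows(
    classify_duplications(sf, NULL, roster),
    classify_losses(sf, NULL, roster)
  ) |> count_events()
  # a new species s4 present once in every grass subfamily, roster updated
  roster2 <- list(grass = c(roster$grass, "s4"), eudicot = roster$eudicot)
  sf2 <- dplyr::bind_rows(
    sf,
    sf_row("GSF1", "grass", "c1", "s4", "ESF1"),
    sf_row("GSF2", "grass", "c2", "s4", "ESF1")
  )
  after <- dplyr::bind_rows(
    classify_duplications(sf2, NULL, roster2),
    classify_losses(sf2, NULL, roster2)
  ) |> count_events()
  expect_equal(before, after)
})
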