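# Rule-based inference of gene duplication and loss events from subfamily
# structure, with the old/recent dichotomy: old events precede a clade's
# radiation (shared by its species), recent events are species-specific.

#' Classify gene duplications from subfamily structure
#'
#' A clade with k >= 2 (placed) subfamilies carries k - 1 old duplications (a
#' binary-duplication parsimony count); a species with m >= 2 members inside
#' one subfamily carries m - 1 recent duplications.
#'
#' @param subfamilies Tibble from [partition_subfamilies()].
#' @param clade_map Tibble mapping `gene_id` to `species` and `clade`.
#' @param species_lists Named list `grass`/`eudicot` with the full expected
#'   species roster per clade (unused for duplications, kept for a uniform
#'   signature).
#' @return Tibble `kind`, `clade`, `species`, `subfamily`.
#' @export
classify_duplications <- function(subfamilies, clade_map,
                                  species_lists = NULL) {
  if (nrow(subfamilies) == 0) {
    stop("empty subfamily set", call. = FALSE)
  }
  placed <- subfamilies |> dplyr::filter(!.data$unplaced)
  old <- placed |>
    dplyr::distinct(.data$clade, .data$subfamily_id) |>
    dplyr::count(.data$clade, name = "k") |>
    dplyr::filter(.data$k >= 2)
  old_events <- old |>
    dplyr::reframe(
      kind = "old_dup", clade = rep(.data$clade, .data$k - 1),
      species = NA_character_, subfamily = NA_character_
    ) |>
    dplyr::select("kind", "clade", "species", "subfamily")

  recent_events <- subfamilies |>
    dplyr::count(.data$subfamily_id, .data$clade, .data$species, name = "m") |>
    dplyr::filter(.data$m >= 2) |>
    dplyr::reframe(
      kind = "recent_dup",
      clade = rep(.data$clade, .data$m - 1),
      species = rep(.data$species, .data$m - 1),
      subfamily = rep(.data$subfamily_id, .data$m - 1)
    )
  dplyr::bind_rows(old_events, recent_events)
}

#' Classify gene losses from subfamily structure
#'
#' A recent loss is scored for every (subfamily, roster species) combination
#' in which the species is absent from the subfamily. An old loss is scored
#' for clade B when a subfamily of clade A has no mutual orthologous partner
#' in B (the pattern of a clade-wide absence of an orthologous subclade);
#' losses are reported as inferred, pending any external validation.
#'
#' @inheritParams classify_duplications
#' @param species_lists Named list `grass`/`eudicot` of expected species.
#' @return Tibble `kind`, `clade`, `species`, `subfamily`.
#' @export
classify_losses <- function(subfamilies, clade_map, species_lists) {
  if (nrow(subfamilies) == 0) {
    stop("empty subfamily set", call. = FALSE)
  }
  stopifnot(all(c("grass", "eudicot") %in% names(species_lists)))
  placed <- subfamilies |> dplyr::filter(!.data$unplaced)

  recent <- placed |>
    dplyr::distinct(.data$subfamily_id, .data$clade) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      kind = "recent_loss",
      clade = .data$clade,
      species = setdiff(
        species_lists[[.data$clade]],
        subfamilies$species[subfamilies$subfamily_id == .data$subfamily_id]
      ),
      subfamily = .data$subfamily_id
    )

  # old loss: non-mutual orthology pairing
  sf <- placed |>
    dplyr::distinct(.data$subfamily_id, .data$clade, .data$partners)
  partner_sets <- strsplit(sf$partners, ",")
  names(partner_sets) <- sf$subfamily_id
  old <- NULL
  for (i in seq_len(nrow(sf))) {
    mine <- partner_sets[[sf$subfamily_id[i]]]
    mine <- mine[nzchar(mine)]
    other_clade <- setdiff(c("grass", "eudicot"), sf$clade[i])
    if (length(mine) == 0) {
      # no subfamily at all in the other clade
      old <- dplyr::bind_rows(old, tibble::tibble(
        kind = "old_loss", clade = other_clade, species = NA_character_,
        subfamily = sf$subfamily_id[i]
      ))
      next
    }
    mutual <- any(vapply(mine, function(p) {
      sf$subfamily_id[i] %in% partner_sets[[p]]
    }, logical(1)))
    if (!mutual) {
      old <- dplyr::bind_rows(old, tibble::tibble(
        kind = "old_loss", clade = other_clade, species = NA_character_,
        subfamily = sf$subfamily_id[i]
      ))
    }
  }
  dplyr::bind_rows(recent, old)
}

#' Aggregate events into a per-family count table
#'
#' @param events Tibble of events (from the classifiers), optionally with a
#'   `family` column.
#' @return Tibble `family` (if present), `clade`, `kind`, `n`.
#' @export
count_events <- function(events) {
  keys <- intersect(c("family", "clade", "kind"), names(events))
  if (nrow(events) == 0) {
    return(tibble::tibble(
      clade = character(0), kind = character(0), n = integer(0)
    ))
  }
  events |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}
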