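# Clusters of orthologous groups from all-vs-all protein similarity tables:
# in-paralog collapse, best hits per target species (BeTs), symmetric BeTs,
# and triangle-seeded COG construction.

outfmt6_cols <- c(
  "query_gene", "subject_gene", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read an all-vs-all similarity hit table
#'
#' Accepts the 12-column tab-separated BLAST `outfmt 6` dialect (no header);
#' extra columns are ignored.
#'
#' @param path Path to the hit table.
#' @return Tibble with columns `query_gene`, `subject_gene`, ..., `bitscore`.
#' @export
read_hits <- function(path) {
  hits <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(hits) < 12) {
    stop("hit table needs at least 12 outfmt-6 columns", call. = FALSE)
  }
  hits <- hits[, 1:12]
  names(hits) <- outfmt6_cols
  hits
}

# attach species to query and subject; error listing unknown genes
resolve_species <- function(hits, clade_map) {
  species_of <- setNames(clade_map$species, clade_map$gene_id)
  genes <- unique(c(hits$query_gene, hits$subject_gene))
  unknown <- setdiff(genes, names(species_of))
  if (length(unknown) > 0) {
    stop(
      "genes with unknown species: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  hits |>
    dplyr::mutate(
      query_species = unname(species_of[.data$query_gene]),
      subject_species = unname(species_of[.data$subject_gene])
    )
}

#' Best hit per (gene, target species)
#'
#' For every gene and every other species, selects the single subject gene
#' with the highest bitscore among the gene's hits into that species; ties
#' break by smaller e-value, then lexicographic subject id. Intra-species
#' hits are ignored.
#'
#' @param hits Hit-table tibble (see [read_hits()]).
#' @param clade_map Tibble mapping `gene_id` to `species` (and `clade`).
#' @return Tibble `query_gene`, `target_species`, `best_hit`, `bitscore`,
#'   `evalue`.
#' @export
compute_bets <- function(hits, clade_map) {
  if (nrow(hits) == 0) stop("empty hit table", call. = FALSE)
  resolve_species(hits, clade_map) |>
    dplyr::filter(.data$query_species != .data$subject_species) |>
    dplyr::group_by(.data$query_gene, target_species = .data$subject_species) |>
    dplyr::arrange(
      dplyr::desc(.data$bitscore), .data$evalue, .data$subject_gene,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      query_gene = .data$query_gene,
      target_species = .data$target_species,
      best_hit = .data$subject_gene,
      bitscore = .data$bitscore, evalue = .data$evalue
    ) |>
    dplyr::arrange(.data$query_gene, .data$target_species)
}

#' Symmetric best hits
#'
#' An undirected edge joins genes a and b when each is the other's best hit
#' into the partner's species.
#'
#' @param bets Output of [compute_bets()].
#' @param clade_map Tibble mapping `gene_id` to `species`.
#' @return Tibble of edges `gene_a`, `gene_b` (lexicographically ordered),
#'   with species columns.
#' @export
symmetric_bets <- function(bets, clade_map) {
  species_of <- setNames(clade_map$species, clade_map$gene_id)
  fwd <- bets |>
    dplyr::transmute(a = .data$query_gene, b = .data$best_hit)
  rev <- fwd |> dplyr::rename(a = "b", b = "a")
  sym <- dplyr::inner_join(fwd, rev, by = c("a", "b")) |>
    dplyr::filter(.data$a < .data$b) |>
    dplyr::distinct()
  tibble::tibble(
    gene_a = sym$a, gene_b = sym$b,
    species_a = unname(species_of[sym$a]),
    species_b = unname(species_of[sym$b])
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Build COGs by triangle seeding and edge-sharing merge
#'
#' Seeds are triangles of symmetric best hits spanning three distinct
#' species; triangles sharing an edge are merged transitively, and each
#' merged structure is reported as one cluster of orthologous groups. Genes
#' in no triangle are left unassigned.
#'
#' @param edges Output of [symmetric_bets()].
#' @param clade_map Tibble mapping `gene_id` to `species` and `clade`.
#' @return Tibble `cog_id`, `gene_id`, `species`, `clade`.
#' @export
build_cogs <- function(edges, clade_map) {
  empty <- tibble::tibble(
    cog_id = character(0), gene_id = character(0),
    species = character(0), clade = character(0)
  )
  if (nrow(edges) == 0) {
    return(empty)
  }
  species_of <- setNames(clade_map$species, clade_map$gene_id)
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")],
    directed = FALSE
  )
  tri <- igraph::triangles(g)
  if (length(tri) == 0) {
    return(empty)
  }
  tri <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
  # keep triangles spanning three distinct species
  keep <- apply(tri, 1, function(x) length(unique(species_of[x])) == 3)
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0) {
    return(empty)
  }
  # union-find over triangles keyed by shared edges
  parent <- seq_len(nrow(tri))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tri))) {
    v <- sort(tri[i, ])
    for (k in list(c(1, 2), c(1, 3), c(2, 3))) {
      key <- edge_key(v[k[1]], v[k[2]])
      j <- seen[[key]]
      if (is.null(j)) {
        assign(key, i, envir = seen)
      } else {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(nrow(tri)), find, integer(1))
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  out <- lapply(split(seq_len(nrow(tri)), comp), function(rows) {
    genes <- sort(unique(as.vector(tri[rows, , drop = FALSE])))
    tibble::tibble(gene_id = genes)
  })
  # deterministic cog ids by first member
  ord <- order(vapply(out, function(x) x$gene_id[1], character(1)))
  dplyr::bind_rows(out[ord], .id = NULL) -> members
  ids <- rep(
    sprintf("COG%03d", seq_along(out)),
    vapply(out[ord], nrow, integer(1))
  )
  members |>
    dplyr::mutate(
      cog_id = ids,
      species = unname(species_of[.data$gene_id]),
      clade = unname(clade_of[.data$gene_id]),
      .before = 1
    ) |>
    dplyr::relocate("cog_id", "gene_id", "species", "clade")
}

#' Collapse obvious in-paralogs before BeT detection
#'
#' Within each species, two genes are in-paralogs when their mutual
#' intra-species bitscore exceeds the best inter-species bitscore of each of
#' the two genes (the classical in-paralog criterion: more similar to each
#' other than either is to any gene of another species); clusters are the
#' transitive closure of that relation, represented by
#' their longest member (gene length taken from the gene's self-hit alignment
#' length; ties break lexicographically).
#'
#' @param hits Hit-table tibble including intra-species (and self) hits.
#' @param clade_map Tibble mapping `gene_id` to `species`.
#' @return Tibble `gene_id`, `representative`.
#' @export
collapse_paralogs <- function(hits, clade_map) {
  hits <- resolve_species(hits, clade_map)
  genes <- unique(c(hits$query_gene, hits$subject_gene))

  self_len <- hits |>
    dplyr::filter(.data$query_gene == .data$subject_gene) |>
    dplyr::group_by(.data$query_gene) |>
    dplyr::summarise(len = max(.data$length))
  fallback_len <- hits |>
    tidyr::pivot_longer(c("query_gene", "subject_gene"), values_to = "gene") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(len = max(.data$length))
  len_of <- setNames(fallback_len$len, fallback_len$gene)
  len_of[self_len$query_gene] <- self_len$len

  best_inter <- hits |>
    dplyr::filter(.data$query_species != .data$subject_species) |>
    dplyr::group_by(.data$query_gene) |>
    dplyr::summarise(best = max(.data$bitscore))
  inter_of <- setNames(best_inter$best, best_inter$query_gene)

  intra_hits <- hits |>
    dplyr::filter(
      .data$query_species == .data$subject_species,
      .data$query_gene != .data$subject_gene
    )
  intra <- if (nrow(intra_hits) == 0) {
    tibble::tibble(a = character(0), b = character(0), score = numeric(0))
  } else {
    intra_hits |>
      dplyr::mutate(
        a = pmin(.data$query_gene, .data$subject_gene),
        b = pmax(.data$query_gene, .data$subject_gene)
      ) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(score = max(.data$bitscore), .groups = "drop") |>
      dplyr::filter(
        .data$score > dplyr::coalesce(inter_of[.data$a], -Inf) &
          .data$score > dplyr::coalesce(inter_of[.data$b], -Inf)
      )
  }

  # union-find transitive closure
  parent <- setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(intra))) {
    ra <- find(intra$a[i])
    rb <- find(intra$b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(genes, find, character(1))
  reps <- vapply(split(genes, roots), function(members) {
    lens <- dplyr::coalesce(unname(len_of[members]), 0)
    members[order(-lens, members)][1]
  }, character(1))
  tibble::tibble(
    gene_id = genes,
    representative = unname(reps[roots])
  ) |>
    dplyr::arrange(.data$gene_id)
}

#' Full COG construction from a hit table
#'
#' Convenience wrapper: collapse in-paralogs, compute BeTs on
#' representatives, take symmetric BeTs, and build COGs. Members of collapsed
#' paralog clusters are restored into their representative's COG.
#'
#' @inheritParams collapse_paralogs
#' @return Tibble `cog_id`, `gene_id`, `species`, `clade`.
#' @export
cogs_from_hits <- function(hits, clade_map) {
  collapse <- collapse_paralogs(hits, clade_map)
  rep_of <- setNames(collapse$representative, collapse$gene_id)
  reps <- unique(collapse$representative)
  hits_rep <- hits |>
    dplyr::mutate(
      query_gene = unname(rep_of[.data$query_gene]),
      subject_gene = unname(rep_of[.data$subject_gene])
    ) |>
    dplyr::filter(
      .data$query_gene %in% reps, .data$subject_gene %in% reps
    )
  bets <- compute_bets(hits_rep, clade_map)
  edges <- symmetric_bets(bets, clade_map)
  cogs <- build_cogs(edges, clade_map)
  if (nrow(cogs) == 0) {
    return(cogs)
  }
  species_of <- setNames(clade_map$species, clade_map$gene_id)
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  collapse |>
    dplyr::inner_join(cogs |> dplyr::select("cog_id", "gene_id"),
      by = c(representative = "gene_id")
    ) |>
    dplyr::transmute(
      cog_id = .data$cog_id, gene_id = .data$gene_id,
      species = unname(species_of[.data$gene_id]),
      clade = unname(clade_of[.data$gene_id])
    ) |>
    dplyr::arrange(.data$cog_id, .data$gene_id)
}
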