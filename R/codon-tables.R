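# Codon bookkeeping for the universal genetic code over the 61 sense codons.
# Nucleotide order T, C, A, G (the conventional codon-model ordering).

cs_nucs <- c("T", "C", "A", "G")

#' Sense codons of the universal genetic code
#'
#' The 61 non-stop codons in T/C/A/G-major order. This fixed ordering defines
#' the state space of every rate matrix, frequency vector and likelihood in
#' the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

# Amino acid for each of the 61 sense codons (one-letter code).
codon_amino_acids <- function() {
  codon_tables()$aa
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

# Build (once) all static lookup tables: codon list, translation, the
# single-nucleotide-change structure used by GY94, per-codon NG86 site counts
# and the pathway-averaged NG86 difference counts for every codon pair.
codon_tables <- function() {
  if (!is.null(.cs_cache$tables)) {
    return(.cs_cache$tables)
  }
  all64 <- apply(expand.grid(cs_nucs, cs_nucs, cs_nucs,
    stringsAsFactors = FALSE
  )[, 3:1], 1, paste0, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  n <- length(sense)
  stopifnot(n == 61L)
  idx <- setNames(seq_len(n), sense)
  mat <- do.call(rbind, strsplit(sense, ""))

  # single-nucleotide neighbour structure over the 61 sense codons
  diffpos <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  syn <- matrix(FALSE, n, n)
  for (p in 1:3) {
    dp <- outer(mat[, p], mat[, p], "!=")
    diffpos <- diffpos + dp
  }
  single <- diffpos == 1L
  for (i in seq_len(n)) {
    js <- which(single[i, ])
    for (j in js) {
      p <- which(mat[i, ] != mat[j, ])
      ts[i, j] <- is_transition(mat[i, p], mat[j, p])
      syn[i, j] <- aa[i] == aa[j]
    }
  }

  tabs <- list(
    codons = sense, aa = aa, index = idx, nuc = mat,
    ndiff = diffpos, single = single, transition = ts, synonymous = syn,
    gc61 = setNames(aa, sense)
  )
  tabs$ng86 <- ng86_tables(tabs)
  .cs_cache$tables <- tabs
  tabs
}

# NG86 site and difference counts.
# Sites: at each codon position the synonymous fraction is the share of
# synonymous changes among the single-nucleotide changes that do not create a
# stop codon; S + N = 3 per codon by construction.
# Differences: counts of synonymous/nonsynonymous steps averaged with equal
# weight over all minimal mutational pathways; pathways passing through a stop
# codon are excluded (all-blocked pairs fall back to averaging over every
# pathway).
ng86_tables <- function(tabs) {
  gc <- Biostrings::GENETIC_CODE
  n <- length(tabs$codons)
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    cod <- strsplit(tabs$codons[i], "")[[1]]
    s <- 0
    for (p in 1:3) {
      tot <- 0L
      ns <- 0L
      for (b in setdiff(cs_nucs, cod[p])) {
        mut <- cod
        mut[p] <- b
        mutc <- paste0(mut, collapse = "")
        if (gc[[mutc]] == "*") next
        tot <- tot + 1L
        if (gc[[mutc]] == gc[[tabs$codons[i]]]) ns <- ns + 1L
      }
      if (tot > 0L) s <- s + ns / tot
    }
    syn_sites[i] <- s
  }

  step_counts <- function(a, b) {
    # one-step change a -> b (sense codons): c(syn, nonsyn)
    if (gc[[a]] == gc[[b]]) c(1, 0) else c(0, 1)
  }
  sd_mat <- matrix(0, n, n)
  nd_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- strsplit(tabs$codons[i], "")[[1]]
      b <- strsplit(tabs$codons[j], "")[[1]]
      pos <- which(a != b)
      d <- length(pos)
      if (d == 1L) {
        sc <- step_counts(tabs$codons[i], tabs$codons[j])
        sd_mat[i, j] <- sc[1]
        nd_mat[i, j] <- sc[2]
        next
      }
      perms <- if (d == 2L) {
        list(pos, rev(pos))
      } else {
        lapply(
          list(
            c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
          ),
          function(o) pos[o]
        )
      }
      path_counts <- function(allow_stops) {
        acc <- NULL
        for (ord in perms) {
          cur <- a
          sy <- 0
          ny <- 0
          ok <- TRUE
          for (p in ord) {
            nxt <- cur
            nxt[p] <- b[p]
            curc <- paste0(cur, collapse = "")
            nxtc <- paste0(nxt, collapse = "")
            if (gc[[nxtc]] == "*" && !allow_stops) {
              ok <- FALSE
              break
            }
            if (gc[[curc]] == "*" || gc[[nxtc]] == "*") {
              # stop intermediates carry no syn/nonsyn identity; count as
              # nonsynonymous in the fallback averaging
              ny <- ny + 1
            } else if (gc[[curc]] == gc[[nxtc]]) {
              sy <- sy + 1
            } else {
              ny <- ny + 1
            }
            cur <- nxt
          }
          if (ok) acc <- rbind(acc, c(sy, ny))
        }
        acc
      }
      acc <- path_counts(allow_stops = FALSE)
      if (is.null(acc)) acc <- path_counts(allow_stops = TRUE)
      sd_mat[i, j] <- mean(acc[, 1])
      nd_mat[i, j] <- mean(acc[, 2])
    }
  }
  list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
}

# Split a nucleotide string into codons; returns character vector.
split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  nc <- nchar(seq)
  if (nc %% 3 != 0) {
    stop("sequence length ", nc, " is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1, nc, by = 3), seq(3, nc, by = 3))
}

# Map codons to 1..61 indices; gaps/ambiguity -> NA; stop codons -> error
# unless allow_stop.
codon_indices <- function(codons, allow_stop = FALSE) {
  tabs <- codon_tables()
  idx <- unname(tabs$index[codons])
  bad <- is.na(idx) & !grepl("[^ACGT]", codons)
  if (any(bad)) {
    if (!allow_stop) {
      stop(
        "stop codon(s) present: ",
        paste(unique(codons[bad]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  idx
}
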