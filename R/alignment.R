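# Alignment containers. A codon alignment is a tibble with columns `gene_id`
# and `seq` (equal-length, in-frame nucleotide strings); a protein alignment
# is the same shape with amino-acid strings.

#' Read an in-frame codon alignment from FASTA
#'
#' Loads aligned coding sequences and validates the codon-alignment contract:
#' equal lengths divisible by three and no internal stop codons. Alignment
#' columns in which any sequence carries a stop codon are removed (the
#' conventional treatment of termination codons before dN/dS analysis); gap
#' codons (`---`) are kept and treated as missing data downstream.
#'
#' @param path Path to a FASTA file of aligned coding sequences.
#' @return A tibble with columns `gene_id`, `seq`.
#' @export
read_codon_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  as_codon_alignment(tibble::tibble(
    gene_id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x))
  ))
}

#' Validate (and clean) a codon alignment tibble
#'
#' @param aln Tibble with columns `gene_id` and `seq`.
#' @return The validated tibble, with stop-codon columns dropped.
#' @export
as_codon_alignment <- function(aln) {
  stopifnot(all(c("gene_id", "seq") %in% names(aln)))
  aln <- tibble::as_tibble(aln)
  if (anyDuplicated(aln$gene_id)) {
    stop("duplicated gene ids in alignment", call. = FALSE)
  }
  lens <- nchar(aln$seq)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (lens[1] %% 3 != 0) {
    stop("aligned length must be a multiple of 3", call. = FALSE)
  }
  cod <- codon_matrix(aln)
  tabs <- codon_tables()
  is_stop <- matrix(cod %in% c("TAA", "TAG", "TGA"), nrow = nrow(cod))
  bad_col <- which(apply(is_stop, 2, any))
  if (length(bad_col) > 0) {
    warning(
      "dropping ", length(bad_col),
      " alignment column(s) containing stop codons"
    )
    cod <- cod[, -bad_col, drop = FALSE]
    aln$seq <- apply(cod, 1, paste0, collapse = "")
  }
  aln
}

# genes x codon-columns character matrix
codon_matrix <- function(aln) {
  t(vapply(aln$seq, function(s) split_codons(s),
    character(nchar(aln$seq[1]) / 3),
    USE.NAMES = FALSE
  ))
}

#' Translate a codon alignment to a protein alignment
#'
#' Gap codons translate to `-`; partially gapped codons to `X`.
#'
#' @param aln Codon alignment tibble.
#' @return Tibble with columns `gene_id`, `seq` (amino acids).
#' @export
translate_alignment <- function(aln) {
  tabs <- codon_tables()
  cod <- codon_matrix(aln)
  aa <- matrix("X", nrow(cod), ncol(cod))
  aa[cod == "---"] <- "-"
  known <- cod %in% names(tabs$gc61)
  aa[known] <- tabs$gc61[cod[known]]
  tibble::tibble(
    gene_id = aln$gene_id,
    seq = apply(aa, 1, paste0, collapse = "")
  )
}

#' Read a protein alignment from FASTA
#'
#' @param path Path to a FASTA file of aligned amino-acid sequences.
#' @return Tibble with columns `gene_id`, `seq`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- tibble::tibble(
    gene_id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x))
  )
  if (length(unique(nchar(out$seq))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  out
}

#' Write an alignment tibble to FASTA
#'
#' @param aln Tibble with columns `gene_id`, `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(setNames(aln$seq, aln$gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a gene-to-species-to-clade map
#'
#' @param path TSV with columns `gene_id`, `species`, `clade`
#'   (clade is `grass` or `eudicot`).
#' @return A tibble.
#' @export
read_clade_map <- function(path) {
  cm <- readr::read_tsv(path, show_col_types = FALSE)
  validate_clade_map(cm)
}

validate_clade_map <- function(cm) {
  stopifnot(all(c("gene_id", "species", "clade") %in% names(cm)))
  bad <- setdiff(unique(cm$clade), c("grass", "eudicot"))
  if (length(bad) > 0) {
    stop("unknown clade label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(cm)
}
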