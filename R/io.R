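# Readers, writers and validation for in-frame codon alignments, trees,
# variant tables and external score tables.

#' Construct a codon alignment
#'
#' @param sequences named character vector of aligned, in-frame nucleotide
#'   sequences over `A,C,G,T,N,-` (IUPAC ambiguity characters are tolerated
#'   and treated as ambiguous). Names are species identifiers and must be
#'   unique.
#' @param query_id identifier of the query (reference) species.
#' @return An object of class `codon_alignment` with fields `species`,
#'   `query_id`, `codons` (species x codon-column character matrix) and
#'   `n_codons`.
#' @export
codon_alignment <- function(sequences, query_id) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by species identifier")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have identical length; offending record(s): ",
         paste(names(sequences)[lens != lens[1L]], collapse = ", "))
  if (lens[1L] %% 3L != 0L)
    stop("alignment length ", lens[1L], " is not divisible by 3 (record ",
         names(sequences)[1L], ")")
  if (!query_id %in% names(sequences))
    stop("query_id '", query_id, "' not found among alignment species")
  n_codons <- unname(lens[1L]) %/% 3L
  mat <- matrix(NA_character_, nrow = length(sequences), ncol = n_codons,
                dimnames = list(names(sequences), NULL))
  for (i in seq_along(sequences)) {
    s <- strsplit(sequences[[i]], "")[[1L]]
    mat[i, ] <- paste0(s[c(TRUE, FALSE, FALSE)],
                       s[c(FALSE, TRUE, FALSE)],
                       s[c(FALSE, FALSE, TRUE)])
  }
  structure(list(species = names(sequences), query_id = query_id,
                 codons = mat, n_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$species), "sequences x", x$n_codons,
      "codons; query =", x$query_id, "\n")
  invisible(x)
}

# full sequences as a named character vector
.aln_sequences <- function(aln) {
  out <- apply(aln$codons, 1L, paste0, collapse = "")
  names(out) <- aln$species
  out
}

#' Read an in-frame codon alignment from FASTA
#'
#' Sequence case is normalised, gaps are preserved. Sequences containing
#' ambiguous characters are accepted at read time; use
#' [filter_ambiguous_sequences()] before likelihood computation.
#'
#' @param path path to an aligned nucleotide FASTA file.
#' @param query_id identifier of the query species.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, query_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- ape::read.FASTA(path)
  seqs <- vapply(as.character(recs), paste0, "", collapse = "")
  names(seqs) <- names(recs)
  codon_alignment(seqs, query_id = query_id)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output file path.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- .aln_sequences(aln)
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Drop homologs with ambiguous nucleotides
#'
#' Sequences whose characters are not all in `{A,C,G,T,-}` are discarded
#' before any likelihood computation. The query sequence is never discarded:
#' its ambiguous codons are already treated as missing data by the
#' likelihood machinery, and dropping the query would leave the reference /
#' alternate allele counts undefined.
#'
#' @param aln a [codon_alignment()].
#' @return The filtered alignment (species order preserved). Idempotent.
#' @export
filter_ambiguous_sequences <- function(aln) {
  seqs <- .aln_sequences(aln)
  clean <- !grepl("[^ACGT-]", seqs)
  keep <- clean | names(seqs) == aln$query_id
  if (sum(keep & names(seqs) != aln$query_id) == 0L)
    stop("degenerate alignment: no unambiguous homolog sequences remain")
  codon_alignment(seqs[keep], query_id = aln$query_id)
}

#' Map query CDS codon positions to alignment columns
#'
#' Variant coordinates are 1-based codon indices on the query sequence's
#' ungapped CDS; alignment columns where the query codon is entirely gaps
#' do not consume a CDS position.
#'
#' @param aln a [codon_alignment()].
#' @param codon_pos vector of 1-based query CDS codon positions.
#' @return Integer vector of alignment codon columns (`NA` when out of
#'   range).
#' @export
query_codon_column <- function(aln, codon_pos) {
  q <- aln$codons[aln$query_id, ]
  is_cds <- q != "---"
  colmap <- which(is_cds)
  out <- rep(NA_integer_, length(codon_pos))
  ok <- codon_pos >= 1L & codon_pos <= length(colmap)
  out[ok] <- colmap[codon_pos[ok]]
  out
}

#' Read a Newick tree with branch lengths in dS units
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] object. Polytomies are permitted on input.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths: ", path)
  if (anyNA(tr$edge.length))
    stop("tree has missing branch lengths: ", path)
  if (any(tr$edge.length < 0))
    stop("negative branch length in tree: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree: ", path)
  tr
}

# a tree may only be paired with an alignment covering all its tips
.check_tree_alignment <- function(tree, aln) {
  missing <- setdiff(tree$tip.label, aln$species)
  if (length(missing))
    stop("tree tips absent from alignment: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a variant table
#'
#' Tab-separated with header; required columns `gene`, `codon_pos`,
#' `ref_aa`, `alt_aa`; optional `label` (`positive`/`negative`), `mac`
#' (minor allele count) and `tags`. Unknown columns are preserved.
#'
#' @param path path to the TSV file.
#' @return A data frame of typed variant records.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene", "codon_pos", "ref_aa", "alt_aa")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$codon_pos) || any(df$codon_pos != as.integer(df$codon_pos)))
    stop("codon_pos must be integer")
  df$codon_pos <- as.integer(df$codon_pos)
  validate_variants(df)
  df
}

#' Validate variant records
#'
#' @param df data frame with at least `gene`, `codon_pos`, `ref_aa`, `alt_aa`.
#' @return The data frame, invisibly, if valid; otherwise an error.
#' @export
validate_variants <- function(df) {
  bad_aa <- !(df$ref_aa %in% AMINO_ACIDS) | !(df$alt_aa %in% AMINO_ACIDS)
  if (any(bad_aa))
    stop("non-standard amino acid in variant row(s): ",
         paste(which(bad_aa), collapse = ", "))
  same <- df$ref_aa == df$alt_aa
  if (any(same))
    stop("ref_aa equals alt_aa in variant row(s): ",
         paste(which(same), collapse = ", "))
  if (any(df$codon_pos < 1L)) stop("codon_pos must be >= 1")
  invisible(df)
}

#' Write per-variant predictions to TSV
#'
#' @param df data frame of variant records plus computed columns
#'   (p-values, Rn, An, constraint, probabilities, ...).
#' @param path output path.
#' @export
write_predictions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-approach score table
#'
#' Tab-separated with header; key columns `gene`, `codon_pos`, `ref_aa`,
#' `alt_aa`; every remaining numeric column is an approach score. Missing
#' scores are `NA` and are never silently imputed.
#'
#' @param path path to the TSV file.
#' @return A data frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  key <- c("gene", "codon_pos", "ref_aa", "alt_aa")
  miss <- setdiff(key, names(df))
  if (length(miss)) stop("score table missing key columns: ",
                         paste(miss, collapse = ", "))
  keys <- do.call(paste, c(df[key], sep = "\r"))
  if (anyDuplicated(keys)) stop("duplicate variant keys in score table")
  df
}
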