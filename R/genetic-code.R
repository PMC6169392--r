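# Universal genetic code tables and the single-nucleotide neighbour structure
# used by the MG94 rate matrix, the allele counters and the GERP codon rule.
# Built once at load; codons are indexed 1..61 over the sense codons in
# lexicographic (A, C, G, T) order.

NUCLEOTIDES <- c("A", "C", "G", "T")

# standard (universal) code, codon -> one-letter amino acid, '*' = stop
GENETIC_CODE_UNIVERSAL <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AMINO_ACIDS <- sort(unique(GENETIC_CODE_UNIVERSAL[GENETIC_CODE_UNIVERSAL != "*"]))

.code_env <- new.env(parent = emptyenv())

.build_code_tables <- function() {
  g <- expand.grid(p3 = NUCLEOTIDES, p2 = NUCLEOTIDES, p1 = NUCLEOTIDES,
                   stringsAsFactors = FALSE)
  all_codons <- paste0(g$p1, g$p2, g$p3)
  all_codons <- sort(all_codons)           # lexicographic ACGT order
  aa_all <- GENETIC_CODE_UNIVERSAL[all_codons]
  sense <- all_codons[aa_all != "*"]
  stopifnot(length(sense) == 61L)
  aa <- unname(aa_all[aa_all != "*"])

  idx <- seq_along(sense)
  names(idx) <- sense

  # single-nucleotide neighbour pairs among sense codons
  from <- integer(0); to <- integer(0); pos <- integer(0)
  tgt <- integer(0); syn <- logical(0)
  split_nt <- do.call(rbind, strsplit(sense, ""))
  for (i in idx) {
    for (p in 1:3) {
      for (n in 1:4) {
        if (split_nt[i, p] == NUCLEOTIDES[n]) next
        cod <- split_nt[i, ]
        cod[p] <- NUCLEOTIDES[n]
        j <- idx[paste(cod, collapse = "")]
        if (is.na(j)) next                 # change leads to a stop codon
        from <- c(from, i); to <- c(to, unname(j))
        pos <- c(pos, p); tgt <- c(tgt, n)
        syn <- c(syn, aa[i] == aa[unname(j)])
      }
    }
  }
  .code_env$sense_codons <- sense
  .code_env$codon_index <- idx
  .code_env$codon_aa <- aa
  .code_env$codon_nt <- split_nt          # 61 x 3 nucleotide characters
  .code_env$pairs <- list(from = from, to = to, pos = pos,
                          target = tgt, syn = syn)
  invisible(NULL)
}

.code <- function() {
  if (is.null(.code_env$sense_codons)) .build_code_tables()
  .code_env
}

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons in lexicographic order;
#'   this ordering defines the state indexing of all rate and transition
#'   matrices in the package.
#' @export
sense_codons <- function() .code()$sense_codons

#' Translate codons to one-letter amino acids
#'
#' Codons containing gaps, `N` or other non-ACGT characters translate to
#' `NA`; stop codons translate to `"*"`.
#'
#' @param codons character vector of 3-letter codons.
#' @return Character vector of amino acids (`NA` for unresolvable codons).
#' @export
translate_codons <- function(codons) {
  codons <- toupper(codons)
  out <- unname(GENETIC_CODE_UNIVERSAL[codons])
  out[is.na(out) & !is.na(codons)] <- NA_character_
  out
}

# integer state (1..61) for sense codons, NA otherwise
.codon_state <- function(codons) {
  unname(.code()$codon_index[toupper(codons)])
}
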