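#' Bacterial genetic code (translation table 11)
#'
#' Named character vector mapping codons (DNA alphabet) to one-letter amino
#' acids, with `*` for stops; alternative initiation codons ATG/GTG/TTG are
#' accepted as starts throughout the package.
#' @return named character vector of length 64.
#' @export
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

START_CODONS <- c("ATG", "GTG", "TTG")

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Construct a validated coding sequence
#'
#' A coding sequence is the in-frame CDS of a gene: 1-based coordinates with
#' position 1 the first base of the start codon. Validation (on by default)
#' requires length divisible by 3, a bacterial start codon (ATG/GTG/TTG), a
#' terminal stop and no internal in-frame stop. Optional 5'/3' flanking
#' sequence is carried for mRNA-window extraction near the gene ends.
#'
#' @param nucleotides CDS as a character string over A/C/G/T (case folded).
#' @param id sequence identifier.
#' @param flank5,flank3 optional flanking sequence (outside the CDS).
#' @param validate check the CDS invariants (disable for mutant sequences,
#'   which may legitimately contain a premature stop).
#' @return object of class `"coding_sequence"`.
#' @examples
#' coding_sequence("ATGGGTAAAGGCTAA", id = "toy")
#' @export
coding_sequence <- function(nucleotides, id = "cds", flank5 = "", flank3 = "",
                            validate = TRUE) {
  nucleotides <- toupper(as.character(nucleotides))
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (grepl("[^ACGT]", nucleotides))
    stop("CDS contains characters outside {A,C,G,T}")
  if (validate) {
    if (nchar(nucleotides) %% 3 != 0)
      stop("CDS length not divisible by 3")
    cod <- split_codons(nucleotides)
    gc <- genetic_code_11()
    if (!(cod[1] %in% START_CODONS))
      stop("CDS does not begin with a start codon (ATG/GTG/TTG)")
    aa <- gc[cod]
    if (aa[length(aa)] != "*")
      stop("CDS does not end with a stop codon")
    if (any(aa[-length(aa)] == "*"))
      stop("CDS contains an internal in-frame stop codon")
  }
  structure(list(id = id, nucleotides = nucleotides,
                 flank5 = flank5, flank3 = flank3),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence %s: %d nt (%d codons), flanks %d/%d nt>\n",
              x$id, nchar(x$nucleotides), nchar(x$nucleotides) %/% 3,
              nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used unless `which` is given.
#' @param which record name or index.
#' @inheritParams coding_sequence
#' @return a [coding_sequence()].
#' @export
read_coding_sequence <- function(path, which = 1L, validate = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  coding_sequence(as.character(ss[[which]]), id = names(ss)[which],
                  validate = validate)
}

#' Describe a point mutation in CDS coordinates
#'
#' @param cds_position 1-based position within the CDS.
#' @param ref_base,alt_base reference and alternate nucleotide.
#' @return object of class `"point_mutation"` with derived `codon_index`
#'   (1-based) and `codon_position` (1-3).
#' @export
point_mutation <- function(cds_position, ref_base, alt_base) {
  cds_position <- as.integer(cds_position)
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(cds_position >= 1,
            ref_base %in% c("A", "C", "G", "T"),
            alt_base %in% c("A", "C", "G", "T"))
  if (ref_base == alt_base) stop("alt_base must differ from ref_base")
  structure(list(cds_position = cds_position,
                 ref_base = ref_base, alt_base = alt_base,
                 codon_index = (cds_position - 1L) %/% 3L + 1L,
                 codon_position = (cds_position - 1L) %% 3L + 1L),
            class = "point_mutation")
}

check_mutation <- function(cds, mut) {
  if (mut$cds_position > nchar(cds$nucleotides))
    stop("mutation position ", mut$cds_position, " beyond CDS end (",
         nchar(cds$nucleotides), " nt)")
  have <- substr(cds$nucleotides, mut$cds_position, mut$cds_position)
  if (have != mut$ref_base)
    stop("reference mismatch at CDS position ", mut$cds_position,
         ": CDS has ", have, ", mutation lists ", mut$ref_base,
         " (check coordinates/strand)")
  invisible(TRUE)
}

#' Apply a point mutation to a coding sequence
#'
#' Returns the mutant CDS (unvalidated, since nonsense mutants contain a
#' premature stop by construction).
#' @param cds a [coding_sequence()].
#' @param mut a [point_mutation()].
#' @return a `coding_sequence`.
#' @export
apply_mutation <- function(cds, mut) {
  check_mutation(cds, mut)
  s <- cds$nucleotides
  substr(s, mut$cds_position, mut$cds_position) <- mut$alt_base
  coding_sequence(s, id = paste0(cds$id, "_mut", mut$cds_position,
                                 mut$ref_base, ">", mut$alt_base),
                  flank5 = cds$flank5, flank3 = cds$flank3, validate = FALSE)
}

#' Classify a point mutation as synonymous, nonsynonymous or nonsense
#'
#' Translates the reference and mutant codon under translation table 11:
#' synonymous if the amino acid is unchanged, nonsense if the mutant codon
#' is a stop, nonsynonymous otherwise.
#'
#' @inheritParams apply_mutation
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`.
#' @examples
#' cds <- coding_sequence("ATGGGTAAAGGCTAA")
#' classify_mutation(cds, point_mutation(6, "T", "C"))  # GGT -> GGC
#' @export
classify_mutation <- function(cds, mut) {
  check_mutation(cds, mut)
  gc <- genetic_code_11()
  i0 <- (mut$codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds$nucleotides, i0, i0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, mut$codon_position, mut$codon_position) <- mut$alt_base
  aa_ref <- gc[[ref_codon]]
  aa_alt <- gc[[alt_codon]]
  if (aa_ref == "*")
    stop("mutation falls in the stop codon; not a sense-codon substitution")
  if (aa_alt == "*") "nonsense"
  else if (aa_alt == aa_ref) "synonymous"
  else "nonsynonymous"
}

#' Mutation labels in gene notation
#'
#' `mutation_label()` gives amino-acid notation (`G38G`, `A10T`, `W12*`);
#' `site_label()` gives codon-site notation (`39-3T`: codon 39, third codon
#' position, mutant base T).
#' @inheritParams apply_mutation
#' @return character scalar.
#' @export
mutation_label <- function(cds, mut) {
  gc <- genetic_code_11()
  i0 <- (mut$codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds$nucleotides, i0, i0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, mut$codon_position, mut$codon_position) <- mut$alt_base
  paste0(gc[[ref_codon]], mut$codon_index, gc[[alt_codon]])
}

#' @rdname mutation_label
#' @export
site_label <- function(cds, mut) {
  paste0(mut$codon_index, "-", mut$codon_position, mut$alt_base)
}

#' Relative-adaptiveness codon weights from a reference gene set
#'
#' Builds the Sharp-Li codon usage table for CAI: codon counts are pooled
#' over the reference genes (typically highly expressed genes such as
#' ribosomal proteins), zero counts are smoothed to 0.5, and each sense
#' codon's weight is its count divided by the maximum count within its
#' synonymous family, so the preferred codon of every family has weight 1.
#'
#' @param reference character vector of CDS sequences, a `DNAStringSet`, or
#'   the path to a FASTA file of reference genes.
#' @return object of class `"codon_usage_table"`: `weights` (named over the
#'   61 sense codons), `counts`, and the amino-acid map used.
#' @export
codon_usage_table <- function(reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  seqs <- toupper(as.character(reference))
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  counts <- setNames(numeric(length(sense)), sense)
  for (s in seqs) {
    if (nchar(s) %% 3 != 0)
      stop("reference sequence length not divisible by 3")
    cod <- split_codons(s)
    cod <- cod[cod %in% sense]
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts[counts == 0] <- 0.5   # seqinr-style smoothing: no zero weights
  aa <- gc[sense]
  fam_max <- tapply(counts, aa, max)
  weights <- setNames(as.numeric(counts) / as.numeric(fam_max[aa]), sense)
  structure(list(weights = weights, counts = counts, amino_acids = aa),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table: 61 sense codons,",
      sum(x$counts %% 1 == 0.5), "smoothed zero counts>\n")
  invisible(x)
}

sequence_codons <- function(x) {
  if (inherits(x, "coding_sequence")) {
    cod <- split_codons(x$nucleotides)
  } else if (is.character(x) && length(x) == 1 && nchar(x[1]) > 3) {
    cod <- split_codons(toupper(x))
  } else {
    cod <- toupper(as.character(x))
  }
  if (any(nchar(cod) != 3)) stop("sequence length not a multiple of 3")
  cod
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative-adaptiveness weights of a gene's codons.
#' Following the standard definition, stop codons and codons of
#' single-codon families (ATG, TGG) are excluded, since their weight is 1
#' by construction and carries no usage information.
#'
#' @param x a [coding_sequence()], a CDS string, or a character vector of
#'   codons.
#' @param usage a [codon_usage_table()].
#' @return list with `cai`, `codon_weights` (weights of the included
#'   codons, in gene order) and `n_included`.
#' @export
compute_cai <- function(x, usage) {
  stopifnot(inherits(usage, "codon_usage_table"))
  cod <- sequence_codons(x)
  gc <- genetic_code_11()
  aa <- gc[cod]
  single <- names(table(gc[gc != "*"]))[table(gc[gc != "*"]) == 1]
  keep <- aa != "*" & !(aa %in% single)
  cod <- cod[keep]
  if (length(cod) == 0) stop("no codons left after CAI exclusions")
  w <- usage$weights[cod]
  list(cai = exp(mean(log(w))),
       codon_weights = setNames(as.numeric(w), cod),
       n_included = length(cod))
}
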