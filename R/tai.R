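#' tRNA gene-copy table for tAI
#'
#' Holds tRNA gene copy numbers per anticodon (DNA alphabet, written 5'->3',
#' so the wobble base 34 is the first character) together with the wobble
#' pairing penalties used to compute per-codon absolute adaptiveness. The
#' default penalties are the standard published constants for
#' codon-anticodon wobble: `sGU` (anticodon G34 reading a U-ending codon),
#' `sIC`/`sIA` (A34, read as inosine, reading C-/A-ending codons) and `sUG`
#' (U34 reading a G-ending codon); Watson-Crick pairs have penalty 0.
#' Species-specific re-optimisation of these constants is out of scope and
#' noted as a limitation.
#'
#' @param copies data.frame with columns `anticodon` and `copies`, or a
#'   named numeric vector (names = anticodons).
#' @param penalties named numeric vector with elements `sGU`, `sIC`, `sIA`,
#'   `sUG`, all in `[0, 1]`.
#' @return object of class `"trna_copy_table"`.
#' @export
trna_copy_table <- function(copies,
                            penalties = c(sGU = 0.41, sIC = 0.28,
                                          sIA = 0.9999, sUG = 0.68)) {
  if (is.data.frame(copies)) {
    v <- setNames(as.numeric(copies$copies), toupper(copies$anticodon))
  } else {
    v <- setNames(as.numeric(copies), toupper(names(copies)))
  }
  if (any(v < 0)) stop("tRNA copy numbers must be >= 0")
  if (any(nchar(names(v)) != 3) || any(grepl("[^ACGT]", names(v))))
    stop("anticodons must be 3-letter DNA strings (use T, not U)")
  stopifnot(all(c("sGU", "sIC", "sIA", "sUG") %in% names(penalties)))
  structure(list(copies = v, penalties = penalties),
            class = "trna_copy_table")
}

#' @export
print.trna_copy_table <- function(x, ...) {
  cat("<trna_copy_table:", length(x$copies), "anticodons,",
      sum(x$copies), "gene copies>\n")
  invisible(x)
}

# Absolute adaptiveness W_c = sum over decoding anticodons of
# (1 - penalty) * copies, for every sense codon.
codon_absolute_adaptiveness <- function(trna) {
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  p <- trna$penalties
  # pairing penalty of anticodon base 34 against codon base 3 (DNA letters);
  # NA = no decoding
  pair <- matrix(NA_real_, 4, 4,
                 dimnames = list(a34 = c("A", "C", "G", "T"),
                                 n3 = c("A", "C", "G", "T")))
  pair["A", "T"] <- 0          # Watson-Crick (I:U)
  pair["C", "G"] <- 0
  pair["G", "C"] <- 0
  pair["T", "A"] <- 0
  pair["G", "T"] <- p[["sGU"]] # G34 : U3 wobble
  pair["A", "C"] <- p[["sIC"]] # I(A)34 : C3
  pair["A", "A"] <- p[["sIA"]] # I(A)34 : A3
  pair["T", "G"] <- p[["sUG"]] # U34 : G3

  getcopy <- function(ac) {
    v <- trna$copies[ac]
    ifelse(is.na(v), 0, v)
  }
  W <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    n3 <- substr(cod, 3, 3)
    tail2 <- revcomp(substr(cod, 1, 2))  # anticodon positions 35-36
    for (a34 in c("A", "C", "G", "T")) {
      s <- pair[a34, n3]
      if (!is.na(s)) W[cod] <- W[cod] + (1 - s) * getcopy(paste0(a34, tail2))
    }
  }
  W
}

#' tRNA adaptation index (tAI)
#'
#' Per-codon absolute adaptiveness is the penalty-weighted sum of gene
#' copies over all anticodons that decode the codon under the wobble rules
#' of [trna_copy_table()]. Relative weights divide by the maximum; codons
#' with zero absolute adaptiveness receive the geometric mean of the
#' nonzero relative weights (the standard convention). tAI of a gene is the
#' geometric mean of its codons' relative weights, stop codon excluded.
#'
#' @inheritParams compute_cai
#' @param trna a [trna_copy_table()].
#' @return list with `tai`, `codon_weights` (relative weights in gene
#'   order), `relative_weights` (the full 61-codon weight vector) and
#'   `n_included`.
#' @export
compute_tai <- function(x, trna) {
  stopifnot(inherits(trna, "trna_copy_table"))
  W <- codon_absolute_adaptiveness(trna)
  if (all(W == 0)) stop("all codon adaptiveness values are zero: empty tRNA table?")
  w <- W / max(W)
  nz <- w > 0
  if (any(!nz)) w[!nz] <- exp(mean(log(w[nz])))
  cod <- sequence_codons(x)
  gc <- genetic_code_11()
  cod <- cod[gc[cod] != "*"]
  if (length(cod) == 0) stop("no sense codons in sequence")
  ww <- w[cod]
  list(tai = exp(mean(log(ww))),
       codon_weights = setNames(as.numeric(ww), cod),
       relative_weights = w,
       n_included = length(cod))
}
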