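## Central S4 containers: NirKSet (sequences + taxon metadata),
## ReferenceMap (target <-> reference residue numbering), Primer.

ALPHABETS <- list(
  protein    = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
  nucleotide = names(Biostrings::IUPAC_CODE_MAP)
)

#' Sequence collection with taxon metadata
#'
#' A `NirKSet` bundles a set of protein or nucleotide sequences with the
#' per-sequence taxon metadata (species, strain, phylum) that the
#' classification pipeline needs.  Sequences are stored as a
#' [Biostrings::BStringSet] whose names are the unique sequence ids;
#' metadata rows are kept in the same order.
#'
#' @slot seqs A [Biostrings::BStringSet] of upper-case residues.
#' @slot alphabet `"protein"` (20 amino acids plus `X`) or `"nucleotide"`
#'   (15-letter IUPAC code, which includes `N`).
#' @slot meta A `data.frame` with columns `id`, `species`, `strain`,
#'   `phylum`, `source` (`"real"` or `"synthetic"`), one row per sequence.
#'
#' @seealso [readFasta()], [writeFasta()], [seqMeta()], [sequences()]
#' @export
setClass("NirKSet",
  representation(seqs = "BStringSet", alphabet = "character",
                 meta = "data.frame"))

setValidity("NirKSet", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named by a non-empty id")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate sequence id(s): ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@alphabet) != 1L ||
      !object@alphabet %in% names(ALPHABETS))
    msg <- c(msg, "alphabet must be 'protein' or 'nucleotide'")
  else {
    bad <- .illegalResidue(as.character(object@seqs), object@alphabet)
    if (!is.null(bad))
      msg <- c(msg, sprintf(
        "illegal character '%s' for %s alphabet in record '%s' at position %d",
        bad$char, object@alphabet, ids[bad$row], bad$pos))
    if (any(Biostrings::width(object@seqs) == 0L))
      msg <- c(msg, "empty sequence(s) present")
  }
  need <- c("id", "species", "strain", "phylum", "source")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("metadata must have columns:",
                        paste(need, collapse = ", ")))
  else if (!identical(object@meta$id, unname(ids)))
    msg <- c(msg, "metadata rows must match sequence ids in order")
  if (length(msg)) msg else TRUE
})

# first illegal character over a character vector of sequences, or NULL
.illegalResidue <- function(x, alphabet) {
  allowed <- ALPHABETS[[alphabet]]
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      return(list(row = i, pos = bad[1L], char = ch[bad[1L]]))
  }
  NULL
}

#' Mapping between a target sequence and reference residue numbering
#'
#' Produced by [mapToReference()].  Records, for every residue of a target
#' protein, whether it is aligned to a reference position, inserted between
#' reference positions, or part of an N-/C-terminal overhang; and, for every
#' reference position, which target residue (if any) occupies it.
#'
#' @slot target_id Id of the mapped sequence.
#' @slot target_to_ref Integer vector, one entry per target residue: the
#'   1-based reference position it is aligned to, or `NA` for insertions and
#'   overhangs.
#' @slot ref_to_target Integer vector, one entry per reference position: the
#'   1-based target index aligned there, or `NA` where the reference position
#'   is deleted in the target.
#' @slot n_term_overhang,c_term_overhang Number of target residues before
#'   reference position 1 / after the reference end.
#' @slot score Alignment score.
#' @slot aligned_target,aligned_ref The two gapped alignment rows.
#'
#' @seealso [residueAt()], [mapToReference()]
#' @export
setClass("ReferenceMap",
  representation(target_id = "character",
                 target_to_ref = "integer", ref_to_target = "integer",
                 n_term_overhang = "integer", c_term_overhang = "integer",
                 score = "numeric",
                 aligned_target = "character", aligned_ref = "character"))

setValidity("ReferenceMap", function(object) {
  msg <- character()
  t2r <- object@target_to_ref[!is.na(object@target_to_ref)]
  if (is.unsorted(t2r, strictly = TRUE))
    msg <- c(msg, "mapped reference positions must be strictly increasing")
  r2t <- object@ref_to_target[!is.na(object@ref_to_target)]
  if (is.unsorted(r2t, strictly = TRUE))
    msg <- c(msg, "mapped target indices must be strictly increasing")
  if (object@n_term_overhang < 0L || object@c_term_overhang < 0L)
    msg <- c(msg, "overhangs must be non-negative")
  if (nchar(object@aligned_target) != nchar(object@aligned_ref))
    msg <- c(msg, "alignment rows must have equal length")
  if (length(msg)) msg else TRUE
})

#' PCR primer with IUPAC-degenerate sequence
#'
#' @slot name Primer name (e.g. `"F1aCu"`).
#' @slot sequence IUPAC nucleotide string, written 5'->3'.
#' @slot orientation `"forward"` or `"reverse"`.
#'
#' @seealso [primer()], [bestBindingSite()]
#' @export
setClass("Primer",
  representation(name = "character", sequence = "character",
                 orientation = "character"))

setValidity("Primer", function(object) {
  msg <- character()
  if (!nzchar(object@sequence))
    msg <- c(msg, "primer sequence must be non-empty")
  ch <- strsplit(toupper(object@sequence), "")[[1]]
  bad <- setdiff(ch, ALPHABETS$nucleotide)
  if (length(bad))
    msg <- c(msg, paste0("non-IUPAC symbol(s) in primer: ",
                         paste(unique(bad), collapse = ", ")))
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' Construct a Primer object
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string (5'->3'); case-insensitive.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A [Primer-class] object.
#' @examples
#' primer("F1aCu", "ATCATGGTSCTGCCGCG", "forward")
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  new("Primer", name = as.character(name),
      sequence = toupper(as.character(sequence)), orientation = orientation)
}

setMethod("show", "NirKSet", function(object) {
  cat(sprintf("NirKSet of %d %s sequence(s)\n", length(object@seqs),
              object@alphabet))
  w <- Biostrings::width(object@seqs)
  if (length(w))
    cat(sprintf("  lengths: %d-%d; phyla: %s\n", min(w), max(w),
                paste(unique(object@meta$phylum), collapse = ", ")))
})

setMethod("show", "ReferenceMap", function(object) {
  cat(sprintf(
    "ReferenceMap for '%s': %d/%d reference positions occupied,\n",
    object@target_id, sum(!is.na(object@ref_to_target)),
    length(object@ref_to_target)))
  cat(sprintf("  overhangs N=%d C=%d, score %.1f\n",
              object@n_term_overhang, object@c_term_overhang, object@score))
})

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s (%s): 5'-%s-3'\n", object@name, object@orientation,
              object@sequence))
})

#' @describeIn NirKSet-class Number of sequences in the set.
#' @param x A `NirKSet`.
#' @export
setMethod("length", "NirKSet", function(x) length(x@seqs))

#' Accessors for NirKSet
#'
#' `seqIds()` returns the sequence ids, `seqMeta()` the metadata
#' `data.frame`, and `sequences()` the residues as a named character vector.
#'
#' @param x A [NirKSet-class].
#' @return See description.
#' @name nirkset-accessors
#' @export
seqIds <- function(x) names(x@seqs)

#' @rdname nirkset-accessors
#' @export
seqMeta <- function(x) x@meta

#' @rdname nirkset-accessors
#' @export
sequences <- function(x) setNames(as.character(x@seqs), names(x@seqs))

#' @describeIn NirKSet-class Subset by index, id or logical vector.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "NirKSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  m <- x@meta[i, , drop = FALSE]
  rownames(m) <- NULL
  new("NirKSet", seqs = x@seqs[i], alphabet = x@alphabet, meta = m)
})
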