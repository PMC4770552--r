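## FASTA/TSV input-output and IUPAC nucleotide semantics.

#' Build a NirKSet from residues and metadata
#'
#' Low-level constructor used by [readFasta()] and the synthetic generator.
#' Residues are upper-cased; missing metadata fields are filled with `NA`.
#'
#' @param residues Named character vector of sequences (names = ids).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param meta Optional `data.frame` with column `id` and any of `species`,
#'   `strain`, `phylum`; matched to sequences by id.
#' @param source `"real"` or `"synthetic"`.
#' @return A [NirKSet-class].
#' @export
nirkSet <- function(residues, alphabet = c("protein", "nucleotide"),
                    meta = NULL, source = "real") {
  alphabet <- match.arg(alphabet)
  if (length(residues) == 0L) stop("no sequences supplied")
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named by an id")
  residues <- toupper(residues)
  m <- data.frame(id = unname(ids), species = NA_character_,
                  strain = NA_character_, phylum = NA_character_,
                  source = source, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    if (!"id" %in% names(meta)) stop("metadata must have an 'id' column")
    j <- match(m$id, meta$id)
    for (col in intersect(c("species", "strain", "phylum"), names(meta)))
      m[[col]] <- as.character(meta[[col]][j])
  }
  obj <- new("NirKSet",
             seqs = Biostrings::BStringSet(setNames(residues, ids)),
             alphabet = alphabet, meta = m)
  validObject(obj)
  obj
}

#' Read sequences from FASTA with an optional TSV metadata sidecar
#'
#' The first whitespace-delimited token of each FASTA header is the sequence
#' id; the remainder is ignored (free description).  Taxon metadata travels
#' in a separate tab-delimited sidecar with columns `id`, `species`,
#' `strain`, `phylum`, merged by id, because FASTA headers of public
#' sequence data are not reliably parseable.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`; characters outside the
#'   declared alphabet are rejected with the offending record and position.
#' @param metadata Optional path to the TSV sidecar.
#' @param source Provenance tag stored per record.
#' @return A [NirKSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 some nirK", "MAHHHCK", ">s2", "MAHHACK"), fa)
#' readFasta(fa, "protein")
#' @export
readFasta <- function(path, alphabet = c("protein", "nucleotide"),
                      metadata = NULL, source = "real") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- if (!is.null(metadata)) readMetadata(metadata) else NULL
  nirkSet(setNames(as.character(ss), ids), alphabet, meta, source)
}

#' @rdname readFasta
#' @param x A [NirKSet-class] to write.
#' @param width Line-wrap width for residues.
#' @export
writeFasta <- function(x, path, width = 60L) {
  stopifnot(is(x, "NirKSet"))
  Biostrings::writeXStringSet(x@seqs, path, width = width)
  invisible(path)
}

#' Read or write the taxon metadata sidecar (TSV)
#'
#' @param path Path to a tab-delimited file with header columns `id`,
#'   `species`, `strain`, `phylum`.
#' @return `readMetadata()`: a `data.frame`.
#' @export
readMetadata <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"id" %in% names(m)) stop("metadata sidecar must have an 'id' column")
  m
}

#' @rdname readMetadata
#' @param x A [NirKSet-class] whose metadata to write.
#' @export
writeMetadata <- function(x, path) {
  write.table(seqMeta(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## IUPAC nucleotide semantics ------------------------------------------------

# 15x15 logical matrix: do the base sets of two IUPAC symbols intersect?
.iupacCompatMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
      codes <- names(sets)
      mm <- matrix(FALSE, length(codes), length(codes),
                   dimnames = list(codes, codes))
      for (a in codes) for (b in codes)
        mm[a, b] <- length(intersect(sets[[a]], sets[[b]])) > 0L
      m <<- mm
    }
    m
  }
})

#' IUPAC degenerate-base compatibility
#'
#' Two IUPAC nucleotide symbols are compatible iff the base sets they denote
#' intersect: `R` (A/G) is compatible with `A`, while `S` (C/G) is not.
#' The relation is symmetric and reflexive; `N` intersects everything.
#' This is the mismatch criterion used throughout the primer analysis.
#'
#' @param a,b Single IUPAC nucleotide symbols (case-insensitive). Vectors are
#'   recycled elementwise.
#' @return Logical vector.
#' @examples
#' iupacCompatible("R", "A")  # TRUE
#' iupacCompatible("S", "A")  # FALSE
#' @export
iupacCompatible <- function(a, b) {
  m <- .iupacCompatMatrix()
  a <- toupper(a); b <- toupper(b)
  bad <- setdiff(unique(c(a, b)), rownames(m))
  if (length(bad))
    stop("non-IUPAC nucleotide symbol(s): ", paste(bad, collapse = ", "))
  m[cbind(a, b)]
}
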