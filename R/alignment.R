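# ---- DNA alignments ----------------------------------------------------------
#
# A seq_alignment is an uppercase character matrix (taxa x sites) restricted to
# the IUPAC alphabet plus '-' (gap) and '?' (missing). Ambiguity letters and N
# are retained in storage but treated as missing by the distance and parsimony
# code.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-", "?", IUPAC_AMBIG)

#' Construct a DNA sequence alignment
#'
#' @param x character matrix (rows = taxa, columns = sites) or a named
#'   character vector of equal-length sequence strings.
#' @return an object of class `seq_alignment`: an uppercase character matrix
#'   with unique row names.
#' @examples
#' aln <- seq_alignment(c(t1 = "ACGT", t2 = "AC-T"))
#' @export
seq_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequences must have unique names", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("unequal length: sequences of length ",
           paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
    x <- do.call(rbind, lapply(strsplit(x, ""), identity))
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("alignment rows must carry unique taxon names", call. = FALSE)
  x[] <- toupper(x)
  bad <- matrix(!(x %in% DNA_ALPHABET), nrow(x))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown symbol '", x[bad][1], "' in taxon '", rownames(x)[w[1]],
         "' at site ", w[2], call. = FALSE)
  }
  structure(x, class = c("seq_alignment", "matrix", "array"))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' Read a DNA alignment
#'
#' FASTA files are read with ape; NEXUS files must carry a DATA or CHARACTERS
#' block with `datatype=dna`. Ragged rows and symbols outside the IUPAC
#' alphabet are rejected with explicit errors; declared `ntax`/`nchar` must
#' match the matrix.
#'
#' @param path file path.
#' @param format `"fasta"` or `"nexus"`; the default guesses from the
#'   extension.
#' @return a [seq_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    recs <- ape::read.FASTA(path)
    seqs <- toupper(vapply(as.character(recs), paste, character(1),
                           collapse = ""))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("unequal length: FASTA records of length ",
           paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
    return(seq_alignment(seqs))
  }
  txt <- readLines(path, warn = FALSE)
  nt <- .nexus_declared(txt, "ntax")
  nc <- .nexus_declared(txt, "nchar")
  recs <- ape::read.nexus.data(path)
  seqs <- toupper(vapply(recs, paste, character(1), collapse = ""))
  aln <- seq_alignment(seqs)
  if (!is.na(nt) && nt != nrow(aln))
    stop("NEXUS declares ntax=", nt, " but matrix has ", nrow(aln), " taxa",
         call. = FALSE)
  if (!is.na(nc) && nc != ncol(aln))
    stop("NEXUS declares nchar=", nc, " but matrix has ", ncol(aln), " sites",
         call. = FALSE)
  aln
}

.nexus_declared <- function(lines, key) {
  m <- regmatches(lines, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), lines,
                                 perl = TRUE))
  m <- unlist(m)
  if (!length(m)) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m[1]))
}

#' Write an alignment to FASTA or NEXUS
#'
#' @param aln a [seq_alignment()].
#' @param path output file.
#' @param format `"fasta"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "seq_alignment"))
  rows <- apply(unclass(aln), 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(paste0(">", names(rows), "\n", rows), path)
  } else {
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", nrow(aln), " NCHAR=", ncol(aln), ";"),
      "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
      "  MATRIX",
      paste0("    ", format(names(rows)), "  ", rows),
      "  ;",
      "END;"), path)
  }
  invisible(path)
}
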