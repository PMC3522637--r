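# ---- morphological character matrices ----------------------------------------
#
# A morph_matrix is an integer matrix (taxa x characters), states coded 0..9,
# NA for missing ('?'). Characters are unordered and unweighted.

#' Construct a morphological character matrix
#'
#' @param x integer matrix (rows = taxa) with unique row names; `NA` codes a
#'   missing observation. States must lie in 0..9.
#' @return an object of class `morph_matrix`.
#' @examples
#' m <- morph_matrix(rbind(t1 = c(0L, 1L), t2 = c(0L, NA), t3 = c(1L, 1L)))
#' @export
morph_matrix <- function(x) {
  if (!is.matrix(x)) stop("morphology must be a matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("morphology rows must carry unique taxon names", call. = FALSE)
  storage.mode(x) <- "integer"
  v <- x[!is.na(x)]
  if (any(v < 0L | v > 9L))
    stop("morphological states must be coded 0..9", call. = FALSE)
  structure(x, class = c("morph_matrix", "matrix", "array"))
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("Morphological matrix:", nrow(x), "taxa x", ncol(x), "characters (",
      sum(is.na(x)), "missing cells )\n")
  invisible(x)
}

#' Read a morphological matrix
#'
#' CSV input has taxa in the first column and one character per remaining
#' column; NEXUS input must be a `datatype=standard` DATA/CHARACTERS block
#' with one digit per character and `?` for missing. Any symbol other than a
#' digit or `?` is rejected.
#'
#' @param path file path.
#' @param format `"csv"` or `"nexus"` (default guesses from extension).
#' @return a [morph_matrix()].
#' @export
read_morph_matrix <- function(path, format = c("auto", "csv", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
    taxa <- df[[1]]
    cells <- as.matrix(df[, -1, drop = FALSE])
    rownames(cells) <- taxa
  } else {
    txt <- readLines(path, warn = FALSE)
    recs <- ape::read.nexus.data(path)
    cells <- do.call(rbind, recs)
    nt <- .nexus_declared(txt, "ntax")
    nc <- .nexus_declared(txt, "nchar")
    if (!is.na(nt) && nt != nrow(cells))
      stop("NEXUS declares ntax=", nt, " but matrix has ", nrow(cells),
           call. = FALSE)
    if (!is.na(nc) && nc != ncol(cells))
      stop("NEXUS declares nchar=", nc, " but matrix has ", ncol(cells),
           call. = FALSE)
  }
  bad <- matrix(!(cells %in% c(as.character(0:9), "?", NA)), nrow(cells))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid state symbol '", cells[bad][1], "' for taxon '",
         rownames(cells)[w[1]], "', character ", w[2], call. = FALSE)
  }
  cells[cells == "?"] <- NA
  m <- matrix(as.integer(cells), nrow = nrow(cells),
              dimnames = list(rownames(cells), colnames(cells)))
  morph_matrix(m)
}

#' Write a morphological matrix
#'
#' @param m a [morph_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"nexus"` (standard datatype).
#' @return `path`, invisibly.
#' @export
write_morph_matrix <- function(m, path, format = c("csv", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "morph_matrix"))
  chr <- matrix(as.character(unclass(m)), nrow = nrow(m),
                dimnames = dimnames(m))
  chr[is.na(chr)] <- "?"
  if (format == "csv") {
    df <- data.frame(taxon = rownames(m), chr, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- apply(chr, 1, paste, collapse = "")
    sym <- sort(unique(as.vector(chr[chr != "?"])))
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", nrow(m), " NCHAR=", ncol(m), ";"),
      paste0("  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"",
             paste(sym, collapse = ""), "\";"),
      "  MATRIX",
      paste0("    ", format(rownames(m)), "  ", rows),
      "  ;",
      "END;"), path)
  }
  invisible(path)
}
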