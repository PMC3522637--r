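# ---- labeled distance matrices -----------------------------------------------
#
# The shared currency of the distances, patrocladistics and UPGMA code: a
# symmetric numeric matrix with zero diagonal and fixed label order. NA_real_
# is the saturation / undefined sentinel (documented; upgma() refuses it).

#' Construct a labeled distance matrix
#'
#' @param m square numeric matrix with identical row and column names,
#'   symmetric with zero diagonal. `NA` entries are permitted and denote
#'   saturated/undefined pairs.
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must carry identical row/column labels",
         call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate labels", call. = FALSE)
  mt <- t(m)
  if (!identical(is.na(m), is.na(mt)))
    stop("distance matrix must be symmetric", call. = FALSE)
  off <- !is.na(m) & !is.na(mt)
  if (any(abs(m[off] - mt[off]) > 1e-9))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12, na.rm = TRUE))
    stop("distance matrix must have zero diagonal", call. = FALSE)
  if (any(m[!is.na(m)] < 0))
    stop("distances must be nonnegative", call. = FALSE)
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix over", nrow(x), "taxa",
      if (anyNA(x)) paste0("(", sum(is.na(x[upper.tri(x)])),
                           " saturated/undefined pairs)"), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Write a distance matrix to disk
#'
#' @param dm a [dist_matrix()].
#' @param path output file.
#' @param format `"csv"` (labels in first row/column) or `"phylip"`
#'   (square PHYLIP: count line, then label + row per taxon).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  dm <- dist_matrix(unclass(dm))  # re-validate; refuses non-symmetric input
  if (format == "csv") {
    utils::write.csv(as.data.frame(unclass(dm)), path, row.names = TRUE)
  } else {
    rows <- apply(unclass(dm), 1, function(r)
      paste(formatC(r, digits = 10, format = "g"), collapse = " "))
    writeLines(c(as.character(nrow(dm)),
                 paste(format(rownames(dm), width = 10), rows)), path)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path file path.
#' @param format `"csv"` or `"phylip"`.
#' @return a [dist_matrix()].
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    colnames(m) <- colnames(df)
  } else {
    lines <- readLines(path, warn = FALSE)
    n <- as.integer(trimws(lines[1]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
    labels <- vapply(parts, `[`, character(1), 1)
    m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(m) <- list(labels, labels)
  }
  dist_matrix(m)
}
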