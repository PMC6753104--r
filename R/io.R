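# Delimited-text I/O for matrices, coordinates, partitions and cohort
# manifests. All numeric output uses %.17g so write/read round-trips are
# bitwise exact; non-edges are written as 0 in weight files and "inf" in
# length files.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else "\t"
}

#' Read a numeric matrix from delimited text
#'
#' Accepts CSV or TSV with an optional header row and label column (detected
#' from non-numeric fields). The strings `inf`/`Inf` parse to `Inf`.
#'
#' @param path file path.
#' @return numeric matrix, with dimnames when labels are present.
#' @export
read_matrix <- function(path) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  numlike <- function(x) {
    x <- tolower(trimws(x))
    x == "" | x == "inf" | x == "-inf" |
      !is.na(suppressWarnings(as.numeric(x)))
  }
  has_header <- !all(numlike(first))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           row.names = if (has_header) 1 else NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  m <- apply(as.matrix(raw), c(1, 2), function(x) {
    x <- trimws(x)
    if (tolower(x) == "inf") Inf
    else if (tolower(x) == "-inf") -Inf
    else as.numeric(x)
  })
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("non-numeric entry at cell (%d, %d) of %s",
                 bad[1, 1], bad[1, 2], path))
  }
  if (!has_header) dimnames(m) <- NULL
  m
}

#' Write a numeric matrix to delimited text
#'
#' Full float precision (`%.17g`); `Inf` is written as `inf`. The delimiter
#' follows the file extension (`.csv` comma, otherwise tab).
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param labels optional row/column labels to write as a header row and a
#'   leading label column.
#' @export
write_matrix <- function(m, path, labels = rownames(m)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.infinite(x) & x > 0] <- "inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    out
  }
  rows <- apply(m, 1, function(r) paste(fmt(r), collapse = sep))
  if (!is.null(labels)) {
    rows <- paste(labels, rows, sep = sep)
    rows <- c(paste(c("", labels), collapse = sep), rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a connectome matrix file as a weighted network
#'
#' @param path delimited text file holding a square nonnegative matrix,
#'   optionally with a label header row/column.
#' @param directed logical; if `FALSE`, input asymmetric beyond 1e-9 is
#'   rejected.
#' @param coordinates optional coordinate table path (see
#'   [read_coordinates()]) or matrix.
#' @return a validated `weighted_network`.
#' @export
read_network <- function(path, directed = FALSE, coordinates = NULL) {
  m <- read_matrix(path)
  if (nrow(m) != ncol(m)) {
    stop("non-square matrix in ", path, ": ", nrow(m), " x ", ncol(m))
  }
  if (is.character(coordinates)) {
    coordinates <- read_coordinates(coordinates, labels = rownames(m))
  }
  weighted_network(m, coordinates = coordinates, directed = directed)
}

#' Write a weighted network to delimited text
#' @param net a `weighted_network`.
#' @param path output path (`.csv` for comma, otherwise tab).
#' @export
write_network <- function(net, path) {
  stopifnot_network(net)
  write_matrix(net$weights, path, labels = net$labels)
}

#' Read node coordinates
#'
#' Delimited text with columns `label, x, y[, z]` (header optional).
#'
#' @param path file path.
#' @param labels optional node ordering to align rows to.
#' @return numeric matrix with row names.
#' @export
read_coordinates <- function(path, labels = NULL) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE)
  xyz <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(xyz) <- "double"
  rownames(xyz) <- as.character(tab[[1]])
  if (!is.null(labels)) {
    missing <- setdiff(labels, rownames(xyz))
    if (length(missing) > 0) {
      stop("coordinates missing for nodes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    xyz <- xyz[labels, , drop = FALSE]
  }
  xyz
}

#' Write node coordinates
#' @param coordinates numeric matrix with row names (labels).
#' @param path output path.
#' @export
write_coordinates <- function(coordinates, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  hdr <- paste(c("label", c("x", "y", "z")[seq_len(ncol(coordinates))]),
               collapse = sep)
  rows <- paste(rownames(coordinates),
                apply(coordinates, 1,
                      function(r) paste(sprintf("%.17g", r), collapse = sep)),
                sep = sep)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a node-to-subsystem partition
#'
#' Two-column delimited text `label, subsystem` (header optional).
#' @param path file path.
#' @return named character vector mapping node label to subsystem.
#' @export
read_partition <- function(path) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (tolower(tab[1, 1]) %in% c("label", "node")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Read a cohort manifest
#'
#' One matrix path per line (relative paths resolved against the manifest's
#' directory); subject order is manifest order. A directory path instead
#' globs `*.csv`/`*.tsv` in lexicographic order.
#'
#' @param path manifest file or directory.
#' @return character vector of matrix paths.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(csv|tsv|txt)$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no matrix files found in ", path)
    return(files)
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty manifest: ", path)
  base <- dirname(path)
  ifelse(file.exists(lines), lines, file.path(base, lines))
}
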