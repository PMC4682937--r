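#' Construct a presence/absence marker matrix
#'
#' The universal substrate of the package: an accessions x markers grid of
#' dominant-marker calls, each cell 1 (band present), 0 (band absent) or `NA`
#' (missing). Stored as a plain integer matrix with accession IDs as row names
#' and marker IDs as column names, plus the class `"marker_matrix"`.
#'
#' @param scores numeric/integer matrix with values in \{0, 1, NA\}.
#' @param accession_ids optional character vector of unique row labels;
#'   defaults to existing row names.
#' @param marker_ids optional character vector of unique column labels;
#'   defaults to existing column names.
#' @return an integer matrix of class `"marker_matrix"`, rows = accessions.
#' @examples
#' m <- marker_matrix(rbind(a1 = c(m1 = 1, m2 = 0), a2 = c(1, NA)))
#' @export
marker_matrix <- function(scores, accession_ids = rownames(scores),
                          marker_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(nrow(scores)))
  if (is.null(marker_ids))   marker_ids   <- paste0("mk", seq_len(ncol(scores)))
  if (length(accession_ids) != nrow(scores) || length(marker_ids) != ncol(scores))
    stop("ID vectors do not match matrix dimensions")
  if (anyDuplicated(accession_ids))
    stop("duplicate accession IDs: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker IDs: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  bad <- !(scores %in% c(0L, 1L)) & !is.na(scores)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("score not in {0,1,NA} at row %d, column %d: %s",
                 (i - 1L) %% nrow(scores) + 1L, (i - 1L) %/% nrow(scores) + 1L,
                 format(scores[i])))
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(accession_ids, marker_ids)
  class(scores) <- c("marker_matrix", "matrix", "array")
  scores
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d accessions x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a 0/1 marker matrix from a delimited text file
#'
#' Expects a rectangular table with a header row of marker IDs and accession
#' IDs in the first column (or the transpose, with `transposed = TRUE`).
#' Any of the tokens in `missing_tokens` is read as a missing call.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param missing_tokens character vector of tokens parsed as missing.
#' @param transposed logical; `TRUE` if the file is markers x accessions.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, sep = "\t",
                               missing_tokens = c("NA", "-", ""),
                               transposed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("marker matrix file needs a header and >=1 data row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  # header may or may not carry a stub for the ID column
  body_w <- widths[-1L]
  if (length(unique(body_w)) != 1L)
    stop("ragged rows: widths ", paste(unique(body_w), collapse = ","),
         " after header")
  nc <- body_w[1L]
  header <- cells[[1L]]
  if (length(header) == nc) header <- header[-1L]
  else if (length(header) != nc - 1L)
    stop("header width ", length(header) + 1L, " inconsistent with data rows")
  row_ids <- vapply(cells[-1L], `[[`, "", 1L)
  raw <- t(vapply(cells[-1L], function(r) r[-1L], character(nc - 1L)))
  parse_cell <- function(tok, i, j) {
    tok <- trimws(tok)
    if (tok %in% missing_tokens) return(NA_integer_)
    if (tok == "0") return(0L)
    if (tok == "1") return(1L)
    stop(sprintf("unparseable score '%s' at data row %d ('%s'), column %d ('%s')",
                 tok, i, row_ids[i], j, header[j]))
  }
  vals <- matrix(NA_integer_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw)))
    vals[, j] <- vapply(seq_len(nrow(raw)),
                        function(i) parse_cell(raw[i, j], i, j), integer(1L))
  if (transposed) {
    marker_matrix(t(vals), accession_ids = header, marker_ids = row_ids)
  } else {
    marker_matrix(vals, accession_ids = row_ids, marker_ids = header)
  }
}

#' Write a marker matrix to a delimited text file
#'
#' Missing calls are written as `"NA"`. [read_marker_matrix()] on the result
#' reproduces the input exactly.
#'
#' @param x a [marker_matrix()].
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_marker_matrix <- function(x, path, sep = "\t") {
  out <- rbind(c("accession", colnames(x)),
               cbind(rownames(x), ifelse(is.na(x), "NA", as.character(x))))
  writeLines(apply(out, 1L, paste, collapse = sep), path)
  invisible(path)
}
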