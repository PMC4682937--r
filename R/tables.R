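#' Read a genetic map table
#'
#' Tab-separated table with columns `marker`, `lg`, `cm` (and optionally
#' `phase`). Positions must be nonnegative centimorgan floats; duplicate
#' marker IDs are rejected.
#'
#' @param path file path.
#' @return data frame sorted by `lg` then `cm`.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "lg", "cm")
  if (!all(need %in% names(m)))
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$marker))
    stop("duplicate marker(s) in map: ",
         paste(unique(m$marker[duplicated(m$marker)]), collapse = ", "))
  if (any(m$cm < 0, na.rm = TRUE)) stop("cM positions must be nonnegative")
  m[order(m$lg, m$cm, m$marker), , drop = FALSE]
}

#' Write a genetic map table
#'
#' @param map data frame with columns `marker`, `lg`, `cm`, ...
#' @param path output file path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a physical anchor table
#'
#' Tab-separated table with columns `marker`, `chr`, `bp` (1-based physical
#' coordinates on the diploid reference). May additionally carry genetic
#' columns (`lg`, `cm`) for joint use in the synteny comparison.
#'
#' @param path file path.
#' @return data frame; one row per marker.
#' @export
read_anchors <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chr", "bp")
  if (!all(need %in% names(a)))
    stop("anchor table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(a$marker))
    stop("duplicate marker(s) in anchors: ",
         paste(unique(a$marker[duplicated(a$marker)]), collapse = ", "))
  if (any(a$bp < 1, na.rm = TRUE)) stop("bp coordinates are 1-based (>= 1)")
  a
}

#' Join a genetic map with physical anchors
#'
#' @param map data frame from [read_genetic_map()].
#' @param anchors data frame from [read_anchors()].
#' @return data frame with `marker`, `lg`, `cm`, `chr`, `bp` (NA where a
#'   marker lacks a physical anchor).
#' @export
join_anchors <- function(map, anchors) {
  i <- match(map$marker, anchors$marker)
  out <- map[, c("marker", "lg", "cm")]
  out$chr <- anchors$chr[i]
  out$bp <- anchors$bp[i]
  out
}
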