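#' Read a numeric matrix from CSV
#'
#' Plain comma-separated numeric matrix, no row or column names; comment
#' lines starting with `#` (used for convention headers) are skipped.
#' Ragged or non-numeric input raises an error naming the offending line.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data in ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  nc <- lengths(parts)
  if (length(unique(nc)) != 1)
    stop("ragged rows in ", path, ": line ", lineno[which(nc != nc[1])[1]])
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric cell in ", path, ": line ", lineno[bad[1]])
  do.call(rbind, vals)
}

#' Write a numeric matrix to CSV
#'
#' @param m Matrix or vector (written as one column).
#' @param path File path.
#' @param header Optional comment line (written prefixed with `#`),
#'   e.g. naming the sign or normalization convention.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, header = NULL) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read resting-state network masks
#'
#' Two-column whitespace- or comma-separated text: network name and
#' 0-based region index. Returns 1-based index sets.
#'
#' @param path File path.
#' @return Named list of sorted integer vectors.
#' @export
read_rsn_masks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  if (any(lengths(parts) != 2))
    stop("expected two columns (network, 0-based index) in ", path)
  net <- vapply(parts, `[[`, character(1), 1)
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(idx)) stop("non-integer region index in ", path)
  lapply(split(idx + 1L, net), sort)
}

#' Write resting-state network masks
#'
#' @param masks Named list of 1-based integer vectors.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rsn_masks <- function(masks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# network region_index_0based", con)
  for (nm in names(masks))
    writeLines(sprintf("%s %d", nm, masks[[nm]] - 1L), con)
  invisible(path)
}

#' Write a run manifest
#'
#' Flat `key: value` text file recording seeds, parameter values, and the
#' files a pipeline run produced.
#'
#' @param entries Named list of atomic values (vectors are
#'   comma-collapsed).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(!is.null(names(entries)), all(nzchar(names(entries))))
  fmt1 <- function(v) {
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE)
    else as.character(v)
  }
  lines <- vapply(names(entries), function(k)
    sprintf("%s: %s", k, paste(fmt1(entries[[k]]), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path File path.
#' @return Named list of character values (split on commas).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort Tibble as produced by [gen_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path File path.
#' @return Tibble with the [gen_cohort()] columns.
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
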