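#' Read CLIP read alignments from BED6
#'
#' The BED name column is expected to encode read provenance as
#' `condition:replicate:read_id` (biological-complexity and per-condition
#' counting need replicate labels, and BED has no dedicated column for them).
#' Intervals are 0-based half-open; input order is preserved.
#'
#' @param path BED6 file path.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `condition`, `replicate`, `read_id`.
#' @export
read_bed6 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), condition = character(),
                  replicate = integer(), read_id = character()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop(sprintf("malformed BED6 line %d: expected 6 fields, got %d",
                 which(nf != 6)[1], nf[nf != 6][1]))
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED6 line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]))
  }
  if (any(start >= end)) {
    stop(sprintf("malformed BED6 line %d: start >= end", which(start >= end)[1]))
  }
  if (any(!m[, 6] %in% c("+", "-"))) {
    stop(sprintf("malformed BED6 line %d: strand must be + or -",
                 which(!m[, 6] %in% c("+", "-"))[1]))
  }
  name_parts <- stringr::str_split_fixed(m[, 4], ":", 3)
  if (any(name_parts[, 1] == "" | name_parts[, 2] == "" | name_parts[, 3] == "")) {
    stop(sprintf(
      "malformed BED6 line %d: name must be condition:replicate:read_id",
      which(name_parts[, 1] == "" | name_parts[, 2] == "" |
              name_parts[, 3] == "")[1]))
  }
  replicate <- suppressWarnings(as.integer(name_parts[, 2]))
  if (anyNA(replicate)) {
    stop(sprintf("malformed BED6 line %d: replicate must be an integer",
                 which(is.na(replicate))[1]))
  }
  tibble(
    chrom = m[, 1], start = start, end = end, strand = m[, 6],
    condition = name_parts[, 1], replicate = replicate,
    read_id = name_parts[, 3]
  )
}

#' @rdname read_bed6
#' @param reads A read tibble as returned by `read_bed6()`.
#' @export
write_bed6 <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\t%s:%d:%s\t0\t%s",
                   reads$chrom, reads$start, reads$end,
                   reads$condition, reads$replicate, reads$read_id,
                   reads$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by any of `chrom`, `start` and the first `*_id` column that
#' are present, floating-point columns are rendered with fixed precision, and
#' missing values become the literal `NA`, so identical inputs produce
#' byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param digits Number of significant digits for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(records, path, digits = 6) {
  records <- as_tibble(records)
  keys <- intersect(c("chrom", "start"), names(records))
  id_col <- grep("(^|_)id$", names(records), value = TRUE)
  keys <- c(keys, head(id_col, 1))
  if (length(keys)) records <- arrange(records, across(all_of(keys)))
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.*g", digits, x))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    body <- do.call(paste, c(lapply(records, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a BedGraph conservation track
#'
#' Tolerates unsorted input and `track`/comment lines. Scores are per-base
#' values over 0-based half-open intervals.
#'
#' @param path BedGraph file path.
#' @return Tibble with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), score = double()))
  }
  m <- stringr::str_split_fixed(lines, "[ \t]+", 4)
  tibble(chrom = m[, 1], start = as.integer(m[, 2]),
         end = as.integer(m[, 3]), score = as.double(m[, 4]))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  sets
}
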