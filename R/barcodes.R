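# Barcode mapping: hash lookup of designed barcodes and all their Hamming-1
# mutants, so reads are assigned with at-most-one-substitution tolerance.
# For a designed set with pairwise distance >= 3 the Hamming-1 balls are
# disjoint and mapping is unambiguous; closer inputs have their shared
# mutants logged as collisions and excluded (never guessed).

#' Build a single-mismatch barcode lookup index
#'
#' @param barcodes character vector of equal-length DNA barcodes
#' @param variant_ids ids mapped to; defaults to the barcodes themselves
#' @return object of class `barcode_index`: hash keys (each barcode plus its
#'   `3 * L` single-substitution mutants), target ids, and a collision log of
#'   mutants claimed by more than one barcode
#' @export
build_index <- function(barcodes, variant_ids = barcodes) {
  if (length(barcodes) != length(variant_ids))
    stop("barcodes and variant_ids must align", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("validation error: duplicate barcodes", call. = FALSE)
  len <- unique(nchar(barcodes))
  if (length(len) != 1L)
    stop("validation error: barcodes must be the same length", call. = FALSE)
  if (any(grepl("[^ACGT]", barcodes)))
    stop("validation error: barcodes must be DNA (A/C/G/T)", call. = FALSE)

  n <- length(barcodes)
  neigh <- lapply(barcodes, hamming1_neighbours)
  keys <- c(barcodes, unlist(neigh))
  ids <- c(variant_ids, rep(variant_ids, each = 3L * len))
  exact <- rep(c(TRUE, FALSE), c(n, n * 3L * len))

  # a mutant key equal to a designed barcode, or claimed by two different
  # barcodes, is ambiguous; designed (exact) keys always win
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  collisions <- character(0)
  if (any(dup)) {
    amb <- tapply(ids[dup], keys[dup], function(x) length(unique(x)) > 1L)
    collisions <- names(amb)[amb]
    drop <- keys %in% collisions & !exact
    keys <- keys[!drop]; ids <- ids[!drop]; exact <- exact[!drop]
    keep1 <- !duplicated(keys)
    # order so exact keys survive deduplication
    o <- order(!exact)
    keys <- keys[o]; ids <- ids[o]
    keep1 <- !duplicated(keys)
    keys <- keys[keep1]; ids <- ids[keep1]
    collisions <- setdiff(collisions, barcodes)
  }
  structure(list(keys = keys, ids = ids, barcode_len = len,
                 n_barcodes = n, collisions = collisions),
            class = "barcode_index")
}

#' Look up barcodes in an index
#'
#' @param index a `barcode_index`
#' @param queries character vector of candidate barcode sequences
#' @return character vector of variant ids (NA where unmapped)
#' @export
lookup_barcodes <- function(index, queries) {
  index$ids[match(queries, index$keys)]
}

#' @export
print.barcode_index <- function(x, ...) {
  cat("barcode_index:", x$n_barcodes, "barcodes of length", x$barcode_len,
      "|", length(x$keys), "keys |", length(x$collisions),
      "collision mutants excluded\n")
  invisible(x)
}

#' Read a (possibly gzipped) FASTQ file
#'
#' Minimal strict 4-line-record reader; malformed records raise a parse
#' error carrying the record number.
#' @param path FASTQ path (`.gz` allowed)
#' @return character vector of read sequences
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop("parse error: truncated FASTQ record ",
         length(lines) %/% 4L + 1L, " in ", path, call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- which(substr(lines[idx], 1L, 1L) != "@")
  if (length(bad_hdr) > 0L)
    stop("parse error: FASTQ record ", bad_hdr[1L],
         " missing '@' header in ", path, call. = FALSE)
  bad_sep <- which(substr(lines[idx + 2L], 1L, 1L) != "+")
  if (length(bad_sep) > 0L)
    stop("parse error: FASTQ record ", bad_sep[1L],
         " missing '+' separator in ", path, call. = FALSE)
  lines[idx + 1L]
}

#' Default barcode locator
#'
#' Barcodes are located by two fixed flanking anchors with a fixed-offset
#' fallback (amplicon structure is constant but configurable).
#'
#' @param anchor_up,anchor_down flanking anchor sequences
#' @param offset 0-based fallback offset of the barcode in the read
#' @return locator list consumed by [count_reads()]
#' @export
barcode_locator <- function(anchor_up = READ_ANCHOR_UP,
                            anchor_down = READ_ANCHOR_DOWN,
                            offset = nchar(anchor_up)) {
  list(anchor_up = anchor_up, anchor_down = anchor_down, offset = offset)
}

#' Count reads per variant from FASTQ files
#'
#' Locates the barcode in each read (anchor match, fixed-offset fallback)
#' and maps it through the index; reads at Hamming distance > 1 from every
#' designed barcode, or whose mutant key was excluded as a collision, count
#' as unmapped. Total reads are conserved: mapped + unmapped = n_reads.
#'
#' @param paths named character vector of FASTQ paths (names = sample ids)
#' @param index a [build_index()] result
#' @param locator a [barcode_locator()]
#' @param drop_n drop reads containing N before mapping (still tallied as
#'   unmapped)
#' @return list with `counts` (data.frame variants x samples), `unmapped`
#'   (per-sample tally) and `n_reads`
#' @export
count_reads <- function(paths, index, locator = barcode_locator(),
                        drop_n = FALSE) {
  if (is.null(names(paths)))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  all_ids <- unique(index$ids)
  counts <- matrix(0L, nrow = length(all_ids), ncol = length(paths),
                   dimnames = list(all_ids, names(paths)))
  unmapped <- setNames(integer(length(paths)), names(paths))
  n_reads <- setNames(integer(length(paths)), names(paths))
  for (s in names(paths)) {
    reads <- read_fastq(paths[[s]])
    n_reads[[s]] <- length(reads)
    if (length(reads) == 0L) next
    if (drop_n) {
      has_n <- grepl("N", reads, fixed = TRUE)
    } else has_n <- rep(FALSE, length(reads))
    bcs <- .locate_barcodes(reads, locator, index$barcode_len)
    hits <- lookup_barcodes(index, bcs)
    hits[has_n] <- NA_character_
    ok <- !is.na(hits)
    tab <- table(hits[ok])
    counts[names(tab), s] <- counts[names(tab), s] + as.integer(tab)
    unmapped[[s]] <- sum(!ok)
  }
  list(counts = data.frame(variant_id = all_ids, counts,
                           row.names = NULL, check.names = FALSE,
                           stringsAsFactors = FALSE),
       unmapped = unmapped, n_reads = n_reads)
}

#' @noRd
.locate_barcodes <- function(reads, locator, len) {
  pos <- regexpr(locator$anchor_up, reads, fixed = TRUE)
  start <- ifelse(pos > 0L, pos + nchar(locator$anchor_up),
                  locator$offset + 1L)
  substr(reads, start, start + len - 1L)
}

#' Assemble a count table from per-sample read counts
#'
#' @param counted result of [count_reads()] over RNA/DNA samples whose names
#'   follow the `dna_t0` / `rna_t<t>` convention
#' @return count-table data.frame (same schema as [simulate_counts()])
#' @export
counts_to_table <- function(counted) {
  df <- counted$counts
  needed <- c("dna_t0")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0L)
    stop("schema error: missing sample column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
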