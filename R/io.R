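#' Read a dense heatmap file
#'
#' Reads the tab-delimited dense dialect used by classic Hi-C heatmap
#' tooling: one header row and one header column of bin labels of the form
#' `name|assembly|chrom:start-end`, numeric body cells, `NA` for masked
#' entries.
#'
#' @param path Path to the dense matrix file.
#' @param normalization Normalisation state to record on the map.
#' @return A [contact_map()].
#' @export
read_dense_matrix <- function(path, normalization = "raw") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort("Dense matrix file needs a header and at least one row.")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  if (any(vapply(cells, length, 1L) != width)) {
    abort("Ragged rows: all lines must have the same number of fields.")
  }
  col_hdr <- cells[[1]][-1]
  row_hdr <- vapply(cells[-1], `[[`, "", 1L)
  body <- do.call(rbind, lapply(cells[-1], function(x) {
    suppressWarnings(as.numeric(x[-1]))
  }))
  raw_cells <- do.call(rbind, lapply(cells[-1], function(x) x[-1]))
  bad <- is.na(body) & !(toupper(raw_cells) %in% c("NA", "NAN", ""))
  if (any(bad)) abort("Non-numeric body cell that is not 'NA'.")

  rows <- parse_bin_headers(row_hdr)
  cols <- parse_bin_headers(col_hdr)
  contact_map(body, rows$region, cols$region, bin_size = rows$bin_size,
              normalization = normalization, assembly = rows$assembly)
}

parse_bin_headers <- function(hdr) {
  m <- regmatches(hdr, regexec("^([^|]*)\\|([^|]*)\\|([^:]+):([0-9]+)-([0-9]+)$", hdr))
  ok <- vapply(m, length, 1L) == 6L
  if (!all(ok)) {
    abort(sprintf("Malformed bin header '%s' (want name|assembly|chrom:start-end).",
                  hdr[!ok][1]))
  }
  chrom <- vapply(m, `[[`, "", 4L)
  start <- as.numeric(vapply(m, `[[`, "", 5L))
  end <- as.numeric(vapply(m, `[[`, "", 6L))
  if (length(unique(chrom)) != 1L) abort("Bin headers span multiple chromosomes.")
  sizes <- end - start
  if (length(unique(sizes)) != 1L) abort("Bin headers have unequal bin sizes.")
  if (length(start) > 1L && any(start[-1] != end[-length(end)])) {
    abort("Bin coordinates are not monotone and contiguous.")
  }
  list(region = region(chrom[1], start[1], end[length(end)]),
       bin_size = sizes[1], assembly = vapply(m, `[[`, "", 3L)[1])
}

#' Write a dense heatmap file
#'
#' Inverse of [read_dense_matrix()]; masked entries are written as `NA`.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  hdr <- function(axis) {
    b <- map_bins(map, axis)
    sprintf("bin%d|%s|%s:%s-%s", b$bin - 1L, map$assembly, b$chrom,
            format(b$start, scientific = FALSE, trim = TRUE),
            format(b$end, scientific = FALSE, trim = TRUE))
  }
  rh <- hdr("row")
  body <- apply(map$values, 1L, function(x) {
    paste(ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE,
                                        digits = 15)),
          collapse = "\t")
  })
  writeLines(c(paste(c(sprintf("%dx%d", nrow(map$values), ncol(map$values)),
                       hdr("col")), collapse = "\t"),
               paste(rh, body, sep = "\t")),
             path)
  invisible(path)
}

#' Read a sparse triplet contact file
#'
#' Reads the sparse "matrix + bed" dialect produced by standard Hi-C
#' binning pipelines: a BED4 bin table (`chrom start end id`) and a
#' whitespace-delimited triplet file (`id_i id_j count`, upper triangle).
#' Counts are mirrored to both `(i, j)` and `(j, i)` on densification;
#' absent pairs are zero.
#'
#' @param matrix_path Path to the triplet file.
#' @param bed_path Path to the bin table.
#' @param chrom Chromosome to materialise when the bin table covers more
#'   than one (default: the single chromosome present).
#' @param normalization Normalisation state to record.
#' @return A dense symmetric [contact_map()].
#' @export
read_sparse_triplet <- function(matrix_path, bed_path, chrom = NULL,
                                normalization = "raw") {
  bed <- utils::read.table(bed_path, header = FALSE, col.names = c("chrom", "start", "end", "id"),
                           colClasses = c("character", "numeric", "numeric", "integer"))
  if (is.null(chrom)) {
    if (length(unique(bed$chrom)) != 1L) {
      abort("Bin table covers multiple chromosomes; pass `chrom`.")
    }
    chrom <- bed$chrom[1]
  }
  all_ids <- as.character(bed$id)
  bed <- bed[bed$chrom == chrom, , drop = FALSE]
  if (nrow(bed) == 0L) abort(sprintf("No bins on chromosome '%s'.", chrom))
  bed <- bed[order(bed$start), , drop = FALSE]
  sizes <- bed$end - bed$start
  if (length(unique(sizes)) != 1L) abort("Unequal bin sizes in bin table.")
  if (nrow(bed) > 1L && any(bed$start[-1] != bed$end[-nrow(bed)])) {
    abort("Bin table is not contiguous.")
  }
  n <- nrow(bed)
  idx <- setNames(seq_len(n), bed$id)

  trip <- tryCatch(
    utils::read.table(matrix_path, header = FALSE,
                      col.names = c("i", "j", "count")),
    error = function(e) data.frame(i = integer(), j = integer(),
                                   count = numeric()))
  v <- matrix(0, n, n)
  if (nrow(trip) > 0L) {
    if (!all(c(as.character(trip$i), as.character(trip$j)) %in% all_ids)) {
      abort("Triplet references a bin id absent from the bin table.")
    }
    both <- as.character(trip$i) %in% names(idx) & as.character(trip$j) %in% names(idx)
    trip <- trip[both, , drop = FALSE]
    if (any(trip$count < 0)) abort("Negative contact count in triplet file.")
    ii <- idx[as.character(trip$i)]
    jj <- idx[as.character(trip$j)]
    for (k in seq_along(ii)) {
      v[ii[k], jj[k]] <- v[ii[k], jj[k]] + trip$count[k]
      if (ii[k] != jj[k]) v[jj[k], ii[k]] <- v[jj[k], ii[k]] + trip$count[k]
    }
  }
  contact_map(v, region(chrom, bed$start[1], bed$end[n]),
              bin_size = sizes[1], normalization = normalization)
}

#' Write a sparse triplet contact file
#'
#' @param map Intra-chromosomal [contact_map()].
#' @param matrix_path,bed_path Output paths for the triplet file and the
#'   BED4 bin table.
#' @param first_id Id assigned to the first bin.
#' @return `matrix_path`, invisibly.
#' @export
write_sparse_triplet <- function(map, matrix_path, bed_path, first_id = 1L) {
  stopifnot(inherits(map, "contact_map"), is_intra(map))
  b <- map_bins(map, "row")
  utils::write.table(data.frame(b$chrom, format(b$start, scientific = FALSE, trim = TRUE),
                                format(b$end, scientific = FALSE, trim = TRUE),
                                b$bin - 1L + first_id),
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ut <- which(upper.tri(map$values, diag = TRUE) & map$values != 0 &
                !is.na(map$values), arr.ind = TRUE)
  utils::write.table(data.frame(ut[, 1] - 1L + first_id, ut[, 2] - 1L + first_id,
                                map$values[ut]),
                     matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Read peak intervals from a BED file
#'
#' BED3/BED6; the strand column, when absent, is reported as `"*"`.
#'
#' @param path BED file path.
#' @return A tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (one peak per row, 0-based half-open).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

peaks_to_granges <- function(peaks, score = NULL) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    score = score %||% rep(0, nrow(peaks)))
}

#' Write a per-interval value track as bedGraph
#'
#' @param track Data frame with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "score") {
  keep <- is.finite(track[[value]])
  gr <- peaks_to_granges(track[keep, , drop = FALSE],
                         score = track[[value]][keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write intervals with a score column as BED
#'
#' @inheritParams write_bedgraph
#' @export
write_bed <- function(track, path, value = "score") {
  gr <- peaks_to_granges(track, score = track[[value]])
  if (!is.null(track$name)) gr$name <- track$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
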