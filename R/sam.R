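#' Write SAM records to a file
#'
#' Emits @HD/@SQ/@PG headers followed by the records; the NM tag carries
#' the edit distance for aligned records.
#'
#' @param records a `sam_records` data.frame from [align_reads()] or
#'   [align_read_pairs()].
#' @param index the `fm_index` (or `reference_set`) the records were
#'   aligned against, used for the @SQ header lines.
#' @param path output file path.
#' @param cl command line to record in the @PG line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, index, path, cl = "tagalign") {
  stopifnot(is.data.frame(records))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", index$names, "\tLN:", index$seqlen),
    paste0("@PG\tID:tagalign\tPN:tagalign\tVN:",
           as.character(utils::packageVersion("tagalign")), "\tCL:", cl))
  nm <- ifelse(is.na(records$nm), "", paste0("\tNM:i:", records$nm))
  body <- paste0(records$qname, "\t", records$flag, "\t", records$rname,
                 "\t", format(records$pos, scientific = FALSE, trim = TRUE),
                 "\t", records$mapq, "\t", records$cigar, "\t",
                 records$rnext, "\t",
                 format(records$pnext, scientific = FALSE, trim = TRUE),
                 "\t", format(records$tlen, scientific = FALSE, trim = TRUE),
                 "\t", records$seq, "\t", records$qual, nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Minimal SAM parser for round-tripping this package's own output and
#' feeding the evaluator. Optional tags beyond NM are ignored.
#'
#' @param path SAM file path.
#' @return list with `header` (character vector of header lines) and
#'   `records` (`sam_records` data.frame).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr]
  if (length(body) == 0) {
    rec <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = numeric(),
                      mapq = integer(), cigar = character(),
                      rnext = character(), pnext = numeric(),
                      tlen = numeric(), seq = character(),
                      qual = character(), nm = integer(),
                      stringsAsFactors = FALSE)
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    nfield <- vapply(f, length, integer(1))
    if (any(nfield < 11)) stop("malformed SAM record (fewer than 11 fields)")
    get <- function(i) vapply(f, `[[`, character(1), i)
    nm <- vapply(f, function(x) {
      hit <- grep("^NM:i:", x[-(1:11)], value = TRUE)
      if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
    }, integer(1))
    rec <- data.frame(
      qname = get(1), flag = as.integer(get(2)), rname = get(3),
      pos = as.numeric(get(4)), mapq = as.integer(get(5)),
      cigar = get(6), rnext = get(7), pnext = as.numeric(get(8)),
      tlen = as.numeric(get(9)), seq = get(10), qual = get(11), nm = nm,
      stringsAsFactors = FALSE)
  }
  class(rec) <- c("sam_records", "data.frame")
  list(header = lines[is_hdr], records = rec)
}

#' Read reads from FASTQ
#'
#' Plain or gzip FASTQ via Biostrings.
#'
#' @param path FASTQ file path.
#' @return data.frame with `id`, `seq`, `qual` suitable for
#'   [align_reads()].
#' @export
read_fastq <- function(path) {
  # suppress Biostrings' informational note about dropped metadata columns
  sr <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(sr)),
             seq = as.character(sr),
             qual = as.character(Biostrings::quality(sr)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq` and optionally `qual`
#'   (missing qualities become constant "I").
#' @param path output path (".gz" suffix triggers gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- normalize_reads(reads)
  qual <- ifelse(is.na(reads$qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep("I", n), character(1)),
                 reads$qual)
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

cigar_lengths <- function(cigar) {
  # returns list(read = M+I sum, ref = M+D sum) per cigar string
  ops <- gregexpr("[0-9]+[MID]", cigar)
  res <- lapply(regmatches(cigar, ops), function(x) {
    n <- as.integer(sub("[MID]$", "", x))
    o <- sub("^[0-9]+", "", x)
    c(read = sum(n[o %in% c("M", "I")]), ref = sum(n[o %in% c("M", "D")]))
  })
  list(read = vapply(res, `[[`, numeric(1), "read"),
       ref = vapply(res, `[[`, numeric(1), "ref"))
}
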