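#' Read and write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; sequence ids and content round-trip
#' exactly.
#'
#' @param x [Biostrings::DNAStringSet].
#' @param file path (optionally `.gz`).
#' @return `read_genome_fasta` returns a [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(x, file) {
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}

#' Write IES annotations as GFF3
#'
#' IESs are written as `internal_eliminated_sequence` features in germline
#' (MAC+IES) coordinates, converting the internal 0-based half-open offsets
#' to GFF3's 1-based inclusive convention (`start = germline_start + 1`,
#' `end = germline_start + length`), with `ID` and `length` attributes.
#' Metadata (tool version, config hash, seed) is carried as comment lines
#' after the `##gff-version` pragma.
#'
#' @param annotations IES annotation data.frame.
#' @param file output path.
#' @param meta optional named list written as `# key: value` comments.
#' @export
write_ies_gff3 <- function(annotations, file, meta = NULL) {
  a <- annotations
  gr <- GenomicRanges::GRanges(
    seqnames = a$replicon,
    ranges = IRanges::IRanges(start = a$germline_start + 1L,
                              end = a$germline_start + a$length),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "iesret"
  S4Vectors::mcols(gr)$type <- "internal_eliminated_sequence"
  S4Vectors::mcols(gr)$ID <- a$ies_id
  S4Vectors::mcols(gr)$length <- a$length
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  rtracklayer::export(gr, tmp, format = "gff3")
  lines <- readLines(tmp)
  pragma <- grepl("^##gff-version", lines)
  writeLines(c(lines[pragma], .meta_header(meta), lines[!pragma]), file)
  invisible(file)
}

#' Read IES annotations from GFF3
#'
#' Reconstructs the full annotation table (including 0-based offsets, MAC
#' insertion points and germline IES sequences) from a GFF3 file plus the
#' germline genome. The MAC insertion point of the *i*-th IES on a replicon
#' is its germline start minus the cumulative length of the preceding IESs.
#' Records with `start > end` or coordinates outside the replicon are
#' validation errors reporting the offending line.
#'
#' @param file GFF3 path.
#' @param germline [Biostrings::DNAStringSet] germline genome.
#' @return IES annotation data.frame (see [generate_genome_pair()]).
#' @export
read_ies_gff3 <- function(file, germline) {
  raw <- readLines(file)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("%s: malformed GFF3 record at line %d", file, i),
           call. = FALSE)
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop(sprintf("%s: invalid coordinates (start > end?) at line %d",
                   file, i), call. = FALSE)
    if (!f[1] %in% names(germline) ||
        e > Biostrings::width(germline[f[1]]))
      stop(sprintf("%s: coordinate outside replicon at line %d", file, i),
           call. = FALSE)
  }
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "internal_eliminated_sequence"]
  df <- data.frame(
    ies_id = S4Vectors::mcols(gr)$ID,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    germline_start = GenomicRanges::start(gr) - 1L,
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE)
  df <- df[order(df$replicon, df$germline_start), , drop = FALSE]
  df$mac_position <- NA_integer_
  df$sequence <- NA_character_
  for (rn in unique(df$replicon)) {
    sel <- which(df$replicon == rn)
    g <- as.character(germline[[rn]])
    len <- df$length[sel]
    df$mac_position[sel] <- df$germline_start[sel] -
      c(0L, cumsum(len)[-length(len)])
    df$sequence[sel] <- substring(g, df$germline_start[sel] + 1L,
                                  df$germline_start[sel] + len)
  }
  rownames(df) <- NULL
  df[, c("ies_id", "replicon", "mac_position", "germline_start", "length",
         "sequence")]
}

#' Write and read paired FASTQ
#'
#' Reads are error-free by construction, so qualities are written as a
#' constant maximal score.
#'
#' @param reads an `ies_read_set` (or any list with `read1`/`read2`
#'   [Biostrings::DNAStringSet]).
#' @param prefix output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return `write_fastq_pair` returns the two paths; `read_fastq_pair`
#'   returns a list with `read1` and `read2` kept in sync.
#' @export
write_fastq_pair <- function(reads, prefix) {
  files <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (i in 1:2) {
    x <- reads[[c("read1", "read2")[i]]]
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, files[i], format = "fastq",
                                compress = TRUE, qualities = qual)
  }
  invisible(files)
}

#' @rdname write_fastq_pair
#' @param file1,file2 FASTQ paths for the two mates.
#' @export
read_fastq_pair <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate files differ in read count", call. = FALSE)
  # keep ids in sync (strip any /1 /2 suffixes)
  names(r1) <- sub("/[12]$", "", sub(" .*$", "", names(r1)))
  names(r2) <- sub("/[12]$", "", sub(" .*$", "", names(r2)))
  if (!identical(names(r1), names(r2)))
    stop("mate files are not in the same read order", call. = FALSE)
  list(read1 = r1, read2 = r2)
}

#' Write / read a tab-separated table with a metadata header
#'
#' The interchange format between pipeline stages: plain TSV with `# key:
#' value` comment lines (tool version, config hash, seeds) above the column
#' header.
#'
#' @param df data.frame.
#' @param file path.
#' @param meta optional named list of metadata.
#' @export
write_tsv <- function(df, file, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  writeLines(.meta_header(meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write the per-IES truth table of a simulation
#'
#' @param truth an `ies_truth`.
#' @param annotations IES annotation data.frame.
#' @param profile named density vector.
#' @param file path.
#' @param meta optional metadata list.
#' @export
write_truth_tsv <- function(truth, annotations, profile, file, meta = NULL) {
  df <- data.frame(ies_id = annotations$ies_id,
                   r = unname(truth$retention[annotations$ies_id]),
                   density = unname(profile[annotations$ies_id]),
                   length = annotations$length,
                   stringsAsFactors = FALSE)
  write_tsv(df, file, meta = c(meta, list(rho = truth$rho)))
  invisible(file)
}

#' Write / read a simulation or pipeline configuration as YAML
#'
#' @param config a configuration list (e.g. [simulation_config()]).
#' @param file path.
#' @export
write_config_yaml <- function(config, file) {
  lines <- c(.meta_header(list(config_hash = config_hash(unclass(config)))),
             yaml::as.yaml(unclass(config)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(file) {
  yaml::read_yaml(file)
}
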