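#' Stranded aligned read set for one individual
#'
#' Container for the genomic footprints of one individual's enrichment
#' library. Coordinates are 0-based half-open throughout the package;
#' 1-based conventions appear only at SAM and display boundaries.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `read_id`.
#' @param individual individual id the reads belong to.
#' @param genome optional [genome_model()] used to validate chromosome
#'   names and bounds.
#' @param sort sort by (chrom, start)?
#' @return an object of class `aligned_reads`.
#' @export
aligned_reads <- function(reads, individual = "sample", genome = NULL,
                          sort = TRUE) {
  need <- c("chrom", "start", "end", "strand", "read_id")
  stopifnot(is.data.frame(reads), all(need %in% names(reads)))
  reads <- as.data.frame(reads)[need]
  reads$chrom <- as.character(reads$chrom)
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  if (nrow(reads) > 0 && any(reads$start < 0 | reads$end <= reads$start))
    stop_ltr("read intervals must satisfy 0 <= start < end")
  if (!is.null(genome) && nrow(reads) > 0) {
    len <- chrom_length(genome, reads$chrom)  # errors on unknown chrom
    if (any(reads$end > len))
      stop_ltr("read beyond chromosome end on ",
               reads$chrom[which(reads$end > len)[1L]])
  }
  if (sort && nrow(reads) > 0) {
    reads <- reads[order(reads$chrom, reads$start, reads$end), ]
    rownames(reads) <- NULL
  }
  structure(list(individual = individual, reads = reads, sorted = sort),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("aligned_reads:", nrow(x$reads), "reads for", x$individual, "\n")
  invisible(x)
}

#' Read aligned enrichment reads from BED6 or minimal SAM
#'
#' BED6 columns map to (chrom, start, end, read id, score, strand), already
#' 0-based half-open. SAM input is restricted to mapped primary records
#' with a single-match-run CIGAR (`<n>M`); POS is converted from 1-based by
#' subtracting one and FLAG bit 16 sets strand `-`.
#'
#' @param path input file.
#' @param format `"bed6"` or `"sam"`.
#' @param individual individual id to attach.
#' @param genome optional [genome_model()] for validation. For SAM input
#'   the `@SQ` header lines are always used to check chromosome names.
#' @return an [aligned_reads()] object. An empty file yields an empty set.
#' @export
read_aligned_reads <- function(path, format = c("bed6", "sam"),
                               individual = "sample", genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ltr("no such file: ", path)
  if (format == "bed6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0)
      return(aligned_reads(empty_reads(), individual, genome))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6))
      stop_ltr("malformed BED6 line ", which(nf < 6)[1L], " in ", path)
    m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    bad <- is.na(start) | is.na(end) | !(m[, 6] %in% c("+", "-", "."))
    if (any(bad))
      stop_ltr("malformed BED6 line ", which(bad)[1L], " in ", path)
    reads <- data.frame(chrom = m[, 1], start = start, end = end,
                        strand = m[, 6], read_id = m[, 4])
    return(aligned_reads(reads, individual, genome))
  }
  # minimal SAM
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr & grepl("^@SQ", lines)]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  body <- which(!hdr & nzchar(lines))
  if (length(body) == 0)
    return(aligned_reads(empty_reads(), individual, genome))
  recs <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(recs)
  if (any(nf < 11))
    stop_ltr("malformed SAM line ", body[nf < 11][1L], " in ", path)
  flag <- as.integer(vapply(recs, `[`, "", 2L))
  keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x100) == 0 &
    bitwAnd(flag, 0x800) == 0
  recs <- recs[keep]
  lineno <- body[keep]
  if (length(recs) == 0)
    return(aligned_reads(empty_reads(), individual, genome))
  rname <- vapply(recs, `[`, "", 3L)
  if (length(sq_names) > 0 && any(!(rname %in% sq_names)))
    stop_ltr("unknown chromosome in SAM: ",
             rname[!(rname %in% sq_names)][1L])
  cigar <- vapply(recs, `[`, "", 6L)
  ok <- grepl("^[0-9]+M$", cigar)
  if (any(!ok))
    stop_ltr("unsupported CIGAR at SAM line ", lineno[!ok][1L],
             " (only single match runs are accepted)")
  pos1 <- as.integer(vapply(recs, `[`, "", 4L))
  len <- as.integer(sub("M$", "", cigar))
  reads <- data.frame(
    chrom = rname,
    start = pos1 - 1L,
    end = pos1 - 1L + len,
    strand = ifelse(bitwAnd(as.integer(vapply(recs, `[`, "", 2L)), 0x10) != 0,
                    "-", "+"),
    read_id = vapply(recs, `[`, "", 1L))
  aligned_reads(reads, individual, genome)
}

empty_reads <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), read_id = character())
}

#' Write aligned reads as BED6
#'
#' Score column is a mapping-quality placeholder (60).
#'
#' @param x an `aligned_reads` object.
#' @param path output path.
#' @export
write_reads_bed <- function(x, path) {
  r <- x$reads
  bed <- data.table::data.table(chrom = r$chrom, start = r$start,
                                end = r$end, name = r$read_id, score = 60L,
                                strand = r$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write aligned reads as minimal SAM
#'
#' Header carries `@SQ` lines from the genome model; FLAG is limited to
#' 0/16, CIGAR to a single match run, SEQ/QUAL are omitted (`*`).
#'
#' @param x an `aligned_reads` object.
#' @param genome a [genome_model()] providing the `@SQ` header.
#' @param path output path.
#' @export
write_reads_sam <- function(x, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genome$chromosomes$name,
                     genome$chromosomes$length), con)
  r <- x$reads
  if (nrow(r) > 0) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       r$read_id, ifelse(r$strand == "-", 16L, 0L), r$chrom,
                       r$start + 1L, r$end - r$start), con)
  }
  invisible(path)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 (via rtracklayer) keeps only records of type `gene`; the gene id is
#' the `ID` attribute and 1-based inclusive coordinates are converted to
#' 0-based half-open. BED input is six-column (name = gene id). The TSS is
#' the interval start for `+` genes and the interval end for `-` genes.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return data.frame with gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- as.character(S4Vectors::mcols(gr)$ID)
    if (length(gr) > 0 && (is.null(ids) || anyNA(ids) || any(!nzchar(ids))))
      stop_ltr("GFF3 gene record without ID attribute in ", path)
    genes <- data.frame(
      gene_id = ids %||% character(0),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else {
    if (file.size(path) == 0) {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
    } else {
      bed <- data.table::fread(path, header = FALSE, sep = "\t")
      if (ncol(bed) < 6) stop_ltr("gene BED needs 6 columns: ", path)
      genes <- data.frame(gene_id = as.character(bed[[4]]),
                          chrom = as.character(bed[[1]]),
                          start = as.integer(bed[[2]]),
                          end = as.integer(bed[[3]]),
                          strand = as.character(bed[[6]]))
    }
  }
  if (nrow(genes) > 0 && any(genes$start >= genes$end))
    stop_ltr("gene with start >= end in ", path)
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes
}

#' Write / read called-site tables
#'
#' TSV with both internal 0-based half-open coordinates and a 1-based
#' browser-style display label for the junction (e.g. `chrB2:55,690,560`).
#' `read_site_table()` restores the internal coordinates losslessly.
#'
#' @param sites data.frame of called sites (see [call_sites()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("chrom", "start", "end", "junction", "polarity", "peak_depth",
            "n_reads", "individual", "env_flagged")
  out <- as.data.frame(sites)[intersect(cols, names(sites))]
  out$display <- if (nrow(out) > 0)
    site_label(out$chrom, out$junction) else character(0)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  df <- as.data.frame(dt)
  for (col in c("start", "end", "junction", "peak_depth", "n_reads"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  if ("env_flagged" %in% names(df)) df$env_flagged <- as.logical(df$env_flagged)
  df$display <- NULL
  df
}

#' Export a coverage track as bedGraph
#'
#' Four columns, 0-based half-open, collapsed runs — the same layout as
#' `bedtools genomecov -bg`.
#'
#' @param track a `coverage_track` (see [compute_coverage()]).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)[c("chrom", "start", "end", "depth")]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
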