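#' Read a genome from a FASTA file
#'
#' Loads all records of a FASTA file into a [Biostrings::DNAStringSet].
#' Sequence names are taken as the first whitespace-delimited word of each
#' header. Duplicate names are an error; an empty file yields an empty genome
#' with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names (the genome).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(DNAStringSet())
  }
  genome <- readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names in ", path, ": ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  genome
}

#' Contig lengths of a genome
#'
#' @param genome A `DNAStringSet` genome.
#' @return Named integer vector of contig lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(width(genome), names(genome))
}

#' Seqinfo for a genome
#' @param genome A `DNAStringSet` genome.
#' @return A [GenomeInfoDb::Seqinfo] with contig names and lengths.
#' @export
genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = unname(width(genome)))
}

#' Strand-aware upstream/downstream window around feature starts
#'
#' For a stranded feature the window extends `up` bp upstream of its 5' end
#' and `down` bp downstream of (and including) that end, mirroring the
#' extraction of upstream promoter sequence around 21U-RNA mapping sites
#' (default geometry: 110 bp upstream, 30 bp downstream). Windows running off
#' a contig are clipped to the contig bounds and flagged in the `clipped`
#' metadata column.
#'
#' @param sites A stranded [GenomicRanges::GRanges].
#' @param up,down Window extent in bp upstream / downstream of the 5' end.
#' @param genome A `DNAStringSet` genome used for contig bounds.
#' @return A `GRanges` of windows with a logical `clipped` metadata column.
#' @export
upstream_window <- function(sites, up = 110, down = 30, genome) {
  if (any(strand(sites) == "*"))
    stop("upstream_window() requires stranded sites")
  win <- promoters(sites, upstream = up, downstream = down)
  lens <- genome_lengths(genome)
  missing <- setdiff(as.character(GenomeInfoDb::seqlevels(win)), names(lens))
  if (length(missing))
    stop("contigs absent from genome: ", paste(missing, collapse = ", "))
  contig_len <- lens[as.character(seqnames(win))]
  clipped <- start(win) < 1L | end(win) > contig_len
  start(win) <- pmax(start(win), 1L)
  end(win) <- pmin(end(win), contig_len)
  mcols(win)$clipped <- clipped
  win
}

#' Extract strand-aware sequence for intervals
#'
#' Returns the sequence of each interval; minus-strand intervals are
#' reverse-complemented so sequences read 5' to 3' on the feature strand.
#'
#' @param genome A `DNAStringSet` genome.
#' @param intervals A `GRanges` (strand `*` treated as `+`).
#' @return A `DNAStringSet`, one sequence per interval.
#' @export
extract_sequence <- function(genome, intervals) {
  contig <- as.character(seqnames(intervals))
  unknown <- setdiff(unique(contig), names(genome))
  if (length(unknown))
    stop("unknown contig(s): ", paste(unknown, collapse = ", "))
  lens <- genome_lengths(genome)[contig]
  if (length(intervals) && (any(start(intervals) < 1L) || any(end(intervals) > lens)))
    stop("interval out of contig bounds")
  out <- DNAStringSet(lapply(seq_along(intervals), function(i) {
    s <- subseq(genome[[contig[i]]], start(intervals)[i], end(intervals)[i])
    if (as.character(strand(intervals)[i]) == "-") s <- reverseComplement(s)
    s
  }))
  names(out) <- if (!is.null(names(intervals))) names(intervals) else NULL
  out
}

#' Read interval annotations from BED or GFF3
#'
#' BED input is 0-based half-open on disk and is converted to the internal
#' 1-based closed `GRanges` convention; GFF3 is already 1-based closed.
#' Zero-width records are rejected.
#'
#' @param path Path to the annotation file.
#' @param format `"BED"` or `"GFF3"`.
#' @return A `GRanges` with any attribute columns carried in `mcols`.
#' @export
read_intervals <- function(path, format = c("BED", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = ifelse(format == "BED", "bed", "gff3"))
  bad <- which(width(gr) < 1L)
  if (length(bad))
    stop("record(s) with end <= start after conversion at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  gr
}

#' Write intervals to BED
#'
#' Coordinates are converted back to the BED 0-based half-open convention on
#' disk. The `name` column, if present in `mcols`, is carried through.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a read-site table (TSV)
#'
#' External read-site tables are TSV with header columns `contig`, `start`,
#' `end` (0-based half-open on disk), `strand`, `length`, `count`,
#' `chemistry`, `unique`. Converted to a `GRanges` with those attributes.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with `length`, `count`, `chemistry`, `unique` mcols.
#' @export
read_sites_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "length", "count", "chemistry", "unique")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  gr <- GRanges(df$contig, IRanges(df$start + 1L, df$end), strand = df$strand)
  mcols(gr) <- DataFrame(length = as.integer(df$length),
                         count = as.integer(df$count),
                         chemistry = df$chemistry,
                         unique = as.logical(df$unique))
  if (any(mcols(gr)$length != width(gr)))
    stop("length column inconsistent with interval width")
  if (any(mcols(gr)$count < 0)) stop("negative read counts")
  gr
}

#' Write a read-site table (TSV)
#' @param sites A `GRanges` with `length`, `count`, `chemistry`, `unique` mcols.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- data.frame(contig = as.character(seqnames(sites)),
                   start = start(sites) - 1L,
                   end = end(sites),
                   strand = as.character(strand(sites)),
                   length = mcols(sites)$length,
                   count = mcols(sites)$count,
                   chemistry = mcols(sites)$chemistry,
                   unique = mcols(sites)$unique)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
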