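#' Genome assemblies and sequence I/O
#'
#' A genome assembly is represented as a [GenomeInfoDb::Seqinfo] object
#' (chromosome names and lengths); genome sequence as a
#' [Biostrings::DNAStringSet]. These are the containers the rest of the
#' package's interval and track arithmetic is built on.
#'
#' @name assembly
NULL

#' Build an assembly from named chromosome lengths
#'
#' @param chrom_sizes Named numeric/integer vector of chromosome lengths
#'   (bp), or an existing `Seqinfo` (returned unchanged), or a
#'   `DNAStringSet` (lengths taken from the sequences).
#' @return A `Seqinfo` object.
#' @export
as_assembly <- function(chrom_sizes) {
  if (is(chrom_sizes, "Seqinfo")) return(chrom_sizes)
  if (is(chrom_sizes, "DNAStringSet")) {
    return(Seqinfo(seqnames = names(chrom_sizes),
                   seqlengths = Biostrings::width(chrom_sizes)))
  }
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stop("chrom_sizes must have unique names")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = names(chrom_sizes),
          seqlengths = as.integer(chrom_sizes))
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns: chromosome name, length (bp).
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  as_assembly(stats::setNames(df$size, df$chrom))
}

#' Write a chrom.sizes file
#' @param assembly `Seqinfo` or named lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  si <- as_assembly(assembly)
  utils::write.table(
    data.frame(seqnames(si), seqlengths(si)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genome sequence from FASTA
#'
#' Sequences are uppercased and U is mapped to T; any character outside
#' {A,C,G,T,N} is rejected. Duplicated record names are an error.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  # read as raw strings first: case is normalised and U mapped to T before
  # imposing the DNA alphabet, so RNA-style records are accepted while
  # genuinely invalid characters are rejected rather than silently dropped
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(raw) == 0) stop("FASTA file '", path, "' contains no records")
  # keep only the first whitespace-delimited token of each header
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate FASTA record name(s): ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0))
    stop("empty FASTA record(s): ",
         paste(names(raw)[Biostrings::width(raw) == 0], collapse = ", "))
  txt <- chartr("acgtunU", "ACGTTNT", as.character(raw))
  bad <- gsub("[ACGTN]", "", txt)
  if (any(nchar(bad) > 0)) {
    offending <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    stop("sequence contains non-ACGTN characters: ",
         paste(offending, collapse = ", "))
  }
  Biostrings::DNAStringSet(txt)
}

#' Write genome sequence as FASTA (60-column wrapped)
#' @param seqs `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# Check that peaks lie within their assembly; used by coverage computations.
.check_within_assembly <- function(gr, assembly) {
  si <- as_assembly(assembly)
  sl <- seqlengths(si)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  missing <- setdiff(unique(chr), seqnames(si))
  if (length(missing))
    stop("chromosome(s) absent from assembly: ",
         paste(missing, collapse = ", "))
  over <- end(gr) > sl[chr] | start(gr) < 1L
  if (any(over))
    stop(sum(over), " interval(s) extend beyond chromosome bounds ",
         "(first: ", chr[which(over)[1]], ":", start(gr)[which(over)[1]] - 1L,
         "-", end(gr)[which(over)[1]], ")")
  invisible(TRUE)
}

# Attach an assembly to a GRanges regardless of current seqlevel order.
.set_assembly <- function(gr, si) {
  si <- as_assembly(si)
  GenomeInfoDb::seqlevels(gr) <- seqnames(si)
  seqinfo(gr) <- si
  gr
}
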