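#' Open a reference FASTA for GC queries
#'
#' Uses random access through a `.fai` index when one is present (plain
#' FASTA or bgzip), otherwise loads the sequences into memory.  Sequence
#' names are truncated at the first whitespace, matching alignment-header
#' convention.
#'
#' @param path FASTA file.
#' @return An object of class `reference_sequence`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: '", path, "'")
  fai <- paste0(path, ".fai")
  if (file.exists(fai)) {
    fa <- Rsamtools::FaFile(path)
    obj <- list(type = "indexed", fa = fa, path = path)
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    obj <- list(type = "memory", seqs = seqs, path = path)
  }
  class(obj) <- "reference_sequence"
  obj
}

reference_lengths <- function(ref) {
  if (ref$type == "indexed") {
    gr <- Rsamtools::scanFaIndex(ref$fa)
    stats::setNames(GenomicRanges::width(gr),
                    as.character(GenomicRanges::seqnames(gr)))
  } else {
    stats::setNames(Biostrings::width(ref$seqs), names(ref$seqs))
  }
}

# Fetch [start, end) of a chromosome as an uppercase character string.
reference_slice <- function(ref, chrom, start, end) {
  lens <- reference_lengths(ref)
  if (!chrom %in% names(lens))
    stop("chromosome '", chrom, "' not found in reference '", ref$path, "'")
  if (start < 0L || end > lens[[chrom]] || start >= end)
    stop(sprintf("region [%d, %d) outside reference sequence %s (length %d)",
                 start, end, chrom, lens[[chrom]]))
  if (ref$type == "indexed") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    as.character(Rsamtools::scanFa(ref$fa, gr)[[1L]])
  } else {
    as.character(Biostrings::subseq(ref$seqs[[chrom]], start + 1L, end))
  }
}

# (#G + #C, #A + #C + #G + #T), case-insensitive; N and other IUPAC
# ambiguity codes count in neither term.
gc_counts <- function(seq_chars) {
  s <- Biostrings::DNAString(toupper(paste(seq_chars, collapse = "")))
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  c(gc = unname(f[["C"]] + f[["G"]]),
    acgt = unname(f[["A"]] + f[["C"]] + f[["G"]] + f[["T"]]))
}

#' GC percentage of a region or gene model
#'
#' `100 * (#G + #C) / (#A + #C + #G + #T)`, case-insensitive, computed from
#' the reference only (never from alignments).  `N` and IUPAC ambiguity
#' codes are excluded from both numerator and denominator so that assembly
#' gaps do not depress GC — important when the column feeds copy-number
#' normalization.  Returns `NA` (reported as `-`) when the region contains
#' no unambiguous base.  For a gene model the counts are pooled across the
#' merged parts.
#'
#' @param ref a [read_reference()] handle.
#' @param region either a region (list with `chrom`, `start`, `end`) or a
#'   gene model (list with `chrom`, `parts`).
#' @return GC percentage in `[0, 100]`, or `NA_real_` when undefined.
#' @examples
#' \dontrun{
#' gc_percent(ref, list(chrom = "chr1", start = 0, end = 4))
#' }
#' @export
gc_percent <- function(ref, region) {
  total <- gc_counts_region(ref, region)
  if (total[["acgt"]] == 0) return(NA_real_)
  100 * total[["gc"]] / total[["acgt"]]
}

# Pooled (gc, acgt) counts of a region or gene model; used by gc_percent and
# by the report writer's whole-genome Total row, which must pool raw counts
# rather than average percentages.
gc_counts_region <- function(ref, region) {
  stopifnot(inherits(ref, "reference_sequence"))
  parts <- if (!is.null(region$parts)) region$parts
           else cbind(as.integer(region$start), as.integer(region$end))
  total <- c(gc = 0, acgt = 0)
  for (i in seq_len(nrow(parts)))
    total <- total + gc_counts(reference_slice(ref, region$chrom,
                                               parts[i, 1L], parts[i, 2L]))
  total
}
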