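#' Create a blocked per-base depth accumulator for one chromosome
#'
#' Depth is held in fixed-capacity blocks (default 1 MiB of positions) that
#' are materialized lazily: a chromosome slice with no reads costs no memory,
#' and peak memory is bounded by the number of touched blocks, not by
#' chromosome length.  Counts are stored as doubles, exact up to 2^53, so
#' per-base depth has no practical ceiling.
#'
#' The accumulator is an environment and is updated in place; functions that
#' modify it also return it invisibly.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param block_size block capacity in bp; default `1048576` (1 MiB).
#' @return An object of class `depth_blocks`.
#' @export
depth_blocks <- function(chrom, chrom_length, block_size = 1048576L) {
  chrom_length <- as.integer(chrom_length)
  block_size <- as.integer(block_size)
  stopifnot(length(chrom) == 1L, chrom_length >= 1L, block_size >= 1L)
  d <- new.env(parent = emptyenv())
  d$chrom <- chrom
  d$chrom_length <- chrom_length
  d$block_size <- block_size
  d$blocks <- list()          # names are 0-based block indices as strings
  class(d) <- "depth_blocks"
  d
}

#' @export
print.depth_blocks <- function(x, ...) {
  cat(sprintf("<depth_blocks> %s (%d bp), block_size=%d, %d block(s) materialized\n",
              x$chrom, x$chrom_length, x$block_size, length(x$blocks)))
  invisible(x)
}

# Tokenize a CIGAR string into (len, op) vectors; errors on trailing garbage.
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: '", cigar, "'")
  list(len = as.integer(sub(".$", "", toks)),
       op = substring(toks, nchar(toks)))
}

# Reference segments covered by aligned bases: M, = and X consume reference
# and add depth; D and N consume reference silently; I, S, H, P consume none.
cigar_covered_segments <- function(pos, len, op) {
  adds <- op %in% c("M", "=", "X")
  consumes <- adds | op %in% c("D", "N")
  ends <- pos + cumsum(ifelse(consumes, len, 0L))
  starts <- ends - ifelse(consumes, len, 0L)
  cbind(start = starts[adds], end = ends[adds])
}

# += value over [start, end) spanning block boundaries as needed.
add_range <- function(d, start, end, value = 1) {
  bs <- d$block_size
  b0 <- start %/% bs
  b1 <- (end - 1L) %/% bs
  for (b in b0:b1) {
    key <- as.character(b)
    blk <- d$blocks[[key]]
    if (is.null(blk)) {
      blk_len <- min(bs, d$chrom_length - b * bs)
      blk <- numeric(blk_len)
    }
    lo <- max(start, b * bs) - b * bs + 1L
    hi <- min(end, (b + 1L) * bs) - b * bs
    blk[lo:hi] <- blk[lo:hi] + value
    d$blocks[[key]] <- blk
  }
  invisible(d)
}

#' Accumulate one alignment record into the depth blocks
#'
#' Walks the CIGAR from the alignment position: `M`, `=` and `X` operations
#' increment depth at every reference base they span; `D` and `N` advance the
#' reference cursor without incrementing; `I`, `S`, `H` and `P` do neither.
#' Increments past the chromosome end are discarded with a warning.  The
#' record is assumed to have already passed filtering.
#'
#' @param d a [depth_blocks()] accumulator for the record's chromosome.
#' @param pos 0-based leftmost aligned reference base.
#' @param cigar CIGAR string (non-empty for mapped records).
#' @return `d`, invisibly (updated in place).
#' @export
accumulate_read <- function(d, pos, cigar) {
  stopifnot(inherits(d, "depth_blocks"))
  pc <- parse_cigar(cigar)
  seg <- cigar_covered_segments(as.integer(pos), pc$len, pc$op)
  clipped <- FALSE
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, 1L]; e <- seg[i, 2L]
    if (e > d$chrom_length) { clipped <- TRUE; e <- d$chrom_length }
    if (s < e) add_range(d, s, e)
  }
  if (clipped)
    warning(sprintf("read at %s:%d extends past chromosome end (%d bp); overhang discarded",
                    d$chrom, pos + 1L, d$chrom_length))
  invisible(d)
}

#' Accumulate a table of records into the depth blocks
#'
#' Convenience wrapper around [accumulate_read()] for a record data frame
#' (as returned by [stream_records()]); rows not on `d`'s chromosome or
#' without a CIGAR are ignored.
#'
#' @param d a [depth_blocks()] accumulator.
#' @param recs data frame with `ref_name`, `pos`, `cigar`.
#' @return `d`, invisibly.
#' @export
accumulate_records <- function(d, recs) {
  on_chrom <- !is.na(recs$ref_name) & recs$ref_name == d$chrom &
    nzchar(recs$cigar)
  idx <- which(on_chrom)
  for (i in idx) accumulate_read(d, recs$pos[i], recs$cigar[i])
  invisible(d)
}

# covered/total over [start, end), visiting only materialized blocks.
slice_reduce <- function(d, start, end) {
  bs <- d$block_size
  covered <- 0; total <- 0
  b0 <- start %/% bs
  b1 <- (end - 1L) %/% bs
  for (b in b0:b1) {
    blk <- d$blocks[[as.character(b)]]
    if (is.null(blk)) next
    lo <- max(start, b * bs) - b * bs + 1L
    hi <- min(end, (b + 1L) * bs) - b * bs
    x <- blk[lo:hi]
    covered <- covered + sum(x >= 1)
    total <- total + sum(x)
  }
  c(covered = covered, total = total)
}

#' Extract the per-base depth vector of a region
#'
#' Mainly for inspection and testing; the reporting path never materializes
#' full-length vectors.
#'
#' @param d a [depth_blocks()] accumulator.
#' @param start,end 0-based half-open bounds (defaults: whole chromosome).
#' @return Numeric vector of length `end - start`.
#' @export
depth_vector <- function(d, start = 0L, end = d$chrom_length) {
  stopifnot(start >= 0L, end <= d$chrom_length, start < end)
  bs <- d$block_size
  out <- numeric(end - start)
  for (b in (start %/% bs):((end - 1L) %/% bs)) {
    blk <- d$blocks[[as.character(b)]]
    lo <- max(start, b * bs); hi <- min(end, (b + 1L) * bs)
    if (!is.null(blk))
      out[(lo - start + 1L):(hi - start)] <- blk[(lo - b * bs + 1L):(hi - b * bs)]
    else
      out[(lo - start + 1L):(hi - start)] <- 0
  }
  out
}

region_stats_core <- function(covered, total, len) {
  list(covered_site = covered, total_depth = total,
       coverage_pct = 100 * covered / len, mean_depth = total / len,
       length = len)
}

#' Reduce a region to its coverage statistics
#'
#' Covered sites are reference bases in `[start, end)` with depth >= 1;
#' total depth is the sum of per-base depths; coverage percent and mean
#' depth divide by the region length.  A read need not start inside the
#' region to contribute — aligned bases are counted wherever they fall.
#'
#' @param d a [depth_blocks()] accumulator.
#' @param region list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return List with `covered_site`, `total_depth`, `coverage_pct`,
#'   `mean_depth`, `length`.
#' @export
region_stats <- function(d, region) {
  stopifnot(inherits(d, "depth_blocks"))
  start <- as.integer(region$start); end <- as.integer(region$end)
  if (!identical(as.character(region$chrom), d$chrom))
    stop("region chromosome '", region$chrom, "' does not match accumulator '",
         d$chrom, "'")
  if (start < 0L || end > d$chrom_length || start >= end)
    stop(sprintf("region [%d, %d) outside chromosome bounds [0, %d)",
                 start, end, d$chrom_length))
  r <- slice_reduce(d, start, end)
  region_stats_core(r[["covered"]], r[["total"]], end - start)
}

#' Reduce a gene model (merged parts) to its coverage statistics
#'
#' As [region_stats()], aggregated over the gene's merged CDS/exon parts;
#' the denominator is the merged-part total length, so each reference base
#' counts once.
#'
#' @param d a [depth_blocks()] accumulator.
#' @param gene gene model with `chrom` and `parts` (interval matrix), as
#'   produced by [parse_annotation()].
#' @return As [region_stats()].
#' @export
gene_stats <- function(d, gene) {
  stopifnot(inherits(d, "depth_blocks"))
  if (!identical(gene$chrom, d$chrom))
    stop("gene chromosome '", gene$chrom, "' does not match accumulator '",
         d$chrom, "'")
  covered <- 0; total <- 0; len <- 0L
  for (i in seq_len(nrow(gene$parts))) {
    s <- unname(gene$parts[i, 1L]); e <- unname(gene$parts[i, 2L])
    if (s < 0L || e > d$chrom_length)
      stop(sprintf("gene part [%d, %d) outside chromosome bounds [0, %d)",
                   s, e, d$chrom_length))
    r <- slice_reduce(d, s, e)
    covered <- covered + r[["covered"]]; total <- total + r[["total"]]
    len <- len + (e - s)
  }
  region_stats_core(covered, total, len)
}
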