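#' Filtering configuration for alignment records
#'
#' Bundles the two read-level filters applied before depth accumulation: a
#' SAM FLAG exclusion mask and a minimum mapping quality.  A record is kept
#' iff `bitwAnd(flag, exclude_flag_mask) == 0` and `mapq >= min_mapq`.
#'
#' The default mask `0x704` excludes unmapped (`0x4`), secondary (`0x100`),
#' QC-fail (`0x200`) and duplicate (`0x400`) records.  Supplementary
#' alignments (`0x800`) are *not* excluded by default; add the bit yourself
#' if you want them gone.  A user-supplied mask *replaces* the default rather
#' than adding to it — one knob, least surprise.
#'
#' @param exclude_flag_mask integer in `[0, 65535]`; records with any of
#'   these FLAG bits set are dropped.  Default `0x704`.
#' @param min_mapq integer `>= 0`; records with lower mapping quality are
#'   dropped.  Default 0 (no MAPQ-based loss).
#' @return An object of class `filter_config`.
#' @examples
#' cfg <- filter_config()
#' passes_filters(list(flag = 0x400L, mapq = 60L), cfg)  # duplicate: FALSE
#' @export
filter_config <- function(exclude_flag_mask = 0x704L, min_mapq = 0L) {
  exclude_flag_mask <- as.integer(exclude_flag_mask)
  min_mapq <- as.integer(min_mapq)
  if (length(exclude_flag_mask) != 1L || is.na(exclude_flag_mask) ||
      exclude_flag_mask < 0L || exclude_flag_mask > 65535L)
    stop("exclude_flag_mask must be a single integer in [0, 65535]")
  if (length(min_mapq) != 1L || is.na(min_mapq) || min_mapq < 0L)
    stop("min_mapq must be a single non-negative integer")
  structure(list(exclude_flag_mask = exclude_flag_mask, min_mapq = min_mapq),
            class = "filter_config")
}

#' Test whether alignment records pass the FLAG/MAPQ filters
#'
#' Pure predicate: depends only on `flag` and `mapq`.  Vectorized — `rec`
#' may hold one record or many (e.g. a record data frame from
#' [stream_records()]).
#'
#' @param rec a list or data frame with elements `flag` and `mapq`.
#' @param cfg a [filter_config()].
#' @return Logical vector, `TRUE` for records that survive filtering.
#' @export
passes_filters <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  bitwAnd(as.integer(rec$flag), cfg$exclude_flag_mask) == 0L &
    as.integer(rec$mapq) >= cfg$min_mapq
}

# Sniff the container format from magic bytes: BGZF (gzip) => BAM,
# "CRAM" => CRAM.  Extension is deliberately not trusted.
detect_alignment_format <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && all(magic == charToRaw("CRAM"))) return("CRAM")
  if (length(magic) >= 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    return("BAM")
  stop("'", path, "' is neither BAM (BGZF) nor CRAM: unrecognized magic bytes")
}

samtools_path <- function() {
  st <- Sys.which("samtools")
  if (!nzchar(st))
    stop("samtools executable not found on PATH (required for CRAM support)")
  st
}

# Companion index discovery by conventional naming.
find_alignment_index <- function(path, format) {
  cands <- if (format == "BAM") {
    c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path), paste0(path, ".csi"))
  } else {
    c(paste0(path, ".crai"), sub("\\.cram$", ".crai", path))
  }
  any(file.exists(cands))
}

#' Open a BAM or CRAM alignment file
#'
#' Reads the header and returns a lightweight handle exposing the reference
#' sequences (`@SQ` lines, in header order), whether a companion index
#' (BAI/CSI/CRAI) is present, and the detected container format.  BAM files
#' are handled by Rsamtools; CRAM files are decoded through `samtools view`
#' restricted to the five fields this package needs (FLAG, RNAME, POS, MAPQ,
#' CIGAR), so no reference genome is required for depth calculation.
#'
#' @param path path to a BAM or CRAM file.
#' @param reference optional reference FASTA path, stored on the handle and
#'   passed to samtools for CRAM decoding (only needed if the CRAM cannot be
#'   decoded without it).
#' @return An object of class `alignment_source` with elements `path`,
#'   `format` (`"BAM"` or `"CRAM"`), `chroms` (data frame with `name`,
#'   `length`), `has_index` and `reference`.
#' @export
open_alignment <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("alignment file not found: '", path, "'")
  format <- detect_alignment_format(path)
  if (format == "BAM") {
    hdr <- tryCatch(Rsamtools::scanBamHeader(path)[[1L]],
                    error = function(e)
                      stop("failed to read BAM header from '", path,
                           "': ", conditionMessage(e)))
    targets <- hdr$targets
    chroms <- data.frame(name = names(targets),
                         length = as.integer(unname(targets)),
                         stringsAsFactors = FALSE)
  } else {
    if (!is.null(reference) && !file.exists(reference))
      stop("CRAM reference FASTA not found: '", reference, "'")
    st <- samtools_path()
    hdr_lines <- suppressWarnings(
      system2(st, c("view", "-H", shQuote(path)), stdout = TRUE, stderr = TRUE))
    status <- attr(hdr_lines, "status")
    if (!is.null(status) && status != 0L)
      stop("failed to read CRAM header from '", path, "': ",
           paste(hdr_lines, collapse = " "))
    sq <- grep("^@SQ\t", hdr_lines, value = TRUE)
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    chroms <- data.frame(name = nm, length = ln, stringsAsFactors = FALSE)
  }
  if (nrow(chroms) && anyDuplicated(chroms$name))
    stop("duplicate reference names in header of '", path, "'")
  if (nrow(chroms) && any(chroms$length < 1L))
    stop("non-positive reference length in header of '", path, "'")
  structure(list(path = normalizePath(path), format = format, chroms = chroms,
                 has_index = find_alignment_index(path, format),
                 reference = reference),
            class = "alignment_source")
}

#' @export
print.alignment_source <- function(x, ...) {
  cat(sprintf("<alignment_source> %s (%s, %s)\n  %d reference sequence(s), %s bp total\n",
              x$path, x$format, if (x$has_index) "indexed" else "no index",
              nrow(x$chroms), format(sum(as.numeric(x$chroms$length)),
                                     big.mark = ",")))
  invisible(x)
}

# Normalize a five-field record table to the package-wide convention:
# ref_name NA / pos -1 / mapq 0 / cigar "" for unmapped records; pos 0-based.
normalize_records <- function(ref_name, pos1, flag, mapq, cigar) {
  flag <- as.integer(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L | is.na(ref_name)
  pos <- as.integer(pos1) - 1L
  pos[unmapped] <- -1L
  mapq <- as.integer(mapq)
  # Rsamtools reports MAPQ 255 ("unavailable") as NA; keep 255 on mapped reads.
  mapq[is.na(mapq) & !unmapped] <- 255L
  mapq[unmapped] <- 0L
  cigar <- as.character(cigar)
  cigar[unmapped | is.na(cigar) | cigar == "*"] <- ""
  ref_name <- as.character(ref_name)
  ref_name[unmapped] <- NA_character_
  data.frame(ref_name = ref_name, pos = pos, flag = flag, mapq = mapq,
             cigar = cigar, stringsAsFactors = FALSE)
}

#' Stream minimally-decoded alignment records
#'
#' Yields the five fields needed for depth calculation — `ref_name`, `pos`
#' (0-based leftmost aligned reference base), `flag`, `mapq`, `cigar` — for
#' every record in the file, or for records overlapping one chromosome when
#' `region` is given (requires an index).  Sequence and base qualities are
#' never decoded.  Unmapped records are passed through with `ref_name = NA`,
#' `pos = -1`, `mapq = 0` and an empty CIGAR; dropping them is the filter's
#' job, not the reader's.
#'
#' @param src an [open_alignment()] handle.
#' @param region optional chromosome name to fetch via the index.
#' @return A data frame with columns `ref_name`, `pos`, `flag`, `mapq`,
#'   `cigar`, one row per record.
#' @export
stream_records <- function(src, region = NULL) {
  stopifnot(inherits(src, "alignment_source"))
  if (!is.null(region)) {
    if (!region %in% src$chroms$name)
      stop("region '", region, "' is not in the header; valid names: ",
           paste(src$chroms$name, collapse = ", "))
    if (!src$has_index)
      stop("region fetch on '", src$path, "' requires an index file")
  }
  if (src$format == "BAM") stream_bam(src, region) else stream_cram(src, region)
}

stream_bam <- function(src, region) {
  what <- c("rname", "pos", "flag", "mapq", "cigar")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what)
    res <- Rsamtools::scanBam(src$path, param = param)[[1L]]
  } else {
    len <- src$chroms$length[match(region, src$chroms$name)]
    which <- GenomicRanges::GRanges(region, IRanges::IRanges(1L, len))
    param <- Rsamtools::ScanBamParam(what = what, which = which)
    res <- Rsamtools::scanBam(src$path, param = param)[[1L]]
  }
  normalize_records(as.character(res$rname), res$pos, res$flag, res$mapq,
                    res$cigar)
}

# CRAM path: htslib's required_fields=62 (FLAG|RNAME|POS|MAPQ|CIGAR) skips
# sequence/quality decoding entirely, so the reference is not needed; cut
# keeps columns 2-6 so nothing past MAPQ/CIGAR ever reaches R.
stream_cram <- function(src, region) {
  st <- samtools_path()
  args <- c("view", "--input-fmt-option", "required_fields=62")
  if (!is.null(src$reference))
    args <- c(args, "-T", shQuote(src$reference))
  args <- c(args, shQuote(src$path), if (!is.null(region)) shQuote(region))
  cmd <- paste(shQuote(st), paste(args, collapse = " "), "| cut -f2-6")
  errf <- tempfile("cram_err"); on.exit(unlink(errf), add = TRUE)
  tab <- tryCatch(
    data.table::fread(cmd = paste(cmd, "2>", shQuote(errf)), header = FALSE,
                      sep = "\t", quote = "",
                      colClasses = list(integer = c(1L, 3L, 4L),
                                        character = c(2L, 5L)),
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) cram_decode_error(src, errf, e))
  err <- if (file.exists(errf)) readLines(errf, warn = FALSE) else character()
  if (any(grepl("[Rr]eference|REF_PATH|M5", err)) && nrow(tab) == 0L)
    cram_decode_error(src, errf, NULL)
  if (nrow(tab) == 0L)
    return(normalize_records(character(), integer(), integer(), integer(),
                             character()))
  nm <- tab[[2L]]
  nm[nm == "*"] <- NA_character_
  normalize_records(nm, tab[[3L]], tab[[1L]], tab[[4L]], tab[[5L]])
}

cram_decode_error <- function(src, errf, e) {
  detail <- if (file.exists(errf))
    paste(readLines(errf, warn = FALSE), collapse = "; ") else ""
  ref <- if (is.null(src$reference)) "none supplied (-T/reference argument)"
         else src$reference
  stop("failed to decode CRAM '", src$path, "' (reference: ", ref, "). ",
       detail, if (!is.null(e)) paste0(" [", conditionMessage(e), "]"))
}
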