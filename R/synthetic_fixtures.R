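#' Configuration for the synthetic alignment fixture generator
#'
#' The defaults sketch a small but realistic short-read resequencing slice:
#' a few chromosomes of a few kb, ~8x depth, a typical PCR-duplicate rate
#' (~5%), a few percent secondary/unmapped records, ~10% low-MAPQ
#' multi-mappers, and bwa-like indel/soft-clip rates with occasional spliced
#' (N) alignments.  Every fraction can be driven to 0 or up to stress a
#' specific code path.  The same seed always produces byte-identical files.
#'
#' @param chrom_lengths positive integer chromosome lengths.
#' @param n_reads number of records to emit.
#' @param read_length fixed read length, or `c(min, max)` range.
#' @param frac_duplicate,frac_secondary,frac_unmapped,frac_qcfail fractions
#'   of records carrying FLAG `0x400` / `0x100` / `0x4` / `0x200`.
#' @param frac_low_mapq fraction of mapped records with MAPQ drawn from
#'   0..19 (others draw from 20/30/40/60).
#' @param p_indel,p_splice,p_softclip per-read probabilities of an I-or-D
#'   event, an N (splice) event, and leading/trailing soft clips.
#' @param n_run_fraction fraction of each reference chromosome covered by a
#'   single run of `N` bases (0 = none).
#' @param seed RNG seed; keep below 2^30.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(5000L, 3000L, 1200L),
                       n_reads = 400L, read_length = 100L,
                       frac_duplicate = 0.05, frac_secondary = 0.03,
                       frac_unmapped = 0.03, frac_qcfail = 0.02,
                       frac_low_mapq = 0.10, p_indel = 0.08,
                       p_splice = 0.03, p_softclip = 0.08,
                       n_run_fraction = 0, seed = 1L) {
  probs <- c(frac_duplicate, frac_secondary, frac_unmapped, frac_qcfail,
             frac_low_mapq, p_indel, p_splice, p_softclip, n_run_fraction)
  if (any(probs < 0 | probs > 1)) stop("all fractions must be in [0, 1]")
  if (any(chrom_lengths < 1L)) stop("chromosome lengths must be >= 1")
  if (length(read_length) > 2L || any(read_length < 1L))
    stop("read_length must be a length or a (min, max) range")
  structure(list(chrom_lengths = as.integer(chrom_lengths),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 frac_duplicate = frac_duplicate,
                 frac_secondary = frac_secondary,
                 frac_unmapped = frac_unmapped, frac_qcfail = frac_qcfail,
                 frac_low_mapq = frac_low_mapq, p_indel = p_indel,
                 p_splice = p_splice, p_softclip = p_softclip,
                 n_run_fraction = n_run_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

#' Generate a reproducible random reference FASTA
#'
#' Chromosomes are named `chr1`, `chr2`, ... with the configured lengths;
#' sequence is uniform random A/C/G/T with an optional single run of `N`
#' per chromosome.  A `.fai` index is written alongside.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List with `path` (FASTA), `chroms` (data frame `name`, `length`).
#' @export
generate_reference <- function(cfg, dir = tempfile("covdepth_fix")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  path <- file.path(dir, "ref.fa")
  lines <- character()
  for (i in seq_along(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[i]
    seq <- random_dna(len)
    if (cfg$n_run_fraction > 0 && len >= 3L) {
      run <- max(1L, as.integer(ceiling(cfg$n_run_fraction * len)))
      run <- min(run, len)
      at <- sample.int(len - run + 1L, 1L)
      substr(seq, at, at + run - 1L) <- strrep("N", run)
    }
    lines <- c(lines, paste0(">chr", i),
               substring(seq, seq.int(1L, len, 60L),
                         pmin(seq.int(1L, len, 60L) + 59L, len)))
  }
  writeLines(lines, path)
  Rsamtools::indexFa(path)
  list(path = path,
       chroms = data.frame(name = paste0("chr", seq_along(cfg$chrom_lengths)),
                           length = cfg$chrom_lengths,
                           stringsAsFactors = FALSE))
}

# Build one read's CIGAR pieces.  At most one mid-read event (N preferred
# over I/D when both fire) keeps the generator simple while still exercising
# every reference-consumption class; soft clips are independent.
sim_one_cigar <- function(L, p_indel, p_splice, p_softclip, chrom_len) {
  ls <- 0L; ts <- 0L
  if (stats::runif(1) < p_softclip) ls <- sample.int(max(1L, L %/% 5L), 1L)
  if (stats::runif(1) < p_softclip) ts <- sample.int(max(1L, L %/% 5L), 1L)
  core <- L - ls - ts
  if (core < 2L) { ls <- 0L; ts <- 0L; core <- L }
  mid_op <- ""
  mid_len <- 0L
  if (stats::runif(1) < p_splice) {
    mid_op <- "N"; mid_len <- sample(20:200, 1L)
  } else if (stats::runif(1) < p_indel) {
    mid_op <- sample(c("I", "D"), 1L); mid_len <- sample.int(5L, 1L)
  }
  if (mid_op == "I" && core - mid_len < 2L) { mid_op <- ""; mid_len <- 0L }
  if (mid_op == "") {
    m1 <- core; m2 <- 0L
  } else {
    aligned <- if (mid_op == "I") core - mid_len else core
    m1 <- sample.int(aligned - 1L, 1L); m2 <- aligned - m1
  }
  ref_span <- m1 + m2 + if (mid_op %in% c("D", "N")) mid_len else 0L
  if (ref_span >= chrom_len) {           # degenerate tiny chromosome
    m1 <- max(1L, min(L, chrom_len - 1L)); m2 <- 0L
    mid_op <- ""; mid_len <- 0L; ls <- 0L; ts <- 0L
    ref_span <- m1
  }
  cigar <- paste0(if (ls) paste0(ls, "S"), m1, "M",
                  if (mid_op != "") paste0(mid_len, mid_op),
                  if (m2) paste0(m2, "M"), if (ts) paste0(ts, "S"))
  qlen <- ls + m1 + m2 + ts + if (identical(mid_op, "I")) mid_len else 0L
  list(cigar = cigar, ref_span = ref_span, qlen = qlen)
}

#' Generate synthetic alignments with a known truth table
#'
#' Emits the same record set as an unsorted SAM, an unsorted BAM, a
#' coordinate-sorted + indexed BAM, and a matching indexed CRAM (via
#' samtools), together with a plain-text truth table of
#' `(ref_name, pos, flag, mapq, cigar)` — the independent input of
#' [oracle_depth()], so a reader bug cannot hide on both sides of an
#' equivalence test.  Reads are placed uniformly; configured fractions of
#' duplicate / secondary / QC-fail / unmapped / low-MAPQ records and
#' indel / splice / soft-clip CIGAR events are drawn per record.
#'
#' @param cfg a [sim_config()].
#' @param ref a [generate_reference()] result (or compatible list).
#' @param dir output directory; defaults to the reference's directory.
#' @return List with paths `sam`, `unsorted_bam`, `bam`, `cram`,
#'   `truth_path`, plus `truth` (the truth-table data frame, unmapped rows
#'   normalized to `ref_name = NA`, `pos = -1`, `mapq = 0`, `cigar = ""`).
#' @export
generate_alignments <- function(cfg, ref, dir = dirname(ref$path)) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- samtools_path()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_reads
  lens <- stats::setNames(ref$chroms$length, ref$chroms$name)

  ref_name <- character(n); pos <- integer(n); flag <- integer(n)
  mapq <- integer(n); cigar <- character(n); seq <- character(n)
  for (i in seq_len(n)) {
    L <- if (length(cfg$read_length) == 2L)
      sample(cfg$read_length[1L]:cfg$read_length[2L], 1L) else cfg$read_length
    if (stats::runif(1) < cfg$frac_unmapped) {
      ref_name[i] <- NA_character_; pos[i] <- -1L; flag[i] <- 4L
      mapq[i] <- 0L; cigar[i] <- ""; seq[i] <- random_dna(L)
      next
    }
    f <- 0L
    if (stats::runif(1) < cfg$frac_duplicate) f <- f + 1024L
    if (stats::runif(1) < cfg$frac_secondary) f <- f + 256L
    if (stats::runif(1) < cfg$frac_qcfail) f <- f + 512L
    ch <- sample(ref$chroms$name, 1L, prob = ref$chroms$length)
    cg <- sim_one_cigar(L, cfg$p_indel, cfg$p_splice, cfg$p_softclip,
                        lens[[ch]])
    ref_name[i] <- ch
    pos[i] <- sample.int(lens[[ch]] - cg$ref_span + 1L, 1L) - 1L
    flag[i] <- f
    mapq[i] <- if (stats::runif(1) < cfg$frac_low_mapq) sample(0:19, 1L)
               else sample(c(20L, 30L, 40L, 60L), 1L)
    cigar[i] <- cg$cigar
    seq[i] <- random_dna(cg$qlen)
  }
  truth <- data.frame(ref_name = ref_name, pos = pos, flag = flag,
                      mapq = mapq, cigar = cigar, stringsAsFactors = FALSE)

  truth_path <- file.path(dir, "truth.tsv")
  tt <- truth
  tt$ref_name[is.na(tt$ref_name)] <- "*"
  tt$cigar[tt$cigar == ""] <- "*"
  utils::write.table(tt, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sam <- file.path(dir, "aln.sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$chroms$name, ref$chroms$length))
  recs <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  seq_len(n), flag,
                  ifelse(is.na(ref_name), "*", ref_name),
                  ifelse(is.na(ref_name), 0L, pos + 1L),
                  mapq,
                  ifelse(cigar == "", "*", cigar),
                  seq)
  writeLines(c(hdr, recs), sam)

  unsorted_bam <- file.path(dir, "aln.unsorted.bam")
  bam <- file.path(dir, "aln.bam")
  cram <- file.path(dir, "aln.cram")
  run_samtools(st, c("view", "-b", "-o", unsorted_bam, sam))
  run_samtools(st, c("sort", "-o", bam, sam))
  run_samtools(st, c("index", bam))
  run_samtools(st, c("view", "-C", "-T", ref$path, "-o", cram, bam))
  run_samtools(st, c("index", cram))
  list(sam = sam, unsorted_bam = unsorted_bam, bam = bam, cram = cram,
       truth = truth, truth_path = truth_path)
}

run_samtools <- function(st, args) {
  out <- suppressWarnings(system2(st, shQuote(args), stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("samtools ", args[1L], " failed: ", paste(out, collapse = " "))
  invisible(NULL)
}

#' Naive per-base pileup oracle
#'
#' Deliberately simple, independent re-implementation of depth counting used
#' as the ground truth in equivalence tests: for each truth-table record
#' that passes the FLAG/MAPQ filters (re-implemented inline), the CIGAR is
#' scanned character by character and a full-length depth array is
#' incremented base by base for M/=/X, with D/N advancing the cursor and
#' everything else ignored.  Shares no code with the blocked depth engine.
#'
#' @param truth truth-table data frame from [generate_alignments()] (or any
#'   frame with `ref_name`, `pos`, `flag`, `mapq`, `cigar`).
#' @param chrom chromosome to pile up.
#' @param chrom_length its length in bp.
#' @param exclude_flag_mask,min_mapq filters, defaults `0x704` and 0.
#' @return Integer vector of per-base depths, length `chrom_length`.
#' @export
oracle_depth <- function(truth, chrom, chrom_length,
                         exclude_flag_mask = 0x704L, min_mapq = 0L) {
  depth <- integer(chrom_length)
  digits <- as.character(0:9)
  for (i in seq_len(nrow(truth))) {
    if (bitwAnd(truth$flag[i], exclude_flag_mask) != 0L) next
    if (truth$mapq[i] < min_mapq) next
    if (is.na(truth$ref_name[i]) || truth$ref_name[i] != chrom) next
    cig <- truth$cigar[i]
    if (!nzchar(cig) || cig == "*") next
    cur <- truth$pos[i]
    num <- 0L
    for (chx in strsplit(cig, "", fixed = TRUE)[[1L]]) {
      if (chx %in% digits) { num <- num * 10L + as.integer(chx); next }
      if (chx %in% c("M", "=", "X")) {
        for (k in seq_len(num)) {
          if (cur >= 0L && cur < chrom_length) depth[cur + 1L] <- depth[cur + 1L] + 1L
          cur <- cur + 1L
        }
      } else if (chx %in% c("D", "N")) {
        cur <- cur + num
      }
      num <- 0L
    }
  }
  depth
}
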