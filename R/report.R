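#' Run a coverage/depth calculation
#'
#' End-to-end driver: opens the alignment file, builds the target list
#' (whole chromosomes by default, or per-gene merged CDS/exon sets from
#' `annotation`, BED regions from `bed`, or fixed-size windows from
#' `window` — mutually exclusive), filters records by FLAG mask and MAPQ,
#' accumulates per-base depth in blocked arrays, and reduces every target to
#' covered sites, total depth, coverage percent and mean depth, with
#' optional GC percent from the reference FASTA.
#'
#' When the input has an index, records are fetched per chromosome (not per
#' tiny region) and chromosomes are processed in parallel according to
#' [build_plan()]; each worker accumulates one chromosome once and then
#' reduces all of its targets, so overlapping regions are never
#' double-fetched.  Unindexed (e.g. unsorted) inputs are streamed once,
#' serially.  Output is identical for every `threads` value.
#'
#' @param input BAM or CRAM file.
#' @param annotation GFF3/GTF file for per-gene output.
#' @param bed BED file for per-region output.
#' @param window window size in bp for tiled output.
#' @param reference reference FASTA (needed for `gc = TRUE`; optionally used
#'   for CRAM decoding).
#' @param gc compute a GC percent column from `reference`.
#' @param min_mapq minimum mapping quality (default 0).
#' @param exclude_flags FLAG exclusion mask; default `0x704` (unmapped,
#'   secondary, QC-fail, duplicate).  A supplied value replaces the default.
#' @param threads worker count for chromosome-parallel execution.
#' @param block_size depth-block capacity in bp (default 1 MiB); results do
#'   not depend on it.
#' @param feature_preference annotation feature preference order, default
#'   `c("CDS", "exon")`.
#' @return An object of class `coverage_result`: `mode`, `rows` (one data
#'   frame row per target, coordinates 0-based half-open), `gc_enabled`,
#'   `counts` (records seen / contributing depth) and `params`.
#' @export
coverage_run <- function(input, annotation = NULL, bed = NULL, window = NULL,
                         reference = NULL, gc = FALSE, min_mapq = 0L,
                         exclude_flags = 0x704L, threads = 1L,
                         block_size = 1048576L,
                         feature_preference = c("CDS", "exon")) {
  n_modes <- sum(!is.null(annotation), !is.null(bed), !is.null(window))
  if (n_modes > 1L)
    stop("annotation, bed and window are mutually exclusive")
  if (gc && is.null(reference))
    stop("GC calculation requires a reference FASTA")
  cfg <- filter_config(exclude_flags, min_mapq)
  src <- open_alignment(input, reference)
  chroms <- src$chroms
  if (!nrow(chroms)) stop("alignment header declares no reference sequences")
  len_of <- stats::setNames(chroms$length, chroms$name)

  mode <- if (!is.null(annotation)) "gene" else if (!is.null(bed)) "bed"
          else if (!is.null(window)) "window" else "chromosome"
  genes <- NULL
  targets <- switch(mode,
    chromosome = data.frame(chrom = chroms$name, start = 0L,
                            end = chroms$length, label = chroms$name,
                            stringsAsFactors = FALSE),
    window = make_windows(chroms, window),
    bed = parse_bed(bed, chroms),
    gene = {
      genes <- parse_annotation(annotation, chroms, feature_preference)
      data.frame(chrom = vapply(genes, `[[`, "", "chrom"),
                 start = vapply(genes, function(g) g$parts[1L, 1L], 0L),
                 end = vapply(genes, function(g) g$parts[nrow(g$parts), 2L], 0L),
                 label = vapply(genes, `[[`, "", "gene_id"),
                 stringsAsFactors = FALSE)
    })
  targets$.id <- seq_len(nrow(targets))
  need <- chroms[chroms$name %in% unique(targets$chrom), , drop = FALSE]

  reduce_chrom <- function(ch, recs) {
    keep <- passes_filters(recs, cfg) & !is.na(recs$ref_name) &
      nzchar(recs$cigar)
    used <- recs[keep, , drop = FALSE]
    d <- depth_blocks(ch, len_of[[ch]], block_size)
    accumulate_records(d, used)
    tg <- targets[targets$chrom == ch, , drop = FALSE]
    stats_list <- if (mode == "gene") {
      gs <- genes[vapply(genes, `[[`, "", "chrom") == ch]
      lapply(gs, function(g) gene_stats(d, g))
    } else {
      lapply(seq_len(nrow(tg)), function(i) region_stats(d, tg[i, ]))
    }
    tg$covered_site <- vapply(stats_list, `[[`, 0, "covered_site")
    tg$total_depth <- vapply(stats_list, `[[`, 0, "total_depth")
    tg$coverage_pct <- vapply(stats_list, `[[`, 0, "coverage_pct")
    tg$mean_depth <- vapply(stats_list, `[[`, 0, "mean_depth")
    tg$length <- vapply(stats_list, `[[`, 0, "length")
    list(rows = tg, n_seen = nrow(recs), n_contributing = nrow(used))
  }

  if (src$has_index) {
    plan <- build_plan(need, threads, indexed = TRUE)
    res <- run_plan(plan, function(ch) reduce_chrom(ch, stream_records(src, ch)))
  } else {
    all_recs <- stream_records(src)
    res <- lapply(stats::setNames(need$name, need$name), function(ch)
      reduce_chrom(ch, all_recs[!is.na(all_recs$ref_name) &
                                  all_recs$ref_name == ch, , drop = FALSE]))
    # unmapped records are seen once, not per chromosome
    res[[1L]]$n_seen <- res[[1L]]$n_seen +
      sum(is.na(all_recs$ref_name))
  }

  rows <- do.call(rbind, lapply(res, `[[`, "rows"))
  rows <- rows[order(rows$.id), , drop = FALSE]
  rows$.id <- NULL
  rownames(rows) <- NULL
  if (mode == "gene") names(rows)[names(rows) == "label"] <- "gene_id"

  if (gc) {
    ref <- read_reference(reference)
    check_reference_lengths(ref, chroms)
    cnts <- lapply(seq_len(nrow(rows)), function(i) {
      reg <- if (mode == "gene") genes[[i]]
             else list(chrom = rows$chrom[i], start = rows$start[i],
                       end = rows$end[i])
      gc_counts_region(ref, reg)
    })
    rows$gc_bases <- vapply(cnts, `[[`, 0, "gc")
    rows$acgt_bases <- vapply(cnts, `[[`, 0, "acgt")
    rows$gc_pct <- ifelse(rows$acgt_bases > 0,
                          100 * rows$gc_bases / rows$acgt_bases, NA_real_)
  }

  structure(list(mode = mode, rows = rows, gc_enabled = gc,
                 counts = list(n_seen = sum(vapply(res, `[[`, 0L, "n_seen")),
                               n_contributing = sum(vapply(res, `[[`, 0L,
                                                           "n_contributing"))),
                 params = list(input = input, format = src$format,
                               has_index = src$has_index,
                               exclude_flag_mask = cfg$exclude_flag_mask,
                               min_mapq = cfg$min_mapq, threads = threads,
                               block_size = block_size)),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> mode=%s, %d row(s), %d of %d record(s) contributed depth\n",
              x$mode, nrow(x$rows), x$counts$n_contributing, x$counts$n_seen))
  invisible(x)
}

# Fixed two-decimal formatting with half-up rounding; NA -> "-" sentinel.
fmt2 <- function(x) {
  out <- sprintf("%.2f", floor(x * 100 + 0.5) / 100)
  out[is.na(x)] <- "-"
  out
}

fmt_int <- function(x) sprintf("%.0f", x)

#' Write the tab-separated coverage report
#'
#' Emits one row per target with the layout declared for each mode:
#' chromosome mode `#Chr Length ... plus a whole-genome Total row`;
#' window and BED modes add `Start End` (1-based inclusive display) after
#' `#Chr`; gene mode leads with `#GeneID Chr Start End` where the span
#' covers the outermost merged parts and `Length` is the merged total.
#' A `GC(%)` column is inserted before `Covered_site` when GC was computed.
#' Percentages and mean depth are fixed two-decimal (half-up); counts are
#' raw integers.  Output is gzip-compressed when the path ends in `.gz`.
#'
#' @param x a [coverage_run()] result (or a compatible row data frame, in
#'   which case `mode` and `gc_enabled` must be given).
#' @param out output path, or `""` for standard output.
#' @param mode,gc_enabled only used when `x` is a bare data frame.
#' @return The report lines, invisibly.
#' @export
write_report <- function(x, out = "", mode = NULL, gc_enabled = FALSE) {
  if (inherits(x, "coverage_result")) {
    rows <- x$rows; mode <- x$mode; gc_enabled <- x$gc_enabled
  } else {
    rows <- x
    if (is.null(mode)) stop("mode must be given when x is a data frame")
  }
  gc_col <- function(r) if (gc_enabled) fmt2(r$gc_pct) else NULL
  metric_cols <- function(r)
    cbind(gc_col(r), fmt_int(r$covered_site), fmt_int(r$total_depth),
          fmt2(r$coverage_pct), fmt2(r$mean_depth))
  metric_names <- c(if (gc_enabled) "GC(%)", "Covered_site", "Total_depth",
                    "Coverage(%)", "Mean_depth")
  body <- switch(mode,
    chromosome = cbind(rows$chrom, fmt_int(rows$length), metric_cols(rows)),
    window = ,
    bed = cbind(rows$chrom, fmt_int(rows$start + 1), fmt_int(rows$end),
                fmt_int(rows$length), metric_cols(rows)),
    gene = cbind(rows$gene_id, rows$chrom, fmt_int(rows$start + 1),
                 fmt_int(rows$end), fmt_int(rows$length), metric_cols(rows)),
    stop("unknown mode '", mode, "'"))
  header <- switch(mode,
    chromosome = c("#Chr", "Length", metric_names),
    window = ,
    bed = c("#Chr", "Start", "End", "Length", metric_names),
    gene = c("#GeneID", "Chr", "Start", "End", "Length", metric_names))
  lines <- c("##coordinates: 1-based inclusive",
             paste(header, collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  if (mode == "chromosome") {
    tot_len <- sum(rows$length); tot_cov <- sum(rows$covered_site)
    tot_dep <- sum(rows$total_depth)
    tot_gc <- if (gc_enabled) {
      den <- sum(rows$acgt_bases)
      fmt2(if (den > 0) 100 * sum(rows$gc_bases) / den else NA_real_)
    }
    lines <- c(lines, paste(c("Total", fmt_int(tot_len), tot_gc,
                              fmt_int(tot_cov), fmt_int(tot_dep),
                              fmt2(100 * tot_cov / tot_len),
                              fmt2(tot_dep / tot_len)), collapse = "\t"))
  }
  if (identical(out, "") || is.null(out)) {
    writeLines(lines)
  } else {
    con <- if (grepl("\\.gz$", out)) gzfile(out, "wb") else file(out, "wb")
    ok <- tryCatch({ writeLines(lines, con); TRUE },
                   error = function(e) { close(con)
                     stop("cannot write report to '", out, "': ",
                          conditionMessage(e)) })
    close(con)
  }
  invisible(lines)
}

# Warn when reference FASTA lengths disagree with the alignment header;
# the FASTA wins for GC purposes.
check_reference_lengths <- function(ref, chroms) {
  lens <- reference_lengths(ref)
  common <- intersect(names(lens), chroms$name)
  bad <- common[lens[common] != len_lookup(chroms)[common]]
  if (length(bad))
    warning("reference length differs from alignment header for: ",
            paste(bad, collapse = ", "), " (trusting the FASTA for GC)")
  invisible(NULL)
}

len_lookup <- function(chroms) stats::setNames(chroms$length, chroms$name)
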