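#' Merge half-open intervals
#'
#' Sorts intervals by start and collapses overlapping *and touching* pairs
#' into single intervals, so each reference base is represented at most once.
#' Touching intervals merge because per-gene covered-site statistics must not
#' double-count a shared boundary base.  Idempotent and order-invariant.
#'
#' @param intervals two-column matrix or data frame of 0-based half-open
#'   `(start, end)` pairs.
#' @return Integer matrix with columns `start`, `end`, rows disjoint,
#'   non-touching, sorted by start.
#' @examples
#' merge_intervals(rbind(c(0, 10), c(4, 20)))   # -> (0, 20)
#' merge_intervals(rbind(c(0, 5), c(5, 10)))    # touching -> (0, 10)
#' @export
merge_intervals <- function(intervals) {
  m <- as.matrix(intervals)
  if (length(m) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  if (ncol(m) != 2L) stop("intervals must have two columns (start, end)")
  storage.mode(m) <- "integer"
  bad <- which(m[, 1L] >= m[, 2L])
  if (length(bad))
    stop(sprintf("invalid interval [%d, %d): start must be < end",
                 m[bad[1L], 1L], m[bad[1L], 2L]))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out_s <- integer(nrow(m)); out_e <- integer(nrow(m))
  k <- 1L; out_s[1L] <- m[1L, 1L]; out_e[1L] <- m[1L, 2L]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    if (m[i, 1L] <= out_e[k]) {            # overlap or touch: extend
      if (m[i, 2L] > out_e[k]) out_e[k] <- m[i, 2L]
    } else {
      k <- k + 1L; out_s[k] <- m[i, 1L]; out_e[k] <- m[i, 2L]
    }
  }
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

# 1-based inclusive display label for a 0-based half-open interval.
display_label <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start + 1L, end)
}

#' Parse a BED file into target regions
#'
#' BED's 0-based half-open coordinates are preserved verbatim; each data line
#' becomes one region, including overlapping ones — the user asked for those
#' exact regions, so no merging is done.  Lines starting with `#`, `track` or
#' `browser` are skipped.  The label is column 4 when present, otherwise
#' `chrom:start-end` in 1-based inclusive display coordinates.
#'
#' @param path BED file (plain or gzip).
#' @param chroms data frame with `name`, `length` (e.g.
#'   `open_alignment(...)$chroms`) used for validation.
#' @return Data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
parse_bed <- function(path, chroms) {
  if (!file.exists(path)) stop("BED file not found: '", path, "'")
  lines <- readLines(con <- gzfile(path)); close(con)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("BED file '", path, "' contains no data lines")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  len_of <- stats::setNames(chroms$length, chroms$name)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]; lineno <- idx[i]
    if (length(f) < 3L)
      stop(sprintf("BED line %d: expected >= 3 tab-separated columns, got %d",
                   lineno, length(f)))
    chrom <- f[1L]
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("BED line %d: non-numeric start/end", lineno))
    if (!chrom %in% names(len_of))
      stop(sprintf("BED line %d: chromosome '%s' not in alignment header",
                   lineno, chrom))
    if (start < 0L || start >= end)
      stop(sprintf("BED line %d: invalid interval [%d, %d)", lineno, start, end))
    if (end > len_of[[chrom]])
      stop(sprintf("BED line %d: end %d exceeds %s length %d",
                   lineno, end, chrom, len_of[[chrom]]))
    label <- if (length(f) >= 4L && nzchar(f[4L])) f[4L]
             else display_label(chrom, start, end)
    out[[i]] <- list(chrom, start, end, label)
  }
  data.frame(chrom = vapply(out, `[[`, "", 1L),
             start = vapply(out, `[[`, 0L, 2L),
             end = vapply(out, `[[`, 0L, 3L),
             label = vapply(out, `[[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Tile chromosomes with fixed-size windows
#'
#' Non-overlapping windows `[0, w), [w, 2w), ...` per chromosome; the final
#' window is truncated at the chromosome length, so window lengths always sum
#' exactly to the chromosome length.
#'
#' @param chroms data frame with `name`, `length`.
#' @param window_size window width in bp, `>= 1`.
#' @return Data frame with columns `chrom`, `start`, `end`, `label` (1-based
#'   inclusive display).
#' @export
make_windows <- function(chroms, window_size) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) || window_size < 1L)
    stop("window_size must be a single positive integer")
  pieces <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    starts <- seq.int(0L, len - 1L, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = chroms$name[i], start = starts, end = ends,
               label = display_label(chroms$name[i], starts, ends),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# GFF3 vs GTF dialect sniffing from the attribute column: key=value with
# ID=/Parent= means GFF3; key "value"; means GTF.
detect_annotation_dialect <- function(path) {
  con <- gzfile(path, "r"); on.exit(close(con))
  n_checked <- 0L
  while (n_checked < 50L) {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) next
    attr <- f[9L]
    if (grepl("(^|;)\\s*(ID|Parent)=", attr)) return("gff3")
    if (grepl("\\w+\\s+\"", attr)) return("gtf")
    if (grepl("=", attr, fixed = TRUE)) return("gff3")
    n_checked <- n_checked + 1L
  }
  stop("could not detect GFF3/GTF dialect of '", path, "'")
}

# Resolve the gene ancestor of a feature ID by walking Parent links until a
# feature whose type matches /gene$/ (gene, pseudogene, ncRNA_gene, ...).
resolve_gene_ancestor <- function(ids, parent_of, type_of) {
  vapply(ids, function(id) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && !cur %in% seen) {
      seen <- c(seen, cur)
      ty <- type_of[[cur]]
      if (!is.null(ty) && grepl("gene$", ty)) return(cur)
      nxt <- parent_of[[cur]]
      cur <- if (is.null(nxt) || !length(nxt)) NA_character_ else nxt[[1L]]
    }
    NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Parse GFF3/GTF annotation into per-gene merged interval models
#'
#' For each gene, collects the features of the first preferred type that the
#' gene actually has (`CDS` if the gene has any CDS, else `exon`), pools them
#' across all of the gene's transcripts, converts 1-based closed GFF/GTF
#' coordinates to 0-based half-open, and merges overlapping/touching pieces
#' with [merge_intervals()].  Non-coding genes therefore fall back to exons
#' gene-by-gene, not file-globally.  Strand is ignored.
#'
#' Gene identity comes from the GFF3 ancestor of type `gene` (via `Parent`
#' chains) or the GTF `gene_id` attribute.  Features whose gene cannot be
#' resolved, or that sit on a chromosome absent from the alignment header,
#' are skipped with a counted warning.
#'
#' @param path GFF3 or GTF file (plain or gzip); dialect is auto-detected
#'   from the attribute syntax.
#' @param chroms data frame with `name`, `length` for validation.
#' @param feature_preference ordered character vector of feature types;
#'   default `c("CDS", "exon")`.
#' @return List of gene models, each a list with `gene_id`, `chrom`, `parts`
#'   (merged interval matrix), sorted by chromosome (header order) then
#'   leftmost start.
#' @export
parse_annotation <- function(path, chroms,
                             feature_preference = c("CDS", "exon")) {
  if (!file.exists(path)) stop("annotation file not found: '", path, "'")
  dialect <- detect_annotation_dialect(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  feat_idx <- which(type %in% feature_preference)

  if (dialect == "gff3") {
    ids <- as.character(mc$ID)
    parents <- mc$Parent            # CharacterList
    has_id <- !is.na(ids) & nzchar(ids)
    type_of <- as.list(stats::setNames(type[has_id], ids[has_id]))
    parent_of <- as.list(stats::setNames(as.list(parents[has_id]), ids[has_id]))
    # a feature may belong to several transcripts: resolve each parent
    feat_parent <- as.list(parents[feat_idx])
    anchor <- vapply(seq_along(feat_idx), function(k) {
      p <- feat_parent[[k]]
      if (length(p)) p[[1L]]
      else if (has_id[feat_idx[k]]) ids[feat_idx[k]] else NA_character_
    }, character(1L))
    gene_id <- resolve_gene_ancestor(anchor, parent_of, type_of)
  } else {
    gene_id <- as.character(mc$gene_id)[feat_idx]
    gene_id[!is.na(gene_id) & !nzchar(gene_id)] <- NA_character_
  }

  chrom <- as.character(GenomicRanges::seqnames(gr))[feat_idx]
  start0 <- GenomicRanges::start(gr)[feat_idx] - 1L  # 1-based closed -> half-open
  end0 <- GenomicRanges::end(gr)[feat_idx]
  ftype <- type[feat_idx]

  known <- chrom %in% chroms$name
  orphan <- is.na(gene_id)
  n_skip <- sum(orphan | !known)
  if (n_skip)
    warning(sprintf("skipped %d feature(s): %d with no resolvable gene, %d on chromosomes absent from the header",
                    n_skip, sum(orphan), sum(!orphan & !known)))
  keep <- !orphan & known
  if (!any(keep)) stop("no genes recovered from '", path, "'")
  gene_id <- gene_id[keep]; chrom <- chrom[keep]
  start0 <- start0[keep]; end0 <- end0[keep]; ftype <- ftype[keep]

  len_of <- stats::setNames(chroms$length, chroms$name)
  over <- end0 > len_of[chrom]
  if (any(over))
    stop(sprintf("annotation feature [%d, %d] exceeds %s length %d",
                 start0[which(over)[1L]] + 1L, end0[which(over)[1L]],
                 chrom[which(over)[1L]], len_of[[chrom[which(over)[1L]]]]))

  models <- lapply(split(seq_along(gene_id), gene_id), function(ii) {
    gchrom <- unique(chrom[ii])
    if (length(gchrom) != 1L) {
      warning("gene '", gene_id[ii[1L]], "' spans multiple chromosomes; skipped")
      return(NULL)
    }
    use <- integer()
    for (pref in feature_preference) {
      use <- ii[ftype[ii] == pref]
      if (length(use)) break
    }
    if (!length(use)) return(NULL)
    list(gene_id = gene_id[use[1L]], chrom = gchrom,
         parts = merge_intervals(cbind(start0[use], end0[use])))
  })
  models <- models[!vapply(models, is.null, TRUE)]
  if (!length(models)) stop("no genes recovered from '", path, "'")
  ord <- order(match(vapply(models, `[[`, "", "chrom"), chroms$name),
               vapply(models, function(g) g$parts[1L, 1L], 0L))
  unname(models[ord])
}
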