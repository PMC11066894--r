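# Shared fixtures, built once per test process and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# A mid-sized 4-chromosome fixture exercising every filter and CIGAR path.
fixture_std <- function() {
  if (is.null(.fixture_cache$std)) {
    cfg <- sim_config(chrom_lengths = c(2000L, 1500L, 900L, 600L),
                      n_reads = 300L, read_length = c(60L, 100L),
                      frac_duplicate = 0.10, frac_secondary = 0.05,
                      frac_unmapped = 0.05, frac_qcfail = 0.03,
                      frac_low_mapq = 0.20, p_indel = 0.15,
                      p_splice = 0.08, p_softclip = 0.15, seed = 42L)
    ref <- generate_reference(cfg)
    fx <- generate_alignments(cfg, ref)
    .fixture_cache$std <- list(cfg = cfg, ref = ref, fx = fx)
  }
  .fixture_cache$std
}

# Reduce an oracle per-base depth array over [start, end) half-open.
oracle_reduce <- function(depth, start, end) {
  x <- depth[(start + 1L):end]
  list(covered_site = sum(x >= 1L), total_depth = sum(x))
}

# Brute-force interval union oracle: per-base membership over [0, len).
union_mask <- function(intervals, len) {
  m <- logical(len)
  for (i in seq_len(nrow(intervals)))
    m[(intervals[i, 1L] + 1L):intervals[i, 2L]] <- TRUE
  m
}

# Hand-built annotation files with multi-transcript genes, overlapping and
# touching exons, CDS-bearing and CDS-free genes.
write_test_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t300\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tmRNA\t151\t300\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tsrc\texon\t151\t300\t.\t+\t.\tParent=t2",
    "chr1\tsrc\tgene\t401\t560\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t401\t560\t.\t-\t.\tID=t3;Parent=g2",
    "chr1\tsrc\texon\t401\t480\t.\t-\t.\tParent=t3",
    "chr1\tsrc\texon\t481\t560\t.\t-\t.\tParent=t3",  # touching -> one part
    "chr1\tsrc\tCDS\t411\t440\t.\t-\t0\tID=c1;Parent=t3",
    "chr1\tsrc\tCDS\t441\t470\t.\t-\t0\tID=c2;Parent=t3",
    "chr2\tsrc\tgene\t1\t50\t.\t+\t.\tID=g3",
    "chr2\tsrc\tmRNA\t1\t50\t.\t+\t.\tID=t4;Parent=g3",
    "chr2\tsrc\texon\t1\t50\t.\t+\t.\tParent=t4"), path)
  path
}

write_test_gtf <- function(path) {
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\";"),
    paste0("chr1\tsrc\texon\t151\t300\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t2\";"),
    paste0("chr1\tsrc\texon\t401\t480\t.\t-\t.\t",
           "gene_id \"g2\"; transcript_id \"t3\";"),
    paste0("chr1\tsrc\texon\t481\t560\t.\t-\t.\t",
           "gene_id \"g2\"; transcript_id \"t3\";"),
    paste0("chr1\tsrc\tCDS\t411\t440\t.\t-\t0\t",
           "gene_id \"g2\"; transcript_id \"t3\";"),
    paste0("chr1\tsrc\tCDS\t441\t470\t.\t-\t0\t",
           "gene_id \"g2\"; transcript_id \"t3\";"),
    paste0("chr2\tsrc\texon\t1\t50\t.\t+\t.\t",
           "gene_id \"g3\"; transcript_id \"t4\";")), path)
  path
}

# Expected merged parts of the hand-built annotations (0-based half-open):
# g1 exons pooled across transcripts, g2 prefers CDS, g3 exon fallback.
expected_gene_parts <- function() {
  list(g1 = cbind(start = 100L, end = 300L),
       g2 = cbind(start = 410L, end = 470L),
       g3 = cbind(start = 0L, end = 50L))
}

std_chroms <- function() {
  data.frame(name = c("chr1", "chr2"), length = c(2000L, 1500L),
             stringsAsFactors = FALSE)
}
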