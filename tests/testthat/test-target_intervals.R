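test_that("merge_intervals merges overlaps and touching pairs", {
  expect_identical(merge_intervals(rbind(c(0L, 10L), c(4L, 20L))),
                   cbind(start = 0L, end = 20L))
  expect_identical(merge_intervals(rbind(c(0L, 5L), c(5L, 10L))),
                   cbind(start = 0L, end = 10L))
  expect_identical(merge_intervals(rbind(c(10L, 20L), c(0L, 5L))),
                   cbind(start = c(0L, 10L), end = c(5L, 20L)))
  expect_error(merge_intervals(rbind(c(5L, 5L))), "start must be < end")
})

test_that("merge_intervals is idempotent, order-invariant and contracting", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:12, 1L)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:80, n, replace = TRUE)
    m <- merge_intervals(cbind(s, e))
    expect_identical(merge_intervals(m), m)                       # idempotent
    perm <- sample(n)
    expect_identical(merge_intervals(cbind(s[perm], e[perm])), m) # order-inv
    expect_lte(sum(m[, 2L] - m[, 1L]), sum(e - s))                # contracting
    expect_true(all(diff(m[, 1L]) > 0))
    if (nrow(m) > 1L)           # disjoint and non-touching
      expect_true(all(m[-1L, 1L] > m[-nrow(m), 2L]))
    # union preserved, checked per-base
    expect_identical(union_mask(m, 600L), union_mask(cbind(s, e), 600L))
  }
})

test_that("parse_bed preserves coordinates and validates lines", {
  chroms <- std_chroms()
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x", "browser position chr1",
               "chr1\t0\t100\tgeneA", "chr1\t50\t60", "chr2\t10\t20\t"),
             bed)
  out <- parse_bed(bed, chroms)
  expect_identical(out$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(out$start, c(0L, 50L, 10L))
  expect_identical(out$end, c(100L, 60L, 20L))
  # label: column 4 if present, else 1-based display
  expect_identical(out$label, c("geneA", "chr1:51-60", "chr2:11-20"))

  bad <- withr::local_tempfile()
  writeLines("chrZ\t0\t10", bad)
  expect_error(parse_bed(bad, chroms), "line 1.*chrZ")
  writeLines(c("chr1\t5\t10", "chr1\t9\t3"), bad)
  expect_error(parse_bed(bad, chroms), "line 2")
  writeLines("chr2\t0\t999999", bad)
  expect_error(parse_bed(bad, chroms), "exceeds")
  writeLines("chr1\t1", bad)
  expect_error(parse_bed(bad, chroms), ">= 3")
})

test_that("make_windows tiles chromosomes exactly", {
  chroms <- data.frame(name = c("a", "b", "c"),
                       length = c(250L, 100L, 50L))
  w <- make_windows(chroms, 100L)
  a <- w[w$chrom == "a", ]
  expect_identical(a$start, c(0L, 100L, 200L))
  expect_identical(a$end, c(100L, 200L, 250L))          # remainder truncated
  expect_identical(w[w$chrom == "b", ]$end, 100L)       # exact fit
  expect_identical(w[w$chrom == "c", ]$end, 50L)        # window > chromosome
  expect_identical(a$label[1L], "a:1-100")
  # window lengths sum exactly to chromosome length, for random sizes
  set.seed(3)
  for (size in sample(1:400, 10L)) {
    ws <- make_windows(chroms, size)
    sums <- tapply(ws$end - ws$start, ws$chrom, sum)
    expect_identical(as.integer(sums[chroms$name]), chroms$length)
  }
  expect_error(make_windows(chroms, 0L), "positive")
})

test_that("parse_annotation builds merged per-gene models from GFF3", {
  gff <- write_test_gff3(withr::local_tempfile(fileext = ".gff3"))
  genes <- parse_annotation(gff, std_chroms())
  expect_identical(vapply(genes, `[[`, "", "gene_id"), c("g1", "g2", "g3"))
  exp <- expected_gene_parts()
  for (g in genes) {
    expect_identical(unname(g$parts), unname(exp[[g$gene_id]]))
    expect_true(all(g$parts[, 1L] >= 0L))
    expect_true(all(g$parts[, 2L] <=
                      std_chroms()$length[std_chroms()$name == g$chrom]))
  }
  # round-trip: half-open back to 1-based closed reproduces the GFF exon
  g1 <- genes[[1L]]
  expect_identical(unname(c(g1$parts[1L, 1L] + 1L, g1$parts[1L, 2L])),
                   c(101L, 300L))
})

test_that("parse_annotation handles GTF dialect with gene_id grouping", {
  gtf <- write_test_gtf(withr::local_tempfile(fileext = ".gtf"))
  genes <- parse_annotation(gtf, std_chroms())
  expect_identical(vapply(genes, `[[`, "", "gene_id"), c("g1", "g2", "g3"))
  exp <- expected_gene_parts()
  for (g in genes)
    expect_identical(unname(g$parts), unname(exp[[g$gene_id]]))
})

test_that("feature preference is per gene and configurable", {
  gff <- write_test_gff3(withr::local_tempfile(fileext = ".gff3"))
  # exon-only preference ignores the CDS of g2
  genes <- parse_annotation(gff, std_chroms(), feature_preference = "exon")
  g2 <- genes[[which(vapply(genes, `[[`, "", "gene_id") == "g2")]]
  expect_identical(unname(g2$parts), cbind(400L, 560L))  # touching exons merged
})

test_that("parse_annotation skips orphans and unknown chromosomes, fails on zero genes", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t10\t20\t.\t+\t.\tParent=ghost",
               "chrZ\tsrc\tgene\t1\t50\t.\t+\t.\tID=gz",
               "chrZ\tsrc\texon\t1\t50\t.\t+\t.\tParent=gz",
               "chr1\tsrc\tgene\t1\t30\t.\t+\t.\tID=ok",
               "chr1\tsrc\texon\t1\t30\t.\t+\t.\tParent=ok"), p)
  expect_warning(genes <- parse_annotation(p, std_chroms()), "skipped 2")
  expect_identical(vapply(genes, `[[`, "", "gene_id"), "ok")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t10\t20\t.\t+\t.\tParent=ghost"), p)
  expect_error(suppressWarnings(parse_annotation(p, std_chroms())),
               "no genes")
})
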