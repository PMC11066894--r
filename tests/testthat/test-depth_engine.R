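test_that("accumulate_read follows CIGAR reference-consumption semantics", {
  d <- depth_blocks("c", 40L)
  accumulate_read(d, 0L, "10M")
  expect_identical(depth_vector(d), c(rep(1, 10), rep(0, 30)))

  # insertion consumes no reference
  d <- depth_blocks("c", 40L)
  accumulate_read(d, 0L, "5M2I5M")
  expect_identical(depth_vector(d), c(rep(1, 10), rep(0, 30)))

  # deletion advances the cursor without incrementing
  d <- depth_blocks("c", 40L)
  accumulate_read(d, 0L, "3M2D3M")
  expect_identical(depth_vector(d), c(1, 1, 1, 0, 0, 1, 1, 1, rep(0, 32)))

  # N skips like D; S/H/P neither consume nor count
  d <- depth_blocks("c", 40L)
  accumulate_read(d, 2L, "2S3M4N3M1H")
  expect_identical(which(depth_vector(d) > 0), c(3:5, 10:12))

  expect_error(accumulate_read(depth_blocks("c", 40L), 0L, "5M2Q"),
               "malformed CIGAR")
})

test_that("reads spanning block boundaries split correctly", {
  # two-block toy, block_size 8, read crossing the boundary
  d <- depth_blocks("c", 20L, block_size = 8L)
  accumulate_read(d, 5L, "12M")
  expect_identical(depth_vector(d), c(rep(0, 5), rep(1, 12), rep(0, 3)))
  expect_identical(sort(names(d$blocks)), c("0", "1", "2"))
  # same pattern at the declared 1 MiB default boundary
  d2 <- depth_blocks("c", 1048600L)
  accumulate_read(d2, 1048570L, "12M")
  expect_identical(depth_vector(d2, 1048568L, 1048584L),
                   c(0, 0, rep(1, 12), 0, 0))
  expect_identical(sort(names(d2$blocks)), c("0", "1"))
})

test_that("increments past the chromosome end are discarded with a warning", {
  d <- depth_blocks("c", 10L)
  expect_warning(accumulate_read(d, 6L, "8M"), "past chromosome end")
  expect_identical(depth_vector(d), c(rep(0, 6), rep(1, 4)))
})

test_that("region_stats arithmetic matches the definitions", {
  d <- depth_blocks("c", 5L)
  accumulate_read(d, 2L, "1M")
  accumulate_read(d, 3L, "1M")
  accumulate_read(d, 3L, "1M")
  # depth array [0,0,1,2,0]
  s <- region_stats(d, list(chrom = "c", start = 0L, end = 5L))
  expect_identical(s$covered_site, 2)
  expect_identical(s$total_depth, 3)
  expect_equal(s$coverage_pct, 40.0)
  expect_equal(s$mean_depth, 0.6)

  empty <- region_stats(depth_blocks("c", 100L),
                        list(chrom = "c", start = 0L, end = 100L))
  expect_identical(unlist(empty[1:4]),
                   c(covered_site = 0, total_depth = 0, coverage_pct = 0,
                     mean_depth = 0))
  expect_error(region_stats(d, list(chrom = "c", start = 0L, end = 6L)),
               "outside chromosome bounds")
  expect_error(region_stats(d, list(chrom = "x", start = 0L, end = 5L)),
               "does not match")
})

test_that("gene_stats aggregates merged parts with pooled denominator", {
  d <- depth_blocks("c", 40L)
  accumulate_read(d, 0L, "30M")
  accumulate_read(d, 0L, "30M")
  g <- list(gene_id = "g", chrom = "c",
            parts = cbind(start = c(0L, 20L), end = c(10L, 30L)))
  s <- gene_stats(d, g)
  expect_identical(s$covered_site, 20)
  expect_identical(s$total_depth, 40)
  expect_equal(s$coverage_pct, 100.0)
  expect_equal(s$mean_depth, 2.0)
  expect_identical(s$length, 20L)
  # single-part gene reduces to region_stats on that part
  g1 <- list(gene_id = "g1", chrom = "c", parts = cbind(5L, 25L))
  expect_identical(gene_stats(d, g1)[1:4],
                   region_stats(d, list(chrom = "c", start = 5L, end = 25L))[1:4])
  # zero-depth gene
  g0 <- list(gene_id = "g0", chrom = "c", parts = cbind(35L, 40L))
  expect_identical(gene_stats(d, g0)$total_depth, 0)
})

test_that("blocked engine equals the naive oracle for any block size", {
  s <- fixture_std()
  truth <- s$fx$truth
  recs <- truth[passes_filters(truth, filter_config()) &
                  !is.na(truth$ref_name), ]
  for (ch in s$ref$chroms$name) {
    len <- s$ref$chroms$length[s$ref$chroms$name == ch]
    od <- oracle_depth(truth, ch, len)
    ref_stats <- oracle_reduce(od, 0L, len)
    for (bs in c(7L, 64L, 1048576L)) {
      d <- depth_blocks(ch, len, block_size = bs)
      accumulate_records(d, recs)
      st <- region_stats(d, list(chrom = ch, start = 0L, end = len))
      expect_identical(st$covered_site, as.numeric(ref_stats$covered_site))
      expect_identical(st$total_depth, as.numeric(ref_stats$total_depth))
      expect_identical(depth_vector(d), as.numeric(od))
    }
  }
})

test_that("accumulation is order-invariant and monotone", {
  s <- fixture_std()
  truth <- s$fx$truth
  recs <- truth[passes_filters(truth, filter_config()) &
                  !is.na(truth$ref_name) & truth$ref_name == "chr2", ]
  len <- 1500L
  d1 <- depth_blocks("chr2", len, block_size = 64L)
  accumulate_records(d1, recs)
  set.seed(5)
  d2 <- depth_blocks("chr2", len, block_size = 64L)
  accumulate_records(d2, recs[sample(nrow(recs)), ])
  expect_identical(depth_vector(d1), depth_vector(d2))

  before <- region_stats(d1, list(chrom = "chr2", start = 0L, end = len))
  accumulate_read(d1, 100L, "50M")
  after <- region_stats(d1, list(chrom = "chr2", start = 0L, end = len))
  expect_gte(after$covered_site, before$covered_site)
  expect_gte(after$total_depth, before$total_depth)
})

test_that("lazy blocks: untouched chromosome slices cost no memory", {
  d <- depth_blocks("c", 10000000L)      # 10 Mb, ten potential blocks
  expect_length(d$blocks, 0L)
  accumulate_read(d, 0L, "10M")
  expect_length(d$blocks, 1L)
})
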