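test_that("FASTA reading normalizes case and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr", "acTAgt"), fa)
  g <- read_genome(fa, circular = FALSE)
  expect_equal(as.character(g), "ACTAGT")
  expect_equal(nchar(g), 6L)

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa2)
  expect_error(read_genome(fa2), "multiple")
})

test_that("TA site enumeration matches a direct substring scan", {
  for (seed in 1:3) {
    seq <- random_seq(3000, seed)
    sites <- find_ta_sites(seq, circular = FALSE)
    expect_equal(sites$position, scan_ta_oracle(seq))
  }
})

test_that("TA enumeration handles overlaps, edges and circular wrap", {
  s <- find_ta_sites("GGTACC", circular = FALSE)
  expect_equal(s$position, 2L)
  expect_equal(s$context6, "GGTACC")
  expect_false(s$excluded)

  s <- find_ta_sites("TATATA", circular = FALSE)
  expect_equal(s$position, c(0L, 2L, 4L))
  # edge sites of a linear genome get N-padded context and are excluded
  expect_true(s$excluded[1])
  expect_true(s$excluded[3])
  expect_false(s$excluded[2])
  expect_equal(s$context6[2], "TATATA")

  s <- find_ta_sites("TAGGGG", circular = TRUE)
  expect_equal(s$position, 0L)
  expect_equal(s$context6, "GGTAGG")
  expect_false(s$excluded)
})

test_that("canonical motif is strand-symmetric, idempotent, and partitions", {
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(a = nt, b = nt, c = nt, d = nt,
                   stringsAsFactors = FALSE)
  ctx <- paste0(g$a, g$b, "TA", g$c, g$d)
  rc <- tifa:::revcomp_chr(ctx)
  canon <- canonical_motif(ctx)
  expect_equal(canonical_motif(rc), canon)
  expect_equal(canonical_motif(canon), canon)
  expect_equal(length(unique(canon)), 136L)
  expect_equal(sum(ctx == rc), 16L)
  # every context maps into the enumerated class set
  expect_true(all(canon %in% enumerate_motif_classes()$motif_class))
  # hand-derived class merges and palindromes
  expect_equal(canonical_motif("GTTAAC"), "GTTAAC")
  expect_equal(canonical_motif("AATATT"), "AATATT")
  expect_equal(canonical_motif("TATATG"), canonical_motif("CATATA"))
  expect_error(canonical_motif("GGGGGG"), "TA")
})

test_that("insertion filtering applies the read, mapping and TA rules", {
  seq <- "GGTACCGGTACCGGTACC"  # TA sites at 2, 8, 14
  sites <- find_ta_sites(seq, circular = FALSE)
  rec <- data.frame(
    position = c(2L, 8L, 14L, 3L, 5L),
    unique = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    reads_s1 = c(10L, 3L, 50L, 9L, 20L),
    reads_s2 = c(5L, 4L, 0L, 0L, 1L))
  flt <- filter_insertions(rec, sites)
  # rec1 kept; rec2 has 7 reads (low); rec3 non-unique; rec4 at position+1
  # collapses onto the TA at 2; rec5 is at a non-TA position
  expect_equal(flt$report,
               c(non_unique = 1L, low_count = 1L, non_ta = 1L))
  expect_equal(sum(flt$report) + nrow(flt$retained), flt$n_input)
  expect_setequal(flt$retained$site_position, c(2L, 2L))
  # idempotent: filtering the retained set changes nothing
  again <- filter_insertions(flt$retained[names(rec)], sites)
  expect_equal(nrow(again$retained), nrow(flt$retained))
  expect_equal(sum(again$report), 0L)
  expect_error(filter_insertions(transform(rec, position = 99L), sites),
               "beyond")
})

test_that("sample combination is a union over retained records", {
  seq <- random_seq(2000, 9)
  sites <- find_ta_sites(seq, circular = FALSE)
  pos <- sites$position
  a <- pos[1:10]
  b <- pos[11:15]
  rec <- data.frame(position = c(a, b), unique = TRUE,
                    reads_s1 = c(rep(20L, 10), rep(0L, 5)),
                    reads_s2 = c(rep(0L, 10), rep(20L, 5)))
  flt <- filter_insertions(rec, sites)
  got <- combine_samples(sites, flt$retained)
  expect_equal(sum(got$inserted), 15L)
  expect_true(all(got$inserted[match(c(a, b), got$position)]))
})

test_that("site-to-gene assignment excludes overlaps and trims the 3' end", {
  # genome of pure TA repeats: a site every 2 nt
  seq <- strrep("TA", 300)  # length 600
  sites <- find_ta_sites(seq, circular = TRUE)
  genes <- data.frame(locus_id = c("gA", "gB", "gC"),
                      start = c(0L, 80L, 200L),
                      end = c(100L, 180L, 400L),
                      strand = c("+", "+", "-"))
  asg <- assign_sites(sites, genes)
  # sites in [80, 100) covered by both gA and gB are excluded
  ov <- asg$ta_sites$position >= 80 & asg$ta_sites$position < 100
  expect_true(all(asg$ta_sites$excluded[ov]))
  expect_true(all(asg$ta_sites$reason[ov] == "overlap"))
  # plus strand: core drops sites at offset >= 98% of length
  gA_core_pos <- asg$ta_sites$position[asg$genes$core_idx[[1]]]
  expect_true(all(gA_core_pos < 80))            # overlap zone excluded too
  gB_sites <- asg$ta_sites$position[asg$genes$site_idx[[2]]]
  gB_core <- asg$ta_sites$position[asg$genes$core_idx[[2]]]
  expect_true(all(gB_core - 80 < 0.98 * 100))
  expect_true(length(gB_sites) > length(gB_core))
  # minus strand: 3' end is the low-coordinate end
  gC_core <- asg$ta_sites$position[asg$genes$core_idx[[3]]]
  expect_true(all(gC_core - 200 >= 0.02 * 200))
  expect_true(all(asg$genes$s <= asg$genes$s_all))
})

test_that("tabular gene and operon readers round-trip", {
  gtsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "locus_id\tstart\tend\tstrand",
               "g1\t0\t300\t+", "g2\t400\t900\t-"), gtsv)
  genes <- read_genes(gtsv)
  expect_equal(genes$locus_id, c("g1", "g2"))
  expect_equal(genes$end, c(300L, 900L))

  otsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("operon_id\tgenes", "op1\tg1,g2"), otsv)
  ops <- read_operons(otsv)
  expect_equal(ops$op1, c("g1", "g2"))
})
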