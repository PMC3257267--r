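test_that("raw activity reader parses clean rows and reports malformed ones", {
  f <- toy_activity_file(c(
    toy_activity_row(molregno = "M1"),
    toy_activity_row(molregno = "M2", value = "250", units = "uM"),
    toy_activity_row(molregno = "M3", standard_type = "pKi", value = "7.5",
                     units = "")
  ))
  out <- read_activity_table(f)
  expect_equal(nrow(out$records), 3L)
  expect_equal(nrow(out$errors), 0L)
  expect_equal(out$records$compound_id, c("M1", "M2", "M3"))
  expect_equal(out$records$value, c(10, 250, 7.5))

  # header-only file
  f2 <- toy_activity_file(character(0))
  out2 <- read_activity_table(f2)
  expect_equal(nrow(out2$records), 0L)

  # one unparseable value -> 2 records + 1 row error with its line number
  f3 <- toy_activity_file(c(
    toy_activity_row(molregno = "M1"),
    toy_activity_row(molregno = "M2", value = "abc"),
    toy_activity_row(molregno = "M3")
  ))
  out3 <- read_activity_table(f3)
  expect_equal(nrow(out3$records), 2L)
  expect_equal(out3$records$compound_id, c("M1", "M3"))
  expect_equal(out3$errors$line, 3L) # line number includes the header
})

test_that("missing mapped columns are a configuration error", {
  f <- write_tsv_lines(c("molregno\tvalue", "M1\t5"))
  expect_error(read_activity_table(f), "absent from header")
})

test_that("paired-table dialects recompute diff and handle scales and signs", {
  s2 <- write_tsv_lines(c(
    "prefName\tUniprot1\tUniprot2\tAfnty1\tAfnty2\tmolregno",
    "T one\tP1\tQ1\t8.0\t7.0\tM1",
    "T one\tP1\tQ1\t6.5\t−7.5\tM2" # Unicode minus accepted
  ))
  out <- read_paired_table(s2, "S2")
  expect_equal(out$diff, c(1.0, 14.0))
  expect_equal(out$accession_b, c("Q1", "Q1"))

  # S3 identity auto-detected as percent when any value > 1
  s3 <- write_tsv_lines(c(
    "Accession1\tAccession2\tseqId\tmolregno\tAfnty1\tAfnty2",
    "P1\tP2\t35\tM1\t8\t6",
    "P1\tP3\t90\tM2\t5\t5.5"
  ))
  out3 <- read_paired_table(s3, "S3")
  expect_equal(out3$identity_full, c(0.35, 0.90))
  expect_equal(out3$diff, c(2, -0.5))

  # explicit fraction override disables the auto-detection
  s3f <- write_tsv_lines(c(
    "Accession1\tAccession2\tseqId\tmolregno\tAfnty1\tAfnty2",
    "P1\tP2\t0.4\tM1\t8\t6"
  ))
  expect_equal(read_paired_table(s3f, "S3", seqid_scale = "fraction")$identity_full,
               0.4)

  # S1 stored diff is cross-checked, not trusted
  s1 <- write_tsv_lines(c(
    "prefName\ttid\tAfnty1\tAfnty2\tmolregno\tmeasured\tdiff",
    "T\tT1\t8.0\t7.0\tM1\t2\t1.0",
    "T\tT1\t6.0\t7.0\tM2\t2\t0.5" # stored diff wrong
  ))
  out1 <- read_paired_table(s1, "S1")
  expect_equal(out1$diff, c(1, -1)) # always recomputed
  disc <- attr(out1, "discrepancies")
  expect_equal(disc$line, 3L)
  expect_equal(disc$stored_diff, 0.5)

  # rows keep their file order
  expect_equal(out3$compound_id, c("M1", "M2"))
})

test_that("alignment FASTA reader enforces the two-record equal-length contract", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF-HIKL", ">b", "ACDEFGHIK-"), f)
  ap <- read_alignment_pair(f)
  expect_equal(nchar(ap$seq_a), 10L)
  expect_equal(ap$seq_a, "ACDEF-HIKL")

  writeLines(c(">a", "ACDEF", ">b", "ACDEF", ">c", "ACDEF"), f)
  expect_error(read_alignment_pair(f), "exactly 2 records")

  writeLines(c(">a", "ACDEF", ">b", "ACD"), f)
  expect_error(read_alignment_pair(f), "unequal lengths")

  # sequences are uppercased
  writeLines(c(">a", "acdef", ">b", "acdef"), f)
  expect_equal(read_alignment_pair(f)$seq_a, "ACDEF")
})

test_that("screen report is sorted by adjusted p and keeps absent counts empty", {
  res <- tibble::tibble(
    name = c("slow", "hit"), delta_mean = c(0.1, 1.2),
    n_compounds = c(10L, 50L), n_chemotypes = c(NA_integer_, 4L),
    mapped_domain = c("DOM01", NA), p_adj = c(0.3, 0.01),
    flagged = c(FALSE, TRUE)
  )
  f <- tempfile(fileext = ".tsv")
  write_screen_table(res, f)
  lines <- readLines(f)
  expect_match(lines[2], "^hit\t") # flagged row first
  expect_match(lines[3], "^slow\t0.1\t10\t\t") # empty cell, not 0

  # empty input -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_screen_table(res[0, ], f2)
  expect_length(readLines(f2), 1L)
})

test_that("paired and screen tables round-trip through write/read to 6 decimals", {
  paired <- tibble::tibble(
    pref_name = c("T1", "T2"), accession_a = c("P1", "P2"),
    accession_b = c("Q1", "Q2"), compound_id = c("M1", "M2"),
    afnty1 = c(8.1234567, 5.7654321), afnty2 = c(7.0000001, 6.25),
    diff = c(8.1234567 - 7.0000001, 5.7654321 - 6.25)
  )
  f <- tempfile(fileext = ".tsv")
  write_paired_table(paired, f, "S2")
  back <- read_paired_table(f, "S2")
  expect_equal(back$afnty1, paired$afnty1, tolerance = 1e-6)
  expect_equal(back$diff, paired$diff, tolerance = 1e-6)

  paired$identity_full <- c(0.334455, 0.912345)
  f3 <- tempfile(fileext = ".tsv")
  write_paired_table(paired, f3, "S3")
  back3 <- read_paired_table(f3, "S3")
  expect_equal(back3$identity_full, paired$identity_full, tolerance = 1e-6)

  res <- tibble::tibble(
    name = "T1", delta_mean = 0.591234, n_compounds = 325L,
    n_chemotypes = 30L, mapped_domain = "DOM01", p_adj = 0.0123456,
    flagged = TRUE
  )
  fs <- tempfile(fileext = ".tsv")
  write_screen_table(res, fs)
  backs <- read_screen_table(fs)
  expect_equal(backs$delta_mean, res$delta_mean, tolerance = 1e-6)
  expect_equal(backs$p_adj, res$p_adj, tolerance = 1e-6)
})

test_that("domain and site annotation readers validate coordinates", {
  f <- write_tsv_lines(c("accession\tpfam_acc\tstart\tend",
                         "P1\tDOM01\t10\t200", "P1\tDOM02\t1\t9"))
  dom <- read_domain_table(f)
  expect_equal(nrow(dom), 2L)
  expect_equal(dom$start, c(10L, 1L))

  bad <- write_tsv_lines(c("accession\tpfam_acc\tstart\tend",
                           "P1\tDOM01\t50\t40"))
  expect_error(read_domain_table(bad), "start > end")

  s <- write_tsv_lines(c("accession\tpositions", "P1\t3,5, 8"))
  site <- read_site_table(s)
  expect_equal(site$positions[[1]], c(3L, 5L, 8L))
})
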