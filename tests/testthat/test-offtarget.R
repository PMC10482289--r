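# Off-target caller: I/O, orientation, filters, replicate/control rules

test_that("count tables round-trip through the native TSV schema and map foreign columns", {
  tab <- rbind(passing_row("d1"), passing_row("d2"),
               count_row("d1", 7, "G", A = 40, G = 60))
  f <- tempfile(fileext = ".tsv")
  write_site_counts(tab, f)
  back <- read_site_counts(f)
  expect_identical(back$rna_T, tab$rna_T)
  expect_identical(back$dna_ref, tab$dna_ref)

  # JACUSA-style export with foreign column names, ingested via mapping
  foreign <- tab
  names(foreign) <- c("sample", "chrom", "pos", "ref", "bcA", "bcC", "bcG", "bcT")
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(foreign, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  mapped <- read_site_counts(f2, col_map = c(
    dataset = "sample", contig = "chrom", position = "pos", dna_ref = "ref",
    rna_A = "bcA", rna_C = "bcC", rna_G = "bcG", rna_T = "bcT"))
  expect_identical(mapped, back)

  # zero-coverage rows dropped with a message; empty file yields empty frame
  tab0 <- rbind(tab, count_row("d1", 9, "C"))
  f3 <- tempfile(fileext = ".tsv")
  write_site_counts(tab0, f3)
  expect_message(res <- read_site_counts(f3), "zero-coverage")
  expect_identical(nrow(res), 3L)
  f4 <- tempfile(fileext = ".tsv")
  write_site_counts(tab[0, ], f4)
  expect_identical(nrow(read_site_counts(f4)), 0L)

  expect_error(read_site_counts(f2), "missing mandatory")
  bad <- tab; bad$rna_A <- c("x", "0", "0")
  f5 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, f5, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_counts(f5), "non-numeric.*line 2")
})

test_that("orientation derives strand, purity and edit fraction per the criteria", {
  x <- orient_sites(rbind(
    count_row("d", 1, "C", A = 0, C = 900, G = 5, T = 95),
    count_row("d", 2, "G", A = 40, C = 0, G = 60, T = 0),
    count_row("d", 3, "A", A = 100)))
  expect_identical(x$strand, c("+", "-", NA))
  expect_identical(x$candidate, c(TRUE, TRUE, FALSE))
  expect_equal(x$transition_purity[1], 995 / 1000)
  expect_equal(x$edit_frac[1], 95 / 995)
  expect_equal(x$transition_purity[2], 1.0)
  expect_equal(x$edit_frac[2], 0.40)
})

test_that("the four criteria use the stated comparison directions at their boundaries", {
  p <- caller_params()
  # coverage 29 with otherwise perfect evidence fails only criterion (i)
  r29 <- passes_filters(orient_sites(count_row("d", 1, "C", C = 26, T = 3)), p)
  expect_false(r29$cov_ok); expect_true(r29$purity_ok); expect_true(r29$signal_ok)
  # coverage exactly 30 passes (>= threshold)
  r30 <- passes_filters(orient_sites(count_row("d", 1, "C", C = 27, T = 3)), p)
  expect_true(r30$cov_ok); expect_true(r30$pass)
  # transition purity exactly 0.99 fails the strict > comparison
  rp <- passes_filters(orient_sites(count_row("d", 1, "C", C = 90, T = 9, G = 1)), p)
  expect_false(rp$purity_ok)
  # edit fraction exactly 0.01 passes; 0.009 fails criterion (iv)
  rs <- passes_filters(orient_sites(count_row("d", 1, "C", C = 990, T = 10)), p)
  expect_true(rs$signal_ok)
  rs2 <- passes_filters(orient_sites(count_row("d", 1, "C", C = 991, T = 9)), p)
  expect_false(rs2$signal_ok)
  # DNA purity exactly 0.98 fails strict >; absent DNA counts are assumed pure
  rd <- passes_filters(orient_sites(
    count_row("d", 1, "C", C = 180, T = 20, dna = c(0, 98, 2, 0))), p)
  expect_false(rd$dna_ok); expect_false(rd$dna_assumed)
  rno <- passes_filters(orient_sites(count_row("d", 1, "C", C = 180, T = 20)), p)
  expect_true(rno$dna_ok); expect_true(rno$dna_assumed)
})

test_that("replicate restriction and control exclusion gate the calls", {
  sets <- dataset_set("PPR56", c("t1", "t2", "t3"), "w1")
  # passes in 2 of 3 treatment datasets, silent in control -> called
  counts <- rbind(passing_row("t1"), passing_row("t2"),
                  count_row("t3", 100, "C", C = 200),
                  count_row("w1", 100, "C", C = 200))
  calls <- call_offtargets(counts, sets)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_supporting, 2L)
  expect_identical(calls$supporting_datasets, "t1,t2")

  # passing in exactly 1 dataset -> not called
  one <- rbind(passing_row("t1"), count_row("t2", 100, "C", C = 200),
               count_row("t3", 100, "C", C = 200))
  expect_identical(nrow(call_offtargets(one, sets)), 0L)

  # edited >= 1% in a covered control dataset -> excluded
  leak <- rbind(passing_row("t1"), passing_row("t2"),
                count_row("w1", 100, "C", C = 95, T = 5))
  expect_identical(nrow(call_offtargets(leak, sets)), 0L)
  # control coverage below min_control_coverage cannot exclude
  thin <- rbind(passing_row("t1"), passing_row("t2"),
                count_row("w1", 100, "C", C = 4, T = 5))
  expect_identical(nrow(call_offtargets(thin, sets)), 1L)

  expect_error(dataset_set("PPR56", c("t1", "t2"), c("t2", "w1")), "overlap")
})

test_that("aggregate efficiency is the read-sum rule and the Sanger ratio matches", {
  expect_equal(aggregate_efficiency(c(10, 30), c(90, 70)), 0.20)
  expect_equal(aggregate_efficiency(38, 62), 0.38)
  # read-sum equals the coverage-weighted mean of per-dataset fractions
  expect_equal(aggregate_efficiency(c(1, 99), c(9, 891)), 100 / 1000)
  set.seed(31)
  for (i in 1:20) {
    ed <- sample(0:50, 3); un <- sample(1:50, 3)
    expect_equal(aggregate_efficiency(ed, un),
                 sum((ed + un) / sum(ed + un) * ed / (ed + un)))
  }
  expect_error(aggregate_efficiency(0, 0), "undefined")

  expect_equal(quantify_peaks(0, 5), 0)
  expect_equal(quantify_peaks(5, 0), 1)
  expect_equal(quantify_peaks(3, 1), 0.75)
  expect_error(quantify_peaks(0, 0), "undefined")
})

test_that("the caller agrees with a naive nested-loop reference on random tables", {
  sets <- dataset_set("PPR56", c("t1", "t2", "t3"), "w1")
  set.seed(47)
  for (i in 1:15) {
    counts <- random_counts()
    mine <- as.data.frame(call_offtargets(counts, sets))
    ref <- naive_call(counts, sets$treatment, sets$control)
    expect_identical(mine$position, ref$position)
    expect_identical(mine$strand, ref$strand)
    expect_equal(mine$aggregate_efficiency, ref$aggregate_efficiency)
  }
})

test_that("tightening any threshold never increases the number of called sites", {
  sets <- dataset_set("PPR56", c("t1", "t2", "t3"), "w1")
  set.seed(53)
  counts <- do.call(rbind, lapply(1:4, function(i) random_counts(n_pos = 15)))
  counts$contig <- rep(c("c1", "c2"), length.out = nrow(counts))
  base_n <- nrow(call_offtargets(counts, sets))
  tighter <- list(
    caller_params(min_coverage = 60),
    caller_params(min_transition_purity = 0.999),
    caller_params(min_dna_purity = 0.999),
    caller_params(min_edit_frac = 0.05),
    caller_params(min_replicates = 3),
    caller_params(min_control_frac = 0.001),
    caller_params(min_control_coverage = 1))
  for (p in tighter) {
    expect_lte(nrow(call_offtargets(counts, sets, p)), base_n)
  }
})

test_that("reverse-complementing the table flips strands but preserves the call set", {
  sets <- dataset_set("PPR56", c("t1", "t2", "t3"), "w1")
  set.seed(59)
  counts <- random_counts()
  flip <- counts
  flip$dna_ref <- chartr("ACGT", "TGCA", counts$dna_ref)
  flip$rna_A <- counts$rna_T; flip$rna_T <- counts$rna_A
  flip$rna_C <- counts$rna_G; flip$rna_G <- counts$rna_C
  a <- as.data.frame(call_offtargets(counts, sets))
  b <- as.data.frame(call_offtargets(flip, sets))
  expect_identical(nrow(a), nrow(b))
  expect_identical(a$position, b$position)
  expect_identical(a$strand, chartr("+-", "-+", b$strand))
  expect_equal(a$aggregate_efficiency, b$aggregate_efficiency)
})

test_that("identical inputs give byte-identical output tables", {
  sets <- dataset_set("PPR56", c("t1", "t2", "t3"), "w1")
  set.seed(61)
  counts <- random_counts()
  f1 <- tempfile(); f2 <- tempfile()
  write_offtargets(call_offtargets(counts, sets), f1)
  write_offtargets(call_offtargets(counts, sets), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("calls are labelled and shift-classified when annotation and array are given", {
  # reference with the nad4 context planted; a CDS covering it
  ctx <- window_string(native_target_window("nad4"), dna = TRUE)
  seqs <- Biostrings::DNAStringSet(c(chrom = paste0(
    strrep("a", 30), "atg", strrep("gct", 20), ctx, strrep("gct", 10))))
  cpos <- 30L + 3L + 60L + 17L  # the edited C (offset 0 at window position 17)
  gff <- tempfile(fileext = ".gff3")
  cds_end <- length(seqs[[1]])
  writeLines(c("##gff-version 3",
               sprintf("chrom\ttest\tCDS\t31\t%d\t.\t+\t0\tID=x;gene=nad4",
                       cds_end)), gff)
  sets <- dataset_set("PPR56", c("t1", "t2"), character(0))
  counts <- rbind(passing_row("t1", position = cpos, contig = "chrom"),
                  passing_row("t2", position = cpos, contig = "chrom"))
  calls <- call_offtargets(counts, sets, annotation = gff, reference = seqs,
                           array = ppr56())
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$shift_class, 0L)
  expect_match(calls$label, "^nad4eU[0-9]+")
})
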