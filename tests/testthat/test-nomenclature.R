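# Label grammars, target mutations, site naming, codon engineering

test_that("protein labels parse into typed mutations and round-trip", {
  p <- parse_protein_label("PPR56|DYW:G3A")
  expect_identical(p$factor, "PPR56")
  m <- p$mutations[[1]]
  expect_identical(m[c("kind", "domain", "position", "from_aa", "to_aa")],
                   list(kind = "domain_point", domain = "DYW", position = 3L,
                        from_aa = "G", to_aa = "A"))

  d <- parse_protein_label("PPR56|S-7TD>TN|S-4TN>TD")
  expect_length(d$mutations, 2)
  expect_identical(d$mutations[[1]]$motif_index, -7L)
  expect_identical(d$mutations[[2]]$to_pair, c("T", "D"))

  for (lbl in c("PPR56", "PPR56|E1:N34D", "PPR56|S2-1ND>NS",
                "PPR56|DYW:G3A|E2:K34A", "PPR56|trunc:P-12",
                "PPR56|P-6ND>TD")) {
    expect_identical(format_protein_label(parse_protein_label(lbl)), lbl)
  }

  expect_error(parse_protein_label("PPR56|Q-3XX"), "segment")
  expect_error(parse_protein_label("|DYW:G3A"), "factor")
  expect_error(parse_protein_label("PPR56|S-4TN>TD|S-4TD>TN"), "distinct")
})

test_that("site labels parse positions, codon changes and stops", {
  s <- parse_site_label("nad4eU272SL")
  expect_identical(s[c("locus", "position", "aa_from", "aa_to")],
                   list(locus = "nad4", position = 272L, aa_from = "S",
                        aa_to = "L"))
  stop_site <- parse_site_label("fdhEeU403Q*")
  expect_identical(stop_site$aa_to, "*")
  up <- parse_site_label("folDeU-5")
  expect_identical(up$position, -5L)
  expect_true(is.na(up$aa_from))

  for (lbl in c("nad4eU272SL", "fdhEeU403Q*", "folDeU-5", "cox3eU290SF",
                "yegHeU419SL", "paoCeU542TM")) {
    expect_identical(format_site_label(parse_site_label(lbl)), lbl)
  }
  expect_error(parse_site_label("nad4U272SL"), "eU")
  expect_error(parse_site_label("nad4eU0SL"), "0")
})

test_that("target labels parse ordered substitutions incl. the pre-edited c0u", {
  v <- parse_target_label("nad4eU272SL|u-4g")
  expect_identical(v$substitutions$offset, -4L)
  expect_identical(v$substitutions$to, "g")

  pre <- parse_target_label("nad4eU272SL|c0u")
  expect_identical(pre$substitutions$offset, 0L)

  tri <- parse_target_label("nad3eU230SL|u-16a|u-9g|c-6u")
  expect_identical(tri$substitutions$offset, c(-16L, -9L, -6L))

  for (lbl in c("nad4eU272SL|u-4g", "nad4eU272SL|c0u",
                "nad3eU230SL|u-16a|u-9g|c-6u", "nad4eU272SL|u-1a|a+1g")) {
    expect_identical(format_target_label(parse_target_label(lbl)), lbl)
  }
  # DNA alphabet accepted, canonicalized to u
  expect_identical(format_target_label(parse_target_label("nad4eU272SL|t-4g")),
                   "nad4eU272SL|u-4g")
  expect_error(parse_target_label("nad4eU272SL|u-4u"), "differ")
  expect_error(parse_target_label("nad4eU272SL|u-4g|a-4c"), "unique")
})

test_that("target substitutions apply with from-base checking and are invertible", {
  w3 <- native_target_window("nad3")
  mut <- apply_target_mutations(w3, "c-6u")
  expect_identical(window_base(mut, -6), "u")
  expect_identical(window_base(w3, -6), "c")  # original untouched

  expect_error(apply_target_mutations(native_target_window("nad4"), "u-4g|c-6u"),
               "offset -6")  # nad4 has u at -6
  expect_error(apply_target_mutations(w3, "g+99a"), "outside")

  # identity and round-trip inversion on random substitution sets
  set.seed(3)
  for (i in 1:20) {
    w <- random_window(-16, 2)
    offs <- sample(setdiff(-16:2, 0), sample(1:4, 1))
    subs <- do.call(rbind, lapply(offs, function(o) {
      from <- window_base(w, o)
      data.frame(offset = o, from = from,
                 to = sample(setdiff(c("a", "c", "g", "u"), from), 1))
    }))
    v <- structure(list(site = site_label("x", 1), substitutions = subs),
                   class = "target_variant")
    w2 <- apply_target_mutations(w, v)
    expect_identical(unclass(apply_target_mutations(w2, invert_target_variant(v))),
                     unclass(w))
  }
  expect_identical(
    unclass(apply_target_mutations(w3, parse_target_label("nad3eU230SL"))),
    unclass(w3))
})

test_that("site naming from a CDS reproduces the printed codon changes", {
  # UCA (Ser) at codon 91, edit at its middle base 272 -> S to L
  cds4 <- paste0(strrep("gct", 90), "tcattt")
  expect_identical(format_site_label(name_site(cds4, 272, "nad4")),
                   "nad4eU272SL")
  # CAA (Gln) starting at 403, edit at its first base -> Q to stop
  cdsE <- paste0(strrep("gct", 134), "caatct")
  expect_identical(format_site_label(name_site(cdsE, 403, "fdhE")),
                   "fdhEeU403Q*")
  # upstream of the start codon
  expect_identical(format_site_label(name_site("atg", -5, "folD")), "folDeU-5")
  # editing a non-C position is a consistency error
  expect_error(name_site(cds4, 271, "nad4"), "not c")
})

test_that("site naming agrees with brute-force translation of the whole CDS", {
  translate_chars <- function(chars) {
    n <- floor(length(chars) / 3)
    vapply(seq_len(n), function(i) {
      codon <- paste(chars[(3 * i - 2):(3 * i)], collapse = "")
      codon <- toupper(chartr("u", "t", codon))
      Biostrings::GENETIC_CODE[[codon]]
    }, character(1))
  }
  set.seed(17)
  for (i in 1:25) {
    n_codons <- sample(5:40, 1)
    chars <- sample(c("a", "c", "g", "t"), 3 * n_codons, replace = TRUE)
    cpos <- which(chars == "c")
    if (!length(cpos)) next
    pos <- sample(rep(cpos, 2), 1)
    lab <- name_site(paste(chars, collapse = ""), pos, "locus")
    aa_before <- translate_chars(chars)
    chars2 <- chars; chars2[pos] <- "u"
    aa_after <- translate_chars(chars2)
    ci <- as.integer(ceiling(pos / 3))
    expect_identical(lab$aa_from, aa_before[ci])
    expect_identical(lab$aa_to, aa_after[ci])
    expect_identical(which(aa_before != aa_after),
                     if (aa_before[ci] == aa_after[ci]) integer(0) else ci)
  }
})

test_that("annotation-based naming handles CDS hits, upstream sites and both strands", {
  ref <- Biostrings::DNAStringSet(c(chrom = paste0(
    strrep("a", 50),
    paste0(strrep("gct", 90), "tcattt"),    # CDS on + strand at 51..323
    strrep("a", 40))))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrom\ttest\tCDS\t51\t323\t.\t+\t0\tID=cds1;gene=nad4"),
             gff)
  expect_identical(
    name_site_from_annotation("chrom", 51 + 271, "+", gff, ref), "nad4eU272SL")
  expect_identical(
    name_site_from_annotation("chrom", 46, "+", gff, ref), "nad4eU-5")
  expect_identical(
    name_site_from_annotation("chrom", 10, "+", gff, ref), "chrom:10")

  # minus-strand CDS: reverse complement of the same gene body
  body <- paste0(strrep("gct", 90), "tcattt")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  ref2 <- Biostrings::DNAStringSet(c(chrom = paste0(strrep("t", 20), rc,
                                                    strrep("t", 20))))
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chrom\ttest\tCDS\t21\t%d\t.\t-\t0\tID=c2;gene=nad4",
                       20 + nchar(body))), gff2)
  # CDS position 272 lies at genomic position end - 272 + 1
  gpos <- (20 + nchar(body)) - 272 + 1
  expect_identical(name_site_from_annotation("chrom", gpos, "-", gff2, ref2),
                   "nad4eU272SL")
})

test_that("codon designs enumerate all three stops and the start for the nad4 context", {
  designs <- design_codon_edits(native_target_window("nad4"))
  stops <- Filter(function(d) d$category == "stop", designs)
  starts <- Filter(function(d) d$category == "start", designs)
  expect_length(stops, 3)
  expect_length(starts, 1)
  expect_setequal(vapply(stops, `[[`, character(1), "codon"),
                  c("uaa", "uag", "uga"))

  by_codon <- setNames(designs, vapply(designs, `[[`, character(1), "codon"))
  expect_identical(by_codon$uaa$substitutions,
                   data.frame(offset = 2L, from = "u", to = "a"))
  expect_identical(by_codon$uag$substitutions,
                   data.frame(offset = 2L, from = "u", to = "g"))
  expect_identical(by_codon$uga$substitutions,
                   data.frame(offset = c(1L, 2L), from = c("a", "u"),
                              to = c("g", "a")))
  expect_identical(by_codon$aug$substitutions,
                   data.frame(offset = c(-1L, 1L), from = c("u", "a"),
                              to = c("a", "g")))
})

test_that("re-translating engineered windows after in-silico editing yields the claimed codon", {
  set.seed(23)
  for (i in 1:20) {
    w <- random_window(-3, 3)
    w <- apply_target_mutations(w, local({
      b <- window_base(w, 0)
      if (b == "c") parse_target_label("xeU1") else
        structure(list(site = site_label("x", 1),
                       substitutions = data.frame(offset = 0L, from = b,
                                                  to = "c")),
                  class = "target_variant")
    }))
    for (d in design_codon_edits(w)) {
      w2 <- w
      for (j in seq_len(nrow(d$substitutions))) {
        v <- structure(list(site = site_label("x", 1),
                            substitutions = d$substitutions[j, , drop = FALSE]),
                       class = "target_variant")
        w2 <- apply_target_mutations(w2, v)
      }
      # apply the edit itself, then read the design's frame
      frame <- if (d$category == "stop") 0:2 else -1:1
      bases <- window_base(w2, frame)
      bases[frame == 0] <- "u"
      expect_identical(paste(bases, collapse = ""), d$codon)
    }
  }
  # a window already reading uaa after editing needs no substitutions
  w <- target_window("uucaa", from = -2)
  d <- design_codon_edits(w)
  expect_identical(nrow(d[[1]]$substitutions), 0L)
  expect_error(design_codon_edits(target_window("uuuau", from = -2)), "cytidine")
})
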