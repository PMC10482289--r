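# Independent oracles and small fixture builders used across the suite.

# literal position-by-position application of the recognition code, written
# against its own copy of the code table (kept independent of the package's
# scoring path on purpose)
oracle_code <- list(TN = "a", SN = "a", TD = "g", SD = "g",
                    ND = "u", NS = "c", NN = c("c", "u"))

oracle_score <- function(array, window_chars, window_from) {
  df <- as.data.frame(array)
  n_match <- 0L; n_mismatch <- 0L
  mismatch_at <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!df$kind[i] %in% c("P", "S", "P2", "S2")) next
    off <- df$index[i] - 3L
    j <- off - window_from + 1L
    if (j < 1L || j > length(window_chars)) next
    obs <- window_chars[j]
    if (is.na(df$aa5[i]) || is.na(df$aaL[i])) next
    pref <- oracle_code[[paste0(df$aa5[i], df$aaL[i])]]
    if (is.null(pref) || obs == "n") next
    if (obs %in% pref) n_match <- n_match + 1L
    else { n_mismatch <- n_mismatch + 1L; mismatch_at <- c(mismatch_at, off) }
  }
  list(n_match = n_match, n_mismatch = n_mismatch,
       mismatch_at = sort(mismatch_at))
}

# random PLS array ending in P2-L2-S2, for property tests
random_array <- function(n_extra = 6, p_unknown = 0.1) {
  aa <- c("T", "S", "N", "M", "V", "L", "D", "K")
  kinds <- c(sample(c("P", "L", "S"), n_extra, replace = TRUE), "P2", "L2", "S2")
  idx <- seq(-(n_extra + 3), -1)
  rows <- lapply(seq_along(kinds), function(i) {
    if (runif(1) < p_unknown) {
      pprcue::ppr_motif(kinds[i], idx[i])
    } else {
      pprcue::ppr_motif(kinds[i], idx[i], sample(aa, 1), sample(aa, 1))
    }
  })
  pprcue::ppr_array(rows, name = "random")
}

random_window <- function(from = -20, to = 5, include_n = FALSE) {
  alpha <- c("a", "c", "g", "u", if (include_n) "n")
  pprcue::target_window(sample(alpha, to - from + 1, replace = TRUE),
                        offsets = from:to)
}

# one count-table row in the native schema
count_row <- function(dataset, position, ref, A = 0, C = 0, G = 0, T = 0,
                      contig = "c1", dna = NULL) {
  row <- data.frame(dataset = dataset, contig = contig, position = position,
                    dna_ref = ref, rna_A = A, rna_C = C, rna_G = G, rna_T = T,
                    stringsAsFactors = FALSE)
  if (!is.null(dna)) {
    row$dna_A <- dna[1]; row$dna_C <- dna[2]; row$dna_G <- dna[3]
    row$dna_T <- dna[4]
  }
  row
}

# a clean forward-candidate row passing all four criteria
passing_row <- function(dataset, position = 100, edited = 20, unedited = 180,
                        contig = "c1") {
  count_row(dataset, position, "C", C = unedited, T = edited, contig = contig)
}

# naive reference caller: nested loops, no indexing; independent of the
# package's grouping logic
naive_call <- function(counts, treatment, control, params = pprcue::caller_params()) {
  keys <- unique(counts[, c("contig", "position")])
  called <- list()
  for (r in seq_len(nrow(keys))) {
    for (strand in c("+", "-")) {
      ref_want <- if (strand == "+") "C" else "G"
      supporting <- character(0)
      ed_sum <- un_sum <- 0
      for (ds in treatment) {
        row <- counts[counts$dataset == ds & counts$contig == keys$contig[r] &
                        counts$position == keys$position[r] &
                        counts$dna_ref == ref_want, , drop = FALSE]
        if (nrow(row) != 1L) next
        cov <- row$rna_A + row$rna_C + row$rna_G + row$rna_T
        ed <- if (strand == "+") row$rna_T else row$rna_A
        un <- if (strand == "+") row$rna_C else row$rna_G
        if (cov < params$min_coverage) next
        if (!((ed + un) / cov > params$min_transition_purity)) next
        if (all(c("dna_A", "dna_C", "dna_G", "dna_T") %in% names(row))) {
          dcov <- row$dna_A + row$dna_C + row$dna_G + row$dna_T
          refn <- if (strand == "+") row$dna_C else row$dna_G
          if (dcov > 0 && !(refn / dcov > params$min_dna_purity)) next
        }
        if (ed + un == 0 || !(ed / (ed + un) >= params$min_edit_frac)) next
        supporting <- c(supporting, ds)
        ed_sum <- ed_sum + ed; un_sum <- un_sum + un
      }
      if (length(supporting) < params$min_replicates) next
      bad <- FALSE
      for (ds in control) {
        row <- counts[counts$dataset == ds & counts$contig == keys$contig[r] &
                        counts$position == keys$position[r] &
                        counts$dna_ref == ref_want, , drop = FALSE]
        if (nrow(row) != 1L) next
        cov <- row$rna_A + row$rna_C + row$rna_G + row$rna_T
        ed <- if (strand == "+") row$rna_T else row$rna_A
        un <- if (strand == "+") row$rna_C else row$rna_G
        if (cov >= params$min_control_coverage && (ed + un) > 0 &&
            ed / (ed + un) >= params$min_control_frac) bad <- TRUE
      }
      if (bad) next
      called[[length(called) + 1L]] <-
        data.frame(contig = keys$contig[r], position = keys$position[r],
                   strand = strand,
                   aggregate_efficiency = ed_sum / (ed_sum + un_sum),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(called)) {
    return(data.frame(contig = character(0), position = integer(0),
                      strand = character(0),
                      aggregate_efficiency = numeric(0)))
  }
  out <- do.call(rbind, called)
  out[order(out$contig, out$position, out$strand), , drop = FALSE]
}

# random small count tables exercising all caller paths
random_counts <- function(n_pos = 12, datasets = c("t1", "t2", "t3", "w1")) {
  rows <- list()
  for (ds in datasets) {
    for (p in seq_len(n_pos)) {
      ref <- sample(c("A", "C", "G", "T"), 1)
      cov <- sample(c(5, 25, 30, 60, 200), 1)
      main <- round(cov * runif(1, 0.9, 1))
      ed <- min(cov - main, round(cov * runif(1, 0, 0.3)))
      rest <- cov - main - ed
      counts <- c(A = 0, C = 0, G = 0, T = 0)
      counts[ref] <- main
      alt <- switch(ref, C = "T", G = "A", A = "G", T = "C")
      counts[alt] <- counts[alt] + ed
      if (rest > 0) {
        oth <- sample(setdiff(names(counts), c(ref, alt)), 1)
        counts[oth] <- counts[oth] + rest
      }
      rows[[length(rows) + 1L]] <-
        count_row(ds, p, ref, counts["A"], counts["C"], counts["G"], counts["T"])
    }
  }
  do.call(rbind, rows)
}
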