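# PPR-RNA recognition code ------------------------------------------------

#' The PPR-RNA recognition code table
#'
#' The code maps the amino acids at PPR positions 5 and Last to favored
#' nucleotides: T/S+N:A, T/S+D:G, N+D:U, N+S:C and N+N:Y (pyrimidine, i.e.
#' C or U). Pairs absent from the table are neutral (empty preference set).
#' The code applies to P- and S-type PPRs only.
#'
#' @return a named list: names are `"<aa5><aaL>"` pairs, values character
#'   vectors over `A C G U`.
#' @examples
#' default_code_table()[["TN"]]
#' @export
default_code_table <- function() {
  list(TN = "A", SN = "A",
       TD = "G", SD = "G",
       ND = "U",
       NS = "C",
       NN = c("C", "U"))
}

#' Favored nucleotides of a 5/Last amino-acid pair
#'
#' @param aa5,aaL one-letter amino-acid codes (may be `NA` for unknown).
#' @param table a code table as from [default_code_table()].
#' @return character vector of favored nucleotides; `character(0)` means
#'   neutral (combination outside the code).
#' @examples
#' code_preference("T", "N")  # "A"
#' code_preference("N", "N")  # pyrimidines
#' code_preference("M", "D")  # neutral
#' @export
code_preference <- function(aa5, aaL, table = default_code_table()) {
  if (is.na(aa5) || is.na(aaL)) return(character(0))
  .check_aa(aa5, "position 5"); .check_aa(aaL, "position Last")
  pref <- table[[paste0(aa5, aaL)]]
  if (is.null(pref)) character(0) else pref
}

# Last-residue-only preference used when optionally scoring E1 position 34
# as a PPR-like Last residue: D selects keto (G/U), N amino (A/C), S C.
.last_only_preference <- function(aaL) {
  if (is.na(aaL)) return(character(0))
  switch(aaL, D = c("G", "U"), N = c("A", "C"), S = "C", character(0))
}

# per-motif preference sets for an array
.array_preferences <- function(array, table, score_e1 = FALSE) {
  lapply(seq_len(nrow(array)), function(i) {
    k <- array$kind[i]
    if (k == "E1" && score_e1) return(.last_only_preference(array$aaL[i]))
    if (k %in% c("E1", "E2")) return(character(0))
    code_preference(array$aa5[i], array$aaL[i], table)
  })
}

.scored_kinds <- function(score_classes) {
  stopifnot(all(score_classes %in% c("P", "L", "S")))
  out <- character(0)
  if ("P" %in% score_classes) out <- c(out, "P", "P2")
  if ("S" %in% score_classes) out <- c(out, "S", "S2")
  if ("L" %in% score_classes) out <- c(out, "L", "L2")
  out
}

# shared scoring core; window may lack offset 0 here (shifted evaluation)
.score_core <- function(array, window, table, score_classes, score_e1) {
  offs <- juxtapose(array)
  prefs <- .array_preferences(array, table, score_e1 = score_e1)
  scored_kind <- array$kind %in% .scored_kinds(score_classes) |
    (score_e1 & array$kind == "E1")
  obs <- window_base(window, offs)
  verdict <- character(nrow(array))
  for (i in seq_len(nrow(array))) {
    verdict[i] <-
      if (!scored_kind[i]) "not_scored"
      else if (is.na(obs[i])) "not_scored"
      else if (length(prefs[[i]]) == 0L) "neutral"
      else if (obs[i] == "n") "neutral"
      else if (toupper(obs[i]) %in% prefs[[i]]) "match"
      else "mismatch"
  }
  data.frame(motif = motif_labels(array), kind = array$kind,
             target_position = unname(offs), observed = unname(obs),
             preference = vapply(prefs, paste, character(1), collapse = ""),
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Score a target window against a PPR array
#'
#' Applies the PPR-RNA recognition code motif by motif: each indexed motif
#' faces the window base at its juxtaposed offset ([juxtapose()]). A scored
#' position is a `match` if the observed base lies in the motif's preference
#' set, a `mismatch` if the set is non-empty and the base lies outside it,
#' and `neutral` if the set is empty (unknown pair, or `n` observed). By
#' default only P- and S-class motifs (including P2/S2) are scored, since
#' the code does not apply to L-type PPRs; L motifs and E1/E2 come back
#' `not_scored`. Offsets missing from the window are `not_scored`, never
#' fabricated.
#'
#' @param array a [ppr_array].
#' @param window a [target_window] containing offset 0.
#' @param table code table ([default_code_table()]).
#' @param score_classes motif classes to score, subset of `c("P","S","L")`
#'   (class covers the deviant 2-variants, e.g. `"P"` scores P and P2).
#' @param score_e1 also score E1 via its Last (position 34) residue using the
#'   amino/keto rule (D: G/U, N: A/C, S: C)?
#' @return a `match_report`: per-motif `data.frame` with columns `motif,
#'   kind, target_position, observed, preference, verdict` and attributes
#'   `n_match`, `n_mismatch`, `n_scored` and `score` (= n_match - n_mismatch),
#'   all over scored motifs only.
#' @examples
#' rep <- score_window(ppr56(), native_target_window("nad4"))
#' attr(rep, "n_match")
#' @export
score_window <- function(array, window, table = default_code_table(),
                         score_classes = c("P", "S"), score_e1 = FALSE) {
  stopifnot(inherits(array, "ppr_array"))
  if (!inherits(window, "target_window")) window <- target_window(window, from = 0L)
  if (!"0" %in% names(window)) stop("window lacks offset 0", call. = FALSE)
  rep <- .score_core(array, window, table, score_classes, score_e1)
  structure(rep,
            class = c("match_report", "data.frame"),
            n_match = sum(rep$verdict == "match"),
            n_mismatch = sum(rep$verdict == "mismatch"),
            n_scored = sum(rep$verdict != "not_scored"),
            score = sum(rep$verdict == "match") - sum(rep$verdict == "mismatch"))
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match report: %d match / %d mismatch (%d scored), score %d\n",
              attr(x, "n_match"), attr(x, "n_mismatch"),
              attr(x, "n_scored"), attr(x, "score")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Mismatched offsets of a match report
#' @param report a `match_report` from [score_window()].
#' @return integer offsets with verdict `mismatch`.
#' @export
mismatch_offsets <- function(report) {
  sort(report$target_position[report$verdict == "mismatch"])
}

# Sequence scanning -------------------------------------------------------

#' Scan a sequence for candidate editing sites
#'
#' Slides the PPR array along a transcript (or transcriptome contig) and
#' scores every position whose base is a potential editing center: `C` for
#' genuine editing candidates, `U`/`T` for sites that may already exist in a
#' pre-edited state, or both. A candidate is kept when its match report
#' satisfies the thresholds and, optionally, when the base immediately 5' of
#' the center is not a G (the classical -1 guanosine avoidance).
#'
#' @param array a [ppr_array].
#' @param seq a character string, `DNAString`/`RNAString`, or a named
#'   `DNAStringSet`/`RNAStringSet` (scanned record by record).
#' @param center_base `"C"`, `"U"` or `"both"` (`U` matches `T` in DNA input).
#' @param min_matches minimum `n_match` to report.
#' @param max_mismatches maximum `n_mismatch` to report.
#' @param forbid_g_minus1 drop candidates with `g` at position -1?
#' @param table,score_classes,score_e1 passed to the scoring core.
#' @return `data.frame` with columns `contig, position` (1-based),
#'   `center_base, n_match, n_mismatch, n_scored, score`, sorted by
#'   descending score then ascending position.
#' @examples
#' s <- paste0("aaaaa", window_string(native_target_window("nad4")), "aaaaa")
#' scan_sequence(ppr56(), s, min_matches = 7)
#' @export
scan_sequence <- function(array, seq, center_base = c("C", "U", "both"),
                          min_matches = 0L, max_mismatches = Inf,
                          forbid_g_minus1 = FALSE,
                          table = default_code_table(),
                          score_classes = c("P", "S"), score_e1 = FALSE) {
  center_base <- match.arg(center_base)
  if (inherits(seq, c("DNAStringSet", "RNAStringSet"))) {
    nms <- if (is.null(names(seq))) as.character(seq_along(seq)) else names(seq)
    out <- lapply(seq_along(seq), function(i) {
      r <- scan_sequence(array, seq[[i]], center_base, min_matches,
                         max_mismatches, forbid_g_minus1, table,
                         score_classes, score_e1)
      if (nrow(r)) r$contig <- nms[i]
      r
    })
    out <- do.call(rbind, out)
    return(out[order(-out$score, out$contig, out$position), , drop = FALSE])
  }
  chars <- .seq_chars(seq, "sequence")
  n <- length(chars)
  centers <- switch(center_base, C = "c", U = "u", both = c("c", "u"))
  cand <- which(chars %in% centers)
  if (forbid_g_minus1 && length(cand)) {
    g1 <- cand - 1L
    bad <- g1 >= 1L & chars[pmax(g1, 1L)] == "g"
    cand <- cand[!bad]
  }
  empty <- data.frame(contig = character(0), position = integer(0),
                      center_base = character(0), n_match = integer(0),
                      n_mismatch = integer(0), n_scored = integer(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)

  offs <- juxtapose(array)
  prefs <- .array_preferences(array, table, score_e1 = score_e1)
  scored <- array$kind %in% .scored_kinds(score_classes) |
    (score_e1 & array$kind == "E1")
  n_match <- n_mismatch <- n_scored <- integer(length(cand))
  for (i in which(scored)) {
    pos <- cand + offs[i]
    ok <- pos >= 1L & pos <= n
    obs <- rep(NA_character_, length(cand))
    obs[ok] <- chars[pos[ok]]
    pref <- prefs[[i]]
    if (length(pref) == 0L) { n_scored <- n_scored + as.integer(ok); next }
    known <- ok & obs != "n"
    m <- known & toupper(obs) %in% pref
    n_match <- n_match + as.integer(m)
    n_mismatch <- n_mismatch + as.integer(known & !m)
    n_scored <- n_scored + as.integer(ok)
  }
  res <- data.frame(contig = rep("seq", length(cand)), position = cand,
                    center_base = chars[cand], n_match = n_match,
                    n_mismatch = n_mismatch, n_scored = n_scored,
                    score = n_match - n_mismatch, stringsAsFactors = FALSE)
  res <- res[res$n_match >= min_matches & res$n_mismatch <= max_mismatches, ,
             drop = FALSE]
  res <- res[order(-res$score, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Shift search ------------------------------------------------------------

#' Best alignment shift of an array on a window
#'
#' Off-targets sometimes match the PPR array better after sliding the array
#' by one or more nucleotides relative to the canonical S2-1 / -4 anchoring.
#' `best_offset()` evaluates all shifts `s` in `[-max_shift, +max_shift]`
#' (positive `s` slides the array toward the transcript 3' end, so a motif
#' anchored at offset `o` reads the base at `o + s`) and returns the shift
#' maximizing the number of code matches. Ties are broken toward 0, then
#' toward negative shifts.
#'
#' @param array a [ppr_array].
#' @param window a [target_window], ideally extended beyond the juxtaposed
#'   offsets so shifted alignments can be evaluated.
#' @param max_shift non-negative integer.
#' @param table,score_classes,score_e1 passed to the scoring core.
#' @return a single integer shift; 0 means the unshifted alignment is optimal.
#' @examples
#' best_offset(ppr56(), native_target_window("nad4"), max_shift = 2)
#' @export
best_offset <- function(array, window, max_shift = 2L,
                        table = default_code_table(),
                        score_classes = c("P", "S"), score_e1 = FALSE) {
  stopifnot(max_shift >= 0L)
  if (!inherits(window, "target_window")) window <- target_window(window, from = 0L)
  shifts <- seq.int(-max_shift, max_shift)
  nm <- vapply(shifts, function(s) {
    rep <- .score_core(array, .shift_window(window, s), table,
                       score_classes, score_e1)
    sum(rep$verdict == "match")
  }, integer(1))
  ord <- order(-nm, abs(shifts), shifts)
  as.integer(shifts[ord[1]])
}

# Protein mutations on the array ------------------------------------------

#' Apply protein mutations to a PPR array
#'
#' Applies PPR 5/Last shorthand mutations (e.g. `S-4TN>TD`), E-motif point
#' mutations at position 34 (e.g. `E1:N34D`) and N-terminal truncations
#' (`trunc:P-12` removes all motifs from the N-terminus through P-12) to an
#' array. DYW-domain point mutations do not address the PPR array and raise
#' an error. For 5/Last mutations the current identities must equal the
#' stated "from" pair.
#'
#' @param array a [ppr_array].
#' @param mutation a label string (a full protein label such as
#'   `"PPR56|S-4TN>TD"` or bare segments separated by `|`), a
#'   `protein_label` from [parse_protein_label()], or a single mutation
#'   element of one.
#' @return a new [ppr_array]; the input is untouched. The array name gains
#'   the mutation segments so that `array_name()` is the full mutant label.
#' @examples
#' mut <- apply_ppr_mutation(ppr56(), "PPR56|S-4TN>TD")
#' subset(as.data.frame(mut), kind == "S" & index == -4)
#' @export
apply_ppr_mutation <- function(array, mutation) {
  stopifnot(inherits(array, "ppr_array"))
  if (is.character(mutation)) {
    factor_name <- strsplit(array_name(array), "|", fixed = TRUE)[[1]][1]
    lbl <- if (grepl("^[A-Za-z0-9_]+\\|", mutation)) mutation
           else paste0(factor_name, "|", mutation)
    mutation <- parse_protein_label(lbl)
  }
  if (inherits(mutation, "protein_label")) {
    muts <- mutation$mutations
  } else if (inherits(mutation, "protein_mutation")) {
    muts <- list(mutation)
  } else stop("unsupported mutation object", call. = FALSE)

  out <- as.data.frame(array)
  segs <- character(0)
  for (m in muts) {
    segs <- c(segs, format_protein_mutation(m))
    if (m$kind == "ppr_5L") {
      i <- which(out$kind == m$motif_kind & !is.na(out$index) &
                 out$index == m$motif_index)
      if (!length(i)) {
        stop(sprintf("motif %s%d not present in array", m$motif_kind,
                     m$motif_index), call. = FALSE)
      }
      cur <- c(out$aa5[i], out$aaL[i])
      if (anyNA(cur) || !identical(unname(cur), m$from_pair)) {
        stop(sprintf("motif %s%d is %s, not %s as the mutation states",
                     m$motif_kind, m$motif_index,
                     paste(cur, collapse = ""),
                     paste(m$from_pair, collapse = "")), call. = FALSE)
      }
      out$aa5[i] <- m$to_pair[1]; out$aaL[i] <- m$to_pair[2]
    } else if (m$kind == "domain_point") {
      if (m$domain == "DYW") {
        stop("DYW-domain mutations do not address the PPR array", call. = FALSE)
      }
      i <- which(out$kind == m$domain)
      if (!length(i)) stop(sprintf("%s motif not present", m$domain), call. = FALSE)
      col <- if (m$position == 34L) "aaL" else if (m$position == 5L) "aa5" else
        stop("only positions 5 and 34 of E motifs map onto the array",
             call. = FALSE)
      cur <- out[[col]][i]
      if (is.na(cur) || cur != m$from_aa) {
        stop(sprintf("%s position %d is %s, not %s", m$domain, m$position,
                     ifelse(is.na(cur), "unknown", cur), m$from_aa),
             call. = FALSE)
      }
      out[[col]][i] <- m$to_aa
    } else if (m$kind == "truncation") {
      i <- which(out$kind == m$motif_kind & !is.na(out$index) &
                 out$index == m$motif_index)
      if (!length(i)) {
        stop(sprintf("motif %s%d not present in array", m$motif_kind,
                     m$motif_index), call. = FALSE)
      }
      out <- out[-seq_len(i), , drop = FALSE]
    } else stop("unknown mutation kind", call. = FALSE)
  }
  ppr_array(out, name = paste(c(array_name(array), segs), collapse = "|"))
}
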