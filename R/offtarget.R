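# Replicate-supported C-to-U off-target calling ---------------------------

#' Caller thresholds
#'
#' The four per-site criteria plus the replicate and control rules used to
#' call C-to-U off-targets from per-site base-count tables:
#' (i) RNA read coverage of at least `min_coverage` (30),
#' (ii) a clear transition signal in the RNA reads — T+C (forward) or G+A
#' (reverse) strictly above `min_transition_purity` (99\%),
#' (iii) a clear DNA reference position — reference-base fraction of the DNA
#' reads strictly above `min_dna_purity` (98\%),
#' (iv) a C-to-U signal of at least `min_edit_frac` (1\%).
#' A site must pass all four in at least `min_replicates` (2) datasets from
#' expression of the same protein and must not be edited in any control
#' (wild-type or other-factor) dataset: controls with coverage of at least
#' `min_control_coverage` and an edit fraction of at least
#' `min_control_frac` exclude the site.
#'
#' @param min_coverage,min_transition_purity,min_dna_purity,min_edit_frac,min_replicates,min_control_frac,min_control_coverage
#'   see description.
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 30, min_transition_purity = 0.99,
                          min_dna_purity = 0.98, min_edit_frac = 0.01,
                          min_replicates = 2, min_control_frac = 0.01,
                          min_control_coverage = 10) {
  fr <- c(min_transition_purity, min_dna_purity, min_edit_frac, min_control_frac)
  stopifnot(all(fr >= 0 & fr <= 1), min_coverage >= 1, min_replicates >= 1)
  structure(list(min_coverage = min_coverage,
                 min_transition_purity = min_transition_purity,
                 min_dna_purity = min_dna_purity,
                 min_edit_frac = min_edit_frac,
                 min_replicates = min_replicates,
                 min_control_frac = min_control_frac,
                 min_control_coverage = min_control_coverage),
            class = "caller_params")
}

#' Treatment / control dataset grouping
#'
#' @param protein_label label of the expressed factor (e.g. `"PPR56"`).
#' @param treatment dataset ids from expression of this protein.
#' @param control dataset ids from wild-type cells or cells expressing other
#'   editing factors; must be disjoint from `treatment`.
#' @return a list of class `dataset_set`.
#' @export
dataset_set <- function(protein_label, treatment, control = character(0)) {
  treatment <- as.character(treatment); control <- as.character(control)
  if (length(intersect(treatment, control))) {
    stop("treatment and control dataset ids overlap", call. = FALSE)
  }
  structure(list(protein_label = protein_label, treatment = treatment,
                 control = control), class = "dataset_set")
}

# Count-table I/O ----------------------------------------------------------

.SC_COLS <- c("dataset", "contig", "position", "dna_ref",
              "rna_A", "rna_C", "rna_G", "rna_T")
.SC_DNA_COLS <- c("dna_A", "dna_C", "dna_G", "dna_T")

#' Read a per-site base-count table
#'
#' The native schema is a TSV with header columns `dataset, contig, position`
#' (1-based), `dna_ref` (plus-strand reference base), `rna_A, rna_C, rna_G,
#' rna_T` (plus-strand RNA read counts) and optionally `dna_A..dna_T` (DNA
#' read counts). Variant-call exports with other column names (e.g.
#' JACUSA-style tables) are ingested via `col_map`.
#'
#' @param path TSV file path.
#' @param col_map optional named character vector mapping native column
#'   names to the file's column names, e.g. `c(position = "pos")`.
#' @param drop_zero drop rows with zero RNA coverage (default; a message
#'   reports how many were dropped).
#' @return a `data.frame` in the native schema.
#' @export
read_site_counts <- function(path, col_map = NULL, drop_zero = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    miss <- setdiff(unname(col_map), names(tab))
    if (length(miss)) {
      stop(sprintf("mapped column(s) absent from file: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    names(tab)[match(unname(col_map), names(tab))] <- names(col_map)
  }
  miss <- setdiff(.SC_COLS, names(tab))
  if (length(miss)) {
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  keep <- intersect(c(.SC_COLS, .SC_DNA_COLS), names(tab))
  tab <- tab[, keep, drop = FALSE]
  num_cols <- setdiff(keep, c("dataset", "contig", "dna_ref"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column %s, line %d", cc, bad[1] + 1L),
           call. = FALSE)
    }
    tab[[cc]] <- v
  }
  if (nrow(tab) && any(tab[, c("rna_A", "rna_C", "rna_G", "rna_T")] < 0, na.rm = TRUE)) {
    stop("negative counts", call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  tab$dna_ref <- toupper(tab$dna_ref)
  if (drop_zero && nrow(tab)) {
    cov <- rowSums(tab[, c("rna_A", "rna_C", "rna_G", "rna_T")])
    if (any(cov == 0)) {
      message(sprintf("dropped %d zero-coverage row(s)", sum(cov == 0)))
      tab <- tab[cov > 0, , drop = FALSE]
    }
  }
  rownames(tab) <- NULL
  tab
}

#' @rdname read_site_counts
#' @param counts a count `data.frame` in the native schema.
#' @export
write_site_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Orientation & filters -----------------------------------------------------

#' Orient candidate sites and derive editing evidence
#'
#' C-to-U editing appears as C-to-T differences on the plus strand when the
#' reference base is C (forward candidate) and as G-to-A differences when it
#' is G (the edited C lies on the reverse strand). Reference A or T rows are
#' not transition candidates.
#'
#' @param counts count `data.frame` (native schema, see [read_site_counts()]).
#' @return the input with added columns `coverage`, `candidate` (logical),
#'   `strand` (`"+"`/`"-"`/`NA`), `edited`, `unedited`, `transition_purity`
#'   (= (edited + unedited) / coverage) and `edit_frac`
#'   (= edited / (edited + unedited)).
#' @examples
#' x <- data.frame(dataset = "d1", contig = "c", position = 1, dna_ref = "C",
#'                 rna_A = 0, rna_C = 900, rna_G = 5, rna_T = 95)
#' orient_sites(x)[, c("strand", "transition_purity", "edit_frac")]
#' @export
orient_sites <- function(counts) {
  cov <- counts$rna_A + counts$rna_C + counts$rna_G + counts$rna_T
  fwd <- counts$dna_ref == "C"
  rev <- counts$dna_ref == "G"
  edited <- ifelse(fwd, counts$rna_T, ifelse(rev, counts$rna_A, NA_real_))
  unedited <- ifelse(fwd, counts$rna_C, ifelse(rev, counts$rna_G, NA_real_))
  counts$coverage <- cov
  counts$candidate <- fwd | rev
  counts$strand <- ifelse(fwd, "+", ifelse(rev, "-", NA_character_))
  counts$edited <- edited
  counts$unedited <- unedited
  counts$transition_purity <- (edited + unedited) / cov
  counts$edit_frac <- ifelse(edited + unedited > 0, edited / (edited + unedited),
                             NA_real_)
  counts
}

#' Evaluate the four filter criteria per row
#'
#' @param oriented output of [orient_sites()].
#' @param params a [caller_params()].
#' @return the input with logical columns `cov_ok`, `purity_ok`, `dna_ok`
#'   (with `dna_assumed` flagging rows lacking DNA counts, for which the
#'   reference is assumed pure), `signal_ok` and `pass` (all four, candidate
#'   rows only).
#' @export
passes_filters <- function(oriented, params = caller_params()) {
  x <- oriented
  x$cov_ok <- x$coverage >= params$min_coverage
  x$purity_ok <- !is.na(x$transition_purity) &
    x$transition_purity > params$min_transition_purity
  has_dna <- all(.SC_DNA_COLS %in% names(x))
  if (has_dna) {
    dna_cov <- x$dna_A + x$dna_C + x$dna_G + x$dna_T
    ref_n <- ifelse(x$dna_ref == "C", x$dna_C,
             ifelse(x$dna_ref == "G", x$dna_G,
             ifelse(x$dna_ref == "A", x$dna_A, x$dna_T)))
    x$dna_assumed <- dna_cov == 0
    x$dna_ok <- ifelse(dna_cov > 0, ref_n / dna_cov > params$min_dna_purity, TRUE)
  } else {
    x$dna_assumed <- TRUE
    x$dna_ok <- TRUE
  }
  x$signal_ok <- !is.na(x$edit_frac) & x$edit_frac >= params$min_edit_frac
  x$pass <- x$candidate & x$cov_ok & x$purity_ok & x$dna_ok & x$signal_ok
  x
}

#' Read-sum aggregate editing efficiency
#'
#' Final efficiency at a site is computed by adding up the RNA reads from
#' all supporting datasets: `sum(edited) / sum(edited + unedited)`. This
#' equals the coverage-weighted mean of the per-dataset fractions.
#'
#' @param edited,unedited per-dataset edited / unedited read counts.
#' @return a single fraction in `[0, 1]`.
#' @examples
#' aggregate_efficiency(c(10, 30), c(90, 70))  # 0.2
#' @export
aggregate_efficiency <- function(edited, unedited) {
  den <- sum(edited) + sum(unedited)
  if (!is.finite(den) || den <= 0) {
    stop("aggregate efficiency undefined: no transition reads", call. = FALSE)
  }
  sum(edited) / den
}

#' Sanger peak-ratio editing quantification
#'
#' Editing at a site in a Sanger trace is quantified as the thymidine peak
#' height over the sum of the thymidine and cytidine peaks.
#'
#' @param peak_T,peak_C non-negative peak heights, not both zero.
#' @return `peak_T / (peak_T + peak_C)` (vectorized).
#' @examples
#' quantify_peaks(3, 1)  # 0.75
#' @export
quantify_peaks <- function(peak_T, peak_C) {
  if (any(peak_T < 0 | peak_C < 0)) stop("peak heights must be >= 0", call. = FALSE)
  if (any(peak_T + peak_C == 0)) {
    stop("editing fraction undefined for zero peaks", call. = FALSE)
  }
  peak_T / (peak_T + peak_C)
}

# The caller ----------------------------------------------------------------

#' Call C-to-U off-targets across replicate datasets
#'
#' Runs the full detection cascade on per-site base-count tables: per-row
#' orientation and the four filter criteria ([passes_filters()]), the
#' replicate rule (a site must pass in at least `min_replicates` treatment
#' datasets), control exclusion (no control dataset may show the site edited
#' at `min_control_frac` or more with coverage of at least
#' `min_control_coverage`), and read-sum efficiency aggregation over the
#' supporting ("hitting") datasets.
#'
#' @param counts count `data.frame` covering all datasets (native schema).
#' @param sets a [dataset_set()].
#' @param params a [caller_params()].
#' @param annotation,reference optional: CDS annotation (GFF3/BED path or
#'   `GRanges`) and reference sequences (FASTA path or `DNAStringSet`) for
#'   site labelling via [name_site_from_annotation()].
#' @param array optional [ppr_array]; with `reference`, attaches the
#'   `shift_class` of each call via [best_offset()].
#' @param max_shift shift window for `shift_class`.
#' @param window context window used for shift classification.
#' @return a `data.frame` of class `offtarget_calls`, sorted by contig then
#'   position: `contig, position, strand, label, n_supporting,
#'   supporting_datasets, per_dataset` (collapsed `id=fraction` pairs),
#'   `aggregate_efficiency, shift_class`. Attribute `rejections` carries
#'   per-filter rejection counts for the run log.
#' @export
call_offtargets <- function(counts, sets, params = caller_params(),
                            annotation = NULL, reference = NULL,
                            array = NULL, max_shift = 2L, window = -20:5) {
  stopifnot(inherits(sets, "dataset_set"), inherits(params, "caller_params"))
  known <- c(sets$treatment, sets$control)
  counts <- counts[counts$dataset %in% known, , drop = FALSE]
  if (length(unique(counts$dataset[counts$dataset %in% sets$treatment])) <
      params$min_replicates && nrow(counts)) {
    warning("fewer treatment datasets than min_replicates; nothing can be called")
  }
  x <- passes_filters(orient_sites(counts), params)
  is_treat <- x$dataset %in% sets$treatment

  rejections <- c(
    not_candidate = sum(is_treat & !x$candidate),
    coverage = sum(is_treat & x$candidate & !x$cov_ok),
    transition_purity = sum(is_treat & x$candidate & x$cov_ok & !x$purity_ok),
    dna_purity = sum(is_treat & x$candidate & x$cov_ok & x$purity_ok & !x$dna_ok),
    edit_signal = sum(is_treat & x$candidate & x$cov_ok & x$purity_ok &
                        x$dna_ok & !x$signal_ok))

  tp <- x[is_treat & x$pass, , drop = FALSE]
  out <- data.frame(contig = character(0), position = integer(0),
                    strand = character(0), label = character(0),
                    n_supporting = integer(0), supporting_datasets = character(0),
                    per_dataset = character(0), aggregate_efficiency = numeric(0),
                    shift_class = integer(0), stringsAsFactors = FALSE)
  if (nrow(tp)) {
    key <- paste(tp$contig, tp$position, tp$strand, sep = "\r")
    ctrl <- x[x$dataset %in% sets$control & x$candidate, , drop = FALSE]
    ctrl_bad <- unique(paste(ctrl$contig, ctrl$position, ctrl$strand,
                             sep = "\r")[
      ctrl$coverage >= params$min_control_coverage &
        !is.na(ctrl$edit_frac) & ctrl$edit_frac >= params$min_control_frac])
    rows <- lapply(split(seq_len(nrow(tp)), key), function(idx) {
      sub <- tp[idx, , drop = FALSE]
      if (length(unique(sub$dataset)) < params$min_replicates) return(NULL)
      k <- paste(sub$contig[1], sub$position[1], sub$strand[1], sep = "\r")
      if (k %in% ctrl_bad) return(NULL)
      data.frame(contig = sub$contig[1], position = sub$position[1],
                 strand = sub$strand[1], label = NA_character_,
                 n_supporting = length(unique(sub$dataset)),
                 supporting_datasets = paste(sort(unique(sub$dataset)),
                                             collapse = ","),
                 per_dataset = paste(sprintf("%s=%.6g", sub$dataset,
                                             sub$edit_frac), collapse = ";"),
                 aggregate_efficiency = aggregate_efficiency(sub$edited,
                                                             sub$unedited),
                 shift_class = NA_integer_, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  n_excluded_control <- if (nrow(tp)) {
    length(unique(paste(tp$contig, tp$position, tp$strand, sep = "\r"))) -
      nrow(out) } else 0L

  if (nrow(out)) {
    if (!is.null(reference) && is.character(reference)) {
      reference <- Biostrings::readDNAStringSet(reference)
      names(reference) <- sub("\\s.*$", "", names(reference))
    }
    if (!is.null(annotation) && !is.null(reference)) {
      out$label <- vapply(seq_len(nrow(out)), function(i) {
        name_site_from_annotation(out$contig[i], out$position[i],
                                  out$strand[i], annotation, reference)
      }, character(1))
    } else {
      out$label <- sprintf("%s:%d", out$contig, out$position)
    }
    if (!is.null(array) && !is.null(reference)) {
      out$shift_class <- vapply(seq_len(nrow(out)), function(i) {
        ctx <- extract_context(reference, out$contig[i], out$position[i],
                               out$strand[i], window = window)
        best_offset(array, ctx, max_shift = max_shift)
      }, integer(1))
    }
    out <- out[order(out$contig, out$position, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("offtarget_calls", "data.frame"),
            rejections = rejections,
            n_excluded = n_excluded_control,
            protein_label = sets$protein_label)
}

#' Write called off-targets as TSV
#'
#' Coordinates are 1-based and fully closed; the header line records this.
#' @param calls an `offtarget_calls` data.frame.
#' @param path output path.
#' @export
write_offtargets <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# off-target calls; coordinates are 1-based, fully closed", con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare caller output against a printed off-target summary
#'
#' Re-runs replicate restriction, control exclusion and shift classification
#' for one or more proteins and compares total and shifted/unshifted call
#' counts (and optionally per-site efficiencies) against expected values,
#' e.g. the published summary of a full-scale experiment. Intended for
#' validation against deposited variant-call datasets converted to the
#' native count schema.
#'
#' @param counts counts covering all datasets.
#' @param sets_list list of [dataset_set()] objects, one per protein.
#' @param expected `data.frame` with columns `protein, n_total, n_unshifted,
#'   n_shifted` (`NA` entries are not compared), and optionally a list of
#'   expected per-site efficiencies via `site_efficiencies` (named numeric,
#'   names `contig:position`).
#' @param array,reference,params passed to [call_offtargets()].
#' @param tolerance absolute tolerance on efficiencies.
#' @return `data.frame` with observed and expected counts and a logical
#'   `ok` column.
#' @export
validate_offtarget_summary <- function(counts, sets_list, expected,
                                       array = ppr56(), reference = NULL,
                                       params = caller_params(),
                                       site_efficiencies = NULL,
                                       tolerance = 0.01) {
  rows <- lapply(sets_list, function(sets) {
    calls <- call_offtargets(counts, sets, params, reference = reference,
                             array = array)
    n_unsh <- sum(calls$shift_class == 0, na.rm = TRUE)
    data.frame(protein = sets$protein_label, n_total = nrow(calls),
               n_unshifted = if (all(is.na(calls$shift_class))) NA_integer_
                             else n_unsh,
               n_shifted = if (all(is.na(calls$shift_class))) NA_integer_
                           else nrow(calls) - n_unsh,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows)
  m <- merge(obs, expected, by = "protein", suffixes = c("", "_expected"))
  cmp <- function(a, b) is.na(b) | (!is.na(a) & a == b)
  m$ok <- cmp(m$n_total, m$n_total_expected) &
    cmp(m$n_unshifted, m$n_unshifted_expected) &
    cmp(m$n_shifted, m$n_shifted_expected)
  m
}
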