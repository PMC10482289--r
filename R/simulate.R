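# Synthetic editome simulator ----------------------------------------------
#
# Generates self-contained synthetic experiments at the per-site count level
# the caller consumes: a random reference with planted editing-site contexts,
# per-dataset RNA (and DNA) base-count tables with binomial C-to-U editing at
# the planted sites, sequencing error, replicate treatment datasets, controls
# and one decoy per filter criterion plus replicate-rule and control-leak
# decoys. No read-level FASTQ or alignment is simulated.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 3 treatment + 1 control dataset, negative-binomial coverage with
#' mean 200 and dispersion 5, uniform substitution error rate 0.001, 20
#' planted sites with efficiencies evenly spread over 0.02..0.99 (contexts:
#' the two native targets plus array-matched sampled contexts), and one
#' decoy engineered to fail exactly one filter criterion each.
#'
#' @param seed integer seed governing all randomness (per-dataset streams
#'   are derived from it deterministically).
#' @param reference_length length of the random background contig.
#' @param gc_content background GC fraction.
#' @param n_treatment,n_control dataset counts.
#' @param coverage_mean,coverage_dispersion negative-binomial RNA coverage
#'   model per site (`mu`, `size`).
#' @param error_rate per-base sequencing error rate (uniform substitution to
#'   the three other bases, so transitions are not privileged); must be
#'   in `[0, 0.05]`.
#' @param dna_coverage,dna_purity DNA read depth and reference purity for
#'   the emitted DNA counts.
#' @param efficiencies true editing efficiencies of the planted sites.
#' @param n_sampled_mismatches code mismatches introduced into sampled
#'   (array-matched) planted contexts.
#' @param frac_reverse fraction of planted sites placed on the reverse
#'   strand.
#' @param decoys character vector of decoy classes to plant, from
#'   `c("coverage", "purity", "dna_purity", "signal", "single_replicate",
#'   "in_control")`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, reference_length = 20000L, gc_content = 0.5,
                       n_treatment = 3L, n_control = 1L,
                       coverage_mean = 200, coverage_dispersion = 5,
                       error_rate = 0.001, dna_coverage = 200L,
                       dna_purity = 0.995,
                       efficiencies = seq(0.02, 0.99, length.out = 20),
                       n_sampled_mismatches = 2L, frac_reverse = 0.25,
                       decoys = c("coverage", "purity", "dna_purity",
                                  "signal", "single_replicate", "in_control")) {
  stopifnot(error_rate >= 0, error_rate <= 0.05,
            all(efficiencies >= 0 & efficiencies <= 1),
            n_treatment >= 1, seed == as.integer(seed))
  structure(list(seed = as.integer(seed), reference_length = reference_length,
                 gc_content = gc_content, n_treatment = n_treatment,
                 n_control = n_control, coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate, dna_coverage = dna_coverage,
                 dna_purity = dna_purity, efficiencies = efficiencies,
                 n_sampled_mismatches = n_sampled_mismatches,
                 frac_reverse = frac_reverse,
                 decoys = match.arg(decoys, several.ok = TRUE)),
            class = "sim_config")
}

#' Dataset ids of a simulated experiment
#' @param config a [sim_config()].
#' @return a [dataset_set()] with ids `treat1..n` / `ctrl1..m`.
#' @export
sim_dataset_set <- function(config) {
  dataset_set("PPR56",
              paste0("treat", seq_len(config$n_treatment)),
              if (config$n_control > 0) paste0("ctrl", seq_len(config$n_control))
              else character(0))
}

#' Sample a target window matching an array
#'
#' Draws a random context whose code-scored positions match the array's
#' preferences except for a chosen number of mismatches; unscored positions
#' are uniform random, offset 0 is `c` and offset -1 avoids `g`.
#'
#' @param array a [ppr_array].
#' @param n_mismatch number of scored positions forced to a non-preferred
#'   base.
#' @param window offsets of the context.
#' @param table code table.
#' @return a [target_window]. Uses the current RNG stream.
#' @export
sample_matching_window <- function(array, n_mismatch = 0L, window = -20:5,
                                   table = default_code_table()) {
  window <- as.integer(window)
  offs <- juxtapose(array)
  prefs <- .array_preferences(array, table)
  scored <- array$kind %in% .scored_kinds(c("P", "S")) &
    vapply(prefs, length, integer(1)) > 0L
  bases <- sample(c("a", "c", "g", "u"), length(window), replace = TRUE)
  names(bases) <- window
  for (i in which(scored)) {
    o <- as.character(offs[i])
    if (o %in% names(bases)) bases[o] <- tolower(sample(rep(prefs[[i]], 2), 1))
  }
  scorable_offs <- intersect(as.character(offs[scored]), names(bases))
  if (n_mismatch > 0L) {
    mm <- sample(scorable_offs, min(n_mismatch, length(scorable_offs)))
    for (o in mm) {
      i <- which(offs == as.integer(o) & scored)[1]
      others <- setdiff(c("a", "c", "g", "u"), tolower(prefs[[i]]))
      bases[o] <- sample(rep(others, 2), 1)
    }
  }
  bases["0"] <- "c"
  if ("-1" %in% names(bases) && bases["-1"] == "g") {
    bases["-1"] <- sample(c("a", "c", "u"), 1)
  }
  target_window(unname(bases), offsets = window)
}

.DECOY_EFF <- 0.5  # planted efficiency for decoys that do not force the signal

#' Build a synthetic reference with planted site contexts
#'
#' Generates a random background contig and plants editing-site contexts at
#' recorded positions and strands: the two native target windows verbatim
#' plus array-matched sampled contexts, and one context per configured decoy.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param array array used for sampled contexts (default [ppr56()]).
#' @return `list(reference = DNAStringSet(1), truth = data.frame)` where
#'   `truth` has columns `site_id, contig, position, strand, efficiency,
#'   class` (`native_nad4`, `native_nad3`, `sampled`, or `decoy_<criterion>`).
#'   `position` is the 1-based plus-strand coordinate of the edited C (the
#'   plus-strand base is G for reverse-strand sites).
#' @export
make_reference <- function(config, array = ppr56()) {
  set.seed(config$seed %% 1000000000L)
  L <- config$reference_length
  gc <- config$gc_content
  p <- c(a = (1 - gc) / 2, c = gc / 2, g = gc / 2, t = (1 - gc) / 2)
  chars <- sample(names(p), L, replace = TRUE, prob = p)

  eff <- config$efficiencies
  n_sites <- length(eff)
  classes <- c("native_nad4", "native_nad3",
               rep("sampled", max(0L, n_sites - 2L)))[seq_len(n_sites)]
  decoy_classes <- paste0("decoy_", config$decoys)
  all_classes <- c(classes, decoy_classes)
  n_all <- length(all_classes)

  contexts <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    contexts[[i]] <- switch(sub("^decoy_.*$", "sampled0", all_classes[i]),
      native_nad4 = native_target_window("nad4"),
      native_nad3 = native_target_window("nad3"),
      sampled = sample_matching_window(array, config$n_sampled_mismatches),
      sampled0 = sample_matching_window(array, 0L))
  }
  ctx_len <- vapply(contexts, length, integer(1))
  if (max(ctx_len) + 10L > L / n_all) {
    stop("reference too short for the planted contexts", call. = FALSE)
  }
  # non-overlapping slots, deterministic layout with jitter
  slot <- floor(L / n_all)
  starts <- (seq_len(n_all) - 1L) * slot +
    sample.int(max(1L, slot - max(ctx_len) - 40L), n_all, replace = TRUE) + 20L
  strands <- ifelse(stats::runif(n_all) < config$frac_reverse, "-", "+")

  truth <- data.frame(site_id = sprintf("site%02d", seq_len(n_all)),
                      contig = "synth1", position = NA_integer_,
                      strand = strands,
                      efficiency = c(eff, rep(.DECOY_EFF,
                                              length(decoy_classes))),
                      class = all_classes, stringsAsFactors = FALSE)
  truth$efficiency[truth$class == "decoy_signal"] <- 0.005

  for (i in seq_len(n_all)) {
    w <- contexts[[i]]
    offs <- window_offsets(w)
    bases <- unclass(w); bases[bases == "u"] <- "t"
    if (strands[i] == "+") {
      pos0 <- starts[i] - min(offs)  # plus-strand position of the edited C
      chars[starts[i]:(starts[i] + length(offs) - 1L)] <- bases
    } else {
      rc <- rev(unname(c(a = "t", c = "g", g = "c", t = "a")[bases]))
      chars[starts[i]:(starts[i] + length(offs) - 1L)] <- rc
      pos0 <- starts[i] + (length(offs) - 1L) + min(offs)
    }
    truth$position[i] <- pos0
  }
  ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref) <- "synth1"
  list(reference = ref, truth = truth)
}

# distribute per-position error reads among the three non-reference bases
.spread_errors <- function(err) {
  e1 <- stats::rbinom(length(err), err, 1 / 3)
  e2 <- stats::rbinom(length(err), err - e1, 1 / 2)
  cbind(e1, e2, err - e1 - e2)
}

#' Simulate per-dataset base-count tables
#'
#' For every reference position, RNA coverage is drawn from the configured
#' negative binomial and reads start out as the reference base; each read is
#' independently mis-read at the error rate, uniformly to the three other
#' bases. At planted sites in treatment datasets, edited reads are drawn as
#' `Binomial(coverage, efficiency)` and moved from the reference base to T
#' (plus strand) or A (reverse strand, plus-strand representation). Decoy
#' sites violate exactly their designated criterion: `coverage` caps RNA
#' coverage at 29, `purity` injects non-transition reads to force the
#' transition purity to 0.98, `dna_purity` forces the DNA reference fraction
#' to 0.98, `signal` plants efficiency 0.005, `single_replicate` edits only
#' the first treatment dataset, and `in_control` additionally edits every
#' control dataset.
#'
#' @param reference `DNAStringSet` from [make_reference()].
#' @param truth ground-truth table from [make_reference()].
#' @param config a [sim_config()].
#' @return a count `data.frame` in the native schema (all datasets stacked),
#'   with DNA count columns.
#' @export
simulate_counts <- function(reference, truth, config) {
  chars <- toupper(.seq_chars(reference[[1]]))
  chars[chars == "U"] <- "T"
  contig <- names(reference)[1]
  L <- length(chars)
  nts <- c("A", "C", "G", "T")
  sets <- sim_dataset_set(config)
  datasets <- c(sets$treatment, sets$control)
  is_treat <- datasets %in% sets$treatment

  out <- vector("list", length(datasets))
  for (d in seq_along(datasets)) {
    set.seed((config$seed %% 1000000000L) + 7919L * d)
    cov <- stats::rnbinom(L, size = config$coverage_dispersion,
                          mu = config$coverage_mean)
    counts <- matrix(0L, L, 4, dimnames = list(NULL, nts))
    ref_idx <- match(chars, nts)
    err <- stats::rbinom(L, cov, config$error_rate)
    spread <- .spread_errors(err)
    counts[cbind(seq_len(L), ref_idx)] <- cov - err
    nonref <- t(vapply(ref_idx, function(r) setdiff(1:4, r), integer(3)))
    for (k in 1:3) {
      counts[cbind(seq_len(L), nonref[, k])] <-
        counts[cbind(seq_len(L), nonref[, k])] + spread[, k]
    }

    # plant editing
    for (i in seq_len(nrow(truth))) {
      cls <- truth$class[i]
      edited_here <- if (cls == "decoy_single_replicate") is_treat[d] && d == 1L
        else if (cls == "decoy_in_control") TRUE
        else is_treat[d]
      pos <- truth$position[i]
      refb <- chars[pos]
      edit_to <- if (truth$strand[i] == "+") "T" else "A"
      n <- cov[pos]
      if (cls == "decoy_coverage" && n > 29L) n <- 29L
      row <- integer(4); names(row) <- nts
      row[refb] <- n
      if (edited_here && n > 0L) {
        ed <- stats::rbinom(1, n, truth$efficiency[i])
        row[refb] <- row[refb] - ed
        row[edit_to] <- row[edit_to] + ed
      }
      if (cls == "decoy_purity") {
        # inject non-transition reads so (edited+unedited)/coverage = 0.98
        extra <- ceiling(sum(row) * 0.02 / 0.98)
        bad_nt <- setdiff(nts, c(refb, edit_to))[1]
        row[bad_nt] <- row[bad_nt] + extra
      }
      counts[pos, ] <- row
    }
    cov_final <- rowSums(counts)
    keep <- cov_final > 0
    df <- data.frame(dataset = datasets[d], contig = contig,
                     position = which(keep), dna_ref = chars[keep],
                     rna_A = counts[keep, "A"], rna_C = counts[keep, "C"],
                     rna_G = counts[keep, "G"], rna_T = counts[keep, "T"],
                     stringsAsFactors = FALSE)
    # DNA counts: reference pure at dna_purity; the dna_purity decoy at 0.98
    dn <- config$dna_coverage
    ref_reads <- rep(round(dn * config$dna_purity), nrow(df))
    dp <- truth$position[truth$class == "decoy_dna_purity"]
    ref_reads[df$position %in% dp] <- round(dn * 0.98)
    alt <- .spread_errors(dn - ref_reads)
    dna <- matrix(0L, nrow(df), 4, dimnames = list(NULL, nts))
    ridx <- match(df$dna_ref, nts)
    dna[cbind(seq_len(nrow(df)), ridx)] <- ref_reads
    nonref <- t(vapply(ridx, function(r) setdiff(1:4, r), integer(3)))
    for (k in 1:3) {
      dna[cbind(seq_len(nrow(df)), nonref[, k])] <-
        dna[cbind(seq_len(nrow(df)), nonref[, k])] + alt[, k]
    }
    df$dna_A <- dna[, "A"]; df$dna_C <- dna[, "C"]
    df$dna_G <- dna[, "G"]; df$dna_T <- dna[, "T"]
    out[[d]] <- df
  }
  do.call(rbind, out)
}

#' Simulate a full synthetic experiment
#'
#' Convenience wrapper: [make_reference()] + [simulate_counts()] +
#' [sim_dataset_set()].
#'
#' @param config a [sim_config()].
#' @param array array for sampled contexts.
#' @return `list(reference, truth, counts, sets)`.
#' @export
simulate_experiment <- function(config = sim_config(), array = ppr56()) {
  ref <- make_reference(config, array)
  counts <- simulate_counts(ref$reference, ref$truth, config)
  list(reference = ref$reference, truth = ref$truth, counts = counts,
       sets = sim_dataset_set(config))
}

#' Simulate a Sanger peak pair
#'
#' Peak heights proportional to `(e, 1 - e)` plus truncated Gaussian noise;
#' [quantify_peaks()] recovers `e` within the noise bounds.
#'
#' @param efficiency true editing efficiency in `[0, 1]` (vectorized).
#' @param noise_sd standard deviation of the additive noise.
#' @return a two-column matrix `peak_T, peak_C`.
#' @examples
#' quantify_peaks(1, 0)  # fully edited trace
#' @export
simulate_sanger <- function(efficiency, noise_sd = 0) {
  stopifnot(all(efficiency >= 0 & efficiency <= 1), noise_sd >= 0)
  n <- length(efficiency)
  t_peak <- pmax(0, efficiency + stats::rnorm(n, 0, noise_sd))
  c_peak <- pmax(0, 1 - efficiency + stats::rnorm(n, 0, noise_sd))
  both0 <- t_peak + c_peak == 0
  t_peak[both0] <- efficiency[both0]; c_peak[both0] <- 1 - efficiency[both0]
  cbind(peak_T = t_peak, peak_C = c_peak)
}
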