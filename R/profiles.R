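# Efficiency-weighted nucleotide profiles ----------------------------------

#' Extract the sequence context of a call
#'
#' Slices the reference around an edited position and orients the slice so
#' that the edited base reads `c` at offset 0 with upstream sequence at
#' negative offsets: plus-strand calls give the plus-strand slice,
#' minus-strand calls its reverse complement. Positions beyond the contig
#' ends are padded with `n`.
#'
#' @param reference named `DNAStringSet`/`RNAStringSet` or FASTA path.
#' @param contig,position,strand call coordinates (1-based; strand of the
#'   edited C).
#' @param window integer offsets to cover (default `-20:5`).
#' @return a [target_window].
#' @export
extract_context <- function(reference, contig, position, strand = "+",
                            window = -20:5) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!contig %in% names(reference)) {
    stop(sprintf("contig '%s' not in reference", contig), call. = FALSE)
  }
  chars <- .seq_chars(reference[[contig]], "reference")
  window <- sort(as.integer(window))
  if (any(diff(window) != 1L) || !0L %in% window) {
    stop("window must be contiguous and contain 0", call. = FALSE)
  }
  pos <- if (strand == "+") position + window else position - window
  ok <- pos >= 1L & pos <= length(chars)
  bases <- rep("n", length(window))
  bases[ok] <- chars[pos[ok]]
  if (strand == "-") {
    comp <- c(a = "u", c = "g", g = "c", u = "a", n = "n")
    bases <- unname(comp[bases])
  }
  target_window(bases, offsets = window)
}

#' Build an efficiency-weighted nucleotide profile
#'
#' Computes per-offset nucleotide frequencies over a set of site contexts,
#' each weighted by its editing efficiency, plus Shannon information content
#' for logo rendering: `freq(o, b) = sum_i w_i [seq_i(o) = b] / sum_i w_i`
#' with `n` bases excluded from both sums, and
#' `ic(o) = 2 + sum_b f log2 f` bits (0 log 0 = 0).
#'
#' @param contexts a list of [target_window]s (or a single one).
#' @param weights positive weights, recycled; typically the aggregate
#'   editing efficiencies of the sites.
#' @param window offsets of the profile (default `-20:5`).
#' @return an object of class `weighted_profile`: `list(window, freq, ic,
#'   n_sequences, total_weight)` with `freq` a 4 x length(window) matrix
#'   (rows `A C G U`).
#' @examples
#' p <- build_profile(list(native_target_window("nad4")), window = -16:2)
#' p$ic[["0"]]  # single sequence: 2 bits
#' @export
build_profile <- function(contexts, weights = 1, window = -20:5) {
  if (inherits(contexts, "target_window")) contexts <- list(contexts)
  stopifnot(length(contexts) >= 1L,
            all(vapply(contexts, inherits, logical(1), "target_window")))
  weights <- rep_len(weights, length(contexts))
  if (any(weights <= 0) || all(weights == 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  window <- as.integer(window)
  nts <- c("A", "C", "G", "U")
  freq <- matrix(0, 4, length(window), dimnames = list(nts, window))
  wtot <- numeric(length(window))
  for (i in seq_along(contexts)) {
    obs <- toupper(window_base(contexts[[i]], window))
    hit <- !is.na(obs) & obs != "N"
    for (j in which(hit)) {
      freq[obs[j], j] <- freq[obs[j], j] + weights[i]
      wtot[j] <- wtot[j] + weights[i]
    }
  }
  freq <- sweep(freq, 2, ifelse(wtot > 0, wtot, NA_real_), "/")
  ic <- apply(freq, 2, function(f) {
    if (anyNA(f)) return(NA_real_)
    2 + sum(ifelse(f > 0, f * log2(f), 0))
  })
  structure(list(window = window, freq = freq, ic = ic,
                 n_sequences = length(contexts),
                 total_weight = sum(weights)),
            class = "weighted_profile")
}

#' @export
print.weighted_profile <- function(x, ...) {
  cat(sprintf("weighted profile: %d sequence(s), total weight %.4g, offsets %d..%d\n",
              x$n_sequences, x$total_weight, min(x$window), max(x$window)))
  invisible(x)
}

#' Partition calls into unshifted and shifted sets
#'
#' Off-targets whose best array alignment requires a nucleotide shift are
#' conventionally excluded from consensus profiles. Uses the `shift_class`
#' column when present, otherwise computes [best_offset()] from the
#' reference.
#'
#' @param calls an `offtarget_calls` data.frame.
#' @param array a [ppr_array].
#' @param reference reference sequences (needed when `shift_class` is absent
#'   or `NA`).
#' @param max_shift shift window.
#' @param window context window for shift evaluation.
#' @return `list(unshifted =, shifted =)` of `data.frame`s.
#' @export
exclude_shifted <- function(calls, array, reference = NULL, max_shift = 2L,
                            window = -20:5) {
  calls <- as.data.frame(calls)
  if (!nrow(calls)) return(list(unshifted = calls, shifted = calls))
  sc <- if ("shift_class" %in% names(calls)) calls$shift_class else
    rep(NA_integer_, nrow(calls))
  todo <- which(is.na(sc))
  if (length(todo)) {
    if (is.null(reference)) {
      stop("reference needed to compute shift classes", call. = FALSE)
    }
    sc[todo] <- vapply(todo, function(i) {
      ctx <- extract_context(reference, calls$contig[i], calls$position[i],
                             calls$strand[i], window = window)
      best_offset(array, ctx, max_shift = max_shift)
    }, integer(1))
  }
  list(unshifted = calls[sc == 0L, , drop = FALSE],
       shifted = calls[sc != 0L, , drop = FALSE])
}

#' Export / import a profile matrix
#'
#' TSV with offsets as rows and columns `offset, A, C, G, U, ic`; the
#' round trip through `read_profile()` is lossless up to numeric printing
#' precision.
#'
#' @param profile a `weighted_profile`.
#' @param path file path.
#' @export
export_profile <- function(profile, path) {
  stopifnot(inherits(profile, "weighted_profile"))
  if (!length(profile$window)) stop("empty profile", call. = FALSE)
  tab <- data.frame(offset = profile$window, t(profile$freq),
                    ic = profile$ic, check.names = FALSE)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  freq <- t(as.matrix(tab[, c("A", "C", "G", "U")]))
  colnames(freq) <- tab$offset
  structure(list(window = as.integer(tab$offset), freq = freq,
                 ic = stats::setNames(as.numeric(tab$ic),
                                      as.character(tab$offset)),
                 n_sequences = NA_integer_, total_weight = NA_real_),
            class = "weighted_profile")
}
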