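# Internal alphabet helpers -----------------------------------------------

# normalize a character vector of single bases to lowercase RNA (t -> u);
# anything outside acgun raises an error unless allow_n = FALSE
.norm_bases <- function(x, what = "sequence") {
  x <- tolower(as.character(x))
  x[x == "t"] <- "u"
  bad <- !(x %in% c("a", "c", "g", "u", "n"))
  if (any(bad)) {
    stop(sprintf("invalid %s character(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

.seq_chars <- function(seq, what = "sequence") {
  if (inherits(seq, c("DNAString", "RNAString", "BString", "DNAStringSet",
                      "RNAStringSet"))) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  .norm_bases(strsplit(seq, "")[[1]], what = what)
}

.revcomp_chars <- function(x) {
  comp <- c(a = "u", c = "g", g = "c", u = "a", n = "n")
  rev(unname(comp[x]))
}

#' Target window around an editing site
#'
#' A `target_window` holds the nucleotide context of a (candidate) C-to-U
#' editing site, indexed by signed offsets relative to the edited cytidine:
#' offset 0 is the edited base itself, negative offsets are 5' (upstream),
#' positive offsets are 3' (downstream). Bases are stored in the lowercase
#' RNA alphabet (`a c g u n`); DNA input (`t`) is normalized to `u`.
#'
#' @param bases a single string or a character vector of single bases.
#' @param offsets integer vector of offsets, contiguous and containing 0.
#'   When `bases` is given as a string, `offsets` may instead be given as
#'   `from`, the offset of the first base.
#' @param from offset of the first base (alternative to `offsets`).
#' @return an object of class `target_window`: a named character vector of
#'   lowercase RNA bases whose names are the offsets.
#' @examples
#' w <- target_window("uuCau", from = -2)
#' window_base(w, 0)
#' @export
target_window <- function(bases, offsets = NULL, from = NULL) {
  if (length(bases) == 1L && nchar(bases[1]) > 1L) {
    bases <- .seq_chars(bases, "window")
  } else {
    bases <- .norm_bases(bases, "window")
  }
  n <- length(bases)
  if (is.null(offsets)) {
    if (is.null(from)) stop("supply 'offsets' or 'from'", call. = FALSE)
    offsets <- seq.int(from, length.out = n)
  }
  offsets <- as.integer(offsets)
  if (length(offsets) != n) stop("offsets and bases differ in length", call. = FALSE)
  if (any(diff(offsets) != 1L)) stop("offsets must be contiguous", call. = FALSE)
  if (!0L %in% offsets) stop("window must contain offset 0 (the edited base)", call. = FALSE)
  names(bases) <- offsets
  structure(bases, class = "target_window")
}

#' @export
print.target_window <- function(x, ...) {
  off <- window_offsets(x)
  cat(sprintf("target_window [%d..%d]\n", min(off), max(off)))
  shown <- unclass(x)
  shown[off == 0L] <- toupper(shown[off == 0L])
  cat(" ", paste(shown, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Offsets covered by a target window
#' @param window a `target_window`.
#' @return integer vector of offsets.
#' @export
window_offsets <- function(window) as.integer(names(window))

#' Base at a given offset
#'
#' @param window a `target_window`.
#' @param offset integer offset(s); offsets outside the window yield `NA`.
#' @return lowercase RNA base(s), `NA` where outside the window.
#' @export
window_base <- function(window, offset) {
  unname(unclass(window)[match(as.character(as.integer(offset)), names(window))])
}

#' Window as a plain string
#' @param window a `target_window`.
#' @param dna logical; render in DNA alphabet (u -> t)?
#' @return single character string, 5' to 3'.
#' @export
window_string <- function(window, dna = FALSE) {
  s <- unclass(window)
  if (dna) s[s == "u"] <- "t"
  paste(s, collapse = "")
}

# relabel offsets by -shift: the base formerly at offset o + s is seen at o.
# Used for shifted alignment scoring; no offset-0 validation on purpose.
.shift_window <- function(window, shift) {
  out <- unclass(window)
  names(out) <- as.integer(names(out)) - as.integer(shift)
  class(out) <- "target_window"
  out
}

# Native targets ----------------------------------------------------------

#' Native editing-target windows of PPR56
#'
#' Sequence context (-16..+2) of the two native mitochondrial targets of the
#' moss editing factor PPR56, nad4eU272SL and nad3eU230SL. Both share the
#' core `uuCau` around the edited cytidine; they differ at the positions
#' juxtaposed with several P-, S- and L-type PPRs (notably -16, -9 and -6).
#'
#' @param site `"nad4eU272SL"` or `"nad3eU230SL"` (prefix match on the locus
#'   is accepted, e.g. `"nad4"`).
#' @return a [target_window] spanning offsets -16..+2.
#' @examples
#' native_target_window("nad4")
#' @export
native_target_window <- function(site = c("nad4eU272SL", "nad3eU230SL")) {
  site <- match.arg(tolower(substr(site[1], 1, 4)), c("nad4", "nad3"))
  seqs <- c(nad4 = "auagacgguaucucuucau",
            nad3 = "uuggaagucaccuuuucau")
  target_window(seqs[[site]], from = -16L)
}
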