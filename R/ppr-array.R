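# PLS-type PPR array model ------------------------------------------------

.PPR_KINDS <- c("P", "L", "S", "P2", "L2", "S2", "E1", "E2")
.INDEXED_KINDS <- c("P", "L", "S", "P2", "L2", "S2")
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_aa <- function(x, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% .AA)
  if (any(bad)) {
    stop(sprintf("invalid amino-acid letter for %s: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Construct a single PPR motif
#'
#' PLS-type arrays of plant RNA editing factors are built from P (canonical),
#' L (long) and S (short) PPR variants, a deviant C-terminal P2-L2-S2 triplet
#' and the TPR-like E1/E2 extension motifs. Motifs are numbered backwards:
#' the C-terminal PLS motif S2 carries index -1 and indices decrease toward
#' the N-terminus; E1/E2 carry no index.
#'
#' @param kind one of `"P" "L" "S" "P2" "L2" "S2" "E1" "E2"`.
#' @param index negative integer for indexed (non-E) motifs; `NA` for E1/E2.
#' @param aa5,aaL one-letter amino-acid identities at motif positions 5 and
#'   Last; `NA` when unknown (the motif then scores as neutral).
#' @return a one-row `data.frame` with columns `kind, index, aa5, aaL`.
#' @export
ppr_motif <- function(kind, index = NA, aa5 = NA, aaL = NA) {
  kind <- match.arg(kind, .PPR_KINDS)
  index <- suppressWarnings(as.integer(index))
  if (kind %in% .INDEXED_KINDS) {
    if (is.na(index) || index >= 0L) {
      stop(sprintf("%s motifs need a negative index", kind), call. = FALSE)
    }
  } else if (!is.na(index)) {
    stop("E1/E2 motifs carry no index", call. = FALSE)
  }
  data.frame(kind = kind, index = index,
             aa5 = .check_aa(aa5, "position 5"),
             aaL = .check_aa(aaL, "position Last"),
             stringsAsFactors = FALSE)
}

#' Construct a PPR array
#'
#' @param motifs a `data.frame` of motifs (rows from [ppr_motif()], ordered
#'   N- to C-terminus) or a list of such rows.
#' @param name factor identifier, e.g. `"PPR56"`.
#' @return an object of class `ppr_array`: the motif `data.frame` with a
#'   `name` attribute. Indexed motifs must have strictly increasing indices
#'   toward -1, at most one motif per index, and any E1/E2 motifs must come
#'   last.
#' @export
ppr_array <- function(motifs, name = "array") {
  if (is.list(motifs) && !is.data.frame(motifs)) motifs <- do.call(rbind, motifs)
  stopifnot(is.data.frame(motifs),
            all(c("kind", "index", "aa5", "aaL") %in% names(motifs)))
  motifs <- motifs[, c("kind", "index", "aa5", "aaL")]
  motifs$index <- as.integer(motifs$index)
  if (!all(motifs$kind %in% .PPR_KINDS)) stop("unknown motif kind", call. = FALSE)
  idx <- motifs$index[motifs$kind %in% .INDEXED_KINDS]
  if (anyNA(idx) || any(idx >= 0L)) {
    stop("indexed motifs must have negative indices", call. = FALSE)
  }
  if (any(duplicated(idx))) stop("at most one motif per index", call. = FALSE)
  if (any(diff(idx) <= 0L)) {
    stop("motif indices must strictly increase toward -1", call. = FALSE)
  }
  e_rows <- which(motifs$kind %in% c("E1", "E2"))
  i_rows <- which(motifs$kind %in% .INDEXED_KINDS)
  if (length(e_rows) && length(i_rows) && min(e_rows) < max(i_rows)) {
    stop("E1/E2 motifs must follow all indexed motifs", call. = FALSE)
  }
  .check_aa(motifs$aa5, "position 5")
  .check_aa(motifs$aaL, "position Last")
  rownames(motifs) <- NULL
  structure(motifs, class = c("ppr_array", "data.frame"), name = name)
}

#' @export
print.ppr_array <- function(x, ...) {
  cat(sprintf("PPR array '%s' (%d motifs)\n", array_name(x), nrow(x)))
  cat(" ", format_ppr_array(x), "\n", sep = "")
  invisible(x)
}

#' @rdname ppr_array
#' @param array a `ppr_array`.
#' @export
array_name <- function(array) attr(array, "name")

#' Motif labels of an array
#'
#' Indexed motifs are labelled `kind` + `index` (e.g. `"S-13"`), E motifs by
#' their kind alone.
#' @param array a `ppr_array`.
#' @return character vector, one label per motif.
#' @export
motif_labels <- function(array) {
  ifelse(array$kind %in% .INDEXED_KINDS,
         paste0(array$kind, array$index), array$kind)
}

# Inline string form ------------------------------------------------------

#' Parse and format the inline PPR-array string form
#'
#' Arrays are written as comma-separated motif tokens, N- to C-terminal:
#' `kind index aa5 aaL` for indexed motifs (e.g. `"S-13NS"`; the amino-acid
#' letters may be omitted when unknown, e.g. `"L-14"`), and `kind` plus the
#' Last residue for E motifs (e.g. `"E1N"`, `"E2K"`).
#'
#' @param x inline string, e.g. `"S-13NS,P-12NN,...,S2-1ND,E1N,E2K"`.
#' @param name array name.
#' @return `parse_ppr_array()`: a [ppr_array]; `format_ppr_array()`: a string.
#' @examples
#' parse_ppr_array("S-4TN,P2-3ND,L2-2VD,S2-1ND", name = "mini")
#' @export
parse_ppr_array <- function(x, name = "array") {
  tokens <- trimws(strsplit(x, ",")[[1]])
  rows <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^(P2|L2|S2|P|L|S)(-[0-9]+)([A-Z]{2})?$", tok))[[1]]
    if (length(m)) {
      aa <- if (nzchar(m[4])) strsplit(m[4], "")[[1]] else c(NA, NA)
      return(ppr_motif(m[2], as.integer(m[3]), aa[1], aa[2]))
    }
    m <- regmatches(tok, regexec("^(E1|E2)([A-Z])?$", tok))[[1]]
    if (length(m)) {
      return(ppr_motif(m[2], NA, NA, if (nzchar(m[3])) m[3] else NA))
    }
    stop(sprintf("cannot parse motif token '%s'", tok), call. = FALSE)
  })
  ppr_array(rows, name = name)
}

#' @rdname parse_ppr_array
#' @param array a `ppr_array`.
#' @export
format_ppr_array <- function(array) {
  tok <- vapply(seq_len(nrow(array)), function(i) {
    r <- array[i, ]
    if (r$kind %in% .INDEXED_KINDS) {
      aa <- if (is.na(r$aa5) || is.na(r$aaL)) "" else paste0(r$aa5, r$aaL)
      paste0(r$kind, r$index, aa)
    } else {
      paste0(r$kind, if (is.na(r$aaL)) "" else r$aaL)
    }
  }, character(1))
  paste(tok, collapse = ",")
}

#' Read / write a PPR array as a motif table
#'
#' Tab-separated table with columns `kind, index, aa5, aaL` (one row per
#' motif, N- to C-terminal; empty fields for unknown identities).
#'
#' @param path file path.
#' @param name array name for `read_ppr_array`.
#' @return `read_ppr_array()` returns a [ppr_array].
#' @export
read_ppr_array <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  tab$aa5[!nzchar(tab$aa5) | is.na(tab$aa5)] <- NA
  tab$aaL[!nzchar(tab$aaL) | is.na(tab$aaL)] <- NA
  ppr_array(tab, name = name)
}

#' @rdname read_ppr_array
#' @param array a `ppr_array`.
#' @export
write_ppr_array <- function(array, path) {
  tab <- as.data.frame(array)
  tab$aa5[is.na(tab$aa5)] <- ""
  tab$aaL[is.na(tab$aaL)] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The PPR56 array
#'
#' The PLS-type PPR array of the Physcomitrium patens mitochondrial editing
#' factor PPR56: fourteen PLS motifs (L-14 ... S2-1) followed by E1 and E2.
#' Position 5 / Last identities of L-14 are not established and are stored
#' as unknown (the motif scores as neutral); E1 and E2 carry their position
#' 34 ("Last") residues N and K.
#'
#' @return a [ppr_array] named `"PPR56"`.
#' @examples
#' juxtapose(ppr56())
#' @export
ppr56 <- function() {
  parse_ppr_array(paste0(
    "L-14,S-13NS,P-12NN,L-11MD,S-10TD,P-9TN,L-8VD,S-7TD,",
    "P-6ND,L-5LD,S-4TN,P2-3ND,L2-2VD,S2-1ND,E1N,E2K"),
    name = "PPR56")
}

# Juxtaposition -----------------------------------------------------------

#' Map motifs to juxtaposed target offsets
#'
#' PPRs are numbered backwards with the terminal PPR S2-1 juxtaposed with
#' target position -4, so every indexed motif faces target offset
#' `index - 3`; the E1 and E2 motifs face offsets -3 and -2.
#'
#' @param array a [ppr_array]; its indexed part must end in an S2 motif.
#' @return named integer vector of target offsets, names from
#'   [motif_labels()].
#' @examples
#' juxtapose(ppr56())[c("S2-1", "S-13", "E2")]
#' @export
juxtapose <- function(array) {
  stopifnot(inherits(array, "ppr_array"))
  indexed <- array$kind %in% .INDEXED_KINDS
  if (!any(indexed) || array$kind[max(which(indexed))] != "S2") {
    stop("array must end in an S2 motif (before any E1/E2)", call. = FALSE)
  }
  off <- ifelse(indexed, array$index - 3L,
                ifelse(array$kind == "E1", -3L, -2L))
  stats::setNames(as.integer(off), motif_labels(array))
}
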