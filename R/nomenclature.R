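# Mutation & editing-site nomenclature ------------------------------------
#
# Protein labels:  factor name plus pipe-separated mutation segments, e.g.
#   PPR56|DYW:G3A          domain point mutation
#   PPR56|P-6ND>TD         PPR 5/Last shorthand
#   PPR56|E1:N34D          E-motif point mutation
#   PPR56|trunc:P-12       N-terminal truncation through a motif (extension)
# Site labels:     locus + "eU" + 1-based position from the start-codon A
#   (negative = upstream of start, no zero) + codon change, e.g. nad4eU272SL,
#   fdhEeU403Q*, folDeU-5.
# Target labels:   site label plus lowercase substitution segments relative
#   to the edited base, e.g. nad4eU272SL|u-4g, nad4eU272SL|c0u.

.P_DOMAIN <- "^(DYW|E1|E2):([A-Z])([0-9]+)([A-Z*])$"
.P_5L     <- "^(P2|L2|S2|P|L|S)(-[0-9]+)([A-Z]{2})>([A-Z]{2})$"
.P_TRUNC  <- "^trunc:(P2|L2|S2|P|L|S)(-[0-9]+)$"

#' Parse a protein-mutation label
#'
#' @param label a label of the form `factor(|segment)*`, e.g.
#'   `"PPR56|S-7TD>TN|S-4TN>TD"`.
#' @return an object of class `protein_label`: `list(factor, mutations)`
#'   where each mutation is a `protein_mutation` list with a `kind` of
#'   `"domain_point"`, `"ppr_5L"` or `"truncation"` and the corresponding
#'   fields (`domain, position, from_aa, to_aa` / `motif_kind, motif_index,
#'   from_pair, to_pair` / `motif_kind, motif_index`).
#' @examples
#' parse_protein_label("PPR56|DYW:G3A")
#' parse_protein_label("PPR56|S-4TN>TD")$mutations[[1]]$to_pair
#' @export
parse_protein_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(parts[1])) {
    stop("label must start with a factor name", call. = FALSE)
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", parts[1])) {
    stop(sprintf("invalid factor name '%s'", parts[1]), call. = FALSE)
  }
  muts <- lapply(parts[-1], function(seg) {
    m <- regmatches(seg, regexec(.P_DOMAIN, seg))[[1]]
    if (length(m)) {
      return(structure(list(kind = "domain_point", domain = m[2],
                            position = as.integer(m[4]), from_aa = m[3],
                            to_aa = m[5]), class = "protein_mutation"))
    }
    m <- regmatches(seg, regexec(.P_5L, seg))[[1]]
    if (length(m)) {
      from <- strsplit(m[4], "")[[1]]; to <- strsplit(m[5], "")[[1]]
      return(structure(list(kind = "ppr_5L", motif_kind = m[2],
                            motif_index = as.integer(m[3]),
                            from_pair = from, to_pair = to),
                       class = "protein_mutation"))
    }
    m <- regmatches(seg, regexec(.P_TRUNC, seg))[[1]]
    if (length(m)) {
      return(structure(list(kind = "truncation", motif_kind = m[2],
                            motif_index = as.integer(m[3])),
                       class = "protein_mutation"))
    }
    stop(sprintf("cannot parse mutation segment '%s'", seg), call. = FALSE)
  })
  addr <- vapply(muts, function(m) {
    if (m$kind == "domain_point") paste0(m$domain, ":", m$position)
    else paste0(m$motif_kind, m$motif_index)
  }, character(1))
  if (anyDuplicated(addr)) {
    stop("chained mutations must address distinct motifs/positions", call. = FALSE)
  }
  structure(list(factor = parts[1], mutations = muts), class = "protein_label")
}

#' @rdname parse_protein_label
#' @param mutation a single `protein_mutation`.
#' @export
format_protein_mutation <- function(mutation) {
  switch(mutation$kind,
    domain_point = sprintf("%s:%s%d%s", mutation$domain, mutation$from_aa,
                           mutation$position, mutation$to_aa),
    ppr_5L = sprintf("%s%d%s>%s", mutation$motif_kind, mutation$motif_index,
                     paste(mutation$from_pair, collapse = ""),
                     paste(mutation$to_pair, collapse = "")),
    truncation = sprintf("trunc:%s%d", mutation$motif_kind,
                         mutation$motif_index),
    stop("unknown mutation kind", call. = FALSE))
}

#' Format a protein-mutation label
#'
#' Inverse of [parse_protein_label()]; `format(parse(x)) == x` for canonical
#' labels. An empty mutation list yields the bare factor name.
#'
#' @param x a `protein_label`.
#' @return the canonical label string.
#' @export
format_protein_label <- function(x) {
  stopifnot(inherits(x, "protein_label"))
  paste(c(x$factor, vapply(x$mutations, format_protein_mutation,
                           character(1))), collapse = "|")
}

#' @export
print.protein_label <- function(x, ...) {
  cat("protein label:", format_protein_label(x), "\n")
  invisible(x)
}

# Site labels --------------------------------------------------------------

#' Parse / format an editing-site label
#'
#' Editing sites are labelled by locus, the token `eU` for the editing event
#' towards uridine, the transcript position counting from the first
#' nucleotide of the AUG start codon (1-based; negative positions lie
#' upstream of the start, there is no position 0) and, for sites within an
#' annotated CDS, the resulting codon change in one-letter code with `*` for
#' a stop codon (e.g. `nad4eU272SL`, `fdhEeU403Q*`, `folDeU-5`).
#'
#' @param label site label text.
#' @return `parse_site_label()`: an object of class `site_label`,
#'   `list(locus, position, aa_from, aa_to)` (aa fields `NA` when absent);
#'   `format_site_label()`: the canonical label string.
#' @examples
#' parse_site_label("fdhEeU403Q*")
#' format_site_label(site_label("nad4", 272, "S", "L"))
#' @export
parse_site_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label,
                  regexec("^(.+?)eU(-?[0-9]+)([A-Z*]{2})?$", label))[[1]]
  if (!length(m)) {
    stop(sprintf("cannot parse site label '%s' (missing eU token?)", label),
         call. = FALSE)
  }
  pos <- as.integer(m[3])
  if (pos == 0L) stop("site position 0 does not exist", call. = FALSE)
  aa <- if (nzchar(m[4])) strsplit(m[4], "")[[1]] else c(NA, NA)
  if (!is.na(aa[1]) && pos < 0L) {
    stop("upstream sites carry no codon change", call. = FALSE)
  }
  site_label(m[2], pos, aa[1], aa[2])
}

#' @rdname parse_site_label
#' @param locus gene name.
#' @param position signed 1-based transcript position (no zero).
#' @param aa_from,aa_to amino acids before/after editing (`*` = stop), or
#'   `NA` for non-codon-changing sites.
#' @export
site_label <- function(locus, position, aa_from = NA, aa_to = NA) {
  position <- as.integer(position)
  if (is.na(position) || position == 0L) {
    stop("position must be a non-zero integer", call. = FALSE)
  }
  ok_aa <- function(a) is.na(a) || a %in% c(.AA, "*")
  if (!ok_aa(aa_from) || !ok_aa(aa_to)) stop("invalid amino-acid letter", call. = FALSE)
  if (is.na(aa_from) != is.na(aa_to)) {
    stop("aa_from and aa_to must be given together", call. = FALSE)
  }
  structure(list(locus = locus, position = position,
                 aa_from = aa_from, aa_to = aa_to), class = "site_label")
}

#' @rdname parse_site_label
#' @param x a `site_label`.
#' @export
format_site_label <- function(x) {
  stopifnot(inherits(x, "site_label"))
  aa <- if (is.na(x$aa_from)) "" else paste0(x$aa_from, x$aa_to)
  sprintf("%seU%d%s", x$locus, x$position, aa)
}

#' @export
print.site_label <- function(x, ...) {
  cat("site label:", format_site_label(x), "\n")
  invisible(x)
}

# Target variants ----------------------------------------------------------

#' Parse / format a target-variant label
#'
#' A target variant is a site label followed by lowercase substitution
#' segments relative to the edited base: `nad4eU272SL|u-4g` exchanges the U
#' four nucleotides upstream for G; offset 0 denotes the edited cytidine
#' itself, so `nad4eU272SL|c0u` is the pre-edited state. DNA-alphabet `t` is
#' accepted for `u`.
#'
#' @param label target label text.
#' @return `parse_target_label()`: an object of class `target_variant`,
#'   `list(site, substitutions)` with `substitutions` a `data.frame`
#'   of `offset, from, to` in the order given.
#' @examples
#' parse_target_label("nad3eU230SL|u-16a|u-9g|c-6u")$substitutions
#' @export
parse_target_label <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  site <- parse_site_label(parts[1])
  subs <- lapply(parts[-1], function(seg) {
    m <- regmatches(seg, regexec("^([acgut])([+-]?[0-9]+)([acgut])$", seg))[[1]]
    if (!length(m)) {
      stop(sprintf("cannot parse substitution segment '%s'", seg), call. = FALSE)
    }
    data.frame(offset = as.integer(m[3]),
               from = .norm_bases(m[2]), to = .norm_bases(m[4]),
               stringsAsFactors = FALSE)
  })
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(offset = integer(0), from = character(0), to = character(0))
  if (anyDuplicated(subs$offset)) stop("substitution offsets must be unique", call. = FALSE)
  if (any(subs$from == subs$to)) stop("from and to base must differ", call. = FALSE)
  structure(list(site = site, substitutions = subs), class = "target_variant")
}

#' @rdname parse_target_label
#' @param x a `target_variant`.
#' @export
format_target_label <- function(x) {
  stopifnot(inherits(x, "target_variant"))
  off <- x$substitutions$offset
  off_txt <- ifelse(off > 0, paste0("+", off), as.character(off))
  segs <- sprintf("%s%s%s", x$substitutions$from, off_txt, x$substitutions$to)
  paste(c(format_site_label(x$site), segs), collapse = "|")
}

#' @export
print.target_variant <- function(x, ...) {
  cat("target variant:", format_target_label(x), "\n")
  invisible(x)
}

#' Apply target substitutions to a window
#'
#' @param window a [target_window].
#' @param variant a `target_variant` from [parse_target_label()], or a label
#'   string (which may also be bare substitution segments like `"c-6u"`,
#'   i.e. without a site label, separated by `|`).
#' @return a new [target_window] with the substitutions installed; the
#'   original is untouched. Every substitution's `from` base must equal the
#'   current window base at its offset, and all offsets must lie within the
#'   window.
#' @examples
#' w <- apply_target_mutations(native_target_window("nad3"), "c-6u")
#' window_base(w, -6)
#' @export
apply_target_mutations <- function(window, variant) {
  stopifnot(inherits(window, "target_window"))
  if (is.character(variant)) {
    variant <- if (grepl("eU", variant, fixed = TRUE)) {
      parse_target_label(variant)
    } else {
      parse_target_label(paste(c("xeU1", strsplit(variant, "|", fixed = TRUE)[[1]]),
                               collapse = "|"))
    }
  }
  stopifnot(inherits(variant, "target_variant"))
  out <- unclass(window)
  subs <- variant$substitutions
  for (i in seq_len(nrow(subs))) {
    key <- as.character(subs$offset[i])
    if (!key %in% names(out)) {
      stop(sprintf("offset %d outside the window", subs$offset[i]), call. = FALSE)
    }
    if (out[[key]] != subs$from[i]) {
      stop(sprintf("window has %s at offset %d, not %s", out[[key]],
                   subs$offset[i], subs$from[i]), call. = FALSE)
    }
    out[[key]] <- subs$to[i]
  }
  class(out) <- "target_window"
  out
}

#' Reverse a set of target substitutions
#' @param variant a `target_variant`.
#' @return the `target_variant` with `from`/`to` swapped (applying it undoes
#'   the original).
#' @export
invert_target_variant <- function(variant) {
  stopifnot(inherits(variant, "target_variant"))
  s <- variant$substitutions
  variant$substitutions <- data.frame(offset = s$offset, from = s$to,
                                      to = s$from, stringsAsFactors = FALSE)
  variant
}

# Site naming from a CDS ---------------------------------------------------

.translate_codon <- function(codon) {
  codon <- toupper(gsub("u", "t", codon))
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Name an editing site from its coding sequence
#'
#' Computes the `eU` label of a C-to-U editing event from the CDS it falls
#' in: positions count from the first nucleotide of the AUG start codon, the
#' affected codon is `ceiling(position / 3)`, and the amino acids before and
#' after the C-to-U substitution give the codon-change suffix (`*` for a
#' stop codon; synonymous changes are rendered with the repeated letter,
#' e.g. `PP`). Negative positions (upstream of the start codon) carry no
#' suffix.
#'
#' @param cds coding sequence from the start codon on (string, `DNAString`
#'   or `RNAString`); only needed for positive positions.
#' @param position signed position, 1-based from the A of the start codon.
#' @param locus gene name used in the label.
#' @return a `site_label`.
#' @examples
#' cds <- paste0(strrep("gca", 90), "tca")  # codon 91 = UCA (Ser)
#' format_site_label(name_site(cds, 272, "nad4"))
#' @export
name_site <- function(cds, position, locus = "locus") {
  position <- as.integer(position)
  if (position == 0L) stop("position 0 does not exist", call. = FALSE)
  if (position < 0L) return(site_label(locus, position))
  chars <- .seq_chars(cds, "CDS")
  if (position > length(chars)) {
    stop("position lies beyond the supplied CDS", call. = FALSE)
  }
  if (chars[position] != "c") {
    stop(sprintf("CDS base at position %d is %s, not c", position,
                 chars[position]), call. = FALSE)
  }
  ci <- ceiling(position / 3)
  cstart <- 3L * ci - 2L
  codon <- chars[cstart:(cstart + 2L)]
  if (anyNA(codon)) stop("codon extends beyond the CDS", call. = FALSE)
  aa_from <- .translate_codon(paste(codon, collapse = ""))
  codon[position - cstart + 1L] <- "u"
  aa_to <- .translate_codon(paste(codon, collapse = ""))
  site_label(locus, position, aa_from, aa_to)
}

#' Name a genomic site from annotation
#'
#' Locates a transcriptome position in CDS annotation (GFF3 or BED) and
#' derives its `eU` label: sites inside a CDS get 1-based CDS coordinates
#' and the codon change, sites within `max_upstream` nucleotides 5' of a CDS
#' start on the same strand get a negative position, anything else falls
#' back to the raw `contig:position` form.
#'
#' @param contig,position,strand site coordinates (1-based; strand of the
#'   edited C, `"+"` or `"-"`).
#' @param annotation a `GRanges` (e.g. from `rtracklayer::import()`) or the
#'   path to a GFF3/BED file; features of type `CDS` are used when a `type`
#'   column is present. Gene names are taken from the first available of
#'   `gene`, `Name`, `ID`.
#' @param reference a named `DNAStringSet` (or FASTA path) supplying the
#'   CDS sequence for codon-change computation.
#' @param max_upstream how far upstream of a start codon a site may lie and
#'   still be named relative to that CDS (default 30 nt).
#' @return label text.
#' @export
name_site_from_annotation <- function(contig, position, strand, annotation,
                                      reference, max_upstream = 30L) {
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  md <- as.data.frame(annotation)
  if ("type" %in% names(md)) {
    keep <- md$type == "CDS"
    annotation <- annotation[keep]; md <- md[keep, , drop = FALSE]
  }
  if (!nrow(md)) return(sprintf("%s:%d", contig, position))
  gene_col <- intersect(c("gene", "Name", "ID", "name"), names(md))[1]
  genes <- if (is.na(gene_col)) rep(NA_character_, nrow(md)) else
    as.character(md[[gene_col]])
  same <- md$seqnames == contig & md$strand == strand
  # inside a CDS
  inside <- same & md$start <= position & md$end >= position
  if (any(inside)) {
    i <- which(inside)[1]
    cds_pos <- if (strand == "+") position - md$start[i] + 1L else
      md$end[i] - position + 1L
    seq <- reference[[contig]]
    cds <- Biostrings::subseq(seq, md$start[i], md$end[i])
    if (strand == "-") cds <- Biostrings::reverseComplement(cds)
    lab <- name_site(as.character(cds), cds_pos,
                     locus = ifelse(is.na(genes[i]), contig, genes[i]))
    return(format_site_label(lab))
  }
  # upstream of a start codon
  up <- which(same & ((md$strand == "+" & position < md$start &
                         md$start - position <= max_upstream) |
                      (md$strand == "-" & position > md$end &
                         position - md$end <= max_upstream)))
  if (length(up)) {
    i <- up[which.min(ifelse(md$strand[up] == "+", md$start[up] - position,
                             position - md$end[up]))]
    offset <- if (md$strand[i] == "+") position - md$start[i] else
      md$end[i] - position
    lab <- site_label(ifelse(is.na(genes[i]), contig, genes[i]), offset)
    return(format_site_label(lab))
  }
  sprintf("%s:%d", contig, position)
}

# Codon engineering --------------------------------------------------------

#' Enumerate stop/start codons creatable by C-to-U editing
#'
#' Given the context of an editable cytidine, enumerates the minimal
#' substitution sets in offsets -1, +1 and +2 (never the edited base itself)
#' such that editing C(0) to U creates a stop codon in frame (0,+1,+2) —
#' UAA, UAG or UGA — or a start codon AUG in frame (-1,0,+1).
#'
#' @param window a [target_window] spanning at least offsets -1..+2 with `c`
#'   at offset 0.
#' @return a list of designs, each `list(category, codon, substitutions)`
#'   with `substitutions` a `data.frame(offset, from, to)` (zero rows when
#'   the window already reads the codon after editing). Exactly three stop
#'   designs and one start design are returned.
#' @examples
#' designs <- design_codon_edits(native_target_window("nad4"))
#' vapply(designs, `[[`, character(1), "codon")
#' @export
design_codon_edits <- function(window) {
  stopifnot(inherits(window, "target_window"))
  need <- c(-1L, 0L, 1L, 2L)
  if (anyNA(window_base(window, need))) {
    stop("window must span offsets -1..+2", call. = FALSE)
  }
  if (window_base(window, 0L) != "c") {
    stop("no cytidine at offset 0", call. = FALSE)
  }
  subs_for <- function(frame_offsets, target_codon) {
    tc <- strsplit(target_codon, "")[[1]]
    rows <- lapply(seq_along(frame_offsets), function(i) {
      o <- frame_offsets[i]
      cur <- if (o == 0L) "u" else window_base(window, o)  # 0 reads u post-edit
      if (o != 0L && cur != tc[i]) {
        data.frame(offset = o, from = cur, to = tc[i], stringsAsFactors = FALSE)
      } else NULL
    })
    do.call(rbind, c(rows, list(data.frame(offset = integer(0),
                                           from = character(0),
                                           to = character(0)))))
  }
  designs <- lapply(c("uaa", "uag", "uga"), function(codon) {
    list(category = "stop", codon = codon,
         substitutions = subs_for(0:2, codon))
  })
  designs <- c(designs, list(list(category = "start", codon = "aug",
                                  substitutions = subs_for(-1:1, "aug"))))
  designs
}
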