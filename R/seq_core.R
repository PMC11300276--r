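# Sequence primitives, IMGT scheme, alignment, translation and FASTA I/O.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter codes, in alphabetical order.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.as_chars <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    strsplit(x, "", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

#' Amino-acid sequence
#'
#' Lightweight container for a protein sequence. The alphabet is the 20
#' standard residues plus `X` (unknown), `-` (gap) and `*` (stop marker, as
#' produced by [translate_nt()]).
#'
#' @param id sequence identifier.
#' @param residues character vector of one-letter codes, or a single string.
#' @return an object of class `aa_seq` with fields `id` and `chars`.
#' @export
aa_seq <- function(id, residues) {
  chars <- .as_chars(residues)
  if (length(chars) == 0L) stop("empty amino-acid sequence", call. = FALSE)
  bad <- setdiff(unique(chars), c(AA_STANDARD, "X", "-", "*"))
  if (length(bad) > 0L) {
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = as.character(id), chars = chars), class = "aa_seq")
}

NT_PLAIN <- c("A", "C", "G", "T")
NT_DEGENERATE <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Nucleotide sequence
#'
#' @param id sequence identifier.
#' @param bases character vector of bases or a single string. IUPAC degeneracy
#'   codes are only accepted when `degenerate_ok = TRUE`.
#' @param degenerate_ok allow IUPAC ambiguity codes.
#' @return an object of class `nt_seq` with fields `id`, `chars` and
#'   `degenerate` (logical: does the sequence contain ambiguity codes).
#' @export
nt_seq <- function(id, bases, degenerate_ok = FALSE) {
  chars <- toupper(.as_chars(bases))
  if (length(chars) == 0L) stop("empty nucleotide sequence", call. = FALSE)
  allowed <- if (degenerate_ok) c(NT_PLAIN, NT_DEGENERATE) else NT_PLAIN
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0L) {
    stop("invalid base(s)", if (!degenerate_ok) " (degeneracy not flagged)",
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = as.character(id), chars = chars,
                 degenerate = any(chars %in% NT_DEGENERATE)),
            class = "nt_seq")
}

#' @export
as.character.aa_seq <- function(x, ...) paste(x$chars, collapse = "")
#' @export
as.character.nt_seq <- function(x, ...) paste(x$chars, collapse = "")
#' @export
length.aa_seq <- function(x) length(x$chars)
#' @export
length.nt_seq <- function(x) length(x$chars)
#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq> %s (%d aa)\n%s\n", x$id, length(x$chars),
              as.character(x)))
  invisible(x)
}
#' @export
print.nt_seq <- function(x, ...) {
  cat(sprintf("<nt_seq> %s (%d nt%s)\n%s\n", x$id, length(x$chars),
              if (x$degenerate) ", degenerate" else "", as.character(x)))
  invisible(x)
}

.seq_chars <- function(x) {
  if (inherits(x, "aa_seq") || inherits(x, "nt_seq")) return(x$chars)
  if (inherits(x, "annotated_nanobody")) return(x$sequence$chars)
  .as_chars(x)
}

# ---------------------------------------------------------------------------
# IMGT scheme

#' IMGT region scheme for nanobody variable domains
#'
#' Region spans in IMGT coordinates (FR1 1-26, CDR1 27-38, FR2 39-55,
#' CDR2 56-66, FR3 67-104, CDR3 105-117, FR4 118-128), the four FR2 hallmark
#' positions (42, 49, 50, 52) that distinguish VHH from human VH frameworks,
#' and the conserved CDR anchor residues kept fixed or only slightly
#' randomized during library design. Position 66 belongs to CDR2 in this
#' scheme.
#'
#' @return an object of class `imgt_scheme`.
#' @export
imgt_scheme <- function() {
  regions <- data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start  = c(1L, 27L, 39L, 56L, 67L, 105L, 118L),
    end    = c(26L, 38L, 55L, 66L, 104L, 117L, 128L),
    stringsAsFactors = FALSE
  )
  stopifnot(all(regions$start[-1] == regions$end[-nrow(regions)] + 1L))
  hallmarks <- c(42L, 49L, 50L, 52L)
  fr2 <- regions[regions$region == "FR2", ]
  stopifnot(all(hallmarks >= fr2$start & hallmarks <= fr2$end))
  anchors <- c(`27` = "G", `29` = "I", `35` = "A",   # CDR1
               `56` = "I", `63` = "G", `65` = "T",   # CDR2
               `105` = "A", `117` = "Y")             # CDR3
  structure(list(regions = regions, hallmarks = hallmarks, anchors = anchors),
            class = "imgt_scheme")
}

.region_span <- function(scheme, region) {
  r <- scheme$regions[scheme$regions$region == region, ]
  if (nrow(r) != 1L) stop("unknown region: ", region, call. = FALSE)
  r$start:r$end
}

.is_cdr <- function(region) region %in% c("CDR1", "CDR2", "CDR3")

#' IMGT position labels for a CDR of a given length
#'
#' Loops shorter than the IMGT span lose positions symmetrically from the
#' loop apex outward, the extra residue on ties going to the N-terminal half
#' (IMGT convention). Loops longer than the span gain inserted positions at
#' the apex, labelled `111.1`, `112.1`, `111.2`, ... for CDR3 (and
#' analogously for other regions), the first extra position on the
#' N-terminal side.
#'
#' @param region `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param len loop length in amino acids.
#' @param scheme an [imgt_scheme()].
#' @return character vector of `len` IMGT position labels in sequence order.
#' @export
imgt_cdr_labels <- function(region, len, scheme = imgt_scheme()) {
  if (!.is_cdr(region)) stop("not a CDR region: ", region, call. = FALSE)
  if (len < 1L) stop("CDR length must be positive", call. = FALSE)
  span <- .region_span(scheme, region)
  s <- length(span)
  if (len <= s) {
    n_n <- ceiling(len / 2)
    n_c <- len - n_n
    lab <- c(span[seq_len(n_n)],
             if (n_c > 0) span[(s - n_c + 1L):s])
    return(as.character(lab))
  }
  extra <- len - s
  mid <- ceiling(s / 2)                 # apex position index (e.g. 111 in CDR3)
  left_base <- span[mid]
  right_base <- span[mid + 1L]
  n_left <- ceiling(extra / 2)
  n_right <- extra - n_left
  ins <- c(paste0(left_base, ".", seq_len(n_left)),
           if (n_right > 0) paste0(right_base, ".", rev(seq_len(n_right))))
  as.character(c(span[seq_len(mid)], ins, span[(mid + 1L):s]))
}

.imgt_label_key <- function(labels) {
  # numeric sort key putting 111.x ascending after 111 and 112.x descending
  # before 112 (insertion convention)
  parts <- strsplit(labels, ".", fixed = TRUE)
  vapply(parts, function(p) {
    base <- as.numeric(p[[1L]])
    if (length(p) == 1L) return(base)
    sub <- as.numeric(p[[2L]])
    # left-side insertions (odd apex base) ascend, right-side descend
    if (base %% 2 == 1) base + sub / 1000 else base - sub / 1000
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Global alignment (Needleman-Wunsch, linear gap penalty)

.nw_core <- function(a, b, smat, gap) {
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1L, m + 1L)
  M[1L, ] <- gap * (0:m)
  M[, 1L] <- gap * (0:n)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    cand <- pmax(M[i, jj] + smat[i, ], M[i, jj + 1L] + gap)
    # fold in the left-dependency with a running max (linear gap makes the
    # row recursion M[i+1,j] = max(cand[j], M[i+1,j-1] + gap) a cummax)
    pref <- cummax(c(M[i + 1L, 1L], cand - gap * jj))
    M[i + 1L, jj + 1L] <- gap * jj + pref[-1L]
  }
  # deterministic traceback: diagonal > up (gap in b) > left (gap in a)
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L && here == M[i, j] + smat[i, j]) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == M[i, j + 1L] + gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L
    }
  }
  list(a = ra, b = rb, score = M[n + 1L, m + 1L])
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with configurable match/mismatch scores and a linear gap
#' penalty. Identity is defined as matches divided by alignment columns
#' (gap columns included in the denominator).
#'
#' @param a,b sequences ([aa_seq()], [nt_seq()], annotated nanobodies or
#'   plain strings).
#' @param match,mismatch,gap alignment scores (defaults +1 / 0 / -1).
#' @return a list of class `pairwise_alignment`: gapped character vectors
#'   `a` and `b`, `score`, `identity`, `n_columns`, `n_matches`.
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  if (length(ca) == 0L || length(cb) == 0L) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  smat <- matrix(mismatch, length(ca), length(cb))
  smat[outer(ca, cb, "==")] <- match
  res <- .nw_core(ca, cb, smat, gap)
  n_match <- sum(res$a == res$b & res$a != "-")
  structure(list(a = res$a, b = res$b, score = res$score,
                 identity = n_match / length(res$a),
                 n_columns = length(res$a), n_matches = n_match),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.3f over %d columns\n",
              x$score, x$identity, x$n_columns))
  cat(paste(x$a, collapse = ""), "\n")
  cat(paste(x$b, collapse = ""), "\n")
  invisible(x)
}

#' Alignment identity between two sequences
#'
#' @inheritParams global_align
#' @return identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, ...) global_align(a, b, ...)$identity

# ---------------------------------------------------------------------------
# Translation

#' Translate a nucleotide sequence
#'
#' Standard genetic code. Premature stop codons are reported with their codon
#' index; a trailing partial codon is dropped and flagged.
#'
#' @param nt an [nt_seq()] (non-degenerate).
#' @param frame reading-frame offset (0, 1 or 2).
#' @return list with `aa` (an [aa_seq()] possibly containing `*`), `stops`
#'   (1-based codon indices of stop codons) and `partial` (was a trailing
#'   partial codon dropped).
#' @export
translate_nt <- function(nt, frame = 0L) {
  if (!inherits(nt, "nt_seq")) nt <- nt_seq("nt", nt, degenerate_ok = TRUE)
  if (nt$degenerate) {
    stop("degenerate bases present; expand before translating", call. = FALSE)
  }
  chars <- nt$chars
  if (frame < 0L || frame > 2L) stop("frame must be 0, 1 or 2", call. = FALSE)
  usable <- chars[seq.int(frame + 1L, length(chars))]
  n_cod <- length(usable) %/% 3L
  partial <- (length(usable) %% 3L) != 0L
  if (n_cod == 0L) stop("no complete codon in frame", call. = FALSE)
  m <- matrix(usable[seq_len(3L * n_cod)], nrow = 3L)
  codons <- paste0(m[1L, ], m[2L, ], m[3L, ])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  list(aa = aa_seq(nt$id, aa), stops = stops, partial = partial)
}

#' Preferred codon table for back-translation
#'
#' One deterministic codon per amino acid (common E. coli usage), so that
#' `translate_nt(back_translate(x))` returns `x`.
#'
#' @return named character vector mapping residues to codons.
#' @export
preferred_codons <- function() {
  c(A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC",
    Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
    L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
    S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")
}

#' Back-translate an amino-acid sequence
#'
#' @param aa an [aa_seq()] without gaps or unknown residues.
#' @param codon_table named residue-to-codon map (see [preferred_codons()]).
#' @return an [nt_seq()].
#' @export
back_translate <- function(aa, codon_table = preferred_codons()) {
  if (!inherits(aa, "aa_seq")) aa <- aa_seq("aa", aa)
  if (any(aa$chars == "-")) stop("gapped sequence cannot be back-translated",
                                 call. = FALSE)
  if (any(aa$chars %in% c("X", "*"))) {
    stop("'X'/'*' residues cannot be back-translated", call. = FALSE)
  }
  nt_seq(aa$id, paste(codon_table[aa$chars], collapse = ""))
}

# ---------------------------------------------------------------------------
# Annotation

.build_annotation <- function(seq, region_chars, scheme) {
  # region_chars: named list FR1..FR4 -> character vectors (in order)
  order_regions <- scheme$regions$region
  map <- do.call(rbind, lapply(order_regions, function(rg) {
    chars <- region_chars[[rg]]
    n <- length(chars)
    if (n == 0L) return(NULL)
    span <- .region_span(scheme, rg)
    labels <- if (.is_cdr(rg)) {
      imgt_cdr_labels(rg, n, scheme)
    } else {
      if (n != length(span)) {
        stop("framework region ", rg, " has length ", n,
             " but the IMGT span is ", length(span), call. = FALSE)
      }
      as.character(span)
    }
    data.frame(region = rg, imgt = labels, residue = chars,
               stringsAsFactors = FALSE)
  }))
  map$index <- seq_len(nrow(map))
  regs <- lapply(order_regions, function(rg) {
    span <- .region_span(scheme, rg)
    chars <- region_chars[[rg]]
    list(region = rg, sequence = paste(chars, collapse = ""),
         length = length(chars),
         imgt_start = span[1L], imgt_end = span[length(span)])
  })
  names(regs) <- order_regions
  structure(list(
    sequence = seq,
    position_map = map[, c("index", "imgt", "region", "residue")],
    regions = regs,
    cdr3_length = length(region_chars[["CDR3"]]),
    scheme = scheme
  ), class = "annotated_nanobody")
}

#' Annotate a nanobody by known region lengths
#'
#' Bootstrap annotation for sequences whose CDR lengths are known a priori
#' (for example a library scaffold). Framework regions are assumed to be at
#' full IMGT span length; CDR positions follow [imgt_cdr_labels()].
#'
#' @param seq an [aa_seq()].
#' @param cdr_lengths numeric vector `c(cdr1 =, cdr2 =, cdr3 =)`.
#' @param scheme an [imgt_scheme()].
#' @return an `annotated_nanobody`.
#' @export
annotate_by_lengths <- function(seq, cdr_lengths, scheme = imgt_scheme()) {
  if (!inherits(seq, "aa_seq")) seq <- aa_seq("seq", seq)
  cdr_lengths <- as.integer(cdr_lengths[c("cdr1", "cdr2", "cdr3")])
  fr_len <- vapply(c("FR1", "FR2", "FR3", "FR4"),
                   function(r) length(.region_span(scheme, r)), integer(1))
  lens <- c(fr_len["FR1"], cdr_lengths[1L], fr_len["FR2"], cdr_lengths[2L],
            fr_len["FR3"], cdr_lengths[3L], fr_len["FR4"])
  if (sum(lens) != length(seq$chars)) {
    stop("sequence length ", length(seq$chars),
         " does not match region lengths summing to ", sum(lens),
         call. = FALSE)
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  rnames <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  region_chars <- Map(function(s, e) seq$chars[seq.int(s, e)], starts, ends)
  names(region_chars) <- rnames
  .build_annotation(seq, region_chars, scheme)
}

#' Annotate nanobody regions by alignment to a numbered anchor
#'
#' Regions are transferred from a framework reference of known IMGT numbering
#' through a global alignment. Framework regions must align at full span
#' length and above a minimum identity; CDR loops take their own length, with
#' IMGT positions assigned symmetrically from the loop apex
#' ([imgt_cdr_labels()]).
#'
#' @param seq sequence to annotate ([aa_seq()] or `annotated_nanobody`).
#' @param frame_anchor an `annotated_nanobody` of known numbering.
#' @param scheme an [imgt_scheme()].
#' @param min_fr_identity minimum per-framework-region alignment identity.
#' @return an `annotated_nanobody`.
#' @export
annotate_regions <- function(seq, frame_anchor, scheme = imgt_scheme(),
                             min_fr_identity = 0.7) {
  if (inherits(seq, "annotated_nanobody")) seq <- seq$sequence
  if (!inherits(seq, "aa_seq")) seq <- aa_seq("seq", seq)
  if (!inherits(frame_anchor, "annotated_nanobody")) {
    stop("frame_anchor must be an annotated_nanobody (see annotate_by_lengths)",
         call. = FALSE)
  }
  aln <- global_align(seq, frame_anchor)
  anchor_region <- frame_anchor$position_map$region

  # per-column indices into seq / anchor
  si <- cumsum(aln$a != "-"); si[aln$a == "-"] <- NA
  ai <- cumsum(aln$b != "-"); ai[aln$b == "-"] <- NA
  col_region <- ifelse(is.na(ai), NA, anchor_region[ai])
  # insertions: join the following CDR if sandwiched before one, else the
  # preceding region
  for (k in which(is.na(col_region))) {
    prev <- if (k > 1L) col_region[k - 1L] else NA
    rest <- if (k < length(col_region)) col_region[(k + 1L):length(col_region)] else character(0)
    w <- which(!is.na(rest))
    nxt <- if (length(w) > 0L) rest[w[1L]] else NA
    col_region[k] <- if (!is.na(nxt) && .is_cdr(nxt)) nxt
                     else if (!is.na(prev)) prev else nxt
  }

  fr_names <- c("FR1", "FR2", "FR3", "FR4")
  fr_id <- vapply(fr_names, function(rg) {
    cols <- which(col_region == rg & !is.na(ai))
    if (length(cols) == 0L) return(0)
    sum(aln$a[cols] == aln$b[cols] & aln$a[cols] != "-") / length(cols)
  }, numeric(1))
  if (any(fr_id < min_fr_identity)) {
    worst <- fr_names[which.min(fr_id)]
    stop(sprintf(
      "annotation failure: framework identity below %.2f (worst region %s at %.2f)",
      min_fr_identity, worst, min(fr_id)), call. = FALSE)
  }

  rnames <- scheme$regions$region
  region_chars <- lapply(rnames, function(rg) {
    cols <- which(col_region == rg & !is.na(si))
    aln$a[cols]
  })
  names(region_chars) <- rnames
  for (rg in fr_names) {
    span_len <- length(.region_span(scheme, rg))
    if (length(region_chars[[rg]]) != span_len) {
      stop(sprintf(
        "annotation failure: framework region %s aligned at length %d (span %d)",
        rg, length(region_chars[[rg]]), span_len), call. = FALSE)
    }
  }
  .build_annotation(seq, region_chars, scheme)
}

#' @export
print.annotated_nanobody <- function(x, ...) {
  cat(sprintf("<annotated_nanobody> %s (%d aa, CDR3 %d aa)\n",
              x$sequence$id, length(x$sequence$chars), x$cdr3_length))
  for (rg in x$regions) {
    cat(sprintf("  %-4s %3d-%3d (%2d aa) %s\n", rg$region, rg$imgt_start,
                rg$imgt_end, rg$length, rg$sequence))
  }
  invisible(x)
}

#' Residue at an IMGT position
#'
#' @param an an `annotated_nanobody`.
#' @param position IMGT position label (number or string such as `"111.1"`).
#' @return single residue, or `NA` if the position is not occupied.
#' @export
residue_at <- function(an, position) {
  stopifnot(inherits(an, "annotated_nanobody"))
  hit <- match(as.character(position), an$position_map$imgt)
  if (is.na(hit)) NA_character_ else an$position_map$residue[hit]
}

#' Annotation report table
#'
#' @param an an `annotated_nanobody`.
#' @return data frame with columns `id`, `region`, `imgt_start`, `imgt_end`,
#'   `length`, `sequence`.
#' @export
annotation_table <- function(an) {
  stopifnot(inherits(an, "annotated_nanobody"))
  do.call(rbind, lapply(an$regions, function(rg) {
    data.frame(id = an$sequence$id, region = rg$region,
               imgt_start = rg$imgt_start, imgt_end = rg$imgt_end,
               length = rg$length, sequence = rg$sequence,
               stringsAsFactors = FALSE)
  }))
}

# ---------------------------------------------------------------------------
# FASTA I/O (Biostrings-backed)

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file.
#' @return list of [aa_seq()] objects.
#' @export
read_fasta_aa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) aa_seq(ids[i], as.character(set[[i]])))
  names(out) <- ids
  out
}

#' Read nucleotide sequences from FASTA
#'
#' @param path FASTA file.
#' @param degenerate_ok allow IUPAC ambiguity codes.
#' @return list of [nt_seq()] objects.
#' @export
read_fasta_nt <- function(path, degenerate_ok = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    nt_seq(ids[i], as.character(set[[i]]), degenerate_ok = degenerate_ok)
  })
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a single sequence or list of [aa_seq()] / [nt_seq()] objects
#'   (a mixture is not allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, c("aa_seq", "nt_seq"))) seqs <- list(seqs)
  strings <- vapply(seqs, as.character, character(1))
  ids <- vapply(seqs, function(s) s$id, character(1))
  set <- if (inherits(seqs[[1L]], "nt_seq")) {
    Biostrings::DNAStringSet(strings)
  } else {
    Biostrings::AAStringSet(strings)
  }
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
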