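# Repertoire curation and positional statistics: dedup clustering, complex
# dataset filtering, frequency profiles, consensus distillation and
# hallmark/CDR3-length association.

#' Nanobody repertoire
#'
#' @param members list of `annotated_nanobody` objects sharing one scheme.
#' @param provenance free-text origin note.
#' @return object of class `repertoire`.
#' @export
repertoire <- function(members, provenance = "") {
  if (length(members) == 0L) stop("empty repertoire", call. = FALSE)
  ok <- vapply(members, inherits, logical(1), "annotated_nanobody")
  if (!all(ok)) stop("all members must be annotated nanobodies", call. = FALSE)
  structure(list(members = members, provenance = provenance),
            class = "repertoire")
}

#' @export
length.repertoire <- function(x) length(x$members)
#' @export
print.repertoire <- function(x, ...) {
  lens <- vapply(x$members, function(m) m$cdr3_length, integer(1))
  cat(sprintf("<repertoire> %d members (CDR3 lengths %s)%s\n",
              length(x$members),
              paste(sort(unique(lens)), collapse = "/"),
              if (nzchar(x$provenance)) paste0(" - ", x$provenance) else ""))
  invisible(x)
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Members are sorted longest-first; each sequence joins the first existing
#' cluster whose representative shares pairwise global-alignment identity
#' strictly greater than `threshold`, otherwise it founds a new cluster.
#'
#' @param rep a [repertoire()].
#' @param threshold identity fraction in `(0, 1]`.
#' @return list with `clusters` (list of integer vectors of original member
#'   indices, representative first), `representatives` (a [repertoire()]) and
#'   `assignment` (cluster id per member).
#' @export
dedup_cluster <- function(rep, threshold = 0.9) {
  stopifnot(inherits(rep, "repertoire"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n <- length(rep$members)
  lens <- vapply(rep$members, function(m) length(m$sequence$chars), integer(1))
  ord <- order(-lens, seq_len(n))      # longest first, stable
  cluster_of <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (ci in seq_along(reps)) {
      idty <- seq_identity(rep$members[[i]], rep$members[[reps[ci]]])
      if (idty > threshold) {
        cluster_of[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      cluster_of[i] <- length(reps)
    }
  }
  clusters <- lapply(seq_along(reps), function(ci) {
    members <- which(cluster_of == ci)
    c(reps[ci], setdiff(members, reps[ci]))
  })
  list(clusters = clusters,
       representatives = repertoire(rep$members[reps],
                                    provenance = rep$provenance),
       assignment = cluster_of)
}

#' Curate a nanobody-antigen complex dataset
#'
#' Applies, in order: CDR3-length filter, resolution filter, identity
#' reduction (greedy [dedup_cluster()] keeping representatives), and a
#' distinct-antigen filter keeping the first record per antigen in input
#' order. Removal counts per filter are returned.
#'
#' @param records data frame with columns `id`, `seq`, `cdr3_len`,
#'   `resolution`, `antigen`.
#' @param allowed_cdr3_lengths CDR3 lengths (aa) retained.
#' @param max_resolution maximum structure resolution in Angstrom.
#' @param identity_threshold identity above which records are redundant.
#' @param distinct_antigens drop later records sharing an antigen.
#' @param frame_anchor optional `annotated_nanobody` used to annotate `seq`
#'   for identity clustering; when `NULL`, identity is computed on raw
#'   sequences.
#' @return list with `records` (survivors, original order), `removed` (named
#'   counts per filter) and `empty` flag.
#' @export
curate_complex_dataset <- function(records,
                                   allowed_cdr3_lengths = c(8L, 11L, 14L),
                                   max_resolution = 3.0,
                                   identity_threshold = 0.9,
                                   distinct_antigens = TRUE,
                                   frame_anchor = NULL) {
  req <- c("id", "seq", "cdr3_len", "resolution", "antigen")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$resolution <= 0)) stop("resolution must be > 0", call. = FALSE)
  removed <- c(length = 0L, resolution = 0L, identity = 0L, antigen = 0L)

  keep <- records$cdr3_len %in% allowed_cdr3_lengths
  removed["length"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$resolution <= max_resolution
  removed["resolution"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  if (nrow(records) > 1L) {
    members <- lapply(seq_len(nrow(records)), function(i) {
      s <- aa_seq(records$id[i], records$seq[i])
      if (is.null(frame_anchor)) {
        # minimal annotation wrapper: identity clustering only needs chars
        structure(list(sequence = s,
                       position_map = data.frame(index = seq_along(s$chars),
                                                 imgt = as.character(seq_along(s$chars)),
                                                 region = "FR1",
                                                 residue = s$chars,
                                                 stringsAsFactors = FALSE),
                       regions = list(), cdr3_length = records$cdr3_len[i],
                       scheme = NULL),
                  class = "annotated_nanobody")
      } else {
        annotate_regions(s, frame_anchor)
      }
    })
    dd <- dedup_cluster(repertoire(members), threshold = identity_threshold)
    rep_idx <- sort(vapply(dd$clusters, `[`, integer(1), 1L))
    removed["identity"] <- nrow(records) - length(rep_idx)
    records <- records[rep_idx, , drop = FALSE]
  }

  if (distinct_antigens && nrow(records) > 0L) {
    keep <- !duplicated(records$antigen)
    removed["antigen"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  list(records = records, removed = removed, empty = nrow(records) == 0L)
}

#' Per-position amino-acid frequency profile
#'
#' Empirical residue frequencies at every occupied IMGT position of a
#' repertoire. Gaps never enter the denominator: a member simply contributes
#' nothing at positions its loops do not occupy.
#'
#' @param rep a [repertoire()].
#' @return object of class `positional_profile`: `freq` (positions x 20
#'   matrix, rows summing to 1, `NA` rows where support is zero), `support`
#'   (sequences contributing per position), `positions`.
#' @export
positional_profile <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  maps <- lapply(rep$members, function(m) m$position_map)
  all_pos <- unique(unlist(lapply(maps, function(m) m$imgt)))
  all_pos <- all_pos[order(.imgt_label_key(all_pos))]
  freq <- matrix(0, nrow = length(all_pos), ncol = length(AA_STANDARD),
                 dimnames = list(all_pos, AA_STANDARD))
  support <- setNames(integer(length(all_pos)), all_pos)
  for (m in maps) {
    keep <- m$residue %in% AA_STANDARD
    pos <- m$imgt[keep]; res <- m$residue[keep]
    idx <- cbind(match(pos, all_pos), match(res, AA_STANDARD))
    freq[idx] <- freq[idx] + 1
    support[pos] <- support[pos] + 1L
  }
  defined <- support > 0L
  freq[defined, ] <- freq[defined, , drop = FALSE] / support[defined]
  freq[!defined, ] <- NA_real_
  structure(list(freq = freq, support = support, positions = all_pos,
                 n_members = length(rep$members)),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> %d positions over %d sequences\n",
              length(x$positions), x$n_members))
  invisible(x)
}

#' Distill a consensus from a positional profile
#'
#' Retains positions whose modal residue reaches a minimum conservation.
#' Frequency ties are broken alphabetically and flagged; undefined positions
#' (zero support) are skipped with a warning.
#'
#' @param profile a [positional_profile()].
#' @param min_conservation minimum modal frequency to retain a position.
#' @return object of class `consensus_profile`: data frame with columns
#'   `position`, `residue`, `conservation`, `tie`.
#' @export
distill_consensus <- function(profile, min_conservation = 0.8) {
  stopifnot(inherits(profile, "positional_profile"))
  undef <- profile$support == 0L
  if (any(undef)) {
    warning(sum(undef), " position(s) with zero support skipped")
  }
  rows <- lapply(profile$positions[!undef], function(p) {
    f <- profile$freq[p, ]
    top <- max(f)
    modal <- names(f)[f == top]          # alphabetical order of AA_STANDARD
    data.frame(position = p, residue = modal[1L], conservation = top,
               tie = length(modal) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$conservation >= min_conservation, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Hallmark residue usage split by CDR3 length
#'
#' Partitions a repertoire at a CDR3 length threshold and tabulates residue
#' frequencies at each FR2 hallmark position per partition, in a
#' sequence-logo-ready matrix form (rows = hallmark positions, columns = 20
#' residues, rows summing to 1).
#'
#' @param rep a [repertoire()].
#' @param split_length partition boundary: CDR3 length `<= split_length`
#'   versus `>` (default 14).
#' @param scheme an [imgt_scheme()] supplying the hallmark positions.
#' @return list of class `hallmark_association`: `split_length`, and per
#'   partition (`short`, `long`) the member count `n`, the frequency matrix
#'   `freq`, and a `defined` flag (FALSE for an empty partition).
#' @export
hallmark_cdr3_association <- function(rep, split_length = 14L,
                                      scheme = imgt_scheme()) {
  stopifnot(inherits(rep, "repertoire"))
  if (split_length <= 0) stop("split_length must be positive", call. = FALSE)
  hall <- as.character(scheme$hallmarks)
  lens <- vapply(rep$members, function(m) m$cdr3_length, integer(1))
  part <- list(short = which(lens <= split_length),
               long = which(lens > split_length))
  tab_one <- function(idx) {
    if (length(idx) == 0L) {
      return(list(n = 0L, freq = NULL, defined = FALSE))
    }
    freq <- matrix(0, nrow = length(hall), ncol = length(AA_STANDARD),
                   dimnames = list(hall, AA_STANDARD))
    support <- setNames(integer(length(hall)), hall)
    for (m in rep$members[idx]) {
      for (p in hall) {
        r <- residue_at(m, p)
        if (!is.na(r) && r %in% AA_STANDARD) {
          freq[p, r] <- freq[p, r] + 1
          support[p] <- support[p] + 1L
        }
      }
    }
    ok <- support > 0L
    freq[ok, ] <- freq[ok, , drop = FALSE] / support[ok]
    freq[!ok, ] <- NA_real_
    list(n = length(idx), freq = freq, defined = TRUE)
  }
  structure(list(split_length = split_length,
                 short = tab_one(part$short),
                 long = tab_one(part$long),
                 partition_sizes = vapply(part, length, integer(1))),
            class = "hallmark_association")
}

#' @export
print.hallmark_association <- function(x, ...) {
  cat(sprintf("<hallmark_association> split at CDR3 length %d: %d short / %d long\n",
              x$split_length, x$short$n, x$long$n))
  invisible(x)
}

#' Write a positional profile (or any matrix-backed table) as TSV
#'
#' @param x a [positional_profile()], [hallmark_association()] partition
#'   matrix, or plain matrix/data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  m <- if (inherits(x, "positional_profile")) {
    cbind(data.frame(position = x$positions, support = unname(x$support)),
          as.data.frame(x$freq, row.names = NULL))
  } else {
    as.data.frame(x)
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
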