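# CDR randomization strategy: degenerate codon expansion, exhaustive codon
# optimization against target amino-acid distributions, diversity specs and
# summaries.

.nf_cache <- new.env(parent = emptyenv())

.iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
}

#' Amino-acid distribution of a degenerate codon
#'
#' Expands an IUPAC triplet uniformly over its codon set and computes the
#' implied amino-acid distribution (excluding stops), the stop fraction and
#' the cysteine fraction under the standard genetic code.
#'
#' @param triplet three-letter IUPAC string, e.g. `"NNK"`.
#' @return object of class `degenerate_codon`: `triplet`, `codon_set`,
#'   `aa_dist` (named, sums to `1 - stop_fraction`), `stop_fraction`,
#'   `cys_fraction`.
#' @export
codon_aa_distribution <- function(triplet) {
  triplet <- toupper(triplet)
  chars <- .as_chars(triplet)
  sets <- .iupac_sets()
  if (length(chars) != 3L || !all(chars %in% names(sets))) {
    stop("invalid IUPAC triplet: ", triplet, call. = FALSE)
  }
  codons <- as.vector(outer(
    as.vector(outer(sets[[chars[1L]]], sets[[chars[2L]]], paste0)),
    sets[[chars[3L]]], paste0))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  p <- table(aa) / length(codons)
  stop_fraction <- if ("*" %in% names(p)) as.numeric(p[["*"]]) else 0
  aa_dist <- p[names(p) != "*"]
  aa_dist <- setNames(as.numeric(aa_dist), names(aa_dist))
  aa_dist <- aa_dist[order(names(aa_dist))]
  structure(list(triplet = paste(chars, collapse = ""), codon_set = codons,
                 aa_dist = aa_dist, stop_fraction = stop_fraction,
                 cys_fraction = if ("C" %in% names(aa_dist)) aa_dist[["C"]] else 0),
            class = "degenerate_codon")
}

#' @export
print.degenerate_codon <- function(x, ...) {
  cat(sprintf("<degenerate_codon> %s: %d codons, stop %.4f, Cys %.4f\n",
              x$triplet, length(x$codon_set), x$stop_fraction, x$cys_fraction))
  invisible(x)
}

# Precomputed search table over all 15^3 = 3375 IUPAC triplets, in
# lexicographic order (the deterministic tie-break of the optimizer).
.codon_search_table <- function() {
  if (!is.null(.nf_cache$search)) return(.nf_cache$search)
  sets <- .iupac_sets()
  codes <- sort(names(sets))
  triplets <- as.vector(t(outer(
    as.vector(t(outer(codes, codes, paste0))), codes, paste0)))
  triplets <- sort(triplets)
  cats <- c(AA_STANDARD, "*")
  P <- matrix(0, nrow = length(triplets), ncol = length(cats),
              dimnames = list(triplets, cats))
  gc_aa <- Biostrings::GENETIC_CODE
  for (i in seq_along(triplets)) {
    ch <- strsplit(triplets[i], "", fixed = TRUE)[[1L]]
    codons <- as.vector(outer(
      as.vector(outer(sets[[ch[1L]]], sets[[ch[2L]]], paste0)),
      sets[[ch[3L]]], paste0))
    tab <- table(unname(gc_aa[codons])) / length(codons)
    P[i, names(tab)] <- as.numeric(tab)
  }
  .nf_cache$search <- list(triplets = triplets, P = P)
  .nf_cache$search
}

.full_target <- function(target) {
  target <- target[!is.na(target)]
  if (abs(sum(target) - 1) > 1e-6) {
    stop("target distribution must sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(target), AA_STANDARD)
  if (length(bad) > 0L) stop("unknown residues in target: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  full <- setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
  full[names(target)] <- target
  full
}

#' Optimize a degenerate codon against a target distribution
#'
#' Exhaustive search over all 3375 IUPAC triplets minimizing total-variation
#' distance to the target amino-acid distribution (stop codons counted as an
#' extra category with zero target mass) plus soft penalties on the stop and
#' cysteine fractions. Ties are broken by lexicographic triplet order. An
#' infinite penalty excludes the corresponding triplets outright.
#'
#' @param target named amino-acid distribution summing to 1.
#' @param stop_penalty weight on the stop fraction (default 10).
#' @param cys_penalty weight on the cysteine fraction (default 5).
#' @return object of class `codon_choice`: `codon` (a
#'   [codon_aa_distribution()] result), `divergence` (TV distance),
#'   `penalty_terms`, `objective`.
#' @export
optimize_degenerate_codon <- function(target, stop_penalty = 10,
                                      cys_penalty = 5) {
  full <- .full_target(target)
  tab <- .codon_search_table()
  P <- tab$P
  tv <- 0.5 * (rowSums(abs(sweep(P[, AA_STANDARD], 2L, full))) + P[, "*"])
  pen_stop <- ifelse(P[, "*"] > 0, stop_penalty * P[, "*"], 0)
  pen_cys <- ifelse(P[, "C"] > 0, cys_penalty * P[, "C"], 0)
  obj <- tv + pen_stop + pen_cys
  best <- which.min(obj)                  # first minimum = lexicographic tie-break
  codon <- codon_aa_distribution(tab$triplets[best])
  structure(list(codon = codon, divergence = unname(tv[best]),
                 penalty_terms = c(stop = unname(pen_stop[best]),
                                   cys = unname(pen_cys[best])),
                 objective = unname(obj[best])),
            class = "codon_choice")
}

#' @export
print.codon_choice <- function(x, ...) {
  cat(sprintf("<codon_choice> %s (TV %.4f, stop %.4f, Cys %.4f)\n",
              x$codon$triplet, x$divergence, x$codon$stop_fraction,
              x$codon$cys_fraction))
  invisible(x)
}

.strip_cys <- function(p) {
  # remove cysteine mass and redistribute proportionally
  p["C"] <- 0
  s <- sum(p)
  if (s <= 0) {
    # degenerate column (all-Cys): fall back to uniform over the other 19
    p[setdiff(names(p), "C")] <- 1 / (length(p) - 1L)
    return(p)
  }
  p / s
}

#' Build a per-position CDR randomization plan
#'
#' CDR1 and CDR2 use a constant length of 8 amino acids; CDR3 carries one
#' position set per length class (default 8, 11 and 14 aa). Anchor positions
#' ("retained or slightly randomized" hydrophobic-core and flexibility
#' residues) receive `anchor_floor` mass on the anchor residue plus the
#' renormalized natural distribution on the rest; all other positions mimic
#' the natural profile. Cysteine mass is always removed and redistributed
#' proportionally.
#'
#' @param profile a [positional_profile()] covering the CDR positions.
#' @param anchors named character vector of anchor residues keyed by IMGT
#'   position (default: the scheme's conserved anchor set).
#' @param lengths CDR3 length classes.
#' @param anchor_floor minimum target mass on an anchor residue.
#' @param length_weights distribution over CDR3 length classes (default
#'   uniform).
#' @param fixed named character vector of positions to hold at a point mass.
#' @param scheme an [imgt_scheme()].
#' @return object of class `diversity_spec`: `cdr1`, `cdr2` (lists of 8
#'   position specs), `cdr3` (list per length class), `length_weights`.
#' @export
build_diversity_spec <- function(profile, anchors = imgt_scheme()$anchors,
                                 lengths = c(8L, 11L, 14L),
                                 anchor_floor = 0.5, length_weights = NULL,
                                 fixed = character(0),
                                 scheme = imgt_scheme()) {
  stopifnot(inherits(profile, "positional_profile"))
  if (anchor_floor < 0 || anchor_floor > 1) {
    stop("anchor_floor must be in [0, 1]", call. = FALSE)
  }
  if (is.null(length_weights)) {
    length_weights <- setNames(rep(1 / length(lengths), length(lengths)),
                               as.character(lengths))
  }
  length_weights <- length_weights[as.character(lengths)]
  if (abs(sum(length_weights) - 1) > 1e-9) {
    stop("length_weights must sum to 1", call. = FALSE)
  }

  natural_at <- function(pos) {
    if (pos %in% profile$positions && profile$support[pos] > 0L) {
      .strip_cys(profile$freq[pos, ])
    } else {
      warning("position ", pos, " has no profile support; using uniform target")
      p <- setNames(rep(1 / 19, length(AA_STANDARD)), AA_STANDARD)
      p["C"] <- 0
      p
    }
  }
  spec_at <- function(pos) {
    if (pos %in% names(fixed)) {
      res <- fixed[[pos]]
      tgt <- setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
      tgt[res] <- 1
      return(list(imgt = pos, mode = "fixed", anchor = res, target = tgt))
    }
    nat <- natural_at(pos)
    if (pos %in% names(anchors)) {
      res <- anchors[[pos]]
      if (!(res %in% names(nat)) || nat[res] == 0) {
        warning("anchor residue ", res, " absent from profile support at ",
                pos, "; proceeding")
      }
      tgt <- (1 - anchor_floor) * nat
      tgt[res] <- tgt[res] + anchor_floor
      return(list(imgt = pos, mode = "anchored", anchor = res, target = tgt))
    }
    list(imgt = pos, mode = "natural", anchor = NA_character_, target = nat)
  }

  cdr1 <- lapply(imgt_cdr_labels("CDR1", 8L, scheme), spec_at)
  cdr2 <- lapply(imgt_cdr_labels("CDR2", 8L, scheme), spec_at)
  cdr3 <- lapply(lengths, function(L) {
    lapply(imgt_cdr_labels("CDR3", L, scheme), spec_at)
  })
  names(cdr3) <- as.character(lengths)
  structure(list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
                 length_weights = length_weights),
            class = "diversity_spec")
}

#' @export
print.diversity_spec <- function(x, ...) {
  cat(sprintf("<diversity_spec> CDR1/CDR2: 8 + 8 positions; CDR3 classes: %s\n",
              paste(names(x$cdr3), collapse = "/")))
  invisible(x)
}

.spec_positions <- function(spec, length_class = NULL) {
  # flat list of position specs; CDR3 restricted to one class when given
  out <- c(lapply(spec$cdr1, function(s) c(s, region = "CDR1", class = NA)),
           lapply(spec$cdr2, function(s) c(s, region = "CDR2", class = NA)))
  classes <- if (is.null(length_class)) names(spec$cdr3) else as.character(length_class)
  for (cl in classes) {
    out <- c(out, lapply(spec$cdr3[[cl]],
                         function(s) c(s, region = "CDR3", class = cl)))
  }
  out
}

#' Choose degenerate codons for a whole diversity spec
#'
#' Runs [optimize_degenerate_codon()] once per position (CDR3 positions once
#' per length class).
#'
#' @param spec a [build_diversity_spec()] result.
#' @param stop_penalty,cys_penalty passed to the optimizer.
#' @return data frame of class `codon_plan`: `region`, `length_class`,
#'   `imgt`, `mode`, `triplet`, `divergence`, `stop_fraction`,
#'   `cys_fraction`, `n_aa` (distinct residues reachable).
#' @export
plan_codons <- function(spec, stop_penalty = 10, cys_penalty = 5) {
  stopifnot(inherits(spec, "diversity_spec"))
  flat <- .spec_positions(spec)
  memo <- new.env(parent = emptyenv())
  rows <- lapply(flat, function(ps) {
    key <- paste0(ps$region, ":", ps$imgt)
    choice <- if (!is.null(memo[[key]])) memo[[key]] else {
      ch <- optimize_degenerate_codon(ps$target[ps$target > 0],
                                      stop_penalty, cys_penalty)
      memo[[key]] <- ch
      ch
    }
    data.frame(region = ps$region, length_class = ps$class, imgt = ps$imgt,
               mode = ps$mode, triplet = choice$codon$triplet,
               divergence = choice$divergence,
               stop_fraction = choice$codon$stop_fraction,
               cys_fraction = choice$codon$cys_fraction,
               n_aa = sum(choice$codon$aa_dist > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("codon_plan", "data.frame")
  out
}

#' Summarise a diversity spec and its codon plan
#'
#' Per length class: the expected stop-containing-clone fraction
#' `1 - prod(1 - stop_i)`, the expected cysteine-containing fraction, and the
#' theoretical sequence-space size `prod(n_aa_i)`; plus the overall expected
#' stop/Cys fractions weighted by the CDR3 length distribution and the
#' per-position divergence table.
#'
#' @param spec a [build_diversity_spec()] result.
#' @param plan the matching [plan_codons()] data frame.
#' @return list of class `spec_summary`.
#' @export
spec_summary <- function(spec, plan) {
  stopifnot(inherits(spec, "diversity_spec"), inherits(plan, "codon_plan"))
  shared <- plan[plan$region != "CDR3", , drop = FALSE]
  per_class <- lapply(names(spec$cdr3), function(cl) {
    rows <- rbind(shared,
                  plan[plan$region == "CDR3" & plan$length_class == cl, ,
                       drop = FALSE])
    list(length_class = cl,
         n_positions = nrow(rows),
         stop_clone_fraction = 1 - prod(1 - rows$stop_fraction),
         cys_clone_fraction = 1 - prod(1 - rows$cys_fraction),
         theoretical_size = prod(rows$n_aa))
  })
  names(per_class) <- names(spec$cdr3)
  w <- spec$length_weights
  structure(list(
    per_class = per_class,
    expected_stop_clone_fraction = sum(w * vapply(per_class, `[[`, numeric(1),
                                                  "stop_clone_fraction")),
    expected_cys_clone_fraction = sum(w * vapply(per_class, `[[`, numeric(1),
                                                 "cys_clone_fraction")),
    divergence_table = plan[, c("region", "length_class", "imgt", "triplet",
                                "divergence", "stop_fraction", "cys_fraction")]
  ), class = "spec_summary")
}

#' @export
print.spec_summary <- function(x, ...) {
  cat("<spec_summary>\n")
  for (pc in x$per_class) {
    cat(sprintf("  CDR3 %s aa: %d positions, stop-clone %.4f, Cys-clone %.4f, size %.3g\n",
                pc$length_class, pc$n_positions, pc$stop_clone_fraction,
                pc$cys_clone_fraction, pc$theoretical_size))
  }
  cat(sprintf("  overall expected stop-clone fraction: %.4f\n",
              x$expected_stop_clone_fraction))
  invisible(x)
}

#' Write a codon plan as TSV
#'
#' @param plan a [plan_codons()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_plan_tsv <- function(plan, path) {
  utils::write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
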