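# Scaffold humanization: hallmark substitutions toward a germline, consensus
# framework substitutions, humanness scoring and design application.

#' Germline reference
#'
#' @param id germline gene name (for example an IGHV3 family member).
#' @param annotated an `annotated_nanobody` whose framework covers FR1-FR3 at
#'   least.
#' @return object of class `germline_reference`.
#' @export
germline_reference <- function(id, annotated) {
  stopifnot(inherits(annotated, "annotated_nanobody"))
  for (rg in c("FR1", "FR2", "FR3")) {
    if (is.null(annotated$regions[[rg]]) || annotated$regions[[rg]]$length == 0L) {
      stop("germline annotation must cover ", rg, call. = FALSE)
    }
  }
  structure(list(id = id, annotated = annotated), class = "germline_reference")
}

.empty_subs <- function() {
  data.frame(position = character(0), from = character(0), to = character(0),
             source = character(0), conservation = numeric(0),
             caution = logical(0), note = character(0),
             stringsAsFactors = FALSE)
}

#' Propose hallmark humanization substitutions
#'
#' For each hallmark position where the template differs from the germline,
#' emits a substitution to the germline residue. Substitutions at IMGT
#' position 50 toward leucine carry a caution flag: R50 belongs to the highly
#' conserved consensus framework and its loss is associated with aggregation
#' at high concentration, so R50L buys thermostability at a formulation cost.
#'
#' @param template an `annotated_nanobody`.
#' @param germline a [germline_reference()].
#' @param hallmarks IMGT hallmark positions to consider (defaults to the
#'   scheme's four FR2 hallmarks).
#' @return substitution data frame (`position`, `from`, `to`, `source`,
#'   `conservation`, `caution`, `note`).
#' @export
propose_hallmark_humanization <- function(template, germline,
                                          hallmarks = imgt_scheme()$hallmarks) {
  stopifnot(inherits(template, "annotated_nanobody"),
            inherits(germline, "germline_reference"))
  rows <- lapply(as.character(hallmarks), function(p) {
    t <- residue_at(template, p)
    g <- residue_at(germline$annotated, p)
    if (is.na(t) || is.na(g)) {
      stop("hallmark position ", p, " unresolvable in template or germline",
           call. = FALSE)
    }
    if (t == g) return(NULL)
    caution <- (p == "50" && g == "L")
    data.frame(position = p, from = t, to = g, source = "hallmark",
               conservation = NA_real_, caution = caution,
               note = if (caution)
                 "R50 is consensus-framework conserved; R50L risks aggregation at high concentration"
               else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .empty_subs() else out
}

#' Propose consensus framework substitutions
#'
#' Among framework positions where the template differs from the consensus
#' modal residue, candidates are ranked by conservation (descending), ties
#' broken by preferring positions where the consensus residue also matches
#' the germline, then by ascending IMGT position; the top `k` are returned.
#'
#' @param template an `annotated_nanobody`.
#' @param consensus a [distill_consensus()] result.
#' @param germline a [germline_reference()].
#' @param k number of substitutions requested.
#' @return substitution data frame; if fewer than `k` candidates exist, all
#'   are returned with attribute `short = TRUE`.
#' @export
propose_consensus_substitutions <- function(template, consensus, germline,
                                            k = 3L) {
  stopifnot(inherits(template, "annotated_nanobody"),
            inherits(consensus, "consensus_profile"),
            inherits(germline, "germline_reference"))
  if (k == 0L) return(.empty_subs())
  fr_pos <- template$position_map[
    !.is_cdr(template$position_map$region), "imgt"]
  cand <- consensus[consensus$position %in% fr_pos, , drop = FALSE]
  if (nrow(cand) > 0L) {
    t_res <- vapply(cand$position, function(p) residue_at(template, p),
                    character(1))
    g_res <- vapply(cand$position, function(p) residue_at(germline$annotated, p),
                    character(1))
    differs <- !is.na(t_res) & t_res != cand$residue
    cand <- cand[differs, , drop = FALSE]
    t_res <- t_res[differs]; g_res <- g_res[differs]
  }
  if (nrow(cand) == 0L) return(.empty_subs())
  germ_agree <- !is.na(g_res) & g_res == cand$residue
  ord <- order(-cand$conservation, !germ_agree,
               .imgt_label_key(cand$position))
  take <- head(ord, k)
  out <- data.frame(position = cand$position[take], from = t_res[take],
                    to = cand$residue[take], source = "consensus",
                    conservation = cand$conservation[take],
                    caution = FALSE, note = "", stringsAsFactors = FALSE)
  attr(out, "short") <- nrow(out) < k
  out
}

#' Humanness score: identity to a human germline
#'
#' Global-alignment identity between the template and germline over the
#' selected regions. Framework-only is the default: CDRs are diversified by
#' the library anyway, and immunogenicity driven by framework divergence is
#' what humanization targets.
#'
#' @param seq an `annotated_nanobody`.
#' @param germline a [germline_reference()].
#' @param regions `"framework"` or `"full"`.
#' @return identity fraction in `[0, 1]`.
#' @export
humanness_score <- function(seq, germline, regions = c("framework", "full")) {
  stopifnot(inherits(seq, "annotated_nanobody"),
            inherits(germline, "germline_reference"))
  regions <- match.arg(regions)
  if (regions == "full") {
    return(seq_identity(seq, germline$annotated))
  }
  fr <- c("FR1", "FR2", "FR3", "FR4")
  shared <- fr[vapply(fr, function(rg) {
    !is.null(seq$regions[[rg]]) && seq$regions[[rg]]$length > 0L &&
      !is.null(germline$annotated$regions[[rg]]) &&
      germline$annotated$regions[[rg]]$length > 0L
  }, logical(1))]
  a <- paste(vapply(shared, function(rg) seq$regions[[rg]]$sequence,
                    character(1)), collapse = "")
  b <- paste(vapply(shared, function(rg) germline$annotated$regions[[rg]]$sequence,
                    character(1)), collapse = "")
  seq_identity(a, b)
}

#' Apply a substitution set to a template
#'
#' Emits the scaffold sequence, verifies that it differs from the template at
#' exactly `nrow(substitutions)` positions, and reports the humanness score
#' before and after when a germline is supplied. Substitutions must target
#' framework positions, must not conflict, and must match the template
#' residue.
#'
#' @param template an `annotated_nanobody`.
#' @param substitutions substitution data frame as produced by
#'   [propose_hallmark_humanization()] / [propose_consensus_substitutions()]
#'   (rows may be concatenated with `rbind`).
#' @param germline optional [germline_reference()] for humanness reporting.
#' @return object of class `scaffold_design`: `template`, `substitutions`,
#'   `scaffold` (annotated), `n_changed`, `humanness_before`,
#'   `humanness_after`.
#' @export
apply_design <- function(template, substitutions, germline = NULL) {
  stopifnot(inherits(template, "annotated_nanobody"))
  map <- template$position_map
  if (nrow(substitutions) > 0L) {
    if (anyDuplicated(substitutions$position)) {
      stop("conflicting substitutions at position(s): ",
           paste(unique(substitutions$position[duplicated(substitutions$position)]),
                 collapse = ", "), call. = FALSE)
    }
    hit <- match(as.character(substitutions$position), map$imgt)
    if (anyNA(hit)) {
      stop("substitution position(s) absent from template: ",
           paste(substitutions$position[is.na(hit)], collapse = ", "),
           call. = FALSE)
    }
    in_cdr <- .is_cdr(map$region[hit])
    if (any(in_cdr)) {
      stop("substitution at CDR position(s) rejected (framework-only): ",
           paste(substitutions$position[in_cdr], collapse = ", "),
           call. = FALSE)
    }
    mism <- map$residue[hit] != substitutions$from
    if (any(mism)) {
      stop("'from' residue does not match template at position(s): ",
           paste(substitutions$position[mism], collapse = ", "), call. = FALSE)
    }
  }
  chars <- template$sequence$chars
  if (nrow(substitutions) > 0L) {
    chars[map$index[hit]] <- substitutions$to
  }
  scaffold_seq <- aa_seq(paste0(template$sequence$id, "_scaffold"), chars)
  cdrl <- c(cdr1 = template$regions$CDR1$length,
            cdr2 = template$regions$CDR2$length,
            cdr3 = template$regions$CDR3$length)
  scaffold <- annotate_by_lengths(scaffold_seq, cdrl, template$scheme)
  n_changed <- sum(chars != template$sequence$chars)
  if (n_changed != nrow(substitutions)) {
    stop("scaffold differs from template at ", n_changed,
         " positions, expected ", nrow(substitutions), call. = FALSE)
  }
  hb <- ha <- NA_real_
  if (!is.null(germline)) {
    hb <- humanness_score(template, germline)
    ha <- humanness_score(scaffold, germline)
  }
  structure(list(template = template, substitutions = substitutions,
                 scaffold = scaffold, n_changed = n_changed,
                 humanness_before = hb, humanness_after = ha),
            class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf("<scaffold_design> %d substitution(s)\n", x$n_changed))
  if (x$n_changed > 0L) {
    with(x$substitutions, cat(paste0("  ", from, position, to, " [", source,
                                     ifelse(caution, ", caution", ""), "]",
                                     collapse = "\n"), "\n"))
  }
  if (!is.na(x$humanness_before)) {
    cat(sprintf("  framework humanness: %.3f -> %.3f\n",
                x$humanness_before, x$humanness_after))
  }
  invisible(x)
}

#' Write a scaffold design report as TSV
#'
#' @param design a [apply_design()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  stopifnot(inherits(design, "scaffold_design"))
  utils::write.table(design$substitutions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
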