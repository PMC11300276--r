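# Primer/fragment planning, in-silico library sampling, synthesis-error
# simulation, clone-defect classification and QC statistics.

SFI_SITE <- "GGCCCAGCCGGCC"   # matches the SfiI recognition motif GGCCNNNNNGGCC
NOT_SITE <- "GCGGCCGC"        # NotI

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.plan_codon_map <- function(plan, length_class) {
  shared <- plan[plan$region %in% c("CDR1", "CDR2"), , drop = FALSE]
  cdr3 <- plan[plan$region == "CDR3" & plan$length_class == as.character(length_class), ,
               drop = FALSE]
  rbind(shared, cdr3)
}

#' Design the primer/fragment plan for a library
#'
#' The scaffold is back-translated region by region; CDR codons are replaced
#' by the degenerate triplets of the codon plan. The coding sequence is split
#' in the middle of FR3 into an upstream fragment carrying CDR1 and CDR2
#' (amplified by the F-2/R-2 degenerate primer pair) and a downstream
#' fragment carrying CDR3 and FR4 (F-3/R-3), one downstream variant per CDR3
#' length class. The two fragments share a non-degenerate overlap for overlap
#' extension; the F-1/R-1 pair adds an upstream SfiI and downstream NotI
#' flank.
#'
#' @param scaffold an `annotated_nanobody`.
#' @param plan a [plan_codons()] data frame.
#' @param spec the matching [build_diversity_spec()] result.
#' @param codon_table back-translation table for framework regions.
#' @param overlap_len length of the shared fragment overlap (nt).
#' @param min_overlap minimum admissible overlap.
#' @return object of class `primer_plan`: `fragments` (`F2R2` and per-class
#'   `F3R3`), `overlap`, `flank_sites`, per-class degenerate `products`
#'   (flanked), and bookkeeping for sampling/classification.
#' @export
design_primers <- function(scaffold, plan, spec,
                           codon_table = preferred_codons(),
                           overlap_len = 21L, min_overlap = 15L) {
  stopifnot(inherits(scaffold, "annotated_nanobody"),
            inherits(plan, "codon_plan"), inherits(spec, "diversity_spec"))
  if (overlap_len < min_overlap) {
    stop("overlap (", overlap_len, " nt) shorter than minimum ", min_overlap,
         " at junction FR3", call. = FALSE)
  }
  fr_nt <- lapply(c(FR1 = "FR1", FR2 = "FR2", FR3 = "FR3", FR4 = "FR4"),
                  function(rg) as.character(back_translate(
                    scaffold$regions[[rg]]$sequence, codon_table)))
  trip_of <- function(rows, labels) {
    hit <- match(labels, rows$imgt)
    if (anyNA(hit)) {
      stop("codon plan does not cover position(s): ",
           paste(labels[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    rows$triplet[hit]
  }
  cdr1_trip <- trip_of(plan[plan$region == "CDR1", ],
                       vapply(spec$cdr1, `[[`, character(1), "imgt"))
  cdr2_trip <- trip_of(plan[plan$region == "CDR2", ],
                       vapply(spec$cdr2, `[[`, character(1), "imgt"))
  cdr3_trip <- lapply(names(spec$cdr3), function(cl) {
    rows <- plan[plan$region == "CDR3" & plan$length_class == cl, ]
    trip_of(rows, vapply(spec$cdr3[[cl]], `[[`, character(1), "imgt"))
  })
  names(cdr3_trip) <- names(spec$cdr3)

  upstream <- paste0(fr_nt$FR1, paste(cdr1_trip, collapse = ""), fr_nt$FR2,
                     paste(cdr2_trip, collapse = ""))
  cut <- 3L * (nchar(fr_nt$FR3) %/% 6L)          # codon-aligned mid-FR3 cut
  if (cut < overlap_len) stop("FR3 too short for the requested overlap",
                              call. = FALSE)
  fr3_up <- substr(fr_nt$FR3, 1L, cut)
  fr3_down <- substr(fr_nt$FR3, cut + 1L, nchar(fr_nt$FR3))
  frag_a <- paste0(upstream, fr3_up)
  overlap <- substr(frag_a, nchar(frag_a) - overlap_len + 1L, nchar(frag_a))
  frag_b <- lapply(names(spec$cdr3), function(cl) {
    paste0(overlap, fr3_down, paste(cdr3_trip[[cl]], collapse = ""), fr_nt$FR4)
  })
  names(frag_b) <- names(spec$cdr3)

  cores <- lapply(frag_b, function(fb) {
    paste0(frag_a, substr(fb, overlap_len + 1L, nchar(fb)))
  })
  products <- lapply(cores, function(core) paste0(SFI_SITE, core, NOT_SITE))
  for (cl in names(products)) {
    if (lengths(regmatches(products[[cl]],
                           gregexpr("GGCC.{5}GGCC", products[[cl]]))) != 1L ||
        lengths(regmatches(products[[cl]],
                           gregexpr(NOT_SITE, products[[cl]], fixed = TRUE))) != 1L) {
      stop("flank motif not unique in product for CDR3 length ", cl,
           call. = FALSE)
    }
  }
  structure(list(
    fragments = list(F2R2 = frag_a, F3R3 = frag_b),
    overlap = list(sequence = overlap, length = overlap_len),
    flank_sites = c(sfiI = SFI_SITE, notI = NOT_SITE),
    cores = cores, products = products,
    framework_nt = fr_nt, scaffold = scaffold,
    cdr_triplets = list(cdr1 = cdr1_trip, cdr2 = cdr2_trip, cdr3 = cdr3_trip)
  ), class = "primer_plan")
}

#' @export
print.primer_plan <- function(x, ...) {
  cat(sprintf("<primer_plan> F-2/R-2 fragment %d nt; F-3/R-3 variants: %s; overlap %d nt\n",
              nchar(x$fragments$F2R2),
              paste(names(x$fragments$F3R3), collapse = "/"),
              x$overlap$length))
  invisible(x)
}

#' Assemble the library product by overlap extension in silico
#'
#' Joins the F-2/R-2 fragment to each F-3/R-3 variant through their shared
#' overlap (which must match exactly) and adds the SfiI/NotI flanks.
#'
#' @param plan a [design_primers()] result (fragments may have been edited).
#' @return named list of degenerate [nt_seq()] products, one per CDR3 length
#'   class.
#' @export
assemble_in_silico <- function(plan) {
  stopifnot(inherits(plan, "primer_plan"))
  ov <- plan$overlap$length
  a_tail <- substr(plan$fragments$F2R2,
                   nchar(plan$fragments$F2R2) - ov + 1L,
                   nchar(plan$fragments$F2R2))
  out <- lapply(names(plan$fragments$F3R3), function(cl) {
    fb <- plan$fragments$F3R3[[cl]]
    b_head <- substr(fb, 1L, ov)
    if (a_tail != b_head) {
      mism <- which(strsplit(a_tail, "")[[1L]] != strsplit(b_head, "")[[1L]])[1L]
      stop("overlap mismatch at junction FR3 position ", mism,
           " (CDR3 length ", cl, ")", call. = FALSE)
    }
    core <- paste0(plan$fragments$F2R2, substr(fb, ov + 1L, nchar(fb)))
    nt_seq(paste0("library_", cl), paste0(SFI_SITE, core, NOT_SITE),
           degenerate_ok = TRUE)
  })
  names(out) <- names(plan$fragments$F3R3)
  out
}

#' Sample clones from the designed library
#'
#' Per clone, a CDR3 length class is drawn from the spec's length weights and
#' every degenerate base is expanded uniformly over its codon set, exactly as
#' a degenerate primer synthesis would. Deterministic under a fixed seed.
#'
#' @param plan a [design_primers()] result.
#' @param spec the matching [build_diversity_spec()] result.
#' @param n number of clones.
#' @param seed RNG seed.
#' @param include_nt assemble full nucleotide sequences (disable for large
#'   frequency-only runs).
#' @return data frame of class `clone_set`: `id`, `length_class`, `nt`
#'   (optional), `aa`, `cdr1`, `cdr2`, `cdr3`, `cdr_signature`,
#'   `classification` (`correct` or `stop_codon` at this stage).
#' @export
sample_library <- function(plan, spec, n, seed = 1L, include_nt = TRUE) {
  stopifnot(inherits(plan, "primer_plan"), inherits(spec, "diversity_spec"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  fr_aa <- lapply(c(FR1 = "FR1", FR2 = "FR2", FR3 = "FR3", FR4 = "FR4"),
                  function(rg) plan$scaffold$regions[[rg]]$sequence)
  gc_aa <- Biostrings::GENETIC_CODE
  .with_seed(seed, {
    classes <- sample(names(spec$length_weights), n, replace = TRUE,
                      prob = spec$length_weights)
    chunks <- lapply(names(spec$cdr3), function(cl) {
      idx <- which(classes == cl)
      nc <- length(idx)
      if (nc == 0L) return(NULL)
      triplets <- c(plan$cdr_triplets$cdr1, plan$cdr_triplets$cdr2,
                    plan$cdr_triplets$cdr3[[cl]])
      n1 <- length(plan$cdr_triplets$cdr1)
      n2 <- length(plan$cdr_triplets$cdr2)
      cod <- lapply(triplets, function(tr) {
        set <- codon_aa_distribution(tr)$codon_set
        set[sample.int(length(set), nc, replace = TRUE)]
      })
      aa <- lapply(cod, function(v) unname(gc_aa[v]))
      paste_cols <- function(cols) {
        if (length(cols) == 0L) character(nc) else do.call(paste0, cols)
      }
      cdr1 <- paste_cols(aa[seq_len(n1)])
      cdr2 <- paste_cols(aa[n1 + seq_len(n2)])
      cdr3 <- paste_cols(aa[(n1 + n2 + 1L):length(aa)])
      full_aa <- paste0(fr_aa$FR1, cdr1, fr_aa$FR2, cdr2, fr_aa$FR3, cdr3,
                        fr_aa$FR4)
      nt <- if (include_nt) {
        do.call(paste0, c(list(plan$framework_nt$FR1), cod[seq_len(n1)],
                          list(plan$framework_nt$FR2), cod[n1 + seq_len(n2)],
                          list(plan$framework_nt$FR3),
                          cod[(n1 + n2 + 1L):length(cod)],
                          list(plan$framework_nt$FR4)))
      } else {
        NA_character_
      }
      data.frame(idx = idx, length_class = cl, nt = nt, aa = full_aa,
                 cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, chunks)
    out <- out[order(out$idx), , drop = FALSE]
    out$id <- sprintf("clone_%06d", out$idx)
    out$idx <- NULL
    out$cdr_signature <- paste0(out$cdr1, out$cdr2, out$cdr3)
    out$classification <- ifelse(grepl("*", out$aa, fixed = TRUE),
                                 "stop_codon", "correct")
    rownames(out) <- NULL
    class(out) <- c("clone_set", "data.frame")
    out
  })
}

#' Synthesis/cloning error model
#'
#' Per-clone event probabilities (failed insert, large deletion) and per-base
#' error rates, emulating the defect spectrum observed when sequencing a
#' freshly assembled library: stop codons, single-base loss, frameshifts and
#' large missing regions. Defaults are typical of multi-cycle PCR assembly of
#' degenerate primers.
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base rates.
#' @param large_deletion_rate per-clone probability of a large dropout.
#' @param large_deletion_size inclusive nt size range of large dropouts.
#' @param no_insert_rate per-clone probability of an empty vector.
#' @return list of class `error_model`.
#' @export
error_model <- function(substitution_rate = 1e-3, insertion_rate = 3e-4,
                        deletion_rate = 3e-4, large_deletion_rate = 0.03,
                        large_deletion_size = c(15L, 100L),
                        no_insert_rate = 0.04) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate,
             large_deletion_rate, no_insert_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 large_deletion_rate = large_deletion_rate,
                 large_deletion_size = as.integer(large_deletion_size),
                 no_insert_rate = no_insert_rate),
            class = "error_model")
}

.mutate_one <- function(chars, model) {
  events <- list(n_sub = 0L, n_ins = 0L, n_del = 0L, large_del = FALSE)
  L <- length(chars)
  if (model$large_deletion_rate > 0 &&
      stats::runif(1) < model$large_deletion_rate) {
    size <- sample(seq.int(model$large_deletion_size[1L],
                           min(model$large_deletion_size[2L], L)), 1L)
    start <- sample.int(L - size + 1L, 1L)
    chars <- chars[-seq.int(start, start + size - 1L)]
    events$large_del <- TRUE
    L <- length(chars)
  }
  if (L > 0L && model$substitution_rate > 0) {
    hit <- which(stats::runif(L) < model$substitution_rate)
    for (p in hit) chars[p] <- sample(setdiff(NT_PLAIN, chars[p]), 1L)
    events$n_sub <- length(hit)
  }
  if (L > 0L && model$deletion_rate > 0) {
    hit <- which(stats::runif(L) < model$deletion_rate)
    if (length(hit) > 0L) chars <- chars[-hit]
    events$n_del <- length(hit)
    L <- length(chars)
  }
  if (L > 0L && model$insertion_rate > 0) {
    hit <- which(stats::runif(L) < model$insertion_rate)
    if (length(hit) > 0L) {
      ins <- sample(NT_PLAIN, length(hit), replace = TRUE)
      for (k in rev(seq_along(hit))) {
        chars <- append(chars, ins[k], after = hit[k])
      }
    }
    events$n_ins <- length(hit)
  }
  list(chars = chars, events = events)
}

.truth_label <- function(events, nt, no_insert) {
  if (no_insert) return("no_insert")
  if (events$large_del) return("large_region_missing")
  net <- events$n_ins - events$n_del
  if (net %% 3L != 0L) return("base_shifting")
  if (events$n_ins + events$n_del > 0L) return("base_missing")
  if (nchar(nt) >= 3L) {
    tr <- translate_nt(nt_seq("c", nt))
    if (length(tr$stops) > 0L && min(tr$stops) < nchar(nt) %/% 3L) {
      return("stop_codon")
    }
  }
  "correct"
}

#' Simulate synthesis and cloning errors on sampled clones
#'
#' Applies per-clone no-insert and large-deletion events, then per-base
#' substitutions, deletions and insertions, and records a ground-truth defect
#' label per clone using the same priority rule as [classify_clone()].
#'
#' @param clones a [sample_library()] clone set (with `nt`).
#' @param model an [error_model()].
#' @param seed RNG seed.
#' @return the clone set with mutated `nt`, plus columns `truth`, `n_sub`,
#'   `n_ins`, `n_del`, `large_del`, `no_insert`.
#' @export
simulate_synthesis_errors <- function(clones, model = error_model(),
                                      seed = 1L) {
  stopifnot(inherits(clones, "data.frame"))
  if (any(is.na(clones$nt))) {
    stop("clones must carry nucleotide sequences (include_nt = TRUE)",
         call. = FALSE)
  }
  .with_seed(seed, {
    n <- nrow(clones)
    no_ins <- stats::runif(n) < model$no_insert_rate
    out <- clones
    out$no_insert <- no_ins
    out$truth <- NA_character_
    out$n_sub <- out$n_ins <- out$n_del <- 0L
    out$large_del <- FALSE
    for (i in seq_len(n)) {
      if (no_ins[i]) {
        out$nt[i] <- ""
        out$truth[i] <- "no_insert"
        next
      }
      mut <- .mutate_one(strsplit(clones$nt[i], "")[[1L]], model)
      out$nt[i] <- paste(mut$chars, collapse = "")
      out$n_sub[i] <- mut$events$n_sub
      out$n_ins[i] <- mut$events$n_ins
      out$n_del[i] <- mut$events$n_del
      out$large_del[i] <- mut$events$large_del
      out$truth[i] <- .truth_label(mut$events, out$nt[i], FALSE)
    }
    out$classification <- NA_character_
    out
  })
}

# degenerate-aware nucleotide compatibility lookup
.nt_compat <- function() {
  if (!is.null(.nf_cache$compat)) return(.nf_cache$compat)
  sets <- .iupac_sets()
  codes <- names(sets)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(sets[[a]], sets[[b]])) > 0L
  }
  .nf_cache$compat <- m
  m
}

#' Classify a clone against the reference design
#'
#' Priority rule: `no_insert` (alignment coverage below the floor) >
#' `large_region_missing` (contiguous loss of at least `large_del_nt`) >
#' `base_shifting` (net indel not divisible by 3) > `base_missing` (in-frame
#' indel) > `stop_codon` (premature stop) > `correct`. The alignment treats a
#' clone base matching any expansion of a degenerate reference base as a
#' match, so classification is invariant to synonymous substitutions and to
#' the sampled identity of degenerate positions.
#'
#' @param clone_nt clone nucleotide sequence (string or [nt_seq()]); the
#'   insert region without vector flanks.
#' @param plan a [design_primers()] result (its degenerate `cores` are the
#'   references).
#' @param coverage_floor insert-positivity floor on reference coverage.
#' @param large_del_nt contiguous-deletion threshold in nt.
#' @return classification string.
#' @export
classify_clone <- function(clone_nt, plan, coverage_floor = 0.5,
                           large_del_nt = 15L) {
  stopifnot(inherits(plan, "primer_plan"))
  nt <- if (inherits(clone_nt, "nt_seq")) as.character(clone_nt) else clone_nt
  if (is.na(nt) || nchar(nt) == 0L) return("no_insert")
  ref_lens <- vapply(plan$cores, nchar, integer(1))
  cl <- names(plan$cores)[which.min(abs(ref_lens - nchar(nt)))]
  ref <- strsplit(plan$cores[[cl]], "")[[1L]]
  obs <- strsplit(nt, "")[[1L]]
  compat <- .nt_compat()
  smat <- matrix(0, length(ref), length(obs))
  ok_obs <- obs %in% colnames(compat)
  smat[, ok_obs] <- compat[ref, obs[ok_obs]] * 1
  aln <- .nw_core(ref, obs, smat, gap = -1)
  covered <- sum(aln$a != "-" & aln$b != "-")
  if (covered / length(ref) < coverage_floor) return("no_insert")
  del_runs <- rle(aln$b == "-")
  max_del <- if (any(del_runs$values)) max(del_runs$lengths[del_runs$values]) else 0L
  net <- length(obs) - length(ref)
  # a single large dropout can have its gap run shaved at the edges where
  # degenerate reference positions match anything, so a net loss of the same
  # magnitude also counts
  if (max_del >= large_del_nt || net <= -large_del_nt) {
    return("large_region_missing")
  }
  if (net %% 3L != 0L) return("base_shifting")
  if (any(aln$a == "-") || any(aln$b == "-")) return("base_missing")
  tr <- translate_nt(nt_seq("clone", nt))
  if (length(tr$stops) > 0L && min(tr$stops) < length(obs) %/% 3L) {
    return("stop_codon")
  }
  "correct"
}

#' Classify a set of clones
#'
#' @param clones clone set data frame with an `nt` column.
#' @inheritParams classify_clone
#' @return the clone set with its `classification` column filled.
#' @export
classify_clones <- function(clones, plan, coverage_floor = 0.5,
                            large_del_nt = 15L) {
  clones$classification <- vapply(clones$nt, classify_clone, character(1),
                                  plan = plan, coverage_floor = coverage_floor,
                                  large_del_nt = large_del_nt,
                                  USE.NAMES = FALSE)
  clones
}

#' Library QC report
#'
#' Insertion rate from a colony-PCR picking assay, correctness rate and CDR
#' redundancy from sequencing.
#'
#' @param n_picked clones picked for the insert assay.
#' @param n_insert_positive clones scoring insert-positive.
#' @param classifications character vector of per-sequenced-clone
#'   classifications (see [classify_clone()]).
#' @param cdr_signatures optional CDR signatures (one per sequenced clone)
#'   used to count redundant correct clones.
#' @param effective_size optional library size estimate (see
#'   [titer_from_dilution()]).
#' @return list of class `library_qc_report`.
#' @export
qc_report <- function(n_picked, n_insert_positive, classifications,
                      cdr_signatures = NULL, effective_size = NA_real_) {
  if (n_picked <= 0L) stop("zero denominator: n_picked", call. = FALSE)
  n_sequenced <- length(classifications)
  if (n_sequenced == 0L) stop("zero denominator: no sequenced clones",
                              call. = FALSE)
  if (n_insert_positive < 0L || n_insert_positive > n_picked) {
    stop("n_insert_positive must be in [0, n_picked]", call. = FALSE)
  }
  n_correct <- sum(classifications == "correct")
  n_redundant <- if (!is.null(cdr_signatures)) {
    stopifnot(length(cdr_signatures) == n_sequenced)
    sig <- cdr_signatures[classifications == "correct"]
    length(sig) - length(unique(sig))
  } else {
    NA_integer_
  }
  structure(list(
    n_picked = n_picked, n_insert_positive = n_insert_positive,
    insertion_rate = n_insert_positive / n_picked,
    n_sequenced = n_sequenced, n_correct = n_correct,
    correctness_rate = n_correct / n_sequenced,
    n_redundant = n_redundant,
    defect_counts = table(classifications[classifications != "correct"]),
    effective_size = effective_size
  ), class = "library_qc_report")
}

#' @export
print.library_qc_report <- function(x, ...) {
  cat(sprintf("<library_qc_report>\n  insertion rate: %d/%d = %.1f%%\n",
              x$n_insert_positive, x$n_picked, 100 * x$insertion_rate))
  cat(sprintf("  correctness rate: %d/%d = %.1f%%\n", x$n_correct,
              x$n_sequenced, 100 * x$correctness_rate))
  if (!is.na(x$n_redundant)) {
    cat(sprintf("  redundant correct clones: %d\n", x$n_redundant))
  }
  if (length(x$defect_counts) > 0L) {
    cat("  defects:", paste(names(x$defect_counts), x$defect_counts,
                            sep = "=", collapse = ", "), "\n")
  }
  if (!is.na(x$effective_size)) {
    cat(sprintf("  effective size: %.3g\n", x$effective_size))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#'
#' @param report a [qc_report()] result.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "library_qc_report"))
  x <- unclass(report)
  x$defect_counts <- as.list(x$defect_counts)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Library size from serial dilution counts
#'
#' For every countable plate, size = count x dilution factor x
#' (total volume / plated volume); the estimate is the mean over countable
#' plates.
#'
#' @param colony_counts colonies per plate.
#' @param dilution_factors dilution factor per plate (e.g. `1e7`).
#' @param plated_volume volume plated per plate.
#' @param total_volume total library volume, same unit as `plated_volume`.
#' @param countable inclusive colony-count range considered countable
#'   (microbiological convention 30-300).
#' @return effective library size (colony-forming units).
#' @export
titer_from_dilution <- function(colony_counts, dilution_factors,
                                plated_volume = 1, total_volume = 1,
                                countable = c(30L, 300L)) {
  stopifnot(length(colony_counts) == length(dilution_factors))
  if (plated_volume <= 0 || total_volume <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  ok <- colony_counts >= countable[1L] & colony_counts <= countable[2L]
  if (!any(ok)) {
    stop("no countable plate (counts within [", countable[1L], ", ",
         countable[2L], "])", call. = FALSE)
  }
  est <- colony_counts[ok] * dilution_factors[ok] *
    (total_volume / plated_volume)
  mean(est)
}
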