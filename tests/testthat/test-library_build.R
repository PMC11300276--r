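test_that("design_primers emits one downstream variant per CDR3 length with
          unique flank motifs", {
  pp <- fx_primer_plan()
  expect_equal(names(pp$fragments$F3R3), c("8", "11", "14"))
  expect_gte(pp$overlap$length, 15L)
  for (cl in names(pp$products)) {
    prod <- pp$products[[cl]]
    expect_match(prod, "^GGCC.{5}GGCC")                    # SfiI-compatible
    expect_match(prod, "GCGGCCGC$")                        # NotI
    expect_equal(lengths(regmatches(prod, gregexpr("GCGGCCGC", prod))), 1L)
    # full length = flanks (21 nt) + 3 * (92 framework + 16 CDR1/2 + L)
    L <- as.integer(cl)
    expect_equal(nchar(prod), 21L + 3L * (108L + L))
  }
  expect_error(design_primers(fx_scaffold()$scaffold, fx_plan(), fx_spec(),
                              overlap_len = 10L), "overlap")
})

test_that("an all-fixed spec yields fully non-degenerate fragments and
          constant clones", {
  scaffold <- fx_scaffold()$scaffold
  labels <- c(imgt_cdr_labels("CDR1", 8), imgt_cdr_labels("CDR2", 8),
              imgt_cdr_labels("CDR3", 14))
  fixed <- vapply(labels, function(p) residue_at(scaffold, p), character(1))
  spec <- suppressWarnings(
    build_diversity_spec(fx_profile(), lengths = 14L, anchors = character(0),
                         fixed = fixed))
  plan <- plan_codons(spec)
  pp <- design_primers(scaffold, plan, spec)
  expect_false(grepl("[^ACGT]", pp$fragments$F2R2))
  expect_false(grepl("[^ACGT]", pp$fragments$F3R3[["14"]]))
  clones <- sample_library(pp, spec, 5, seed = 1)
  expect_length(unique(clones$aa), 1L)
  # the constant clone reproduces the scaffold exactly
  expect_equal(clones$aa[1], as.character(scaffold$sequence))
})

test_that("assembly round-trips and reports mismatched overlaps", {
  pp <- fx_primer_plan()
  prods <- assemble_in_silico(pp)
  for (cl in names(prods)) {
    expect_equal(as.character(prods[[cl]]), pp$products[[cl]])
  }
  broken <- pp
  frag <- broken$fragments$F3R3[["8"]]
  substr(frag, 3, 3) <- if (substr(frag, 3, 3) == "A") "C" else "A"
  broken$fragments$F3R3[["8"]] <- frag
  expect_error(assemble_in_silico(broken), "junction FR3 position 3")
})

test_that("a sampled instantiation of the product translates back to the
          scaffold framework", {
  pp <- fx_primer_plan()
  clones <- sample_library(pp, fx_spec(), 3, seed = 2)
  sc <- fx_scaffold()$scaffold
  for (i in 1:3) {
    aa <- translate_nt(nt_seq("c", clones$nt[i]))$aa
    an <- annotate_regions(aa, sc)
    for (rg in c("FR1", "FR2", "FR3", "FR4")) {
      expect_equal(an$regions[[rg]]$sequence, sc$regions[[rg]]$sequence)
    }
  }
})

test_that("sample_library respects length classes and is seed-deterministic", {
  pp <- fx_primer_plan()
  clones <- sample_library(pp, fx_spec(), 400, seed = 7, include_nt = FALSE)
  expect_setequal(unique(clones$length_class), c("8", "11", "14"))
  expect_true(all(nchar(clones$cdr1) == 8L))
  expect_true(all(nchar(clones$cdr2) == 8L))
  expect_true(all(nchar(clones$cdr3) == as.integer(clones$length_class)))
  again <- sample_library(pp, fx_spec(), 400, seed = 7, include_nt = FALSE)
  expect_identical(clones, again)
  other <- sample_library(pp, fx_spec(), 400, seed = 8, include_nt = FALSE)
  expect_false(identical(clones$cdr_signature, other$cdr_signature))
})

test_that("sampled per-position frequencies match codon-implied distributions", {
  pp <- fx_primer_plan()
  spec <- fx_spec()
  plan <- fx_plan()
  clones <- sample_library(pp, spec, 20000, seed = 13, include_nt = FALSE)
  # CDR1 positions, all clones
  cdr1_mat <- do.call(rbind, strsplit(clones$cdr1, ""))
  for (k in c(1, 4, 7)) {
    row <- plan[plan$region == "CDR1", ][k, ]
    dc <- codon_aa_distribution(row$triplet)
    emp <- table(factor(cdr1_mat[, k], levels = AA_STANDARD)) / nrow(cdr1_mat)
    dist <- setNames(numeric(20), AA_STANDARD)
    dist[names(dc$aa_dist)] <- dc$aa_dist
    tv <- 0.5 * sum(abs(as.numeric(emp) - dist / sum(dist)))
    expect_lt(tv, 0.03)
  }
})

test_that("error simulation honours its rates", {
  pp <- fx_primer_plan()
  clones <- sample_library(pp, fx_spec(), 40, seed = 3)
  none <- error_model(substitution_rate = 0, insertion_rate = 0,
                      deletion_rate = 0, large_deletion_rate = 0,
                      no_insert_rate = 0)
  out <- simulate_synthesis_errors(clones, none, seed = 4)
  expect_identical(out$nt, clones$nt)
  expect_true(all(out$truth == "correct" | out$truth == "stop_codon"))

  all_del <- error_model(substitution_rate = 0, insertion_rate = 0,
                         deletion_rate = 1, large_deletion_rate = 0,
                         no_insert_rate = 0)
  gone <- simulate_synthesis_errors(clones[1:3, ], all_del, seed = 4)
  expect_true(all(nchar(gone$nt) == 0L))

  # empirical substitution count within the binomial 99% CI at >= 1e5 bases
  subs_only <- error_model(substitution_rate = 1e-3, insertion_rate = 0,
                           deletion_rate = 0, large_deletion_rate = 0,
                           no_insert_rate = 0)
  big <- sample_library(pp, fx_spec(), 300, seed = 5)
  n_bases <- sum(nchar(big$nt))
  expect_gte(n_bases, 1e5)
  mut <- simulate_synthesis_errors(big, subs_only, seed = 6)
  ci <- qbinom(c(0.005, 0.995), n_bases, 1e-3)
  expect_gte(sum(mut$n_sub), ci[1])
  expect_lte(sum(mut$n_sub), ci[2])
  expect_identical(mut$nt, simulate_synthesis_errors(big, subs_only, seed = 6)$nt)
})

test_that("classify_clone follows the defect priority rule", {
  pp <- fx_primer_plan()
  clones <- sample_library(pp, fx_spec(), 6, seed = 21)
  clean <- clones$nt[clones$classification == "correct"][1]

  expect_equal(classify_clone(clean, pp), "correct")
  expect_equal(classify_clone("", pp), "no_insert")
  expect_equal(classify_clone(substr(clean, 1, 60), pp), "no_insert")

  # in-frame premature stop inside CDR3 (FR4 is the last 33 nt)
  stop_pos <- nchar(clean) - 33L - 23L       # codon-aligned? force it below
  stop_pos <- stop_pos - (stop_pos %% 3L)    # codon start, 0-based
  stopped <- paste0(substr(clean, 1, stop_pos), "TAA",
                    substr(clean, stop_pos + 4L, nchar(clean)))
  expect_equal(classify_clone(stopped, pp), "stop_codon")

  # single-base deletion in FR3 -> frameshift wins over stop detection
  del1 <- paste0(substr(clean, 1, 199), substr(clean, 201, nchar(clean)))
  expect_equal(classify_clone(del1, pp), "base_shifting")

  # in-frame 3-nt deletion -> base_missing
  del3 <- paste0(substr(clean, 1, 198), substr(clean, 202, nchar(clean)))
  expect_equal(classify_clone(del3, pp), "base_missing")

  # 30-nt contiguous loss -> large_region_missing
  del30 <- paste0(substr(clean, 1, 150), substr(clean, 181, nchar(clean)))
  expect_equal(classify_clone(del30, pp), "large_region_missing")
})

test_that("classification is invariant to synonymous substitutions", {
  pp <- fx_primer_plan()
  clones <- sample_library(pp, fx_spec(), 4, seed = 22)
  clean <- clones$nt[clones$classification == "correct"][1]
  # FR1 starts with CAG GTG CAG CTG ... ; CTG (L) -> CTC (L) is synonymous
  expect_equal(substr(clean, 10, 12), "CTG")
  syn <- clean
  substr(syn, 12, 12) <- "C"
  expect_equal(classify_clone(syn, pp), "correct")
})

test_that("qc_report reproduces the worked picking/sequencing statistics", {
  qc <- qc_report(50, 48, c(rep("correct", 21),
                            rep("stop_codon", 4), rep("base_missing", 2),
                            rep("base_shifting", 2), "large_region_missing"),
                  cdr_signatures = c(sprintf("sig%02d", 1:21),
                                     sprintf("bad%02d", 1:9)))
  expect_equal(qc$insertion_rate, 0.96)
  expect_equal(qc$correctness_rate, 0.70)
  expect_equal(qc$n_redundant, 0L)

  # redundancy counts duplicated signatures among correct clones only
  qc2 <- qc_report(10, 9, rep("correct", 4),
                   cdr_signatures = c("a", "a", "b", "c"))
  expect_equal(qc2$n_redundant, 1L)
  expect_error(qc_report(0, 0, "correct"), "denominator")
  expect_error(qc_report(10, 5, character(0)), "denominator")

  js <- jsonlite::fromJSON(qc_report_json(qc))
  expect_equal(js$insertion_rate, 0.96)
})

test_that("titer_from_dilution averages countable plates", {
  expect_equal(titer_from_dilution(370, 1e7, countable = c(30, 400)), 3.7e9)
  expect_equal(titer_from_dilution(c(200, 40), c(1e6, 1e7)),
               mean(c(2e8, 4e8)))
  expect_equal(titer_from_dilution(c(500, 100), c(1e6, 1e7)), 1e9)
  expect_equal(titer_from_dilution(100, 1e6, plated_volume = 0.1,
                                   total_volume = 1), 1e9)
  expect_error(titer_from_dilution(c(0, 0), c(1e6, 1e7)), "countable")
})
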