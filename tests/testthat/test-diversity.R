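test_that("codon_aa_distribution enumerates degenerate codons exactly", {
  w <- codon_aa_distribution("TGG")
  expect_equal(w$aa_dist, c(W = 1))
  expect_equal(w$stop_fraction, 0)
  expect_equal(w$cys_fraction, 0)

  nnk <- codon_aa_distribution("NNK")
  expect_length(nnk$codon_set, 32L)
  expect_length(nnk$aa_dist, 20L)           # all 20 amino acids reachable
  expect_equal(nnk$stop_fraction, 1 / 32)
  expect_equal(nnk$cys_fraction, 1 / 32)
  expect_equal(sum(nnk$aa_dist) + nnk$stop_fraction, 1)

  kmt <- codon_aa_distribution("KMT")
  expect_equal(kmt$aa_dist[order(names(kmt$aa_dist))],
               c(A = 0.25, D = 0.25, S = 0.25, Y = 0.25))
  expect_equal(kmt$stop_fraction, 0)

  expect_error(codon_aa_distribution("NNO"), "invalid")
  expect_error(codon_aa_distribution("NN"), "invalid")
})

test_that("optimizer finds zero-divergence triplets where they exist", {
  ch <- optimize_degenerate_codon(c(W = 1))
  expect_equal(ch$codon$triplet, "TGG")
  expect_equal(ch$divergence, 0)

  # KMT encodes uniform {D,A,Y,S}; so does KMC, which sorts first under the
  # lexicographic tie-break — the contract is the zero divergence, and the
  # returned triplet must be the first zero-divergence one
  ch <- optimize_degenerate_codon(c(D = 0.25, A = 0.25, Y = 0.25, S = 0.25))
  expect_equal(ch$divergence, 0)
  expect_equal(ch$codon$triplet, "KMC")
  expect_equal(ch$codon$aa_dist[order(names(ch$codon$aa_dist))],
               c(A = 0.25, D = 0.25, S = 0.25, Y = 0.25))

  # A/G 50:50 under an infinite stop penalty: a stop-free exact triplet
  ch <- optimize_degenerate_codon(c(A = 0.5, G = 0.5), stop_penalty = Inf)
  expect_equal(ch$divergence, 0)
  expect_equal(ch$codon$stop_fraction, 0)
  expect_equal(ch$codon$aa_dist[order(names(ch$codon$aa_dist))],
               c(A = 0.5, G = 0.5))
})

test_that("optimizer objective matches hand-computed scores and is never beaten", {
  target <- c(S = 0.4, G = 0.3, Y = 0.2, R = 0.1)
  stop_pen <- 10; cys_pen <- 5
  obj_of <- function(triplet) {
    dc <- codon_aa_distribution(triplet)
    full <- setNames(numeric(20), AA_STANDARD)
    full[names(target)] <- target
    dist <- setNames(numeric(20), AA_STANDARD)
    dist[names(dc$aa_dist)] <- dc$aa_dist
    tv <- 0.5 * (sum(abs(full - dist)) + dc$stop_fraction)
    tv + stop_pen * dc$stop_fraction + cys_pen * dc$cys_fraction
  }
  best <- optimize_degenerate_codon(target, stop_pen, cys_pen)
  expect_equal(best$objective, obj_of(best$codon$triplet))
  # hand-verifiable spot triplets can never beat the exhaustive optimum
  for (tr in c("NNK", "AGC", "RGC", "KMT", "WSC")) {
    expect_lte(best$objective, obj_of(tr))
  }
  # nor can a random sample of the search space
  set.seed(3)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
             "H", "V", "N")
  for (i in 1:50) {
    tr <- paste(sample(codes, 3, replace = TRUE), collapse = "")
    expect_lte(best$objective, obj_of(tr))
  }
})

test_that("build_diversity_spec shapes and targets follow the design rules", {
  spec <- fx_spec()
  expect_length(spec$cdr1, 8L)
  expect_length(spec$cdr2, 8L)
  expect_equal(names(spec$cdr3), c("8", "11", "14"))
  expect_equal(sum(spec$length_weights), 1)
  for (ps in c(spec$cdr1, spec$cdr2, unlist(spec$cdr3, recursive = FALSE))) {
    expect_equal(sum(ps$target), 1, tolerance = 1e-9)
    if (ps$mode == "natural") {
      expect_equal(unname(ps$target["C"]), 0)   # Cys excluded by design
    }
    if (ps$mode == "anchored") {
      expect_gte(unname(ps$target[ps$anchor]), 0.5)
    }
  }
  # anchors land where the scheme says
  anchored <- vapply(Filter(function(p) p$mode == "anchored",
                            c(spec$cdr1, spec$cdr2, spec$cdr3[["14"]])),
                     `[[`, character(1), "imgt")
  expect_setequal(anchored, names(imgt_scheme()$anchors))
})

test_that("natural targets equal the profile with Cys removed and renormalized", {
  freq <- matrix(0, nrow = 1, ncol = 20, dimnames = list("107", AA_STANDARD))
  freq["107", c("A", "C", "G", "S")] <- c(0.3, 0.2, 0.3, 0.2)
  prof <- structure(list(freq = freq, support = c(`107` = 10L),
                         positions = "107", n_members = 10L),
                    class = "positional_profile")
  # cover the other CDR positions with the same row to satisfy the spec
  all_pos <- unique(c(imgt_cdr_labels("CDR1", 8), imgt_cdr_labels("CDR2", 8),
                      imgt_cdr_labels("CDR3", 8)))
  freq_all <- freq[rep(1, length(all_pos)), , drop = FALSE]
  rownames(freq_all) <- all_pos
  prof <- structure(list(freq = freq_all,
                         support = setNames(rep(10L, length(all_pos)), all_pos),
                         positions = all_pos, n_members = 10L),
                    class = "positional_profile")
  spec <- suppressWarnings(
    build_diversity_spec(prof, lengths = 8L, anchors = character(0)))
  tgt <- spec$cdr3[["8"]][[3]]$target     # position 107, mode natural
  # arithmetic oracle: (0.3, 0.3, 0.2)/0.8
  expect_equal(unname(tgt[c("A", "G", "S")]), c(0.3, 0.3, 0.2) / 0.8)
  expect_equal(unname(tgt["C"]), 0)
})

test_that("spec_summary closed forms are exact", {
  spec <- fx_spec()
  plan <- fx_plan()
  s <- spec_summary(spec, plan)
  # a stop-free plan implies a zero expected stop-clone fraction
  if (all(plan$stop_fraction == 0)) {
    expect_equal(s$expected_stop_clone_fraction, 0)
  }
  expect_equal(
    s$per_class[["8"]]$stop_clone_fraction,
    1 - prod(1 - .subset2(rbind(plan[plan$region != "CDR3", ],
                                plan[plan$region == "CDR3" &
                                       plan$length_class == "8", ]),
                          "stop_fraction")))

  # 24 positions at stop fraction 1/32 -> 1 - (31/32)^24
  fake <- plan
  fake$stop_fraction <- 1 / 32
  s24 <- spec_summary(spec, fake)
  expect_equal(s24$per_class[["8"]]$stop_clone_fraction, 1 - (31 / 32)^24)

  # theoretical size is the product of per-position support
  fake2 <- plan
  fake2$n_aa <- 2L
  s2 <- spec_summary(spec, fake2)
  expect_equal(s2$per_class[["8"]]$theoretical_size, 2^24)
  expect_equal(s2$per_class[["14"]]$theoretical_size, 2^30)

  # divergence reported equals an independently recomputed TV distance
  flat <- c(spec$cdr1, spec$cdr2)
  for (k in c(1, 5, 9)) {
    ps <- flat[[k]]
    region <- if (k <= 8) "CDR1" else "CDR2"
    row <- plan[plan$region == region & plan$imgt == ps$imgt, ][1, ]
    dc <- codon_aa_distribution(row$triplet)
    dist <- setNames(numeric(20), AA_STANDARD)
    dist[names(dc$aa_dist)] <- dc$aa_dist
    tv <- 0.5 * (sum(abs(ps$target - dist)) + dc$stop_fraction)
    expect_equal(row$divergence, tv, tolerance = 1e-12)
  }
})
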