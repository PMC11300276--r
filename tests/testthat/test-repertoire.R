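make_member <- function(id, cdr3_len = 8L, mutate_at = integer(0),
                        to = "A") {
  base <- gen_repertoire(1, seed = 1, conservation = 1, anchor_conservation = 1,
                         fr_sub_rate = 0,
                         length_weights = setNames(1, cdr3_len))$members[[1]]
  chars <- base$sequence$chars
  chars[mutate_at] <- to
  annotate_by_lengths(aa_seq(id, chars),
                      c(cdr1 = 8L, cdr2 = 8L, cdr3 = cdr3_len))
}

test_that("dedup_cluster collapses duplicates and separates distinct sequences", {
  a <- make_member("a"); b <- make_member("b")
  dd <- dedup_cluster(repertoire(list(a, b)), threshold = 0.9)
  expect_length(dd$clusters, 1L)
  # sequences mutated at >10% of positions all become singletons
  members <- lapply(1:4, function(i) {
    make_member(paste0("m", i), mutate_at = seq(i, 114, by = 4), to = "H")
  })
  dd <- dedup_cluster(repertoire(members), threshold = 0.9)
  expect_length(dd$clusters, 4L)
  expect_error(dedup_cluster(repertoire(list(a)), threshold = 1.5), "threshold")
})

test_that("dedup_cluster matches an all-pairs greedy oracle on constructed input", {
  set.seed(5)
  members <- c(
    lapply(1:3, function(i) make_member(paste0("g1_", i), mutate_at = i, to = "W")),
    lapply(1:3, function(i) make_member(paste0("g2_", i), cdr3_len = 14L,
                                        mutate_at = 20 + i, to = "H")),
    lapply(1:4, function(i) make_member(paste0("solo_", i),
                                        mutate_at = seq(i, 110, by = 3), to = "Y"))
  )
  rep <- repertoire(members)
  dd <- dedup_cluster(rep, threshold = 0.9)

  # oracle: precompute the full identity matrix, then run the greedy rule
  n <- length(members)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <- seq_identity(members[[i]], members[[j]])
  }
  lens <- vapply(members, function(m) length(m$sequence$chars), integer(1))
  ord <- order(-lens, seq_len(n))
  reps <- integer(0); assign_oracle <- integer(n)
  for (i in ord) {
    hit <- which(idm[i, reps] > 0.9)
    if (length(hit) > 0) {
      assign_oracle[i] <- hit[1L]
    } else {
      reps <- c(reps, i)
      assign_oracle[i] <- length(reps)
    }
  }
  expect_equal(dd$assignment, assign_oracle)
})

test_that("threshold 1.0 never merges distinct sequences", {
  members <- c(lapply(1:3, function(i) make_member(paste0("d", i))),
               list(make_member("m", mutate_at = 5L, to = "W")))
  dd <- dedup_cluster(repertoire(members), threshold = 1.0)
  for (cl in dd$clusters) {
    seqs <- vapply(members[cl], function(m) as.character(m$sequence),
                   character(1))
    expect_length(unique(seqs), 1L)
  }
})

test_that("curate_complex_dataset applies the four filters in order", {
  base <- as.character(make_member("x")$sequence)
  mutant <- function(at, to = "W") {
    ch <- strsplit(base, "")[[1]]; ch[at] <- to; paste(ch, collapse = "")
  }
  records <- data.frame(
    id = paste0("r", 1:6),
    seq = c(base, mutant(3), mutant(seq(1, 110, by = 3), "Y"),
            base, mutant(seq(2, 110, by = 3), "H"),
            mutant(seq(3, 110, by = 3), "F")),
    cdr3_len = c(8L, 12L, 8L, 8L, 8L, 8L),
    resolution = c(2.1, 2.0, 3.5, 2.4, 2.8, 2.2),
    antigen = c("ag1", "ag2", "ag3", "ag4", "ag5", "ag1"),
    stringsAsFactors = FALSE)
  out <- curate_complex_dataset(records)
  # hand enumeration: r2 fails length (12 aa), r3 fails resolution (3.5 A),
  # r4 is identical to r1 (identity filter), r6 shares ag1 with r1
  expect_equal(out$records$id, c("r1", "r5"))
  expect_equal(unname(out$removed),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(out$removed), nrow(records) - nrow(out$records))
  expect_false(out$empty)
  # empty survivors are flagged, not an error
  out2 <- curate_complex_dataset(records[2, ])
  expect_true(out2$empty)
})

test_that("positional_profile counts residues per IMGT position", {
  a <- make_member("a"); b <- make_member("b")
  prof <- positional_profile(repertoire(list(a, b)))
  expect_true(all(abs(rowSums(prof$freq) - 1) < 1e-9))
  expect_true(all(apply(prof$freq, 1, max) == 1))  # identical members

  b2 <- make_member("b2", mutate_at = 30L, to = "G")  # position 30 differs
  pos <- a$position_map$imgt[30]
  prof <- positional_profile(repertoire(list(a, b2)))
  r <- a$position_map$residue[30]
  expect_equal(unname(prof$freq[pos, r]), 0.5)
  expect_equal(unname(prof$freq[pos, "G"]), 0.5)
})

test_that("positional_profile matches a direct column-count oracle", {
  rep <- fx_repertoire()
  sub <- repertoire(rep$members[1:50])
  prof <- positional_profile(sub)
  # oracle: tabulate residues per position straight from the maps
  counts <- list()
  for (m in sub$members) {
    for (k in seq_len(nrow(m$position_map))) {
      p <- m$position_map$imgt[k]; r <- m$position_map$residue[k]
      counts[[p]] <- c(counts[[p]], r)
    }
  }
  for (p in sample(names(counts), 25)) {
    tab <- table(factor(counts[[p]], levels = AA_STANDARD)) / length(counts[[p]])
    expect_equal(unname(prof$freq[p, ]), as.numeric(tab), info = p)
    expect_equal(unname(prof$support[p]), length(counts[[p]]))
  }
  expect_true(all(prof$support <= length(sub$members)))
})

test_that("distill_consensus keeps conserved positions and flags ties", {
  freq <- matrix(0, nrow = 4, ncol = 20,
                 dimnames = list(c("1", "2", "3", "4"), AA_STANDARD))
  freq["1", "R"] <- 1
  freq["2", c("A", "G")] <- 0.5
  freq["3", "W"] <- 0.85; freq["3", "F"] <- 0.15
  freq["4", c("D", "E")] <- 0.45; freq["4", "K"] <- 0.10
  prof <- structure(list(freq = freq,
                         support = c(`1` = 10L, `2` = 10L, `3` = 10L, `4` = 10L),
                         positions = rownames(freq), n_members = 10L),
                    class = "positional_profile")
  cons <- distill_consensus(prof, min_conservation = 0.8)
  expect_equal(cons$position, c("1", "3"))
  expect_equal(cons$residue, c("R", "W"))
  cons <- distill_consensus(prof, min_conservation = 0.4)
  tie_row <- cons[cons$position == "4", ]
  expect_true(tie_row$tie)
  expect_equal(tie_row$residue, "D")    # alphabetical tie-break
  # at any threshold a fully conserved column survives
  expect_true("1" %in% distill_consensus(prof, 1.0)$position)
})

test_that("hallmark association recovers planted length-conditional usage", {
  # constructed separation: short CDR3 carries Y42, long carries F42
  rep <- gen_repertoire(
    60, seed = 9,
    length_weights = c(`8` = 0.5, `16` = 0.5),
    hallmark_profiles = list(short = list(`42` = c(Y = 1)),
                             long = list(`42` = c(F = 1))))
  ha <- hallmark_cdr3_association(rep, split_length = 14)
  expect_equal(unname(ha$short$freq["42", "Y"]), 1)
  expect_equal(unname(ha$long$freq["42", "F"]), 1)
  expect_equal(sum(ha$partition_sizes), 60L)
  expect_true(all(abs(rowSums(ha$short$freq) - 1) < 1e-9))

  # single-partition input flags the other side undefined
  rep8 <- gen_repertoire(10, seed = 2, length_weights = c(`8` = 1))
  ha8 <- hallmark_cdr3_association(rep8, split_length = 14)
  expect_false(ha8$long$defined)
  expect_true(ha8$short$defined)

  # planted 0.8/0.2 usage is recovered within counting error
  rep2 <- gen_repertoire(
    1000, seed = 31,
    length_weights = c(`8` = 0.5, `16` = 0.5),
    hallmark_profiles = list(short = list(`42` = c(Y = 0.8, F = 0.2)),
                             long = list(`42` = c(F = 0.8, Y = 0.2))))
  ha2 <- hallmark_cdr3_association(rep2, split_length = 14)
  expect_lt(abs(ha2$short$freq["42", "Y"] - 0.8), 0.05)
  expect_lt(abs(ha2$long$freq["42", "F"] - 0.8), 0.05)
})
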