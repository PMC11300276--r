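# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_template <- function() fx_memo("template", nf_template)
fx_germline <- function() fx_memo("germline", nf_germline)

fx_repertoire <- function() {
  fx_memo("repertoire", function() gen_repertoire(120, seed = 101L))
}

fx_profile <- function() {
  fx_memo("profile", function() positional_profile(fx_repertoire()))
}

fx_spec <- function() {
  fx_memo("spec", function() build_diversity_spec(fx_profile()))
}

fx_plan <- function() {
  fx_memo("plan", function() plan_codons(fx_spec()))
}

fx_scaffold <- function() {
  fx_memo("scaffold", function() {
    t <- fx_template(); g <- fx_germline()
    subs <- rbind(propose_hallmark_humanization(t, g, hallmarks = c(49, 50)),
                  propose_consensus_substitutions(t, demo_consensus(), g, 3))
    apply_design(t, subs, germline = g)
  })
}

fx_primer_plan <- function() {
  fx_memo("primer_plan", function() {
    design_primers(fx_scaffold()$scaffold, fx_plan(), fx_spec())
  })
}

# Independent exhaustive global-alignment oracle: enumerates every global
# alignment recursively and returns the maximum score.
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(a), length(b))
}

# Independent oracle for symmetric CDR gap placement: enumerate every
# contiguous gap block in the span, keep the placement with the most even
# N/C residue split, break ties toward the N-terminal side.
oracle_cdr_positions <- function(span, len) {
  stopifnot(len <= length(span))
  g <- length(span) - len
  if (g == 0L) return(as.character(span))
  best <- NULL; best_key <- NULL
  for (s in seq_len(length(span) - g + 1L)) {
    n_n <- s - 1L
    n_c <- length(span) - g - n_n
    key <- c(abs(n_n - n_c), -n_n)   # even split first, then N-terminal bias
    if (is.null(best_key) ||
        key[1L] < best_key[1L] ||
        (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
      best_key <- key
      best <- span[-(s:(s + g - 1L))]
    }
  }
  as.character(best)
}

random_aa <- function(n, alphabet = setdiff(AA_STANDARD, character(0))) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
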