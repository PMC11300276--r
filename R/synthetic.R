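# Seeded generators and packaged demo fixtures. Everything here is synthetic:
# the template/germline/consensus fixtures are illustrative stand-ins that
# reproduce the structure of the published design (hallmark substitutions
# Q49G and R50L toward the nearest human germline plus three consensus
# substitutions), not the actual deposited sequences, which are not printed
# in text form anywhere.

#' Synthetic template nanobody (demo fixture)
#'
#' A 122-aa VHH-like template with camelid hallmarks Y42/Q49/R50/F52, a
#' 14-aa CDR3 and the conserved CDR anchors of the scheme. This is a
#' synthetic stand-in, not a deposited sequence.
#'
#' @return an `annotated_nanobody`.
#' @export
nf_template <- function() {
  seq <- aa_seq("Nb_template_synthetic", paste0(
    "QVQLVESGGGLVQPGGSLRLSCAASG",   # FR1 1-26
    "GFISAYST",                     # CDR1 (8 aa): G27, I29, A35
    "WVRYQAPGKGQREFVAA",            # FR2 39-55: Y42 Q49 R50 F52
    "ITSGGSTY",                     # CDR2 (8 aa): I56, G63, T65
    "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC",  # FR3 67-104
    "ARDLSTAVSYYKDY",               # CDR3 (14 aa): A105 ... Y117
    "WGQGTQVTVSS"))                 # FR4 118-128
  annotate_by_lengths(seq, c(cdr1 = 8L, cdr2 = 8L, cdr3 = 14L))
}

#' Synthetic human germline reference (demo fixture)
#'
#' An IGHV3-family-like germline stand-in with human hallmarks V42/G49/L50/W52
#' and framework differences from [nf_template()] at positions 1, 12, 49, 50,
#' 42, 52, 89 and 123. Synthetic, for demonstration and testing.
#'
#' @return a [germline_reference()].
#' @export
nf_germline <- function() {
  seq <- aa_seq("IGHV3_demo_synthetic", paste0(
    "EVQLVESGGGLIQPGGSLRLSCAASG",   # FR1: E1, I12
    "GFTVSSNY",                     # CDR1 (8 aa)
    "WVRVQAPGKGGLEWVAA",            # FR2: V42 G49 L50 W52
    "IYSGGSTY",                     # CDR2 (8 aa)
    "YYADSVKGRFTISRDNSKNTLYVQMNSLRAEDTAVYYC",  # FR3: V89
    "ARDGSYDY",                     # CDR3 (8 aa)
    "WGQGTLVTVSS"))                 # FR4 (J-region-like)
  germline_reference("IGHV3_demo_synthetic",
                     annotate_by_lengths(seq, c(cdr1 = 8L, cdr2 = 8L,
                                                cdr3 = 8L)))
}

#' Synthetic framework consensus (demo fixture)
#'
#' A distilled consensus with three highly conserved framework positions at
#' which [nf_template()] deviates (1E, 12I, 89V) plus positions the template
#' already satisfies. Stands in for a consensus distilled from a curated
#' repertoire.
#'
#' @return a `consensus_profile`.
#' @export
demo_consensus <- function() {
  out <- data.frame(
    position = c("1", "12", "89", "43", "98"),
    residue = c("E", "I", "V", "Q", "D"),
    conservation = c(0.97, 0.93, 0.91, 0.99, 0.95),
    tie = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("consensus_profile", "data.frame")
  out
}

CDR_BACKGROUND <- local({
  # typical CDR loop composition (cysteine excluded by design)
  p <- c(A = 0.05, C = 0, D = 0.08, E = 0.04, F = 0.04, G = 0.11, H = 0.02,
         I = 0.03, K = 0.04, L = 0.06, M = 0.01, N = 0.05, P = 0.04,
         Q = 0.03, R = 0.08, S = 0.12, T = 0.07, V = 0.05, W = 0.02,
         Y = 0.08)
  p / sum(p)
})

#' Generate a synthetic nanobody repertoire
#'
#' Sequences are drawn position-wise around a scaffold: framework residues
#' mutate at a small rate, CDR residues keep the scaffold residue with
#' probability `conservation` and otherwise draw from a CDR background
#' distribution; CDR3 length varies per `length_weights`. Length-conditional
#' hallmark profiles can be planted to emulate the association between FR2
#' hallmarks and CDR3 length.
#'
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param scaffold an `annotated_nanobody` (default [nf_template()]).
#' @param length_weights named CDR3-length distribution.
#' @param conservation probability of keeping the scaffold residue at a
#'   non-anchor CDR position (hypervariable loops are weakly conserved).
#' @param anchor_conservation probability of keeping the residue at scheme
#'   anchor positions (structurally conserved in natural repertoires).
#' @param fr_sub_rate per-position framework substitution rate.
#' @param hallmark_profiles optional
#'   `list(short = list("42" = c(Y = ...), ...), long = ...)` of residue
#'   distributions planted at hallmark positions conditional on CDR3 length
#'   relative to `split_length`.
#' @param split_length boundary for `hallmark_profiles`.
#' @return a [repertoire()].
#' @export
gen_repertoire <- function(n, seed = 1L, scaffold = nf_template(),
                           length_weights = c(`8` = 1/3, `11` = 1/3,
                                              `14` = 1/3),
                           conservation = 0.35, anchor_conservation = 0.9,
                           fr_sub_rate = 0.02,
                           hallmark_profiles = NULL, split_length = 14L) {
  stopifnot(n >= 1L, inherits(scaffold, "annotated_nanobody"))
  if (abs(sum(length_weights) - 1) > 1e-9) {
    stop("length_weights must sum to 1", call. = FALSE)
  }
  scheme <- scaffold$scheme
  map <- scaffold$position_map
  anchor_pos <- names(scheme$anchors)
  draw_res <- function(base, labels) {
    cons <- ifelse(labels %in% anchor_pos, anchor_conservation, conservation)
    keep <- stats::runif(length(base)) < cons
    alt <- sample(names(CDR_BACKGROUND), length(base), replace = TRUE,
                  prob = CDR_BACKGROUND)
    ifelse(keep, base, alt)
  }
  .with_seed(seed, {
    lens <- as.integer(sample(names(length_weights), n, replace = TRUE,
                              prob = length_weights))
    members <- vector("list", n)
    fr_chars <- lapply(c("FR1", "FR2", "FR3", "FR4"), function(rg) {
      .as_chars(scaffold$regions[[rg]]$sequence)
    })
    names(fr_chars) <- c("FR1", "FR2", "FR3", "FR4")
    for (i in seq_len(n)) {
      fr <- lapply(fr_chars, function(ch) {
        hit <- stats::runif(length(ch)) < fr_sub_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(r) sample(setdiff(AA_STANDARD, r), 1L),
                            character(1))
        }
        ch
      })
      # planted hallmark usage, conditional on CDR3 length
      if (!is.null(hallmark_profiles)) {
        side <- if (lens[i] <= split_length) "short" else "long"
        prof <- hallmark_profiles[[side]]
        for (p in names(prof)) {
          idx <- as.integer(p) - scaffold$regions$FR2$imgt_start + 1L
          fr$FR2[idx] <- sample(names(prof[[p]]), 1L, prob = prof[[p]])
        }
      }
      cdr <- lapply(list(CDR1 = 8L, CDR2 = 8L, CDR3 = lens[i]), function(L) L)
      cdr_chars <- lapply(names(cdr), function(rg) {
        labels <- imgt_cdr_labels(rg, cdr[[rg]], scheme)
        base <- vapply(labels, function(lb) {
          r <- map$residue[match(lb, map$imgt)]
          if (is.na(r)) sample(names(CDR_BACKGROUND), 1L,
                               prob = CDR_BACKGROUND) else r
        }, character(1))
        draw_res(base, labels)
      })
      names(cdr_chars) <- names(cdr)
      chars <- c(fr$FR1, cdr_chars$CDR1, fr$FR2, cdr_chars$CDR2, fr$FR3,
                 cdr_chars$CDR3, fr$FR4)
      members[[i]] <- annotate_by_lengths(
        aa_seq(sprintf("nb_%05d", i), chars),
        c(cdr1 = 8L, cdr2 = 8L, cdr3 = lens[i]), scheme)
    }
    repertoire(members, provenance = sprintf("synthetic (seed %d)", seed))
  })
}

#' Generate a synthetic two-state melt curve
#'
#' Two-state sigmoid with linear baselines evaluated on a temperature grid
#' plus Gaussian noise scaled to the transition amplitude.
#'
#' @param tm melting temperature (deg C).
#' @param width transition width (deg C).
#' @param folded_baseline,unfolded_baseline `c(intercept, slope)` in
#'   mean-residue molar ellipticity units.
#' @param temperatures temperature grid (deg C).
#' @param noise_frac noise standard deviation as a fraction of the transition
#'   amplitude at `tm`.
#' @param seed RNG seed.
#' @return data frame: `temperature`, `signal`.
#' @export
gen_melt_curve <- function(tm = 73.7, width = 2.2,
                           folded_baseline = c(-11000, 10),
                           unfolded_baseline = c(-3500, 5),
                           temperatures = seq(25, 95, by = 1),
                           noise_frac = 0.02, seed = 1L) {
  stopifnot(noise_frac >= 0)
  f <- 1 / (1 + exp((temperatures - tm) / width))
  th_f <- folded_baseline[1L] + folded_baseline[2L] * temperatures
  th_u <- unfolded_baseline[1L] + unfolded_baseline[2L] * temperatures
  clean <- th_f * f + th_u * (1 - f)
  amp <- abs((folded_baseline[1L] + folded_baseline[2L] * tm) -
               (unfolded_baseline[1L] + unfolded_baseline[2L] * tm))
  .with_seed(seed, {
    data.frame(temperature = temperatures,
               signal = clean + stats::rnorm(length(temperatures),
                                             sd = noise_frac * amp))
  })
}

#' Generate a synthetic ELISA dilution series
#'
#' Four-parameter logistic response over a serial dilution plus Gaussian
#' noise scaled to the dynamic range.
#'
#' @param ec50 half-maximal concentration (molar).
#' @param hill hill slope.
#' @param top,bottom response asymptotes.
#' @param concentrations molar concentrations (default: 10-point 3-fold
#'   dilution from 1000 nM).
#' @param noise_frac noise sd as a fraction of `top - bottom`.
#' @param seed RNG seed.
#' @return data frame: `concentration`, `response`.
#' @export
gen_binding_series <- function(ec50 = 22.16e-9, hill = 1, top = 2,
                               bottom = 0.05,
                               concentrations = 1e-6 / 3^(0:9),
                               noise_frac = 0.05, seed = 1L) {
  stopifnot(ec50 > 0, noise_frac >= 0)
  clean <- bottom + (top - bottom) / (1 + (ec50 / concentrations)^hill)
  .with_seed(seed, {
    data.frame(concentration = concentrations,
               response = clean + stats::rnorm(length(concentrations),
                                               sd = noise_frac * (top - bottom)))
  })
}

#' Generate clone reads with ground-truth defect labels
#'
#' Samples clones from the designed library and passes them through the
#' synthesis-error simulator; truth labels follow the same priority rule as
#' [classify_clone()], so classifier/truth disagreements isolate genuine
#' event collisions.
#'
#' @param plan a [design_primers()] result.
#' @param spec the matching [build_diversity_spec()].
#' @param model an [error_model()].
#' @param n number of clones.
#' @param seed RNG seed (the error pass uses `seed + 1`).
#' @return clone set data frame with mutated `nt` and `truth` labels.
#' @export
gen_clone_reads <- function(plan, spec, model = error_model(), n = 100L,
                            seed = 1L) {
  clones <- sample_library(plan, spec, n, seed = seed, include_nt = TRUE)
  simulate_synthesis_errors(clones, model, seed = seed + 1L)
}
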