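# Seeded synthetic SMILES generator. Emulates the signal structure the
# pipeline is built to detect: a background of diverse small molecules
# (varied scaffolds and decorations) and positives whose epitope status is
# ruled by a repetitive substructure — a long carbon chain attached to a
# scaffold and/or a planted motif fragment. Count fingerprints see chain
# length as a feature count; bit fingerprints do not, which the "bit-blind"
# scenario exploits.

.SYNTH_SCAFFOLDS <- c(
  pyranose   = "OC1OC({R})C(O{D})C(O)C1O",
  aromatic   = "c1cc({D})c({R})cc1",
  glycerol   = "OCC(O{D})C(O){R}",
  fatty_acid = "O=C(O{D})C{R}"
)

.SYNTH_DECOR <- c("", "C", "CC", "CCC", "C(C)C", "CO", "CCO", "CC(C)C",
                  "C(=O)C", "CCN", "CCCC", "CC=C", "CCCO", "CC(C)O",
                  "C(=O)CC", "CCCN", "CC(C)CC", "CCCCC", "CC(C)(C)C",
                  "CCOC")

#' Specification of a synthetic labeled molecule dataset
#'
#' Molecules are built from scaffold templates with a sampled unbranched
#' carbon chain at one site (repeated CH2 environments: the count-feature
#' signal) and a random decoration at a second site (structural diversity so
#' canonical deduplication keeps the set intact). Positives and background
#' draw chain lengths from separate ranges and the planted motif is attached
#' to positives with probability `motif_q`. Generated labels satisfy the
#' label rule exactly; identical seeds give byte-identical datasets.
#'
#' @param n_background,n_positive Class sizes (total must be at least 20).
#' @param assay Which assay the positives are positive in: `"b"`, `"t"` or
#'   `"both"`.
#' @param scaffolds Named character vector of templates with `{R}` (chain)
#'   and `{D}` (decoration) sites.
#' @param chain_background,chain_positive Inclusive integer ranges
#'   `c(min, max)` of chain lengths per class.
#' @param planted_motif Fragment SMILES appended to the chain of motif
#'   carriers (default an ethyl-phosphate ester).
#' @param motif_q Probability a positive carries the motif.
#' @param label_rule `"chain"` (epitope iff chain length >= threshold),
#'   `"motif"` (iff motif present) or `"either"`.
#' @param chain_threshold Length threshold for the chain rule.
#' @param seed Integer seed.
#' @return An object of class `"npek_synthetic_spec"`.
#' @export
synthetic_spec <- function(n_background = 270L, n_positive = 30L,
                           assay = c("t", "b", "both"),
                           scaffolds = .SYNTH_SCAFFOLDS,
                           chain_background = c(2L, 8L),
                           chain_positive = c(12L, 20L),
                           planted_motif = "OP(=O)(OCC)O",
                           motif_q = 0,
                           label_rule = c("chain", "motif", "either"),
                           chain_threshold = 10L,
                           seed = 1L) {
  assay <- match.arg(assay)
  label_rule <- match.arg(label_rule)
  if (n_background + n_positive < 20L)
    npek_stop("total dataset size must be at least 20", "npek_param_error")
  structure(
    list(n_background = as.integer(n_background),
         n_positive = as.integer(n_positive), assay = assay,
         scaffolds = scaffolds,
         chain_background = as.integer(chain_background),
         chain_positive = as.integer(chain_positive),
         planted_motif = planted_motif, motif_q = motif_q,
         label_rule = label_rule,
         chain_threshold = as.integer(chain_threshold),
         seed = as.integer(seed)),
    class = "npek_synthetic_spec"
  )
}

#' @noRd
.synth_build <- function(template, chain_len, deco, motif) {
  chain <- strrep("C", chain_len)
  r_part <- paste0(chain, motif)
  s <- template
  for (sub in list(c("R", r_part), c("D", deco))) {
    ph <- paste0("{", sub[1], "}")
    if (nzchar(sub[2])) {
      s <- gsub(ph, sub[2], s, fixed = TRUE)
    } else {
      s <- gsub(paste0("(", ph, ")"), "", s, fixed = TRUE)
      s <- gsub(ph, "", s, fixed = TRUE)
    }
  }
  s
}

#' @noRd
.synth_rule <- function(spec, chain_len, has_motif) {
  switch(spec$label_rule,
    chain = chain_len >= spec$chain_threshold,
    motif = has_motif,
    either = chain_len >= spec$chain_threshold | has_motif
  )
}

#' Generate a synthetic labeled molecule set
#'
#' @param spec A [synthetic_spec()].
#' @return A molecule set with exact class sizes, unique canonical SMILES,
#'   `mol_id`s `bg_*` / `epi_*` and labels per the spec's rule and assay.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "npek_synthetic_spec"))
  set.seed(spec$seed)
  # sanity: every scaffold must yield a parsable molecule
  for (nm in names(spec$scaffolds)) {
    probe <- canonical_smiles(.synth_build(spec$scaffolds[[nm]], 3L, "", ""))
    if (is.na(probe))
      npek_stop(paste0("scaffold template '", nm, "' cannot yield valid SMILES"),
                "npek_generation_error")
  }
  draw_class <- function(n, range, positive) {
    smiles <- character(0); lens <- integer(0); motifs <- logical(0)
    attempts <- 0L
    while (length(smiles) < n) {
      attempts <- attempts + 1L
      if (attempts > 60L)
        npek_stop("cannot generate enough unique molecules; widen the spec",
                  "npek_generation_error")
      m <- max(4L * (n - length(smiles)), 16L)
      len <- sample(seq(range[1], range[2]), m, replace = TRUE)
      tpl <- sample(spec$scaffolds, m, replace = TRUE)
      deco <- sample(.SYNTH_DECOR, m, replace = TRUE)
      has_motif <- positive & stats::runif(m) < spec$motif_q
      raw <- vapply(seq_len(m), function(i)
        .synth_build(tpl[i], len[i], deco[i],
                     if (has_motif[i]) spec$planted_motif else ""), "")
      can <- canonical_smiles(raw)
      ok <- !is.na(can) & !duplicated(can) & !can %in% smiles
      smiles <- c(smiles, can[ok])
      lens <- c(lens, len[ok]); motifs <- c(motifs, has_motif[ok])
    }
    list(smiles = smiles[seq_len(n)], lens = lens[seq_len(n)],
         motifs = motifs[seq_len(n)])
  }
  bg <- draw_class(spec$n_background, spec$chain_background, FALSE)
  pos <- draw_class(spec$n_positive, spec$chain_positive, TRUE)
  # positives colliding with a background structure are re-drawn implicitly
  # by the uniqueness filter below
  clash <- pos$smiles %in% bg$smiles
  while (any(clash)) {
    extra <- draw_class(sum(clash), spec$chain_positive, TRUE)
    pos$smiles[clash] <- extra$smiles
    pos$lens[clash] <- extra$lens
    pos$motifs[clash] <- extra$motifs
    clash <- pos$smiles %in% bg$smiles | duplicated(pos$smiles)
  }
  lab_bg <- .synth_rule(spec, bg$lens, bg$motifs)
  lab_pos <- .synth_rule(spec, pos$lens, pos$motifs)
  if (any(lab_bg) || !all(lab_pos))
    npek_stop(paste0("spec is inconsistent with its label rule ('",
                     spec$label_rule, "'): adjust chain ranges / motif_q"),
              "npek_generation_error")
  n_b <- spec$n_background; n_p <- spec$n_positive
  lb <- spec$assay %in% c("b", "both")
  lt <- spec$assay %in% c("t", "both")
  molecule_set(
    mol_id = c(sprintf("bg_%04d", seq_len(n_b)), sprintf("epi_%04d", seq_len(n_p))),
    smiles = c(bg$smiles, pos$smiles),
    source = rep(c("background", "epitope"), c(n_b, n_p)),
    label_b = rep(c(FALSE, lb), c(n_b, n_p)),
    label_t = rep(c(FALSE, lt), c(n_b, n_p)),
    provenance = paste0("synthetic (seed ", spec$seed, ")"),
    canonicalize = FALSE
  )
}

#' Spec for the bit-blind scenario
#'
#' Two classes on a single fatty-acid scaffold differing only in chain
#' length beyond the fingerprint radius: for radius 3 every chain of length
#' >= 8 exposes the same set of distinct environments, so folded bit
#' fingerprints carry no class signal while count fingerprints separate the
#' classes — the rationale for count features.
#'
#' @param n_per_class Molecules per class.
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
bit_blind_spec <- function(n_per_class = 60L, seed = 1L) {
  synthetic_spec(
    n_background = n_per_class, n_positive = n_per_class, assay = "t",
    scaffolds = .SYNTH_SCAFFOLDS["fatty_acid"],
    chain_background = c(8L, 11L), chain_positive = c(14L, 20L),
    motif_q = 0, label_rule = "chain", chain_threshold = 12L, seed = seed
  )
}

#' Fixed hand-listed toy molecule set
#'
#' Twenty-four small molecules spanning chains, rings, a chiral pair and a
#' canonical-duplicate pair (`"CCO"` / `"OCC"`), with hand-assigned labels;
#' intended for exact-value unit tests. Size and label counts are fixed
#' constants: 24 molecules, 5 B-positives, 4 T-positives.
#'
#' @return A molecule set (not deduplicated: the duplicate pair is kept).
#' @export
toy_fixture <- function() {
  rows <- list(
    #      id        smiles                          b      t
    list("toy_01", "CCO",                          FALSE, FALSE),
    list("toy_02", "OCC",                          FALSE, FALSE),  # duplicate of toy_01
    list("toy_03", "C",                            FALSE, FALSE),
    list("toy_04", "CC",                           FALSE, FALSE),
    list("toy_05", "CCCCCC",                       FALSE, FALSE),
    list("toy_06", "CCCCCCCCCCCC",                 FALSE, TRUE),
    list("toy_07", "CCCCCCCCCCCCCC",               FALSE, TRUE),
    list("toy_08", "O=C(O)CCCCCCCCCCC",            FALSE, TRUE),
    list("toy_09", "O=C(O)CC",                     FALSE, FALSE),
    list("toy_10", "C[C@H](N)O",                   FALSE, FALSE),  # chiral pair
    list("toy_11", "C[C@@H](N)O",                  FALSE, FALSE),
    list("toy_12", "c1ccccc1",                     FALSE, FALSE),
    list("toy_13", "c1ccccc1O",                    TRUE,  FALSE),
    list("toy_14", "c1ccncc1",                     TRUE,  FALSE),
    list("toy_15", "C1CC1",                        FALSE, FALSE),
    list("toy_16", "C1CCCCC1",                     FALSE, FALSE),
    list("toy_17", "OC1OCC(O)C(O)C1O",             TRUE,  FALSE),
    list("toy_18", "OC1OC(CCCCCCCCCCCC)C(O)C(O)C1O", TRUE, TRUE),
    list("toy_19", "CC(=O)NC",                     FALSE, FALSE),
    list("toy_20", "CC(=O)OCC",                    FALSE, FALSE),
    list("toy_21", "NCC(=O)O",                     FALSE, FALSE),
    list("toy_22", "OP(=O)(O)OCC",                 TRUE,  FALSE),
    list("toy_23", "ClC(Cl)Cl",                    FALSE, FALSE),
    list("toy_24", "CC(C)CC",                      FALSE, FALSE)
  )
  molecule_set(
    mol_id = vapply(rows, `[[`, "", 1L),
    smiles = vapply(rows, `[[`, "", 2L),
    source = "background",
    label_b = vapply(rows, `[[`, TRUE, 3L),
    label_t = vapply(rows, `[[`, TRUE, 4L),
    provenance = "toy fixture (hand-listed)"
  )
}
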