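# Isoform-aware featurization: transcription start sites are enumerated per
# construct, and each of the top-5 isoforms contributes a fixed block of
# features (RppH-site one-hot, rate terms, secondary-structure anatomy,
# tertiary-structure flags, motif counts, ITR one-hot). The default schema
# has 496 named features.

#' Detect G-quadruplex / i-motif spans
#'
#' Leftmost non-overlapping matches of `runs` base-runs of length `run_len`
#' separated by loops of `loop_min`..`loop_max` nt (defaults: the
#' four-G3-runs, 6-nt-loop pattern; use `base = "C"` for i-motifs).
#'
#' @param seq RNA string
#' @param runs number of base runs (default 4)
#' @param run_len run length (default 3)
#' @param loop_min,loop_max loop length range (default exactly 6)
#' @param base run base, `"G"` or `"C"`
#' @return data.frame `start0`, `end0` (0-based half-open), `width`
#' @export
detect_quadruplex <- function(seq, runs = 4L, run_len = 3L, loop_min = 6L,
                              loop_max = 6L, base = "G") {
  pat <- paste0(base, "{", run_len, "}",
                "(?:[ACGU]{", loop_min, ",", loop_max, "}",
                base, "{", run_len, "}){", runs - 1L, "}")
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      width = integer(0)))
  w <- attr(m, "match.length")
  data.frame(start0 = as.integer(m) - 1L,
             end0 = as.integer(m) - 1L + w, width = w)
}

#' Count overlapping IUPAC motif occurrences
#'
#' @param seq RNA string
#' @param motif_set named character vector of IUPAC motifs
#' @return named integer vector of overlapping occurrence counts
#' @export
count_motifs <- function(seq, motif_set = default_motif_set()) {
  if (length(motif_set) == 0L) return(setNames(integer(0), character(0)))
  vapply(motif_set, function(m) {
    rx <- paste0("(?=", iupac_to_regex(m), ")")
    hits <- gregexpr(rx, seq, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }, integer(1))
}

#' Default motif set: RNase E-proposed and CsrA-binding motifs
#'
#' Reconstructed defaults (the canonical lists live in the primary
#' literature); both families are supplied as IUPAC strings and fully
#' configurable.
#'
#' @return named character vector of 16 IUPAC motifs
#' @export
default_motif_set <- function() {
  c(rne_rauuw = "RAUUW", rne_auuua = "AUUUA", rne_uauuu = "UAUUU",
    rne_aauuw = "AAUUW", rne_auuga = "AUUGA", rne_uuuau = "UUUAU",
    rne_acagk = "ACAGK", rne_gauuy = "GAUUY",
    csra_agga = "AGGA", csra_angga = "ANGGA", csra_aggga = "AGGGA",
    csra_rgga = "RGGA", csra_aagga = "AAGGA", csra_acgga = "ACGGA",
    csra_augga = "AUGGA", csra_aggaug = "AGGAUG")
}

ANATOMY_FIELDS <- c("ssrna_total_nt", "ssrna_segment_count",
                    "ssrna_max_segment", "ssrna_mean_segment",
                    "ssrna_frac_a", "ssrna_frac_c", "ssrna_frac_g",
                    "ssrna_frac_u", "paired_nt", "hairpin_count",
                    "duplex_total_bp", "duplex_max_len", "duplex_mean_len",
                    "loop_total_nt", "loop_max_len", "loop_mean_len",
                    "bulge_count", "internal_loop_count", "multiloop_count",
                    "g4_present", "g4_span_nt", "imotif_present",
                    "imotif_span_nt")

#' Fold a 5' UTR (+ CDS window) and annotate its structural anatomy
#'
#' Folds the window with the supplied provider and tallies structural decay
#' determinants within the UTR portion: maximal unpaired (ssRNA) runs and
#' their composition, helix (duplex) lengths, hairpin loop lengths, bulges,
#' internal loops, and detected G-quadruplex / i-motif spans. In
#' `g4_aware` mode tertiary spans are excluded from pairing and from the
#' ssRNA tally (unpaired + paired + tertiary = UTR length); in
#' `secondary_only` mode the sequence folds freely and tertiary spans are
#' not subtracted.
#'
#' @param seq RNA string (UTR first, optionally followed by a CDS window)
#' @param utr_len length of the UTR portion (default whole sequence)
#' @param fold_provider folding function
#' @param tertiary_mode `"g4_aware"` or `"secondary_only"`
#' @param loop_min,loop_max tertiary-pattern loop range (default exactly 6)
#' @return list with `pair_table`, `dotbracket`, and the anatomy scalars of
#'   `ANATOMY_FIELDS`
#' @export
fold_and_annotate <- function(seq, utr_len = nchar(seq),
                              fold_provider = fold_rna,
                              tertiary_mode = c("g4_aware",
                                                "secondary_only"),
                              loop_min = 6L, loop_max = 6L) {
  tertiary_mode <- match.arg(tertiary_mode)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  n <- nchar(seq)
  utr_len <- min(utr_len, n)
  g4 <- detect_quadruplex(seq, base = "G", loop_min = loop_min,
                          loop_max = loop_max)
  im <- detect_quadruplex(seq, base = "C", loop_min = loop_min,
                          loop_max = loop_max)
  blocked <- rep(FALSE, n)
  for (i in seq_len(nrow(g4))) blocked[(g4$start0[i] + 1L):g4$end0[i]] <- TRUE
  for (i in seq_len(nrow(im))) blocked[(im$start0[i] + 1L):im$end0[i]] <- TRUE
  use_block <- tertiary_mode == "g4_aware"
  pt <- fold_provider(seq, blocked = if (use_block) blocked else NULL)
  if (length(pt) != n || any(pt < 0L | pt > n))
    stop("validation error: inconsistent pair table", call. = FALSE)
  paired_idx <- which(pt > 0L)
  if (any(pt[pt[paired_idx]] != paired_idx))
    stop("validation error: pair table is not symmetric", call. = FALSE)

  in_utr <- seq_len(utr_len)
  tert <- use_block & blocked
  unpaired <- pt == 0L & !tert
  # ssRNA segments: maximal unpaired runs within the UTR
  ss_mask <- unpaired[in_utr]
  runs <- rle(ss_mask)
  seg_lens <- runs$lengths[runs$values]
  ss_pos <- which(ss_mask)
  ss_comp <- if (length(ss_pos) > 0L)
    base_fractions(paste0(seq_chars(seq)[ss_pos], collapse = "")) else
      setNames(rep(0, 4), RNA_ALPHABET)
  hel <- .helix_anatomy(pt, utr_len)
  g4_utr <- g4[g4$start0 < utr_len, , drop = FALSE]
  im_utr <- im[im$start0 < utr_len, , drop = FALSE]

  anatomy <- c(
    ssrna_total_nt = sum(ss_mask),
    ssrna_segment_count = length(seg_lens),
    ssrna_max_segment = if (length(seg_lens) > 0L) max(seg_lens) else 0L,
    ssrna_mean_segment = if (length(seg_lens) > 0L) mean(seg_lens) else 0,
    ssrna_frac_a = ss_comp[["A"]], ssrna_frac_c = ss_comp[["C"]],
    ssrna_frac_g = ss_comp[["G"]], ssrna_frac_u = ss_comp[["U"]],
    paired_nt = sum(pt[in_utr] > 0L),
    hel,
    g4_present = as.integer(nrow(g4_utr) > 0L),
    g4_span_nt = sum(pmin(g4_utr$end0, utr_len) - g4_utr$start0),
    imotif_present = as.integer(nrow(im_utr) > 0L),
    imotif_span_nt = sum(pmin(im_utr$end0, utr_len) - im_utr$start0))
  c(list(pair_table = pt, dotbracket = pairs_to_dotbracket(pt),
         tertiary_nt = sum(tert[in_utr])),
    as.list(anatomy))
}

# Traverse a pair table: helices (maximal stacked pair runs), hairpin
# loops, bulges, internal loops, multiloops. Elements are attributed to the
# UTR if their outermost 5' position lies within it.
#' @noRd
.helix_anatomy <- function(pt, utr_len) {
  n <- length(pt)
  opens <- which(pt > seq_len(n))
  helices <- list()
  if (length(opens) > 0L) {
    start <- opens[1L]
    prev <- opens[1L]
    for (i in opens[-1L]) {
      if (i == prev + 1L && pt[i] == pt[prev] - 1L) {
        prev <- i
      } else {
        helices[[length(helices) + 1L]] <- c(start, prev)
        start <- i; prev <- i
      }
    }
    helices[[length(helices) + 1L]] <- c(start, prev)
  }
  duplex_lens <- integer(0)
  loop_lens <- integer(0)
  bulges <- 0L; internals <- 0L; multi <- 0L; hairpins <- 0L
  for (h in helices) {
    if (h[1L] > utr_len) next
    duplex_lens <- c(duplex_lens, h[2L] - h[1L] + 1L)
    # inner side of the helix: (i2, j2)
    i2 <- h[2L]; j2 <- pt[h[2L]]
    inside <- if (j2 - i2 > 1L) (i2 + 1L):(j2 - 1L) else integer(0)
    inner_pairs <- inside[pt[inside] > 0L]
    if (length(inner_pairs) == 0L) {
      hairpins <- hairpins + 1L
      loop_lens <- c(loop_lens, length(inside))
    } else {
      child_opens <- inner_pairs[pt[inner_pairs] > inner_pairs]
      child_helix_starts <- child_opens[c(TRUE,
        diff(child_opens) != 1L | pt[child_opens][-1L] !=
          pt[child_opens][-length(child_opens)] - 1L)]
      if (length(child_helix_starts) > 1L) {
        multi <- multi + 1L
      } else {
        i3 <- min(child_opens)
        j3 <- pt[i3]
        left_gap <- i3 - i2 - 1L
        right_gap <- j2 - j3 - 1L
        if (left_gap > 0L && right_gap > 0L) internals <- internals + 1L
        else if (left_gap > 0L || right_gap > 0L) bulges <- bulges + 1L
      }
    }
  }
  c(hairpin_count = hairpins,
    duplex_total_bp = sum(duplex_lens),
    duplex_max_len = if (length(duplex_lens) > 0L) max(duplex_lens) else 0L,
    duplex_mean_len = if (length(duplex_lens) > 0L) mean(duplex_lens) else 0,
    loop_total_nt = sum(loop_lens),
    loop_max_len = if (length(loop_lens) > 0L) max(loop_lens) else 0L,
    loop_mean_len = if (length(loop_lens) > 0L) mean(loop_lens) else 0,
    bulge_count = bulges,
    internal_loop_count = internals,
    multiloop_count = multi)
}

#' Enumerate the most predominant mRNA isoforms of a construct
#'
#' Candidate transcription start sites ranked by predicted initiation rate
#' (ties broken by smaller offset); the top `n` become isoforms 1..n.
#'
#' @param construct DNA string (promoter + UTR + CDS)
#' @param providers provider set from [default_providers()]
#' @param n number of isoforms (default 5)
#' @param max_offset largest admissible start offset (0-based); defaults to
#'   leaving at least 5 nt of UTR upstream of the CDS
#' @param cds_offset 0-based offset of the CDS within the construct
#' @return data.frame: `rank`, `tss_offset`, `tx_rate`, `mrna_seq` (RNA),
#'   `rpph_site`, `utr_len` (nt between start site and CDS)
#' @export
enumerate_isoforms <- function(construct, providers = default_providers(),
                               n = 5L, cds_offset = NULL,
                               max_offset = NULL) {
  len <- nchar(construct)
  if (is.null(cds_offset)) cds_offset <- len
  if (is.null(max_offset)) max_offset <- cds_offset - 5L
  sites <- providers$tx(construct)
  sites <- sites[sites$tss_offset <= max_offset, , drop = FALSE]
  if (nrow(sites) == 0L)
    stop("provider error: no candidate start sites", call. = FALSE)
  sites <- sites[order(-sites$tx_rate, sites$tss_offset), , drop = FALSE]
  top <- head(sites, n)
  mrna <- dna_to_rna(substring(construct, top$tss_offset + 1L, len))
  data.frame(rank = seq_len(nrow(top)),
             tss_offset = top$tss_offset,
             tx_rate = top$tx_rate,
             mrna_seq = mrna,
             rpph_site = substr(mrna, 1L, 4L),
             utr_len = cds_offset - top$tss_offset,
             stringsAsFactors = FALSE)
}

ITR_ONEHOT_NT <- 10L  # one-hot positions 5..14 of each isoform transcript

#' Construct the named feature schema
#'
#' The default schema has 1 global feature (construct length) plus 99
#' features for each of 5 isoforms: 16 RppH-site one-hot, log10
#' transcription rate, log10 TIR, UTR length, GC fraction, 23 structure
#' anatomy scalars, 16 motif counts, and a 40-entry one-hot of transcript
#' positions 5-14 — 496 features in total. Feature families can be
#' excluded by name prefix (the post-pruning reduced schema).
#'
#' @param n_isoforms isoforms tracked (default 5)
#' @param motif_set motif set defining the motif-count block
#' @param exclude character vector of anatomy/family name prefixes to drop
#' @return object of class `feature_schema`: `names`, `n_isoforms`,
#'   `motif_set`, `exclude`, `hash`
#' @export
feature_schema <- function(n_isoforms = 5L, motif_set = default_motif_set(),
                           exclude = character(0)) {
  block <- c(paste0("rpph_", rep(1:4, each = 4L), rep(c("a", "c", "g", "u"),
                                                      4L)),
             "log_tx", "log_tir", "utr_len", "gc_frac",
             ANATOMY_FIELDS,
             paste0("motif_", names(motif_set)),
             paste0("itr", rep(seq_len(ITR_ONEHOT_NT), each = 4L),
                    rep(c("a", "c", "g", "u"), ITR_ONEHOT_NT)))
  if (length(exclude) > 0L) {
    drop <- Reduce(`|`, lapply(exclude, function(p) startsWith(block, p)))
    block <- block[!drop]
  }
  nms <- c("construct_len",
           unlist(lapply(seq_len(n_isoforms), function(r)
             paste0("iso", r, "_", block))))
  structure(list(names = nms, n_isoforms = n_isoforms,
                 motif_set = motif_set, exclude = exclude,
                 hash = .fnv1a(paste(nms, collapse = "|"))),
            class = "feature_schema")
}

# Polynomial rolling hash (hex), for schema fingerprints and manifests.
#' @noRd
.fnv1a <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

PAD_SENTINEL <- -1

#' Assemble the feature vector of one variant
#'
#' @param isoforms data.frame from [enumerate_isoforms()]
#' @param anatomies list of [fold_and_annotate()] results, one per isoform
#' @param tirs numeric vector of TIRs (au), one per isoform
#' @param schema a [feature_schema()]
#' @param construct_len construct length (nt)
#' @return named numeric vector matching `schema$names`; blocks of absent
#'   isoforms are padded with the sentinel value -1
#' @export
assemble_features <- function(isoforms, anatomies, tirs, schema,
                              construct_len) {
  if (nrow(isoforms) > schema$n_isoforms)
    stop("schema error: more isoforms than the schema tracks",
         call. = FALSE)
  out <- setNames(rep(PAD_SENTINEL, length(schema$names)), schema$names)
  out["construct_len"] <- construct_len
  for (r in seq_len(nrow(isoforms))) {
    pre <- paste0("iso", r, "_")
    iso <- isoforms[r, ]
    vals <- c(.onehot_block(iso$rpph_site, "rpph_", 4L),
              log_tx = log10(iso$tx_rate),
              log_tir = log10(max(tirs[r], 1e-6)),
              utr_len = iso$utr_len,
              gc_frac = gc_fraction(substr(iso$mrna_seq, 1L, iso$utr_len)),
              unlist(anatomies[[r]][ANATOMY_FIELDS]),
              setNames(as.numeric(count_motifs(
                substr(iso$mrna_seq, 1L, iso$utr_len), schema$motif_set)),
                paste0("motif_", names(schema$motif_set))),
              .onehot_block(substr(iso$mrna_seq, 5L, 4L + ITR_ONEHOT_NT),
                            "itr", ITR_ONEHOT_NT))
    keep <- intersect(paste0(pre, names(vals)), schema$names)
    out[keep] <- vals[sub(pre, "", keep, fixed = TRUE)]
  }
  out
}

#' @noRd
.onehot_block <- function(seq, prefix, n_pos) {
  ch <- seq_chars(tolower(seq))
  vals <- setNames(rep(0, n_pos * 4L),
                   paste0(prefix, rep(seq_len(n_pos), each = 4L),
                          rep(c("a", "c", "g", "u"), n_pos)))
  for (i in seq_along(ch)) {
    key <- paste0(prefix, i, ch[i])
    if (key %in% names(vals)) vals[key] <- 1
  }
  vals
}

#' Featurize a design library
#'
#' Builds each variant's construct (promoter + UTR + CDS prefix),
#' enumerates isoforms, folds and annotates each isoform's UTR (plus a
#' 30-nt CDS window), computes surrogate TIRs, and assembles schema-ordered
#' feature vectors. Deterministic: repeated featurization is identical.
#'
#' @param library design library data.frame
#' @param providers provider set
#' @param schema feature schema
#' @param tertiary_mode structure mode passed to [fold_and_annotate()]
#' @param cds_window nt of CDS included in the folding window
#' @return numeric matrix (variants x features) with rownames =
#'   variant_id, and attribute `schema_hash`
#' @export
featurize_library <- function(library, providers = default_providers(),
                              schema = feature_schema(),
                              tertiary_mode = "g4_aware",
                              cds_window = 30L) {
  n <- nrow(library)
  out <- matrix(NA_real_, nrow = n, ncol = length(schema$names),
                dimnames = list(library$variant_id, schema$names))
  cds_rna <- dna_to_rna(CDS_DNA)
  for (i in seq_len(n)) {
    construct <- paste0(PROMOTER_DNA, rna_to_dna(library$utr_seq[i]),
                        CDS_DNA)
    cds_off <- nchar(PROMOTER_DNA) + nchar(library$utr_seq[i])
    isos <- enumerate_isoforms(construct, providers,
                               n = schema$n_isoforms,
                               cds_offset = cds_off)
    anat <- vector("list", nrow(isos))
    tirs <- numeric(nrow(isos))
    for (r in seq_len(nrow(isos))) {
      ulen <- isos$utr_len[r]
      window <- substr(isos$mrna_seq[r], 1L, ulen + cds_window)
      anat[[r]] <- fold_and_annotate(window, utr_len = ulen,
                                     fold_provider = providers$fold,
                                     tertiary_mode = tertiary_mode)
      tirs[r] <- providers$tir(isos$mrna_seq[r], ulen,
                               fold_provider = providers$fold)
    }
    out[i, ] <- assemble_features(isos, anat, tirs, schema,
                                  nchar(construct))
  }
  attr(out, "schema_hash") <- schema$hash
  out
}
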