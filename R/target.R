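#' Construct an SGE target specification
#'
#' A target specification describes one saturation genome editing (SGE)
#' region: the unedited reference sequence, the "edited" reference carrying
#' the fixed (HDR-marker) edits, the interval over which variants are
#' programmed, the CRISPR cut site, and annotation needed downstream
#' (homopolymer runs, excluded cell-line positions, the RNA amplicon
#' window, and the coding frame used to assign molecular consequences).
#'
#' All coordinates are target-local, 1-based and inclusive.
#'
#' @param target_id Character label for the region (e.g. `"exon3A"`).
#' @param ref_seq Unedited reference sequence (A/C/G/T string).
#' @param edited_region Integer vector `c(start, end)`: the interval in
#'   which variants are programmed.
#' @param fixed_edits Data frame with columns `pos`, `ref`, `alt`: the
#'   synonymous substitutions engineered into every repair template to
#'   block re-cutting and mark HDR-derived alleles.
#' @param cut_site Target-local position of the Cas9 cut site.
#' @param coding_region Integer `c(start, end)` of the coding portion
#'   inside `edited_region` (length a multiple of 3, read in frame from
#'   its first base). Positions in the edited region but outside the
#'   coding region are annotated as intronic/splice.
#' @param genomic_offset 1-based genomic coordinate of target-local
#'   position 1 (used as the smoothing coordinate).
#' @param exon_label Exon annotation carried by all variants of the target.
#' @param excluded_positions Target-local positions carrying known or
#'   suspected cell-line variants; variants there are dropped from analysis.
#' @param rna_window Interval covered by the RNA amplicon (defaults to the
#'   edited region).
#'
#' @return An object of class `sge_target`.
#' @export
sge_target <- function(target_id, ref_seq, edited_region, fixed_edits,
                       cut_site, coding_region = edited_region,
                       genomic_offset = 1L, exon_label = "exon1",
                       excluded_positions = integer(),
                       rna_window = edited_region) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L, nzchar(ref_seq))
  len <- nchar(ref_seq)
  stopifnot(length(edited_region) == 2L,
            edited_region[1] >= 1L, edited_region[2] <= len,
            edited_region[1] <= edited_region[2])
  stopifnot(is.data.frame(fixed_edits),
            all(c("pos", "ref", "alt") %in% names(fixed_edits)),
            nrow(fixed_edits) >= 1L)
  if (any(fixed_edits$pos < 1L | fixed_edits$pos > len)) {
    stop("fixed edit positions must lie inside ref_seq")
  }
  if (any(str_at(ref_seq, fixed_edits$pos) != fixed_edits$ref)) {
    stop("fixed edit ref alleles do not match ref_seq")
  }
  if (any(fixed_edits$ref == fixed_edits$alt)) {
    stop("fixed edits must change the base")
  }
  if (cut_site < edited_region[1] || cut_site > edited_region[2]) {
    stop("cut_site must lie within the edited region")
  }
  stopifnot(coding_region[1] >= edited_region[1],
            coding_region[2] <= edited_region[2])
  if ((coding_region[2] - coding_region[1] + 1L) %% 3L != 0L) {
    stop("coding_region length must be a multiple of 3")
  }
  stopifnot(rna_window[1] >= edited_region[1],
            rna_window[2] <= edited_region[2])

  edited <- ref_seq
  for (i in seq_len(nrow(fixed_edits))) {
    substring(edited, fixed_edits$pos[i], fixed_edits$pos[i]) <-
      fixed_edits$alt[i]
  }

  structure(list(
    target_id = target_id,
    ref_seq = ref_seq,
    edited_ref_seq = edited,
    edited_region = as.integer(edited_region),
    fixed_edits = fixed_edits,
    cut_site = as.integer(cut_site),
    coding_region = as.integer(coding_region),
    genomic_offset = as.integer(genomic_offset),
    exon_label = exon_label,
    homopolymer_runs = find_homopolymer_runs(edited),
    excluded_positions = as.integer(excluded_positions),
    rna_window = as.integer(rna_window)
  ), class = "sge_target")
}

#' Find homopolymer runs in a sequence
#'
#' Runs of a single base of length `min_len` or more. Read validity in
#' [classify_read()] tolerates a sequenced length change of up to two
#' bases at such runs, mirroring amplicon-sequencing slippage.
#'
#' @param seq DNA string.
#' @param min_len Minimum run length to report (default 4).
#' @return Data frame with columns `start`, `length`, `base`.
#' @export
find_homopolymer_runs <- function(seq, min_len = 4L) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_len
  data.frame(start = start[keep], length = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' @export
print.sge_target <- function(x, ...) {
  cat(sprintf(
    "<sge_target> %s: %d nt, edited region %d-%d, cut site %d, %d fixed edits, %d homopolymer runs\n",
    x$target_id, nchar(x$ref_seq), x$edited_region[1], x$edited_region[2],
    x$cut_site, nrow(x$fixed_edits), nrow(x$homopolymer_runs)))
  invisible(x)
}

#' Generate a random SGE target specification
#'
#' Draws a random reference sequence and places the edited region, coding
#' region, cut site and synonymous fixed edits the way a real SGE design
#' does: the edited region is flanked by PCR-handle sequence, the coding
#' portion sits inside the edited region with short intronic flanks, and
#' the fixed edits are wobble-position synonymous substitutions near the
#' cut site. Deterministic for a fixed seed.
#'
#' @param length Total target length in nt (default 160, i.e. a ~120-nt
#'   edited region plus 20-nt flanks).
#' @param cut_site Target-local cut-site position; default is the middle
#'   of the edited region.
#' @param n_fixed_edits Number of fixed edits (>= 1).
#' @param seed Integer seed.
#' @param flank Flank width outside the edited region on each side.
#' @param intron_flank Width of the intronic part of the edited region on
#'   each side of the coding portion (0 for a fully coding region;
#'   default 12, mirroring designs that cover 10+ nt of intron around
#'   each exon so canonical-splice, splice-region and intronic variants
#'   all arise).
#' @param target_id,exon_label,genomic_offset Passed to [sge_target()].
#' @param n_excluded Number of randomly placed cell-line-variant positions.
#' @return An `sge_target`.
#' @export
generate_target <- function(length = 160L, cut_site = NULL,
                            n_fixed_edits = 2L, seed = 1L,
                            flank = 20L, intron_flank = 12L,
                            target_id = "sim1", exon_label = "exon1",
                            genomic_offset = 1000L, n_excluded = 0L) {
  if (length < 30L) stop("length must be >= 30")
  if (n_fixed_edits < 1L) stop("n_fixed_edits must be >= 1")
  er <- c(flank + 1L, length - flank)
  if (er[2] - er[1] < 8L) stop("length/flank leave too small an edited region")
  if (is.null(cut_site)) cut_site <- (er[1] + er[2]) %/% 2L
  if (cut_site < er[1] || cut_site > er[2]) {
    stop("cut_site must fall inside the edited region")
  }

  cr_start <- er[1] + intron_flank
  cr_len <- ((er[2] - intron_flank) - cr_start + 1L) %/% 3L * 3L
  if (cr_len < 3L) stop("edited region too small for a coding portion")
  cr <- c(cr_start, cr_start + cr_len - 1L)

  with_seed(seed, {
    # sample coding codons from non-stop codons so the reference ORF is open
    codons <- names(Biostrings::GENETIC_CODE)
    codons <- codons[Biostrings::GENETIC_CODE != "*"]
    seq_chars <- strsplit(random_dna(length), "", fixed = TRUE)[[1]]
    coding <- strsplit(paste(sample(codons, cr_len / 3L, replace = TRUE),
                             collapse = ""), "", fixed = TRUE)[[1]]
    seq_chars[cr[1]:cr[2]] <- coding
    ref_seq <- paste(seq_chars, collapse = "")

    fe <- pick_synonymous_fixed_edits(ref_seq, cr, cut_site, n_fixed_edits)
    excl <- if (n_excluded > 0L) {
      sort(sample(setdiff(seq(er[1], er[2]), fe$pos), n_excluded))
    } else integer()

    sge_target(target_id = target_id, ref_seq = ref_seq,
               edited_region = er, fixed_edits = fe, cut_site = cut_site,
               coding_region = cr, genomic_offset = genomic_offset,
               exon_label = exon_label, excluded_positions = excl)
  })
}

# Choose n synonymous single-base substitutions at codon wobble positions,
# preferring positions close to the cut site (they exist to block recutting).
pick_synonymous_fixed_edits <- function(ref_seq, coding_region, cut_site, n) {
  cand <- list()
  for (codon_i in seq_len((coding_region[2] - coding_region[1] + 1L) %/% 3L)) {
    p0 <- coding_region[1] + (codon_i - 1L) * 3L
    codon <- substring(ref_seq, p0, p0 + 2L)
    aa <- translate_codon(codon)
    for (off in 0:2) {
      pos <- p0 + off
      ref <- str_at(ref_seq, pos)
      for (alt in setdiff(DNA_BASES, ref)) {
        alt_codon <- codon
        substring(alt_codon, off + 1L, off + 1L) <- alt
        if (identical(translate_codon(alt_codon), aa)) {
          cand[[length(cand) + 1L]] <- data.frame(
            pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
        }
      }
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) < n) {
    stop("could not find enough synonymous fixed-edit sites")
  }
  cand <- cand[order(abs(cand$pos - cut_site)), ]
  cand <- cand[!duplicated(cand$pos), ]
  if (nrow(cand) < n) stop("could not find enough distinct fixed-edit positions")
  fe <- cand[seq_len(n), c("pos", "ref", "alt")]
  fe <- fe[order(fe$pos), ]
  rownames(fe) <- NULL
  fe
}

#' Enumerate all programmed variants of a target
#'
#' Three SNVs per edited-region base (relative to the edited reference,
#' i.e. the repair-template backbone carrying the fixed edits) and one
#' 3-bp deletion per start position fully contained in the edited region.
#' Molecular consequences are assigned from the target's coding frame:
#' coding SNVs are translated (synonymous / missense / stop_gained /
#' stop_lost / start_lost), non-coding edited-region positions become
#' canonical_splice (1-2 nt from the coding boundary), splice_region
#' (3-8 nt) or intron; 3-bp deletions are inframe_deletion.
#'
#' @param target An `sge_target`.
#' @return Data frame of class `sge_variants` with one row per variant:
#'   `variant_id`, `vtype` ("snv"/"del3"), `pos`, `ref_allele`,
#'   `alt_allele`, `consequence`, `aa_change`, `exon_label`, `position`
#'   (genomic smoothing coordinate), `canonical` / `canonical_id`
#'   (deletions yielding a read sequence identical to an earlier start
#'   are aliases of the leftmost, canonical one).
#' @export
enumerate_variants <- function(target) {
  stopifnot(inherits(target, "sge_target"))
  er <- target$edited_region
  edited <- target$edited_ref_seq
  rows <- vector("list", 0L)

  for (pos in seq(er[1], er[2])) {
    ref <- str_at(edited, pos)
    for (alt in setdiff(DNA_BASES, ref)) {
      ann <- annotate_snv(target, pos, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = snv_id(target, pos, ref, alt),
        vtype = "snv", pos = pos, ref_allele = ref, alt_allele = alt,
        consequence = ann$consequence, aa_change = ann$aa_change,
        stringsAsFactors = FALSE)
    }
  }
  for (pos in seq(er[1], er[2] - 2L)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = del3_id(target, pos),
      vtype = "del3", pos = pos,
      ref_allele = substring(edited, pos, pos + 2L), alt_allele = "",
      consequence = "inframe_deletion", aa_change = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$exon_label <- target$exon_label
  out$position <- target$genomic_offset + out$pos - 1L

  # Deletions in repeat contexts can yield identical read sequences from
  # different start positions; mark the leftmost of each equivalence set
  # as canonical (read calling left-aligns, so only canonical deletions
  # are distinguishable at the read level).
  res_seq <- vapply(seq_len(nrow(out)), function(i) {
    variant_sequence(target, out[i, ])
  }, character(1))
  first <- match(res_seq, res_seq)
  out$canonical <- first == seq_along(first)
  out$canonical_id <- out$variant_id[first]

  # SNVs programmed on top of a fixed edit destroy the HDR marker, so
  # their reads always fail the all-fixed-edits rule: uncallable by design
  out$callable <- !(out$vtype == "snv" & out$pos %in% target$fixed_edits$pos)

  class(out) <- c("sge_variants", "data.frame")
  out
}

snv_id <- function(target, pos, ref, alt) {
  sprintf("%s:c.%d%s>%s", target$target_id, pos, ref, alt)
}

del3_id <- function(target, pos) {
  sprintf("%s:c.%d_%ddel", target$target_id, pos, pos + 2L)
}

# Molecular consequence of a single-base substitution, relative to the
# edited reference and the target's coding frame.
annotate_snv <- function(target, pos, alt) {
  cr <- target$coding_region
  if (pos < cr[1] || pos > cr[2]) {
    d <- min(abs(pos - cr[1]), abs(pos - cr[2]))
    cons <- if (d <= 2L) "canonical_splice" else if (d <= 8L) "splice_region" else "intron"
    return(list(consequence = cons, aa_change = ""))
  }
  codon_i <- (pos - cr[1]) %/% 3L
  p0 <- cr[1] + codon_i * 3L
  codon <- substring(target$edited_ref_seq, p0, p0 + 2L)
  alt_codon <- codon
  substring(alt_codon, pos - p0 + 1L, pos - p0 + 1L) <- alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  cons <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "stop_gained"
  } else if (aa_ref == "*") {
    "stop_lost"
  } else if (codon_i == 0L && aa_ref == "M") {
    "start_lost"
  } else {
    "missense"
  }
  aa_change <- if (cons == "synonymous") {
    sprintf("p.%s%d=", aa_three(aa_ref), codon_i + 1L)
  } else {
    sprintf("p.%s%d%s", aa_three(aa_ref), codon_i + 1L, aa_three(aa_alt))
  }
  list(consequence = cons, aa_change = aa_change)
}

#' Sequence of a read carrying one programmed variant
#'
#' Applies a programmed SNV or 3-bp deletion to the edited reference
#' sequence (the repair-template backbone including all fixed edits).
#'
#' @param target An `sge_target`.
#' @param variant One row of the [enumerate_variants()] table (or a list
#'   with `vtype`, `pos`, `alt_allele`).
#' @return Character string: the expected merged-read sequence.
#' @export
variant_sequence <- function(target, variant) {
  s <- target$edited_ref_seq
  if (variant$vtype == "snv") {
    substring(s, variant$pos, variant$pos) <- variant$alt_allele
    s
  } else {
    paste0(substring(s, 1L, variant$pos - 1L),
           substring(s, variant$pos + 3L, nchar(s)))
  }
}
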