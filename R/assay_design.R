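#' Primer/probe set for one duplex target
#'
#' @param name Assay name.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param probe Optional hydrolysis probe sequence.
#' @param declared_amplicon_bp Optional expected amplicon size.
#' @return An object of class `oligo_set`. Sequences are stored uppercase;
#'   the alphabet is restricted to IUPAC DNA codes.
#' @export
oligo_set <- function(name, forward, reverse, probe = NULL,
                      declared_amplicon_bp = NULL) {
  check_seq <- function(s, what) {
    s <- toupper(gsub("\\s", "", s))
    if (nchar(s) == 0) stop(what, " sequence is empty", call. = FALSE)
    if (grepl("[^ACGTRYSWKMBDHVN]", s))
      stop(what, " contains non-IUPAC characters", call. = FALSE)
    s
  }
  structure(
    list(name = name,
         forward = check_seq(forward, "forward"),
         reverse = check_seq(reverse, "reverse"),
         probe = if (!is.null(probe)) check_seq(probe, "probe"),
         declared_amplicon_bp = declared_amplicon_bp),
    class = "oligo_set"
  )
}

#' Bundled duplex RT-ddPCR oligo sets
#'
#' The cifA, cifB and beta-Spectrin primer/probe sets used by the duplex
#' assays this package analyzes, with their expected amplicon sizes.
#'
#' @return A named list of [oligo_set()]s (`cifA`, `cifB`, `bspec`).
#' @export
cif_oligo_sets <- function() {
  list(
    cifA = oligo_set("cifA_dd",
                     forward = "GGTCCTTGGAATAATTTGCGG",
                     reverse = "TCAAACTCAGACTGTGGGC",
                     probe = "TTGCCACTTGATGGTTCTGGTGA",
                     declared_amplicon_bp = 83),
    cifB = oligo_set("cifB_dd",
                     forward = "GCAAGGTACTAGAGCACAGG",
                     reverse = "CACGAGCGTTGTTTCTACG",
                     probe = "AGGTGGTACTTCTACAGCACAAGG",
                     declared_amplicon_bp = 122),
    bspec = oligo_set("bSpec_dd",
                      forward = "ATGACGACGGACATTTCGATTG",
                      reverse = "AACAGTCGGGAACTGGAGTTG",
                      probe = "GGTCCTGGCAACGAGTACATCGAT",
                      declared_amplicon_bp = 107)
  )
}

#' Oligo design-rule thresholds
#'
#' The design windows used for the cif duplex assays: primer length 18-22
#' nt, amplicon 70-150 bp, primer GC 40-60%, a 2-base 3' GC clamp, primer
#' Tm 58-62 °C with at most 2 °C difference within a pair, and poly-X runs
#' of at most 3; probes 18-30 nt, Tm 65-70 °C, GC 30-80%, poly-X at most 5.
#'
#' @param primer_len,amplicon_len,primer_gc,primer_tm,probe_len,probe_tm,probe_gc
#'   Length-2 numeric `c(min, max)` windows.
#' @param gc_clamp Number of 3'-terminal bases required to be G or C.
#' @param max_tm_diff Maximum |Tm difference| between paired primers, °C.
#' @param primer_max_polyx,probe_max_polyx Longest allowed run of identical
#'   consecutive nucleotides.
#' @return An object of class `oligo_constraints`.
#' @export
oligo_constraints <- function(primer_len = c(18, 22),
                              amplicon_len = c(70, 150),
                              primer_gc = c(40, 60),
                              gc_clamp = 2,
                              primer_tm = c(58, 62),
                              max_tm_diff = 2,
                              primer_max_polyx = 3,
                              probe_len = c(18, 30),
                              probe_tm = c(65, 70),
                              probe_gc = c(30, 80),
                              probe_max_polyx = 5) {
  windows <- list(primer_len, amplicon_len, primer_gc, primer_tm,
                  probe_len, probe_tm, probe_gc)
  if (any(vapply(windows, function(w) w[1] >= w[2], logical(1))))
    stop("all constraint intervals must be non-degenerate", call. = FALSE)
  structure(
    list(primer_len = primer_len, amplicon_len = amplicon_len,
         primer_gc = primer_gc, gc_clamp = gc_clamp,
         primer_tm = primer_tm, max_tm_diff = max_tm_diff,
         primer_max_polyx = primer_max_polyx,
         probe_len = probe_len, probe_tm = probe_tm,
         probe_gc = probe_gc, probe_max_polyx = probe_max_polyx),
    class = "oligo_constraints"
  )
}

gc_percent <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

max_polyx_run <- function(seq) {
  max(rle(strsplit(toupper(seq), "")[[1]])$lengths)
}

#' Design-rule QC report for an oligo set
#'
#' Evaluates each design rule against the measured property of each oligo
#' and reports rule, measured value, bounds and verdict. Rules whose
#' measurement is impossible (e.g. the Tm of an oligo containing ambiguous
#' bases, or amplicon size without a template) are marked not evaluable
#' (`pass = NA`). Verdicts are invariant to the case of the input
#' sequences.
#'
#' @param oligos An [oligo_set()].
#' @param constraints An [oligo_constraints()].
#' @param conditions A [thermo_conditions()] for Tm rules.
#' @param template Optional template DNA (character) for the
#'   amplicon-length rule, checked via [insilico_pcr()].
#' @return A tibble: `oligo`, `rule`, `measured`, `lower`, `upper`,
#'   `pass`.
#' @export
oligo_qc <- function(oligos, constraints = oligo_constraints(),
                     conditions = thermo_conditions(), template = NULL) {
  stopifnot(inherits(oligos, "oligo_set"),
            inherits(constraints, "oligo_constraints"))
  rows <- list()
  add <- function(oligo, rule, measured, lower, upper,
                  pass = is.finite(measured) && measured >= lower && measured <= upper) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      oligo = oligo, rule = rule, measured = measured,
      lower = lower, upper = upper, pass = pass)
  }
  safe_tm <- function(seq, conc) {
    tryCatch(as.numeric(melting_temperature(seq, conditions, conc)),
             error = function(e) NA_real_)
  }

  primer_tms <- c(forward = NA_real_, reverse = NA_real_)
  for (side in c("forward", "reverse")) {
    s <- oligos[[side]]
    add(side, "length_nt", nchar(s),
        constraints$primer_len[1], constraints$primer_len[2])
    add(side, "gc_percent", gc_percent(s),
        constraints$primer_gc[1], constraints$primer_gc[2])
    clamp <- substr(s, nchar(s) - constraints$gc_clamp + 1, nchar(s))
    n_gc <- sum(strsplit(clamp, "")[[1]] %in% c("G", "C"))
    add(side, "gc_clamp_3prime", n_gc, constraints$gc_clamp, Inf,
        pass = n_gc >= constraints$gc_clamp)
    add(side, "max_polyx_run", max_polyx_run(s), 1, constraints$primer_max_polyx)
    tm <- safe_tm(s, conditions$primer_conc_nM)
    primer_tms[side] <- tm
    add(side, "tm_c", tm, constraints$primer_tm[1], constraints$primer_tm[2],
        pass = if (is.na(tm)) NA else
          tm >= constraints$primer_tm[1] && tm <= constraints$primer_tm[2])
  }
  dtm <- abs(primer_tms["forward"] - primer_tms["reverse"])
  add("pair", "tm_diff_c", unname(dtm), 0, constraints$max_tm_diff,
      pass = if (is.na(dtm)) NA else dtm <= constraints$max_tm_diff)

  if (!is.null(oligos$probe)) {
    s <- oligos$probe
    add("probe", "length_nt", nchar(s),
        constraints$probe_len[1], constraints$probe_len[2])
    add("probe", "gc_percent", gc_percent(s),
        constraints$probe_gc[1], constraints$probe_gc[2])
    add("probe", "max_polyx_run", max_polyx_run(s), 1, constraints$probe_max_polyx)
    tm <- safe_tm(s, conditions$probe_conc_nM)
    add("probe", "tm_c", tm, constraints$probe_tm[1], constraints$probe_tm[2],
        pass = if (is.na(tm)) NA else
          tm >= constraints$probe_tm[1] && tm <= constraints$probe_tm[2])
  }

  if (!is.null(template)) {
    products <- insilico_pcr(template, oligos$forward, oligos$reverse)
    amp <- if (nrow(products) == 1) products$length else NA_real_
    add("pair", "amplicon_bp", amp,
        constraints$amplicon_len[1], constraints$amplicon_len[2],
        pass = if (is.na(amp)) NA else
          amp >= constraints$amplicon_len[1] && amp <= constraints$amplicon_len[2])
  }

  do.call(rbind, rows)
}

#' In-silico PCR: predict amplicons of a primer pair on a template
#'
#' Finds forward-primer matches on the plus strand and reverse-primer
#' matches (as the reverse complement) downstream of them; the amplicon
#' length is the inclusive span from the forward primer's 5' end to the
#' reverse primer's 5' end on its own strand, so both primers are counted.
#' Coordinates are 1-based inclusive on the template's plus strand.
#'
#' The default is exact matching. A mismatch-tolerant mode
#' (`max_mismatch` up to 2, with the 3'-terminal 3 bases of each primer
#' required to match exactly) is provided for cross-strain checks.
#'
#' @param template Template DNA (character or `DNAString`).
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_mismatch Allowed mismatches per primer (0-2); 3' 3 bases
#'   must always match exactly.
#' @param size_window `c(min, max)` product-size filter in bp.
#' @return A tibble (`start`, `end`, `length`) of products sorted by
#'   start; empty (zero rows) when there is no product.
#' @export
insilico_pcr <- function(template, forward, reverse,
                         max_mismatch = 0, size_window = c(40, 5000)) {
  fwd <- toupper(gsub("\\s", "", forward))
  rev <- toupper(gsub("\\s", "", reverse))
  tpl <- Biostrings::DNAString(toupper(gsub("\\s", "", as.character(template))))
  if (length(tpl) < nchar(fwd) + nchar(rev))
    stop("template shorter than the combined primer length", call. = FALSE)
  if (max_mismatch < 0 || max_mismatch > 2)
    stop("max_mismatch must be 0, 1 or 2", call. = FALSE)

  three_prime_ok <- function(hit_seq, primer, at_start) {
    # 3' end of fwd = last 3 bases of the plus-strand match;
    # 3' end of rev = first 3 bases of its reverse-complement match.
    k <- min(3, nchar(primer))
    if (at_start) substr(hit_seq, 1, k) == substr(primer, 1, k)
    else substr(hit_seq, nchar(primer) - k + 1, nchar(primer)) ==
      substr(primer, nchar(primer) - k + 1, nchar(primer))
  }

  fwd_hits <- Biostrings::matchPattern(fwd, tpl, max.mismatch = max_mismatch)
  rc_rev <- revcomp_chr(rev)
  rev_hits <- Biostrings::matchPattern(rc_rev, tpl, max.mismatch = max_mismatch)

  keep_f <- vapply(seq_along(fwd_hits), function(i)
    three_prime_ok(as.character(fwd_hits[[i]]), fwd, at_start = FALSE),
    logical(1))
  keep_r <- vapply(seq_along(rev_hits), function(i)
    three_prime_ok(as.character(rev_hits[[i]]), rc_rev, at_start = TRUE),
    logical(1))

  f_start <- Biostrings::start(fwd_hits)[keep_f]
  f_end <- Biostrings::end(fwd_hits)[keep_f]
  r_start <- Biostrings::start(rev_hits)[keep_r]
  r_end <- Biostrings::end(rev_hits)[keep_r]

  out <- list()
  for (i in seq_along(f_start)) {
    for (j in seq_along(r_start)) {
      if (r_start[j] > f_end[i]) {
        len <- r_end[j] - f_start[i] + 1
        if (len >= size_window[1] && len <= size_window[2])
          out[[length(out) + 1L]] <- tibble::tibble(
            start = f_start[i], end = r_end[j], length = len)
      }
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' N-masked consensus of an alignment
#'
#' Column-wise consensus used for oligo design against variable targets:
#' a column contributes its shared residue when all non-gap residues
#' agree, an `N` when two or more residue states occur, and is dropped
#' when gaps form the majority of the column (minority gaps are ignored
#' for the residue comparison). Idempotent on its own output when `N` is
#' treated as a variable site.
#'
#' @param alignment Character vector (or `DNAStringSet`) of >= 2 aligned
#'   sequences of equal length; `-` marks gaps.
#' @return The consensus as a single character string.
#' @export
consensus_with_n <- function(alignment) {
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 2)
    stop("need at least 2 aligned sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  cols <- apply(mat, 2, function(col) {
    n_gap <- sum(col == "-")
    if (n_gap > length(col) / 2) return(NA_character_)  # drop column
    res <- unique(col[col != "-"])
    if (length(res) == 1) res else "N"
  })
  paste(cols[!is.na(cols)], collapse = "")
}

#' Filter per-gene alignments by frame-safe gap structure
#'
#' Retains a gene only when (a) every gap run in every sequence has a
#' length divisible by three (no frameshifts) and (b) at most one sample
#' contains any gap; genes failing either rule are dropped with a reason.
#'
#' @param gene_alignments Named list; each element is a character vector
#'   (or `DNAStringSet`) holding one gene's equal-length alignment across
#'   samples.
#' @return A list: `retained` (character vector of gene names) and
#'   `dropped` (tibble `gene`, `reason`).
#' @export
filter_alignment_genes <- function(gene_alignments) {
  stopifnot(length(gene_alignments) >= 1, !is.null(names(gene_alignments)))
  retained <- character()
  dropped <- list()
  for (g in names(gene_alignments)) {
    seqs <- toupper(as.character(gene_alignments[[g]]))
    if (length(unique(nchar(seqs))) != 1)
      stop("gene ", g, ": ragged alignment", call. = FALSE)
    gap_runs_ok <- vapply(seqs, function(s) {
      r <- rle(strsplit(s, "")[[1]] == "-")
      gaps <- r$lengths[r$values]
      length(gaps) == 0 || all(gaps %% 3 == 0)
    }, logical(1))
    n_gapped <- sum(vapply(seqs, function(s) grepl("-", s, fixed = TRUE),
                           logical(1)))
    if (!all(gap_runs_ok)) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        gene = g, reason = "gap run length not a multiple of three")
    } else if (n_gapped > 1) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        gene = g, reason = "gaps in more than one sample")
    } else {
      retained <- c(retained, g)
    }
  }
  list(retained = retained,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else tibble::tibble(gene = character(), reason = character()))
}
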