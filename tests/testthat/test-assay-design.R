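test_that("N-masked consensus follows the column rules", {
  expect_equal(consensus_with_n(c("ACGT", "ACGT")), "ACGT")
  expect_equal(consensus_with_n(c("ACGT", "ACTT")), "ACNT")
  # one gap, one residue state in column 3 -> residue retained
  expect_equal(consensus_with_n(c("ACGT", "AC-T", "ACGT")), "ACGT")
  # gap-majority column dropped
  expect_equal(consensus_with_n(c("A-GT", "A-GT", "ACGT")), "AGT")
  # idempotent on its own output (N treated as just another state)
  cons <- consensus_with_n(c("ACGTA", "ACTTA"))
  expect_equal(consensus_with_n(c(cons, cons)), cons)
  expect_error(consensus_with_n(c("ACG", "ACGT")), "equal length")
})

test_that("nearest-neighbor Tm matches the frozen independent oracle", {
  # oracle values computed with an independent nearest-neighbor
  # implementation (unified parameter table, 0.368 ln[Na+] entropy salt
  # correction, 120*sqrt(divalent - dNTP) monovalent equivalent)
  cond <- thermo_conditions() # 50/3/0.8 mM, 900 nM primers
  p3 <- primer3_conditions()  # 50/1.5/0.6 mM, 50 nM oligos
  expect_equal(as.numeric(melting_temperature("AGCTTGCAACGGTCATAGGC", cond)),
               66.8286, tolerance = 0.01)
  expect_equal(as.numeric(melting_temperature("AGCTTGCAACGGTCATAGGC", p3, 50)),
               61.0267, tolerance = 0.01)
  expect_equal(as.numeric(melting_temperature("GGTCCTTGGAATAATTTGCGG", cond)),
               63.1445, tolerance = 0.01)
  expect_equal(as.numeric(melting_temperature("GGTCCTTGGAATAATTTGCGG", p3, 50)),
               57.5633, tolerance = 0.01)
  expect_equal(as.numeric(melting_temperature("ATGACGACGGACATTTCGATTG", p3, 50)),
               59.3969, tolerance = 0.01)
})

test_that("Tm is monotone in oligo concentration and rejects bad input", {
  cond <- thermo_conditions()
  t1 <- as.numeric(melting_temperature("AGCTTGCAACGGTCATAGGC", cond, 450))
  t2 <- as.numeric(melting_temperature("AGCTTGCAACGGTCATAGGC", cond, 900))
  expect_gt(t2, t1)
  expect_error(melting_temperature("ACGTNNN", cond), "8 nt")
  expect_error(melting_temperature("ACGTNACGTN", cond), "ambiguous")
})

test_that("oligo QC applies the design rules to the bundled sets", {
  sets <- cif_oligo_sets()
  rep_a <- oligo_qc(sets$cifA, conditions = primer3_conditions())
  get <- function(rep, oligo, rule) rep[rep$oligo == oligo & rep$rule == rule, ]
  # cifA forward: length 21 in [18,22]; poly-X run 3 (TTT) allowed; GG clamp
  expect_equal(get(rep_a, "forward", "length_nt")$measured, 21)
  expect_true(get(rep_a, "forward", "length_nt")$pass)
  expect_equal(get(rep_a, "forward", "max_polyx_run")$measured, 3)
  expect_true(get(rep_a, "forward", "max_polyx_run")$pass)
  expect_true(get(rep_a, "forward", "gc_clamp_3prime")$pass)

  # beta-Spec forward ends in TG: one non-G/C base in the 2-base clamp
  rep_b <- oligo_qc(cif_oligo_sets()$bspec, conditions = primer3_conditions())
  expect_false(get(rep_b, "forward", "gc_clamp_3prime")$pass)

  # 17-mer primer fails the length window
  short <- oligo_set("short", "ACGTTGCAACGGTCATG", "AGCTTGCAACGGTCATAGGC")
  rep_s <- oligo_qc(short, conditions = primer3_conditions())
  expect_false(get(rep_s, "forward", "length_nt")$pass)

  # verdicts invariant to sequence case
  lower <- oligo_set("lc", tolower(sets$cifA$forward), tolower(sets$cifA$reverse),
                     tolower(sets$cifA$probe))
  rep_l <- oligo_qc(lower, conditions = primer3_conditions())
  expect_equal(rep_l$pass, rep_a$pass)
})

test_that("in-silico PCR sizes constructed and bundled templates correctly", {
  sets <- cif_oligo_sets()
  # constructed concatenation: fwd + 60 A + revcomp(rev)
  os <- sets$cifA
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(os$reverse)))
  tpl <- paste0(os$forward, strrep("A", 60), rc)
  res <- insilico_pcr(tpl, os$forward, os$reverse)
  expect_equal(nrow(res), 1)
  expect_equal(res$length, nchar(os$forward) + 60 + nchar(os$reverse))

  # bundled synthetic beta-Spec template: single 107 bp product
  fa <- Biostrings::readDNAStringSet(
    system.file("extdata", "bspec_template_synthetic.fasta", package = "cifquant"))
  res <- insilico_pcr(as.character(fa[[1]]), sets$bspec$forward, sets$bspec$reverse)
  expect_equal(nrow(res), 1)
  expect_equal(res$length, 107)
  expect_equal(res$length, sets$bspec$declared_amplicon_bp)

  # the declared size arises for any embedding at the declared spacing
  for (pad in c(0, 17, 133)) {
    spacer <- 107 - nchar(sets$bspec$forward) - nchar(sets$bspec$reverse)
    rc_b <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sets$bspec$reverse)))
    t2 <- paste0(strrep("G", pad), sets$bspec$forward, strrep("C", spacer), rc_b)
    expect_equal(insilico_pcr(t2, sets$bspec$forward, sets$bspec$reverse)$length, 107)
  }

  # primer present twice -> two products sorted by start
  t3 <- paste0(os$forward, strrep("A", 30), rc, strrep("T", 10),
               os$forward, strrep("A", 50), rc)
  res3 <- insilico_pcr(t3, os$forward, os$reverse, size_window = c(40, 120))
  expect_gte(nrow(res3), 2)
  expect_true(!is.unsorted(res3$start))

  # no product -> empty tibble, not an error
  expect_equal(nrow(insilico_pcr(strrep("ACGT", 30), os$forward, os$reverse)), 0)
  expect_error(insilico_pcr("ACGT", os$forward, os$reverse), "shorter")
})

test_that("mismatch-tolerant mode respects the 3-prime anchor", {
  os <- cif_oligo_sets()$cifA
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(os$reverse)))
  # one internal mismatch in the forward site: found only with tolerance
  fwd_mut <- os$forward
  substr(fwd_mut, 5, 5) <- if (substr(fwd_mut, 5, 5) == "A") "C" else "A"
  tpl <- paste0(fwd_mut, strrep("A", 60), rc)
  expect_equal(nrow(insilico_pcr(tpl, os$forward, os$reverse)), 0)
  expect_equal(nrow(insilico_pcr(tpl, os$forward, os$reverse, max_mismatch = 1)), 1)
  # a 3'-terminal mismatch is never tolerated
  fwd_3p <- os$forward
  substr(fwd_3p, nchar(fwd_3p), nchar(fwd_3p)) <- "A" # GG clamp -> GA
  tpl3 <- paste0(fwd_3p, strrep("A", 60), rc)
  expect_equal(nrow(insilico_pcr(tpl3, os$forward, os$reverse, max_mismatch = 2)), 0)
})

test_that("gene alignments are filtered by frame-safe gap structure", {
  genes <- list(
    ok_one_gap = c("ATG---CCC", "ATGAAACCC", "ATGAAACCC"),
    frameshift = c("ATGA--CCC", "ATGAAACCC", "ATGAAACCC"),
    two_gapped = c("ATG---CCC", "ATG---CCC", "ATGAAACCC"),
    clean = c("ATGAAACCC", "ATGAAACCC", "ATGAAACCC")
  )
  res <- filter_alignment_genes(genes)
  expect_setequal(res$retained, c("ok_one_gap", "clean"))
  expect_equal(res$dropped$reason[res$dropped$gene == "frameshift"],
               "gap run length not a multiple of three")
  expect_equal(res$dropped$reason[res$dropped$gene == "two_gapped"],
               "gaps in more than one sample")
  expect_error(filter_alignment_genes(list(bad = c("ACG", "ACGT"))), "ragged")
})
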