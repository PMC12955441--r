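#' Thermodynamic conditions for melting-temperature calculations
#'
#' Ion, dNTP and oligo concentrations used by [melting_temperature()] and
#' [oligo_qc()]. The default reflects the assembled ddPCR reaction: 50 mM
#' monovalent salt, 3 mM divalent cation, 0.8 mM total dNTP, and the
#' 900 nM primer / 250 nM probe concentrations of the premixed oligo sets.
#' [primer3_conditions()] gives the design-time convention instead
#' (50 mM / 1.5 mM / 0.6 mM, 50 nM oligo), which is what primer-design
#' windows such as 58-62 °C conventionally refer to.
#'
#' @param monovalent_mM,divalent_mM,dntp_mM Concentrations in mM; all
#'   >= 0. Divalent cations are converted to a monovalent equivalent via
#'   `Na_eq = monovalent + 120 * sqrt(max(0, divalent - dNTP))`.
#' @param primer_conc_nM,probe_conc_nM Oligo concentrations in nM.
#' @return An object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(monovalent_mM = 50, divalent_mM = 3,
                              dntp_mM = 0.8, primer_conc_nM = 900,
                              probe_conc_nM = 250) {
  vals <- c(monovalent_mM, divalent_mM, dntp_mM, primer_conc_nM, probe_conc_nM)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all thermodynamic conditions must be finite and >= 0", call. = FALSE)
  structure(
    list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
         dntp_mM = dntp_mM, primer_conc_nM = primer_conc_nM,
         probe_conc_nM = probe_conc_nM),
    class = "thermo_conditions"
  )
}

#' @rdname thermo_conditions
#' @export
primer3_conditions <- function() {
  thermo_conditions(monovalent_mM = 50, divalent_mM = 1.5, dntp_mM = 0.6,
                    primer_conc_nM = 50, probe_conc_nM = 50)
}

# Unified nearest-neighbor parameters (duplex DNA):
# dH in kcal/mol, dS in cal/(mol K).
nn_table <- list(
  AA = c(-7.9, -22.2), TT = c(-7.9, -22.2),
  AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
  GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
  CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
  GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
  CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9), CC = c(-8.0, -19.9)
)
nn_init_gc <- c(0.1, -2.8)   # per G/C terminus
nn_init_at <- c(2.3, 4.1)    # per A/T terminus

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic model: stacking dH/dS sums plus terminal initiation
#' terms, `Tm = dH / (dS_salt + R ln(C_T / 4)) - 273.15` with
#' `R = 1.987 cal/(mol K)` and the symmetric-duplex convention `C_T / 4`
#' for the strand concentration. Salt enters through the entropy
#' correction `dS_salt = dS + 0.368 (N - 1) ln[Na_eq]` (N = sequence
#' length), with divalent cations and dNTPs folded into a monovalent
#' equivalent `Na_eq = monovalent + 120 sqrt(max(0, divalent - dNTP))`
#' (all mM).
#'
#' @param seq DNA sequence, 5'->3', unambiguous A/C/G/T only, length >= 8.
#'   Ambiguous (IUPAC) bases are rejected; QC callers report such oligos
#'   as not evaluable.
#' @param conditions A [thermo_conditions()].
#' @param oligo_conc_nM Total oligo concentration C_T in nM; defaults to
#'   the primer concentration in `conditions`.
#' @return Tm in °C, with attributes recording `Na_eq_mM` and the
#'   parameter-set label.
#' @export
melting_temperature <- function(seq, conditions = thermo_conditions(),
                                oligo_conc_nM = conditions$primer_conc_nM) {
  stopifnot(inherits(conditions, "thermo_conditions"))
  s <- toupper(gsub("\\s", "", seq))
  if (nchar(s) < 8)
    stop("sequence must be at least 8 nt for a nearest-neighbor Tm",
         call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop("ambiguous or non-DNA bases: nearest-neighbor Tm not evaluable",
         call. = FALSE)
  bases <- strsplit(s, "")[[1]]
  n <- length(bases)

  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    par <- nn_table[[paste0(bases[i], bases[i + 1])]]
    dh <- dh + par[1]; ds <- ds + par[2]
  }
  for (term in c(bases[1], bases[n])) {
    init <- if (term %in% c("G", "C")) nn_init_gc else nn_init_at
    dh <- dh + init[1]; ds <- ds + init[2]
  }
  if (s == revcomp_chr(s)) ds <- ds - 1.4  # self-complementary symmetry

  na_eq_mM <- conditions$monovalent_mM +
    120 * sqrt(max(0, conditions$divalent_mM - conditions$dntp_mM))
  if (na_eq_mM <= 0) stop("effective monovalent salt must be > 0", call. = FALSE)
  ds_salt <- ds + 0.368 * (n - 1) * log(na_eq_mM / 1000)

  ct <- oligo_conc_nM * 1e-9
  tm <- dh * 1000 / (ds_salt + 1.987 * log(ct / 4)) - 273.15
  structure(tm, Na_eq_mM = na_eq_mM,
            parameters = "unified nearest-neighbor (1998), 0.368 ln[Na+] entropy salt correction")
}
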