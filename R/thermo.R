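# Oligo thermodynamics: GC fraction, homopolymer runs, and duplex melting
# temperature by the unified nearest-neighbor model.

#' Thermodynamic filter configuration
#'
#' Houses every free parameter of the thermodynamic filtering stage. Defaults
#' follow the hybridization conditions of the wet protocol this designer
#' serves: 5x SSC (0.75 M monovalent Na+), 30% formamide, 10 nM probe.
#'
#' @param na_molar Monovalent cation concentration in mol/L (default 0.75,
#'   i.e. 5x SSC).
#' @param formamide_pct Volume percent formamide (default 30). Applied as a
#'   linear Tm depression of 0.6 degrees C per percent.
#' @param oligo_conc_molar Total probe strand concentration in mol/L
#'   (default 1e-8, i.e. 10 nM).
#' @param tm_min_c,tm_max_c Accepted per-arm melting-temperature window in
#'   degrees C, evaluated after the formamide correction (default 40-60).
#' @param gc_min,gc_max Accepted per-arm GC fraction window (default
#'   0.35-0.65).
#' @param max_run Maximum allowed homopolymer run length in nt (default 4).
#' @return A `ThermoConfig` list.
#' @export
thermo_config <- function(na_molar = 0.75, formamide_pct = 30,
                          oligo_conc_molar = 1e-8,
                          tm_min_c = 40, tm_max_c = 60,
                          gc_min = 0.35, gc_max = 0.65, max_run = 4L) {
  stopifnot(
    is.numeric(na_molar), na_molar > 0,
    is.numeric(formamide_pct), formamide_pct >= 0,
    is.numeric(oligo_conc_molar), oligo_conc_molar > 0
  )
  if (!(tm_min_c < tm_max_c)) stop("tm_min_c must be < tm_max_c", call. = FALSE)
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1)) {
    stop("need 0 <= gc_min < gc_max <= 1", call. = FALSE)
  }
  if (max_run < 1) stop("max_run must be >= 1", call. = FALSE)
  structure(list(
    na_molar = na_molar, formamide_pct = formamide_pct,
    oligo_conc_molar = oligo_conc_molar,
    tm_min_c = tm_min_c, tm_max_c = tm_max_c,
    gc_min = gc_min, gc_max = gc_max, max_run = as.integer(max_run)
  ), class = "ThermoConfig")
}

#' GC fraction of a DNA sequence
#'
#' @param seq Character vector of N-free sequences over `A,C,G,T`.
#' @return Numeric vector of (G + C) / length, in `[0, 1]`.
#' @examples gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(seq) {
  check_acgt(seq)
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  gc / n
}

#' Longest homopolymer run
#'
#' @param seq Character vector of non-empty sequences.
#' @return Integer vector: length of the longest run of one repeated base.
#' @examples max_homopolymer_run("AACCCCGG")  # 4
#' @export
max_homopolymer_run <- function(seq) {
  if (any(!nzchar(seq)) || any(is.na(seq))) stop("empty sequence", call. = FALSE)
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), integer(1L))
}

# Unified nearest-neighbor parameters for DNA:DNA stacks (SantaLucia 1998).
# dH in kcal/mol, dS in cal/(mol K); keyed by the 5'->3' dinucleotide on one
# strand (a stack and its reverse complement share parameters).
.nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation per terminal base pair.
.nn_init_dh <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
.nn_init_ds <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)

.gas_const <- 1.9872  # cal/(mol K)

#' Duplex melting temperature (unified nearest-neighbor model)
#'
#' Computes the DNA:DNA melting temperature of a probe arm against its
#' perfect complement: enthalpy and entropy are summed over stacked
#' nearest-neighbor pairs plus the two initiation terms; the entropy is
#' corrected for monovalent salt (`+0.368 (N-1) ln[Na+]` cal/(mol K)); the
#' two-state Tm is evaluated at total strand concentration
#' `cfg$oligo_conc_molar` for non-self-complementary duplexes (CT/4); and a
#' linear formamide depression of 0.6 degrees C per percent is applied last,
#' as a pure offset.
#'
#' Because a duplex and its reverse complement are the same physical duplex,
#' `melting_temperature(s, cfg) == melting_temperature(revcomp(s), cfg)`
#' exactly.
#'
#' @param seq Character vector of N-free DNA sequences, 8-60 nt.
#' @param cfg A [thermo_config()].
#' @return Numeric vector of melting temperatures in degrees C.
#' @export
melting_temperature <- function(seq, cfg = thermo_config()) {
  check_acgt(seq)
  n <- nchar(seq)
  if (any(n < 8L | n > 60L)) {
    stop("melting_temperature is defined for 8-60 nt sequences; got length ",
         paste(n[n < 8L | n > 60L], collapse = ", "), call. = FALSE)
  }
  vapply(seq, function(s) {
    L <- nchar(s)
    stacks <- substring(s, 1:(L - 1L), 2:L)
    dh <- sum(.nn_dh[stacks]) + .nn_init_dh[[substr(s, 1L, 1L)]] +
      .nn_init_dh[[substr(s, L, L)]]
    ds <- sum(.nn_ds[stacks]) + .nn_init_ds[[substr(s, 1L, 1L)]] +
      .nn_init_ds[[substr(s, L, L)]]
    ds_salt <- ds + 0.368 * (L - 1L) * log(cfg$na_molar)
    tm_k <- dh * 1000 / (ds_salt + .gas_const * log(cfg$oligo_conc_molar / 4))
    tm_k - 273.15 - 0.6 * cfg$formamide_pct
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

check_acgt <- function(seq) {
  if (length(seq) == 0L || any(is.na(seq)) || any(!nzchar(seq))) {
    stop("empty sequence", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", seq))) {
    stop("sequence contains characters outside A,C,G,T (masked 'N' windows must not be scored)",
         call. = FALSE)
  }
  invisible(seq)
}
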