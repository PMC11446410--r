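# Deterministic synthetic fixtures: multi-exon targets in both junction
# conventions, decoy transcriptomes with planted off-target segments, and
# paired 3-D spot fields with a known shared fraction. Every generator is a
# pure function of its FixtureSpec (including the seed) and each emits a
# ground-truth record so downstream tests never reach into generator
# internals.

#' Synthetic fixture specification
#'
#' @param seed RNG seed; the same spec always produces byte-identical
#'   outputs.
#' @param n_exons,exon_lengths Target architecture: `exon_lengths` recycles
#'   to `n_exons`.
#' @param n_decoys,decoy_lengths Decoy transcriptome shape.
#' @param plants List of planted verbatim copies, each
#'   `list(decoy_index=, target_start=, length=)` with `target_start`
#'   0-based on the concatenated (junction-masked) target.
#' @param spot_plan `list(n_shared=, n_a_only=, n_b_only=, jitter_sd_nm=,
#'   box_nm=)`: shared spots are duplicated into both fields with
#'   independent per-axis Gaussian localization jitter; exclusive spots are
#'   independent; all positions uniform in a cube of side `box_nm`.
#' @param gc Base composition of random sequence (default 0.5, uniform).
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_exons = 3L, exon_lengths = 700L,
                         n_decoys = 5L, decoy_lengths = 1500L,
                         plants = list(),
                         spot_plan = list(n_shared = 300L, n_a_only = 100L,
                                          n_b_only = 100L, jitter_sd_nm = 50,
                                          box_nm = 20000),
                         gc = 0.5) {
  exon_lengths <- rep_len(as.integer(exon_lengths), n_exons)
  decoy_lengths <- rep_len(as.integer(decoy_lengths), max(n_decoys, 0L))
  stopifnot(all(exon_lengths > 0L), all(decoy_lengths > 0L),
            gc > 0, gc < 1, spot_plan$jitter_sd_nm >= 0)
  structure(list(seed = as.integer(seed), n_exons = as.integer(n_exons),
                 exon_lengths = exon_lengths, n_decoys = as.integer(n_decoys),
                 decoy_lengths = decoy_lengths, plants = plants,
                 spot_plan = spot_plan, gc = gc),
            class = "FixtureSpec")
}

#' Generate a synthetic multi-exon target in both junction conventions
#'
#' Writes the same gene as a single-record FASTA with `N` junction
#' separators and as a one-record-per-exon FASTA, plus a JSON truth record
#' of the exon bounds.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param gene_id Gene name for headers.
#' @return List with `single_fa`, `exons_fa`, `truth_json`, `truth` (list
#'   with `gene_id`, `sequence`, `exon_bounds`).
#' @export
make_target <- function(spec, dir = tempfile("fixture_"), gene_id = "synthGene") {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exons <- with_fixture_seed(spec$seed, 101L, {
    vapply(spec$exon_lengths, random_dna, character(1L), gc = spec$gc)
  })
  seq <- paste(exons, collapse = "N")
  lens <- nchar(exons)
  starts <- cumsum(c(0L, head(lens, -1L) + 1L))
  bounds <- cbind(start = starts, end = starts + lens)
  target <- new_target_sequence(gene_id, seq, bounds, "single_entry_N")

  single_fa <- file.path(dir, paste0(gene_id, "_single.fa"))
  exons_fa <- file.path(dir, paste0(gene_id, "_exons.fa"))
  write_target(target, single_fa, "single_entry_N")
  write_target(target, exons_fa, "multi_entry_exons")
  truth <- list(gene_id = gene_id, sequence = seq,
                exon_bounds = unname(apply(bounds, 1L, as.list, simplify = FALSE)))
  truth_json <- file.path(dir, paste0(gene_id, "_truth.json"))
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, pretty = TRUE)
  list(single_fa = single_fa, exons_fa = exons_fa, truth_json = truth_json,
       truth = truth, target = target)
}

#' Generate a decoy transcriptome with planted off-target segments
#'
#' Decoys are uniform-random sequence except for verbatim copies of target
#' segments specified in `spec$plants`. The truth record lists, for every
#' plant, the exact set of candidate window starts whose overlap with the
#' planted target interval exceeds `max_contig_match` — computed by interval
#' arithmetic only, independently of any screening code.
#'
#' @param spec A [fixture_spec()].
#' @param target The `TargetSequence` the plants are copied from.
#' @param dir Output directory.
#' @param window_len Candidate window length used for the truth record
#'   (default 52).
#' @param max_contig_match Failing-overlap threshold for the truth record
#'   (default 16).
#' @return List with `fasta`, `truth_json`, and `truth`: per plant the
#'   decoy id, position, copied interval, and `failing_window_starts`
#'   (0-based, restricted to N-free windows).
#' @export
make_transcriptome <- function(spec, target, dir = tempfile("fixture_"),
                               window_len = 52L, max_contig_match = 16L) {
  stopifnot(inherits(spec, "FixtureSpec"), inherits(target, "TargetSequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(target$sequence)
  decoys <- with_fixture_seed(spec$seed, 202L, {
    vapply(spec$decoy_lengths, random_dna, character(1L), gc = spec$gc)
  })
  ids <- sprintf("decoy%02d", seq_along(decoys))
  truth_plants <- list()
  for (p in spec$plants) {
    di <- p$decoy_index
    if (di < 1L || di > length(decoys)) stop("plant decoy_index out of range", call. = FALSE)
    if (p$length > nchar(decoys[di])) {
      stop(sprintf("plant of length %d longer than decoy %d (%d nt)",
                   p$length, di, nchar(decoys[di])), call. = FALSE)
    }
    s <- p$target_start; len <- p$length
    if (s < 0L || s + len > L) stop("plant interval outside target bounds", call. = FALSE)
    segment <- substr(target$sequence, s + 1L, s + len)
    if (grepl("N", segment, fixed = TRUE)) {
      stop("plant interval crosses a masked junction; choose an interval within one exon",
           call. = FALSE)
    }
    pos <- with_fixture_seed(spec$seed, 303L + di, {
      sample.int(nchar(decoys[di]) - len + 1L, 1L) - 1L  # 0-based insert position
    })
    substr(decoys[di], pos + 1L, pos + len) <- segment
    truth_plants[[length(truth_plants) + 1L]] <- list(
      decoy_id = ids[di], decoy_pos = pos, target_start = s, length = len,
      failing_window_starts = failing_starts(target$sequence, s, len,
                                             window_len, max_contig_match)
    )
  }
  names(decoys) <- ids
  fasta <- file.path(dir, "transcriptome.fa")
  Biostrings::writeXStringSet(Biostrings::BStringSet(decoys), fasta)
  truth <- list(window_len = window_len, max_contig_match = max_contig_match,
                plants = truth_plants)
  truth_json <- file.path(dir, "transcriptome_truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, pretty = TRUE)
  list(fasta = fasta, truth_json = truth_json, truth = truth)
}

#' Generate paired 3-D spot fields with a known shared fraction
#'
#' Emulates two detection methods imaging the same sample: `n_shared` true
#' positions appear in both fields, each observed with independent per-axis
#' Gaussian localization jitter, plus method-exclusive spots. The truth
#' record carries the expected directional colocalization fractions
#' (shared / total per field) implied by the plan.
#'
#' @param spec A [fixture_spec()] (its `spot_plan` is used).
#' @param dir Output directory.
#' @return List with `csv_a`, `csv_b`, `truth_json`, and `truth` (counts
#'   and `expected_frac_a_near_b` / `expected_frac_b_near_a`).
#' @export
make_spot_fields <- function(spec, dir = tempfile("fixture_")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pl <- spec$spot_plan
  coords <- with_fixture_seed(spec$seed, 404L, {
    shared <- matrix(stats::runif(3L * pl$n_shared, 0, pl$box_nm), ncol = 3L)
    jit <- function(m) m + matrix(stats::rnorm(length(m), 0, pl$jitter_sd_nm),
                                  ncol = 3L)
    list(
      a = rbind(jit(shared),
                matrix(stats::runif(3L * pl$n_a_only, 0, pl$box_nm), ncol = 3L)),
      b = rbind(jit(shared),
                matrix(stats::runif(3L * pl$n_b_only, 0, pl$box_nm), ncol = 3L))
    )
  })
  write_spots <- function(m, path, sample_id = "sim01") {
    df <- data.frame(sample_id = sample_id,
                     x = round(m[, 1L], 2), y = round(m[, 2L], 2),
                     z = round(m[, 3L], 2))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  csv_a <- write_spots(coords$a, file.path(dir, "spots_a.csv"))
  csv_b <- write_spots(coords$b, file.path(dir, "spots_b.csv"))
  n_a <- pl$n_shared + pl$n_a_only
  n_b <- pl$n_shared + pl$n_b_only
  truth <- list(
    n_shared = pl$n_shared, n_a = n_a, n_b = n_b,
    jitter_sd_nm = pl$jitter_sd_nm, box_nm = pl$box_nm,
    expected_frac_a_near_b = if (n_a > 0) pl$n_shared / n_a else NA_real_,
    expected_frac_b_near_a = if (n_b > 0) pl$n_shared / n_b else NA_real_
  )
  truth_json <- file.path(dir, "spots_truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, pretty = TRUE)
  list(csv_a = csv_a, csv_b = csv_b, truth_json = truth_json, truth = truth)
}

# ---- internal helpers -------------------------------------------------------

# Evaluate expr under a derived seed, restoring the caller's RNG state.
with_fixture_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed * 1000L + stream) %% .Machine$integer.max)
  expr
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Window starts s (0-based) whose overlap with [plant_start, plant_start+len)
# exceeds thr, keeping only N-free windows that fit on the target.
failing_starts <- function(target_seq, plant_start, len, window_len, thr) {
  L <- nchar(target_seq)
  if (L < window_len) return(integer(0L))
  starts <- 0:(L - window_len)
  ov <- pmin(starts + window_len, plant_start + len) - pmax(starts, plant_start)
  wins <- substring(target_seq, starts + 1L, starts + window_len)
  starts[ov > thr & !grepl("N", wins, fixed = TRUE)]
}
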