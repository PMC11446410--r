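# Candidate enumeration, thermodynamic filtering, non-overlapping selection,
# and the end-to-end design pipeline.

.reason_levels <- c("CONTAINS_N", "GC_RANGE", "TM_RANGE", "HOMOPOLYMER", "OFFTARGET")

#' Probe design configuration
#'
#' Geometry follows the canonical HCR v3 split-probe layout: two 25-nt
#' binding arms separated by a 2-nt unbound gap on the target, for a 52-nt
#' candidate window. Every dimension is configurable.
#'
#' @param arm_len Binding-arm length in nt (default 25, minimum 10).
#' @param gap_len Unbound target gap between the two arms in nt (default 2).
#' @param min_inter_probe_gap Minimum nt between consecutive selected
#'   windows (default 2).
#' @param target_pairs Desired number of pairs; 0 means "as many as fit"
#'   (default 0). Required > 0 for `selection_mode = "even_spread"`.
#' @param min_pairs_warn Threshold of the sufficiency rule: designs with
#'   fewer pairs get a `FEWER_THAN_MIN_PAIRS` warning (default 5 — at least
#'   five split-probe pairs are recommended for sufficient signal).
#' @param selection_mode `"max_count"` (maximum number of non-overlapping
#'   probes, greedy earliest-end) or `"even_spread"` (exactly
#'   `min(target_pairs, achievable)` probes maximizing the minimum
#'   inter-window spacing).
#' @param thermo A [thermo_config()].
#' @param offtarget An [offtarget_config()].
#' @return A `DesignConfig` list; `window_len` is derived as
#'   `2 * arm_len + gap_len`.
#' @export
design_config <- function(arm_len = 25L, gap_len = 2L,
                          min_inter_probe_gap = 2L, target_pairs = 0L,
                          min_pairs_warn = 5L,
                          selection_mode = c("max_count", "even_spread"),
                          thermo = thermo_config(),
                          offtarget = offtarget_config()) {
  selection_mode <- match.arg(selection_mode)
  arm_len <- as.integer(arm_len); gap_len <- as.integer(gap_len)
  if (arm_len < 10L) stop("arm_len must be >= 10", call. = FALSE)
  if (gap_len < 0L) stop("gap_len must be >= 0", call. = FALSE)
  if (min_inter_probe_gap < 0L) stop("min_inter_probe_gap must be >= 0", call. = FALSE)
  if (min_pairs_warn < 1L) stop("min_pairs_warn must be >= 1", call. = FALSE)
  stopifnot(inherits(thermo, "ThermoConfig"), inherits(offtarget, "OfftargetConfig"))
  structure(list(
    arm_len = arm_len, gap_len = gap_len,
    window_len = 2L * arm_len + gap_len,
    min_inter_probe_gap = as.integer(min_inter_probe_gap),
    target_pairs = as.integer(target_pairs),
    min_pairs_warn = as.integer(min_pairs_warn),
    selection_mode = selection_mode,
    thermo = thermo, offtarget = offtarget
  ), class = "DesignConfig")
}

#' Enumerate all candidate probe windows along a target
#'
#' Emits one candidate per start position `0 ... L - window_len` so the
#' windows cover the entire target. Windows containing any masked (`N`)
#' position — in particular every window spanning an exon-exon junction —
#' are emitted with verdict fail and reason `CONTAINS_N`; all other windows
#' carry per-arm melting temperature, GC fraction and homopolymer-run
#' annotations.
#'
#' @param target A [read_target()] `TargetSequence`.
#' @param cfg A [design_config()].
#' @return A candidate data frame (one row per window, in start order) with
#'   columns `start`, `end` (0-based half-open), `arm1_seq`, `arm2_seq`,
#'   `tm_arm1_c`, `tm_arm2_c`, `gc_arm1`, `gc_arm2`, `run_arm1`, `run_arm2`,
#'   `verdict`, `fail_reasons`; the full window sequences are kept in the
#'   `window_seq` attribute.
#' @export
enumerate_candidates <- function(target, cfg = design_config()) {
  stopifnot(inherits(target, "TargetSequence"))
  w <- cfg$window_len
  L <- nchar(target$sequence)
  if (L < w) {
    stop(sprintf("target '%s' is %d nt but one probe window needs at least %d nt",
                 target$gene_id, L, w), call. = FALSE)
  }
  starts <- 0:(L - w)                      # 0-based
  wins <- substring(target$sequence, starts + 1L, starts + w)
  arm1 <- substr(wins, 1L, cfg$arm_len)
  arm2 <- substr(wins, cfg$arm_len + cfg$gap_len + 1L, w)
  masked <- grepl("N", wins, fixed = TRUE)

  n <- length(starts)
  cands <- data.frame(
    start = starts, end = starts + w,
    arm1_seq = arm1, arm2_seq = arm2,
    tm_arm1_c = NA_real_, tm_arm2_c = NA_real_,
    gc_arm1 = NA_real_, gc_arm2 = NA_real_,
    run_arm1 = NA_integer_, run_arm2 = NA_integer_,
    verdict = !masked,
    fail_reasons = ifelse(masked, "CONTAINS_N", ""),
    stringsAsFactors = FALSE
  )
  if (any(!masked)) {
    i <- !masked
    cands$tm_arm1_c[i] <- melting_temperature(arm1[i], cfg$thermo)
    cands$tm_arm2_c[i] <- melting_temperature(arm2[i], cfg$thermo)
    cands$gc_arm1[i] <- gc_fraction(arm1[i])
    cands$gc_arm2[i] <- gc_fraction(arm2[i])
    cands$run_arm1[i] <- max_homopolymer_run(arm1[i])
    cands$run_arm2[i] <- max_homopolymer_run(arm2[i])
  }
  attr(cands, "window_seq") <- wins
  attr(cands, "gene_id") <- target$gene_id
  cands
}

#' Apply the thermodynamic filter to candidates
#'
#' Each arm of every N-free candidate is tested independently against the
#' GC window, the (post-formamide) Tm window, and the maximum homopolymer
#' run; failing candidates get reasons `GC_RANGE`, `TM_RANGE` and/or
#' `HOMOPOLYMER` appended. Idempotent: re-application changes nothing.
#'
#' @param cands Candidate table from [enumerate_candidates()].
#' @param cfg A [design_config()].
#' @return The candidate table with updated `verdict` and `fail_reasons`.
#' @export
apply_thermo_filter <- function(cands, cfg = design_config()) {
  tc <- cfg$thermo
  nfree <- !grepl("CONTAINS_N", cands$fail_reasons)
  gc_bad <- nfree & (cands$gc_arm1 < tc$gc_min | cands$gc_arm1 > tc$gc_max |
                     cands$gc_arm2 < tc$gc_min | cands$gc_arm2 > tc$gc_max)
  tm_bad <- nfree & (cands$tm_arm1_c < tc$tm_min_c | cands$tm_arm1_c > tc$tm_max_c |
                     cands$tm_arm2_c < tc$tm_min_c | cands$tm_arm2_c > tc$tm_max_c)
  run_bad <- nfree & (cands$run_arm1 > tc$max_run | cands$run_arm2 > tc$max_run)
  for (i in which(gc_bad)) cands <- add_reason(cands, i, "GC_RANGE")
  for (i in which(tm_bad)) cands <- add_reason(cands, i, "TM_RANGE")
  for (i in which(run_bad)) cands <- add_reason(cands, i, "HOMOPOLYMER")
  cands
}

#' Select a final non-overlapping probe set
#'
#' In `max_count` mode, returns a maximum-cardinality set of passing
#' candidates with at least `min_inter_probe_gap` nt between consecutive
#' windows, by the greedy earliest-end scan (optimal for unweighted
#' non-overlapping interval selection). In `even_spread` mode (requires
#' `target_pairs > 0`), returns exactly `min(target_pairs, achievable)`
#' windows maximizing the minimum inter-window spacing, by binary search on
#' the spacing with a greedy feasibility check. Both modes are
#' deterministic; ties break toward the smaller start coordinate.
#'
#' @param cands Candidate table with final verdicts (thermodynamic and
#'   off-target filters applied).
#' @param cfg A [design_config()].
#' @return The selected rows of `cands`, in start order.
#' @export
select_nonoverlapping <- function(cands, cfg = design_config()) {
  pass <- cands[cands$verdict, , drop = FALSE]
  if (nrow(pass) == 0L) return(pass)
  pass <- pass[order(pass$end, pass$start), , drop = FALSE]
  g <- cfg$min_inter_probe_gap

  if (cfg$selection_mode == "max_count" || cfg$target_pairs <= 0L) {
    if (cfg$selection_mode == "even_spread") {
      stop("even_spread selection requires target_pairs > 0", call. = FALSE)
    }
    sel <- greedy_select(pass, g)
    return(sel[order(sel$start), , drop = FALSE])
  }

  # even_spread: max-min spacing for exactly m windows
  m <- cfg$target_pairs
  achievable <- nrow(greedy_select(pass, g))
  m <- min(m, achievable)
  lo <- g
  hi <- max(pass$start) - min(pass$start) + g + 1L   # spacing beyond any feasible value
  while (lo < hi) {                                  # largest s with >= m selectable
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (nrow(greedy_select(pass, mid)) >= m) lo <- mid else hi <- mid - 1L
  }
  sel <- greedy_select(pass, lo)
  sel <- sel[seq_len(m), , drop = FALSE]
  sel[order(sel$start), , drop = FALSE]
}

#' Run the full probe-design pipeline
#'
#' Enumerates candidates, applies the thermodynamic filter, screens against
#' the transcriptome (when one is given), selects a non-overlapping set,
#' and assembles split-initiator probe pairs. A `FEWER_THAN_MIN_PAIRS`
#' warning is recorded when the design ends with fewer than
#' `cfg$min_pairs_warn` pairs (default 5), and `NO_CANDIDATES` when nothing
#' passes the filters.
#'
#' @param target A [read_target()] `TargetSequence`.
#' @param transcriptome A [read_transcriptome()] index, or `NULL` to skip
#'   the off-target screen.
#' @param cfg A [design_config()].
#' @param initiator Initiator id to attach (default `"B1"`), looked up in
#'   `registry`.
#' @param registry Initiator registry from [load_initiators()].
#' @return A `DesignResult`: list with `target`, `candidates`, `selected`,
#'   `pairs`, `warnings`, and the resolved `config`.
#' @export
design <- function(target, transcriptome = NULL, cfg = design_config(),
                   initiator = "B1", registry = load_initiators()) {
  spec <- registry_get(registry, initiator)
  cands <- enumerate_candidates(target, cfg)
  cands <- apply_thermo_filter(cands, cfg)
  if (!is.null(transcriptome)) {
    cands <- apply_offtarget_filter(cands, transcriptome, cfg$offtarget,
                                    arm_len = cfg$arm_len, gap_len = cfg$gap_len)
  }
  selected <- select_nonoverlapping(cands, cfg)
  pairs <- split_and_assemble(selected, spec, cfg)
  warnings <- character()
  if (nrow(selected) == 0L) warnings <- c(warnings, "NO_CANDIDATES")
  if (nrow(pairs) < cfg$min_pairs_warn) warnings <- c(warnings, "FEWER_THAN_MIN_PAIRS")
  structure(list(target = target, candidates = cands, selected = selected,
                 pairs = pairs, warnings = warnings, config = cfg,
                 initiator = spec$id),
            class = "DesignResult")
}

#' @export
print.DesignResult <- function(x, ...) {
  cat(sprintf("DesignResult for '%s': %d candidates, %d passing, %d pairs (initiator %s)\n",
              x$target$gene_id, nrow(x$candidates), sum(x$candidates$verdict),
              nrow(x$pairs), x$initiator))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a DesignResult to deterministic JSON
#'
#' Numeric fields are written with fixed precision so that identical inputs
#' and configuration yield byte-identical serializations.
#'
#' @param result A `DesignResult`.
#' @param path Optional output path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
design_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "DesignResult"))
  cands <- result$candidates
  num <- vapply(cands, is.double, logical(1L))
  cands[num] <- lapply(cands[num], round, 4L)
  sel <- result$selected
  sel[vapply(sel, is.double, logical(1L))] <-
    lapply(sel[vapply(sel, is.double, logical(1L))], round, 4L)
  pairs <- result$pairs
  pairs[vapply(pairs, is.double, logical(1L))] <-
    lapply(pairs[vapply(pairs, is.double, logical(1L))], round, 4L)
  obj <- list(
    gene_id = result$target$gene_id,
    coordinate_note = "start/end are 0-based half-open on the normalized target",
    target_length = nchar(result$target$sequence),
    exon_bounds = result$target$exon_bounds,
    initiator = result$initiator,
    n_candidates = nrow(cands), n_passing = sum(cands$verdict),
    warnings = result$warnings,
    selected = sel, pairs = pairs, candidates = cands
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

# ---- internal helpers -------------------------------------------------------

# Greedy earliest-end scan: keep a window when it starts >= gap after the
# previously kept window's end. Input must be sorted by (end, start).
greedy_select <- function(sorted, gap) {
  keep <- logical(nrow(sorted))
  last_end <- -Inf
  for (i in seq_len(nrow(sorted))) {
    if (sorted$start[i] >= last_end + gap) {
      keep[i] <- TRUE
      last_end <- sorted$end[i]
    }
  }
  sorted[keep, , drop = FALSE]
}

# Append a failure reason (set semantics, canonical order) and clear verdict.
add_reason <- function(cands, i, reason) {
  cur <- strsplit(cands$fail_reasons[i], ",", fixed = TRUE)[[1L]]
  cur <- union(cur[nzchar(cur)], reason)
  cands$fail_reasons[i] <- paste(.reason_levels[.reason_levels %in% cur], collapse = ",")
  cands$verdict[i] <- FALSE
  cands
}
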