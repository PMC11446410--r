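# Off-target screening of candidate probe windows against a transcriptome:
# internal k-mer seed-and-extend backend, or external NCBI blastn.
#
# Criterion: a candidate fails when its 52-nt window shares a contiguous
# exact match longer than max_contig_match nt with any non-excluded
# transcript, on the sense strand only (probes are reverse complements of
# the target, so only sense-identical segments of another transcript can
# capture a probe).

#' Off-target screen configuration
#'
#' @param seed_k Seed length in nt for the internal k-mer screen
#'   (default 15). Must satisfy `8 <= seed_k <= max_contig_match + 1` so
#'   that no failing match can be missed by seeding.
#' @param max_contig_match Longest tolerated contiguous exact match to a
#'   non-target transcript, in nt (default 16: a 17-nt or longer shared
#'   stretch fails the candidate).
#' @param exclude_ids Transcript ids exempt from screening (the target
#'   gene's own isoforms).
#' @param backend `"internal"` (default) or `"blastn"` (requires NCBI
#'   BLAST+ on the PATH and a pre-built nucleotide database).
#' @param blast_evalue Expectation cutoff passed to blastn (default 1.0).
#' @return An `OfftargetConfig` list.
#' @export
offtarget_config <- function(seed_k = 15L, max_contig_match = 16L,
                             exclude_ids = character(),
                             backend = c("internal", "blastn"),
                             blast_evalue = 1.0) {
  backend <- match.arg(backend)
  seed_k <- as.integer(seed_k); max_contig_match <- as.integer(max_contig_match)
  if (seed_k < 8L) stop("seed_k must be >= 8", call. = FALSE)
  if (seed_k > max_contig_match + 1L) {
    stop("seed_k must be <= max_contig_match + 1 (otherwise failing matches could be unseedable)",
         call. = FALSE)
  }
  structure(list(seed_k = seed_k, max_contig_match = max_contig_match,
                 exclude_ids = as.character(exclude_ids), backend = backend,
                 blast_evalue = blast_evalue),
            class = "OfftargetConfig")
}

#' Find maximal exact off-target matches for one candidate window
#'
#' Seeds every `seed_k`-mer of the window in the transcriptome index and
#' extends each hit in both directions to a maximal contiguous exact match.
#' Each maximal match of length `>= seed_k` to a non-excluded transcript is
#' reported exactly once.
#'
#' @param window Candidate window sequence (N-free).
#' @param index A [read_transcriptome()] index built with `k == cfg$seed_k`.
#' @param cfg An [offtarget_config()].
#' @param window_start 0-based start of the window on the target (recorded
#'   in the hits for reporting).
#' @param arm_len,gap_len Window geometry used to annotate which arm(s) a
#'   match overlaps.
#' @return Data frame of `OfftargetHit`s: `candidate_start`, `subject_id`,
#'   `subject_pos` (0-based), `match_len`, `win_pos` (0-based offset of the
#'   match within the window), `arm` (`"arm1"`, `"arm2"`, `"arm1+arm2"`, or
#'   `"gap"`).
#' @export
find_offtargets <- function(window, index, cfg = offtarget_config(),
                            window_start = 0L, arm_len = 25L, gap_len = 2L) {
  stopifnot(inherits(index, "TranscriptomeIndex"))
  if (index$k != cfg$seed_k) {
    stop(sprintf("index was built with k=%d but cfg$seed_k=%d; rebuild the index",
                 index$k, cfg$seed_k), call. = FALSE)
  }
  check_acgt(window)
  k <- cfg$seed_k
  W <- nchar(window)
  hits <- list()
  seen <- new.env(parent = emptyenv())
  if (W >= k) {
    for (i in 0:(W - k)) {                       # 0-based seed offset in window
      km <- substr(window, i + 1L, i + k)
      entry <- get0(km, envir = index$kmer_env, inherits = FALSE)
      if (is.null(entry)) next
      for (j in seq_along(entry$id)) {
        id <- entry$id[j]
        if (id %in% cfg$exclude_ids) next
        subject <- index$records[[id]]
        ext <- extend_match(window, subject, i, entry$pos[j], k)
        key <- paste(id, ext$spos, ext$len, sep = "\r")
        if (!is.null(get0(key, envir = seen, inherits = FALSE))) next
        assign(key, TRUE, envir = seen)
        hits[[length(hits) + 1L]] <- data.frame(
          candidate_start = window_start, subject_id = id,
          subject_pos = ext$spos, match_len = ext$len, win_pos = ext$wpos,
          arm = match_arm(ext$wpos, ext$len, arm_len, gap_len),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) empty_hits() else do.call(rbind, hits)
}

#' Apply the off-target screen to a candidate table
#'
#' Appends the `OFFTARGET` failure reason to every candidate whose window
#' shares a contiguous exact match longer than `cfg$max_contig_match` nt
#' with a non-excluded transcript. By default only candidates still passing
#' the thermodynamic filter are screened (the others are already excluded);
#' set `screen_all = TRUE` to annotate every N-free candidate.
#'
#' @param cands Candidate table from [enumerate_candidates()] (thermo filter
#'   normally already applied).
#' @param index A [read_transcriptome()] index.
#' @param cfg An [offtarget_config()].
#' @param arm_len,gap_len Window geometry (annotation only).
#' @param screen_all Screen failed candidates too (default `FALSE`).
#' @return `cands` with updated `verdict`/`fail_reasons` and an `offtarget_hits`
#'   attribute: one data frame of all hits found, keyed by `candidate_start`.
#' @export
apply_offtarget_filter <- function(cands, index, cfg = offtarget_config(),
                                   arm_len = 25L, gap_len = 2L,
                                   screen_all = FALSE) {
  todo <- if (screen_all) !grepl("CONTAINS_N", cands$fail_reasons) else cands$verdict
  all_hits <- list()
  for (i in which(todo)) {
    win <- paste0(cands$arm1_seq[i],
                  substr_gap(cands, i, arm_len, gap_len),
                  cands$arm2_seq[i])
    h <- find_offtargets(attr(cands, "window_seq")[i] %||% win, index, cfg,
                         window_start = cands$start[i],
                         arm_len = arm_len, gap_len = gap_len)
    if (nrow(h) > 0L) {
      all_hits[[length(all_hits) + 1L]] <- h
      if (any(h$match_len > cfg$max_contig_match)) {
        cands <- add_reason(cands, i, "OFFTARGET")
      }
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else empty_hits()
  attr(cands, "offtarget_hits") <- hits
  cands
}

#' Screen candidate windows with external NCBI blastn
#'
#' Runs `blastn -task blastn-short` on the candidate windows against a
#' pre-built nucleotide BLAST database and converts each alignment's longest
#' contiguous exact stretch (parsed from the BTOP trace) of length
#' `>= cfg$seed_k` into an `OfftargetHit`. Subjects in `cfg$exclude_ids`
#' are dropped. Only plus/plus alignments are considered (sense strand).
#'
#' @param cands Candidate table (windows taken from its `window_seq`
#'   attribute).
#' @param db_path Path prefix of a nucleotide BLAST database
#'   (`makeblastdb -dbtype nucl`).
#' @param cfg An [offtarget_config()].
#' @param arm_len,gap_len Window geometry (annotation only).
#' @return Data frame of `OfftargetHit`s in the same layout as
#'   [find_offtargets()].
#' @export
blastn_screen <- function(cands, db_path, cfg = offtarget_config(),
                          arm_len = 25L, gap_len = 2L) {
  if (Sys.which("blastn") == "") {
    stop("blastn executable not found on PATH; install NCBI BLAST+ or use backend='internal'",
         call. = FALSE)
  }
  wins <- attr(cands, "window_seq")
  if (is.null(wins)) stop("candidate table lacks its window_seq attribute", call. = FALSE)
  ok <- !grepl("N", wins, fixed = TRUE)
  qf <- tempfile(fileext = ".fa"); on.exit(unlink(qf), add = TRUE)
  writeLines(paste0(">", cands$start[ok], "\n", wins[ok]), qf)
  out <- suppressWarnings(system2(
    "blastn",
    c("-task", "blastn-short", "-query", qf, "-db", db_path,
      "-evalue", format(cfg$blast_evalue), "-dust", "no", "-strand", "plus",
      "-outfmt", shQuote("6 qseqid sseqid qstart qend sstart send btop")),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("blastn failed (exit ", status, "):\n", paste(out, collapse = "\n"), call. = FALSE)
  }
  hits <- empty_hits()
  for (line in out) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 7L) {
      stop("unparseable blastn tabular line: ", line, call. = FALSE)
    }
    if (f[2L] %in% cfg$exclude_ids) next
    qstart <- as.integer(f[3L]); sstart <- as.integer(f[5L]); send <- as.integer(f[6L])
    if (send < sstart) next                       # minus-strand alignment
    runs <- btop_runs(f[7L])
    if (nrow(runs) == 0L) next
    best <- runs[which.max(runs$len), ]
    if (best$len < cfg$seed_k) next
    wpos <- qstart - 1L + best$qoff
    hits <- rbind(hits, data.frame(
      candidate_start = as.integer(f[1L]), subject_id = f[2L],
      subject_pos = sstart - 1L + best$soff, match_len = best$len,
      win_pos = wpos, arm = match_arm(wpos, best$len, arm_len, gap_len),
      stringsAsFactors = FALSE
    ))
  }
  unique(hits)
}

# ---- internal helpers -------------------------------------------------------

empty_hits <- function() {
  data.frame(candidate_start = integer(), subject_id = character(),
             subject_pos = integer(), match_len = integer(),
             win_pos = integer(), arm = character(), stringsAsFactors = FALSE)
}

# Maximal bidirectional extension of an exact seed match.
# wi/sj are 0-based match starts in window/subject; returns 0-based coords.
extend_match <- function(window, subject, wi, sj, k) {
  W <- nchar(window); S <- nchar(subject)
  lo <- 0L
  while (wi - lo - 1L >= 0L && sj - lo - 1L >= 0L &&
         substr(window, wi - lo, wi - lo) == substr(subject, sj - lo, sj - lo)) {
    lo <- lo + 1L
  }
  hi <- 0L
  while (wi + k + hi < W && sj + k + hi < S &&
         substr(window, wi + k + hi + 1L, wi + k + hi + 1L) ==
         substr(subject, sj + k + hi + 1L, sj + k + hi + 1L)) {
    hi <- hi + 1L
  }
  list(wpos = wi - lo, spos = sj - lo, len = k + lo + hi)
}

# Which probe arm(s) a match interval [wpos, wpos+len) overlaps.
match_arm <- function(wpos, len, arm_len, gap_len) {
  a1 <- wpos < arm_len
  a2 <- wpos + len > arm_len + gap_len
  if (a1 && a2) "arm1+arm2" else if (a1) "arm1" else if (a2) "arm2" else "gap"
}

# Parse a BLAST BTOP trace into contiguous exact-match runs.
# Returns data frame with qoff/soff (0-based gap-corrected offsets from the
# alignment start on query/subject) and len for every numeric (match) run.
btop_runs <- function(btop) {
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Za-z-]{2}", btop))[[1L]]
  qoff <- 0L; soff <- 0L
  out <- data.frame(qoff = integer(), soff = integer(), len = integer())
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      out <- rbind(out, data.frame(qoff = qoff, soff = soff, len = n))
      qoff <- qoff + n; soff <- soff + n
    } else {
      q <- substr(t, 1L, 1L); s <- substr(t, 2L, 2L)
      if (q != "-") qoff <- qoff + 1L
      if (s != "-") soff <- soff + 1L
    }
  }
  out
}

substr_gap <- function(cands, i, arm_len, gap_len) {
  w <- attr(cands, "window_seq")
  if (!is.null(w)) substr(w[i], arm_len + 1L, arm_len + gap_len) else strrep("N", gap_len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
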