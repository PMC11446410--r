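# Independent oracles used by the property and acceptance tests. Each is a
# deliberately naive reimplementation, kept separate from the package's code
# paths: brute-force summation, diagonal scanning, exhaustive search.

# --- nearest-neighbor Tm: brute-force summation over published unified
# parameters (both strand orientations typed out explicitly), entropy salt
# correction, linear formamide offset.
.or_nn <- utils::read.table(header = TRUE, text = "
pair dh ds
AA -7.9 -22.2
AT -7.2 -20.4
TA -7.2 -21.3
CA -8.5 -22.7
GT -8.4 -22.4
CT -7.8 -21.0
GA -8.2 -22.2
CG -10.6 -27.2
GC -9.8 -24.4
GG -8.0 -19.9
TT -7.9 -22.2
TG -8.5 -22.7
AC -8.4 -22.4
AG -7.8 -21.0
TC -8.2 -22.2
CC -8.0 -19.9
", stringsAsFactors = FALSE)

oracle_tm <- function(s, na = 0.75, formamide = 30, conc = 1e-8) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1L)) {
    row <- .or_nn[.or_nn$pair == paste0(ch[i], ch[i + 1L]), ]
    dh <- dh + row$dh
    ds <- ds + row$ds
  }
  for (e in ch[c(1L, length(ch))]) {
    if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(ch) - 1L) * log(na)
  dh * 1000 / (ds + 1.9872 * log(conc / 4)) - 273.15 - 0.6 * formamide
}

# --- maximal exact matches >= k between a window and a set of subjects,
# by scanning every alignment diagonal character by character.
oracle_offtarget_hits <- function(window, subjects, k) {
  out <- data.frame(subject_id = character(), subject_pos = integer(),
                    match_len = integer(), win_pos = integer(),
                    stringsAsFactors = FALSE)
  wch <- strsplit(window, "", fixed = TRUE)[[1L]]
  W <- length(wch)
  for (id in names(subjects)) {
    sch <- strsplit(subjects[[id]], "", fixed = TRUE)[[1L]]
    S <- length(sch)
    for (d in (-(W - 1L)):(S - 1L)) {        # subject_pos = win_pos + d
      wlo <- max(0L, -d); whi <- min(W - 1L, S - 1L - d)
      if (whi - wlo + 1L < k) next
      run <- 0L
      for (w in wlo:whi) {
        hit <- wch[w + 1L] != "N" && wch[w + 1L] == sch[w + d + 1L]
        if (hit) run <- run + 1L
        if ((!hit || w == whi) && run >= k) {
          st <- if (hit) w + 1L - run else w - run
          out <- rbind(out, data.frame(
            subject_id = id, subject_pos = st + d, match_len = run,
            win_pos = st, stringsAsFactors = FALSE))
        }
        if (!hit) run <- 0L
      }
    }
  }
  out[order(out$subject_id, out$subject_pos, out$win_pos), , drop = FALSE]
}

# --- maximum number of non-overlapping windows with >= gap between
# consecutive ones: exhaustive take/skip search with memoization (explores
# the full decision tree; the cache only collapses repeated states).
oracle_max_select <- function(starts, ends, gap) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  n <- length(starts)
  memo <- rep(NA_integer_, n)
  f <- function(i) {
    if (i > n) return(0L)
    if (!is.na(memo[i])) return(memo[i])
    nxt <- which(starts >= ends[i] + gap)
    nxt <- nxt[nxt > i]
    take <- 1L + if (length(nxt)) f(min(nxt)) else 0L
    best <- max(f(i + 1L), take)
    memo[i] <<- best
    best
  }
  if (n == 0L) 0L else f(1L)
}

# Pure bitmask enumeration (for small n), double-checking the search above.
oracle_max_select_bitmask <- function(starts, ends, gap) {
  n <- length(starts)
  stopifnot(n <= 15L)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1L))) > 0L)
    if (length(idx) <= best) next
    s <- starts[idx]; e <- ends[idx]
    o <- order(s)
    if (all(s[o][-1L] >= e[o][-length(idx)] + gap)) best <- length(idx)
  }
  best
}

# --- all-pairs within-radius check (O(n^2)), same arithmetic as the
# implementation but no spatial index.
brute_near <- function(A, B, r, strict = TRUE) {
  if (nrow(A) == 0L) return(logical(0L))
  if (nrow(B) == 0L) return(rep(FALSE, nrow(A)))
  vapply(seq_len(nrow(A)), function(i) {
    d2 <- (B[, 1L] - A[i, 1L])^2 + (B[, 2L] - A[i, 2L])^2 + (B[, 3L] - A[i, 3L])^2
    if (strict) any(d2 < r * r) else any(d2 <= r * r)
  }, logical(1L))
}

# --- misc test utilities
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

permissive_cfg <- function(...) {
  design_config(
    thermo = thermo_config(tm_min_c = -50, tm_max_c = 150, gc_min = 0,
                           gc_max = 1, max_run = 60L),
    ...
  )
}
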