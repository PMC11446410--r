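# Split-initiator pair assembly and simulated-hybridization validation.
#
# Oligo layout convention (executable contract, not dogma): with arm1 the
# 5'-proximal and arm2 the 3'-proximal arm of the target window,
#   oligo_P1 = half_up + conn_up + revcomp(arm2)
#   oligo_P2 = revcomp(arm1) + conn_dn + half_dn
# The source of truth is validate_pair(), which simulates antiparallel
# binding of both oligos onto the target window and checks that the unbound
# tails reconstitute the full initiator; any layout passing that
# reconstruction is conformant, so the convention can be swapped to match a
# vendor's exact layout without touching the validator.

#' Load the split-initiator registry
#'
#' The packaged default file carries the five published HCR v3 B-series
#' amplifier initiators (B1-B5), each a 36-nt sequence split into two 18-nt
#' halves, plus the default flexible-connector dinucleotides. Users with
#' vendor-issued sequences can point this loader at their own TSV with the
#' same columns (`id`, `full_seq`, `half_up`, `half_dn`, `conn_up`,
#' `conn_dn`); custom ids (for example `B9`) are accepted.
#'
#' @param path TSV file; defaults to the packaged registry.
#' @return Named list of `InitiatorSpec` entries.
#' @export
load_initiators <- function(path = system.file("extdata", "hcr_b_initiators.tsv",
                                               package = "hcrkit")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("initiator registry file not found: '", path, "'", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "full_seq", "half_up", "half_dn", "conn_up", "conn_dn")
  if (!all(need %in% names(tab))) {
    stop("initiator registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  reg <- list()
  for (i in seq_len(nrow(tab))) {
    r <- lapply(tab[i, need], toupper)
    if (nchar(r$half_up) != 18L || nchar(r$half_dn) != 18L) {
      stop(sprintf("initiator '%s': halves must be 18 nt (got %d and %d)",
                   r$id, nchar(r$half_up), nchar(r$half_dn)), call. = FALSE)
    }
    if (paste0(r$half_up, r$half_dn) != r$full_seq) {
      stop(sprintf("initiator '%s': half_up + half_dn must reconstruct full_seq", r$id),
           call. = FALSE)
    }
    if (grepl("[^ACGT]", paste0(r$full_seq, r$conn_up, r$conn_dn))) {
      stop(sprintf("initiator '%s': sequences must be over A,C,G,T", r$id), call. = FALSE)
    }
    reg[[r$id]] <- structure(r, class = "InitiatorSpec")
  }
  reg
}

registry_get <- function(registry, id) {
  spec <- registry[[id]]
  if (is.null(spec)) {
    stop(sprintf("unknown initiator '%s'; available: %s", id,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  spec
}

#' Assemble split-initiator probe pairs from selected windows
#'
#' Splits every selected candidate window into its two binding arms and
#' attaches the connector and initiator half to each, producing the final
#' oligo pair (each oligo = 18-nt initiator half + connector + 25-nt binding
#' arm = 45 nt with the defaults). The binding arm of each oligo is the
#' exact reverse complement of its target arm.
#'
#' @param selected Selected candidate rows from [select_nonoverlapping()].
#' @param spec An `InitiatorSpec` from [load_initiators()].
#' @param cfg A [design_config()].
#' @return Data frame of `ProbePair`s: `pair_index`, `window_start`,
#'   `window_end`, `arm1_seq`, `arm2_seq`, `oligo_P1`, `oligo_P2`,
#'   `initiator_id`, `tm_arm1_c`, `tm_arm2_c`, `gc_arm1`, `gc_arm2`.
#' @export
split_and_assemble <- function(selected, spec, cfg = design_config()) {
  stopifnot(inherits(spec, "InitiatorSpec"))
  if (nrow(selected) == 0L) return(empty_pairs())
  selected <- selected[order(selected$start), , drop = FALSE]
  data.frame(
    pair_index = seq_len(nrow(selected)),
    window_start = selected$start, window_end = selected$end,
    arm1_seq = selected$arm1_seq, arm2_seq = selected$arm2_seq,
    oligo_P1 = paste0(spec$half_up, spec$conn_up, revcomp(selected$arm2_seq)),
    oligo_P2 = paste0(revcomp(selected$arm1_seq), spec$conn_dn, spec$half_dn),
    initiator_id = spec$id,
    tm_arm1_c = selected$tm_arm1_c, tm_arm2_c = selected$tm_arm2_c,
    gc_arm1 = selected$gc_arm1, gc_arm2 = selected$gc_arm2,
    stringsAsFactors = FALSE
  )
}

empty_pairs <- function() {
  data.frame(pair_index = integer(), window_start = integer(),
             window_end = integer(), arm1_seq = character(),
             arm2_seq = character(), oligo_P1 = character(),
             oligo_P2 = character(), initiator_id = character(),
             tm_arm1_c = numeric(), tm_arm2_c = numeric(),
             gc_arm1 = numeric(), gc_arm2 = numeric(), stringsAsFactors = FALSE)
}

#' Validate a probe pair by simulated hybridization
#'
#' Independent of how the pair was assembled, this simulates antiparallel
#' binding of both oligos onto the pair's target window: for each oligo the
#' longest contiguous exact duplex with the window is located (dynamic
#' programming against the window's reverse complement), binding is required
#' to be a full-arm-length mismatch-free duplex on one of the window's two
#' arm intervals, and the unbound single-stranded tails are then read off
#' the bound complex. The reconstituted initiator is read tail-by-tail
#' starting from the tail presented at the window's 3' side, each tail in
#' its own strand's 5'->3' order with the duplex-adjacent connector removed.
#' The check passes iff that read-off equals the initiator's full sequence
#' and both arms bind with zero mismatches.
#'
#' @param pair One row of a [split_and_assemble()] pair table (data frame or
#'   list with `window_start`, `window_end`, `oligo_P1`, `oligo_P2`).
#' @param target The `TargetSequence` the pair was designed against.
#' @param spec The `InitiatorSpec` the pair should reconstitute.
#' @return A `HybridizationCheck`: list with `ok`, `target_window`,
#'   `reconstructed_initiator`, and a `detail` message when `ok` is `FALSE`.
#' @export
validate_pair <- function(pair, target, spec) {
  stopifnot(inherits(target, "TargetSequence"), inherits(spec, "InitiatorSpec"))
  ws <- as.integer(pair$window_start); we <- as.integer(pair$window_end)
  L <- nchar(target$sequence)
  if (ws < 0L || we > L || ws >= we) {
    stop(sprintf("window [%d, %d) out of target bounds [0, %d)", ws, we, L), call. = FALSE)
  }
  window <- substr(target$sequence, ws + 1L, we)
  wlen <- we - ws

  fail <- function(msg) structure(
    list(ok = FALSE, target_window = window, reconstructed_initiator = "",
         detail = msg), class = "HybridizationCheck")

  if (grepl("N", window, fixed = TRUE)) return(fail("window contains masked positions"))

  # Locate each oligo's duplex on the window.
  b1 <- locate_duplex(pair$oligo_P1, window)
  b2 <- locate_duplex(pair$oligo_P2, window)
  if (is.null(b1) || is.null(b2)) {
    return(fail("an oligo has no contiguous duplex with the window"))
  }

  # Binding sites must be the window's two arms: non-overlapping, in order,
  # flush with the window ends, with the gap between them.
  two <- list(b1, b2)
  ord <- order(vapply(two, `[[`, integer(1L), "t_start"))
  up <- two[[ord[1L]]]; dn <- two[[ord[2L]]]
  if (up$t_start != 0L || dn$t_end != wlen || up$t_end > dn$t_start) {
    return(fail("duplexes do not tile the window's arm intervals"))
  }
  arm_len_up <- up$t_end - up$t_start
  arm_len_dn <- dn$t_end - dn$t_start
  oligos <- c(pair$oligo_P1, pair$oligo_P2)[ord]
  # Mismatch-free full-arm binding: the matched duplex must cover the whole
  # binding arm of each oligo, i.e. the oligo's non-tail portion.
  # Tails: an oligo bound to the upstream arm presents its unbound portion at
  # its 3' end (pointing off the window's 5' side); one bound to the
  # downstream arm presents its tail at its 5' end (off the window's 3' side).
  up_tail <- substr(oligos[1L], up$q_end + 1L, nchar(oligos[1L]))     # 3' tail
  dn_tail <- substr(oligos[2L], 1L, dn$q_start)                       # 5' tail
  if (up$q_start != 0L) return(fail("upstream oligo's 5' end is not fully bound (arm mismatch)"))
  if (dn$q_end != nchar(oligos[2L])) return(fail("downstream oligo's 3' end is not fully bound (arm mismatch)"))
  if (arm_len_up < 10L || arm_len_dn < 10L) return(fail("duplex shorter than a plausible arm"))

  # Read-off: the tail presented at the window's 3' side first (the
  # downstream oligo's 5' tail, connector duplex-adjacent at the tail's 3'
  # end), then the window's-5'-side tail (the upstream oligo's 3' tail,
  # connector at the tail's 5' start); each tail in its own 5'->3' order.
  cu <- nchar(spec$conn_up); cd <- nchar(spec$conn_dn)
  half_from_dn <- substr(dn_tail, 1L, max(nchar(dn_tail) - cu, 0L))
  half_from_up <- substr(up_tail, cd + 1L, nchar(up_tail))
  reconstructed <- paste0(half_from_dn, half_from_up)

  ok <- identical(reconstructed, spec$full_seq)
  structure(list(ok = ok, target_window = window,
                 reconstructed_initiator = reconstructed,
                 detail = if (ok) "" else "tails do not reconstitute the full initiator"),
            class = "HybridizationCheck")
}

#' @export
print.HybridizationCheck <- function(x, ...) {
  cat(sprintf("HybridizationCheck: %s%s\n", if (x$ok) "ok" else "FAILED",
              if (nzchar(x$detail)) paste0(" (", x$detail, ")") else ""))
  invisible(x)
}

#' Validate every pair of a design
#'
#' @param pairs A [split_and_assemble()] pair table.
#' @param target The `TargetSequence`.
#' @param spec The `InitiatorSpec`.
#' @return Logical vector, one `ok` flag per pair.
#' @export
validate_pairs <- function(pairs, target, spec) {
  vapply(seq_len(nrow(pairs)),
         function(i) validate_pair(pairs[i, ], target, spec)$ok, logical(1L))
}

# Longest contiguous antiparallel duplex between an oligo and the window:
# the longest common substring of the oligo and revcomp(window), mapped back
# to window coordinates. Returns NULL if shorter than 10 nt, else 0-based
# half-open q_start/q_end on the oligo and t_start/t_end on the window.
locate_duplex <- function(oligo, window) {
  rcw <- revcomp(window)
  a <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  b <- strsplit(rcw, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  best_len <- 0L; best_i <- 0L; best_j <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match_j <- which(b == a[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best_len) { best_len <- cur[j]; best_i <- i; best_j <- j }
    }
    prev <- cur
  }
  if (best_len < 10L) return(NULL)
  q_start <- best_i - best_len       # 0-based
  j_start <- best_j - best_len       # 0-based on revcomp(window)
  # map revcomp(window)[j_start, j_start+len) back onto window coordinates
  t_start <- nchar(window) - (j_start + best_len)
  list(q_start = q_start, q_end = best_i,
       t_start = t_start, t_end = t_start + best_len)
}
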