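# FASTA input and normalization for probe design targets and transcriptomes.
#
# Coordinates are 0-based half-open everywhere inside the package; every
# user-facing report converts to 1-based inclusive and says so in its header.

#' Read a target transcript FASTA with exon-junction awareness
#'
#' Probes must not span exon-exon junctions (a junction-spanning probe fails
#' to detect pre-mRNA). Two input conventions are supported: a single FASTA
#' record with `N` characters separating consecutive exons, or one record per
#' exon in transcript order within a single file. Both conventions applied to
#' the same gene yield an identical normalized target.
#'
#' Normalization: case is folded to upper, `U` is mapped to `T` (RNA input is
#' accepted), and runs of one or more `N` are collapsed to a single masked
#' junction position. Characters outside `A`, `C`, `G`, `T`, `N` (including
#' IUPAC ambiguity codes) are rejected: an ambiguous target cannot be tiled
#' into definite oligo sequences.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param mode Junction convention: `"auto"` (one record implies
#'   `"single_entry_N"`, several imply `"multi_entry_exons"`),
#'   `"single_entry_N"`, or `"multi_entry_exons"`.
#' @return A `TargetSequence`: list with `gene_id`, `sequence` (over
#'   `A,C,G,T,N`), `exon_bounds` (integer matrix, columns `start`,`end`,
#'   0-based half-open, tiling all non-`N` positions), and `source_mode`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">gene1", "AAAANCCCC"), fa)
#' ts <- read_target(fa, mode = "single_entry_N")
#' ts$exon_bounds
#' @export
read_target <- function(path, mode = c("auto", "single_entry_N", "multi_entry_exons")) {
  mode <- match.arg(mode)
  recs <- read_fasta_checked(path)
  if (mode == "auto") {
    mode <- if (length(recs) > 1L) "multi_entry_exons" else "single_entry_N"
  }
  seqs <- normalize_nuc(recs, path)

  if (mode == "single_entry_N") {
    if (length(seqs) != 1L) {
      stop(sprintf(
        "single_entry_N mode requires exactly one FASTA record; '%s' has %d (use multi_entry_exons for per-exon records)",
        path, length(seqs)
      ), call. = FALSE)
    }
    seq <- gsub("N+", "N", seqs[[1L]])
    if (gsub("N", "", seq) == "") {
      stop(sprintf("record '%s' in '%s' contains no unmasked sequence", names(seqs)[1L], path), call. = FALSE)
    }
    # leading/trailing N carry no junction information
    seq <- gsub("^N|N$", "", seq)
    bounds <- nonmasked_bounds(seq)
    new_target_sequence(first_token(names(seqs)[1L]), seq, bounds, "single_entry_N")
  } else {
    if (any(grepl("N", seqs, fixed = TRUE))) {
      bad <- which(grepl("N", seqs, fixed = TRUE))[1L]
      stop(sprintf(
        "record '%s' in '%s' contains 'N' inside an exon; in multi_entry_exons mode each record must be a fully specified exon",
        names(seqs)[bad], path
      ), call. = FALSE)
    }
    seq <- paste(seqs, collapse = "N")
    lens <- nchar(seqs)
    starts <- cumsum(c(0L, head(lens, -1L) + 1L))  # +1 for the single N separator
    bounds <- cbind(start = starts, end = starts + lens)
    # per-exon records conventionally suffix the gene name (write_target does)
    gene <- sub("_exon[0-9]+$", "", first_token(names(seqs)[1L]))
    new_target_sequence(gene, seq, bounds, "multi_entry_exons")
  }
}

#' Write a target back to FASTA in either junction convention
#'
#' Round-trip partner of [read_target()]: re-reading the written file in the
#' same mode reproduces the `TargetSequence` (up to `source_mode`).
#'
#' @param target A `TargetSequence`.
#' @param path Output FASTA path.
#' @param mode `"single_entry_N"` or `"multi_entry_exons"`.
#' @return `path`, invisibly.
#' @export
write_target <- function(target, path, mode = c("single_entry_N", "multi_entry_exons")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "TargetSequence"))
  if (mode == "single_entry_N") {
    set <- Biostrings::BStringSet(structure(target$sequence, names = target$gene_id))
  } else {
    b <- target$exon_bounds
    exons <- substring(target$sequence, b[, "start"] + 1L, b[, "end"])
    names(exons) <- sprintf("%s_exon%d", target$gene_id, seq_len(nrow(b)))
    set <- Biostrings::BStringSet(exons)
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a transcriptome FASTA and build a k-mer seed index
#'
#' The index backs the internal off-target screen: every N-free k-length
#' window of every transcript is recorded under its k-mer, so that candidate
#' probes can be screened by seed lookup and maximal extension. It stands in
#' for an external BLAST nucleotide database.
#'
#' @param path Transcriptome FASTA (plain or gzip); record ids are the
#'   headers up to the first whitespace and must be unique.
#' @param k Seed length in nt, between 8 and 20.
#' @return A `TranscriptomeIndex`: list with `records` (named character
#'   vector of sequences), `kmer_env` (environment mapping k-mer to a list
#'   of `id`/`pos` with 0-based positions), and `k`.
#' @export
read_transcriptome <- function(path, k = 15L) {
  k <- as.integer(k)
  if (is.na(k) || k < 8L || k > 20L) {
    stop("seed length k must be an integer in [8, 20], got ", k, call. = FALSE)
  }
  recs <- read_fasta_checked(path)
  seqs <- normalize_nuc(recs, path)
  ids <- vapply(names(seqs), first_token, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop(sprintf("duplicate transcript id '%s' in '%s'", dup, path), call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("empty record '%s' in '%s'", ids[which(nchar(seqs) == 0L)[1L]], path), call. = FALSE)
  }
  if (any(nchar(seqs) < k)) {
    short <- which(nchar(seqs) < k)[1L]
    stop(sprintf(
      "record '%s' (length %d) in '%s' is shorter than the seed length k=%d",
      ids[short], nchar(seqs)[short], path, k
    ), call. = FALSE)
  }
  names(seqs) <- ids
  env <- build_kmer_env(seqs, k)
  structure(list(records = seqs, kmer_env = env, k = k),
            class = "TranscriptomeIndex")
}

#' @export
print.TranscriptomeIndex <- function(x, ...) {
  cat(sprintf("TranscriptomeIndex: %d transcripts, k = %d, %d distinct k-mers\n",
              length(x$records), x$k, length(ls(x$kmer_env))))
  invisible(x)
}

#' @export
print.TargetSequence <- function(x, ...) {
  cat(sprintf("TargetSequence '%s': %d nt, %d exon(s), source %s\n",
              x$gene_id, nchar(x$sequence), nrow(x$exon_bounds), x$source_mode))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

new_target_sequence <- function(gene_id, sequence, exon_bounds, source_mode) {
  storage.mode(exon_bounds) <- "integer"
  dimnames(exon_bounds) <- list(NULL, c("start", "end"))
  structure(
    list(gene_id = gene_id, sequence = sequence,
         exon_bounds = exon_bounds, source_mode = source_mode),
    class = "TargetSequence"
  )
}

first_token <- function(header) sub("\\s.*$", "", header)

read_fasta_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)), call. = FALSE)
  )
  if (length(recs) == 0L) stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  recs
}

# Upper-case, U->T, validate alphabet {A,C,G,T,N}; returns named character vector.
normalize_nuc <- function(recs, path) {
  seqs <- chartr("u", "t", toupper(as.character(recs)))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    pos <- bad[i]
    stop(sprintf(
      "record '%s' in '%s' has invalid character '%s' at position %d (allowed: A,C,G,T,N; ambiguity codes are rejected)",
      names(seqs)[i], path, substr(seqs[i], pos, pos), pos
    ), call. = FALSE)
  }
  seqs
}

# 0-based half-open intervals of the non-N segments of seq.
nonmasked_bounds <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !r$values
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# Environment mapping each N-free k-mer to list(id=chr, pos=int 0-based).
build_kmer_env <- function(seqs, k) {
  ids <- rep.int(names(seqs), pmax(nchar(seqs) - k + 1L, 0L))
  starts <- unlist(lapply(nchar(seqs), function(L) seq_len(max(L - k + 1L, 0L))), use.names = FALSE)
  kmers <- substring(rep.int(unname(seqs), pmax(nchar(seqs) - k + 1L, 0L)), starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  env <- new.env(parent = emptyenv(), size = max(16L, sum(keep)))
  if (any(keep)) {
    grp <- split(seq_along(kmers)[keep], kmers[keep])
    for (km in names(grp)) {
      idx <- grp[[km]]
      assign(km, list(id = ids[idx], pos = starts[idx] - 1L), envir = env)
    }
  }
  env
}
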