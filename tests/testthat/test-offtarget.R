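make_index <- function(seqs, k = 15L) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  write_fasta(seqs, fa)
  read_transcriptome(fa, k = k)
}

test_that("planted exact copies are found and sub-seed sharing is not", {
  set.seed(41)
  window <- rand_dna(52L)
  decoy <- paste0(rand_dna(100L), substr(window, 11L, 35L), rand_dna(100L))
  idx <- make_index(c(d1 = decoy))
  cfg <- offtarget_config()
  hits <- find_offtargets(window, idx, cfg, window_start = 7L)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$match_len >= 25L))
  expect_true(all(hits$candidate_start == 7L))
  # reported matches are verbatim
  for (i in seq_len(nrow(hits))) {
    expect_identical(
      substr(window, hits$win_pos[i] + 1L, hits$win_pos[i] + hits$match_len[i]),
      substr(idx$records[[hits$subject_id[i]]], hits$subject_pos[i] + 1L,
             hits$subject_pos[i] + hits$match_len[i])
    )
  }

  # 12-nt shared segment with seed_k 15 is unseedable -> no hits
  decoy12 <- paste0(rand_dna(80L), substr(window, 20L, 31L), rand_dna(80L))
  hits12 <- find_offtargets(window, make_index(c(d1 = decoy12)), cfg)
  expect_identical(nrow(hits12[hits12$match_len >= 15L, ]), 0L)
})

test_that("internal screen equals the brute-force maximal-match oracle", {
  set.seed(42)
  cfg <- offtarget_config()
  for (i in 1:30) {
    window <- rand_dna(52L)
    subjects <- c(
      s1 = paste0(rand_dna(sample(50:200, 1L)),
                  substr(window, 5L, 5L + sample(14:30, 1L)),
                  rand_dna(sample(50:200, 1L))),
      s2 = rand_dna(sample(100:500, 1L))
    )
    got <- find_offtargets(window, make_index(subjects), cfg)
    got <- got[order(got$subject_id, got$subject_pos, got$win_pos),
               c("subject_id", "subject_pos", "match_len", "win_pos")]
    want <- oracle_offtarget_hits(window, as.list(subjects), cfg$seed_k)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want[, c("subject_id", "subject_pos", "match_len", "win_pos")])
  }
})

test_that("off-target filter fails exactly the windows overlapping a plant", {
  spec <- fixture_spec(
    seed = 43L, n_exons = 2L, exon_lengths = c(400L, 400L),
    n_decoys = 3L, decoy_lengths = 600L,
    plants = list(list(decoy_index = 2L, target_start = 150L, length = 25L))
  )
  d <- withr::local_tempdir()
  tgt <- make_target(spec, d)
  tx <- make_transcriptome(spec, tgt$target, d)
  idx <- read_transcriptome(tx$fasta, k = 15L)
  cfg <- permissive_cfg()
  cands <- apply_thermo_filter(enumerate_candidates(tgt$target, cfg), cfg)
  cands <- apply_offtarget_filter(cands, idx, cfg$offtarget, screen_all = TRUE)
  flagged <- cands$start[grepl("OFFTARGET", cands$fail_reasons)]
  expect_identical(flagged, tx$truth$plants[[1L]]$failing_window_starts)

  # a plant below the contiguous-match threshold fails nothing
  spec12 <- fixture_spec(seed = 43L, n_exons = 2L, exon_lengths = c(400L, 400L),
                         n_decoys = 3L, decoy_lengths = 600L,
                         plants = list(list(decoy_index = 2L, target_start = 150L,
                                            length = 12L)))
  d2 <- withr::local_tempdir()
  tgt2 <- make_target(spec12, d2)
  tx2 <- make_transcriptome(spec12, tgt2$target, d2)
  expect_length(tx2$truth$plants[[1L]]$failing_window_starts, 0L)
  idx2 <- read_transcriptome(tx2$fasta, k = 15L)
  c2 <- apply_offtarget_filter(apply_thermo_filter(enumerate_candidates(tgt2$target, cfg), cfg),
                               idx2, cfg$offtarget, screen_all = TRUE)
  expect_false(any(grepl("OFFTARGET", c2$fail_reasons)))
})

test_that("self-matches via exclude_ids are exempt and empty screens pass all", {
  set.seed(44)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">self", rand_dna(300L)), fa)
  tgt <- read_target(fa)
  cfg <- permissive_cfg()
  # transcriptome consisting solely of the target's own transcript
  idx <- make_index(c(self = tgt$sequence))
  cands <- apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg)
  screened <- apply_offtarget_filter(cands, idx,
                                     offtarget_config(exclude_ids = "self"),
                                     screen_all = TRUE)
  expect_false(any(grepl("OFFTARGET", screened$fail_reasons)))
  # without the exemption every window fails on its own self-match
  hit <- apply_offtarget_filter(cands, idx, offtarget_config(), screen_all = TRUE)
  expect_true(all(grepl("OFFTARGET", hit$fail_reasons)))

  # unrelated random transcriptome: no candidate fails
  idxr <- make_index(c(r1 = rand_dna(400L), r2 = rand_dna(400L)))
  clean <- apply_offtarget_filter(cands, idxr, offtarget_config(), screen_all = TRUE)
  expect_false(any(grepl("OFFTARGET", clean$fail_reasons)))
})

test_that("lowering max_contig_match never admits more candidates", {
  set.seed(45)
  window_src <- rand_dna(600L)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", window_src), fa)
  tgt <- read_target(fa)
  decoy <- paste0(rand_dna(100L), substr(window_src, 201L, 224L), rand_dna(100L))
  idx <- make_index(c(d = decoy))
  cfg <- permissive_cfg()
  cands <- apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg)
  passing <- vapply(c(23L, 20L, 17L, 16L, 15L), function(mc) {
    out <- apply_offtarget_filter(cands, idx,
                                  offtarget_config(max_contig_match = mc,
                                                   seed_k = min(15L, mc + 1L)),
                                  screen_all = TRUE)
    sum(out$verdict)
  }, integer(1L))
  expect_true(all(diff(passing) <= 0L))
})

test_that("configuration contracts are enforced", {
  expect_error(offtarget_config(seed_k = 7L), ">= 8")
  expect_error(offtarget_config(seed_k = 18L, max_contig_match = 16L), "seed_k")
  idx <- make_index(c(t1 = rand_dna(60L)), k = 12L)
  expect_error(find_offtargets(rand_dna(52L), idx, offtarget_config(seed_k = 15L)),
               "rebuild the index")
})

test_that("blastn backend agrees with the internal screen on planted decoys", {
  set.seed(46)
  target_seq <- rand_dna(400L)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", target_seq), fa)
  tgt <- read_target(fa)
  decoys <- c(
    d1 = paste0(rand_dna(150L), substr(target_seq, 101L, 125L), rand_dna(150L)),
    d2 = rand_dna(300L)
  )
  cfg <- permissive_cfg()
  cands <- enumerate_candidates(tgt, cfg)
  idx <- make_index(decoys)
  internal <- apply_offtarget_filter(cands, idx, offtarget_config(), screen_all = TRUE)
  int_hits <- attr(internal, "offtarget_hits")

  dbdir <- withr::local_tempdir()
  dbfa <- file.path(dbdir, "db.fa")
  write_fasta(decoys, dbfa)
  res <- system2("makeblastdb", c("-in", dbfa, "-dbtype", "nucl"),
                 stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  ext_hits <- blastn_screen(cands, dbfa, offtarget_config())

  # strong matches (>= 20 nt contiguous) must agree on (candidate, subject)
  key <- function(h, n) unique(paste(h$candidate_start[h$match_len >= n],
                                     h$subject_id[h$match_len >= n]))
  expect_setequal(key(ext_hits, 20L), key(int_hits, 20L))

  # absent executable is an actionable error
  expect_error(
    withr::with_envvar(c(PATH = tempdir()), blastn_screen(cands, dbfa, offtarget_config())),
    "internal"
  )
})
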