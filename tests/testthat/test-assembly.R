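reg <- load_initiators()

make_tgt <- function(seq) {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g", seq), fa)
  on.exit(unlink(fa))
  read_target(fa)
}

test_that("the packaged registry carries the five B-series initiators", {
  expect_setequal(names(reg), c("B1", "B2", "B3", "B4", "B5"))
  for (spec in reg) {
    expect_identical(nchar(spec$half_up), 18L)
    expect_identical(nchar(spec$half_dn), 18L)
    expect_identical(paste0(spec$half_up, spec$half_dn), spec$full_seq)
    expect_false(grepl("[^ACGT]", paste0(spec$full_seq, spec$conn_up, spec$conn_dn)))
  }
})

test_that("malformed registries are rejected and custom initiators accepted", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfull_seq\thalf_up\thalf_dn\tconn_up\tconn_dn",
               paste("BX", strrep("A", 35), strrep("A", 18), strrep("A", 17),
                     "AA", "TT", sep = "\t")), bad)
  expect_error(load_initiators(bad), "BX.*18 nt")

  mism <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfull_seq\thalf_up\thalf_dn\tconn_up\tconn_dn",
               paste("BY", strrep("A", 36), strrep("A", 18), strrep("C", 18),
                     "AA", "TT", sep = "\t")), mism)
  expect_error(load_initiators(mism), "reconstruct")

  custom <- withr::local_tempfile(fileext = ".tsv")
  b9 <- paste0(strrep("ACGT", 4L), "AC", strrep("TGCA", 4L), "GT")  # 36 nt
  writeLines(c("id\tfull_seq\thalf_up\thalf_dn\tconn_up\tconn_dn",
               paste("B9", b9, substr(b9, 1, 18), substr(b9, 19, 36),
                     "AA", "TT", sep = "\t")), custom)
  reg9 <- load_initiators(custom)
  expect_identical(names(reg9), "B9")
})

test_that("assembled oligos have the split-initiator anatomy", {
  set.seed(51)
  tgt <- make_tgt(rand_dna(600L))
  cfg <- permissive_cfg()
  sel <- select_nonoverlapping(apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg), cfg)
  sel <- sel[seq_len(min(7L, nrow(sel))), ]
  pairs <- split_and_assemble(sel, reg$B2, cfg)
  expect_identical(nrow(pairs), 7L)                       # 7 windows -> 7 pairs
  expect_identical(length(c(pairs$oligo_P1, pairs$oligo_P2)), 14L)
  expect_true(all(nchar(pairs$oligo_P1) == 45L))          # 18 + 2 + 25
  expect_true(all(nchar(pairs$oligo_P2) == 45L))
  expect_identical(pairs$pair_index, 1:7)
  # binding arm of each oligo is the reverse complement of its target arm
  expect_true(all(substr(pairs$oligo_P1, 21L, 45L) == revcomp(pairs$arm2_seq)))
  expect_true(all(substr(pairs$oligo_P2, 1L, 25L) == revcomp(pairs$arm1_seq)))
  expect_identical(pairs$initiator_id, rep("B2", 7L))
})

test_that("simulated hybridization validates construction and catches defects", {
  set.seed(52)
  tgt <- make_tgt(rand_dna(400L))
  cfg <- permissive_cfg()
  sel <- select_nonoverlapping(apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg), cfg)
  pairs <- split_and_assemble(sel, reg$B1, cfg)
  chk <- validate_pair(pairs[1L, ], tgt, reg$B1)
  expect_true(chk$ok)
  expect_identical(chk$reconstructed_initiator, reg$B1$full_seq)

  # swapped halves: reconstruction reads them in the wrong order
  swapped <- pairs[1L, ]
  swapped$oligo_P1 <- paste0(reg$B1$half_dn, reg$B1$conn_up, revcomp(swapped$arm2_seq))
  swapped$oligo_P2 <- paste0(revcomp(swapped$arm1_seq), reg$B1$conn_dn, reg$B1$half_up)
  expect_false(validate_pair(swapped, tgt, reg$B1)$ok)

  # one mutated base in a binding arm breaks the mismatch-free duplex
  mut <- pairs[1L, ]
  arm <- substr(mut$oligo_P2, 1L, 25L)
  pos <- 13L
  base <- substr(arm, pos, pos)
  substr(arm, pos, pos) <- setdiff(c("A", "C", "G", "T"), base)[1L]
  mut$oligo_P2 <- paste0(arm, substr(mut$oligo_P2, 26L, 45L))
  expect_false(validate_pair(mut, tgt, reg$B1)$ok)

  # wrong initiator spec also fails reconstruction
  expect_false(validate_pair(pairs[1L, ], tgt, reg$B3)$ok)

  # out-of-bounds window is an error
  oob <- pairs[1L, ]
  oob$window_end <- nchar(tgt$sequence) + 10L
  expect_error(validate_pair(oob, tgt, reg$B1), "out of target bounds")
})

test_that("assembly closure holds across geometries and all initiators", {
  set.seed(53)
  for (rep_i in 1:12) {
    arm <- sample(20:30, 1L)
    gap <- sample(0:3, 1L)
    cfg <- design_config(arm_len = arm, gap_len = gap,
                         thermo = thermo_config(tm_min_c = -50, tm_max_c = 150,
                                                gc_min = 0, gc_max = 1, max_run = 60L))
    tgt <- make_tgt(rand_dna(sample(200:500, 1L)))
    sel <- select_nonoverlapping(apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg), cfg)
    spec <- reg[[sample(names(reg), 1L)]]
    pairs <- split_and_assemble(sel, spec, cfg)
    expect_gte(nrow(pairs), 1L)
    expect_true(all(validate_pairs(pairs, tgt, spec)))
    expect_true(all(nchar(pairs$oligo_P1) == 18L + nchar(spec$conn_up) + arm))
  }
})

test_that("order sheets are faithful and carry plate and pooling metadata", {
  set.seed(54)
  tgt <- make_tgt(rand_dna(600L))
  cfg <- permissive_cfg()
  sel <- select_nonoverlapping(apply_thermo_filter(enumerate_candidates(tgt, cfg), cfg), cfg)
  pairs <- split_and_assemble(sel[1:5, ], reg$B1, cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_order_sheet(pairs, csv, gene_id = "lac")

  txt <- readLines(csv)
  expect_true(any(grepl("100 µM", txt)))
  expect_true(any(grepl("1 µM", txt)))

  sheet <- read_order_sheet(csv)
  expect_identical(nrow(sheet), 10L)                      # 5 pairs -> 10 oligos
  expect_identical(sheet$Well, paste0("A", 1:10))
  expect_identical(sheet$Sequence,
                   as.vector(rbind(pairs$oligo_P1, pairs$oligo_P2)))
  expect_true(all(sheet$Scale == "25nm"))
  expect_true(all(sheet$Purification == "STD"))
  expect_match(sheet$Name[1L], "^lac_B1_01_P1$")

  expect_error(write_order_sheet(pairs, csv, format = "xlsx"), "csv")
  expect_error(write_order_sheet(pairs[0L, ], csv), "no pairs")
})

test_that("the probe map reports 1-based coordinates and survives empty designs", {
  set.seed(55)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g_e1", rand_dna(150L), ">g_e2", rand_dna(150L)), fa)
  tgt <- read_target(fa, "multi_entry_exons")
  res <- design(tgt, cfg = permissive_cfg())
  txt <- withr::local_tempfile(fileext = ".txt")
  png <- withr::local_tempfile(fileext = ".png")
  lines <- probe_map_report(res, txt, fig_path = png)
  expect_true(file.exists(txt))
  expect_true(file.size(png) > 0L)
  expect_match(lines[1L], "1-based inclusive")
  expect_match(lines[3L], sprintf("\\b%d\\b", 151L))      # junction at 0-based 150
  # every pair appears exactly once, with start shifted +1 and end unchanged
  for (i in seq_len(nrow(res$pairs))) {
    pat <- sprintf("%-5d %8d %8d", res$pairs$pair_index[i],
                   res$pairs$window_start[i] + 1L, res$pairs$window_end[i])
    expect_identical(sum(startsWith(lines, pat)), 1L)
  }

  # empty design: notice emitted, no crash, figure still renders
  short <- make_tgt(strrep("G", 80L))                     # all windows fail GC
  res0 <- design(short, cfg = design_config())
  expect_true("NO_CANDIDATES" %in% res0$warnings)
  png0 <- withr::local_tempfile(fileext = ".png")
  lines0 <- probe_map_report(res0, fig_path = png0)
  expect_true(any(grepl("NO_CANDIDATES", lines0)))
  expect_true(file.size(png0) > 0L)
})
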