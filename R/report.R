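# Order-sheet and probe-map outputs. All user-facing coordinates here are
# 1-based inclusive, stated in every header.

#' Write the oligo order sheet
#'
#' One row per oligo (two per pair), with a 96-well plate layout assigned
#' row-major (A1, A2, ... A12, B1, ...), the synthesis scale note (25 nmol
#' minimum scale, "25nm") and standard desalting purification ("STD") —
#' the cheapest plate-format synthesis options the probes need. Leading
#' comment lines carry the pooling recommendation (100 uM stock, 1 uM
#' working aliquots); `read_order_sheet()` skips them, and sequences
#' round-trip byte-identically.
#'
#' @param pairs A [split_and_assemble()] pair table.
#' @param path Output path.
#' @param gene_id Gene name used in oligo names
#'   (`{gene}_{initiator}_{pair:02d}_{P1|P2}`).
#' @param format `"csv"` (the supported format; the plate-layout `Well`
#'   column is included). `"xlsx"` is not available in this build and
#'   raises an error pointing at the CSV output.
#' @return `path`, invisibly.
#' @export
write_order_sheet <- function(pairs, path, gene_id = "gene",
                              format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx output is not available in this build; use format='csv' (the plate-layout Well column is included there)",
         call. = FALSE)
  }
  if (nrow(pairs) == 0L) stop("no pairs to write", call. = FALSE)
  if (2L * nrow(pairs) > 96L) {
    warning("more than 96 oligos; well layout wraps past a single plate")
  }
  n <- nrow(pairs)
  name <- sprintf("%s_%s_%02d", gene_id, pairs$initiator_id, pairs$pair_index)
  rows <- data.frame(
    Well = plate_wells(2L * n),
    Name = as.vector(rbind(paste0(name, "_P1"), paste0(name, "_P2"))),
    Sequence = as.vector(rbind(pairs$oligo_P1, pairs$oligo_P2)),
    Scale = "25nm", Purification = "STD",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# HCR split-initiator probe order sheet (sequences written 5'->3')",
    "# Pooling: pool all probes at 100 µM stock concentration; keep aliquots at 1 µM working concentration."
  ), con)
  utils::write.table(rows, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an order sheet back
#'
#' @param path A CSV written by [write_order_sheet()].
#' @return Data frame with columns `Well`, `Name`, `Sequence`, `Scale`,
#'   `Purification`.
#' @export
read_order_sheet <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

plate_wells <- function(n) {
  wells <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
  wells[((seq_len(n) - 1L) %% 96L) + 1L]
}

#' Probe-map report: final probe positions and melting temperatures
#'
#' Writes a plain-text summary of the design (per-pair 1-based inclusive
#' coordinates, per-arm melting temperature and GC, junction positions) and
#' optionally renders the probe map: the target drawn as an axis with the
#' selected windows as intervals annotated with their arm Tm, junctions
#' marked.
#'
#' @param result A [design()] `DesignResult`.
#' @param path Output path for the text summary.
#' @param fig_path Optional PNG path for the figure; `NULL` skips rendering.
#' @return Character vector of summary lines, invisibly.
#' @export
probe_map_report <- function(result, path = NULL, fig_path = NULL) {
  stopifnot(inherits(result, "DesignResult"))
  tgt <- result$target
  pairs <- result$pairs
  junctions0 <- setdiff(0:(nchar(tgt$sequence) - 1L),
                        unlist(apply(tgt$exon_bounds, 1L,
                                     function(b) seq.int(b[1L], b[2L] - 1L),
                                     simplify = FALSE)))
  lines <- c(
    sprintf("Probe map for '%s' (%d nt); all coordinates 1-based inclusive",
            tgt$gene_id, nchar(tgt$sequence)),
    sprintf("Initiator: %s | pairs designed: %d", result$initiator, nrow(pairs)),
    if (length(junctions0)) {
      sprintf("Masked junction position(s): %s", paste(junctions0 + 1L, collapse = ", "))
    },
    if (length(result$warnings)) sprintf("Warnings: %s", paste(result$warnings, collapse = ", "))
  )
  if (nrow(pairs) == 0L) {
    lines <- c(lines, "NO_CANDIDATES: no probe windows passed the filters.")
  } else {
    lines <- c(lines,
      sprintf("%-5s %8s %8s %9s %9s %7s %7s",
              "pair", "start", "end", "Tm_arm1", "Tm_arm2", "GC1", "GC2"),
      sprintf("%-5d %8d %8d %8.1fC %8.1fC %6.1f%% %6.1f%%",
              pairs$pair_index, pairs$window_start + 1L, pairs$window_end,
              pairs$tm_arm1_c, pairs$tm_arm2_c,
              100 * pairs$gc_arm1, 100 * pairs$gc_arm2)
    )
  }
  if (!is.null(path)) writeLines(lines, path)
  if (!is.null(fig_path)) probe_map_figure(result, junctions0, fig_path)
  invisible(lines)
}

# Base-graphics rendering of the probe map.
probe_map_figure <- function(result, junctions0, fig_path) {
  tgt <- result$target
  pairs <- result$pairs
  L <- nchar(tgt$sequence)
  grDevices::png(fig_path, width = 1200, height = 400, res = 120, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  tmr <- if (nrow(pairs)) range(c(pairs$tm_arm1_c, pairs$tm_arm2_c)) else c(0, 1)
  graphics::plot(NA, xlim = c(1, L), ylim = tmr + c(-2, 2),
                 xlab = "target position (nt, 1-based)",
                 ylab = "arm melting temperature (°C)",
                 main = sprintf("%s: %d probe pair(s), initiator %s",
                                tgt$gene_id, nrow(pairs), result$initiator))
  graphics::abline(v = junctions0 + 1L, lty = 2, col = "grey40")
  if (nrow(pairs)) {
    mid <- (pairs$tm_arm1_c + pairs$tm_arm2_c) / 2
    graphics::segments(pairs$window_start + 1L, mid, pairs$window_end, mid,
                       lwd = 6, col = "steelblue")
    graphics::points(pairs$window_start + 1L, pairs$tm_arm1_c, pch = 16, col = "darkorange")
    graphics::points(pairs$window_end, pairs$tm_arm2_c, pch = 17, col = "darkorange")
  } else {
    graphics::text(L / 2, mean(tmr), "no probes selected", col = "grey30")
  }
  invisible(fig_path)
}
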