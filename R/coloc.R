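# Dual-method spot comparison: per-sample counts and directional
# within-radius colocalization fractions between two 3-D spot sets.

#' Load a spot coordinate table
#'
#' Reads a CSV of detected spot centroids with `x`, `y`, `z` columns
#' (case-insensitive). Coordinates are kept in nm throughout the package;
#' pixel/plane-index tables are converted at load by a per-axis voxel size.
#'
#' @param path CSV file with columns `x`, `y`, `z` (extra columns,
#'   e.g. `sample_id`, are ignored for coordinates).
#' @param label Method label for this set (e.g. `"HCR"`, `"smFISH"`).
#' @param voxel_nm Optional length-3 numeric `(x, y, z)` nm-per-unit scale
#'   applied per axis; `NULL` means the file is already in nm.
#' @param sample_id Optional sample identifier.
#' @return A `SpotSet`: list with `label`, `coords` (n x 3 matrix, nm),
#'   `sample_id`.
#' @export
load_spots <- function(path, label = basename(path), voxel_nm = NULL,
                       sample_id = NA_character_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  miss <- setdiff(c("x", "y", "z"), names(tab))
  if (length(miss)) {
    stop(sprintf("spot file '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  coords <- as.matrix(tab[, c("x", "y", "z")])
  if (nrow(coords) > 0L) {
    suppressWarnings(storage.mode(coords) <- "double")
    bad <- which(!apply(is.finite(coords), 1L, all))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite coordinate in '%s' at data row %d",
                   path, bad[1L]), call. = FALSE)
    }
    if (!is.null(voxel_nm)) {
      stopifnot(length(voxel_nm) == 3L, all(voxel_nm > 0))
      coords <- sweep(coords, 2L, as.numeric(voxel_nm), `*`)
    }
  }
  colnames(coords) <- c("x", "y", "z")
  structure(list(label = label, coords = coords, sample_id = sample_id),
            class = "SpotSet")
}

#' Directional within-radius colocalization of two spot sets
#'
#' For each spot of set A, tests whether any spot of set B lies within
#' `radius_nm` (3-D Euclidean distance, strict `<` by default, matching a
#' "within a radius of <750 nm" criterion), and symmetrically for B against
#' A. This is neighbor existence, not one-to-one matching: the two
#' directional fractions are independent statistics. Neighbor search uses a
#' uniform-grid spatial hash with cell size equal to the radius; results
#' are identical to the all-pairs computation.
#'
#' @param a,b `SpotSet`s (coordinates in nm).
#' @param radius_nm Matching radius in nm (default 750).
#' @param strict_less Use `dist < radius` (default `TRUE`); `FALSE` uses
#'   `<=`.
#' @return A `ColocalizationResult`: list with `radius_nm`, `strict_less`,
#'   `label_a`, `label_b`, `n_a`, `n_b`, `n_a_near_b`, `n_b_near_a`,
#'   `frac_a_near_b`, `frac_b_near_a`.
#' @export
colocalize <- function(a, b, radius_nm = 750, strict_less = TRUE) {
  stopifnot(inherits(a, "SpotSet"), inherits(b, "SpotSet"))
  if (!is.numeric(radius_nm) || radius_nm <= 0) {
    stop("radius_nm must be a positive length in nm", call. = FALSE)
  }
  nab <- sum(near_any(a$coords, b$coords, radius_nm, strict_less))
  nba <- sum(near_any(b$coords, a$coords, radius_nm, strict_less))
  na <- nrow(a$coords); nb <- nrow(b$coords)
  structure(list(
    radius_nm = radius_nm, strict_less = strict_less,
    label_a = a$label, label_b = b$label,
    n_a = na, n_b = nb, n_a_near_b = nab, n_b_near_a = nba,
    frac_a_near_b = if (na > 0L) nab / na else NA_real_,
    frac_b_near_a = if (nb > 0L) nba / nb else NA_real_
  ), class = "ColocalizationResult")
}

#' @export
print.ColocalizationResult <- function(x, ...) {
  cat(sprintf(
    "Colocalization at r %s %g nm:\n  %s near %s: %d / %d (%.1f%%)\n  %s near %s: %d / %d (%.1f%%)\n",
    if (x$strict_less) "<" else "<=", x$radius_nm,
    x$label_a, x$label_b, x$n_a_near_b, x$n_a, 100 * x$frac_a_near_b,
    x$label_b, x$label_a, x$n_b_near_a, x$n_b, 100 * x$frac_b_near_a))
  invisible(x)
}

#' Summarize spot counts and colocalization across samples
#'
#' Computes per-method mean spot counts, the relative percent difference
#' `100 * (mean_a - mean_b) / mean_b`, and — when per-sample colocalization
#' results are supplied — the directional fractions under both aggregations
#' (mean of per-sample fractions, and pooled counts across samples).
#'
#' @param results Optional list of per-sample `ColocalizationResult`s.
#' @param counts_a,counts_b Optional per-sample spot counts for the two
#'   methods (taken from `results` when omitted).
#' @param label_a,label_b Method labels (taken from `results` when omitted).
#' @return A list with `label_a`, `label_b`, `n_samples`, `mean_count_a`,
#'   `mean_count_b`, `pct_diff_a_vs_b` (`NA` when `mean_count_b` is 0), and,
#'   with `results`, `frac_a_near_b_mean`, `frac_b_near_a_mean`,
#'   `frac_a_near_b_pooled`, `frac_b_near_a_pooled`.
#' @examples
#' summarize_samples(counts_a = 380, counts_b = 345)$pct_diff_a_vs_b  # ~10.1
#' @export
summarize_samples <- function(results = NULL, counts_a = NULL, counts_b = NULL,
                              label_a = "A", label_b = "B") {
  if (is.null(results) && (is.null(counts_a) || is.null(counts_b))) {
    stop("provide per-sample colocalization results and/or counts for both methods",
         call. = FALSE)
  }
  if (!is.null(results)) {
    stopifnot(all(vapply(results, inherits, logical(1L), "ColocalizationResult")))
    if (is.null(counts_a)) counts_a <- vapply(results, `[[`, numeric(1L), "n_a")
    if (is.null(counts_b)) counts_b <- vapply(results, `[[`, numeric(1L), "n_b")
    label_a <- results[[1L]]$label_a
    label_b <- results[[1L]]$label_b
  }
  mean_a <- mean(counts_a); mean_b <- mean(counts_b)
  out <- list(
    label_a = label_a, label_b = label_b,
    n_samples = max(length(counts_a), length(counts_b)),
    mean_count_a = mean_a, mean_count_b = mean_b,
    pct_diff_a_vs_b = if (mean_b > 0) 100 * (mean_a - mean_b) / mean_b else NA_real_
  )
  if (!is.null(results)) {
    fa <- vapply(results, `[[`, numeric(1L), "frac_a_near_b")
    fb <- vapply(results, `[[`, numeric(1L), "frac_b_near_a")
    naa <- vapply(results, `[[`, numeric(1L), "n_a")
    nbb <- vapply(results, `[[`, numeric(1L), "n_b")
    nab <- vapply(results, `[[`, numeric(1L), "n_a_near_b")
    nba <- vapply(results, `[[`, numeric(1L), "n_b_near_a")
    out$frac_a_near_b_mean <- mean(fa, na.rm = TRUE)
    out$frac_b_near_a_mean <- mean(fb, na.rm = TRUE)
    out$frac_a_near_b_pooled <- if (sum(naa) > 0) sum(nab) / sum(naa) else NA_real_
    out$frac_b_near_a_pooled <- if (sum(nbb) > 0) sum(nba) / sum(nbb) else NA_real_
  }
  out
}

# ---- internal: grid-hash nearest-neighbor-within-radius ---------------------

# For each row of A, TRUE iff some row of B is within r (strict or not).
# Uniform grid with cell size r: a neighbor within r lies in one of the 27
# cells around the query's cell.
near_any <- function(A, B, r, strict) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L) return(logical(0L))
  if (nB == 0L) return(rep(FALSE, nA))
  cellB <- floor(B / r)
  keyB <- paste(cellB[, 1L], cellB[, 2L], cellB[, 3L], sep = ",")
  buckets <- split(seq_len(nB), keyB)
  cellA <- floor(A / r)
  r2 <- r * r
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- logical(nA)
  for (i in seq_len(nA)) {
    keys <- paste(cellA[i, 1L] + off[, 1L], cellA[i, 2L] + off[, 2L],
                  cellA[i, 3L] + off[, 3L], sep = ",")
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- (B[cand, 1L] - A[i, 1L])^2 + (B[cand, 2L] - A[i, 2L])^2 +
      (B[cand, 3L] - A[i, 3L])^2
    out[i] <- if (strict) any(d2 < r2) else any(d2 <= r2)
  }
  out
}
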