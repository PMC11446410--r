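# Configuration loading: defaults <- config file (YAML or JSON) <- CLI
# overrides, with unknown keys rejected (never silently ignored).

# Flat key namespace; each key maps into the config object it parametrizes.
.config_keys <- c(
  # design geometry / selection
  "arm_len", "gap_len", "min_inter_probe_gap", "target_pairs",
  "min_pairs_warn", "selection_mode",
  # thermodynamics
  "na_molar", "formamide_pct", "oligo_conc_molar",
  "tm_min_c", "tm_max_c", "gc_min", "gc_max", "max_run",
  # off-target screen
  "seed_k", "max_contig_match", "exclude_ids", "backend", "blast_evalue",
  # colocalization
  "radius_nm", "strict_less"
)

#' Resolve a design/colocalization configuration
#'
#' Precedence: package defaults, then the config file, then explicit
#' overrides (CLI flags). Keys live in one flat namespace covering design
#' geometry, thermodynamic windows, the off-target screen, and the
#' colocalization radius. Unknown keys raise an error naming the key and
#' suggesting the closest known one.
#'
#' @param path Optional YAML or JSON config file.
#' @param overrides Named list of values taking precedence over the file
#'   (CLI flags).
#' @return List with `design` (a [design_config()], embedding the resolved
#'   [thermo_config()] and [offtarget_config()]), `radius_nm`,
#'   `strict_less`, and `resolved` (the flat key-value list, echoed into
#'   run manifests).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)          # YAML superset: also parses JSON
    if (is.null(vals)) vals <- list()
    check_keys(names(vals), paste0("config file '", path, "'"))
  }
  check_keys(names(overrides), "overrides")
  vals[names(overrides)] <- overrides

  pick <- function(keys) vals[intersect(keys, names(vals))]
  thermo <- do.call(thermo_config, pick(c(
    "na_molar", "formamide_pct", "oligo_conc_molar",
    "tm_min_c", "tm_max_c", "gc_min", "gc_max", "max_run")))
  offt <- do.call(offtarget_config, pick(c(
    "seed_k", "max_contig_match", "exclude_ids", "backend", "blast_evalue")))
  design_args <- pick(c("arm_len", "gap_len", "min_inter_probe_gap",
                        "target_pairs", "min_pairs_warn", "selection_mode"))
  design_args$thermo <- thermo
  design_args$offtarget <- offt
  dcfg <- do.call(design_config, design_args)

  radius <- vals[["radius_nm"]] %||% 750
  strict <- vals[["strict_less"]] %||% TRUE
  resolved <- c(
    dcfg[c("arm_len", "gap_len", "window_len", "min_inter_probe_gap",
           "target_pairs", "min_pairs_warn", "selection_mode")],
    unclass(thermo), unclass(offt),
    list(radius_nm = radius, strict_less = strict)
  )
  list(design = dcfg, radius_nm = radius, strict_less = strict,
       resolved = resolved)
}

check_keys <- function(keys, where) {
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown)) {
    key <- unknown[1L]
    sugg <- agrep(key, .config_keys, max.distance = 0.3, value = TRUE)
    hint <- if (length(sugg)) paste0("; did you mean '", sugg[1L], "'?") else ""
    stop(sprintf("unknown configuration key '%s' in %s%s", key, where, hint),
         call. = FALSE)
  }
  invisible(keys)
}
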