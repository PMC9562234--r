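## Run configuration: one validated list holding the tunable analysis
## settings, optionally loaded from YAML (used by the command-line wrapper).

#' Analysis configuration
#'
#' Collects the tunable settings of the pipeline with defaults reproducing
#' the published cascade: 50 bp call extension, stringent filters (5 reads,
#' FL 8, GQ 10--200, clip 2/2), relaxed filters (1 read, FL 5), cnv/sv
#' deletion thresholds, a 0.4 contrast threshold for the region screen,
#' fixed-locus scope `species_plus_outgroups` and 10\% terminal windows.
#'
#' @param extension_bp one-sided call extension in bp.
#' @param contrast_min_delta region-screen |delta| threshold, in [0, 1].
#' @param fixed_locus_scope `"species_plus_outgroups"`, `"species_only"` or
#'   `"all_groups"`.
#' @param terminal_fraction end-window width fraction, in (0, 0.5).
#' @param stringent,relaxed named lists of insertion-filter thresholds.
#' @param rng_seed integer seed.
#' @return validated list of class `ErvConfig`.
#' @export
ervConfig <- function(extension_bp = 50L,
                      contrast_min_delta = 0.4,
                      fixed_locus_scope = c("species_plus_outgroups",
                                            "species_only", "all_groups"),
                      terminal_fraction = 0.1,
                      stringent = list(min_reads = 5L, min_fl = 8L,
                                       min_gq = 10, max_gq = 200,
                                       min_clip3 = 2L, min_clip5 = 2L),
                      relaxed = list(min_reads = 1L, min_fl = 5L),
                      rng_seed = 1L) {
    fixed_locus_scope <- match.arg(fixed_locus_scope)
    if (extension_bp < 0)
        stop("extension_bp must be non-negative")
    if (contrast_min_delta < 0 || contrast_min_delta > 1)
        stop("contrast_min_delta must lie in [0, 1]")
    if (terminal_fraction <= 0 || terminal_fraction >= 0.5)
        stop("terminal_fraction must lie in (0, 0.5)")
    structure(list(extension_bp = as.integer(extension_bp),
                   contrast_min_delta = contrast_min_delta,
                   fixed_locus_scope = fixed_locus_scope,
                   terminal_fraction = terminal_fraction,
                   stringent = stringent,
                   relaxed = relaxed,
                   rng_seed = as.integer(rng_seed)),
              class = "ErvConfig")
}

#' Load an analysis configuration from YAML
#'
#' Keys absent from the file keep their [ervConfig()] defaults.
#'
#' @param path YAML file path.
#' @return validated list of class `ErvConfig`.
#' @export
readErvConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configuration")
    vals <- yaml::read_yaml(path)
    known <- names(formals(ervConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    do.call(ervConfig, vals)
}
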